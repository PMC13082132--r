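RUN_CONFIG_SECTIONS <- c("schema_version", "physics", "simulate", "quantify",
                         "calibrate", "unmix", "structure", "kinetics")
RUN_CONFIG_SCHEMA <- 1L

#' Read and validate a run configuration
#'
#' Configurations are YAML or JSON with a mandatory `schema_version` and the
#' optional stage sections `physics`, `simulate`, `quantify`, `calibrate`,
#' `unmix`, `structure`, `kinetics`. Unknown top-level keys are rejected, and
#' every stochastic stage must carry an explicit `seed`.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated named list of class `run_config` with attribute
#'   `hash` (md5 of the canonical JSON serialization).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_invalid("config file not found: %s", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg a configuration list (for configs built in code).
#' @export
validate_run_config <- function(cfg) {
  if (!is.list(cfg)) stop_invalid("config must be a mapping")
  unknown <- setdiff(names(cfg), RUN_CONFIG_SECTIONS)
  if (length(unknown))
    stop_invalid("unknown config key(s): %s", paste(unknown, collapse = ", "))
  if (is.null(cfg$schema_version))
    stop_invalid("config is missing schema_version")
  if (as.integer(cfg$schema_version) != RUN_CONFIG_SCHEMA)
    stop_invalid("unsupported schema_version %s (expected %d)",
                 cfg$schema_version, RUN_CONFIG_SCHEMA)
  for (sec in c("simulate", "kinetics")) {
    if (!is.null(cfg[[sec]]) && is.null(cfg[[sec]]$seed))
      stop_invalid("section '%s' needs an explicit seed", sec)
  }
  structure(cfg, hash = config_hash(cfg), class = c("run_config", "list"))
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

pipeline_log <- function(stage, fmt, ..., verbose = TRUE) {
  if (verbose) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run one pipeline stage
#'
#' Executes a subcommand against a validated configuration, writing its
#' artifacts (TIFF stacks, CSV tables, JSON results) under `out_dir`
#' together with a machine-readable JSON report naming the config hash and
#' seeds. Identical configuration and seeds give identical outputs.
#'
#' Subcommands: `simulate` (hyperspectral scene -> stack + ground truth),
#' `quantify` (stack -> spot table + per-spot spectra), `calibrate`
#' (intensity table -> mixture fits + calibration JSON), `unmix` (stack +
#' library -> abundance maps), `structure` (spectrum -> amide-I
#' decomposition), `kinetics` (trace -> dwell table + rate constants).
#'
#' @param config a `run_config` (or path to one).
#' @param subcommand one of the stage names above.
#' @param out_dir output directory (created if needed).
#' @param verbose log stage progress to stderr.
#' @return the parsed report list, invisibly.
#' @export
run_pipeline <- function(config,
                         subcommand = c("simulate", "quantify", "calibrate",
                                        "unmix", "structure", "kinetics"),
                         out_dir = ".", verbose = TRUE) {
  subcommand <- match.arg(subcommand)
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) config <- validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- switch(subcommand,
    simulate = stage_simulate(config, out_dir, verbose),
    quantify = stage_quantify(config, out_dir, verbose),
    calibrate = stage_calibrate(config, out_dir, verbose),
    unmix = stage_unmix(config, out_dir, verbose),
    structure = stage_structure(config, out_dir, verbose),
    kinetics = stage_kinetics(config, out_dir, verbose))
  report <- list(stage = subcommand,
                 config_hash = attr(config, "hash"),
                 package_version = as.character(utils::packageVersion("srpscat")),
                 seeds = stage_seeds(config, subcommand),
                 outputs = outputs)
  report_path <- file.path(out_dir, paste0(subcommand, "_report.json"))
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  pipeline_log(subcommand, "report written to %s", report_path,
               verbose = verbose)
  invisible(report)
}

stage_seeds <- function(config, subcommand) {
  sec <- config[[subcommand]]
  if (is.null(sec)) list() else sec[grepl("seed", names(sec))]
}

default_species_library <- function() {
  list(polystyrene = species_polystyrene(),
       immunoglobulin = species_immunoglobulin(),
       protein = species_protein(),
       dna = species_dna())
}

stage_simulate <- function(config, out_dir, verbose) {
  sim <- config$simulate
  if (is.null(sim)) stop_invalid("config has no 'simulate' section")
  spots <- if (is.null(sim$spots)) {
    data.frame(x_nm = numeric(), y_nm = numeric(), species = character())
  } else as.data.frame(sim$spots)
  scene <- scene_spec(field_px = sim$field_px %||% 64,
                      pixel_size_nm = sim$pixel_size_nm %||% 100,
                      spots = spots,
                      psf_fwhm_nm = sim$psf_fwhm_nm %||% 230)
  noise <- noise_spec(background = sim$background %||% 0,
                      sd = sim$noise_sd %||% 0, seed = sim$seed)
  wn <- if (!is.null(sim$wavenumber)) as.numeric(sim$wavenumber) else
    seq(2800, 3100, by = 10)
  res <- simulate_hyperspectral_stack(scene, default_species_library(),
                                      noise, wn)
  stack_path <- file.path(out_dir, "stack.tif")
  truth_path <- file.path(out_dir, "truth.csv")
  write_stack(res$stack, stack_path)
  utils::write.csv(res$truth, truth_path, row.names = FALSE)
  pipeline_log("simulate", "%d spots, %d bands", nrow(res$truth), length(wn),
               verbose = verbose)
  list(stack = stack_path, sidecar = sidecar_of(stack_path), truth = truth_path)
}

stage_quantify <- function(config, out_dir, verbose) {
  q <- config$quantify
  if (is.null(q) || is.null(q$stack))
    stop_invalid("config 'quantify' section needs a 'stack' path")
  stack <- read_stack(q$stack)
  # detection band: maximum mean signal unless configured
  band <- q$detection_band_index %||%
    which.max(apply(stack$data, 3, mean))
  img <- stack$data[, , band]
  spots <- detect_spots(img, stack$pixel_size_nm,
                        psf_fwhm_nm = q$psf_fwhm_nm %||% 230,
                        min_snr = q$min_snr %||% 5)
  spots_path <- file.path(out_dir, "spots.csv")
  utils::write.csv(as.data.frame(spots), spots_path, row.names = FALSE)
  spectra_path <- NULL
  if (nrow(spots) && inherits(stack, "hyperspectral_stack")) {
    specs <- lapply(seq_len(nrow(spots)), function(i) {
      sp <- tryCatch(extract_spectrum(stack, spots[i, ]),
                     error = function(e) NULL)
      if (is.null(sp)) return(NULL)
      cbind(spot = i, as.data.frame(sp))
    })
    specs <- do.call(rbind, specs)
    spectra_path <- file.path(out_dir, "spectra.csv")
    utils::write.csv(specs, spectra_path, row.names = FALSE)
  }
  pipeline_log("quantify", "%d spots at band %d", nrow(spots), band,
               verbose = verbose)
  c(list(spots = spots_path),
    if (!is.null(spectra_path)) list(spectra = spectra_path))
}

stage_calibrate <- function(config, out_dir, verbose) {
  cal <- config$calibrate
  if (is.null(cal) || is.null(cal$intensities))
    stop_invalid("config 'calibrate' section needs an 'intensities' CSV path")
  tab <- utils::read.csv(cal$intensities)
  if (!all(c("mass_kda", "intensity") %in% names(tab)))
    stop_invalid("intensity table needs mass_kda and intensity columns")
  k <- cal$k %||% 1L
  seed <- cal$seed %||% 1L
  masses <- sort(unique(tab$mass_kda))
  means <- vapply(masses, function(m) {
    f <- fit_mixture(tab$intensity[tab$mass_kda == m], k, seed)
    f$means[which.max(f$weights)]
  }, 0)
  model <- fit_calibration(means, masses)
  cal_path <- file.path(out_dir, "calibration.json")
  jsonlite::write_json(list(slope = model$slope, intercept = model$intercept,
                            average_error_pct = model$average_error_pct,
                            mass_accuracy_kda = model$mass_accuracy_kda,
                            calibrants = model$calibrants),
                       cal_path, auto_unbox = TRUE, digits = NA)
  pipeline_log("calibrate", "slope %.4g, average error %.2f%%",
               model$slope, model$average_error_pct, verbose = verbose)
  list(calibration = cal_path)
}

stage_unmix <- function(config, out_dir, verbose) {
  u <- config$unmix
  if (is.null(u) || is.null(u$stack) || is.null(u$library))
    stop_invalid("config 'unmix' section needs 'stack' and 'library' paths")
  stack <- read_stack(u$stack)
  lib_tab <- utils::read.csv(u$library)
  refs <- setdiff(names(lib_tab), "wavenumber_cm1")
  lib <- reference_library(lib_tab$wavenumber_cm1,
                           as.matrix(lib_tab[refs]), refs)
  am <- lasso_unmix(stack, lib, lambda = u$lambda %||% 0)
  ab_path <- file.path(out_dir, "abundance.tif")
  write_tiff_float(am$abundance, ab_path)
  axis <- data.frame(page_index = seq_along(refs) - 1L, reference = refs)
  utils::write.csv(axis, sidecar_of(ab_path), row.names = FALSE)
  summ <- data.frame(reference = refs,
                     total_abundance = apply(am$abundance, 3, sum))
  summ_path <- file.path(out_dir, "abundance_summary.csv")
  utils::write.csv(summ, summ_path, row.names = FALSE)
  pipeline_log("unmix", "%d references, lambda %g", length(refs),
               u$lambda %||% 0, verbose = verbose)
  list(abundance = ab_path, summary = summ_path)
}

stage_structure <- function(config, out_dir, verbose) {
  s <- config$structure
  if (is.null(s) || is.null(s$spectrum))
    stop_invalid("config 'structure' section needs a 'spectrum' CSV path")
  tab <- utils::read.csv(s$spectrum)
  fit <- deconvolve_amide(tab$wavenumber_cm1, tab$intensity)
  out_path <- file.path(out_dir, "structure.json")
  jsonlite::write_json(list(fractions = as.list(fit$fractions),
                            converged = fit$converged, bands = fit$bands),
                       out_path, auto_unbox = TRUE, digits = NA)
  pipeline_log("structure", "alpha %.1f%%, beta %.1f%%, extended %.1f%%",
               fit$fractions["alpha"], fit$fractions["beta"],
               fit$fractions["extended"], verbose = verbose)
  list(structure = out_path)
}

stage_kinetics <- function(config, out_dir, verbose) {
  kin <- config$kinetics
  if (is.null(kin) || is.null(kin$trace))
    stop_invalid("config 'kinetics' section needs a 'trace' CSV path")
  if (is.null(kin$concentration))
    stop_invalid("config 'kinetics' section needs the ligand concentration (M)")
  tab <- utils::read.csv(kin$trace)
  trace <- intensity_trace(tab$time_s, tab$intensity)
  states <- idealize(trace, threshold = kin$threshold,
                     hysteresis = kin$hysteresis %||% 0,
                     seed = kin$seed)
  dw <- dwells(states)
  rates <- fit_rates(dw, kin$concentration,
                     n_boot = kin$n_boot %||% 1000L, seed = kin$seed)
  dwell_path <- file.path(out_dir, "dwells.csv")
  utils::write.csv(as.data.frame(dw), dwell_path, row.names = FALSE)
  rates_path <- file.path(out_dir, "kinetics.json")
  jsonlite::write_json(list(k_on = rates$k_on, k_off = rates$k_off,
                            K_D = rates$K_D,
                            concentration = rates$concentration,
                            n_bound = rates$n_bound,
                            n_unbound = rates$n_unbound,
                            ci = as.data.frame(rates$ci)),
                       rates_path, auto_unbox = TRUE, digits = NA)
  pipeline_log("kinetics", "k_on %.3g M^-1 s^-1, k_off %.3g s^-1",
               rates$k_on, rates$k_off, verbose = verbose)
  list(dwells = dwell_path, kinetics = rates_path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
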