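#' @keywords internal
"_PACKAGE"

# Full width at half maximum of a Gaussian <-> standard deviation
FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))

fwhm_to_sigma <- function(fwhm) fwhm * FWHM_TO_SIGMA

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    stop_invalid("'%s' must be supplied", name)
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid("'%s' must be a single finite number", name)
  if (strict_lower && x <= lower)
    stop_invalid("'%s' must be > %g (got %g)", name, lower, x)
  if (!strict_lower && x < lower)
    stop_invalid("'%s' must be >= %g (got %g)", name, lower, x)
  if (x > upper)
    stop_invalid("'%s' must be <= %g (got %g)", name, upper, x)
  invisible(x)
}

# Unit-height pseudo-Voigt line: eta * Lorentzian + (1 - eta) * Gaussian,
# both with the same FWHM.
pseudo_voigt <- function(x, center, fwhm, eta = 0.5) {
  g <- exp(-4 * log(2) * ((x - center) / fwhm)^2)
  l <- 1 / (1 + (2 * (x - center) / fwhm)^2)
  eta * l + (1 - eta) * g
}

# Area under a unit-height pseudo-Voigt with FWHM w.
pseudo_voigt_area <- function(fwhm, eta = 0.5) {
  area_g <- fwhm * sqrt(pi / (4 * log(2)))
  area_l <- fwhm * pi / 2
  eta * area_l + (1 - eta) * area_g
}

# Nearest index of `value` on `grid`; errors if farther than half a grid step.
grid_index <- function(grid, value, what = "wavenumber") {
  i <- which.min(abs(grid - value))
  step <- if (length(grid) > 1L) stats::median(diff(grid)) else Inf
  if (abs(grid[i] - value) > step / 2 + 1e-9)
    stop_invalid("%s %g is not on the grid (nearest %g)", what, value, grid[i])
  i
}

# Robust noise scale (MAD-based standard deviation).
robust_sd <- function(x) stats::mad(x, constant = 1.4826)
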