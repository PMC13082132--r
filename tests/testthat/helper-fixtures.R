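# Shared fixture builders (all synthetic, generated at test time).

ps_scene <- function(x_nm, y_nm, field_px = 32, pixel_size_nm = 100) {
  scene_spec(field_px, pixel_size_nm,
             data.frame(x_nm = x_nm, y_nm = y_nm, species = "polystyrene"))
}

# single polystyrene spot image at 3055 cm^-1 with given noise sd and seed
ps_image <- function(noise_sd = 0, seed = 1, x_nm = 1500, y_nm = 1600,
                     field_px = 32) {
  res <- simulate_hyperspectral_stack(
    ps_scene(x_nm, y_nm, field_px),
    species_polystyrene(contrast_per_kda = 1, mass_kda = 100),
    noise_spec(sd = noise_sd, seed = seed), 3055)
  res$stack$data[, , 1]
}

ch_library <- function(wn = seq(2800, 3100, 2)) {
  reference_library(wn, list(
    polystyrene = species_spectrum(species_polystyrene(), wn),
    immunoglobulin = species_spectrum(species_immunoglobulin(), wn),
    protein = species_spectrum(species_protein(), wn)))
}

# brute-force single change-point fit: independent re-implementation used
# as the oracle for detect_step
brute_force_step <- function(y, min_segment = 2L) {
  n <- length(y)
  best_k <- NA_integer_; best_sse <- Inf
  for (k in min_segment:(n - min_segment)) {
    m1 <- mean(y[1:k]); m2 <- mean(y[(k + 1):n])
    sse <- sum((y[1:k] - m1)^2) + sum((y[(k + 1):n] - m2)^2)
    if (sse < best_sse) { best_sse <- sse; best_k <- k }
  }
  list(split = best_k, sse = best_sse)
}
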