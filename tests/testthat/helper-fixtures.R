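# small in-code fixtures shared across tests

coarse_grid <- lattice_preset("coarse")

uniform_curvature <- function(r = 7.5, preset = "coarse") {
  g <- lattice_preset(preset)
  curvature_map(matrix(r, g$side, g$side), g$spacing)
}

uniform_power <- function(d = 45, preset = "coarse") {
  g <- lattice_preset(preset)
  power_map(matrix(d, g$side, g$side), g$spacing)
}

# random smooth valid curvature map (radii around 7.8 mm)
random_curvature <- function(seed, preset = "coarse") {
  g <- lattice_preset(preset)
  withr::with_seed(seed, {
    vals <- matrix(7.8 + rnorm(g$side^2, 0, 0.05), g$side, g$side)
    curvature_map(vals, g$spacing)
  })
}

axis_diff <- function(a, b) {
  d <- abs(canonical_axis_t(a) - canonical_axis_t(b))
  pmin(d, 180 - d)
}

canonical_axis_t <- function(a) {
  a <- a %% 180
  a[a < 0] <- a[a < 0] + 180
  a
}

noise_free_config <- function(n_eyes, preset = "coarse") {
  synth_config(n_eyes = n_eyes, preset = preset, noise_sd = 0,
               perturb_amplitude = 0)
}

deterministic_effect_model <- function(...) {
  flak_effect_model(zone_attenuation = c(center = 1, edge = 1),
                    axis_jitter_sd = 0, magnitude_noise_sd = 0, ...)
}
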