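#' Synthetic-population configuration
#'
#' Parameters of the synthetic cornea generator. Defaults emulate the adult
#' cataract-surgery population with pre-existing regular astigmatism: mean
#' keratometry about 44 D, astigmatism magnitude 1.26 +/- 0.53 D in the range
#' 0.25-2.7 D, a with-the-rule / against-the-rule axis mixture, and ages
#' 25-83 years.
#'
#' @param n_eyes Number of eyes.
#' @param k_mean,k_sd Population mean and SD of the spherical-equivalent
#'   keratometry, D.
#' @param astig_mean,astig_sd Mean and SD of the astigmatism magnitude, D
#'   (sampled as a normal truncated to `astig_mag_range`).
#' @param astig_mag_range Supported magnitude range, D.
#' @param axis_weights Named weights `c(wtr =, atr =, oblique =)` of the
#'   steep-axis mixture: with-the-rule (near 90), against-the-rule (near
#'   0/180), oblique (uniform).
#' @param axis_spread_sd Angular SD (degrees) of the WTR/ATR components.
#' @param age_range Age range, years.
#' @param age_mean,age_sd Mean and SD of age (normal truncated to
#'   `age_range`).
#' @param noise_sd Per-point white measurement noise, D.
#' @param perturb_amplitude Amplitude of the smooth low-order non-toric
#'   irregularity, D.
#' @param preset Lattice preset name ([lattice_preset()]).
#' @param power_window Physiologic plausibility window, D; configurations
#'   that can generate powers outside it are rejected.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_eyes = 451L,
                         k_mean = 44, k_sd = 1.5,
                         astig_mean = 1.26, astig_sd = 0.53,
                         astig_mag_range = c(0.25, 2.7),
                         axis_weights = c(wtr = 0.5, atr = 0.35, oblique = 0.15),
                         axis_spread_sd = 12,
                         age_range = c(25, 83), age_mean = 60, age_sd = 13,
                         noise_sd = 0.1, perturb_amplitude = 0.15,
                         preset = "hires",
                         power_window = c(30, 60)) {
  if (n_eyes < 1L) abort("n_eyes must be >= 1")
  if (noise_sd < 0 || perturb_amplitude < 0) abort("noise terms must be >= 0")
  if (astig_mag_range[2L] < astig_mag_range[1L] || age_range[2L] <= age_range[1L]) {
    abort("empty parameter range")
  }
  # conservative worst case: 4-sigma sphere + half the largest cylinder +
  # perturbation + 5-sigma noise must stay physiologic
  worst <- 4 * k_sd + astig_mag_range[2L] / 2 + 2 * perturb_amplitude + 5 * noise_sd
  if (k_mean - worst < power_window[1L] || k_mean + worst > power_window[2L]) {
    abort("configuration can produce non-physiologic powers outside the plausibility window")
  }
  structure(
    list(n_eyes = as.integer(n_eyes), k_mean = k_mean, k_sd = k_sd,
         astig_mean = astig_mean, astig_sd = astig_sd,
         astig_mag_range = astig_mag_range, axis_weights = axis_weights,
         axis_spread_sd = axis_spread_sd, age_range = age_range,
         age_mean = age_mean, age_sd = age_sd, noise_sd = noise_sd,
         perturb_amplitude = perturb_amplitude, preset = preset,
         power_window = power_window),
    class = "synth_config"
  )
}

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(min(hi, max(lo, mean)), n))
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x
}

sample_axis <- function(config) {
  w <- config$axis_weights / sum(config$axis_weights)
  comp <- sample(names(w), 1L, prob = w)
  ax <- switch(comp,
    wtr = stats::rnorm(1, 90, config$axis_spread_sd),
    atr = stats::rnorm(1, 0, config$axis_spread_sd),
    oblique = stats::runif(1, 0, 180)
  )
  canonical_axis(ax)
}

#' Sample one synthetic pre-operative eye
#'
#' The power surface is a spherical equivalent plus the regular-astigmatism
#' toric term `(M / 2) cos(2 (theta - axis))`, a smooth low-order
#' perturbation (tilt and defocus-like terms with random coefficients), and
#' white measurement noise, converted to radii of curvature. The toric term's
#' `(M, axis)` is returned as the ground-truth astigmatism vector.
#'
#' @param config A [synth_config()].
#' @param seed Integer seed; the draw is fully reproducible.
#' @return A list: `preop` ([curvature_map()]), `true_astigmatism` (one-row
#'   tibble `magnitude`/`axis`), `age` (years), `k_se` (spherical equivalent,
#'   D).
#' @export
#' @examples
#' eye <- sample_preop(synth_config(noise_sd = 0, perturb_amplitude = 0), seed = 1)
#' eye$true_astigmatism
sample_preop <- function(config, seed) {
  stopifnot(inherits(config, "synth_config"))
  with_local_seed(seed, {
    g <- lattice_preset(config$preset)
    co <- lattice_coords(g$side, g$spacing)
    s <- rnorm_trunc(1, config$k_mean, config$k_sd,
                     config$k_mean - 4 * config$k_sd, config$k_mean + 4 * config$k_sd)
    m <- rnorm_trunc(1, config$astig_mean, config$astig_sd,
                     config$astig_mag_range[1L], config$astig_mag_range[2L])
    axis <- sample_axis(config)
    age <- rnorm_trunc(1, config$age_mean, config$age_sd,
                       config$age_range[1L], config$age_range[2L])
    vals <- s + (m / 2) * cos(2 * (co$theta - axis) * pi / 180)
    if (config$perturb_amplitude > 0) {
      z <- stats::rnorm(3)
      rr <- co$r / g$radius
      vals <- vals + config$perturb_amplitude *
        (z[1L] * rr * cos(co$theta * pi / 180) +
         z[2L] * rr * sin(co$theta * pi / 180) +
         z[3L] * (rr^2 - 0.5))
    }
    if (config$noise_sd > 0) {
      vals <- vals + matrix(stats::rnorm(length(vals), 0, config$noise_sd),
                            nrow(vals), ncol(vals))
    }
    pm <- power_map(vals, g$spacing)
    list(
      preop = power_to_curvature(pm),
      true_astigmatism = tibble(magnitude = m, axis = axis),
      age = age, k_se = s
    )
  })
}

#' Surgical response model for arcuate keratotomy
#'
#' A minimal analytic stand-in for the corneal response to arc incisions,
#' chosen so the true induced astigmatism is known in closed form: the
#' incised meridian flattens and the orthogonal meridian steepens equally
#' (the coupling dipole), scaled by arc length, age and a radial profile.
#' The modelled effect magnitude is
#' `effect_per_degree * total_arc_degrees * (1 + age_coefficient * (age - reference_age)) * paired_gain`
#' (the `paired_gain` factor applies to paired plans only), with optional
#' magnitude noise and axis jitter. Defaults are calibrated so the simulated
#' induced astigmatism averages about 1 D over the supported arc-length
#' range — the scale reported for this procedure — and are stand-ins, not
#' clinical claims.
#'
#' @param effect_per_degree Diopters of induced astigmatism per degree of
#'   total arc at the reference age (default 0.016 D/degree).
#' @param age_coefficient Relative effect change per year of age (default
#'   0.01: about +1% per year, the classic arcuate-keratotomy rule of thumb).
#' @param reference_age Years (default 60).
#' @param paired_gain Multiplier applied to paired plans at equal total
#'   degrees (default 1: the effect is linear in total arc).
#' @param zone_attenuation Named pair `c(center =, edge =)`: the radial
#'   profile `s(r)` interpolates quadratically from `center` at the apex to
#'   `edge` at the disk edge. Peripheral incisions act more strongly
#'   peripherally, so the default rises outward. `c(1, 1)` disables the
#'   profile.
#' @param axis_jitter_sd Degrees of jitter between the planned and realised
#'   incision axis (default 5).
#' @param magnitude_noise_sd Diopters of noise on the realised effect
#'   magnitude (default 0.15).
#' @return A list of class `flak_effect_model`.
#' @export
flak_effect_model <- function(effect_per_degree = 0.016,
                              age_coefficient = 0.01,
                              reference_age = 60,
                              paired_gain = 1,
                              zone_attenuation = c(center = 0.9, edge = 1.15),
                              axis_jitter_sd = 5,
                              magnitude_noise_sd = 0.15) {
  if (effect_per_degree <= 0) abort("effect_per_degree must be positive")
  if (any(zone_attenuation <= 0)) abort("zone_attenuation entries must be positive")
  structure(
    list(effect_per_degree = effect_per_degree,
         age_coefficient = age_coefficient,
         reference_age = reference_age,
         paired_gain = paired_gain,
         zone_attenuation = zone_attenuation,
         axis_jitter_sd = axis_jitter_sd,
         magnitude_noise_sd = magnitude_noise_sd),
    class = "flak_effect_model"
  )
}

radial_profile <- function(model, r, r_max = 3.5) {
  za <- model$zone_attenuation
  za[["center"]] + (za[["edge"]] - za[["center"]]) * (r / r_max)^2
}

flak_effect_magnitude <- function(model, plan, age) {
  gain <- if (plan$paired) model$paired_gain else 1
  model$effect_per_degree * total_arc_degrees(plan) *
    (1 + model$age_coefficient * (age - model$reference_age)) * gain
}

#' Simulate arcuate keratotomy on a pre-operative map
#'
#' Subtracts the coupling dipole
#' `s(r) * (M_SIA / 2) * cos(2 (theta - axis))` from the pre-operative power
#' surface, where `M_SIA` and the realised axis come from the
#' [flak_effect_model()]. The realised `(M_SIA, axis)` is returned as the
#' true induced-astigmatism vector. An all-zero-arc plan is a sham procedure
#' and returns the pre-operative map unchanged.
#'
#' @param preop A [curvature_map()].
#' @param plan A [flak_plan()]; per-arc lengths must lie in the supported
#'   25-65 degree range (or be 0 for a sham arc).
#' @param age Age in years.
#' @param model A [flak_effect_model()].
#' @param seed Integer seed for the noise terms.
#' @return A list: `postop` ([curvature_map()]), `true_sia` (one-row tibble
#'   `magnitude`/`axis`).
#' @export
simulate_flak <- function(preop, plan, age, model = flak_effect_model(), seed = 1L) {
  stopifnot(inherits(preop, "curvature_map"), inherits(plan, "flak_plan"),
            inherits(model, "flak_effect_model"))
  if (total_arc_degrees(plan) == 0) {
    return(list(postop = preop,
                true_sia = tibble(magnitude = 0, axis = 0)))
  }
  with_local_seed(seed, {
    m_sia <- flak_effect_magnitude(model, plan, age)
    if (model$magnitude_noise_sd > 0) {
      m_sia <- m_sia + stats::rnorm(1, 0, model$magnitude_noise_sd)
    }
    m_sia <- max(0, m_sia)
    axis <- plan$arcs$axis[1L]
    if (model$axis_jitter_sd > 0) {
      axis <- axis + stats::rnorm(1, 0, model$axis_jitter_sd)
    }
    axis <- canonical_axis(axis)
    pm <- curvature_to_power(preop)
    co <- lattice_coords(nrow(pm$values), pm$spacing)
    deform <- radial_profile(model, co$r) * (m_sia / 2) *
      cos(2 * (co$theta - axis) * pi / 180)
    post_vals <- pm$values - deform
    post <- power_map(post_vals, pm$spacing, mask = pm$mask)
    list(postop = power_to_curvature(post),
         true_sia = tibble(magnitude = m_sia, axis = axis))
  })
}

plan_for_eye <- function(policy, config, model, true_astig, age) {
  target_axis <- true_astig$axis
  if (policy == "uniform") {
    paired <- stats::runif(1) < 0.5
    len <- if (paired) stats::runif(1, 25, 65) else stats::runif(1, 30, 65)
    axis <- canonical_axis(target_axis + stats::rnorm(1, 0, 3))
    return(flak_plan(len, axis = axis, paired = paired))
  }
  # nomogram-like: choose total arc so the modelled effect matches the
  # pre-operative magnitude, paired above 0.9 D, clipped to the supported
  # per-arc range
  agef <- 1 + model$age_coefficient * (age - model$reference_age)
  total <- true_astig$magnitude / (model$effect_per_degree * max(agef, 0.25))
  paired <- true_astig$magnitude > 0.9
  if (paired) total <- total / model$paired_gain
  per_arc <- if (paired) total / 2 else total
  per_arc <- min(65, max(25, per_arc))
  axis <- canonical_axis(target_axis + stats::rnorm(1, 0, 3))
  flak_plan(per_arc, axis = axis, paired = paired)
}

#' Generate a paired pre/post-operative dataset
#'
#' Samples `n_eyes` pre-operative corneas, plans an arc incision for each
#' (by default a nomogram-like rule titrating total arc to the pre-operative
#' astigmatism; a `"uniform"` policy drawing arc lengths uniformly over the
#' supported range is also available), simulates the surgery, and splits the
#' records into training and test sets.
#'
#' @param config A [synth_config()].
#' @param model A [flak_effect_model()].
#' @param split Length-2 fractions `(train, test)` summing to 1.
#' @param seed Integer master seed; the whole dataset is reproducible from
#'   `(config, model, split, seed)`.
#' @param plan_policy `"nomogram"` or `"uniform"`.
#' @return A tibble with one row per eye: `eye_id`, `role` (train/test),
#'   `age`, list-columns `preop`, `postop` ([curvature_map()]s) and `plan`
#'   ([flak_plan()]s), and the ground truth `preop_magnitude`, `preop_axis`,
#'   `sia_magnitude`, `sia_axis`. The generating configuration is attached as
#'   attribute `manifest`.
#' @export
#' @examples
#' ds <- generate_dataset(synth_config(n_eyes = 4, preset = "coarse"), seed = 1)
#' table(ds$role)
generate_dataset <- function(config, model = flak_effect_model(),
                             split = c(train = 386 / 451, test = 65 / 451),
                             seed = 1L, plan_policy = c("nomogram", "uniform")) {
  stopifnot(inherits(config, "synth_config"))
  plan_policy <- match.arg(plan_policy)
  if (abs(sum(split) - 1) > 1e-9) abort("split fractions must sum to 1")
  n <- config$n_eyes
  n_train <- as.integer(round(split[1L] * n))
  n_test <- n - n_train
  if (n_train < 1L || n_test < 1L) abort("n_eyes too small for the requested split")
  with_local_seed(seed, {
    eye_seeds <- sample.int(.Machine$integer.max - 1L, 2L * n)
    roles <- rep("train", n)
    roles[sample.int(n, n_test)] <- "test"
    rows <- lapply(seq_len(n), function(i) {
      eye <- sample_preop(config, seed = eye_seeds[2L * i - 1L])
      plan <- plan_for_eye(plan_policy, config, model, eye$true_astigmatism, eye$age)
      surg <- simulate_flak(eye$preop, plan, eye$age, model,
                            seed = eye_seeds[2L * i])
      tibble(
        eye_id = sprintf("eye%04d", i), role = roles[i], age = eye$age,
        preop = list(eye$preop), postop = list(surg$postop), plan = list(plan),
        preop_magnitude = eye$true_astigmatism$magnitude,
        preop_axis = eye$true_astigmatism$axis,
        sia_magnitude = surg$true_sia$magnitude,
        sia_axis = surg$true_sia$axis
      )
    })
    out <- dplyr::bind_rows(rows)
    attr(out, "manifest") <- dataset_manifest(config, model, split, seed,
                                              plan_policy, n_train, n_test)
    out
  })
}

dataset_manifest <- function(config, model, split, seed, plan_policy,
                             n_train, n_test) {
  list(
    seed = seed, plan_policy = plan_policy,
    split = as.list(stats::setNames(split, c("train", "test"))),
    n_train = n_train, n_test = n_test,
    config = unclass(config), effect_model = unclass(model)
  )
}
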