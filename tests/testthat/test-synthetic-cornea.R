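test_that("sampled eyes are reproducible and carry recoverable ground truth", {
  cfg <- noise_free_config(1)
  e1 <- sample_preop(cfg, seed = 9)
  e2 <- sample_preop(cfg, seed = 9)
  expect_identical(e1$preop$values, e2$preop$values)
  expect_identical(e1$true_astigmatism, e2$true_astigmatism)

  # pure toric: zone keratometry recovers the injected magnitude
  cfg1 <- synth_config(n_eyes = 1, astig_mean = 1, astig_sd = 0,
                       astig_mag_range = c(1, 1), noise_sd = 0,
                       perturb_amplitude = 0, preset = "coarse")
  eye <- sample_preop(cfg1, seed = 3)
  zk <- zone_keratometry(curvature_to_power(eye$preop), 3)
  expect_lt(abs(zk$astig_magnitude - 1), 0.02)
  expect_lt(axis_diff(zk$steep_axis, eye$true_astigmatism$axis), 1)
})

test_that("population moments match the configured targets", {
  cfg <- synth_config(n_eyes = 400, preset = "coarse")
  withr::with_seed(77, seeds <- sample.int(1e6, 400))
  draws <- vapply(seeds, function(s) {
    e <- sample_preop(cfg, seed = s)
    c(e$true_astigmatism$magnitude, e$age)
  }, numeric(2))
  # truncation shifts the mean slightly; 3 SE of the configured (untruncated)
  # moments is the agreed envelope
  se_m <- cfg$astig_sd / sqrt(400)
  expect_lt(abs(mean(draws[1, ]) - cfg$astig_mean), 3 * se_m + 0.02)
  expect_true(all(draws[1, ] >= cfg$astig_mag_range[1] &
                  draws[1, ] <= cfg$astig_mag_range[2]))
  expect_true(all(draws[2, ] >= cfg$age_range[1] &
                  draws[2, ] <= cfg$age_range[2]))
})

test_that("non-physiologic configurations are rejected", {
  expect_error(synth_config(k_mean = 55), "non-physiologic")
  expect_error(synth_config(noise_sd = -1), ">= 0")
  expect_error(synth_config(n_eyes = 0), ">= 1")
})

test_that("a sham plan leaves the cornea untouched and effects add linearly", {
  eye <- sample_preop(noise_free_config(1), seed = 12)
  m <- deterministic_effect_model()
  sham <- simulate_flak(eye$preop, flak_plan(0, axis = 10), eye$age, m, seed = 1)
  expect_identical(sham$postop$values, eye$preop$values)
  expect_equal(sham$true_sia$magnitude, 0)

  # paired vs single at equal total degrees and unit paired gain
  ax <- eye$true_astigmatism$axis
  single_60 <- simulate_flak(eye$preop, flak_plan(60, axis = ax), eye$age, m, seed = 1)
  paired_30 <- simulate_flak(eye$preop, flak_plan(30, axis = ax, paired = TRUE),
                             eye$age, m, seed = 1)
  expect_equal(single_60$true_sia$magnitude, paired_30$true_sia$magnitude,
               tolerance = 1e-12)
  expect_equal(single_60$postop$values, paired_30$postop$values, tolerance = 1e-12)
})

test_that("noise-free surgery closes against Alpins analysis of the maps", {
  eye <- sample_preop(noise_free_config(1), seed = 42)
  pre_vec <- astigmatism_vector(zone_keratometry(curvature_to_power(eye$preop), 3))
  m <- deterministic_effect_model()
  for (arc in c(25, 45, 65)) {
    plan <- flak_plan(arc, axis = eye$true_astigmatism$axis, paired = TRUE)
    s <- simulate_flak(eye$preop, plan, eye$age, m, seed = 1)
    post_vec <- astigmatism_vector(zone_keratometry(curvature_to_power(s$postop), 3))
    oc <- compute_outcomes(pre_vec, post_vec)
    expect_lt(abs(oc$sia_magnitude - s$true_sia$magnitude), 0.03)
    expect_lt(axis_diff(oc$sia_axis, s$true_sia$axis), 1)
  }
})

test_that("age increases the modelled effect through the age coefficient", {
  eye <- sample_preop(noise_free_config(1), seed = 13)
  m <- deterministic_effect_model()
  plan <- flak_plan(40, axis = 20)
  young <- simulate_flak(eye$preop, plan, 40, m, seed = 1)$true_sia$magnitude
  old <- simulate_flak(eye$preop, plan, 80, m, seed = 1)$true_sia$magnitude
  expect_equal(old / young, (1 + 0.01 * 20) / (1 - 0.01 * 20), tolerance = 1e-9)
})

test_that("the deformation is mean-free over the disk", {
  eye <- sample_preop(noise_free_config(1), seed = 14)
  m <- deterministic_effect_model()
  s <- simulate_flak(eye$preop, flak_plan(60, axis = 73), eye$age, m, seed = 1)
  pre <- curvature_to_power(eye$preop)
  post <- curvature_to_power(s$postop)
  expect_lt(abs(mean(post$values[post$mask]) - mean(pre$values[pre$mask])), 0.01)
})

test_that("generate_dataset reproduces the requested split and is deterministic", {
  cfg <- synth_config(n_eyes = 30, preset = "coarse")
  ds1 <- generate_dataset(cfg, split = c(0.8, 0.2), seed = 5)
  ds2 <- generate_dataset(cfg, split = c(0.8, 0.2), seed = 5)
  expect_identical(ds1$preop[[7]]$values, ds2$preop[[7]]$values)
  expect_identical(attr(ds1, "manifest"), attr(ds2, "manifest"))
  expect_equal(sum(ds1$role == "train"), 24)
  expect_equal(sum(ds1$role == "test"), 6)
  # plans stay inside the supported arc range
  for (p in ds1$plan) {
    expect_true(all(p$arcs$arc_length >= 25 & p$arcs$arc_length <= 65))
  }
  expect_error(generate_dataset(cfg, split = c(0.5, 0.4), seed = 1), "sum to 1")
  expect_error(generate_dataset(synth_config(n_eyes = 2, preset = "coarse"),
                                split = c(0.99, 0.01), seed = 1),
               "too small")
})
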