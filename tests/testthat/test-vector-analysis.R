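# independent oracle: double-angle subtraction written directly in
# trigonometric form, kept separate from the package implementation
oracle_sia <- function(pre_mag, pre_ax, post_mag, post_ax) {
  x <- pre_mag * cos(2 * pre_ax * pi / 180) - post_mag * cos(2 * post_ax * pi / 180)
  y <- pre_mag * sin(2 * pre_ax * pi / 180) - post_mag * sin(2 * post_ax * pi / 180)
  mag <- sqrt(x^2 + y^2)
  ax <- (atan2(y, x) * 90 / pi) %% 180
  list(magnitude = mag, axis = ifelse(mag == 0, 0, ax))
}

test_that("double-angle transform matches the textbook points", {
  expect_equal(to_double_angle(tibble::tibble(magnitude = 1, axis = 0)),
               tibble::tibble(da_x = 1, da_y = 0))
  da <- to_double_angle(tibble::tibble(magnitude = 1, axis = 90))
  expect_equal(da$da_x, -1)
  expect_equal(da$da_y, 0, tolerance = 1e-12)
  da <- to_double_angle(tibble::tibble(magnitude = 2, axis = 45))
  expect_equal(da$da_x, 0, tolerance = 1e-12)
  expect_equal(da$da_y, 2)
})

test_that("full-correction and null-surgery limits give CI 1 and 0", {
  full <- compute_outcomes(tibble::tibble(magnitude = 1, axis = 90),
                           tibble::tibble(magnitude = 0, axis = 0))
  expect_equal(full$sia_magnitude, 1)
  expect_equal(full$sia_axis, 90)
  expect_equal(full$dv_magnitude, 0)
  expect_equal(full$ci, 1)

  none <- compute_outcomes(tibble::tibble(magnitude = 1, axis = 90),
                           tibble::tibble(magnitude = 1, axis = 90))
  expect_equal(none$sia_magnitude, 0)
  expect_equal(none$ci, 0)

  undef <- compute_outcomes(tibble::tibble(magnitude = 0, axis = 0),
                            tibble::tibble(magnitude = 0.5, axis = 20))
  expect_true(is.na(undef$ci))
})

test_that("SIA equals the trigonometric oracle and the Alpins identity holds", {
  withr::with_seed(11, {
    n <- 2000
    pre <- tibble::tibble(magnitude = runif(n, 0, 3), axis = runif(n, 0, 180))
    post <- tibble::tibble(magnitude = runif(n, 0, 3), axis = runif(n, 0, 180))
  })
  oc <- compute_outcomes(pre, post)
  ora <- oracle_sia(pre$magnitude, pre$axis, post$magnitude, post$axis)
  expect_lt(max(abs(oc$sia_magnitude - ora$magnitude)), 1e-9)
  expect_lt(max(axis_diff(oc$sia_axis, ora$axis)), 1e-9)
  # TIA = SIA + DV exactly in double-angle space
  tia_da <- to_double_angle(tibble::tibble(magnitude = oc$tia_magnitude, axis = oc$tia_axis))
  sia_da <- to_double_angle(tibble::tibble(magnitude = oc$sia_magnitude, axis = oc$sia_axis))
  dv_da <- to_double_angle(tibble::tibble(magnitude = oc$dv_magnitude, axis = oc$dv_axis))
  expect_lt(max(abs(tia_da$da_x - sia_da$da_x - dv_da$da_x)), 1e-9)
  expect_lt(max(abs(tia_da$da_y - sia_da$da_y - dv_da$da_y)), 1e-9)
  # CI > 1 exactly when |SIA| > |TIA|
  expect_identical(oc$ci > 1, oc$sia_magnitude > oc$tia_magnitude)
})

test_that("worked vector-pair example matches the oracle", {
  oc <- compute_outcomes(tibble::tibble(magnitude = 1.5, axis = 80),
                         tibble::tibble(magnitude = 0.6, axis = 130))
  ora <- oracle_sia(1.5, 80, 0.6, 130)
  expect_equal(oc$sia_magnitude, ora$magnitude, tolerance = 1e-12)
  expect_equal(oc$sia_axis, ora$axis, tolerance = 1e-12)
})

test_that("cohort summaries report arithmetic and geometric means", {
  one <- cohort_summary(tibble::tibble(ci = 1), "ci")
  expect_equal(one$mean, 1)
  expect_equal(one$sd, 0)
  expect_equal(one$geometric_mean, 1)

  two <- cohort_summary(tibble::tibble(ci = c(1, 4)), "ci")
  expect_equal(two$mean, 2.5)
  expect_equal(two$geometric_mean, 2)
  expect_gte(two$mean, two$geometric_mean)
  expect_true(two$min <= two$mean && two$mean <= two$max)

  # log-normal(0, 0.5): geometric mean estimates exp(0) = 1
  withr::with_seed(5, x <- rlnorm(1000, 0, 0.5))
  gm <- cohort_summary(tibble::tibble(ci = x), "ci")$geometric_mean
  se <- 0.5 / sqrt(1000)
  expect_lt(abs(log(gm)), 3 * se)
  expect_error(cohort_summary(tibble::tibble(ci = numeric(0)), "ci"), "no non-missing")
})

test_that("agreement report behaves under identity, shift and swap", {
  oc <- compute_outcomes(
    tibble::tibble(magnitude = c(1, 1.5, 2, 0.8), axis = c(10, 80, 120, 45)),
    tibble::tibble(magnitude = c(0.3, 0.5, 0.9, 0.2), axis = c(15, 70, 110, 50))
  )
  same <- compare_real_synthetic(oc, oc, "sia_magnitude")
  expect_equal(same$pearson_r, 1)
  expect_equal(same$mae, 0)
  expect_equal(same$p_value, 1)
  expect_equal(same$mae_vector, 0)

  shifted <- oc
  shifted$sia_magnitude <- oc$sia_magnitude + 0.1
  sh <- compare_real_synthetic(oc, shifted, "sia_magnitude")
  expect_equal(sh$pearson_r, 1)
  expect_equal(sh$mae, 0.1)

  a <- oc
  b <- shifted
  fwd <- compare_real_synthetic(a, b, "sia_magnitude")
  rev <- compare_real_synthetic(b, a, "sia_magnitude")
  expect_equal(fwd$pearson_r, rev$pearson_r)
  expect_equal(fwd$mae, rev$mae)

  expect_error(compare_real_synthetic(oc, oc[1:2, ], "sia_magnitude"), "equal length")
})

test_that("single-angle plot overlays the double-angle centroid", {
  oc <- tibble::tibble(dv_magnitude = c(1, 2, 1.5), dv_axis = c(30, 60, 100))
  p <- plot_single_angle(oc, "dv_magnitude")
  built <- ggplot2::ggplot_build(p)
  centroid_layer <- built$data[[2]]
  expected <- from_double_angle(tibble::tibble(
    da_x = mean(to_double_angle(tibble::tibble(magnitude = oc$dv_magnitude,
                                               axis = oc$dv_axis))$da_x),
    da_y = mean(to_double_angle(tibble::tibble(magnitude = oc$dv_magnitude,
                                               axis = oc$dv_axis))$da_y)
  ))
  expect_equal(centroid_layer$y, expected$magnitude, tolerance = 1e-9)
  expect_equal(centroid_layer$x, expected$axis, tolerance = 1e-9)
  # deterministic construction
  p2 <- plot_single_angle(oc, "dv_magnitude")
  expect_identical(ggplot2::ggplot_build(p2)$data, built$data)
})

test_that("sample correlation falls inside the Fisher-z interval for rho = 0.9", {
  # single draw sanity check of the machinery used by the calibration suite
  withr::with_seed(21, {
    n <- 65
    rho <- 0.9
    x <- rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  })
  oc_r <- tibble::tibble(sia_magnitude = 1.5 + 0.4 * x)
  oc_s <- tibble::tibble(sia_magnitude = 1.5 + 0.4 * y)
  r <- compare_real_synthetic(oc_r, oc_s, "sia_magnitude")$pearson_r
  z <- atanh(r)
  ci <- tanh(z + c(-1, 1) * 1.96 / sqrt(n - 3))
  expect_true(rho >= ci[1] && rho <= ci[2])
})
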