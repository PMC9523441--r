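small_cfg <- function(epochs = 2, seed = 3, base_filters = 4, ...) {
  train_config(working_res = 16, unet_depth = 2, base_filters = base_filters,
               epochs = epochs, seed = seed, ...)
}

test_that("generator maps a 3-channel stack to a unit-interval plane, deterministically", {
  cfg <- small_cfg()
  G <- build_generator(cfg)
  withr::with_seed(1, x <- array(runif(16 * 16 * 3), c(16, 16, 3)))
  y1 <- flakmap:::gen_forward(G, x)$y
  expect_identical(dim(y1), c(16L, 16L, 1L))
  expect_true(all(y1 >= 0 & y1 <= 1))
  y2 <- flakmap:::gen_forward(G, x)$y
  expect_identical(y1, y2)
  # same seed rebuilds identical weights
  G2 <- build_generator(cfg)
  expect_identical(G$enc[[1]]$w, G2$enc[[1]]$w)
})

test_that("parameter count grows with base filters", {
  n1 <- n_params(build_generator(small_cfg(base_filters = 4)))
  n2 <- n_params(build_generator(small_cfg(base_filters = 8)))
  n3 <- n_params(build_generator(small_cfg(base_filters = 16)))
  expect_lt(n1, n2)
  expect_lt(n2, n3)
})

test_that("discriminator emits a finite patch grid sensitive to its condition", {
  cfg <- small_cfg()
  D <- build_discriminator(cfg)
  withr::with_seed(2, x4 <- array(runif(16 * 16 * 4), c(16, 16, 4)))
  z <- flakmap:::disc_forward(D, x4)$z
  # two stride-2 stages then a stride-1 4x4 conv: 16 -> 4 -> 3
  expect_identical(dim(z), c(3L, 3L, 1L))
  expect_true(all(is.finite(z)))
  # permuting the condition channels changes the scores
  xp <- x4[, , c(3, 1, 2, 4)]
  zp <- flakmap:::disc_forward(D, xp)$z
  expect_false(isTRUE(all.equal(z, zp)))
})

test_that("network gradients agree with finite differences", {
  cfg <- small_cfg()
  G <- build_generator(cfg)
  # inputs kept away from the unit bounds: at the clip boundary the residual
  # head's straight-through gradient intentionally differs from the numeric one
  withr::with_seed(4, {
    x <- array(0.2 + 0.6 * runif(16 * 16 * 3), c(16, 16, 3))
    y <- array(0.2 + 0.6 * runif(16 * 16), c(16, 16, 1))
  })
  loss <- function(G) mean(abs(flakmap:::gen_forward(G, x)$y - y))
  f <- flakmap:::gen_forward(G, x)
  g <- flakmap:::gen_backward(G, f$cache, sign(f$y - y) / length(y))
  eps <- 1e-6
  spots <- list(
    list(path = function(G) G$enc[[1]]$w, grad = g$enc[[1]]$gw,
         set = function(G, i, e) { G$enc[[1]]$w[i] <- G$enc[[1]]$w[i] + e; G }),
    list(path = function(G) G$dec[[1]]$w, grad = g$dec[[1]]$gw,
         set = function(G, i, e) { G$dec[[1]]$w[i] <- G$dec[[1]]$w[i] + e; G }),
    list(path = function(G) G$final$w, grad = g$final$gw,
         set = function(G, i, e) { G$final$w[i] <- G$final$w[i] + e; G }),
    list(path = function(G) G$enc[[2]]$b, grad = g$enc[[2]]$gb,
         set = function(G, i, e) { G$enc[[2]]$b[i] <- G$enc[[2]]$b[i] + e; G })
  )
  withr::with_seed(5, {
    for (sp in spots) {
      for (i in sample(length(sp$path(G)), min(3, length(sp$path(G))))) {
        num <- (loss(sp$set(G, i, eps)) - loss(sp$set(G, i, -eps))) / (2 * eps)
        expect_equal(sp$grad[i], num, tolerance = 1e-4)
      }
    }
  })
})

test_that("discriminator input gradient matches finite differences", {
  cfg <- small_cfg()
  D <- build_discriminator(cfg)
  withr::with_seed(6, x4 <- array(runif(16 * 16 * 4), c(16, 16, 4)))
  lossD <- function(x) {
    flakmap:::adv_loss_value(flakmap:::disc_forward(D, x)$z, 1, "bce")
  }
  fd <- flakmap:::disc_forward(D, x4)
  bd <- flakmap:::disc_backward(D, fd$cache,
                                flakmap:::adv_loss_grad(fd$z, 1, "bce"))
  eps <- 1e-6
  withr::with_seed(7, idx <- sample(length(x4), 6))
  for (i in idx) {
    xp <- x4; xp[i] <- xp[i] + eps
    xm <- x4; xm[i] <- xm[i] - eps
    expect_equal(bd$gx[i], (lossD(xp) - lossD(xm)) / (2 * eps), tolerance = 1e-4)
  }
})

test_that("buffer pool keeps only the latest fake at size one", {
  withr::with_seed(8, {
    pool <- list()
    for (i in 1:10) {
      pool <- flakmap:::pool_push(pool, i, size = 1L)
      expect_identical(flakmap:::pool_draw(pool), i)
    }
    # larger pool retains capacity-many items
    pool <- list()
    for (i in 1:10) pool <- flakmap:::pool_push(pool, i, size = 5L)
    expect_length(pool, 5L)
  })
})

test_that("a short training run is finite, seeded, and sensitive to lambda", {
  ds <- generate_dataset(noise_free_config(8),
                         deterministic_effect_model(),
                         split = c(0.75, 0.25), seed = 19,
                         plan_policy = "uniform")
  train <- ds[ds$role == "train", ]
  cfg <- small_cfg(epochs = 2, seed = 21)
  m1 <- train_pix2pix(train, cfg)
  expect_equal(nrow(m1$history), 2)
  expect_true(all(is.finite(unlist(m1$history[c("g_adv", "d_loss", "l1")]))))
  m1b <- train_pix2pix(train, cfg)
  expect_identical(m1$G$final$w, m1b$G$final$w)

  m0 <- train_pix2pix(train, small_cfg(epochs = 2, seed = 21, l1_weight = 0))
  expect_false(isTRUE(all.equal(m0$history$l1[2], m1$history$l1[2])))

  expect_error(train_pix2pix(train[1, ], cfg), "at least 2")
  nop <- train
  nop$postop[1] <- list(NULL)
  expect_error(train_pix2pix(nop, cfg), "paired")
})

test_that("predictions are deterministic, in-window and on the native lattice", {
  ds <- generate_dataset(noise_free_config(6), deterministic_effect_model(),
                         split = c(0.7, 0.3), seed = 23, plan_policy = "uniform")
  cfg <- small_cfg(epochs = 1, seed = 25)
  m <- train_pix2pix(ds[ds$role == "train", ], cfg)
  test <- ds[ds$role == "test", ]
  p1 <- predict(m, test)
  p2 <- predict(m, test)
  pm <- p1$predicted[[1]]
  expect_s3_class(pm, "power_map")
  expect_identical(dim(pm$values), dim(test$preop[[1]]$values))
  expect_true(all(pm$values[pm$mask] >= 30 & pm$values[pm$mask] <= 60))
  expect_identical(pm$values, p2$predicted[[1]]$values)
  expect_error(predict(m, test, window = c(20, 70)), "window mismatch")
})

test_that("identity ablation passes the pre-operative plane through the pipeline", {
  ds <- generate_dataset(noise_free_config(4), deterministic_effect_model(),
                         split = c(0.5, 0.5), seed = 27, plan_policy = "uniform")
  cfg <- train_config(working_res = 64, unet_depth = 3, base_filters = 4,
                      epochs = 1, seed = 1, identity_ablation = TRUE)
  G <- build_generator(cfg)
  test <- ds[ds$role == "test", ]
  model <- structure(
    list(G = G, D = build_discriminator(cfg), config = cfg,
         history = tibble::tibble(epoch = 0L, g_adv = NA_real_,
                                  d_loss = NA_real_, l1 = NA_real_,
                                  val_l1 = NA_real_),
         spacing = test$preop[[1]]$spacing,
         native_side = nrow(test$preop[[1]]$values)),
    class = "flak_pix2pix")
  pred <- predict(model, test)
  pre_power <- curvature_to_power(test$preop[[1]])
  got <- pred$predicted[[1]]
  inner <- flakmap:::lattice_coords(71, 0.1)$r <= 2.5 & got$mask
  # two resampling passes cost a little fidelity at the 71->64->71 hop
  expect_lt(mean(abs(got$values[inner] - pre_power$values[inner])), 0.1)
})

test_that("loss history tidiers expose the standard broom surface", {
  ds <- generate_dataset(noise_free_config(4), deterministic_effect_model(),
                         split = c(0.5, 0.5), seed = 29, plan_policy = "uniform")
  m <- train_pix2pix(ds[ds$role == "train", ], small_cfg(epochs = 2, seed = 31),
                     val_records = ds[ds$role == "test", ])
  td <- tidy(m)
  expect_true(all(c("epoch", "loss", "value") %in% names(td)))
  expect_equal(sort(unique(td$loss)), sort(c("g_adv", "d_loss", "l1", "val_l1")))
  gl <- glance(m)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$epochs, 2)
  expect_gt(gl$n_params_g, 0)
  p <- ggplot2::ggplot_build(autoplot(m))
  expect_gt(nrow(p$data[[1]]), 0)
})
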