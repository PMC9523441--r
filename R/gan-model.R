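#' Training configuration for the conditional GAN
#'
#' Hyperparameters of the pix2pix-style model: a U-Net generator trained
#' against a patch discriminator with an adversarial plus weighted-L1
#' objective, alternating generator and discriminator stages with a buffer
#' pool of past generator outputs. Defaults follow standard pix2pix practice
#' (L1 weight 100, Adam at 2e-4 with beta1 0.5, pool of 50).
#'
#' @param epochs Training epochs.
#' @param batch_size Samples per parameter update (default 1, the canonical
#'   pix2pix setting).
#' @param lr_g,lr_d Generator / discriminator Adam learning rates.
#' @param beta1,beta2 Adam moment decay rates.
#' @param l1_weight Weight lambda of the L1 reconstruction term.
#' @param buffer_pool_size Capacity of the generated-sample buffer pool
#'   (random replacement; size 1 degenerates to vanilla alternation on the
#'   latest fake).
#' @param unet_depth Number of stride-2 encoder stages (2-7; the working
#'   resolution must be divisible by `2^unet_depth`). The default of 4 gives
#'   a near-global receptive field at the 64-pixel working resolution —
#'   needed because a peripheral arc reshapes the whole central cornea.
#'   Channel counts double per stage, capped at 8x `base_filters`.
#' @param base_filters Channels of the first encoder stage; deeper stages
#'   double it.
#' @param disc_layers Number of stride-2 discriminator stages; together with
#'   the final stride-1 convolution this sets the patch-grid size.
#' @param norm `"instance"` (per-channel instance normalisation after every
#'   convolution except the first and last of each network — the standard
#'   batch-size-1 choice for this model family, and essential for
#'   convergence within a few dozen epochs) or `"none"`.
#' @param residual If `TRUE` (default) the generator predicts a bounded
#'   residual added to the input curvature channel rather than the full
#'   plane: surgery is a small change to the pre-operative map, and the
#'   residual form spends no capacity on reconstruction. `FALSE` restores a
#'   plain sigmoid output head.
#' @param residual_scale Bound of the residual in normalised units
#'   (default 0.25, i.e. 7.5 D on the default window — far beyond any
#'   physiologic surgical change).
#' @param adv_loss `"bce"` (cross-entropy, the log form of the minimax
#'   objective) or `"lsgan"` (least-squares variant).
#' @param adv_weight Weight of the adversarial term in the generator
#'   objective (1 = standard conditional GAN; 0 = pure supervised L1
#'   ablation, which also skips discriminator updates).
#' @param working_res Internal square resolution (power of two); lattice
#'   inputs are resampled to it and predictions resampled back.
#' @param window Power normalisation window in D (must match the encoding).
#' @param age_range Age normalisation range in years.
#' @param incision_placement Passed to [render_incision_map()].
#' @param seed RNG seed governing initialisation, shuffling and the pool.
#' @param patience Early-stopping patience on the held-out L1 (epochs without
#'   improvement; `Inf` disables).
#' @param identity_ablation If `TRUE`, the generator is replaced by the
#'   identity on the curvature channel — an untrained pass-through used to
#'   check the surrounding pipeline.
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 30L, batch_size = 1L,
                         lr_g = 2e-4, lr_d = 2e-4,
                         beta1 = 0.5, beta2 = 0.999,
                         l1_weight = 100, buffer_pool_size = 50L,
                         unet_depth = 4L, base_filters = 16L,
                         disc_layers = 2L,
                         norm = c("instance", "none"),
                         residual = TRUE, residual_scale = 0.25,
                         adv_loss = c("bce", "lsgan"), adv_weight = 1,
                         working_res = 64L,
                         window = c(30, 60), age_range = c(20, 90),
                         incision_placement = "edge",
                         seed = 1L, patience = Inf,
                         identity_ablation = FALSE) {
  adv_loss <- match.arg(adv_loss)
  norm <- match.arg(norm)
  if (epochs < 1L || batch_size < 1L || buffer_pool_size < 1L ||
      base_filters < 1L) abort("counts must be >= 1")
  if (l1_weight < 0) abort("l1_weight must be >= 0")
  if (unet_depth < 2L || unet_depth > 7L) abort("unet_depth must be 2-7")
  if (working_res %% 2L^unet_depth != 0L) {
    abort("working_res must be divisible by 2^unet_depth")
  }
  structure(
    list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         lr_g = lr_g, lr_d = lr_d, beta1 = beta1, beta2 = beta2,
         l1_weight = l1_weight, buffer_pool_size = as.integer(buffer_pool_size),
         unet_depth = as.integer(unet_depth),
         base_filters = as.integer(base_filters),
         disc_layers = as.integer(disc_layers), norm = norm,
         residual = isTRUE(residual), residual_scale = residual_scale,
         adv_loss = adv_loss, adv_weight = adv_weight,
         working_res = as.integer(working_res), window = window,
         age_range = age_range, incision_placement = incision_placement,
         seed = as.integer(seed), patience = patience,
         identity_ablation = identity_ablation),
    class = "train_config"
  )
}

# ---- layers ---------------------------------------------------------------

new_conv_layer <- function(in_ch, out_ch, type = c("conv", "convt"),
                           k = 4L, stride = 2L, pad = 1L, init_sd = 0.02) {
  type <- match.arg(type)
  nw <- if (type == "conv") k * k * in_ch else k * k * out_ch
  ncol_w <- if (type == "conv") out_ch else in_ch
  list(type = type, k = k, stride = stride, pad = pad,
       in_ch = in_ch, out_ch = out_ch,
       w = matrix(stats::rnorm(nw * ncol_w, 0, init_sd), nw, ncol_w),
       b = rep(0, out_ch))
}

layer_forward <- function(layer, x) {
  if (layer$type == "conv") {
    cpp_conv2d_forward(x, layer$w, layer$b, layer$k, layer$k,
                       layer$stride, layer$pad)
  } else {
    cpp_convt2d_forward(x, layer$w, layer$b, layer$k, layer$k,
                        layer$stride, layer$pad)
  }
}

layer_backward <- function(layer, x, gout) {
  res <- if (layer$type == "conv") {
    cpp_conv2d_backward(x, layer$w, gout, layer$k, layer$k,
                        layer$stride, layer$pad)
  } else {
    cpp_convt2d_backward(x, layer$w, gout, layer$k, layer$k,
                         layer$stride, layer$pad)
  }
  res$gb <- as.numeric(res$gb)
  res
}

lrelu <- function(x, slope = 0.2) ifelse(x > 0, x, slope * x)
lrelu_grad <- function(x, slope = 0.2) ifelse(x > 0, 1, slope)
relu <- function(x) pmax(x, 0)
sigmoid_arr <- function(x) 1 / (1 + exp(-x))

# instance normalisation (per-channel, single sample, no affine terms), the
# standard batch-size-1 normalisation of conditional image-to-image GANs
inorm_fwd <- function(x, eps = 1e-5) {
  d <- dim(x)
  m <- matrix(x, d[1L] * d[2L], d[3L])
  mu <- colMeans(m)
  v <- colMeans(m^2) - mu^2
  istd <- 1 / sqrt(v + eps)
  y <- sweep(sweep(m, 2L, mu, "-"), 2L, istd, "*")
  list(y = array(y, d), istd = istd)
}

inorm_bwd <- function(gy, y, istd) {
  d <- dim(gy)
  gm <- matrix(gy, d[1L] * d[2L], d[3L])
  ym <- matrix(y, d[1L] * d[2L], d[3L])
  gx <- sweep(gm, 2L, colMeans(gm), "-") -
    sweep(ym, 2L, colMeans(gm * ym), "*")
  array(sweep(gx, 2L, istd, "*"), d)
}

concat_ch <- function(a, b) {
  out <- array(0, c(dim(a)[1:2], dim(a)[3] + dim(b)[3]))
  out[, , seq_len(dim(a)[3])] <- a
  out[, , dim(a)[3] + seq_len(dim(b)[3])] <- b
  out
}

# ---- generator ------------------------------------------------------------

#' Build the U-Net generator
#'
#' Stride-2 convolutional encoder (leaky-ReLU) down to a bottleneck, mirrored
#' by transposed-convolution decoding with skip connections concatenating
#' each encoder stage's activations, and a final sigmoid mapping to a
#' one-channel plane in `[0, 1]`. Weights are drawn N(0, 0.02) from the
#' config's seed.
#'
#' @param config A [train_config()].
#' @param in_channels Input channels (3: curvature, age, incision).
#' @return A list of class `flak_generator`.
#' @export
build_generator <- function(config, in_channels = 3L) {
  d <- config$unet_depth
  nf <- config$base_filters
  # channels double per stage, capped at 8x base as in standard U-Net GANs
  ch <- pmin(nf * 2L^(seq_len(d) - 1L), 8L * nf)
  with_local_seed(config$seed, {
    enc <- vector("list", d)
    for (k in seq_len(d)) {
      enc[[k]] <- new_conv_layer(if (k == 1L) in_channels else ch[k - 1L],
                                 ch[k], "conv")
    }
    dec <- vector("list", max(0L, d - 1L))
    for (i in seq_len(d - 1L)) {
      k <- d - i  # encoder level whose resolution this step restores
      in_ch <- if (i == 1L) ch[d] else 2L * ch[k + 1L]
      dec[[i]] <- new_conv_layer(in_ch, ch[k], "convt")
    }
    final <- new_conv_layer(2L * ch[1L], 1L, "convt")
    structure(list(enc = enc, dec = dec, final = final, depth = d,
                   channels = ch, norm = config$norm %||% "instance",
                   residual = isTRUE(config$residual %||% TRUE),
                   residual_scale = config$residual_scale %||% 0.25,
                   identity_ablation = isTRUE(config$identity_ablation)),
              class = "flak_generator")
  })
}

# encoder stage 1 is conv + leaky-ReLU; deeper encoder stages and all decoder
# stages insert instance normalisation between the convolution and the
# activation; the output stage is a plain transposed convolution + sigmoid
gen_forward <- function(G, x) {
  if (isTRUE(G$identity_ablation)) {
    y <- array(x[, , 1L], c(dim(x)[1:2], 1L))
    return(list(y = y, cache = NULL))
  }
  d <- G$depth
  pre <- vector("list", d)
  nrm <- vector("list", d)
  h <- vector("list", d)
  inp <- x
  for (k in seq_len(d)) {
    pre[[k]] <- layer_forward(G$enc[[k]], inp)
    if (k > 1L && G$norm == "instance") {
      nrm[[k]] <- inorm_fwd(pre[[k]])
      h[[k]] <- lrelu(nrm[[k]]$y)
    } else {
      h[[k]] <- lrelu(pre[[k]])
    }
    inp <- h[[k]]
  }
  u <- h[[d]]
  dec_in <- vector("list", d - 1L)
  dec_pre <- vector("list", d - 1L)
  dec_nrm <- vector("list", d - 1L)
  for (i in seq_len(d - 1L)) {
    k <- d - i
    dec_in[[i]] <- u
    p <- layer_forward(G$dec[[i]], u)
    dec_pre[[i]] <- p
    if (G$norm == "instance") {
      dec_nrm[[i]] <- inorm_fwd(p)
      u <- concat_ch(relu(dec_nrm[[i]]$y), h[[k]])
    } else {
      u <- concat_ch(relu(p), h[[k]])
    }
  }
  yp <- layer_forward(G$final, u)
  if (G$residual) {
    # the surgery is a bounded change to the input map: predict a residual
    # (tanh-bounded to +/- residual_scale in normalised units) added to the
    # curvature channel, clipped to the unit interval
    tn <- tanh(yp)
    y <- pmin(pmax(array(x[, , 1L], dim(yp)) + G$residual_scale * tn, 0), 1)
  } else {
    tn <- NULL
    y <- sigmoid_arr(yp)
  }
  list(y = y,
       cache = list(x = x, pre = pre, nrm = nrm, h = h, dec_in = dec_in,
                    dec_pre = dec_pre, dec_nrm = dec_nrm, final_in = u,
                    tn = tn, y = y))
}

gen_backward <- function(G, cache, gy) {
  d <- G$depth
  gyp <- if (G$residual) {
    # straight-through the clip; tanh derivative bounds the residual grad
    gy * G$residual_scale * (1 - cache$tn^2)
  } else {
    gy * cache$y * (1 - cache$y)
  }
  grads <- list(enc = vector("list", d), dec = vector("list", d - 1L))
  bf <- layer_backward(G$final, cache$final_in, gyp)
  grads$final <- list(gw = bf$gw, gb = bf$gb)
  gu <- bf$gx
  gh <- vector("list", d)  # skip-connection gradient accumulators
  for (i in rev(seq_len(d - 1L))) {
    k <- d - i
    out_ch <- G$dec[[i]]$out_ch
    gt <- gu[, , seq_len(out_ch), drop = FALSE]
    gskip <- gu[, , out_ch + seq_len(dim(gu)[3] - out_ch), drop = FALSE]
    gh[[k]] <- if (is.null(gh[[k]])) gskip else gh[[k]] + gskip
    if (!is.null(cache$dec_nrm[[i]])) {
      gn <- gt * (cache$dec_nrm[[i]]$y > 0)
      gt_pre <- inorm_bwd(gn, cache$dec_nrm[[i]]$y, cache$dec_nrm[[i]]$istd)
    } else {
      gt_pre <- gt * (cache$dec_pre[[i]] > 0)
    }
    bd <- layer_backward(G$dec[[i]], cache$dec_in[[i]], gt_pre)
    grads$dec[[i]] <- list(gw = bd$gw, gb = bd$gb)
    gu <- bd$gx
  }
  gh[[d]] <- if (is.null(gh[[d]])) gu else gh[[d]] + gu
  gcur <- gh[[d]]
  for (k in rev(seq_len(d))) {
    if (!is.null(cache$nrm[[k]])) {
      gn <- gcur * lrelu_grad(cache$nrm[[k]]$y)
      gpre <- inorm_bwd(gn, cache$nrm[[k]]$y, cache$nrm[[k]]$istd)
    } else {
      gpre <- gcur * lrelu_grad(cache$pre[[k]])
    }
    input_k <- if (k == 1L) cache$x else cache$h[[k - 1L]]
    be <- layer_backward(G$enc[[k]], input_k, gpre)
    grads$enc[[k]] <- list(gw = be$gw, gb = be$gb)
    gcur <- be$gx
    if (k >= 2L && !is.null(gh[[k - 1L]])) gcur <- gcur + gh[[k - 1L]]
  }
  grads
}

# ---- discriminator --------------------------------------------------------

#' Build the patch discriminator
#'
#' A small convolutional classifier over (condition channels, candidate
#' post-operative plane) stacks, emitting a grid of per-patch real/fake
#' scores rather than a single logit.
#'
#' @param config A [train_config()].
#' @param in_channels Condition channels plus one candidate channel.
#' @return A list of class `flak_discriminator`.
#' @export
build_discriminator <- function(config, in_channels = 4L) {
  nf <- config$base_filters
  nl <- config$disc_layers
  with_local_seed(config$seed + 1L, {
    layers <- vector("list", nl + 1L)
    for (k in seq_len(nl)) {
      layers[[k]] <- new_conv_layer(if (k == 1L) in_channels else nf * 2L^(k - 2L),
                                    nf * 2L^(k - 1L), "conv")
    }
    layers[[nl + 1L]] <- new_conv_layer(nf * 2L^(nl - 1L), 1L, "conv",
                                        stride = 1L)
    structure(list(layers = layers, n_stride2 = nl,
                   norm = config$norm %||% "instance"),
              class = "flak_discriminator")
  })
}

# first layer conv + leaky-ReLU, middle layers normalised, final layer raw
disc_forward <- function(D, x) {
  n <- length(D$layers)
  pre <- vector("list", n)
  nrm <- vector("list", n)
  act <- vector("list", n)
  inp <- x
  for (k in seq_len(n)) {
    pre[[k]] <- layer_forward(D$layers[[k]], inp)
    if (k == n) {
      act[[k]] <- pre[[k]]
    } else if (k > 1L && D$norm == "instance") {
      nrm[[k]] <- inorm_fwd(pre[[k]])
      act[[k]] <- lrelu(nrm[[k]]$y)
    } else {
      act[[k]] <- lrelu(pre[[k]])
    }
    inp <- act[[k]]
  }
  list(z = act[[n]], cache = list(x = x, pre = pre, nrm = nrm, act = act))
}

disc_backward <- function(D, cache, gz) {
  n <- length(D$layers)
  grads <- vector("list", n)
  gcur <- gz
  for (k in rev(seq_len(n))) {
    if (k < n) {
      if (!is.null(cache$nrm[[k]])) {
        gn <- gcur * lrelu_grad(cache$nrm[[k]]$y)
        gcur <- inorm_bwd(gn, cache$nrm[[k]]$y, cache$nrm[[k]]$istd)
      } else {
        gcur <- gcur * lrelu_grad(cache$pre[[k]])
      }
    }
    input_k <- if (k == 1L) cache$x else cache$act[[k - 1L]]
    b <- layer_backward(D$layers[[k]], input_k, gcur)
    grads[[k]] <- list(gw = b$gw, gb = b$gb)
    gcur <- b$gx
  }
  list(layers = grads, gx = gcur)
}

#' Parameter count of a generator or discriminator
#'
#' @param net A `flak_generator` or `flak_discriminator`.
#' @return Integer number of trainable parameters.
#' @export
n_params <- function(net) {
  tot <- 0L
  walk <- function(x) {
    if (is.list(x)) {
      if (!is.null(x$w)) {
        tot <<- tot + length(x$w) + length(x$b)
      } else {
        for (el in x) if (is.list(el)) walk(el)
      }
    }
  }
  walk(unclass(net))
  tot
}

# ---- losses ---------------------------------------------------------------

adv_loss_value <- function(z, target, kind) {
  if (kind == "bce") {
    mean(pmax(z, 0) - z * target + log1p(exp(-abs(z))))
  } else {
    mean((z - target)^2)
  }
}

adv_loss_grad <- function(z, target, kind) {
  n <- length(z)
  if (kind == "bce") (sigmoid_arr(z) - target) / n else 2 * (z - target) / n
}

# ---- Adam -----------------------------------------------------------------

adam_init_like <- function(net) {
  walk <- function(x) {
    if (is.list(x)) {
      if (!is.null(x$w)) {
        return(list(mw = x$w * 0, vw = x$w * 0,
                    mb = x$b * 0, vb = x$b * 0))
      }
      lapply(x, function(el) if (is.list(el)) walk(el) else NULL)
    } else NULL
  }
  walk(unclass(net))
}

# grads mirror the net structure with layer-level lists (gw, gb); iteration
# follows the grads structure so metadata fields on the net are untouched
adam_update <- function(net, grads, state, lr, b1, b2, t, eps = 1e-8) {
  walk <- function(x, g, s) {
    if (is.list(x) && !is.null(x$w)) {
      s$mw <- b1 * s$mw + (1 - b1) * g$gw
      s$vw <- b2 * s$vw + (1 - b2) * g$gw^2
      s$mb <- b1 * s$mb + (1 - b1) * g$gb
      s$vb <- b2 * s$vb + (1 - b2) * g$gb^2
      x$w <- x$w - lr * (s$mw / (1 - b1^t)) / (sqrt(s$vw / (1 - b2^t)) + eps)
      x$b <- x$b - lr * (s$mb / (1 - b1^t)) / (sqrt(s$vb / (1 - b2^t)) + eps)
      return(list(x = x, s = s))
    }
    keys <- if (!is.null(names(g))) names(g) else seq_along(g)
    for (k in keys) {
      if (!is.null(g[[k]])) {
        r <- walk(x[[k]], g[[k]], s[[k]])
        x[[k]] <- r$x
        s[[k]] <- r$s
      }
    }
    list(x = x, s = s)
  }
  cls <- class(net)
  r <- walk(unclass(net), grads, state)
  class(r$x) <- cls
  list(net = r$x, state = r$s)
}

# ---- buffer pool ----------------------------------------------------------

# random-replacement buffer of past generator outputs (with their condition
# stacks, since the discriminator is conditional)
pool_push <- function(pool, item, size) {
  if (length(pool) < size) {
    pool[[length(pool) + 1L]] <- item
  } else {
    pool[[sample.int(length(pool), 1L)]] <- item
  }
  pool
}

pool_draw <- function(pool) {
  pool[[sample.int(length(pool), 1L)]]
}

# ---- training -------------------------------------------------------------

prepare_training_pair <- function(preop, postop, age, plan, config) {
  x <- assemble_input(curvature_to_power(preop), age, plan,
                      window = config$window, age_range = config$age_range,
                      incision_placement = config$incision_placement)
  res <- config$working_res
  xr <- array(0, c(res, res, 3L))
  for (c in 1:3) xr[, , c] <- resize_plane(x[, , c], res)
  yr <- NULL
  if (!is.null(postop)) {
    yn <- normalize_curvature(curvature_to_power(postop), config$window)
    yr <- array(resize_plane(unclass(yn), res), c(res, res, 1L))
  }
  list(x = xr, y = yr)
}

records_to_pairs <- function(records, config, need_postop = TRUE) {
  if (need_postop && any(vapply(records$postop, is.null, logical(1)))) {
    abort("training requires paired pre/post-operative records")
  }
  lapply(seq_len(nrow(records)), function(i) {
    prepare_training_pair(records$preop[[i]],
                          if (need_postop) records$postop[[i]] else NULL,
                          records$age[i], records$plan[[i]], config)
  })
}

heldout_l1 <- function(G, pairs) {
  mean(vapply(pairs, function(p) {
    mean(abs(gen_forward(G, p$x)$y - p$y))
  }, numeric(1)))
}

#' Train the conditional GAN
#'
#' Alternating two-stage schedule: for each sample the discriminator is held
#' fixed while the generator takes an adversarial + lambda * L1 step and its
#' output is saved to the buffer pool; then the generator is held fixed while
#' the discriminator trains on the real pair and a fake drawn from the pool.
#' Training is fully reproducible from the config seed.
#'
#' @param records A tibble of paired records as produced by
#'   [generate_dataset()] (uses columns `preop`, `postop`, `age`, `plan`).
#' @param config A [train_config()].
#' @param val_records Optional held-out records; their mean generator L1 is
#'   recorded each epoch and drives early stopping.
#' @param verbose Print per-epoch losses.
#' @return An object of class `flak_pix2pix`: generator, discriminator,
#'   config and a `history` tibble (`epoch`, `g_adv`, `d_loss`, `l1`,
#'   `val_l1`).
#' @export
train_pix2pix <- function(records, config = train_config(),
                          val_records = NULL, verbose = FALSE) {
  if (nrow(records) < 2L) abort("need at least 2 paired records")
  pairs <- records_to_pairs(records, config)
  val_pairs <- if (!is.null(val_records)) records_to_pairs(val_records, config)
  spacing <- records$preop[[1L]]$spacing
  native_side <- nrow(records$preop[[1L]]$values)
  with_local_seed(config$seed, {
    G <- build_generator(config)
    D <- build_discriminator(config)
    sg <- adam_init_like(G)
    sd <- adam_init_like(D)
    pool <- list()
    hist <- vector("list", config$epochs)
    tg <- 0L
    td <- 0L
    best_val <- Inf
    stall <- 0L
    n <- length(pairs)
    npix <- config$working_res^2
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      ep <- c(g_adv = 0, d_loss = 0, l1 = 0)
      gacc <- NULL
      nacc <- 0L
      for (idx in ord) {
        p <- pairs[[idx]]
        # stage 1: discriminator fixed, generator trains; fake saved to pool
        fg <- gen_forward(G, p$x)
        fake <- fg$y
        l1 <- mean(abs(fake - p$y))
        if (config$adv_weight > 0) {
          dstack <- concat_ch(p$x, fake)
          fd <- disc_forward(D, dstack)
          g_adv <- adv_loss_value(fd$z, 1, config$adv_loss)
          gz <- adv_loss_grad(fd$z, 1, config$adv_loss)
          gfake_adv <- config$adv_weight *
            disc_backward(D, fd$cache, gz)$gx[, , 4L, drop = FALSE]
        } else {
          g_adv <- 0
          gfake_adv <- 0
        }
        gfake <- gfake_adv + config$l1_weight * sign(fake - p$y) / npix
        gG <- gen_backward(G, fg$cache, gfake)
        if (is.null(gacc)) gacc <- gG else gacc <- add_grads(gacc, gG)
        nacc <- nacc + 1L
        if (nacc == config$batch_size) {
          tg <- tg + 1L
          up <- adam_update(G, scale_grads(gacc, 1 / nacc), sg,
                            config$lr_g, config$beta1, config$beta2, tg)
          G <- up$net; sg <- up$state
          gacc <- NULL; nacc <- 0L
        }
        pool <- pool_push(pool, list(x = p$x, fake = fake),
                          config$buffer_pool_size)
        if (config$adv_weight == 0) {
          ep <- ep + c(0, 0, l1)
          next
        }
        # stage 2: generator fixed, discriminator trains on real + pool fake
        pf <- pool_draw(pool)
        fr <- disc_forward(D, concat_ch(p$x, p$y))
        ff <- disc_forward(D, concat_ch(pf$x, pf$fake))
        d_loss <- 0.5 * (adv_loss_value(fr$z, 1, config$adv_loss) +
                         adv_loss_value(ff$z, 0, config$adv_loss))
        br <- disc_backward(D, fr$cache,
                            0.5 * adv_loss_grad(fr$z, 1, config$adv_loss))
        bf <- disc_backward(D, ff$cache,
                            0.5 * adv_loss_grad(ff$z, 0, config$adv_loss))
        td <- td + 1L
        gD <- add_grads(list(layers = br$layers), list(layers = bf$layers))
        up <- adam_update(D, gD, sd,
                          config$lr_d, config$beta1, config$beta2, td)
        D <- up$net; sd <- up$state
        ep <- ep + c(g_adv, d_loss, l1)
      }
      ep <- ep / n
      if (!all(is.finite(ep))) {
        abort(sprintf("training diverged at epoch %d (non-finite loss)", epoch))
      }
      val_l1 <- if (!is.null(val_pairs)) heldout_l1(G, val_pairs) else NA_real_
      hist[[epoch]] <- tibble(epoch = epoch, g_adv = ep[["g_adv"]],
                              d_loss = ep[["d_loss"]], l1 = ep[["l1"]],
                              val_l1 = val_l1)
      if (verbose) {
        message(sprintf("epoch %d: g_adv %.4f d %.4f l1 %.5f val_l1 %s",
                        epoch, ep[["g_adv"]], ep[["d_loss"]], ep[["l1"]],
                        ifelse(is.na(val_l1), "-", sprintf("%.5f", val_l1))))
      }
      if (!is.na(val_l1)) {
        if (val_l1 < best_val - 1e-6) {
          best_val <- val_l1
          stall <- 0L
        } else {
          stall <- stall + 1L
          if (stall >= config$patience) break
        }
      }
    }
    structure(
      list(G = G, D = D, config = config,
           history = dplyr::bind_rows(hist),
           spacing = spacing, native_side = native_side),
      class = "flak_pix2pix"
    )
  })
}

add_grads <- function(a, b) {
  walk <- function(x, y) {
    if (is.list(x) && !is.null(x$gw)) {
      return(list(gw = x$gw + y$gw, gb = x$gb + y$gb))
    }
    for (i in seq_along(x)) {
      if (is.list(x[[i]]) && !is.null(y[[i]])) x[[i]] <- walk(x[[i]], y[[i]])
    }
    x
  }
  walk(a, b)
}

scale_grads <- function(g, f) {
  walk <- function(x) {
    if (is.list(x) && !is.null(x$gw)) {
      return(list(gw = x$gw * f, gb = x$gb * f))
    }
    for (i in seq_along(x)) if (is.list(x[[i]])) x[[i]] <- walk(x[[i]])
    x
  }
  walk(g)
}

#' @export
print.flak_pix2pix <- function(x, ...) {
  cat(sprintf("<flak_pix2pix> U-Net depth %d, %d base filters, %d + %d parameters\n",
              x$config$unet_depth, x$config$base_filters,
              n_params(x$G), n_params(x$D)))
  cat(sprintf("  trained %d epochs at %dx%d, lambda_L1 = %g, %s adversarial loss\n",
              max(x$history$epoch), x$config$working_res, x$config$working_res,
              x$config$l1_weight, x$config$adv_loss))
  invisible(x)
}

#' Predict post-operative maps
#'
#' Runs the trained generator on each record's encoded input, resamples the
#' output back to the native lattice, denormalises it through the recorded
#' window and copies the pre-operative validity mask.
#'
#' @param object A trained `flak_pix2pix` model.
#' @param newdata A tibble with columns `preop`, `age`, `plan` (list-columns
#'   as in [generate_dataset()]).
#' @param window Optional override; must equal the training window.
#' @param ... Unused.
#' @return `newdata` with an added list-column `predicted` of [power_map()]s.
#' @export
predict.flak_pix2pix <- function(object, newdata, window = NULL, ...) {
  if (!is.null(window) && !isTRUE(all.equal(window, object$config$window))) {
    abort("normalisation window mismatch with the trained model")
  }
  cfg <- object$config
  preds <- lapply(seq_len(nrow(newdata)), function(i) {
    p <- prepare_training_pair(newdata$preop[[i]], NULL, newdata$age[i],
                               newdata$plan[[i]], cfg)
    y <- gen_forward(object$G, p$x)$y[, , 1L]
    native <- resize_plane(y, object$native_side)
    mask <- newdata$preop[[i]]$mask
    denormalize_curvature(native, cfg$window, mask, object$spacing)
  })
  out <- newdata
  out$predicted <- preds
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the training history
#'
#' @param x A `flak_pix2pix` model.
#' @param ... Unused.
#' @return A long tibble with columns `epoch`, `loss`, `value`.
#' @export
tidy.flak_pix2pix <- function(x, ...) {
  tidyr::pivot_longer(x$history, -"epoch", names_to = "loss",
                      values_to = "value")
}

#' One-row model summary
#'
#' @param x A `flak_pix2pix` model.
#' @param ... Unused.
#' @return A one-row tibble with epochs trained, parameter counts and final
#'   losses.
#' @export
glance.flak_pix2pix <- function(x, ...) {
  h <- x$history[nrow(x$history), ]
  tibble(epochs = h$epoch, n_params_g = n_params(x$G),
         n_params_d = n_params(x$D), g_adv = h$g_adv, d_loss = h$d_loss,
         l1 = h$l1, val_l1 = h$val_l1)
}

#' Plot training losses
#'
#' @param object A `flak_pix2pix` model.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.flak_pix2pix <- function(object, ...) {
  df <- tidy(object)
  df <- df[!is.na(df$value), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss") +
    ggplot2::theme_minimal()
}
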