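#' Write a dataset to disk
#'
#' Emits one curvature CSV per map plus a YAML sidecar per eye (id, role,
#' age, plan, ground truth) and a JSON manifest recording the seed and full
#' generating configuration, so the dataset can be regenerated exactly.
#'
#' @param config A [synth_config()].
#' @param out_dir Output directory (created if missing).
#' @param model A [flak_effect_model()].
#' @param split Train/test fractions.
#' @param seed Master seed.
#' @param plan_policy Passed to [generate_dataset()].
#' @return The dataset tibble, invisibly; artifacts under `out_dir`.
#' @export
cmd_simulate <- function(config, out_dir, model = flak_effect_model(),
                         split = c(train = 386 / 451, test = 65 / 451),
                         seed = 1L, plan_policy = "nomogram") {
  ds <- generate_dataset(config, model, split, seed, plan_policy)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(ds))) {
    id <- ds$eye_id[i]
    write_curvature_csv(ds$preop[[i]], file.path(out_dir, paste0(id, "_pre.csv")))
    write_curvature_csv(ds$postop[[i]], file.path(out_dir, paste0(id, "_post.csv")))
    plan <- ds$plan[[i]]
    sidecar <- list(
      eye_id = id, role = ds$role[i], age = ds$age[i],
      plan = list(arc_lengths = plan$arcs$arc_length, axes = plan$arcs$axis,
                  paired = plan$paired,
                  optical_zone_mm = plan$optical_zone_mm,
                  depth_fraction = plan$depth_fraction),
      truth = list(preop_magnitude = ds$preop_magnitude[i],
                   preop_axis = ds$preop_axis[i],
                   sia_magnitude = ds$sia_magnitude[i],
                   sia_axis = ds$sia_axis[i])
    )
    yaml::write_yaml(sidecar, file.path(out_dir, paste0(id, ".yaml")))
  }
  manifest <- attr(ds, "manifest")
  manifest$n_eyes <- nrow(ds)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(ds)
}

#' Load a dataset written by [cmd_simulate()]
#'
#' @param dir Dataset directory.
#' @return A tibble in the [generate_dataset()] layout.
#' @export
read_dataset <- function(dir) {
  sidecars <- sort(list.files(dir, pattern = "\\.yaml$", full.names = TRUE))
  if (length(sidecars) == 0L) abort(sprintf("no eye sidecars found in %s", dir))
  rows <- lapply(sidecars, function(f) {
    sc <- yaml::read_yaml(f)
    id <- sc$eye_id
    pre <- read_curvature_csv(file.path(dir, paste0(id, "_pre.csv")))
    post_path <- file.path(dir, paste0(id, "_post.csv"))
    post <- if (file.exists(post_path)) read_curvature_csv(post_path)
    plan <- flak_plan(unlist(sc$plan$arc_lengths), axes = unlist(sc$plan$axes),
                      optical_zone_mm = sc$plan$optical_zone_mm,
                      depth_fraction = sc$plan$depth_fraction)
    tibble(
      eye_id = id, role = sc$role, age = sc$age,
      preop = list(pre), postop = list(post), plan = list(plan),
      preop_magnitude = sc$truth$preop_magnitude,
      preop_axis = sc$truth$preop_axis,
      sia_magnitude = sc$truth$sia_magnitude,
      sia_axis = sc$truth$sia_axis
    )
  })
  dplyr::bind_rows(rows)
}

#' Train from a dataset directory or tibble
#'
#' Trains on the records marked `train`, tracking held-out L1 on the `test`
#' records, and persists the model, its config and the loss history.
#'
#' @param dataset A dataset tibble or a directory written by [cmd_simulate()].
#' @param config A [train_config()].
#' @param out_dir Output directory for `model.rds`-free artifacts: weights
#'   are serialised as a JSON-wrapped flat-weight file plus `loss.csv` and
#'   `manifest.json`.
#' @param verbose Passed to [train_pix2pix()].
#' @return The trained `flak_pix2pix` model, invisibly.
#' @export
cmd_train <- function(dataset, config = train_config(), out_dir = NULL,
                      verbose = FALSE) {
  ds <- if (is.character(dataset)) read_dataset(dataset) else dataset
  train <- ds[ds$role == "train", ]
  test <- ds[ds$role == "test", ]
  if (nrow(train) == 0L) abort("dataset has no training records")
  model <- train_pix2pix(train, config,
                         val_records = if (nrow(test) > 0L) test,
                         verbose = verbose)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(model$history, file.path(out_dir, "loss.csv"),
                     row.names = FALSE)
    save_pix2pix(model, file.path(out_dir, "model.json"))
    jsonlite::write_json(
      list(config = unclass(config), n_train = nrow(train),
           n_test = nrow(test), seed = config$seed),
      file.path(out_dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(model)
}

#' Serialise / restore a trained model as JSON text
#'
#' Weights, shapes and config are stored as plain JSON so checkpoints are
#' portable text files.
#'
#' @param model A `flak_pix2pix` model.
#' @param path Output path.
#' @return `path` invisibly; `load_pix2pix()` returns the model.
#' @export
save_pix2pix <- function(model, path) {
  ser_layer <- function(l) {
    list(type = l$type, k = l$k, stride = l$stride, pad = l$pad,
         in_ch = l$in_ch, out_ch = l$out_ch,
         w = as.vector(l$w), w_dim = dim(l$w), b = l$b)
  }
  payload <- list(
    config = unclass(model$config),
    spacing = model$spacing, native_side = model$native_side,
    history = as.list(model$history),
    G = list(depth = model$G$depth, channels = model$G$channels,
             norm = model$G$norm, residual = model$G$residual,
             residual_scale = model$G$residual_scale,
             identity_ablation = model$G$identity_ablation,
             enc = lapply(model$G$enc, ser_layer),
             dec = lapply(model$G$dec, ser_layer),
             final = ser_layer(model$G$final)),
    D = list(n_stride2 = model$D$n_stride2, norm = model$D$norm,
             layers = lapply(model$D$layers, ser_layer))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_pix2pix
#' @export
load_pix2pix <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  de_layer <- function(l) {
    list(type = l$type, k = l$k, stride = l$stride, pad = l$pad,
         in_ch = l$in_ch, out_ch = l$out_ch,
         w = matrix(l$w, l$w_dim[1L], l$w_dim[2L]), b = l$b)
  }
  de_layers <- function(ls) {
    if (is.data.frame(ls)) {
      lapply(seq_len(nrow(ls)), function(i) de_layer(lapply(ls, `[[`, i)))
    } else {
      lapply(ls, de_layer)
    }
  }
  cfg <- p$config
  cfg$window <- as.numeric(cfg$window)
  cfg$age_range <- as.numeric(cfg$age_range)
  class(cfg) <- "train_config"
  structure(
    list(
      G = structure(list(enc = de_layers(p$G$enc), dec = de_layers(p$G$dec),
                         final = de_layer(p$G$final), depth = p$G$depth,
                         channels = p$G$channels,
                         norm = p$G$norm %||% "instance",
                         residual = isTRUE(p$G$residual),
                         residual_scale = p$G$residual_scale %||% 0.25,
                         identity_ablation = isTRUE(p$G$identity_ablation)),
                    class = "flak_generator"),
      D = structure(list(layers = de_layers(p$D$layers),
                         n_stride2 = p$D$n_stride2,
                         norm = p$D$norm %||% "instance"),
                    class = "flak_discriminator"),
      config = cfg,
      history = as_tibble(p$history),
      spacing = p$spacing, native_side = p$native_side
    ),
    class = "flak_pix2pix"
  )
}

#' Evaluate predictions against ground truth
#'
#' For the test records: predicts post-operative maps, then produces the
#' standard report set — per-zone keratometry of real and predicted maps,
#' Alpins vector outcomes, real-versus-synthetic agreement (Pearson r, MAE,
#' paired test) per zone for SIA and DV, and zone-masked image metrics.
#'
#' @param model A trained `flak_pix2pix` model.
#' @param dataset Dataset tibble or directory; rows with `role == "test"` are
#'   evaluated.
#' @param zones Zone diameters, mm.
#' @param out_dir Optional directory for CSV reports and figures.
#' @return A list of tibbles: `keratometry`, `outcomes_real`,
#'   `outcomes_synthetic`, `agreement`, `image_metrics`.
#' @export
cmd_evaluate <- function(model, dataset, zones = c(1, 3, 5), out_dir = NULL) {
  ds <- if (is.character(dataset)) read_dataset(dataset) else dataset
  test <- ds[ds$role == "test", ]
  if (nrow(test) == 0L) abort("dataset has no test records")
  if (any(vapply(test$postop, is.null, logical(1)))) {
    abort("evaluation needs real post-operative maps for the test records")
  }
  pred <- predict(model, test)
  eval_prediction_set(pred, zones = zones, window = model$config$window,
                      out_dir = out_dir)
}

#' Evaluate an already-predicted record set
#'
#' @param pred A tibble with list-columns `preop`, `postop`, `predicted`
#'   (curvature maps for the first two, power maps for `predicted`), plus
#'   `eye_id`, `age`.
#' @param zones Zone diameters, mm.
#' @param window Normalisation window for the image metrics.
#' @param out_dir Optional artifact directory.
#' @return See [cmd_evaluate()].
#' @export
eval_prediction_set <- function(pred, zones = c(1, 3, 5), window = c(30, 60),
                                out_dir = NULL) {
  per_eye <- lapply(seq_len(nrow(pred)), function(i) {
    pre_p <- curvature_to_power(pred$preop[[i]])
    post_p <- curvature_to_power(pred$postop[[i]])
    synth_p <- pred$predicted[[i]]
    zk <- function(map, kind) {
      k <- zone_keratometry_table(map, zones)
      k$eye_id <- pred$eye_id[i]
      k$kind <- kind
      k
    }
    list(
      kerat = dplyr::bind_rows(zk(pre_p, "preop"), zk(post_p, "postop_real"),
                               zk(synth_p, "postop_synthetic")),
      metrics = dplyr::mutate(
        evaluate_pair(post_p, synth_p, zones = zones, window = window),
        eye_id = pred$eye_id[i])
    )
  })
  kerat <- dplyr::bind_rows(lapply(per_eye, `[[`, "kerat"))
  metrics <- dplyr::bind_rows(lapply(per_eye, `[[`, "metrics"))
  out_real <- list()
  out_syn <- list()
  agreement <- list()
  for (z in zones) {
    kz <- kerat[kerat$zone == z, ]
    pre <- astigmatism_vector(kz[kz$kind == "preop", ])
    real <- astigmatism_vector(kz[kz$kind == "postop_real", ])
    syn <- astigmatism_vector(kz[kz$kind == "postop_synthetic", ])
    oc_r <- compute_outcomes(pre, real)
    oc_s <- compute_outcomes(pre, syn)
    oc_r$zone <- z
    oc_s$zone <- z
    out_real[[as.character(z)]] <- oc_r
    out_syn[[as.character(z)]] <- oc_s
    agreement[[as.character(z)]] <- dplyr::mutate(
      dplyr::bind_rows(
        compare_real_synthetic(oc_r, oc_s, "sia_magnitude"),
        compare_real_synthetic(oc_r, oc_s, "dv_magnitude")
      ), zone = z)
  }
  res <- list(
    keratometry = kerat,
    outcomes_real = dplyr::bind_rows(out_real),
    outcomes_synthetic = dplyr::bind_rows(out_syn),
    agreement = dplyr::bind_rows(agreement),
    image_metrics = metrics
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(res)) {
      utils::write.csv(res[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
    for (z in zones) {
      oc <- res$outcomes_synthetic[res$outcomes_synthetic$zone == z, ]
      ggplot2::ggsave(
        file.path(out_dir, sprintf("dv_synthetic_%gmm.png", z)),
        plot_single_angle(oc, "dv_magnitude",
                          sprintf("synthetic DV, %g-mm zone", z)),
        width = 5, height = 5, dpi = 120)
    }
  }
  res
}
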