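#' Double-angle representation of an astigmatism vector
#'
#' Astigmatism vectors add and subtract linearly only in double-angle space,
#' where a (magnitude M, axis theta) pair maps to the cartesian point
#' `(M cos 2 theta, M sin 2 theta)`.
#'
#' @param v A tibble (or data frame) with columns `magnitude` (D) and `axis`
#'   (degrees).
#' @return A tibble with columns `da_x` and `da_y`.
#' @export
#' @examples
#' to_double_angle(tibble::tibble(magnitude = 1, axis = 90))  # (-1, 0)
to_double_angle <- function(v) {
  stopifnot(all(c("magnitude", "axis") %in% names(v)))
  a <- 2 * v$axis * pi / 180
  tibble(da_x = v$magnitude * cos(a), da_y = v$magnitude * sin(a))
}

#' Astigmatism vector from double-angle coordinates
#'
#' Inverse of [to_double_angle()]; the axis is canonicalised to `[0, 180)` and
#' reported as 0 when the magnitude vanishes.
#'
#' @param da A tibble with columns `da_x`, `da_y`.
#' @return A tibble with columns `magnitude`, `axis`.
#' @export
from_double_angle <- function(da) {
  mag <- sqrt(da$da_x^2 + da$da_y^2)
  axis <- canonical_axis(atan2(da$da_y, da$da_x) * 90 / pi)
  axis[mag == 0] <- 0
  tibble(magnitude = mag, axis = axis)
}

#' Alpins astigmatism outcome vectors
#'
#' Per eye, computes the Alpins quantities for arcuate-keratotomy outcomes in
#' the convention where the surgical target is zero astigmatism:
#' * TIA (target-induced astigmatism) — the change the surgeon intends, equal
#'   to the pre-operative corneal astigmatism;
#' * DV (difference vector) — what remains to be corrected, equal to the
#'   post-operative corneal astigmatism;
#' * SIA (surgically induced astigmatism) — the change actually achieved, the
#'   double-angle difference pre minus post;
#' * CI (correction index) — `|SIA| / |TIA|`; above 1 indicates
#'   overcorrection, below 1 undercorrection. Undefined (NA) when TIA is 0.
#'
#' The identity `TIA = SIA + DV` holds exactly in double-angle space.
#'
#' @param preop,postop Tibbles with columns `magnitude`, `axis`, matched row
#'   by row (one row per eye).
#' @return A tibble with columns `tia_magnitude`, `tia_axis`, `sia_magnitude`,
#'   `sia_axis`, `dv_magnitude`, `dv_axis`, `ci`.
#' @export
#' @examples
#' compute_outcomes(
#'   preop  = tibble::tibble(magnitude = 1, axis = 90),
#'   postop = tibble::tibble(magnitude = 0, axis = 0)
#' )  # full correction: SIA = (1, 90), DV = 0, CI = 1
compute_outcomes <- function(preop, postop) {
  if (nrow(preop) != nrow(postop)) abort("preop and postop must have the same number of eyes")
  tia <- tibble(magnitude = preop$magnitude, axis = canonical_axis(preop$axis))
  dv <- tibble(magnitude = postop$magnitude, axis = canonical_axis(postop$axis))
  sia_da <- to_double_angle(tia)
  dv_da <- to_double_angle(dv)
  sia <- from_double_angle(tibble(da_x = sia_da$da_x - dv_da$da_x,
                                  da_y = sia_da$da_y - dv_da$da_y))
  ci <- ifelse(tia$magnitude > 0, sia$magnitude / tia$magnitude, NA_real_)
  tibble(
    tia_magnitude = tia$magnitude, tia_axis = tia$axis,
    sia_magnitude = sia$magnitude, sia_axis = sia$axis,
    dv_magnitude = dv$magnitude, dv_axis = dv$axis,
    ci = ci
  )
}

#' Cohort summary of an outcome quantity
#'
#' Arithmetic mean, SD (n - 1 denominator), range, and — where every value is
#' strictly positive, as for the correction index — the geometric mean.
#'
#' @param outcomes A tibble of per-eye outcomes (any numeric columns).
#' @param quantity Column name to summarise (string).
#' @return A one-row tibble: `quantity`, `n`, `mean`, `sd`, `min`, `max`,
#'   `geometric_mean` (NA if any value is not strictly positive). For a
#'   single value `sd` is reported as 0.
#' @export
cohort_summary <- function(outcomes, quantity) {
  x <- outcomes[[quantity]]
  if (is.null(x)) abort(sprintf("no column `%s` in outcomes", quantity))
  x <- x[!is.na(x)]
  if (length(x) == 0L) abort("no non-missing values to summarise")
  gm <- if (all(x > 0)) exp(mean(log(x))) else NA_real_
  tibble(
    quantity = quantity, n = length(x),
    mean = mean(x), sd = if (length(x) > 1L) stats::sd(x) else 0,
    min = min(x), max = max(x),
    geometric_mean = gm
  )
}

#' Agreement between real and synthetic outcome magnitudes
#'
#' Compares a per-eye outcome magnitude between real and model-synthesised
#' maps: Pearson correlation of the magnitudes, mean absolute error of the
#' magnitudes, the vector-difference-norm variant of the MAE (double-angle
#' distance), and a paired two-sided test.
#'
#' @param real,synthetic Tibbles of per-eye outcomes matched by row, as from
#'   [compute_outcomes()].
#' @param quantity Magnitude column to compare, e.g. `"sia_magnitude"` or
#'   `"dv_magnitude"`.
#' @param test `"wilcoxon"` (paired signed-rank, default — no normality
#'   assumption) or `"t"` (paired t-test).
#' @return A one-row tibble: `quantity`, `n`, `pearson_r`, `mae`,
#'   `mae_vector` (NA unless the matching axis column exists), `p_value`.
#' @export
compare_real_synthetic <- function(real, synthetic, quantity = "sia_magnitude",
                                   test = c("wilcoxon", "t")) {
  test <- match.arg(test)
  if (nrow(real) != nrow(synthetic)) abort("collections must have equal length, matched by eye")
  x <- real[[quantity]]
  y <- synthetic[[quantity]]
  if (is.null(x) || is.null(y)) abort(sprintf("no column `%s`", quantity))
  r <- stats::cor(x, y)
  mae <- mean(abs(x - y))
  axis_col <- sub("_magnitude$", "_axis", quantity)
  mae_vec <- NA_real_
  if (axis_col != quantity && axis_col %in% names(real) && axis_col %in% names(synthetic)) {
    da_r <- to_double_angle(tibble(magnitude = x, axis = real[[axis_col]]))
    da_s <- to_double_angle(tibble(magnitude = y, axis = synthetic[[axis_col]]))
    mae_vec <- mean(sqrt((da_r$da_x - da_s$da_x)^2 + (da_r$da_y - da_s$da_y)^2))
  }
  p <- if (isTRUE(all.equal(x, y))) 1 else if (test == "wilcoxon") {
    suppressWarnings(stats::wilcox.test(x, y, paired = TRUE)$p.value)
  } else {
    stats::t.test(x, y, paired = TRUE)$p.value
  }
  tibble(quantity = quantity, n = length(x), pearson_r = r, mae = mae,
         mae_vector = mae_vec, p_value = p)
}

#' Single-angle polar plot of astigmatism vectors
#'
#' The conventional per-eye scatter of outcome magnitude against axis on a
#' half-polar plot, with the double-angle centroid (the cohort mean vector)
#' overlaid.
#'
#' @param outcomes Per-eye outcome tibble.
#' @param quantity Magnitude column, e.g. `"dv_magnitude"`; the matching
#'   `_axis` column must exist.
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_single_angle <- function(outcomes, quantity = "dv_magnitude", title = NULL) {
  if (nrow(outcomes) == 0L) abort("no outcomes to plot")
  axis_col <- sub("_magnitude$", "_axis", quantity)
  df <- tibble(magnitude = outcomes[[quantity]], axis = outcomes[[axis_col]])
  centroid <- from_double_angle(tibble(
    da_x = mean(to_double_angle(df)$da_x),
    da_y = mean(to_double_angle(df)$da_y)
  ))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$axis, y = .data$magnitude)) +
    ggplot2::geom_point(alpha = 0.6, colour = "#2A6BD6") +
    ggplot2::geom_point(data = centroid,
                        ggplot2::aes(x = .data$axis, y = .data$magnitude),
                        colour = "#C71F1F", shape = 17, size = 3) +
    ggplot2::coord_polar(theta = "x", start = -pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(limits = c(0, 360),
                                breaks = seq(0, 330, 30)) +
    ggplot2::labs(x = "axis (degrees)", y = "magnitude (D)", title = title) +
    ggplot2::theme_minimal()
}

#' Scatter plot of real versus synthetic magnitudes
#'
#' @inheritParams compare_real_synthetic
#' @param title Optional title.
#' @return A ggplot object with the identity line and the Pearson r annotated.
#' @export
plot_agreement <- function(real, synthetic, quantity = "sia_magnitude", title = NULL) {
  df <- tibble(real = real[[quantity]], synthetic = synthetic[[quantity]])
  r <- stats::cor(df$real, df$synthetic)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$real, y = .data$synthetic)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6, colour = "#2A6BD6") +
    ggplot2::annotate("text", x = -Inf, y = Inf, hjust = -0.2, vjust = 1.5,
                      label = sprintf("r = %.2f", r)) +
    ggplot2::labs(x = sprintf("real %s (D)", quantity),
                  y = sprintf("synthetic %s (D)", quantity), title = title) +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}
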