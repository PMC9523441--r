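#' Masked mean squared error
#'
#' Mean of squared differences between two planes over the masked pixels only;
#' the masked pixel count replaces the full `m * n` denominator.
#'
#' @param real,fake Numeric matrices of equal shape.
#' @param mask Logical matrix; at least one pixel must be TRUE.
#' @return A scalar.
#' @export
metric_mse <- function(real, fake, mask) {
  check_planes(real, fake, mask)
  d <- real[mask] - fake[mask]
  mean(d^2)
}

check_planes <- function(real, fake, mask) {
  if (!identical(dim(real), dim(fake)) || !identical(dim(real), dim(mask))) {
    abort("planes and mask must share the same shape")
  }
  if (!any(mask)) abort("empty mask")
  invisible(TRUE)
}

#' Masked peak signal-to-noise ratio
#'
#' `PSNR = 10 log10(MAX^2 / MSE)` in dB, with MAX the dynamic range of the
#' image data. When the planes are identical (MSE = 0) the PSNR is unbounded
#' and `Inf` is returned.
#'
#' @inheritParams metric_mse
#' @param max_value Dynamic range MAX (1 for normalised planes, 255 for 8-bit
#'   rendered rasters).
#' @return A scalar in dB (`Inf` for identical planes).
#' @export
metric_psnr <- function(real, fake, mask, max_value = 1) {
  mse <- metric_mse(real, fake, mask)
  if (mse == 0) return(Inf)
  10 * log10(max_value^2 / mse)
}

#' Masked structural similarity index
#'
#' Global mode (the default) evaluates the SSIM formula once from the moments
#' of the masked pixels —
#' `(2 mu_x mu_y + c1)(2 sigma_xy + c2) / ((mu_x^2 + mu_y^2 + c1)(sigma_x^2 + sigma_y^2 + c2))`
#' with `c1 = (0.01 MAX)^2`, `c2 = (0.03 MAX)^2` and population (1/N)
#' variances. Windowed mode computes the same statistic in square sliding
#' windows fully inside the mask and averages them, for cross-checking against
#' common practice.
#'
#' @inheritParams metric_psnr
#' @param mode `"global"` or `"windowed"`.
#' @param window_size Side of the sliding window (windowed mode only).
#' @return A scalar in `[-1, 1]`; identical planes give exactly 1.
#' @export
metric_ssim <- function(real, fake, mask, max_value = 1,
                        mode = c("global", "windowed"), window_size = 8L) {
  mode <- match.arg(mode)
  check_planes(real, fake, mask)
  c1 <- (0.01 * max_value)^2
  c2 <- (0.03 * max_value)^2
  if (mode == "global") {
    return(ssim_stat(real[mask], fake[mask], c1, c2))
  }
  n <- nrow(real)
  m <- ncol(real)
  vals <- c()
  for (i in seq_len(n - window_size + 1L)) {
    for (j in seq_len(m - window_size + 1L)) {
      ri <- i:(i + window_size - 1L)
      cj <- j:(j + window_size - 1L)
      if (all(mask[ri, cj])) {
        vals <- c(vals, ssim_stat(as.vector(real[ri, cj]),
                                  as.vector(fake[ri, cj]), c1, c2))
      }
    }
  }
  if (length(vals) == 0L) abort("no window fits inside the mask")
  mean(vals)
}

ssim_stat <- function(x, y, c1, c2) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  (2 * mx * my + c1) * (2 * cxy + c2) / ((mx^2 + my^2 + c1) * (vx + vy + c2))
}

#' Zone-wise image-quality report for a predicted map
#'
#' Scores a predicted post-operative map against the real one with masked MSE,
#' PSNR and SSIM inside central disks of the requested diameters, on
#' normalised planes by default (`MAX = 1`); a rendered-raster mode with
#' `MAX = 255` is available since published PSNR scales depend on this choice.
#'
#' @param real,fake [power_map()] objects on the same lattice.
#' @param zones Zone diameters in mm.
#' @param window Normalisation window in D used to scale both maps to
#'   `[0, 1]` before scoring.
#' @param max_value Dynamic range passed to the metrics; if 255 the
#'   normalised planes are quantised to 8-bit levels first.
#' @param ssim_mode Passed to [metric_ssim()].
#' @return A tibble with one row per zone: `zone`, `n_pixels`, `mse`, `psnr`,
#'   `psnr_infinite` flag, `ssim`.
#' @export
evaluate_pair <- function(real, fake, zones = c(1, 3, 5), window = c(30, 60),
                          max_value = 1, ssim_mode = "global") {
  stopifnot(inherits(real, "power_map"), inherits(fake, "power_map"))
  if (!identical(dim(real$values), dim(fake$values)) ||
      !isTRUE(all.equal(real$spacing, fake$spacing))) {
    abort("maps must share the same lattice")
  }
  rp <- normalize_plane(real$values, window)
  fp <- normalize_plane(fake$values, window)
  if (max_value == 255) {
    rp <- round(rp * 255); fp <- round(fp * 255)
  }
  co <- lattice_coords(nrow(rp), real$spacing)
  purrr::map_dfr(zones, function(z) {
    check_zone_fits(real, z)
    zmask <- real$mask & fake$mask & (co$r <= z / 2 + 1e-9)
    mse <- metric_mse(rp, fp, zmask)
    psnr <- metric_psnr(rp, fp, zmask, max_value)
    tibble(
      zone = z, n_pixels = sum(zmask), mse = mse,
      psnr = psnr, psnr_infinite = is.infinite(psnr),
      ssim = metric_ssim(rp, fp, zmask, max_value, ssim_mode)
    )
  })
}

normalize_plane <- function(values, window) {
  if (window[2L] <= window[1L]) abort("degenerate normalisation window")
  # scaled values first so pmin/pmax keep the matrix shape
  pmin(pmax((values - window[1L]) / (window[2L] - window[1L]), 0), 1)
}
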