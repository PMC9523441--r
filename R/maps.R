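#' @useDynLib flakmap, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang abort warn .data `%||%`
#' @importFrom tibble tibble as_tibble
NULL

# keratometric index printed on every topographer; fixed, not configurable,
# so the curvature<->power conversion stays bit-faithful
KERATOMETRIC_CONSTANT <- (1.3375 - 1) * 1000

#' Lattice geometry presets
#'
#' The measured disk has a 3.5-mm radius around the corneal apex. Two square
#' lattice layouts covering it are supported: a high-resolution 141 x 141 grid
#' at 0.05-mm spacing (the default) and a coarser 71 x 71 grid at 0.1-mm
#' spacing. Both have odd side length so the apex is a lattice point.
#'
#' @param preset `"hires"` (141 x 141, 0.05 mm) or `"coarse"` (71 x 71, 0.1 mm).
#' @return A list with elements `side`, `spacing` (mm) and `radius` (mm).
#' @export
#' @examples
#' lattice_preset("coarse")
lattice_preset <- function(preset = c("hires", "coarse")) {
  preset <- match.arg(preset)
  switch(preset,
    hires  = list(side = 141L, spacing = 0.05, radius = 3.5),
    coarse = list(side = 71L,  spacing = 0.1,  radius = 3.5)
  )
}

# x/y/r/theta coordinate matrices for a side x side lattice centred on the
# apex. theta follows ophthalmic notation: degrees counterclockwise from the
# horizontal, with row 1 at the top of the map (+y).
lattice_coords <- function(side, spacing) {
  half <- (side - 1L) / 2L
  ax <- (seq_len(side) - 1L - half) * spacing
  x <- matrix(ax, side, side, byrow = TRUE)
  y <- matrix(rev(ax), side, side, byrow = FALSE)
  r <- sqrt(x^2 + y^2)
  theta <- (atan2(y, x) * 180 / pi) %% 360
  list(x = x, y = y, r = r, theta = theta)
}

disk_mask <- function(side, spacing, radius = 3.5) {
  lattice_coords(side, spacing)$r <= radius + 1e-9
}

new_map <- function(values, spacing, mask, class, unit) {
  structure(
    list(values = values, spacing = spacing, mask = mask),
    class = c(class, "flak_map"),
    unit = unit
  )
}

validate_lattice <- function(values, mask, what) {
  if (!is.matrix(values) || nrow(values) != ncol(values)) {
    abort(sprintf("%s values must be a square matrix", what))
  }
  if (nrow(values) < 3L || nrow(values) %% 2L == 0L) {
    abort(sprintf("%s side length must be odd and >= 3 so the apex is a lattice point", what))
  }
  if (!identical(dim(mask), dim(values))) {
    abort(sprintf("%s mask must have the same dimensions as values", what))
  }
}

#' Anterior curvature map
#'
#' A square lattice of anterior radius-of-curvature values (mm) over a disk of
#' 3.5-mm radius centred on the corneal apex, with a per-point validity mask.
#' Points outside the disk are always invalid.
#'
#' @param values Square numeric matrix of radii of curvature, mm. `NA` cells
#'   are treated as unmeasured.
#' @param spacing Lattice step in mm.
#' @param mask Optional logical matrix of valid points; defaults to the
#'   3.5-mm disk minus `NA` cells.
#' @param radius Disk radius in mm (default 3.5).
#' @return An object of class `curvature_map`.
#' @export
#' @examples
#' g <- lattice_preset("coarse")
#' m <- curvature_map(matrix(7.8, g$side, g$side), g$spacing)
#' summary(range(m$values[m$mask]))
curvature_map <- function(values, spacing, mask = NULL, radius = 3.5) {
  values <- as.matrix(values)
  if (length(values) == 0L) abort("curvature map has no cells")
  if (is.null(mask)) mask <- !is.na(values)
  mask <- mask & disk_mask(nrow(values), spacing, radius) & !is.na(values)
  validate_lattice(values, mask, "curvature_map")
  if (any(values[mask] <= 0)) {
    idx <- which(mask & values <= 0, arr.ind = TRUE)[1L, ]
    abort(sprintf("radius of curvature must be positive; offending lattice index [%d, %d]",
                  idx[1L], idx[2L]))
  }
  new_map(values, spacing, mask, "curvature_map", "mm")
}

#' Keratometric power map
#'
#' Same lattice as [curvature_map()], holding refractive power in diopters
#' after the keratometric conversion `Dpt = (1.3375 - 1) * 1000 / R`.
#'
#' @inheritParams curvature_map
#' @param values Square numeric matrix of powers, diopters.
#' @return An object of class `power_map`.
#' @export
power_map <- function(values, spacing, mask = NULL, radius = 3.5) {
  values <- as.matrix(values)
  if (length(values) == 0L) abort("power map has no cells")
  if (is.null(mask)) mask <- !is.na(values)
  mask <- mask & disk_mask(nrow(values), spacing, radius) & !is.na(values)
  validate_lattice(values, mask, "power_map")
  new_map(values, spacing, mask, "power_map", "D")
}

#' @export
print.flak_map <- function(x, ...) {
  side <- nrow(x$values)
  extent <- (side - 1) / 2 * x$spacing
  cat(sprintf("<%s> %d x %d lattice, %.3g-mm step (+/- %.2f mm), %d valid points\n",
              class(x)[1L], side, side, x$spacing, extent, sum(x$mask)))
  rng <- range(x$values[x$mask])
  cat(sprintf("  valid range: %.3f to %.3f %s\n", rng[1L], rng[2L], attr(x, "unit")))
  invisible(x)
}

#' Convert a map to a tidy tibble
#'
#' One row per lattice point with apex-centred coordinates, polar coordinates
#' (ophthalmic angle convention), the value and the validity flag.
#'
#' @param x A `curvature_map` or `power_map`.
#' @param ... Unused.
#' @return A tibble with columns `row`, `col`, `x`, `y`, `r`, `theta`,
#'   `value`, `valid`.
#' @export
as_tibble.flak_map <- function(x, ...) {
  co <- lattice_coords(nrow(x$values), x$spacing)
  tibble(
    row = rep(seq_len(nrow(x$values)), times = ncol(x$values)),
    col = rep(seq_len(ncol(x$values)), each = nrow(x$values)),
    x = as.vector(co$x), y = as.vector(co$y),
    r = as.vector(co$r), theta = as.vector(co$theta),
    value = as.vector(x$values), valid = as.vector(x$mask)
  )
}

# bilinear interpolation of map values at apex-centred (xq, yq) points, in mm.
# Invalid neighbours are dropped with weight renormalisation; a query whose
# four neighbours are all invalid returns NA.
interp_bilinear <- function(map, xq, yq) {
  side <- nrow(map$values)
  half <- (side - 1) / 2
  # column index grows with x; row index decreases with y
  cf <- xq / map$spacing + half + 1
  rf <- half + 1 - yq / map$spacing
  c0 <- pmax(1L, pmin(side - 1L, floor(cf)))
  r0 <- pmax(1L, pmin(side - 1L, floor(rf)))
  dc <- cf - c0
  dr <- rf - r0
  v <- map$values
  m <- map$mask
  idx <- function(r, c) (c - 1L) * side + r
  w00 <- (1 - dr) * (1 - dc); i00 <- idx(r0, c0)
  w01 <- (1 - dr) * dc;       i01 <- idx(r0, c0 + 1L)
  w10 <- dr * (1 - dc);       i10 <- idx(r0 + 1L, c0)
  w11 <- dr * dc;             i11 <- idx(r0 + 1L, c0 + 1L)
  wm00 <- w00 * m[i00]; wm01 <- w01 * m[i01]
  wm10 <- w10 * m[i10]; wm11 <- w11 * m[i11]
  wt <- wm00 + wm01 + wm10 + wm11
  num <- wm00 * v[i00] + wm01 * v[i01] + wm10 * v[i10] + wm11 * v[i11]
  out <- num / wt
  out[wt <= 0] <- NA_real_
  out
}

# bilinear resize of a plain matrix to out_side x out_side, preserving the
# physical extent (corner-aligned sampling)
resize_plane <- function(values, out_side) {
  side <- nrow(values)
  if (side == out_side) return(values)
  pos <- seq(1, side, length.out = out_side)
  p0 <- pmin(side - 1L, floor(pos))
  d <- pos - p0
  # rows
  a <- values[p0, , drop = FALSE] * (1 - d) + values[p0 + 1L, , drop = FALSE] * d
  # cols
  b <- a[, p0, drop = FALSE] * matrix(1 - d, out_side, out_side, byrow = TRUE) +
    a[, p0 + 1L, drop = FALSE] * matrix(d, out_side, out_side, byrow = TRUE)
  b
}

# run code with a local, restorable RNG state; all package randomness flows
# through explicit seeds so no call disturbs the caller's stream
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

canonical_axis <- function(axis) {
  a <- axis %% 180
  a[a < 0] <- a[a < 0] + 180
  a
}
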