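#' Arcuate-keratotomy surgical plan
#'
#' Describes one or two arc incisions placed on the optical zone: each arc has
#' an angular length and a centre axis on the full circle. Paired arcs sit
#' 180 degrees apart. Incision diameter and depth are held fixed in this
#' procedure family (8.0-mm optical zone, 90% depth) and are carried as
#' metadata only.
#'
#' @param arc_lengths Numeric vector (length 1 or 2) of arc lengths, degrees,
#'   each in `[25, 65]`.
#' @param axis Centre axis of the (first) arc, degrees in `[0, 360)`.
#' @param paired If `TRUE`, a second identical arc is placed at
#'   `axis + 180`. Alternatively pass two `arc_lengths` with `axes`.
#' @param axes Optional explicit per-arc axes (overrides `axis`/`paired`).
#' @param optical_zone_mm Incision circle diameter, mm (default 8.0).
#' @param depth_fraction Incision depth as a fraction of pachymetry
#'   (default 0.90, metadata only).
#' @return An object of class `flak_plan`: a list with an `arcs` tibble
#'   (`arc_length`, `axis`), `paired`, `optical_zone_mm`, `depth_fraction`.
#' @export
#' @examples
#' flak_plan(45, axis = 90, paired = TRUE)
flak_plan <- function(arc_lengths, axis = 0, paired = FALSE, axes = NULL,
                      optical_zone_mm = 8, depth_fraction = 0.9) {
  if (is.null(axes)) {
    if (paired) {
      if (length(arc_lengths) == 1L) arc_lengths <- rep(arc_lengths, 2L)
      axes <- c(axis, axis + 180)
    } else {
      axes <- rep(axis, length(arc_lengths))
    }
  }
  if (length(arc_lengths) != length(axes)) abort("arc_lengths and axes lengths differ")
  if (length(arc_lengths) < 1L || length(arc_lengths) > 2L) {
    abort("a plan holds one or two arcs")
  }
  ok <- arc_lengths == 0 | (arc_lengths >= 25 - 1e-9 & arc_lengths <= 65 + 1e-9)
  if (!all(ok)) {
    abort("arc length outside the supported 25-65 degree range (0 marks a sham arc)")
  }
  paired <- length(arc_lengths) == 2L
  if (paired && abs(((axes[2L] - axes[1L]) %% 360) - 180) > 1e-6) {
    abort("paired arcs must be 180 degrees apart")
  }
  structure(
    list(
      arcs = tibble(arc_length = as.numeric(arc_lengths),
                    axis = as.numeric(axes) %% 360),
      paired = paired,
      optical_zone_mm = optical_zone_mm,
      depth_fraction = depth_fraction
    ),
    class = "flak_plan"
  )
}

#' @export
print.flak_plan <- function(x, ...) {
  cat(sprintf("<flak_plan> %s, %.1f-mm optical zone, depth %.0f%%\n",
              if (x$paired) "paired arcs" else "single arc",
              x$optical_zone_mm, 100 * x$depth_fraction))
  for (i in seq_len(nrow(x$arcs))) {
    cat(sprintf("  arc %d: %.1f degrees at axis %.1f\n", i,
                x$arcs$arc_length[i], x$arcs$axis[i]))
  }
  invisible(x)
}

total_arc_degrees <- function(plan) sum(plan$arcs$arc_length)

#' Normalise a power map to the unit interval
#'
#' Linear map of diopters onto `[0, 1]` over a fixed window, clipped outside;
#' invalid lattice points become 0. The window is attached to the result so
#' predictions can be inverted exactly back to diopters.
#'
#' @param map A [power_map()].
#' @param window `(lo, hi)` in D (default `c(30, 60)`, the physiologic range).
#' @return A numeric matrix in `[0, 1]` with attributes `window` and `mask`.
#' @export
normalize_curvature <- function(map, window = c(30, 60)) {
  stopifnot(inherits(map, "power_map"))
  if (window[2L] <= window[1L]) abort("degenerate normalisation window")
  plane <- normalize_plane(map$values, window)
  plane[!map$mask] <- 0
  attr(plane, "window") <- window
  attr(plane, "mask") <- map$mask
  plane
}

#' Invert [normalize_curvature()]
#'
#' @param plane Matrix in `[0, 1]`.
#' @param window The window the plane was normalised with.
#' @param mask Validity mask for the output map.
#' @param spacing Lattice step, mm.
#' @return A [power_map()].
#' @export
denormalize_curvature <- function(plane, window, mask, spacing) {
  vals <- window[1L] + plane * (window[2L] - window[1L])
  power_map(vals, spacing, mask = mask)
}

#' Constant age plane
#'
#' Age is a scalar; to feed it to a convolutional model it is normalised to
#' `[0, 1]` and upsampled to a constant lattice-shaped plane.
#'
#' @param age Age in years.
#' @param lattice A lattice spec (list with `side`), e.g. from
#'   [lattice_preset()].
#' @param range Normalisation range in years (default `c(20, 90)`, covering
#'   the adult cataract-surgery population; ages outside are clipped).
#' @return A constant matrix in `[0, 1]`.
#' @export
age_plane <- function(age, lattice = lattice_preset(), range = c(20, 90)) {
  if (range[2L] <= range[1L]) abort("degenerate age range")
  v <- min(1, max(0, (age - range[1L]) / (range[2L] - range[1L])))
  matrix(v, lattice$side, lattice$side)
}

#' Rasterise the incision plan as a binary plane
#'
#' Draws each planned arc as a binary band: angular extent equal to the arc
#' length centred on the arc's axis, radial extent a thin band around the
#' placement radius. The 8.0-mm optical zone lies outside the 7.0-mm measured
#' disk, so two placements are supported: `"edge"` (default) draws the band at
#' the outermost valid annulus of the lattice, keeping the incision visible to
#' the model; `"clip"` draws at the true `optical_zone_mm / 2` radius clipped
#' to the lattice (empty when fully off-lattice).
#'
#' @param plan A [flak_plan()].
#' @param lattice Lattice spec with `side`, `spacing`, `radius`.
#' @param thickness Radial band thickness, mm; default three lattice steps
#'   (0.15 mm on the high-resolution preset) — thick enough to stay visible
#'   to small convolution kernels, and to survive resampling to the model's
#'   working resolution, without dominating the plane.
#' @param placement `"edge"` or `"clip"`.
#' @return A binary (0/1) matrix.
#' @export
#' @examples
#' p <- render_incision_map(flak_plan(45, axis = 90, paired = TRUE),
#'                          lattice_preset("coarse"))
#' mean(p)  # small nonzero fraction
render_incision_map <- function(plan, lattice = lattice_preset(),
                                thickness = 3 * lattice$spacing,
                                placement = c("edge", "clip")) {
  placement <- match.arg(placement)
  stopifnot(inherits(plan, "flak_plan"))
  if (nrow(plan$arcs) == 0L) abort("plan has no arcs")
  co <- lattice_coords(lattice$side, lattice$spacing)
  r_target <- plan$optical_zone_mm / 2
  r_max <- lattice$radius
  if (placement == "edge") {
    r_outer <- r_max
    r_inner <- r_max - thickness
  } else {
    r_outer <- min(r_target + thickness / 2, r_max)
    r_inner <- r_target - thickness / 2
  }
  plane <- matrix(0, lattice$side, lattice$side)
  in_band <- co$r >= r_inner & co$r <= r_outer & co$r <= r_max + 1e-9
  for (i in seq_len(nrow(plan$arcs))) {
    half <- plan$arcs$arc_length[i] / 2
    delta <- (co$theta - plan$arcs$axis[i] + 180) %% 360 - 180
    plane[in_band & abs(delta) <= half] <- 1
  }
  plane
}

#' Assemble the three-channel model input
#'
#' Stacks, in a fixed documented order, (1) the normalised pre-operative
#' power plane, (2) the constant normalised age plane, and (3) the binary
#' incision plane, all on the same lattice.
#'
#' @param preop A [power_map()] (pre-operative).
#' @param age Age in years.
#' @param plan A [flak_plan()].
#' @param window Power normalisation window, D.
#' @param age_range Age normalisation range, years.
#' @param incision_placement Passed to [render_incision_map()].
#' @return A `side x side x 3` array of class `model_input` with channels
#'   named `curvature`, `age`, `incision`; the normalisation window, age
#'   range and mask are attached as attributes.
#' @export
assemble_input <- function(preop, age, plan, window = c(30, 60),
                           age_range = c(20, 90),
                           incision_placement = "edge") {
  stopifnot(inherits(preop, "power_map"))
  side <- nrow(preop$values)
  lattice <- list(side = side, spacing = preop$spacing, radius = 3.5)
  curv <- normalize_curvature(preop, window)
  agep <- age_plane(age, lattice, age_range)
  inci <- render_incision_map(plan, lattice, placement = incision_placement)
  if (!all(dim(agep) == c(side, side)) || !all(dim(inci) == c(side, side))) {
    abort("channel shape mismatch")
  }
  x <- array(0, c(side, side, 3L))
  x[, , 1L] <- curv
  x[, , 2L] <- agep
  x[, , 3L] <- inci
  dimnames(x) <- list(NULL, NULL, c("curvature", "age", "incision"))
  structure(x, class = "model_input", window = window, age_range = age_range,
            mask = preop$mask, spacing = preop$spacing)
}
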