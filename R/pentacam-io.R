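#' Read a Pentacam-style raw curvature grid
#'
#' Parses a plain-text CSV export holding one lattice row of anterior radii of
#' curvature (mm) per line. Empty cells and sentinel values mark points outside
#' the measured disk or dropped by the instrument's quality check; they become
#' invalid in the returned map's mask. Export dialects vary by locale, so the
#' delimiter and decimal mark are configurable.
#'
#' @param path Path to the CSV file.
#' @param delim Field delimiter (default `","`; locales using comma decimals
#'   typically export with `";"`).
#' @param decimal Decimal mark, `"."` or `","`.
#' @param sentinels Character vector of cell contents treated as invalid
#'   (default empty string and `"0"`, both seen in real exports).
#' @param spacing Lattice step in mm. If `NULL`, inferred from the side
#'   length: 141 lines read as the 0.05-mm layout, 71 as the 0.1-mm layout;
#'   otherwise spacing must be given.
#' @return A [curvature_map()].
#' @export
#' @examples
#' g <- lattice_preset("coarse")
#' m <- curvature_map(matrix(7.8, g$side, g$side), g$spacing)
#' p <- tempfile(fileext = ".csv")
#' write_curvature_csv(m, p)
#' m2 <- read_curvature_csv(p)
#' all.equal(m$values[m$mask], m2$values[m2$mask])
read_curvature_csv <- function(path, delim = ",", decimal = ".",
                               sentinels = c("", "0"), spacing = NULL) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) abort("empty curvature file")
  # trailing delimiter keeps a final empty (sentinel) field from being dropped
  cells <- strsplit(paste0(lines, delim), delim, fixed = TRUE)
  ncell <- lengths(cells)
  if (length(unique(ncell)) != 1L) {
    bad <- which(ncell != ncell[1L])[1L]
    abort(sprintf("malformed grid: row %d has %d cells, expected %d",
                  bad, ncell[bad], ncell[1L]))
  }
  if (ncell[1L] != length(lines)) {
    abort(sprintf("malformed grid: %d rows by %d columns is not square",
                  length(lines), ncell[1L]))
  }
  flat <- trimws(unlist(cells))
  invalid <- flat %in% sentinels
  if (decimal != ".") flat <- gsub(decimal, ".", flat, fixed = TRUE)
  num <- suppressWarnings(as.numeric(flat))
  num[invalid] <- NA_real_
  if (anyNA(num[!invalid])) {
    bad <- which(!invalid & is.na(num))[1L]
    row <- ((bad - 1L) %/% ncell[1L]) + 1L
    abort(sprintf("malformed grid: non-numeric cell in row %d", row))
  }
  side <- length(lines)
  values <- matrix(num, side, side, byrow = TRUE)
  if (is.null(spacing)) {
    spacing <- switch(as.character(side), "141" = 0.05, "71" = 0.1,
                      abort(sprintf("cannot infer spacing for a %d-line grid; pass `spacing`", side)))
  }
  if (all(is.na(values))) abort("curvature grid contains no valid cells")
  curvature_map(values, spacing)
}

#' Write a curvature map as a raw CSV grid
#'
#' Emits the same plain-text grid layout that [read_curvature_csv()] parses;
#' invalid points are written as the first sentinel so the mask round-trips.
#'
#' @param map A [curvature_map()].
#' @param path Output path.
#' @inheritParams read_curvature_csv
#' @param digits Significant digits to print (default 9, enough for exact
#'   round-trip of instrument-scale values).
#' @return `path`, invisibly.
#' @export
write_curvature_csv <- function(map, path, delim = ",", decimal = ".",
                                sentinels = c("", "0"), digits = 9L) {
  stopifnot(inherits(map, "curvature_map"))
  if (length(map$values) == 0L) abort("refusing to write an empty map")
  txt <- matrix(formatC(map$values, digits = digits, format = "g"),
                nrow(map$values), ncol(map$values))
  if (decimal != ".") txt[] <- gsub(".", decimal, txt, fixed = TRUE)
  txt[!map$mask] <- sentinels[1L]
  con <- tryCatch(file(path, "w"), error = function(e) {
    abort(sprintf("cannot open %s for writing: %s", path, conditionMessage(e)))
  })
  on.exit(close(con))
  writeLines(apply(txt, 1L, paste, collapse = delim), con)
  invisible(path)
}

#' Curvature to keratometric power
#'
#' Applies the keratometric conversion `Dpt = (1.3375 - 1) * 1000 / R` with R
#' in mm, point-wise over the valid lattice. The mask is carried through
#' unchanged.
#'
#' @param map A [curvature_map()].
#' @return A [power_map()] on the same lattice.
#' @export
#' @examples
#' g <- lattice_preset("coarse")
#' p <- curvature_to_power(curvature_map(matrix(7.5, g$side, g$side), g$spacing))
#' p$values[36, 36]  # 337.5 / 7.5 = 45 D
curvature_to_power <- function(map) {
  stopifnot(inherits(map, "curvature_map"))
  bad <- map$mask & map$values <= 0
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    abort(sprintf("non-positive radius at lattice index [%d, %d]", idx[1L], idx[2L]))
  }
  vals <- map$values
  vals[map$mask] <- KERATOMETRIC_CONSTANT / vals[map$mask]
  power_map(vals, map$spacing, mask = map$mask)
}

#' Keratometric power to curvature
#'
#' Inverse of [curvature_to_power()]: `R = 337.5 / Dpt`, needed to emit
#' predicted maps in the instrument's native curvature format.
#'
#' @param map A [power_map()].
#' @return A [curvature_map()] on the same lattice.
#' @export
power_to_curvature <- function(map) {
  stopifnot(inherits(map, "power_map"))
  bad <- map$mask & map$values <= 0
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    abort(sprintf("non-positive power at lattice index [%d, %d]", idx[1L], idx[2L]))
  }
  vals <- map$values
  vals[map$mask] <- KERATOMETRIC_CONSTANT / vals[map$mask]
  curvature_map(vals, map$spacing, mask = map$mask)
}

#' Pseudo-colour axial map colour scale
#'
#' A stepped diverging diopter-to-colour lookup approximating the familiar
#' instrument rendering: cool colours for flat powers, warm for steep, in
#' fixed steps. Purely cosmetic and fully configurable.
#'
#' @param limits Power range in diopters mapped across the palette.
#' @param step Contour step in diopters (default 0.5).
#' @return A list with `limits`, `step`, `breaks` and hex `colors` (one per bin).
#' @export
axial_color_scale <- function(limits = c(35, 52), step = 0.5) {
  if (step <= 0 || limits[2L] <= limits[1L]) abort("invalid colour scale configuration")
  breaks <- seq(limits[1L], limits[2L], by = step)
  n <- length(breaks) + 1L
  pal <- grDevices::colorRampPalette(
    c("#3A26A1", "#2A6BD6", "#27AEE0", "#3FC48E", "#8BD449",
      "#E8E33A", "#F5A623", "#EF5A28", "#C71F1F", "#8E0F52"))(n)
  list(limits = limits, step = step, breaks = breaks, colors = pal)
}

#' Render a pseudo-colour axial power map
#'
#' Fixed, deterministic diopter-to-colour lookup over the valid disk; invalid
#' points are rendered as the background colour. The raster can be written as
#' a PNG.
#'
#' @param map A [power_map()].
#' @param scale Colour scale from [axial_color_scale()].
#' @param background Background colour for invalid points.
#' @param file Optional PNG path; if given the raster is written there.
#' @return An `height x width x 3` RGB array in `[0, 1]` (invisibly if `file`
#'   is given).
#' @export
render_axial_map <- function(map, scale = axial_color_scale(),
                             background = "#303030", file = NULL) {
  stopifnot(inherits(map, "power_map"))
  if (!any(map$mask)) abort("map has no valid points to render")
  bin <- findInterval(map$values, scale$breaks) + 1L
  bin[!map$mask] <- NA_integer_
  cols <- scale$colors[bin]
  cols[is.na(cols)] <- background
  rgb <- grDevices::col2rgb(cols) / 255
  side <- nrow(map$values)
  img <- array(0, c(side, side, 3L))
  for (k in 1:3) img[, , k] <- matrix(rgb[k, ], side, side)
  if (!is.null(file)) {
    png::writePNG(img, file)
    return(invisible(img))
  }
  img
}

#' Plot a map as a ggplot raster
#'
#' @param object A `power_map` or `curvature_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.flak_map <- function(object, ...) {
  df <- as_tibble(object)
  df$value[!df$valid] <- NA_real_
  lab <- if (inherits(object, "power_map")) "power (D)" else "radius (mm)"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradientn(
      colours = axial_color_scale()$colors, na.value = "grey20", name = lab) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
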