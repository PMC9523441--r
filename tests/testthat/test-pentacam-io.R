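test_that("curvature/power conversion follows the keratometric formula and inverts", {
  m <- uniform_curvature(7.5)
  p <- curvature_to_power(m)
  expect_equal(p$values[m$mask], rep(45, sum(m$mask)))

  m2 <- uniform_curvature(6.75)
  expect_equal(curvature_to_power(m2)$values[m2$mask], rep(50, sum(m2$mask)))

  # algebraic inverse on random maps, and order reversal
  for (seed in 1:5) {
    rm <- random_curvature(seed)
    back <- power_to_curvature(curvature_to_power(rm))
    expect_lt(max(abs(back$values[rm$mask] - rm$values[rm$mask])), 1e-9)
    expect_identical(back$mask, rm$mask)
  }
  p1 <- curvature_to_power(uniform_curvature(7.0))
  p2 <- curvature_to_power(uniform_curvature(8.0))
  expect_true(all(p1$values[p1$mask] > p2$values[p2$mask]))
})

test_that("unit cases of the conversion", {
  g <- lattice_preset("coarse")
  p <- power_map(matrix(337.5, g$side, g$side), g$spacing)
  expect_equal(power_to_curvature(p)$values[p$mask], rep(1, sum(p$mask)))
})

test_that("non-positive values are rejected with the lattice index", {
  g <- lattice_preset("coarse")
  vals <- matrix(7.5, g$side, g$side)
  vals[36, 36] <- -1
  expect_error(curvature_map(vals, g$spacing), "\\[36, 36\\]")
})

test_that("csv round-trip preserves values and mask", {
  m <- random_curvature(3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_curvature_csv(m, path)
  m2 <- read_curvature_csv(path)
  expect_equal(m2$values[m2$mask], m$values[m$mask])
  expect_identical(m2$mask, m$mask)
  # corners outside the disk come back invalid
  expect_false(m2$mask[1, 1])
  expect_false(m2$mask[coarse_grid$side, coarse_grid$side])
})

test_that("semicolon/comma-decimal dialect round-trips", {
  m <- random_curvature(4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_curvature_csv(m, path, delim = ";", decimal = ",")
  m2 <- read_curvature_csv(path, delim = ";", decimal = ",")
  expect_equal(m2$values[m2$mask], m$values[m$mask], tolerance = 1e-8)
})

test_that("malformed grids are rejected with the offending row", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("7.5,7.5,7.5", "7.5,7.5", "7.5,7.5,7.5"), path)
  expect_error(read_curvature_csv(path, spacing = 0.1), "row 2")
  writeLines(c("7.5,xx,7.5", "7.5,7.5,7.5", "7.5,7.5,7.5"), path)
  expect_error(read_curvature_csv(path, spacing = 0.1), "row 1")
  writeLines(c("0,0", "0,0"), path)
  expect_error(read_curvature_csv(path, spacing = 0.1), "no valid cells")
})

test_that("sentinel cells map to invalid points", {
  path <- withr::local_tempfile(fileext = ".csv")
  g <- lattice_preset("coarse")
  m <- uniform_curvature()
  m$mask[36, 40] <- FALSE
  write_curvature_csv(m, path)
  m2 <- read_curvature_csv(path)
  expect_false(m2$mask[36, 40])
  expect_equal(sum(m2$mask), sum(m$mask))
})

test_that("a 141-line grid reads as the high-resolution layout", {
  m <- random_curvature(5, preset = "hires")
  path <- withr::local_tempfile(fileext = ".csv")
  write_curvature_csv(m, path)
  m2 <- read_curvature_csv(path)
  expect_identical(dim(m2$values), c(141L, 141L))
  expect_equal(m2$spacing, 0.05)
})

test_that("rendering is deterministic and reflects the toric pattern", {
  pm <- uniform_power(43)
  img1 <- render_axial_map(pm)
  img2 <- render_axial_map(pm)
  expect_identical(img1, img2)
  # constant map: a single colour inside the disk
  center_px <- img1[36, 36, ]
  off <- img1[36, 50, ]
  expect_identical(center_px, off)

  # toric map: warm (steep) colours along the steep meridian, byte-identical
  # PNG on re-render
  tm <- synthetic_toric_power(41, 47, 90, preset = "coarse")
  f1 <- withr::local_tempfile(fileext = ".png")
  f2 <- withr::local_tempfile(fileext = ".png")
  render_axial_map(tm, file = f1)
  render_axial_map(tm, file = f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  img <- render_axial_map(tm)
  # mean red channel along steep (vertical) vs flat (horizontal) meridian
  steep_red <- mean(img[c(10:30, 42:62), 36, 1])
  flat_red <- mean(img[36, c(10:30, 42:62), 1])
  expect_gt(steep_red, flat_red)
  expect_error(render_axial_map(power_map(matrix(NA_real_, 71, 71), 0.1,
                                          mask = matrix(FALSE, 71, 71))),
               "no valid")
})

test_that("degenerate maps are rejected", {
  expect_error(curvature_map(matrix(numeric(0), 0, 0), 0.1), "no cells")
  expect_error(curvature_map(matrix(7.5, 4, 4), 0.1), "odd")
})
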