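test_that("calibration rescaling gives 1 um pixels without interpolating indices", {
  m <- matrix(seq_len(1000 * 400), 400, 1000)
  out <- rescale_unit_pixels(m, 0.975)
  expect_equal(ncol(out), 975L)
  expect_equal(nrow(out), 390L)
  expect_true(all(out %in% m)) # nearest neighbour: values only copied
  expect_identical(rescale_unit_pixels(m, 1), m)
  # aspect ratio preserved to within a pixel
  expect_lt(abs(ncol(out) / nrow(out) - 1000 / 400), 0.01)
})

test_that("background masking invalidates exactly the outside", {
  h <- matrix(31.1, 8, 8)
  grid <- heightgrid(h, valid = matrix(TRUE, 8, 8), px_um = 1, Z = 31.1)
  fp <- matrix(FALSE, 8, 8); fp[3:6, 3:6] <- TRUE
  masked <- mask_background(grid, fp)
  expect_false(masked$valid[1, 1])
  expect_equal(masked$heights[4, 4], 31.1) # inside unchanged
  full <- mask_background(grid, matrix(TRUE, 8, 8))
  expect_identical(full$valid, grid$valid)
  expect_error(mask_background(grid, matrix(FALSE, 8, 8)), "no valid")
})

test_that("aperture mask is filled minus unfilled", {
  ann <- disc_image(15, dim_px = 50, hole_r = 5)
  filled <- extract_outline(ann, 0.18, fill_holes = TRUE)
  unfilled <- extract_outline(ann, 0.18, fill_holes = FALSE)
  ap <- aperture_mask(filled, unfilled)
  ctr <- (50 + 1) / 2
  g <- expand.grid(r = 1:50, c = 1:50)
  hole <- matrix((g$r - ctr)^2 + (g$c - ctr)^2 <= 5^2, 50, 50)
  expect_identical(ap, hole)
  # no hole -> empty mask
  solid <- extract_outline(disc_image(15, dim_px = 50), 0.18, fill_holes = TRUE)
  solid_u <- extract_outline(disc_image(15, dim_px = 50), 0.18,
                             fill_holes = FALSE)
  expect_false(any(aperture_mask(solid, solid_u)))
})

test_that("quartile filter matches its literal definition", {
  # 3x3 window: eight 10s and a focal 100 -> replaced by the mean 20
  h <- matrix(10, 3, 3); h[2, 2] <- 100
  grid <- heightgrid(h, valid = matrix(TRUE, 3, 3), px_um = 1)
  out <- outlier_filter(grid, n = 3L)
  expect_equal(out$heights[2, 2], 20)
  expect_equal(out$heights[1, 1], 10) # 10 = Q1 = Q3: unchanged

  # all-equal window: untouched
  flat <- heightgrid(matrix(7, 5, 5), valid = matrix(TRUE, 5, 5), px_um = 1)
  expect_equal(outlier_filter(flat, 3L)$heights, matrix(7, 5, 5))

  expect_error(outlier_filter(grid, n = 4L), "odd")
  expect_error(outlier_filter(grid, n = 1L), "odd|>= 3")

  # randomized grids against the loop oracle, with and without mask,
  # continuous values (generic path) and quantized values (counting path)
  for (seed in 1:4) {
    set.seed(seed)
    nr <- sample(6:12, 1); nc <- sample(6:12, 1)
    h1 <- matrix(runif(nr * nc, 0, 100), nr, nc)
    v1 <- matrix(runif(nr * nc) > 0.2, nr, nc)
    v1[1, 1] <- TRUE
    g1 <- heightgrid(ifelse(v1, h1, NA), v1, px_um = 1)
    expect_equal(outlier_filter(g1, 5L)$heights,
                 oracle_quartile_filter(ifelse(v1, h1, NA), v1, 5L))
    h2 <- matrix(sample(0:5, nr * nc, replace = TRUE) * 31.1, nr, nc)
    g2 <- heightgrid(ifelse(v1, h2, NA), v1, px_um = 1)
    expect_equal(outlier_filter(g2, 5L)$heights,
                 oracle_quartile_filter(ifelse(v1, h2, NA), v1, 5L))
  }
})

test_that("filtered heights never leave the pre-filter range", {
  for (seed in 1:10) {
    set.seed(seed)
    h <- matrix(sample(0:30, 400, replace = TRUE) * 31.1, 20, 20)
    v <- matrix(runif(400) > 0.1, 20, 20)
    v[10, 10] <- TRUE
    g <- heightgrid(ifelse(v, h, NA), v, px_um = 1)
    out <- outlier_filter(g, 7L)
    expect_gte(min(out$heights[out$valid]), min(h[v]))
    expect_lte(max(out$heights[out$valid]), max(h[v]))
  }
})

test_that("z-level pruning drops sparse levels and the bottom", {
  Z <- 31.1
  # ~1000 valid px: 5 at level 9 (0.5% -> dropped), 20 at level 8 (2% ->
  # kept), bottom level 1 dropped regardless of its count
  h <- matrix(3 * Z, 32, 32)          # 1024 px, mostly level 3
  h[1:5] <- 9 * Z                     # 5/1024 = 0.5%
  h[6:25] <- 8 * Z                    # 20/1024 = 2%
  h[26:225] <- 1 * Z                  # bottom level, 200 px
  grid <- heightgrid(h, valid = matrix(TRUE, 32, 32), px_um = 1, Z = Z)
  out <- prune_z_levels(grid, frac = 0.01, drop_bottom = TRUE)
  lev <- sort(unique(round(out$heights[out$valid] / Z)))
  expect_false(9 %in% lev)  # 5/1024 < 1%
  expect_true(8 %in% lev)   # 20/1024 >= 1%... (2%)
  expect_false(1 %in% lev)  # bottom level removed
  expect_true(3 %in% lev)

  no_bottom <- prune_z_levels(grid, frac = 0.01, drop_bottom = FALSE)
  expect_true(1 %in% round(no_bottom$heights[no_bottom$valid] / Z))

  expect_error(prune_z_levels(heightgrid(matrix(Z, 4, 4),
                                         matrix(TRUE, 4, 4), Z = Z)),
               "2 distinct")
})

test_that("aperture depth floors to the lowest object height", {
  Z <- 31.1
  h <- matrix(5 * Z, 10, 10)
  h[1, ] <- 3 * Z
  v <- matrix(TRUE, 10, 10)
  ap <- matrix(FALSE, 10, 10); ap[5:6, 5:6] <- TRUE
  v[ap] <- FALSE
  grid <- heightgrid(ifelse(v, h, NA), v, px_um = 1, Z = Z)
  out <- set_aperture_depth(grid, ap)
  expect_true(all(out$valid[ap]))
  expect_true(all(out$heights[ap] == 3 * Z)) # single flat level at the min
  # empty aperture: unchanged
  same <- set_aperture_depth(grid, matrix(FALSE, 10, 10))
  expect_identical(same$heights, grid$heights)
})

test_that("triangulation yields one vertex per pixel and 2 triangles per quad", {
  single <- heightgrid(matrix(c(NA, NA, 10, NA), 2, 2),
                       matrix(c(FALSE, FALSE, TRUE, FALSE), 2, 2), px_um = 1)
  m1 <- build_mesh(single)
  expect_equal(nrow(m1$vertices), 1L)
  expect_equal(nrow(m1$faces), 0L)

  quad <- heightgrid(matrix(1, 2, 2), matrix(TRUE, 2, 2), px_um = 1)
  m2 <- build_mesh(quad)
  expect_equal(nrow(m2$vertices), 4L)
  expect_equal(nrow(m2$faces), 2L)

  for (m in c(3L, 5L, 8L)) {
    g <- heightgrid(matrix(runif(m * m, 0, 50), m, m),
                    matrix(TRUE, m, m), px_um = 1)
    mesh <- build_mesh(g)
    expect_equal(nrow(mesh$vertices), m^2)
    expect_equal(nrow(mesh$faces), 2L * (m - 1L)^2)
    expect_true(all(mesh$faces >= 1L & mesh$faces <= m^2))
  }
  expect_error(build_mesh(heightgrid(matrix(NA_real_, 2, 2),
                                     matrix(FALSE, 2, 2))),
               "empty")
})

test_that("interior pixels are watertight (>= 2 incident faces)", {
  g <- heightgrid(matrix(runif(100, 0, 99), 10, 10),
                  matrix(TRUE, 10, 10), px_um = 1)
  mesh <- build_mesh(g)
  counts <- tabulate(as.vector(mesh$faces), nbins = nrow(mesh$vertices))
  interior <- as.vector(matrix(seq_len(100), 10, 10)[2:9, 2:9])
  expect_true(all(counts[interior] >= 2L))
})

test_that("meshes round-trip losslessly through OBJ, OFF and CSV", {
  g <- heightgrid(matrix(runif(36, 0, 77), 6, 6),
                  matrix(runif(36) > 0.15, 6, 6) | diag(6) > 0, px_um = 1)
  mesh <- build_mesh(g)
  for (fmt in c("obj", "off", "csv")) {
    path <- tempfile(fileext = paste0(".", fmt))
    write_mesh(mesh, path)
    back <- read_mesh(path)
    expect_identical(back$vertices, unname(mesh$vertices), label = fmt)
    if (fmt != "csv") expect_identical(back$faces, unname(mesh$faces))
    if (fmt == "csv")
      expect_equal(length(readLines(path)), nrow(mesh$vertices) + 1L)
    if (fmt == "off") {
      counts <- as.integer(strsplit(readLines(path)[2], " ")[[1]])
      expect_equal(counts[1], nrow(mesh$vertices))
      expect_equal(counts[2], nrow(mesh$faces))
    }
    unlink(path)
  }
  expect_error(write_mesh(mesh, "x.ply"), "unknown")

  # downsampling keeps every k-th grid row/column
  big <- build_mesh(heightgrid(matrix(runif(400), 20, 20),
                               matrix(TRUE, 20, 20), px_um = 1))
  path <- tempfile(fileext = ".obj")
  write_mesh(big, path, downsample = 2L)
  ds <- read_mesh(path)
  expect_equal(nrow(ds$vertices), 100L)
  unlink(path)
})
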