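test_that("analytic height fields hit their closed forms", {
  # hemispheroid: apex equals the relief
  f <- make_heightfield(shape_spec("hemispheroid", a_um = 300, relief_um = 300,
                                   center_um = c(320, 320)),
                        dim_px = c(641, 641))
  expect_equal(f$grid$heights[321, 321], 300)
  # grid-summed volume of the hemisphere within 1% of (2/3) pi r^3
  v_closed <- 2 / 3 * pi * 300^3
  expect_equal(f$truth$volume_um3, v_closed)
  v_grid <- sum(f$grid$heights[f$grid$valid])
  expect_lt(abs(v_grid - v_closed) / v_closed, 0.01)

  # cone: apex height at the centroid
  fc <- make_heightfield(shape_spec("cone", a_um = 100, relief_um = 90,
                                    center_um = c(120, 120)),
                         dim_px = c(241, 241))
  expect_equal(fc$grid$heights[121, 121], 90)
  expect_lt(abs(sum(fc$grid$heights[fc$grid$valid]) - fc$truth$volume_um3) /
              fc$truth$volume_um3, 0.005)

  expect_error(make_heightfield(shape_spec("cone", a_um = 100),
                                dim_px = c(50, 50)),
               "exceeds")
})

test_that("ground-truth volume integrates the height field within 0.5%", {
  for (spec in list(shape_spec("sphere_on_plane", a_um = 80,
                               center_um = c(100, 100)),
                    shape_spec("block", a_um = 60, b_um = 40, relief_um = 50,
                               center_um = c(100, 100)),
                    shape_spec("terraced_block", a_um = 60, b_um = 60,
                               relief_um = 90, center_um = c(100, 100)))) {
    f <- make_heightfield(spec, dim_px = c(201, 201), px_um = 1)
    v_grid <- sum(f$grid$heights[f$grid$valid])
    expect_lt(abs(v_grid - f$truth$volume_um3) / f$truth$volume_um3, 0.005)
  }
})

test_that("rendering follows the defocus model", {
  spec <- shape_spec("block", a_um = 60, b_um = 60, relief_um = 311,
                     center_um = c(90, 90))
  f <- make_heightfield(spec, dim_px = c(181, 181))
  zs <- render_zstack(f, optics(noise_sd = 0), s = 31, Z = 31.1, seed = 5)
  expect_s3_class(zs, "zstack")
  expect_length(zs$slices, 31L)

  # noise-free: a pixel at true height 311 um is sharpest on slice 10
  hm <- build_height_map(zs)
  b <- round_half_away(hm$encoded[90, 90] * 30 / 255)
  expect_equal(b, 10)

  # background is exactly 0 in every slice without noise
  expect_true(all(vapply(zs$slices, function(m) m[5, 5] == 0, logical(1L))))

  expect_error(render_zstack(f, optics(blur_coefficient = 0)), "blur")
})

test_that("noise-free focus argmax lands within one slice of round(h/Z)", {
  cs <- hemisphere_case()
  hm <- build_height_map(cs$stack)
  b <- round_half_away(hm$encoded * 30 / 255)
  fp <- cs$field$truth$footprint
  # interior: stay clear of the outline where the window mixes background
  interior <- EBImage::erode(fp * 1, EBImage::makeBrush(15, "box")) > 0
  expected <- round_half_away(cs$field$truth$heights_true / 31.1)
  dev <- abs(b - expected)[interior]
  expect_gte(mean(dev <= 1), 0.99)
})

test_that("slides compose disjoint objects and are seed-reproducible", {
  specs <- list(
    shape_spec("hemispheroid", a_um = 40, relief_um = 60, center_um = c(60, 60)),
    shape_spec("cone", a_um = 35, relief_um = 90, center_um = c(170, 60)),
    shape_spec("block", a_um = 30, b_um = 30, relief_um = 120,
               center_um = c(110, 170)))
  sl <- make_slide(specs, canvas_px = c(230, 230), optics(), seed = 3)
  expect_length(sl$truths, 3L)
  hm <- build_height_map(sl$stack)
  edf <- build_edf(sl$stack, hm)
  regions <- segment_slide(edf, threshold = 0.1)
  expect_length(regions, 3L)

  sl2 <- make_slide(specs, canvas_px = c(230, 230), optics(), seed = 3)
  expect_identical(sl$stack$slices, sl2$stack$slices)

  overlapping <- list(
    shape_spec("hemispheroid", a_um = 40, relief_um = 40, center_um = c(60, 60)),
    shape_spec("hemispheroid", a_um = 40, relief_um = 40, center_um = c(90, 60)))
  expect_error(make_slide(overlapping, c(230, 230), optics()), "overlap")

  empty <- make_slide(list(), c(40, 40), optics(noise_sd = 0), seed = 1)
  expect_true(all(vapply(empty$stack$slices, function(m) all(m == 0),
                         logical(1L))))
})

test_that("shape specs validate their invariants", {
  expect_error(shape_spec("cone", a_um = -5), "dimensions")
  expect_error(shape_spec("cone", a_um = 50, intensity = 0), "intensity")
  expect_error(shape_spec("hemispheroid", a_um = 50,
                          aperture = list(radius_um = 20,
                                          offset_um = c(40, 0))),
               "interior")
  ok <- shape_spec("hemispheroid", a_um = 50,
                   aperture = list(radius_um = 10, offset_um = c(10, 0)))
  expect_s3_class(ok, "shape_spec")
})

test_that("random binary trees are unrooted, binary and reproducible", {
  tr <- random_binary_tree(letters[1:8], seed = 2)
  expect_false(ape::is.rooted(tr))
  expect_true(ape::is.binary(tr))
  # n - 2 internal nodes, all of degree 3
  expect_equal(tr$Nnode, 8L - 2L)
  deg <- tabulate(as.vector(tr$edge))
  expect_true(all(deg[9:length(deg)] == 3L))
  expect_identical(ape::write.tree(tr),
                   ape::write.tree(random_binary_tree(letters[1:8], seed = 2)))
  expect_error(random_binary_tree(c("a", "a", "b"), seed = 1), "duplicate")
  expect_error(random_binary_tree(c("a", "b"), seed = 1), "3 labels")
  # 3 labels: the unique unrooted topology (a single internal node)
  t3 <- random_binary_tree(c("x", "y", "z"), seed = 9)
  expect_equal(t3$Nnode, 1L)
})

test_that("ground truth exports to CSV with per-object closed forms", {
  f1 <- make_heightfield(shape_spec("hemispheroid", a_um = 30, relief_um = 30,
                                    center_um = c(40, 40)), c(81, 81))
  f2 <- make_heightfield(shape_spec("sphere_on_plane", a_um = 25,
                                    center_um = c(40, 40)), c(81, 81))
  csv <- tempfile(fileext = ".csv")
  tdir <- tempfile()
  on.exit(unlink(c(csv, tdir), recursive = TRUE))
  write_ground_truth(list(f1$truth, f2$truth), csv, tiff_dir = tdir)
  df <- read.csv(csv)
  expect_equal(df$volume_um3, c(2 / 3 * pi * 30^3, 5 / 3 * pi * 25^3))
  expect_equal(df$axis_um, c(30, 50))
  expect_length(list.files(tdir, pattern = "\\.tif$"), 2L)
})

test_that("z-stacks round-trip through TIFF + YAML", {
  cs <- hemisphere_case()
  sub <- zstack(lapply(cs$stack$slices[1:3], function(m) m[1:40, 1:40]),
                Z = 31.1, px_um = 1)
  path <- withr::local_tempfile(fileext = ".tif")
  write_zstack(sub, path, bits = 16L)
  back <- read_zstack(path)
  expect_equal(back$s, 3L)
  expect_equal(back$Z, 31.1)
  expect_equal(back$slices[[2L]], sub$slices[[2L]], tolerance = 1e-4)
})
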