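#' Specify a synthetic object for stack rendering
#'
#' Describes one convex-ish shell-like object mounted on the slide plane.
#' Available kinds:
#' \describe{
#'   \item{`hemispheroid`}{half-ellipsoid, lateral semi-axes `a_um`, `b_um`,
#'     apex height `relief_um`.}
#'   \item{`sphere_on_plane`}{a full sphere of radius `a_um` resting on the
#'     slide (emulating spherical shells such as *Orbulina universa*); its
#'     top surface spans heights `a_um` (rim) to `2 a_um` (apex), so the
#'     recoverable axis length is the diameter `2 a_um`.}
#'   \item{`cone`}{elliptical base `a_um` x `b_um`, apex height `relief_um`.}
#'   \item{`block`}{rectangular footprint (half-widths `a_um`, `b_um`) of
#'     constant height `relief_um`.}
#'   \item{`terraced_block`}{same footprint in three concentric tiers at
#'     heights `relief_um`, `2/3 relief_um` and `1/3 relief_um` (useful for
#'     exercising z-level logic).}
#' }
#'
#' @param kind one of `"hemispheroid"`, `"sphere_on_plane"`, `"cone"`,
#'   `"block"`, `"terraced_block"`.
#' @param a_um,b_um lateral semi-axes in micrometres (for
#'   `sphere_on_plane`, `a_um` is the sphere radius and `b_um` is ignored).
#' @param relief_um apex height in micrometres (ignored for
#'   `sphere_on_plane`, where it equals the diameter).
#' @param center_um object centre `(x, y)` in micrometres.
#' @param intensity surface albedo in `(0, 1]`; must exceed the black
#'   background (0).
#' @param aperture optional `list(radius_um =, offset_um = c(dx, dy))`
#'   describing a circular opening rendered dark (intensity 0), strictly
#'   interior to the footprint.
#' @return an object of class `"shape_spec"`.
#' @export
shape_spec <- function(kind, a_um, b_um = a_um, relief_um = a_um,
                       center_um = c(0, 0), intensity = 0.8,
                       aperture = NULL) {
  kind <- match.arg(kind, c("hemispheroid", "sphere_on_plane", "cone",
                            "block", "terraced_block"))
  if (kind == "sphere_on_plane") {
    b_um <- a_um
    relief_um <- 2 * a_um
  }
  if (a_um <= 0 || b_um <= 0 || relief_um <= 0)
    stop("all dimensions must be > 0", call. = FALSE)
  if (intensity <= 0 || intensity > 1)
    stop("`intensity` must lie in (0, 1] and exceed the background (0)",
         call. = FALSE)
  if (!is.null(aperture)) {
    if (is.null(aperture$radius_um) || aperture$radius_um <= 0)
      stop("aperture needs a positive `radius_um`", call. = FALSE)
    if (is.null(aperture$offset_um)) aperture$offset_um <- c(0, 0)
    th <- seq(0, 2 * pi, length.out = 65L)[-65L]
    px <- aperture$offset_um[1L] + aperture$radius_um * cos(th)
    py <- aperture$offset_um[2L] + aperture$radius_um * sin(th)
    inside <- if (kind %in% c("block", "terraced_block")) {
      all(abs(px) < a_um & abs(py) < b_um)
    } else {
      all((px / a_um)^2 + (py / b_um)^2 < 1)
    }
    if (!inside)
      stop("aperture must be strictly interior to the footprint", call. = FALSE)
  }
  structure(list(kind = kind, a_um = a_um, b_um = b_um,
                 relief_um = relief_um, center_um = center_um,
                 intensity = intensity, aperture = aperture),
            class = "shape_spec")
}

#' Optical/noise model for synthetic rendering
#'
#' @param blur_coefficient Gaussian blur spread per micrometre of defocus
#'   (dimensionless, > 0): a pixel whose surface lies `d` um away from the
#'   focal plane is rendered with an isotropic Gaussian blur of
#'   `sigma = blur_coefficient * d` um.
#' @param noise_sd additive Gaussian noise standard deviation, in intensity
#'   units (>= 0).
#' @param artifact_rate per-object probability of injecting a "smear" patch:
#'   a disc rendered at a fixed blur in every slice, so that no slice is
#'   sharpest there (the pathology produced by focus-stacking failures).
#' @param texture_amp relative amplitude of the seeded speckle albedo
#'   texture. Shape-from-focus needs surface texture to detect the sharpest
#'   slice; real shells carry pores and ornament, which this emulates.
#' @param texture_scale_px correlation length of the speckle, in pixels.
#' @param artifact_radius_um radius of the smear patch.
#' @return an object of class `"optics"`.
#' @export
optics <- function(blur_coefficient = 0.05, noise_sd = 0.01,
                   artifact_rate = 0, texture_amp = 0.35,
                   texture_scale_px = 1.5, artifact_radius_um = 40) {
  if (blur_coefficient < 0) stop("`blur_coefficient` must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (artifact_rate < 0 || artifact_rate > 1)
    stop("`artifact_rate` must lie in [0, 1]", call. = FALSE)
  structure(list(blur_coefficient = blur_coefficient, noise_sd = noise_sd,
                 artifact_rate = artifact_rate, texture_amp = texture_amp,
                 texture_scale_px = texture_scale_px,
                 artifact_radius_um = artifact_radius_um),
            class = "optics")
}

# Analytic height of a shape at lateral offsets (dx, dy) um from its centre.
# Returns NA outside the footprint.
shape_height_at <- function(spec, dx, dy) {
  a <- spec$a_um
  b <- spec$b_um
  h <- rep(NA_real_, length(dx))
  if (spec$kind %in% c("block", "terraced_block")) {
    # half-open so the discrete footprint covers exactly 2a x 2b um of cells
    inside <- dx >= -a & dx < a & dy >= -b & dy < b
    if (spec$kind == "block") {
      h[inside] <- spec$relief_um
    } else {
      # three nested half-open boxes at 1/3, 2/3 and full relief
      in2 <- dx[inside] >= -2 * a / 3 & dx[inside] < 2 * a / 3 &
             dy[inside] >= -2 * b / 3 & dy[inside] < 2 * b / 3
      in3 <- dx[inside] >= -a / 3 & dx[inside] < a / 3 &
             dy[inside] >= -b / 3 & dy[inside] < b / 3
      h[inside] <- spec$relief_um * (1 + in2 + in3) / 3
    }
  } else {
    e2 <- (dx / a)^2 + (dy / b)^2
    inside <- e2 <= 1
    if (spec$kind == "hemispheroid") {
      h[inside] <- spec$relief_um * sqrt(pmax(0, 1 - e2[inside]))
    } else if (spec$kind == "cone") {
      h[inside] <- spec$relief_um * (1 - sqrt(e2[inside]))
    } else { # sphere_on_plane, a = radius
      h[inside] <- a + sqrt(pmax(0, a^2 - (dx[inside]^2 + dy[inside]^2)))
    }
  }
  h
}

# Closed-form integral of the height field over the footprint (um^3) and,
# where available, the area of the graph surface (um^2; NA otherwise).
shape_truth_closed <- function(spec) {
  a <- spec$a_um; b <- spec$b_um; c0 <- spec$relief_um
  V <- switch(spec$kind,
    hemispheroid    = 2 / 3 * pi * a * b * c0,
    sphere_on_plane = 5 / 3 * pi * a^3,
    cone            = pi * a * b * c0 / 3,
    block           = 4 * a * b * c0,
    terraced_block  = 4 * a * b * c0 * 14 / 27)
  SA <- NA_real_
  if (spec$kind == "sphere_on_plane") SA <- 2 * pi * a^2
  if (spec$kind == "hemispheroid" && isTRUE(all.equal(a, b)) &&
      isTRUE(all.equal(a, c0))) SA <- 2 * pi * a^2
  if (spec$kind == "cone" && isTRUE(all.equal(a, b)))
    SA <- pi * a * sqrt(a^2 + c0^2)
  if (spec$kind == "block") SA <- 4 * a * b
  list(volume = V, area = SA)
}

#' Sample a synthetic object's height field on a pixel grid
#'
#' Heights are the analytic surface sampled at pixel centres; the ground
#' truth records the footprint, aperture, closed-form volume/area (numeric
#' integration is unnecessary for the supported shapes) and the sharp albedo
#' image used by [render_zstack()].
#'
#' @param spec a [shape_spec()].
#' @param dim_px grid size `c(nrow, ncol)` in pixels.
#' @param px_um pixel size in micrometres.
#' @return an object of class `"synthfield"`: a list with `grid`
#'   (a [heightgrid()]) and `truth` (class `"ground_truth"` with fields
#'   `heights_true`, `footprint`, `aperture`, `volume_um3`, `area_um2`,
#'   `axis_um`, `intensity`).
#' @export
make_heightfield <- function(spec, dim_px, px_um = 1) {
  stopifnot(inherits(spec, "shape_spec"), length(dim_px) == 2L, px_um > 0)
  nr <- as.integer(dim_px[1L]); nc <- as.integer(dim_px[2L])
  # pixel centres: x along columns, y along rows
  x <- (seq_len(nc) - 1) * px_um
  y <- (seq_len(nr) - 1) * px_um
  dx <- matrix(x, nr, nc, byrow = TRUE) - spec$center_um[1L]
  dy <- matrix(y, nr, nc) - spec$center_um[2L]
  h <- matrix(shape_height_at(spec, as.vector(dx), as.vector(dy)), nr, nc)
  fp <- !is.na(h)
  if (!any(fp)) stop("footprint does not intersect the grid", call. = FALSE)
  # the analytic footprint must fit inside the grid
  ext_x <- spec$center_um[1L] + c(-1, 1) * spec$a_um
  ext_y <- spec$center_um[2L] + c(-1, 1) * spec$b_um
  if (ext_x[1L] < min(x) || ext_x[2L] > max(x) ||
      ext_y[1L] < min(y) || ext_y[2L] > max(y))
    stop("footprint exceeds the grid", call. = FALSE)
  ap <- matrix(FALSE, nr, nc)
  if (!is.null(spec$aperture)) {
    adx <- dx - spec$aperture$offset_um[1L]
    ady <- dy - spec$aperture$offset_um[2L]
    ap <- (adx^2 + ady^2 <= spec$aperture$radius_um^2) & fp
  }
  intensity <- matrix(0, nr, nc)
  intensity[fp & !ap] <- spec$intensity
  cf <- shape_truth_closed(spec)
  heights <- h
  heights[!fp] <- NA_real_
  grid <- heightgrid(heights, valid = fp, px_um = px_um)
  truth <- structure(
    list(heights_true = ifelse(fp, h, 0), footprint = fp, aperture = ap,
         volume_um3 = cf$volume, area_um2 = cf$area,
         axis_um = if (spec$kind == "sphere_on_plane") 2 * spec$a_um
                   else spec$relief_um,
         intensity = intensity),
    class = "ground_truth")
  structure(list(grid = grid, truth = truth, px_um = px_um),
            class = "synthfield")
}

# Gaussian blur of a matrix by sigma (pixels) in the Fourier domain.
# sigma = 0 returns the input. The image is assumed to carry a dark margin
# so periodic wrap is immaterial.
fft_gauss <- function(F_img, sigma, nr, nc) {
  if (sigma == 0) return(Re(stats::fft(F_img, inverse = TRUE)) / (nr * nc))
  fr <- c(0:(floor(nr / 2)), -(ceiling(nr / 2) - 1):-1) / nr
  fc <- c(0:(floor(nc / 2)), -(ceiling(nc / 2) - 1):-1) / nc
  G <- exp(-2 * pi^2 * sigma^2 *
             (matrix(fr^2, nr, nc) + matrix(fc^2, nr, nc, byrow = TRUE)))
  Re(stats::fft(F_img * G, inverse = TRUE)) / (nr * nc)
}

#' Render a synthetic z-stack from a height field
#'
#' Slice `k` (k = 1..s) is the focal plane at height `(k-1) * Z` above the
#' slide. Each footprint pixel is rendered as the object's textured albedo
#' blurred with an isotropic Gaussian of spread
#' `blur_coefficient * |h(x, y) - (k-1) Z|` (interpolated from a bank of
#' Fourier-domain blurs), background pixels are exactly 0 before noise, and
#' i.i.d. Gaussian noise is added last. Deterministic given `seed`.
#'
#' @param field a `"synthfield"` from [make_heightfield()] (or a composite
#'   built by [make_slide()]).
#' @param optics an [optics()] model; `blur_coefficient` must be > 0, or the
#'   focus argmax is undefined.
#' @param s number of slices (>= 2).
#' @param Z z-step in micrometres (> 0).
#' @param seed integer RNG seed.
#' @return a [zstack()] with slices in `[0, 1]`.
#' @export
render_zstack <- function(field, optics, s = 31L, Z = 31.1, seed = 1L) {
  stopifnot(inherits(field, "synthfield"), inherits(optics, "optics"))
  if (optics$blur_coefficient == 0)
    stop("`blur_coefficient` must be > 0: with no defocus blur the ",
         "best-focus slice is undefined", call. = FALSE)
  if (s < 2L) stop("`s` must be >= 2", call. = FALSE)
  if (Z <= 0) stop("`Z` must be > 0", call. = FALSE)
  truth <- field$truth
  px_um <- field$px_um
  fp <- truth$footprint
  nr <- nrow(fp); nc <- ncol(fp)
  idx_fp <- which(fp)
  h_fp <- truth$heights_true[idx_fp]

  with_seed(seed, {
    # textured sharp albedo
    sharp <- truth$intensity
    if (optics$texture_amp > 0 && length(idx_fp)) {
      tex <- matrix(rnorm(nr * nc), nr, nc)
      Ft <- stats::fft(tex)
      tex <- fft_gauss(Ft, optics$texture_scale_px, nr, nc)
      tex <- tex / sd(tex)
      sharp <- pmin(pmax(sharp * (1 + optics$texture_amp * tex), 0), 1)
      sharp[!fp] <- 0
      sharp[truth$intensity == 0] <- 0 # keep aperture/background dark
    }

    # bank of blurred copies on a defocus grid (um)
    maxdef <- if (length(h_fp)) max((s - 1) * Z, max(h_fp)) else (s - 1) * Z
    def_grid <- sort(unique(c(0, Z / 2, seq(Z, maxdef + Z, by = Z))))
    smear <- optics$artifact_rate > 0 && length(idx_fp) &&
      runif(1L) < optics$artifact_rate
    sig_art <- optics$blur_coefficient * 4 * Z / px_um
    Fs <- stats::fft(sharp)
    bank <- lapply(optics$blur_coefficient * def_grid / px_um,
                   function(sg) fft_gauss(Fs, sg, nr, nc))
    smear_img <- if (smear) fft_gauss(Fs, sig_art, nr, nc) else NULL
    smear_idx <- integer(0)
    if (smear) {
      ctr <- idx_fp[sample.int(length(idx_fp), 1L)]
      cr <- (ctr - 1L) %% nr + 1L
      cc <- (ctr - 1L) %/% nr + 1L
      rr <- matrix(seq_len(nr), nr, nc)
      cmat <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
      patch <- ((rr - cr)^2 + (cmat - cc)^2) * px_um^2 <=
        optics$artifact_radius_um^2
      smear_idx <- which(patch & fp)
    }

    slices <- vector("list", s)
    for (k in seq_len(s)) {
      img <- matrix(0, nr, nc)
      if (length(idx_fp)) {
        def <- abs(h_fp - (k - 1) * Z)
        j <- findInterval(def, def_grid)
        j <- pmin(j, length(def_grid) - 1L)
        w <- (def - def_grid[j]) / (def_grid[j + 1L] - def_grid[j])
        vals <- numeric(length(idx_fp))
        for (jj in unique(j)) {
          sel <- which(j == jj)
          p <- idx_fp[sel]
          vals[sel] <- bank[[jj]][p] * (1 - w[sel]) + bank[[jj + 1L]][p] * w[sel]
        }
        img[idx_fp] <- vals
        if (length(smear_idx)) img[smear_idx] <- smear_img[smear_idx]
      }
      if (optics$noise_sd > 0)
        img <- img + matrix(rnorm(nr * nc, 0, optics$noise_sd), nr, nc)
      slices[[k]] <- pmin(pmax(img, 0), 1)
    }
    zstack(slices, Z = Z, px_um = px_um)
  })
}

#' Compose several synthetic objects on one slide and render the stack
#'
#' @param specs list of [shape_spec()]s with pairwise disjoint footprints.
#' @param canvas_px canvas size `c(nrow, ncol)` in pixels.
#' @param optics an [optics()] model.
#' @param s,Z,seed as in [render_zstack()].
#' @param px_um pixel size in micrometres.
#' @return list with `stack` (a [zstack()]) and `truths` (one
#'   `"ground_truth"` per object, in input order).
#' @export
make_slide <- function(specs, canvas_px, optics, s = 31L, Z = 31.1,
                       seed = 1L, px_um = 1) {
  stopifnot(is.list(specs))
  nr <- as.integer(canvas_px[1L]); nc <- as.integer(canvas_px[2L])
  if (!length(specs)) {
    empty <- structure(
      list(grid = heightgrid(matrix(NA_real_, nr, nc),
                             valid = matrix(FALSE, nr, nc), px_um = px_um),
           truth = structure(list(heights_true = matrix(0, nr, nc),
                                  footprint = matrix(FALSE, nr, nc),
                                  aperture = matrix(FALSE, nr, nc),
                                  volume_um3 = 0, area_um2 = 0,
                                  axis_um = NA_real_,
                                  intensity = matrix(0, nr, nc)),
                             class = "ground_truth"),
           px_um = px_um),
      class = "synthfield")
    return(list(stack = render_zstack(empty, optics, s = s, Z = Z, seed = seed),
                truths = list()))
  }
  fields <- lapply(specs, make_heightfield, dim_px = c(nr, nc), px_um = px_um)
  fpsum <- Reduce(`+`, lapply(fields, function(f) f$truth$footprint * 1L))
  if (any(fpsum > 1L)) stop("overlapping footprints", call. = FALSE)
  comb_h <- Reduce(`+`, lapply(fields, function(f) f$truth$heights_true))
  comb_fp <- fpsum > 0L
  comb_ap <- Reduce(`|`, lapply(fields, function(f) f$truth$aperture))
  comb_int <- Reduce(`+`, lapply(fields, function(f) f$truth$intensity))
  heights <- comb_h
  heights[!comb_fp] <- NA_real_
  comb <- structure(
    list(grid = heightgrid(heights, valid = comb_fp, px_um = px_um),
         truth = structure(list(heights_true = comb_h, footprint = comb_fp,
                                aperture = comb_ap, volume_um3 = NA_real_,
                                area_um2 = NA_real_, axis_um = NA_real_,
                                intensity = comb_int),
                           class = "ground_truth"),
         px_um = px_um),
    class = "synthfield")
  list(stack = render_zstack(comb, optics, s = s, Z = Z, seed = seed),
       truths = lapply(fields, `[[`, "truth"))
}

#' Random unrooted binary tree with given leaf labels
#'
#' Fixture generator for topological tests: a fully bifurcating, unrooted,
#' leaf-labelled tree, deterministic given `seed`.
#'
#' @param labels character vector of >= 3 distinct leaf labels.
#' @param seed integer RNG seed.
#' @return an [ape::rtree()]-style `phylo` object.
#' @export
random_binary_tree <- function(labels, seed = 1L) {
  labels <- as.character(labels)
  if (length(labels) < 3L) stop("need at least 3 labels", call. = FALSE)
  if (anyDuplicated(labels)) stop("duplicate labels", call. = FALSE)
  with_seed(seed, ape::rtree(length(labels), rooted = FALSE, tip.label = labels))
}

#' Write per-object ground truth to CSV (and, optionally, height TIFFs)
#'
#' @param truths list of `"ground_truth"` objects.
#' @param csv_path output CSV path (object, volume_um3, area_um2, axis_um).
#' @param tiff_dir optional directory for per-object true height fields
#'   (16-bit TIFF scaled to the maximum height, with a YAML scale sidecar).
#' @return `csv_path`, invisibly.
#' @export
write_ground_truth <- function(truths, csv_path, tiff_dir = NULL) {
  df <- data.frame(
    object = seq_along(truths),
    volume_um3 = vapply(truths, function(t) t$volume_um3, numeric(1L)),
    area_um2 = vapply(truths, function(t) t$area_um2, numeric(1L)),
    axis_um = vapply(truths, function(t) t$axis_um, numeric(1L)))
  write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(tiff_dir)) {
    dir.create(tiff_dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(truths)) {
      h <- truths[[i]]$heights_true
      mx <- max(h, 1e-9)
      f <- file.path(tiff_dir, sprintf("truth_%03d.tif", i))
      tiff::writeTIFF(h / mx, f, bits.per.sample = 16L)
      yaml::write_yaml(list(height_scale_um = mx), paste0(f, ".yml"))
    }
  }
  invisible(csv_path)
}
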