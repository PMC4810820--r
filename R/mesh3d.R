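#' Height grid: per-pixel surface heights in micrometres
#'
#' The raster form of a semi-3D half-hull: decoded heights over a validity
#' mask. Straight from [heights_from_map()] every valid height is an integer
#' multiple of the z-step `Z`; after outlier filtering heights may take
#' window-mean values but never leave the pre-filter range.
#'
#' @param heights numeric matrix of heights in micrometres (`NA` where
#'   invalid).
#' @param valid logical matrix; where `FALSE`, heights are ignored.
#' @param px_um pixel size in micrometres.
#' @param Z z-step in micrometres (carried for z-level logic; may be `NA`).
#' @param s slice count of the source stack (may be `NA`).
#' @param aperture optional logical matrix marking aperture pixels.
#' @return an object of class `"heightgrid"`.
#' @export
heightgrid <- function(heights, valid, px_um = 1, Z = NA_real_,
                       s = NA_integer_, aperture = NULL) {
  stopifnot(is.matrix(heights), is.matrix(valid),
            identical(dim(heights), dim(valid)))
  if (any(heights[valid] < 0, na.rm = TRUE))
    stop("valid heights must be >= 0", call. = FALSE)
  heights[!valid] <- NA_real_
  structure(list(heights = heights, valid = valid, px_um = px_um,
                 Z = Z, s = s, aperture = aperture),
            class = "heightgrid")
}

#' @export
print.heightgrid <- function(x, ...) {
  cat(sprintf("<heightgrid> %d x %d px, %d valid px, range [%g, %g] um\n",
              nrow(x$heights), ncol(x$heights), sum(x$valid),
              suppressWarnings(min(x$heights, na.rm = TRUE)),
              suppressWarnings(max(x$heights, na.rm = TRUE))))
  invisible(x)
}

# nearest-neighbour index map: output pixel i (1..n_out) -> input pixel
nn_index <- function(n_in, n_out) {
  i <- ceiling((seq_len(n_out) - 0.5) * n_in / n_out)
  pmin(pmax(as.integer(i), 1L), n_in)
}

#' Rescale images so that 1 pixel = 1 micrometre
#'
#' Applies the microscope calibration (default 0.975 um/px) by
#' nearest-neighbour resampling: encoded height-map values are slice
#' indices and must never be interpolated. Works on a plain matrix, a
#' `"heightmap"`, or a [zstack()] (all slices identically).
#'
#' @param x matrix, `"heightmap"` or `"zstack"`.
#' @param calib_um_per_px micrometres per input pixel (> 0).
#' @return same class as `x`, resampled so `px_um = 1`.
#' @export
rescale_unit_pixels <- function(x, calib_um_per_px = 0.975) {
  if (calib_um_per_px <= 0) stop("`calib_um_per_px` must be > 0", call. = FALSE)
  resize <- function(m) {
    nr <- max(1L, as.integer(round_half_away(nrow(m) * calib_um_per_px)))
    nc <- max(1L, as.integer(round_half_away(ncol(m) * calib_um_per_px)))
    m[nn_index(nrow(m), nr), nn_index(ncol(m), nc), drop = FALSE]
  }
  if (is.matrix(x)) return(resize(x))
  if (inherits(x, "heightmap")) {
    x$encoded <- resize(x$encoded)
    x$valid <- resize(x$valid)
    x$px_um <- 1
    return(x)
  }
  if (inherits(x, "zstack"))
    return(zstack(lapply(x$slices, resize), Z = x$Z, px_um = 1))
  stop("unsupported input", call. = FALSE)
}

#' Mask a height map (or grid) to a footprint
#'
#' Element-wise multiplication of the binary 2D outline against the height
#' map: pixels outside the footprint become invalid, deleting background
#' noise before mesh extraction; pixels inside are unchanged.
#'
#' @param hm a `"heightmap"` or [heightgrid()].
#' @param footprint an `"outline_shape"` (its filled mask), or a logical
#'   matrix.
#' @return `hm` with the background invalidated.
#' @export
mask_background <- function(hm, footprint) {
  mask <- if (inherits(footprint, "outline_shape")) footprint$mask else footprint
  stopifnot(is.matrix(mask))
  if (inherits(hm, "heightmap")) {
    if (!identical(dim(hm$encoded), dim(mask)))
      stop("dimension mismatch", call. = FALSE)
    hm$valid <- hm$valid & mask
    if (!any(hm$valid)) stop("masking left no valid pixels", call. = FALSE)
    return(hm)
  }
  stopifnot(inherits(hm, "heightgrid"))
  if (!identical(dim(hm$heights), dim(mask)))
    stop("dimension mismatch", call. = FALSE)
  hm$valid <- hm$valid & mask
  hm$heights[!hm$valid] <- NA_real_
  if (!any(hm$valid)) stop("masking left no valid pixels", call. = FALSE)
  hm
}

#' Aperture mask from filled and unfilled outlines
#'
#' The aperture is whatever hole filling would have closed: pixels inside
#' the filled footprint but outside the unfilled one. These pixels are
#' excluded from the initial mesh and later floored to the object's lowest
#' height by [set_aperture_depth()].
#'
#' @param filled outline extracted with `fill_holes = TRUE`.
#' @param unfilled outline extracted with `fill_holes = FALSE`.
#' @return logical matrix (possibly all `FALSE`).
#' @export
aperture_mask <- function(filled, unfilled) {
  stopifnot(inherits(filled, "outline_shape"),
            inherits(unfilled, "outline_shape"),
            identical(dim(filled$mask), dim(unfilled$mask)))
  filled$mask & !unfilled$mask
}

#' Sliding-neighbourhood quartile outlier filter
#'
#' One pass over a frozen copy of the grid: for each valid pixel, the
#' type-7 quartiles Q1/Q3 of the valid pixels in its `n x n` window are
#' computed (window truncated at image borders, invalid/background pixels
#' excluded from the statistics); a focal value strictly outside
#' `[Q1, Q3]` is replaced with the mean of the window's valid pixels,
#' otherwise left unchanged. Removes both high and low height-map outliers
#' and smooths the final surface; replacement values always lie within the
#' pre-filter `[min, max]`.
#'
#' @param grid a [heightgrid()].
#' @param n odd window size >= 3; default 45, a good compromise between
#'   noise-patch deletion and over-smoothing at 1 um pixels.
#' @return the filtered [heightgrid()].
#' @export
outlier_filter <- function(grid, n = 45L) {
  stopifnot(inherits(grid, "heightgrid"))
  n <- as.integer(n)
  if (n < 3L || n %% 2L == 0L)
    stop("`n` must be an odd integer >= 3", call. = FALSE)
  h <- grid$heights
  h[!grid$valid] <- 0 # placeholder; excluded via the validity mask
  grid$heights <- .quartile_filter_cpp(h, grid$valid, n)
  grid
}

#' Prune sparse z-levels and the bottom level
#'
#' Heights are re-quantized to the nearest multiple of `Z`; any z-level
#' holding fewer than `frac` of the object's valid pixels is removed
#' (deleting edge noise missed by the outlier filter), then, if
#' `drop_bottom`, the lowest surviving level is removed as well (meshes
#' commonly retain a rim of background around the object).
#'
#' @param grid a [heightgrid()] with `Z` set.
#' @param frac minimum level occupancy as a fraction of valid pixels.
#' @param drop_bottom also remove the lowest remaining level?
#' @return the pruned [heightgrid()].
#' @export
prune_z_levels <- function(grid, frac = 0.01, drop_bottom = TRUE) {
  stopifnot(inherits(grid, "heightgrid"))
  if (is.na(grid$Z)) stop("grid carries no z-step", call. = FALSE)
  lev <- round_half_away(grid$heights / grid$Z)
  lev[!grid$valid] <- NA
  levs <- unique(lev[!is.na(lev)])
  if (length(levs) < 2L)
    stop("need at least 2 distinct z-levels", call. = FALSE)
  total <- sum(grid$valid)
  counts <- table(lev)
  drop <- as.numeric(names(counts))[counts < frac * total]
  kill <- !is.na(lev) & lev %in% drop
  if (drop_bottom) {
    remaining <- setdiff(levs, drop)
    if (length(remaining) > 0L)
      kill <- kill | (!is.na(lev) & lev == min(remaining))
  }
  grid$valid <- grid$valid & !kill
  grid$heights[!grid$valid] <- NA_real_
  if (!any(grid$valid)) stop("pruning removed every pixel", call. = FALSE)
  grid
}

#' Floor aperture pixels to the object's lowest height
#'
#' After pruning, aperture pixels are reinstated as valid with height equal
#' to the minimum over the object's valid heights, so apertures terminate
#' roughly in the centre of the shell rather than spiking.
#'
#' @param grid a pruned [heightgrid()].
#' @param aperture logical matrix from [aperture_mask()] (empty is a no-op).
#' @return the updated [heightgrid()].
#' @export
set_aperture_depth <- function(grid, aperture) {
  stopifnot(inherits(grid, "heightgrid"), is.matrix(aperture),
            identical(dim(grid$heights), dim(aperture)))
  if (!any(aperture)) return(grid)
  floor_h <- min(grid$heights[grid$valid])
  grid$heights[aperture] <- floor_h
  grid$valid <- grid$valid | aperture
  grid$aperture <- aperture
  grid
}

#' Triangulate a height grid into a half-hull mesh
#'
#' One vertex per valid pixel at `(x um, y um, height um)`; every 2 x 2
#' block of mutually valid pixels is split into two triangles along the
#' NW-SE diagonal. No downsampling: the vertex count equals the valid pixel
#' count.
#'
#' @param grid a [heightgrid()].
#' @param provenance optional list recorded on the mesh (object id,
#'   parameters used).
#' @return an object of class `"halfhull_mesh"`: `vertices` (m x 3),
#'   `faces` (k x 3, 1-based), `grid` (the source grid, kept for
#'   downsampled export), `provenance`.
#' @export
build_mesh <- function(grid, provenance = list()) {
  stopifnot(inherits(grid, "heightgrid"))
  valid <- grid$valid
  if (!any(valid)) stop("empty grid", call. = FALSE)
  nr <- nrow(valid); nc <- ncol(valid)
  px <- grid$px_um
  idx <- matrix(0L, nr, nc)
  cells <- which(valid)
  idx[cells] <- seq_along(cells)
  r <- (cells - 1L) %% nr + 1L
  c <- (cells - 1L) %/% nr + 1L
  vertices <- cbind(x = (c - 1) * px, y = (r - 1) * px,
                    z = grid$heights[cells])
  faces <- NULL
  if (nr > 1L && nc > 1L) {
    v_nw <- valid[-nr, -nc] & valid[-1L, -nc] & valid[-nr, -1L] & valid[-1L, -1L]
    q <- which(v_nw)
    if (length(q)) {
      qr <- (q - 1L) %% (nr - 1L) + 1L
      qc <- (q - 1L) %/% (nr - 1L) + 1L
      nw <- idx[cbind(qr, qc)]
      sw <- idx[cbind(qr + 1L, qc)]
      ne <- idx[cbind(qr, qc + 1L)]
      se <- idx[cbind(qr + 1L, qc + 1L)]
      faces <- rbind(cbind(nw, sw, se), cbind(nw, se, ne))
    }
  }
  if (is.null(faces)) faces <- matrix(integer(0), 0L, 3L)
  colnames(faces) <- NULL
  structure(list(vertices = unname(vertices), faces = faces,
                 grid = grid, provenance = provenance),
            class = "halfhull_mesh")
}

#' @export
print.halfhull_mesh <- function(x, ...) {
  cat(sprintf("<halfhull_mesh> %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Write a half-hull mesh to OBJ, OFF or XYZ-CSV
#'
#' OBJ uses `v x y z` and 1-based `f i j k` records; OFF the standard
#' header/counts layout with 0-based faces; CSV one `x_um,y_um,z_um` row
#' per vertex. `downsample = k > 1` keeps every k-th grid row/column and
#' re-triangulates before writing (default 1 = full mesh).
#'
#' @param mesh a `"halfhull_mesh"`.
#' @param path output file.
#' @param fmt `"obj"`, `"off"` or `"csv"` (default guessed from the file
#'   extension).
#' @param downsample integer >= 1.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, fmt = c("auto", "obj", "off", "csv"),
                       downsample = 1L) {
  stopifnot(inherits(mesh, "halfhull_mesh"))
  fmt <- match.arg(fmt)
  if (fmt == "auto") {
    fmt <- tolower(tools::file_ext(path))
    if (!fmt %in% c("obj", "off", "csv"))
      stop("unknown mesh format: ", fmt, call. = FALSE)
  }
  downsample <- as.integer(downsample)
  if (downsample < 1L) stop("`downsample` must be >= 1", call. = FALSE)
  if (downsample > 1L) {
    g <- mesh$grid
    keep_r <- seq(1L, nrow(g$heights), by = downsample)
    keep_c <- seq(1L, ncol(g$heights), by = downsample)
    sub <- heightgrid(g$heights[keep_r, keep_c, drop = FALSE],
                      g$valid[keep_r, keep_c, drop = FALSE],
                      px_um = g$px_um * downsample, Z = g$Z, s = g$s)
    mesh <- build_mesh(sub, mesh$provenance)
  }
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  num <- function(m) apply(m, 1L, function(row)
    paste(sprintf("%.17g", row), collapse = " "))
  if (fmt == "obj") {
    writeLines(c(paste("v", num(v)),
                 if (nrow(f)) paste("f", f[, 1L], f[, 2L], f[, 3L])), con)
  } else if (fmt == "off") {
    writeLines(c("OFF", paste(nrow(v), nrow(f), 0L), num(v),
                 if (nrow(f)) paste(3L, f[, 1L] - 1L, f[, 2L] - 1L, f[, 3L] - 1L)),
               con)
  } else {
    writeLines(c("x_um,y_um,z_um",
                 apply(v, 1L, function(row)
                   paste(sprintf("%.17g", row), collapse = ","))), con)
  }
  invisible(path)
}

#' Read a mesh written by [write_mesh()]
#'
#' @param path OBJ, OFF or CSV file.
#' @param fmt format (default guessed from the extension).
#' @return list with `vertices` (m x 3) and `faces` (k x 3, 1-based; empty
#'   for CSV).
#' @export
read_mesh <- function(path, fmt = c("auto", "obj", "off", "csv")) {
  fmt <- match.arg(fmt)
  if (fmt == "auto") {
    fmt <- tolower(tools::file_ext(path))
    if (!fmt %in% c("obj", "off", "csv"))
      stop("unknown mesh format: ", fmt, call. = FALSE)
  }
  if (fmt == "csv") {
    df <- read.csv(path)
    return(list(vertices = unname(as.matrix(df)),
                faces = matrix(integer(0), 0L, 3L)))
  }
  lines <- readLines(path)
  if (fmt == "obj") {
    vl <- lines[startsWith(lines, "v ")]
    fl <- lines[startsWith(lines, "f ")]
    v <- do.call(rbind, lapply(strsplit(sub("^v ", "", vl), " "), as.numeric))
    f <- if (length(fl))
      do.call(rbind, lapply(strsplit(sub("^f ", "", fl), " "), as.integer))
    else matrix(integer(0), 0L, 3L)
    return(list(vertices = v, faces = f))
  }
  if (lines[1L] != "OFF") stop("not an OFF file", call. = FALSE)
  counts <- as.integer(strsplit(lines[2L], " ")[[1L]])
  nv <- counts[1L]; nf <- counts[2L]
  v <- do.call(rbind, lapply(strsplit(lines[3:(2 + nv)], " "), as.numeric))
  f <- if (nf > 0L)
    do.call(rbind, lapply(strsplit(lines[(3 + nv):(2 + nv + nf)], " "),
                          function(x) as.integer(x[2:4]) + 1L))
  else matrix(integer(0), 0L, 3L)
  list(vertices = v, faces = f)
}
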