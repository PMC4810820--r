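#' Extract a single object's 2D outline from an EDF image
#'
#' Threshold, keep the largest 8-connected component, optionally fill
#' interior holes, and trace the outer boundary as an ordered, closed
#' contour (Moore tracing). Skipping the hole filling (`fill_holes = FALSE`)
#' is how shell apertures are exposed: the aperture renders dark, survives
#' as an interior hole, and the difference between the filled and unfilled
#' masks marks it (see [aperture_mask()]).
#'
#' @param edf grayscale image in `[0, 1]`.
#' @param threshold binarization fraction in `(0, 1)`.
#' @param fill_holes fill interior holes of the retained component?
#' @param px_um pixel size in micrometres.
#' @return an object of class `"outline_shape"`: `mask` (logical),
#'   `boundary` (ordered k x 2 matrix of 1-based (row, col) coordinates),
#'   `holes_filled`, `px_um`.
#' @export
extract_outline <- function(edf, threshold = 0.18, fill_holes = TRUE,
                            px_um = 1) {
  stopifnot(is.matrix(edf))
  if (any(edf < 0 | edf > 1))
    stop("image intensities must be normalized to [0, 1]", call. = FALSE)
  lab <- .label8_cpp(edf > threshold)
  if (max(lab) == 0L) stop("empty mask: no pixel above threshold", call. = FALSE)
  counts <- tabulate(lab[lab > 0L])
  mask <- lab == which.max(counts)
  if (fill_holes) mask <- EBImage::fillHull(mask * 1L) > 0L
  boundary <- .trace_boundary_cpp(mask)
  structure(list(mask = mask, boundary = boundary,
                 holes_filled = fill_holes, px_um = px_um),
            class = "outline_shape")
}

# chain length of an ordered closed contour through pixel centres:
# axis steps count 1, diagonal steps sqrt(2)
chain_length <- function(boundary) {
  if (nrow(boundary) < 2L) return(0)
  p <- rbind(boundary, boundary[1L, , drop = FALSE])
  sum(sqrt(rowSums((p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

# rasterize a polygon (k x 2 (row, col) vertices, pixel centres) by
# even-odd scanline filling; returns a logical matrix
fill_polygon <- function(verts, nr, nc) {
  out <- matrix(FALSE, nr, nc)
  vy <- verts[, 1L]
  vx <- verts[, 2L]
  n <- length(vy)
  nxt <- c(2:n, 1L)
  for (r in seq_len(nr)) {
    cross <- (vy <= r & vy[nxt] > r) | (vy[nxt] <= r & vy > r)
    if (!any(cross)) {
      flat <- which(vy == r & vy[nxt] == r)
      for (i in flat) out[r, min(vx[i], vx[nxt[i]]):max(vx[i], vx[nxt[i]])] <- TRUE
      next
    }
    i <- which(cross)
    xs <- vx[i] + (r - vy[i]) / (vy[nxt[i]] - vy[i]) * (vx[nxt[i]] - vx[i])
    xs <- sort(xs)
    for (j in seq(1L, length(xs) - 1L, by = 2L)) {
      a <- ceiling(xs[j] - 1e-9)
      b <- floor(xs[j + 1L] + 1e-9)
      if (b >= a) out[r, max(a, 1L):min(b, nc)] <- TRUE
    }
  }
  out
}

#' 2D shape parameters of an outline
#'
#' Measures the filled footprint: enclosed area (pixel count), boundary
#' perimeter (8-neighbour chain length, diagonals counting `sqrt(2)`),
#' major/minor axis lengths of the ellipse with the same normalized second
#' central moments as the footprint, eccentricity, aspect ratio
#' (minor/major), rugosity (chain perimeter over the chain perimeter of the
#' rasterized convex hull, so any convex footprint scores 1 up to tracing
#' tolerance) and the footprint centroid.
#'
#' @param outline an `"outline_shape"`.
#' @return an object of class `"shape2d_params"`: list with `area_um2`,
#'   `perimeter_um`, `major_um`, `minor_um`, `eccentricity`,
#'   `aspect_ratio`, `rugosity`, `centroid_um` (x, y), `px_um`.
#' @export
shape_params <- function(outline) {
  stopifnot(inherits(outline, "outline_shape"))
  mask <- outline$mask
  px <- outline$px_um
  npx <- sum(mask)
  if (npx < 2L) stop("degenerate outline: fewer than 2 pixels", call. = FALSE)
  cells <- which(mask)
  r <- (cells - 1L) %% nrow(mask) + 1L
  c <- (cells - 1L) %/% nrow(mask) + 1L
  # second central moments with the 1/12 pixel-extent term (the equal-moment
  # ellipse convention of standard region-properties tooling)
  mr <- mean(r); mc <- mean(c)
  crr <- mean((r - mr)^2) + 1 / 12
  ccc <- mean((c - mc)^2) + 1 / 12
  crc <- mean((r - mr) * (c - mc))
  common <- sqrt((crr - ccc)^2 + 4 * crc^2)
  l1 <- (crr + ccc + common) / 2
  l2 <- (crr + ccc - common) / 2
  major <- 4 * sqrt(l1) * px
  minor <- 4 * sqrt(l2) * px
  per <- chain_length(outline$boundary) * px
  hull_mask <- fill_polygon(
    outline$boundary[chull(outline$boundary[, 2L], outline$boundary[, 1L]), ,
                     drop = FALSE],
    nrow(mask), ncol(mask))
  hull_mask <- hull_mask | mask
  hull_per <- chain_length(.trace_boundary_cpp(hull_mask)) * px
  structure(list(
    area_um2 = npx * px^2,
    perimeter_um = per,
    major_um = major,
    minor_um = minor,
    eccentricity = sqrt(max(0, 1 - l2 / l1)),
    aspect_ratio = minor / major,
    rugosity = if (hull_per > 0) per / hull_per else 1,
    centroid_um = c(x = (mc - 1) * px, y = (mr - 1) * px),
    px_um = px), class = "shape2d_params")
}

#' Resample an outline to n equally spaced perimeter points
#'
#' Points are spaced equally by arc length along the closed boundary polygon
#' and ordered so the polar angle about the centroid starts near 0 and
#' increases. The Euclidean distance from each point to the centroid is
#' attached. For footprints that are not star-convex about their centroid
#' the polar angle cannot be monotone; a warning is issued and the points
#' remain in arc-length order.
#'
#' @param outline an `"outline_shape"`.
#' @param n number of points (>= 3); default 100, the resolution used by the
#'   conical surface-area estimator.
#' @return list with `coords_um` (n x 2, x/y micrometres), `radii_um`
#'   (centroid distances), `centroid_um`.
#' @export
resample_perimeter <- function(outline, n = 100L) {
  stopifnot(inherits(outline, "outline_shape"))
  if (n < 3L) stop("`n` must be >= 3", call. = FALSE)
  px <- outline$px_um
  b <- outline$boundary
  if (nrow(b) < 3L) stop("degenerate outline", call. = FALSE)
  # boundary as closed polygon in (x, y) micrometres
  xy <- cbind((b[, 2L] - 1) * px, (b[, 1L] - 1) * px)
  xy <- rbind(xy, xy[1L, ])
  seg <- sqrt(rowSums(diff(xy)^2))
  cum <- c(0, cumsum(seg))
  L <- cum[length(cum)]
  target <- (seq_len(n) - 1L) * L / n
  i <- findInterval(target, cum, rightmost.closed = TRUE)
  i <- pmin(i, nrow(xy) - 1L)
  w <- (target - cum[i]) / pmax(seg[i], 1e-12)
  pts <- xy[i, , drop = FALSE] * (1 - w) + xy[i + 1L, , drop = FALSE] * w
  cells <- which(outline$mask)
  ctr <- c(mean((cells - 1L) %/% nrow(outline$mask)) * px,
           mean((cells - 1L) %% nrow(outline$mask)) * px)
  ang <- atan2(pts[, 2L] - ctr[2L], pts[, 1L] - ctr[1L]) %% (2 * pi)
  # rotate so the angle starts nearest 0, orient counter-clockwise
  start <- which.min(ang)
  ord <- c(start:n, seq_len(start - 1L))
  pts <- pts[ord, , drop = FALSE]
  ang <- ang[ord]
  if (n > 2L && sum(diff(ang) < 0) > sum(diff(ang) > 0)) {
    pts <- pts[c(1L, n:2L), , drop = FALSE]
    ang <- ang[c(1L, n:2L)]
  }
  if (any(diff(ang) < -0.05))
    warning("polar angle is not monotone along the perimeter ",
            "(footprint not star-convex about its centroid)", call. = FALSE)
  list(coords_um = unname(pts),
       radii_um = sqrt(rowSums(sweep(pts, 2L, ctr)^2)),
       centroid_um = c(x = ctr[1L], y = ctr[2L]))
}
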