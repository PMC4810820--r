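#' Segment a slide-scale EDF image into objects
#'
#' Thresholds the extended-depth-of-focus image (light objects on a black
#' slide), labels 8-connected foreground components and returns them sorted
#' by pixel area, largest first. The default threshold of 0.18 suits
#' well-exposed slides; per-slide overrides are expected (glare or dark
#' specimens shift the optimum).
#'
#' @param edf grayscale image with intensities normalized to `[0, 1]`.
#' @param threshold binarization fraction in `(0, 1)`; pixels strictly above
#'   it are foreground.
#' @param px_um pixel size in micrometres (used for the region size fields).
#' @return list of `"object_region"`s: each has `label`, `area_px`,
#'   `pixels` (cell indices into `edf`), `bbox` (0-based, half-open
#'   `c(r0, c0, r1, c1)`), `width_um` (column extent) and `height_um`
#'   (row extent).
#' @export
segment_slide <- function(edf, threshold = 0.18, px_um = 1) {
  stopifnot(is.matrix(edf))
  if (any(edf < 0 | edf > 1))
    stop("image intensities must be normalized to [0, 1]", call. = FALSE)
  if (threshold <= 0 || threshold >= 1)
    stop("`threshold` must lie in (0, 1)", call. = FALSE)
  lab <- .label8_cpp(edf > threshold)
  n <- max(lab)
  if (n == 0L) return(list())
  regions <- lapply(seq_len(n), function(l) {
    cells <- which(lab == l)
    r <- (cells - 1L) %% nrow(lab) + 1L
    c <- (cells - 1L) %/% nrow(lab) + 1L
    bbox <- c(min(r) - 1L, min(c) - 1L, max(r), max(c)) # 0-based, half-open
    structure(list(label = l, area_px = length(cells), pixels = cells,
                   bbox = bbox,
                   width_um = (bbox[4L] - bbox[2L]) * px_um,
                   height_um = (bbox[3L] - bbox[1L]) * px_um,
                   px_um = px_um),
              class = "object_region")
  })
  regions[order(vapply(regions, `[[`, integer(1L), "area_px"),
                decreasing = TRUE)]
}

#' Filter segmented regions by physical size
#'
#' Keeps regions whose bounding-box maximum dimension, in micrometres, lies
#' inside `[min_um, max_um]` (125-2000 um by default, the working range for
#' adult planktonic foraminifera; smaller hits are dust or juveniles,
#' larger ones glare or clumps). Order is preserved.
#'
#' @param regions list of `"object_region"`s from [segment_slide()].
#' @param px_um pixel size in micrometres.
#' @param min_um,max_um inclusive size bounds in micrometres.
#' @return the retained regions.
#' @export
filter_by_size <- function(regions, px_um, min_um = 125, max_um = 2000) {
  if (min_um >= max_um) stop("`min_um` must be < `max_um`", call. = FALSE)
  if (px_um <= 0) stop("`px_um` must be > 0", call. = FALSE)
  keep <- vapply(regions, function(r) {
    ext <- max(r$bbox[3L] - r$bbox[1L], r$bbox[4L] - r$bbox[2L]) * px_um
    ext >= min_um && ext <= max_um
  }, logical(1L))
  regions[keep]
}

#' Crop a per-object sub-stack out of a slide stack
#'
#' All slices are cropped identically to the region's bounding box expanded
#' by `margin_px` and clipped to the canvas; stack metadata propagates.
#'
#' @param zs the slide-scale [zstack()].
#' @param region an `"object_region"`.
#' @param margin_px margin in pixels around the bounding box.
#' @return a [zstack()] covering just the object.
#' @export
crop_object_stack <- function(zs, region, margin_px = 0L) {
  stopifnot(inherits(zs, "zstack"), inherits(region, "object_region"))
  if (region$area_px == 0L) stop("empty region", call. = FALSE)
  d <- dim(zs$slices[[1L]])
  b <- region$bbox
  r0 <- max(b[1L] + 1L - margin_px, 1L)
  c0 <- max(b[2L] + 1L - margin_px, 1L)
  r1 <- min(b[3L] + margin_px, d[1L])
  c1 <- min(b[4L] + margin_px, d[2L])
  zstack(lapply(zs$slices, function(m) m[r0:r1, c0:c1, drop = FALSE]),
         Z = zs$Z, px_um = zs$px_um)
}

#' Write a segmentation manifest
#'
#' One CSV row per region: label, 0-based half-open bounding box, and sizes
#' in micrometres.
#'
#' @param regions list of `"object_region"`s.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(regions, path) {
  df <- do.call(rbind, lapply(regions, function(r) {
    data.frame(label = r$label, area_px = r$area_px,
               r0 = r$bbox[1L], c0 = r$bbox[2L],
               r1 = r$bbox[3L], c1 = r$bbox[4L],
               width_um = r$width_um, height_um = r$height_um)
  }))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
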