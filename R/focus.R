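#' Local-variance focus measure
#'
#' Per-pixel variance of intensity in a `kernel x kernel` window (truncated
#' at the image borders): the classic shape-from-focus sharpness operator.
#' Sharp texture scores high; defocused or flat regions score near zero.
#'
#' @param image numeric matrix.
#' @param kernel odd window size >= 3 (default 11, the size used for height
#'   map generation throughout this package).
#' @return matrix of non-negative focus scores, same dimension as `image`.
#' @export
focus_measure <- function(image, kernel = 11L) {
  stopifnot(is.matrix(image))
  kernel <- as.integer(kernel)
  if (kernel < 3L || kernel %% 2L == 0L)
    stop("`kernel` must be an odd integer >= 3", call. = FALSE)
  half <- kernel %/% 2L
  n <- box_count(nrow(image), ncol(image), half)
  m1 <- box_sum(image, half) / n
  m2 <- box_sum(image^2, half) / n
  v <- pmax(m2 - m1^2, 0)
  # clamp summed-area-table cancellation dust so flat windows score an
  # exact 0 (ties then resolve to the lower slice deterministically);
  # the dust scales with the table magnitude, i.e. with sum(image^2)
  dust <- 16 * .Machine$double.eps * sum(image^2) / n
  v[v < 1e-10 * m2 + dust] <- 0
  v
}

#' Encode a slice index on the 0-255 height-map scale
#'
#' `encode_slice(b, s) = round(255 b / (s - 1))` with halves rounded away
#' from zero; the exact inverse pair of [decode_height()].
#'
#' @param b slice index (0-based, `0 <= b <= s - 1`).
#' @param s slice count.
#' @return integer grayscale values in `[0, 255]`.
#' @export
encode_slice <- function(b, s) {
  if (any(b < 0 | b > s - 1)) stop("slice index out of range", call. = FALSE)
  as.integer(round_half_away(255 * b / (s - 1)))
}

#' Decode a height-map grayscale value to a height in micrometres
#'
#' The height map stores the best-focus slice index rescaled to 0-255. The
#' physical height is recovered as
#' `round(encoded * (s - 1) / 255) * Z` (halves away from zero), so that
#' `decode_height(encode_slice(b, s), s, Z) == b * Z` exactly for every
#' slice index `b`.
#'
#' @param encoded grayscale values in `[0, 255]`.
#' @param s slice count of the source stack.
#' @param Z z-step in micrometres.
#' @return heights in micrometres.
#' @export
decode_height <- function(encoded, s, Z) {
  if (any(encoded < 0 | encoded > 255, na.rm = TRUE))
    stop("encoded values must lie in [0, 255]", call. = FALSE)
  round_half_away(encoded * (s - 1) / 255) * Z
}

#' Build a height map from a z-stack
#'
#' For every pixel, the best-focus slice is the argmax over slices of the
#' local-variance focus measure (ties broken toward the lower slice, i.e.
#' toward the slide); the 0-based best slice index `b` is stored as
#' `encode_slice(b, s)` on the 0-255 scale.
#'
#' @param zs a [zstack()].
#' @param kernel focus-measure window (odd, >= 3); default 11.
#' @return an object of class `"heightmap"`: list with `encoded` (integer
#'   matrix 0-255), `valid` (logical matrix), `s`, `Z`, `px_um`.
#' @export
build_height_map <- function(zs, kernel = 11L) {
  stopifnot(inherits(zs, "zstack"))
  if (zs$s < 2L) stop("need at least 2 slices", call. = FALSE)
  best <- matrix(0L, nrow(zs$slices[[1L]]), ncol(zs$slices[[1L]]))
  fmax <- focus_measure(zs$slices[[1L]], kernel)
  for (k in 2:zs$s) {
    fk <- focus_measure(zs$slices[[k]], kernel)
    better <- fk > fmax # strict: ties stay on the lower slice
    best[better] <- k - 1L
    fmax[better] <- fk[better]
  }
  structure(
    list(encoded = matrix(encode_slice(best, zs$s), nrow(best), ncol(best)),
         valid = matrix(TRUE, nrow(best), ncol(best)),
         s = zs$s, Z = zs$Z, px_um = zs$px_um),
    class = "heightmap")
}

#' @export
print.heightmap <- function(x, ...) {
  cat(sprintf("<heightmap> %d x %d px, s = %d, Z = %g um, %g um/px (%d%% valid)\n",
              nrow(x$encoded), ncol(x$encoded), x$s, x$Z, x$px_um,
              round(100 * mean(x$valid))))
  invisible(x)
}

#' Extended-depth-of-focus composite
#'
#' Each pixel takes its intensity from the best-focus slice recorded in the
#' height map (an argmax-slice composite).
#'
#' @param zs a [zstack()].
#' @param hm the [build_height_map()] output for the same stack.
#' @return numeric matrix (the EDF image).
#' @export
build_edf <- function(zs, hm) {
  stopifnot(inherits(zs, "zstack"), inherits(hm, "heightmap"))
  d <- dim(zs$slices[[1L]])
  if (!identical(dim(hm$encoded), d))
    stop("height map and stack dimensions differ", call. = FALSE)
  b <- round_half_away(hm$encoded * (zs$s - 1) / 255)
  edf <- matrix(0, d[1L], d[2L])
  for (k in sort(unique(as.vector(b)))) {
    sel <- b == k
    edf[sel] <- zs$slices[[k + 1L]][sel]
  }
  edf
}

#' Decode a height map into a height grid in micrometres
#'
#' @param hm a `"heightmap"`.
#' @return a [heightgrid()] whose heights are exact multiples of `Z`.
#' @export
heights_from_map <- function(hm) {
  stopifnot(inherits(hm, "heightmap"))
  h <- decode_height(hm$encoded, hm$s, hm$Z)
  h[!hm$valid] <- NA_real_
  heightgrid(h, valid = hm$valid, px_um = hm$px_um, Z = hm$Z, s = hm$s)
}

#' Write / read a height map as 8-bit TIFF with YAML sidecar
#'
#' @param hm a `"heightmap"`.
#' @param path TIFF path; `<path>.yml` stores `s`, `Z`, `px_um`.
#' @return `path` invisibly, or the restored `"heightmap"`.
#' @export
write_height_map <- function(hm, path) {
  stopifnot(inherits(hm, "heightmap"))
  tiff::writeTIFF(hm$encoded / 255, path, bits.per.sample = 8L)
  yaml::write_yaml(list(s = hm$s, Z = hm$Z, px_um = hm$px_um),
                   paste0(path, ".yml"))
  invisible(path)
}

#' @rdname write_height_map
#' @export
read_height_map <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yml"))
  enc <- round(tiff::readTIFF(path) * 255)
  structure(list(encoded = matrix(as.integer(enc), nrow(enc), ncol(enc)),
                 valid = matrix(TRUE, nrow(enc), ncol(enc)),
                 s = meta$s, Z = meta$Z, px_um = meta$px_um),
            class = "heightmap")
}
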