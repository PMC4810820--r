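#' Construct a z-stack
#'
#' An ordered set of grayscale slices of identical dimensions, lowest focal
#' plane first (slice 1 sits on the slide surface, index increases upward),
#' with the acquisition geometry attached: z-step `Z` in micrometres between
#' consecutive slices and lateral pixel size `px_um`.
#'
#' @param slices list of numeric matrices in `[0, 1]`, all the same dimension.
#' @param Z z-step in micrometres (> 0).
#' @param px_um lateral pixel size in micrometres per pixel (> 0).
#' @return an object of class `"zstack"` with fields `slices`, `s`
#'   (slice count), `Z`, `px_um`.
#' @export
zstack <- function(slices, Z, px_um) {
  if (!is.list(slices) || length(slices) < 2L)
    stop("a z-stack needs at least 2 slices", call. = FALSE)
  d <- dim(slices[[1L]])
  ok <- vapply(slices, function(m) is.matrix(m) && identical(dim(m), d), logical(1L))
  if (!all(ok)) stop("all slices must be matrices of identical dimension", call. = FALSE)
  stop_if_not_scalar_num(Z, "Z")
  stop_if_not_scalar_num(px_um, "px_um")
  if (Z <= 0) stop("`Z` must be > 0", call. = FALSE)
  if (px_um <= 0) stop("`px_um` must be > 0", call. = FALSE)
  structure(
    list(slices = slices, s = length(slices), Z = Z, px_um = px_um),
    class = "zstack"
  )
}

#' @export
print.zstack <- function(x, ...) {
  d <- dim(x$slices[[1L]])
  cat(sprintf("<zstack> %d slices of %d x %d px, Z = %g um, %g um/px\n",
              x$s, d[1L], d[2L], x$Z, x$px_um))
  invisible(x)
}

#' Write a z-stack as a multi-page TIFF with a YAML sidecar
#'
#' One page per slice (grayscale), plus `<path>.yml` carrying `s`, `Z` and
#' `px_um` so the stack can be read back with its geometry intact.
#'
#' @param zs a [zstack()].
#' @param path output TIFF file path.
#' @param bits bits per sample (8 or 16).
#' @return `path`, invisibly.
#' @export
write_zstack <- function(zs, path, bits = 16L) {
  stopifnot(inherits(zs, "zstack"))
  tiff::writeTIFF(zs$slices, path, bits.per.sample = as.integer(bits))
  yaml::write_yaml(list(s = zs$s, Z = zs$Z, px_um = zs$px_um),
                   paste0(path, ".yml"))
  invisible(path)
}

#' Read a z-stack written by [write_zstack()]
#'
#' @param path TIFF file path; `<path>.yml` must exist alongside.
#' @return a [zstack()].
#' @export
read_zstack <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yml"))
  pages <- tiff::readTIFF(path, all = TRUE)
  zstack(pages, Z = meta$Z, px_um = meta$px_um)
}
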