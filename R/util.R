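#' Round half away from zero
#'
#' The rounding convention used for all height encoding/decoding and
#' rescaling in this package: halves round away from zero (so 59.5 -> 60),
#' unlike [base::round()]'s round-half-to-even.
#'
#' @param x numeric vector.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

# Box sum of a matrix over (2*half+1)^2 windows truncated at borders,
# via a summed-area table. Returns a matrix of the same dimension.
box_sum <- function(m, half) {
  nr <- nrow(m)
  nc <- ncol(m)
  sat <- apply(apply(m, 2L, cumsum), 1L, cumsum) # sat[j, i] = sum m[1:i, 1:j]
  sat <- t(sat)
  satp <- matrix(0, nr + 1L, nc + 1L)
  satp[-1L, -1L] <- sat
  r0 <- pmax(seq_len(nr) - half, 1L)
  r1 <- pmin(seq_len(nr) + half, nr)
  c0 <- pmax(seq_len(nc) - half, 1L)
  c1 <- pmin(seq_len(nc) + half, nc)
  satp[r1 + 1L, c1 + 1L, drop = FALSE] -
    satp[r0, c1 + 1L, drop = FALSE] -
    satp[r1 + 1L, c0, drop = FALSE] +
    satp[r0, c0, drop = FALSE]
}

# Window pixel counts matching box_sum's truncation.
box_count <- function(nr, nc, half) {
  rc <- pmin(seq_len(nr) + half, nr) - pmax(seq_len(nr) - half, 1L) + 1L
  cc <- pmin(seq_len(nc) + half, nc) - pmax(seq_len(nc) - half, 1L) + 1L
  outer(rc, cc)
}

stop_if_not_scalar_num <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
}
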