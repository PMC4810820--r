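# Independent reference implementations used to cross-check the package.
# These deliberately use naive algorithms (loops, full recomputation) and
# never call the code paths they verify.

# --- sliding quartile filter, literal definition ------------------------
oracle_quartile_filter <- function(heights, valid, n) {
  nr <- nrow(heights)
  nc <- ncol(heights)
  half <- n %/% 2
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (!valid[i, j]) next
      rs <- max(1, i - half):min(nr, i + half)
      cs <- max(1, j - half):min(nc, j + half)
      w <- heights[rs, cs][valid[rs, cs]]
      q <- quantile(w, c(0.25, 0.75), type = 7, names = FALSE)
      v <- heights[i, j]
      out[i, j] <- if (v < q[1] || v > q[2]) mean(w) else v
    }
  }
  out
}

# --- agglomerative clustering by direct Lance-Williams recursion --------
# Returns the merge hierarchy as a list of sorted label vectors (one per
# merge, smallest first) plus merge heights.
oracle_agglomerate <- function(D, linkage) {
  D <- as.matrix(D)
  labs <- rownames(D)
  if (is.null(labs)) labs <- as.character(seq_len(nrow(D)))
  clusters <- as.list(labs)
  sizes <- rep(1, length(labs))
  act <- seq_along(labs)
  d <- D
  merges <- list()
  heights <- numeric(0)
  while (length(act) > 1L) {
    best <- c(NA, NA)
    bd <- Inf
    for (a in seq_along(act)) {
      for (b in seq_len(a - 1L)) {
        dd <- d[act[a], act[b]]
        if (dd < bd) { bd <- dd; best <- c(act[b], act[a]) }
      }
    }
    i <- best[1L]; j <- best[2L]
    ni <- sizes[i]; nj <- sizes[j]
    newc <- sort(c(clusters[[i]], clusters[[j]]))
    merges[[length(merges) + 1L]] <- newc
    heights <- c(heights, bd)
    for (k in act) {
      if (k == i || k == j) next
      nk <- sizes[k]
      dn <- switch(linkage,
        single   = 0.5 * d[i, k] + 0.5 * d[j, k] - 0.5 * abs(d[i, k] - d[j, k]),
        complete = 0.5 * d[i, k] + 0.5 * d[j, k] + 0.5 * abs(d[i, k] - d[j, k]),
        average  = ni / (ni + nj) * d[i, k] + nj / (ni + nj) * d[j, k],
        mcquitty = 0.5 * d[i, k] + 0.5 * d[j, k],
        ward     = ((ni + nk) * d[i, k] + (nj + nk) * d[j, k] - nk * bd) /
                   (ni + nj + nk))
      d[i, k] <- d[k, i] <- dn
    }
    clusters[[i]] <- newc
    sizes[i] <- ni + nj
    act <- setdiff(act, j)
  }
  list(merges = merges, heights = heights)
}

# Extract the same representation from an hclust object.
hclust_merges <- function(hc) {
  n <- length(hc$labels)
  members <- vector("list", nrow(hc$merge))
  out <- vector("list", nrow(hc$merge))
  for (m in seq_len(nrow(hc$merge))) {
    grab <- function(x) if (x < 0) hc$labels[-x] else members[[x]]
    members[[m]] <- sort(c(grab(hc$merge[m, 1L]), grab(hc$merge[m, 2L])))
    out[[m]] <- members[[m]]
  }
  list(merges = out, heights = hc$height)
}

# --- path difference by breadth-first search ----------------------------
# Leaf-pair path lengths (edge counts) of a phylo tree, ordered by sorted
# label pairs.
oracle_path_vector <- function(tree) {
  labs <- sort(tree$tip.label)
  nnode <- max(tree$edge)
  adj <- vector("list", nnode)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1L]; b <- tree$edge[e, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  tip_id <- match(labs, tree$tip.label)
  dmat <- matrix(NA_real_, length(labs), length(labs))
  for (i in seq_along(labs)) {
    dist <- rep(NA_real_, nnode)
    dist[tip_id[i]] <- 0
    queue <- tip_id[i]
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[v]]) {
        if (is.na(dist[w])) {
          dist[w] <- dist[v] + 1
          queue <- c(queue, w)
        }
      }
    }
    dmat[i, ] <- dist[tip_id]
  }
  dmat[upper.tri(dmat)]
}

oracle_path_difference <- function(t1, t2) {
  sqrt(sum((oracle_path_vector(t1) - oracle_path_vector(t2))^2))
}

# --- tiny geometry fixtures ---------------------------------------------
disc_image <- function(r_px, dim_px = 2 * r_px + 21, value = 0.5,
                       center = (dim_px + 1) / 2, hole_r = 0) {
  g <- expand.grid(row = seq_len(dim_px), col = seq_len(dim_px))
  d2 <- (g$row - center)^2 + (g$col - center)^2
  img <- matrix(0, dim_px, dim_px)
  img[d2 <= r_px^2] <- value
  if (hole_r > 0) img[d2 <= hole_r^2] <- 0
  img
}

square_image <- function(side_px, dim_px = side_px + 20, value = 0.5) {
  img <- matrix(0, dim_px, dim_px)
  off <- (dim_px - side_px) %/% 2
  img[off + seq_len(side_px), off + seq_len(side_px)] <- value
  img
}

# A small rendered hemisphere stack shared by focus/pipeline tests
# (memoised per session: rendering is the slow part).
hemisphere_case <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- shape_spec("hemispheroid", a_um = 120, relief_um = 120,
                         center_um = c(150, 150))
      f <- make_heightfield(spec, dim_px = c(300, 300), px_um = 1)
      zs <- render_zstack(f, optics(noise_sd = 0), s = 31, Z = 31.1, seed = 11)
      cache <<- list(spec = spec, field = f, stack = zs)
    }
    cache
  }
})
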