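#' Species-mean score matrix
#'
#' Averages per-individual ordination scores (e.g. principal component or
#' discriminant scores) within species, axis by axis. Row order follows the
#' first appearance of each species.
#'
#' @param scores numeric matrix or data frame, one row per individual.
#' @param species character vector of species labels, one per row; no
#'   missing labels.
#' @return species x axis numeric matrix.
#' @export
species_mean <- function(scores, species) {
  scores <- as.matrix(scores)
  if (length(species) != nrow(scores))
    stop("one species label per row is required", call. = FALSE)
  if (anyNA(species) || any(!nzchar(species)))
    stop("unlabelled row", call. = FALSE)
  sp <- unique(species)
  out <- t(vapply(sp, function(s)
    colMeans(scores[species == s, , drop = FALSE]), numeric(ncol(scores))))
  rownames(out) <- sp
  out
}

#' One-hot encode a categorical trait table
#'
#' One indicator column per trait level (e.g. symbiont type, habitat depth,
#' geographical range), the coding used for Jaccard ecological distances.
#'
#' @param traits data frame of categorical traits, rownames = species.
#' @return binary matrix, species x trait levels.
#' @export
onehot_traits <- function(traits) {
  stopifnot(is.data.frame(traits))
  if (anyNA(traits)) stop("trait table has missing cells", call. = FALSE)
  if (anyDuplicated(rownames(traits)))
    stop("species names must be unique", call. = FALSE)
  cols <- lapply(names(traits), function(nm) {
    v <- as.character(traits[[nm]])
    lev <- sort(unique(v))
    m <- vapply(lev, function(l) as.integer(v == l), integer(length(v)))
    m <- matrix(m, nrow = length(v),
                dimnames = list(NULL, paste(nm, lev, sep = "=")))
    m
  })
  out <- do.call(cbind, cols)
  rownames(out) <- rownames(traits)
  out
}

#' Distance matrix between species
#'
#' Euclidean distances between rows of a numeric score matrix, or Jaccard
#' distances (`1 - |intersection| / |union|` over one-hot trait indicators)
#' between rows of a categorical trait table.
#'
#' @param x numeric matrix (euclidean) or trait data frame (jaccard).
#' @param metric `"euclidean"` or `"jaccard"`.
#' @return a symmetric [stats::dist] object with zero diagonal.
#' @export
dist_matrix <- function(x, metric = c("euclidean", "jaccard")) {
  metric <- match.arg(metric)
  if (metric == "euclidean") {
    if (!is.numeric(as.matrix(x)))
      stop("euclidean distances need a numeric matrix", call. = FALSE)
    return(dist(as.matrix(x), method = "euclidean"))
  }
  if (!is.data.frame(x))
    stop("jaccard distances are defined on a categorical trait table",
         call. = FALSE)
  vegan::vegdist(onehot_traits(x), method = "jaccard", binary = TRUE)
}

#' Hierarchical clustering under the five standard linkages
#'
#' Agglomerative clustering of a distance matrix under Ward, single,
#' complete, average (UPGMA) or McQuitty (WPGMA) linkage. `"ward"` uses the
#' classic Lance-Williams recurrence on unsquared distances
#' (`hclust` method `"ward.D"`); set `ward_squared = TRUE` for the
#' squared-distance variant (`"ward.D2"`).
#'
#' @param d a [stats::dist] or symmetric matrix.
#' @param linkage `"ward"`, `"single"`, `"complete"`, `"average"` or
#'   `"mcquitty"`.
#' @param ward_squared use the squared-distance Ward update?
#' @return an [stats::hclust] dendrogram.
#' @export
hcluster <- function(d, linkage = c("ward", "single", "complete", "average",
                                    "mcquitty"), ward_squared = FALSE) {
  linkage <- match.arg(linkage)
  if (is.matrix(d)) {
    if (!isSymmetric(unname(d)))
      stop("distance matrix must be symmetric", call. = FALSE)
    d <- stats::as.dist(d)
  }
  if (attr(d, "Size") < 2L) stop("need at least 2 labels", call. = FALSE)
  method <- switch(linkage,
                   ward = if (ward_squared) "ward.D2" else "ward.D",
                   linkage)
  hclust(d, method = method)
}

#' All-five-linkage dendrograms
#'
#' @param d a distance matrix.
#' @param ward_squared see [hcluster()].
#' @return named list of [stats::hclust] objects.
#' @export
hcluster_all <- function(d, ward_squared = FALSE) {
  linkages <- c("ward", "single", "complete", "average", "mcquitty")
  setNames(lapply(linkages, hcluster, d = d, ward_squared = ward_squared),
           linkages)
}

#' Majority-rule consensus of dendrograms
#'
#' Retains exactly the clades present in strictly more than a fraction `p`
#' of the input trees (50% majority rule by default); the result may be
#' multifurcating. Dendrograms are converted to topologies (merge heights
#' discarded).
#'
#' @param trees list of [stats::hclust] dendrograms or `phylo` trees over
#'   identical leaf sets (>= 2 trees).
#' @param p retention threshold (strict).
#' @return a `phylo` consensus tree.
#' @export
majority_consensus <- function(trees, p = 0.5) {
  if (length(trees) < 2L) stop("need at least 2 trees", call. = FALSE)
  phy <- lapply(trees, function(t)
    if (inherits(t, "phylo")) t else ape::as.phylo(t))
  leaves <- lapply(phy, function(t) sort(t$tip.label))
  if (!all(vapply(leaves, identical, logical(1L), y = leaves[[1L]])))
    stop("trees have mismatched leaf sets", call. = FALSE)
  class(phy) <- "multiPhylo"
  ape::consensus(phy, p = p)
}

#' Topological path difference between two trees
#'
#' The path difference between unrooted topologies: each tree is reduced to
#' the vector of leaf-pair path lengths in edges, and the metric is the
#' Euclidean distance between the two vectors. The comparison is purely
#' topological (edge lengths are ignored). Multifurcations are resolved
#' uniformly at random into binary subtrees; with `n_rep` replicates the
#' mean over replicates is returned (a single evaluation when both trees
#' are already binary).
#'
#' @param t1,t2 `phylo` trees or [stats::hclust] dendrograms on the same
#'   leaf set.
#' @param n_rep number of random-resolution replicates (default 2000).
#' @param seed integer RNG seed for the resolutions.
#' @return mean path difference (a single number).
#' @export
path_difference <- function(t1, t2, n_rep = 2000L, seed = 1L) {
  as_topo <- function(t) {
    t <- if (inherits(t, "phylo")) t else ape::as.phylo(t)
    t$edge.length <- NULL
    ape::unroot(t)
  }
  t1 <- as_topo(t1)
  t2 <- as_topo(t2)
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have mismatched leaf sets", call. = FALSE)
  binary <- ape::is.binary(t1) && ape::is.binary(t2)
  if (binary)
    return(as.numeric(phangorn::path.dist(t1, t2, use.weight = FALSE)))
  with_seed(seed, {
    mean(vapply(seq_len(n_rep), function(i) {
      r1 <- if (ape::is.binary(t1)) t1 else
        ape::unroot(ape::multi2di(t1, random = TRUE))
      r2 <- if (ape::is.binary(t2)) t2 else
        ape::unroot(ape::multi2di(t2, random = TRUE))
      as.numeric(phangorn::path.dist(r1, r2, use.weight = FALSE))
    }, numeric(1L)))
  })
}

#' Bundled ecological trait table
#'
#' Categorical traits (symbiont type, habitat depth, geographical range) for
#' the 15 macroperforate planktonic foraminifer species shared between the
#' semi-3D and CT reference datasets; the input to the ecological Jaccard
#' clustering.
#'
#' @return data frame with rownames = species and columns `symbiont`,
#'   `habitat_depth`, `geographic_range`.
#' @export
ecology_traits <- function() {
  path <- system.file("extdata", "ecology_traits.csv", package = "stackhull",
                      mustWork = TRUE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  rownames(df) <- df$species
  df$species <- NULL
  df
}
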