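#' Exact volume and surface area of the imaged top hull
#'
#' The top (imaged) half-hull is measured exactly from the cleaned grid:
#' volume as the sum of valid pixel heights times the pixel area, surface
#' area as the summed areas of the triangulated heightfield.
#'
#' @param x a [heightgrid()] or a `"halfhull_mesh"`.
#' @return list with `V_top_um3` and `SA_top_um2`.
#' @export
top_hull_measures <- function(x) {
  if (inherits(x, "heightgrid")) {
    if (!any(x$valid)) stop("empty grid", call. = FALSE)
    mesh <- build_mesh(x)
    V <- sum(x$heights[x$valid]) * x$px_um^2
  } else if (inherits(x, "halfhull_mesh")) {
    mesh <- x
    g <- x$grid
    V <- sum(g$heights[g$valid]) * g$px_um^2
  } else stop("need a heightgrid or halfhull_mesh", call. = FALSE)
  v <- mesh$vertices
  f <- mesh$faces
  SA <- if (nrow(f)) {
    a <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
    b <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
    cx <- a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L]
    cy <- a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L]
    cz <- a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L]
    sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
  } else 0
  list(V_top_um3 = V, SA_top_um2 = SA)
}

#' Height of the hull base above the slide plane
#'
#' The distance between the lowest image plane (the slide background) and
#' the lowest z-level of the cleaned mesh: the height `H` assigned to the
#' unobserved back half.
#'
#' @param grid a cleaned [heightgrid()].
#' @return `H_base` in micrometres.
#' @export
base_height <- function(grid) {
  stopifnot(inherits(grid, "heightgrid"))
  if (!any(grid$valid)) stop("empty grid", call. = FALSE)
  min(grid$heights[grid$valid])
}

#' Back-half estimates under three idealized base shapes
#'
#' The unobserved back of the object, a prism of height `H = H_base` below
#' the imaged hull, is bounded by three completions:
#' \describe{
#'   \item{irregular cylinder}{`V = A2D * H`, `SA = P2D * H + A2D` (lateral
#'     wall plus one base cap, following the printed convention);}
#'   \item{irregular cone}{`V = A2D * H / 3` (exactly one third of the
#'     cylinder), lateral `SA` summed over the fan of triangles between
#'     adjacent resampled perimeter points and an apex at depth `H` below
#'     the centroid;}
#'   \item{spheroidal dome}{half-ellipsoid with semi-axes
#'     `s_x = major/2`, `s_y = minor/2`, `s_z = H`:
#'     `V = (2/3) pi s_x s_y s_z`, `SA` by Thomsen's approximation with
#'     exponent `k = 1.6` (exact when all semi-axes coincide).}
#' }
#' Cylinder and cone bracket the attainable volume; the dome is the
#' reference shape for spherical taxa.
#'
#' @param params a [shape_params()] result.
#' @param H_base back-half height in micrometres (>= 0).
#' @param k Thomsen exponent.
#' @param perimeter optional [resample_perimeter()] result; required for the
#'   cone surface area (`NA` otherwise).
#' @return list of back-half `(V_um3, SA_um2)` pairs: `cone`, `cylinder`,
#'   `dome`.
#' @export
estimate_bases <- function(params, H_base, k = 1.6, perimeter = NULL) {
  stopifnot(inherits(params, "shape2d_params"))
  if (H_base < 0) stop("`H_base` must be >= 0", call. = FALSE)
  A <- params$area_um2
  P <- params$perimeter_um
  cyl <- c(V_um3 = A * H_base, SA_um2 = P * H_base + A)
  cone_sa <- NA_real_
  if (!is.null(perimeter)) {
    pts <- perimeter$coords_um
    ctr <- perimeter$centroid_um
    apex <- c(ctr[1L], ctr[2L], H_base)
    p3 <- cbind(pts, 0)
    nxt <- c(2:nrow(p3), 1L)
    a <- p3[nxt, , drop = FALSE] - p3
    b <- matrix(apex, nrow(p3), 3L, byrow = TRUE) - p3
    cx <- a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L]
    cy <- a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L]
    cz <- a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L]
    cone_sa <- sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
  }
  cone <- c(V_um3 = A * H_base / 3, SA_um2 = cone_sa)
  sx <- params$major_um / 2
  sy <- params$minor_um / 2
  sz <- H_base
  dome_sa <- 0.5 * 4 * pi *
    (((sx * sy)^k + (sx * sz)^k + (sy * sz)^k) / 3)^(1 / k)
  dome <- c(V_um3 = 0.5 * 4 / 3 * pi * sx * sy * sz, SA_um2 = dome_sa)
  list(cone = cone, cylinder = cyl, dome = dome)
}

#' Full-object size estimate with back-shape uncertainty
#'
#' Combines the exact top-hull measures with the three back-half
#' completions into full-object estimates `E_con <= E_dom <= E_cyl`
#' (volume), and the back-shape uncertainty
#' `U = 100 (E_cyl - E_con) / E_dom` (percent, computed separately for
#' volume and surface area; the SA spread is signed and may be negative).
#'
#' @param grid the cleaned [heightgrid()].
#' @param params a [shape_params()] result for the same object.
#' @param perimeter a [resample_perimeter()] result (for the cone SA).
#' @param k Thomsen exponent.
#' @return an object of class `"size_estimate"`: `V_top_um3`, `SA_top_um2`,
#'   `H_base_um`, full-object `E_con`, `E_cyl`, `E_dom` (each `(V, SA)`),
#'   `U_vol_pct`, `U_sa_pct`.
#' @export
size_estimate <- function(grid, params, perimeter = NULL, k = 1.6) {
  top <- top_hull_measures(grid)
  H <- base_height(grid)
  backs <- estimate_bases(params, H, k = k, perimeter = perimeter)
  full <- lapply(backs, function(e)
    c(V_um3 = unname(e["V_um3"]) + top$V_top_um3,
      SA_um2 = unname(e["SA_um2"]) + top$SA_top_um2))
  u <- uncertainty(list(E_con = full$cone, E_cyl = full$cylinder,
                        E_dom = full$dome))
  structure(c(list(V_top_um3 = top$V_top_um3, SA_top_um2 = top$SA_top_um2,
                   H_base_um = H, E_con = full$cone, E_cyl = full$cylinder,
                   E_dom = full$dome), u),
            class = "size_estimate")
}

#' Back-shape uncertainty, normalized to the dome estimate
#'
#' `U = 100 (E_cyl - E_con) / E_dom`, computed separately for volume and
#' surface area. The volume spread is always >= 0 (a cylindrical back
#' encloses the conical one); the surface-area spread is signed.
#'
#' @param est list with full-object `E_con`, `E_cyl`, `E_dom`, each a
#'   `(V_um3, SA_um2)` pair.
#' @return list with `U_vol_pct`, `U_sa_pct`.
#' @export
uncertainty <- function(est) {
  for (nm in c("E_con", "E_cyl", "E_dom"))
    if (is.null(est[[nm]])) stop("missing estimate: ", nm, call. = FALSE)
  if (est$E_dom["V_um3"] == 0 ||
      (!is.na(est$E_dom["SA_um2"]) && est$E_dom["SA_um2"] == 0))
    stop("dome estimate is zero", call. = FALSE)
  list(U_vol_pct = unname(100 * (est$E_cyl["V_um3"] - est$E_con["V_um3"]) /
                            est$E_dom["V_um3"]),
       U_sa_pct = unname(100 * (est$E_cyl["SA_um2"] - est$E_con["SA_um2"]) /
                           est$E_dom["SA_um2"]))
}

#' @export
print.size_estimate <- function(x, ...) {
  cat(sprintf(
    "<size_estimate> V_top %.4g um^3, SA_top %.4g um^2, H %.4g um\n",
    x$V_top_um3, x$SA_top_um2, x$H_base_um))
  cat(sprintf("  volume: cone %.4g | dome %.4g | cylinder %.4g (U = %.2f%%)\n",
              x$E_con["V_um3"], x$E_dom["V_um3"], x$E_cyl["V_um3"],
              x$U_vol_pct))
  invisible(x)
}

#' Assemblage size census: per-site kernel densities and quantile contrasts
#'
#' Summarizes per-object 2D outline areas and dome-based semi-3D volumes by
#' site: Gaussian kernel densities (Silverman's rule-of-thumb bandwidth),
#' summary quantiles and pairwise fold-differences of a chosen quantile
#' between sites. Sites with a single object contribute to the table but
#' get no density.
#'
#' @param objects data frame with columns `site`, `area_um2`,
#'   `volume_dome_um3` (one row per object).
#' @param probs quantiles to tabulate.
#' @param fold_prob quantile used for the pairwise fold-difference matrix.
#' @return list with `table` (the input, invisibly augmented),
#'   `density_area`, `density_volume` (named lists of [stats::density()]
#'   objects), `quantiles_area`, `quantiles_volume` (site x prob matrices)
#'   and `fold_volume` (pairwise ratio matrix at `fold_prob`).
#' @export
size_census <- function(objects, probs = c(0.05, 0.25, 0.5, 0.75, 0.95),
                        fold_prob = 0.5) {
  stopifnot(is.data.frame(objects),
            all(c("site", "area_um2", "volume_dome_um3") %in% names(objects)))
  sites <- unique(as.character(objects$site))
  dens <- function(v) if (length(v) >= 2L) density(v, bw = "nrd0") else NULL
  d_area <- setNames(lapply(sites, function(s)
    dens(objects$area_um2[objects$site == s])), sites)
  d_vol <- setNames(lapply(sites, function(s)
    dens(objects$volume_dome_um3[objects$site == s])), sites)
  qmat <- function(col) {
    m <- t(vapply(sites, function(s)
      quantile(objects[[col]][objects$site == s], probs),
      numeric(length(probs))))
    rownames(m) <- sites
    m
  }
  qa <- qmat("area_um2")
  qv <- qmat("volume_dome_um3")
  fq <- vapply(sites, function(s)
    quantile(objects$volume_dome_um3[objects$site == s], fold_prob),
    numeric(1L))
  fold <- outer(fq, fq, `/`)
  dimnames(fold) <- list(sites, sites)
  list(table = objects, density_area = d_area, density_volume = d_vol,
       quantiles_area = qa, quantiles_volume = qv, fold_volume = fold)
}
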