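#' Extract a semi-3D half-hull from a per-object z-stack
#'
#' The full per-object pipeline: build the height map (local-variance
#' shape-from-focus) and EDF composite, rescale both so 1 px = 1 um,
#' extract filled and unfilled 2D outlines from the EDF (the difference
#' marks the aperture), mask the background, decode heights, run the
#' sliding quartile outlier filter, prune sparse z-levels (and the bottom
#' level), floor the aperture to the lowest height, and triangulate.
#'
#' @param zs a per-object [zstack()].
#' @param threshold outline binarization threshold (default 0.18).
#' @param kernel focus-measure window (default 11).
#' @param filter_n quartile-filter window (default 45); `NA` skips the
#'   filter.
#' @param prune_frac minimum z-level occupancy (default 0.01).
#' @param drop_bottom remove the bottom-most z-level (default `TRUE`).
#' @param mask_aperture detect and floor the aperture (default `TRUE`).
#' @param object_id identifier recorded in the mesh provenance.
#' @return list with `heightmap`, `edf`, `outline` (filled),
#'   `outline_unfilled`, `aperture`, `grid` (cleaned [heightgrid()]),
#'   `mesh`, `params` ([shape_params()]), `perimeter`
#'   ([resample_perimeter()]), `size` ([size_estimate()]).
#' @export
extract_halfhull <- function(zs, threshold = 0.18, kernel = 11L,
                             filter_n = 45L, prune_frac = 0.01,
                             drop_bottom = TRUE, mask_aperture = TRUE,
                             object_id = "object") {
  stopifnot(inherits(zs, "zstack"))
  hm <- build_height_map(zs, kernel = kernel)
  edf <- build_edf(zs, hm)
  if (zs$px_um != 1) {
    hm <- rescale_unit_pixels(hm, zs$px_um)
    edf <- rescale_unit_pixels(edf, zs$px_um)
  }
  filled <- extract_outline(edf, threshold, fill_holes = TRUE, px_um = 1)
  unfilled <- extract_outline(edf, threshold, fill_holes = FALSE, px_um = 1)
  ap <- if (mask_aperture) aperture_mask(filled, unfilled)
        else matrix(FALSE, nrow(edf), ncol(edf))
  fp <- filled$mask & !ap
  hm <- mask_background(hm, fp)
  grid <- heights_from_map(hm)
  if (!is.na(filter_n)) grid <- outlier_filter(grid, n = filter_n)
  grid <- prune_z_levels(grid, frac = prune_frac, drop_bottom = drop_bottom)
  grid <- set_aperture_depth(grid, ap)
  params <- shape_params(filled)
  perim <- resample_perimeter(filled, n = 100L)
  mesh <- build_mesh(grid, provenance = list(
    object_id = object_id, threshold = threshold, kernel = kernel,
    filter_n = filter_n, prune_frac = prune_frac))
  size <- size_estimate(grid, params, perimeter = perim)
  list(heightmap = hm, edf = edf, outline = filled,
       outline_unfilled = unfilled, aperture = ap, grid = grid,
       mesh = mesh, params = params, perimeter = perim, size = size)
}

#' Flatten an object's measurements to a one-row data frame
#'
#' The per-object CSV record: 2D shape parameters, exact top-hull measures,
#' the three full-object estimates and the back-shape uncertainties.
#'
#' @param result an [extract_halfhull()] result.
#' @param object_id identifier for the row.
#' @return one-row data frame.
#' @export
measure_row <- function(result, object_id = "object") {
  p <- result$params
  s <- result$size
  data.frame(
    object_id = object_id,
    A2D_um2 = p$area_um2, P2D_um = p$perimeter_um,
    major_um = p$major_um, minor_um = p$minor_um,
    eccentricity = p$eccentricity, aspect_ratio = p$aspect_ratio,
    rugosity = p$rugosity,
    H_base_um = s$H_base_um,
    V_top_um3 = s$V_top_um3, SA_top_um2 = s$SA_top_um2,
    V_cone_um3 = unname(s$E_con["V_um3"]),
    V_cyl_um3 = unname(s$E_cyl["V_um3"]),
    V_dome_um3 = unname(s$E_dom["V_um3"]),
    SA_cone_um2 = unname(s$E_con["SA_um2"]),
    SA_cyl_um2 = unname(s$E_cyl["SA_um2"]),
    SA_dome_um2 = unname(s$E_dom["SA_um2"]),
    U_vol_pct = s$U_vol_pct, U_sa_pct = s$U_sa_pct)
}
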