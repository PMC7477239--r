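#' Mean lamina cribrosa depth (LCD)
#'
#' For every delineated LC grid node whose projection onto the BMO reference
#' plane falls inside the projected BMO polygon, computes the signed
#' perpendicular distance to the plane (positive = posterior/deeper, anterior
#' excursions contribute negative values) and returns the arithmetic mean and
#' the number of contributing nodes. Missing LC is never interpolated;
#' on-boundary projections count as inside.
#'
#' @param volume A [segmented_onh_volume()].
#' @param plane Optional [fit_bmo_plane()] result; fitted from the volume's
#'   BMO ring when omitted.
#' @return List with `mean_lcd` (um) and `n_lcd_samples`.
#' @export
compute_lcd <- function(volume, plane = NULL) {
  stopifnot(inherits(volume, "segmented_onh_volume"))
  if (is.null(plane)) plane <- fit_bmo_plane(volume$bmo_points)
  nodes <- grid_nodes(volume$geometry, volume$lc_height)
  if (nrow(nodes) == 0L)
    stop("compute_lcd: no delineated LC nodes (empty LC)", call. = FALSE)
  poly <- project_to_plane(volume$bmo_points, plane)
  poly <- poly[order_by_angle(poly), , drop = FALSE]
  uv <- project_to_plane(nodes, plane)
  keep <- point_in_polygon(uv[, 1L], uv[, 2L], poly[, 1L], poly[, 2L])
  if (!any(keep))
    stop("compute_lcd: no delineated LC node projects inside the BMO polygon (empty LC)",
         call. = FALSE)
  d <- signed_plane_distance(nodes[keep, , drop = FALSE], plane)
  list(mean_lcd = mean(d), n_lcd_samples = length(d))
}
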