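#' Lamina cribrosa visibility
#'
#' Percentage of the BMO area, seen enface, over which the anterior LC was
#' delineated. The enface (lateral) projection of the BMO ring is rasterised
#' on the scan lattice with cell-centre inclusion: a grid node counts as a
#' BMO cell when it lies inside the enface polygon (boundary counts inside).
#' Visibility is 100 x (BMO cells with non-missing LC) / (BMO cells), i.e.
#' both numerator and denominator are measured on the same raster, so a fully
#' delineated LC scores exactly 100.
#'
#' @param volume A [segmented_onh_volume()].
#' @param plane Unused placeholder kept for interface symmetry with the other
#'   measures (visibility is an enface quantity).
#' @return Visibility in percent, clamped to `[0, 100]`.
#' @export
compute_lc_visibility <- function(volume, plane = NULL) {
  stopifnot(inherits(volume, "segmented_onh_volume"))
  g <- volume$geometry
  gc <- grid_coords(g)
  ring <- volume$bmo_points[, 1:2, drop = FALSE]
  ring <- ring[order_by_angle(ring), , drop = FALSE]
  if (nrow(unique(ring)) < 3L || polygon_area_xy(ring) <= 0)
    stop("compute_lc_visibility: degenerate enface BMO polygon", call. = FALSE)
  nx <- rep(gc$x, each = g$n_bscans)
  ny <- rep(gc$y, times = g$n_ascans)
  inside <- point_in_polygon(nx, ny, ring[, 1L], ring[, 2L])
  n_in <- sum(inside)
  if (n_in == 0L)
    stop("compute_lc_visibility: BMO polygon contains no grid cells",
         call. = FALSE)
  vis <- 100 * sum(is.finite(volume$lc_height[inside])) / n_in
  min(100, max(0, vis))
}
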