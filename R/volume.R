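#' Segmented ONH volume
#'
#' The delineated geometry of one eye at one visit: the internal limiting
#' membrane (ILM) height grid, the anterior lamina cribrosa (LC) height grid
#' (missing where the LC was not delineated), and the ordered ring of Bruch's
#' membrane opening (BMO) points. Heights are axial positions in um with
#' larger z = more posterior (deeper).
#'
#' @param geometry A [scan_geometry()].
#' @param ilm_height Numeric matrix `n_bscans x n_ascans` of ILM axial
#'   positions (um); `NA` allowed.
#' @param lc_height Numeric matrix of the same shape for the anterior LC
#'   surface; `NA` means not delineated there.
#' @param bmo_points Ordered ring of at least 8 points, n x 3 matrix
#'   (x, y, z um). Must form a simple closed ring when projected onto its
#'   best-fit plane.
#' @param axial_range Optional length-2 numeric; all finite heights must lie
#'   within it.
#' @return Object of class `segmented_onh_volume`.
#' @export
segmented_onh_volume <- function(geometry, ilm_height, lc_height, bmo_points,
                                 axial_range = NULL) {
  stopifnot(inherits(geometry, "scan_geometry"))
  ilm_height <- as.matrix(ilm_height)
  lc_height <- as.matrix(lc_height)
  dims <- c(geometry$n_bscans, geometry$n_ascans)
  if (!identical(dim(ilm_height), dims))
    stop("segmented_onh_volume: ilm_height must be n_bscans x n_ascans",
         call. = FALSE)
  if (!identical(dim(lc_height), dims))
    stop("segmented_onh_volume: lc_height must be n_bscans x n_ascans",
         call. = FALSE)
  pts <- as_points_matrix(bmo_points)
  if (nrow(pts) < 8L)
    stop("segmented_onh_volume: BMO ring needs at least 8 points",
         call. = FALSE)
  plane <- fit_bmo_plane(pts)
  uv <- project_to_plane(pts, plane)
  if (!is_simple_polygon(uv))
    stop("segmented_onh_volume: projected BMO ring is self-intersecting",
         call. = FALSE)
  if (!is.null(axial_range)) {
    stopifnot(length(axial_range) == 2L, axial_range[1] <= axial_range[2])
    h <- c(ilm_height, lc_height, pts[, 3L])
    h <- h[is.finite(h)]
    if (length(h) && (min(h) < axial_range[1] || max(h) > axial_range[2]))
      stop("segmented_onh_volume: heights outside declared axial range",
           call. = FALSE)
  }
  structure(
    list(geometry = geometry, ilm_height = ilm_height, lc_height = lc_height,
         bmo_points = pts, axial_range = axial_range,
         axial_convention = "larger z = posterior"),
    class = "segmented_onh_volume"
  )
}

#' @export
print.segmented_onh_volume <- function(x, ...) {
  cat(sprintf(
    "Segmented ONH volume: %d x %d grid, %d BMO points, LC delineated at %d nodes\n",
    x$geometry$n_bscans, x$geometry$n_ascans, nrow(x$bmo_points),
    sum(is.finite(x$lc_height))))
  invisible(x)
}

# Grid nodes as an m x 3 matrix (x, y, z) for finite entries of a height grid.
grid_nodes <- function(geometry, height) {
  gc <- grid_coords(geometry)
  keep <- which(is.finite(height), arr.ind = TRUE)
  cbind(x = gc$x[keep[, 2L]], y = gc$y[keep[, 1L]], z = height[keep])
}
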