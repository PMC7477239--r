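#' OCT raster scan geometry
#'
#' Describes the sampling lattice of a segmented ONH volume. Defaults match a
#' 15 x 15 degree Spectralis ONH raster: 73 horizontal B-scans spaced 62 um
#' apart, 384 A-scans per B-scan. The lateral A-scan spacing is not printed by
#' the instrument for this protocol; the default 11.6 um makes 384 A-scans
#' span approximately the same physical field as the B-scan direction, and it
#' is exposed as a parameter rather than hard-coded behind an eye model.
#'
#' Grid convention: height grids are `n_bscans` rows by `n_ascans` columns;
#' the lateral x axis runs along A-scans (columns), the lateral y axis along
#' B-scans (rows). Axial z is in micrometres with larger z = more posterior.
#'
#' @param n_bscans Number of B-scans (rows), at least 2.
#' @param n_ascans Number of A-scans per B-scan (columns), at least 2.
#' @param bscan_spacing Distance between adjacent B-scans, um.
#' @param ascan_spacing Distance between adjacent A-scans, um.
#' @return An object of class `scan_geometry`.
#' @export
#' @examples
#' g <- scan_geometry()
#' field_extent(g)  # physical field in um (x, y)
scan_geometry <- function(n_bscans = 73L, n_ascans = 384L,
                          bscan_spacing = 62, ascan_spacing = 11.6) {
  n_bscans <- as.integer(n_bscans)
  n_ascans <- as.integer(n_ascans)
  if (is.na(n_bscans) || is.na(n_ascans) || n_bscans < 2L || n_ascans < 2L)
    stop("scan_geometry: counts must be integers >= 2", call. = FALSE)
  if (!is.finite(bscan_spacing) || !is.finite(ascan_spacing) ||
      bscan_spacing <= 0 || ascan_spacing <= 0)
    stop("scan_geometry: spacings must be > 0", call. = FALSE)
  structure(
    list(n_bscans = n_bscans, n_ascans = n_ascans,
         bscan_spacing = as.numeric(bscan_spacing),
         ascan_spacing = as.numeric(ascan_spacing),
         axial_unit = "um"),
    class = "scan_geometry"
  )
}

#' Physical field extent of a scan geometry
#'
#' @param geometry A [scan_geometry()].
#' @return Named numeric: extent along x (A-scan direction) and y (B-scan
#'   direction), in um.
#' @export
field_extent <- function(geometry) {
  stopifnot(inherits(geometry, "scan_geometry"))
  c(x = (geometry$n_ascans - 1L) * geometry$ascan_spacing,
    y = (geometry$n_bscans - 1L) * geometry$bscan_spacing)
}

# Lateral node coordinates of the grid (node-registered).
grid_coords <- function(geometry) {
  list(x = (seq_len(geometry$n_ascans) - 1) * geometry$ascan_spacing,
       y = (seq_len(geometry$n_bscans) - 1) * geometry$bscan_spacing)
}

#' @export
print.scan_geometry <- function(x, ...) {
  ext <- field_extent(x)
  cat(sprintf("OCT scan geometry: %d B-scans x %d A-scans (%.1f x %.1f um field)\n",
              x$n_bscans, x$n_ascans, ext["x"], ext["y"]))
  invisible(x)
}
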