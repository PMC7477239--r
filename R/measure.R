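#' Full morphometry of a segmented ONH volume
#'
#' Fits the BMO reference plane, then computes the four structural measures:
#' BMO area (mm^2), mean lamina cribrosa depth (um, positive = posterior),
#' mean minimum rim width (um, rim-constrained), and LC visibility (percent
#' of the enface BMO area with delineated LC).
#'
#' @param volume A [segmented_onh_volume()].
#' @return Object of class `morphometry_result`: a list with `mean_mrw`,
#'   `mean_lcd`, `bmo_area`, `lc_visibility`, `n_bmo_points`,
#'   `n_lcd_samples`, `rms_plane_residual` and `per_point_mrw`.
#' @export
#' @examples
#' ph <- make_phantom_volume(phantom_params(lc_shape = "flat"))
#' measure_volume(ph$volume)
measure_volume <- function(volume) {
  stopifnot(inherits(volume, "segmented_onh_volume"))
  plane <- fit_bmo_plane(volume$bmo_points)
  area <- compute_bmo_area(volume$bmo_points, plane)
  lcd <- compute_lcd(volume, plane)
  mrw <- compute_mrw(volume, plane = plane)
  vis <- compute_lc_visibility(volume)
  out <- structure(
    list(mean_mrw = mrw$mean_mrw, mean_lcd = lcd$mean_lcd, bmo_area = area,
         lc_visibility = vis, n_bmo_points = nrow(volume$bmo_points),
         n_lcd_samples = lcd$n_lcd_samples,
         rms_plane_residual = plane$rms_fit_residual,
         per_point_mrw = mrw$per_point_mrw),
    class = "morphometry_result"
  )
  if (isTRUE(attr(mrw, "high_missing_ilm"))) {
    attr(out, "high_missing_ilm") <- TRUE
    warning("more than 25% of ILM nodes inside the BMO are missing",
            call. = FALSE)
  }
  out
}

#' @export
print.morphometry_result <- function(x, ...) {
  cat(sprintf(paste0(
    "ONH morphometry\n",
    "  mean MRW:      %8.2f um (over %d BMO points)\n",
    "  mean LCD:      %8.2f um (over %d LC nodes)\n",
    "  BMO area:      %8.4f mm^2\n",
    "  LC visibility: %8.2f %%\n"),
    x$mean_mrw, x$n_bmo_points, x$mean_lcd, x$n_lcd_samples,
    x$bmo_area, x$lc_visibility))
  invisible(x)
}

#' One-row data frame of a morphometry result
#'
#' @param x A `morphometry_result`.
#' @param ... Unused.
#' @export
as.data.frame.morphometry_result <- function(x, ...) {
  data.frame(mean_mrw = x$mean_mrw, mean_lcd = x$mean_lcd,
             bmo_area = x$bmo_area, lc_visibility = x$lc_visibility,
             n_bmo_points = x$n_bmo_points, n_lcd_samples = x$n_lcd_samples)
}
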