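#' Per-interval structural change statistics
#'
#' For each consecutive month interval, computes the per-eye change
#' `metric(m + 1) - metric(m)`, and reports the mean, sample SD (n - 1
#' denominator) and a two-sided one-sample paired t-test p-value across eyes.
#' When all per-eye changes are identical (zero SD) the p-value is reported
#' as 1 by convention and the row is flagged `degenerate`.
#'
#' The original study analysed these contrasts with a repeated-measures mixed
#' model; the paired t-test here is a documented substitution, so printed
#' mixed-model p-values are not exact reproduction targets.
#'
#' @param cohort A `cohort_table` (or any data frame with `primate_id`,
#'   `eye`, `treatment`, `month` and the metric column).
#' @param metric `"mrw"` or `"lcd"`.
#' @param arm Arm selector passed to [cohort_arm()].
#' @return Data frame with one row per interval: `from_month`, `to_month`,
#'   `mean_change`, `sd_change`, `p_value`, `n`, `degenerate`.
#' @export
monthly_change <- function(cohort, metric = c("mrw", "lcd"),
                           arm = c("oht_right", "oht_left", "oht", "control")) {
  metric <- match.arg(metric)
  sub <- cohort_arm(cohort, arm)
  months <- sort(unique(sub$month))
  if (length(months) < 2L || !all(diff(months) == 1L))
    stop("monthly_change: months must be contiguous with at least one interval",
         call. = FALSE)
  key <- paste(sub$primate_id, sub$eye)
  if (length(unique(key)) < 2L)
    stop("monthly_change: need at least 2 eyes in the arm (insufficient data)",
         call. = FALSE)
  rows <- lapply(utils::head(months, -1L), function(m) {
    a <- sub[sub$month == m, c("primate_id", "eye", metric)]
    b <- sub[sub$month == m + 1L, c("primate_id", "eye", metric)]
    mg <- merge(a, b, by = c("primate_id", "eye"), suffixes = c("_a", "_b"))
    diffs <- mg[[paste0(metric, "_b")]] - mg[[paste0(metric, "_a")]]
    diffs <- diffs[!is.na(diffs)]
    n <- length(diffs)
    if (n < 2L)
      stop("monthly_change: fewer than 2 paired eyes in interval ", m,
           call. = FALSE)
    s <- stats::sd(diffs)
    degen <- s == 0
    p <- if (degen) 1 else stats::t.test(diffs)$p.value
    data.frame(from_month = m, to_month = m + 1L, mean_change = mean(diffs),
               sd_change = s, p_value = p, n = n, degenerate = degen)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
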