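#' Aggregate weekly IOP readings into monthly summaries
#'
#' Months are fixed `weeks_per_month`-week blocks anchored at the first study
#' week: month m covers weeks `weeks_per_month * (m - 1) + 1` to
#' `weeks_per_month * m`. The mean and maximum are computed over the present
#' (non-missing) readings of each block; months with no readings are omitted.
#'
#' @param series An `iop_series` or numeric vector of weekly IOP (week 1
#'   first; `NA` = missed visit).
#' @param weeks_per_month Block length, default 4.
#' @return Data frame with columns `month`, `mean_iop`, `max_iop`.
#' @export
#' @examples
#' monthly_aggregate(c(10, 12, 14, 16))  # month 1: mean 13, max 16
monthly_aggregate <- function(series, weeks_per_month = 4L) {
  x <- if (inherits(series, "iop_series")) series$weekly_iop else as.numeric(series)
  if (length(x) == 0L)
    stop("monthly_aggregate: empty series", call. = FALSE)
  wpm <- as.integer(weeks_per_month)
  stopifnot(wpm >= 1L)
  n_months <- ceiling(length(x) / wpm)
  rows <- lapply(seq_len(n_months), function(m) {
    idx <- (wpm * (m - 1L) + 1L):min(wpm * m, length(x))
    v <- x[idx]
    v <- v[!is.na(v)]
    if (length(v) == 0L) return(NULL)
    data.frame(month = m, mean_iop = mean(v), max_iop = max(v))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(month = integer(0), mean_iop = numeric(0),
                                      max_iop = numeric(0))
  out
}

#' Summarise IOP over the ocular-hypertension period
#'
#' Averages the monthly mean IOP and the monthly maximum IOP over a month
#' range (months 2-7 by default, the post-induction period).
#'
#' @param monthly Data frame from [monthly_aggregate()] (columns `month`,
#'   `mean_iop`, `max_iop`).
#' @param from_month,to_month Inclusive month range.
#' @return List with `mean` (average monthly mean IOP, mmHg) and `max_mean`
#'   (average monthly maximum IOP, mmHg).
#' @export
oht_period_summary <- function(monthly, from_month = 2L, to_month = 7L) {
  stopifnot(is.data.frame(monthly),
            all(c("month", "mean_iop", "max_iop") %in% names(monthly)))
  sel <- monthly$month >= from_month & monthly$month <= to_month
  if (!any(sel))
    stop("oht_period_summary: no months in requested range", call. = FALSE)
  list(mean = mean(monthly$mean_iop[sel]),
       max_mean = mean(monthly$max_iop[sel]))
}
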