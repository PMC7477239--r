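#' Group summary of a study table column
#'
#' Arithmetic mean and sample SD (n - 1 denominator) of one column over a
#' selection of rows. Works on the packaged per-animal study tables
#' ([load_fixture()]) and on simulated `cohort_table`s. Selectors are applied
#' only when the corresponding column exists: `group`, `eye`, `timepoint`,
#' `month`, `treatment`. For wide per-animal tables without an `eye` column
#' (one row per animal, columns suffixed `_od`/`_os`), the `eye` selector
#' picks the suffixed column instead.
#'
#' @param table A data frame.
#' @param column Column to summarise (un-suffixed name for wide tables).
#' @param group,eye,timepoint,month,treatment Optional row selectors.
#' @return List with `mean`, `sd` (0 when n = 1, flagged) and `n`.
#' @export
#' @examples
#' t2 <- load_fixture("table2_morphometry")
#' group_summary(t2, "mrw", group = 1, eye = "OD", timepoint = "baseline")
group_summary <- function(table, column, group = NULL, eye = NULL,
                          timepoint = NULL, month = NULL, treatment = NULL) {
  stopifnot(is.data.frame(table))
  sel <- rep(TRUE, nrow(table))
  filt <- function(sel, col, val) {
    if (is.null(val) || !col %in% names(table)) return(sel)
    sel & table[[col]] %in% val
  }
  sel <- filt(sel, "group", group)
  sel <- filt(sel, "timepoint", timepoint)
  sel <- filt(sel, "month", month)
  sel <- filt(sel, "treatment", treatment)
  col <- column
  if (!is.null(eye)) {
    eye_code <- normalize_eye(eye)
    if ("eye" %in% names(table)) {
      sel <- sel & table[[eye_code$column_value]] == eye_code$value
    } else {
      cand <- paste0(column, "_", tolower(eye_code$value))
      if (cand %in% names(table)) col <- cand
      else stop("group_summary: no 'eye' column and no column '", cand, "'",
                call. = FALSE)
    }
  }
  if (!col %in% names(table))
    stop("group_summary: unknown column '", col, "'", call. = FALSE)
  x <- table[[col]][sel]
  x <- x[!is.na(x)]
  if (length(x) == 0L)
    stop("group_summary: empty selection", call. = FALSE)
  out <- list(mean = mean(x),
              sd = if (length(x) == 1L) 0 else stats::sd(x),
              n = length(x))
  if (length(x) == 1L) attr(out, "single_observation") <- TRUE
  out
}

# Accept "OD"/"OS", "right"/"left" in any case.
normalize_eye <- function(eye) {
  e <- toupper(as.character(eye))
  val <- switch(e,
    OD = "OD", RIGHT = "OD",
    OS = "OS", LEFT = "OS",
    stop("unknown eye selector '", eye, "'", call. = FALSE))
  list(value = val, column_value = "eye")
}
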