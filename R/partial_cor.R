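#' Pearson partial correlation controlling for subject
#'
#' Correlation between `x` and `y` after removing subject (primate) effects:
#' both variables are residualised on subject indicator variables, which for
#' a categorical control is the same as centring each within its subject's
#' mean; the Pearson correlation of the residuals is the partial correlation.
#' Degrees of freedom are `n_obs - n_subjects - 1` (subject enters as
#' `n_subjects - 1` indicators plus an intercept).
#'
#' Inference uses [fisher_z_test()].
#'
#' @param x,y Numeric vectors of equal length (pairs with missing values are
#'   dropped).
#' @param subject Subject label for each observation.
#' @return Object of class `partial_correlation`: `rho_hat`, `n_obs`,
#'   `n_subjects`, `df`, `z_stat`, `p_value`.
#' @export
#' @examples
#' # perfect within-subject trend despite offsets that flip the pooled sign
#' x <- c(1:5, 11:15); y <- c(1:5 + 100, 11:15 - 100)
#' s <- rep(c("a", "b"), each = 5)
#' cor(x, y)                             # negative
#' partial_correlation(x, y, s)$rho_hat  # 1
partial_correlation <- function(x, y, subject) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  subject <- as.character(subject)
  if (length(x) != length(y) || length(x) != length(subject))
    stop("partial_correlation: x, y and subject must have equal length",
         call. = FALSE)
  keep <- !is.na(x) & !is.na(y) & !is.na(subject)
  x <- x[keep]; y <- y[keep]; subject <- subject[keep]
  n <- length(x)
  if (n < 3L)
    stop("partial_correlation: need at least 3 complete observations",
         call. = FALSE)
  rx <- x - stats::ave(x, subject)
  ry <- y - stats::ave(y, subject)
  vx <- sum(rx^2)
  vy <- sum(ry^2)
  if (vx <= 0 || vy <= 0)
    stop("partial_correlation: zero within-subject variance in x or y (degenerate)",
         call. = FALSE)
  rho <- sum(rx * ry) / sqrt(vx * vy)
  rho <- min(1, max(-1, rho))
  n_subj <- length(unique(subject))
  df <- n - n_subj - 1L
  if (df < 1L)
    stop("partial_correlation: non-positive degrees of freedom", call. = FALSE)
  res <- structure(
    list(rho_hat = rho, n_obs = n, n_subjects = n_subj, df = df,
         z_stat = NA_real_, p_value = NA_real_),
    class = "partial_correlation"
  )
  zt <- fisher_z_test(res)
  res$z_stat <- zt$z_stat
  res$p_value <- zt$p_value
  res
}

#' Fisher z test of a partial correlation
#'
#' Tests the null hypothesis that the partial correlation is zero using the
#' Fisher transform: `z = atanh(rho) * sqrt(n_obs - n_controls - 3)` with
#' `n_controls = n_subjects - 1` indicator covariates, against a two-sided
#' standard normal reference. A partial correlation of exactly +/-1 gives an
#' infinite statistic; the p-value is reported as 0 and the result is flagged.
#'
#' @param result A `partial_correlation`, or a list with `rho_hat`, `n_obs`,
#'   `n_subjects`.
#' @return List with `z_stat`, `p_value` and logical `infinite`.
#' @export
fisher_z_test <- function(result) {
  rho <- result$rho_hat
  n <- result$n_obs
  n_controls <- result$n_subjects - 1L
  eff <- n - n_controls - 3
  if (eff < 2)
    stop("fisher_z_test: effective sample size too small", call. = FALSE)
  if (abs(rho) >= 1) {
    return(list(z_stat = sign(rho) * Inf, p_value = 0, infinite = TRUE))
  }
  z <- atanh(rho) * sqrt(eff)
  list(z_stat = z, p_value = 2 * stats::pnorm(-abs(z)), infinite = FALSE)
}

#' @export
print.partial_correlation <- function(x, ...) {
  cat(sprintf(
    "Partial correlation (subject-controlled): rho = %.3f (n = %d, %d subjects, df = %d), z = %.3f, p = %.3g\n",
    x$rho_hat, x$n_obs, x$n_subjects, x$df, x$z_stat, x$p_value))
  invisible(x)
}
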