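#' Generate a synthetic longitudinal OHT cohort
#'
#' Simulates the full study: `n_group1` animals with a right OHT eye and a
#' contralateral control eye, plus `n_group2` animals with two OHT eyes.
#' Weekly IOP series are simulated per eye ([simulate_iop_series()]) and
#' aggregated monthly ([monthly_aggregate()]); month 0 holds the baseline
#' measurement. MRW/LCD start at Gaussian baseline draws and change each
#' month by `iop_structure_slope_* x (monthly mean-IOP increment)` plus
#' trajectory noise, so the largest expected structural change falls in the
#' month 1 to 2 interval where the IOP rise concentrates.
#'
#' All randomness derives from `params$seed` through per-eye substreams:
#' identical seeds give bit-identical tables, and adding animals does not
#' perturb existing ones.
#'
#' @param params A [cohort_params()].
#' @return A `cohort_table`: data frame with columns `primate_id`, `eye`
#'   (`OD`/`OS`), `group` (1/2), `treatment` (`OHT`/`control`), `month`
#'   (0 = baseline), `mean_iop`, `max_iop` (mmHg), `mrw`, `lcd` (um).
#' @export
#' @examples
#' tab <- generate_cohort(cohort_params(seed = 42))
#' nrow(tab)  # 16 animals x 2 eyes x 8 months = 256
generate_cohort <- function(params = cohort_params()) {
  stopifnot(inherits(params, "cohort_params"))
  eyes <- cohort_design(params)
  n_months <- floor(params$study_weeks / params$weeks_per_month)
  lag <- params$structure_lag

  rows <- lapply(seq_len(nrow(eyes)), function(i) {
    id <- eyes$primate_id[i]
    eye <- eyes$eye[i]
    series <- simulate_iop_series(
      params, group = eyes$group[i], treatment = eyes$treatment[i],
      seed = derive_seed(params$seed, paste0("cohort/", id, "/", eye)),
      primate_id = id, eye = eye)
    monthly <- monthly_aggregate(series, params$weeks_per_month)
    monthly <- monthly[monthly$month <= n_months, , drop = FALSE]
    iop_mean <- c(series$baseline_iop, monthly$mean_iop)
    iop_max <- c(series$baseline_iop, monthly$max_iop)

    draws <- with_seed(derive_seed(params$seed, paste0("structure/", id, "/", eye)), {
      list(mrw0 = stats::rnorm(1, params$baseline_mrw_mean, params$baseline_mrw_sd),
           lcd0 = stats::rnorm(1, params$baseline_lcd_mean, params$baseline_lcd_sd),
           eps_mrw = stats::rnorm(n_months, 0, params$mrw_traj_noise_sd),
           eps_lcd = stats::rnorm(n_months, 0, params$lcd_traj_noise_sd))
    })
    d_iop <- diff(iop_mean)                       # increments m -> m+1
    if (lag > 0) d_iop <- c(rep(0, lag), utils::head(d_iop, -lag))
    mrw <- draws$mrw0 + cumsum(c(0, params$iop_structure_slope_mrw * d_iop +
                                   draws$eps_mrw))
    lcd <- draws$lcd0 + cumsum(c(0, params$iop_structure_slope_lcd * d_iop +
                                   draws$eps_lcd))
    data.frame(primate_id = id, eye = eye, group = eyes$group[i],
               treatment = eyes$treatment[i], month = 0:n_months,
               mean_iop = iop_mean, max_iop = iop_max, mrw = mrw, lcd = lcd)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cohort_table", "data.frame")
  out
}

# Study design: one row per eye.
cohort_design <- function(params) {
  g1 <- if (params$n_group1 > 0L) {
    ids <- sprintf("G1-%02d", seq_len(params$n_group1))
    data.frame(primate_id = rep(ids, each = 2L),
               eye = rep(c("OD", "OS"), params$n_group1),
               group = 1L,
               treatment = rep(c("OHT", "control"), params$n_group1))
  } else NULL
  g2 <- if (params$n_group2 > 0L) {
    ids <- sprintf("G2-%02d", seq_len(params$n_group2))
    data.frame(primate_id = rep(ids, each = 2L),
               eye = rep(c("OD", "OS"), params$n_group2),
               group = 2L,
               treatment = "OHT")
  } else NULL
  rbind(g1, g2)
}

#' Select an analysis arm of a cohort table
#'
#' @param cohort A `cohort_table`.
#' @param arm One of `"oht_right"` (all OHT right eyes, both groups),
#'   `"oht_left"` (Group-2 left OHT eyes), `"oht"` (all OHT eyes) or
#'   `"control"` (Group-1 untreated left eyes).
#' @return The matching rows of `cohort`.
#' @export
cohort_arm <- function(cohort, arm = c("oht_right", "oht_left", "oht", "control")) {
  arm <- match.arg(arm)
  sel <- switch(arm,
    oht_right = cohort$treatment == "OHT" & cohort$eye == "OD",
    oht_left = cohort$treatment == "OHT" & cohort$eye == "OS",
    oht = cohort$treatment == "OHT",
    control = cohort$treatment == "control")
  cohort[sel, , drop = FALSE]
}
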