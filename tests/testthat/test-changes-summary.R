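make_toy_cohort <- function(values_by_eye, metric = "mrw") {
  rows <- lapply(names(values_by_eye), function(k) {
    v <- values_by_eye[[k]]
    data.frame(primate_id = k, eye = "OD", group = 1L, treatment = "OHT",
               month = seq_along(v) - 1L, mean_iop = 20, max_iop = 25,
               mrw = if (metric == "mrw") v else 0,
               lcd = if (metric == "lcd") v else 0)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cohort_table", "data.frame")
  out
}

test_that("degenerate and two-eye change statistics", {
  tab <- make_toy_cohort(list(a = c(100, 100, 100), b = c(90, 90, 90)))
  ch <- monthly_change(tab, "mrw", arm = "oht_right")
  expect_equal(ch$mean_change, c(0, 0))
  expect_equal(ch$sd_change, c(0, 0))
  expect_equal(ch$p_value, c(1, 1))
  expect_true(all(ch$degenerate))

  tab <- make_toy_cohort(list(a = c(100, 90), b = c(100, 80)))
  ch <- monthly_change(tab, "mrw", arm = "oht_right")
  expect_equal(ch$mean_change, -15)
  expect_equal(ch$sd_change, sd(c(-10, -20)))
  expect_equal(ch$sd_change, 7.0710678, tolerance = 1e-7)
  expect_false(ch$degenerate)
  # cross-check the p-value against the paired t-test it substitutes
  expect_equal(ch$p_value, t.test(c(-10, -20))$p.value)

  expect_error(monthly_change(make_toy_cohort(list(a = c(1, 2))), "mrw"),
               "at least 2 eyes")
})

test_that("group_summary computes mean and n-1 SD with selectors", {
  tab <- generate_cohort(cohort_params(seed = 21))
  gs <- group_summary(tab, "mrw", group = 1, eye = "OD", month = 0)
  arm <- tab[tab$group == 1 & tab$eye == "OD" & tab$month == 0, ]
  expect_equal(gs$mean, mean(arm$mrw))
  expect_equal(gs$sd, sd(arm$mrw))
  expect_equal(gs$n, 10)

  one <- group_summary(tab, "mrw", group = 1, eye = "OD", month = 0,
                       treatment = "OHT")
  expect_equal(one$n, 10)

  single <- group_summary(tab[1, ], "mrw")
  expect_equal(single$sd, 0)
  expect_true(isTRUE(attr(single, "single_observation")))

  expect_error(group_summary(tab, "nope"), "unknown column")
  expect_error(group_summary(tab, "mrw", group = 99), "empty selection")
})

test_that("eye selector maps to suffixed columns on wide per-animal tables", {
  t1 <- load_fixture("table1_iop")
  expect_equal(nrow(t1), 16)
  g <- group_summary(t1, "baseline_iop", group = 1, eye = "right")
  expect_equal(round(g$mean, 1), 12.0)
  expect_error(group_summary(t1, "not_a_column", eye = "OD"), "no column")
})
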