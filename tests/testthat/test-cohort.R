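test_that("cohort table has the study design", {
  tab <- generate_cohort(cohort_params(seed = 42))
  expect_equal(nrow(tab), 256)
  expect_equal(length(unique(tab$primate_id)), 16)
  expect_equal(nrow(unique(tab[, c("primate_id", "eye")])), 32)
  expect_equal(sort(unique(tab$month)), 0:7)
  expect_false(any(duplicated(tab[, c("primate_id", "eye", "month")])))
  # group 1: one OHT and one control eye per animal; group 2: two OHT eyes
  g1 <- unique(tab[tab$group == 1, c("primate_id", "eye", "treatment")])
  per <- table(g1$primate_id, g1$treatment)
  expect_true(all(per[, "OHT"] == 1) && all(per[, "control"] == 1))
  g2 <- unique(tab[tab$group == 2, c("primate_id", "eye", "treatment")])
  expect_true(all(g2$treatment == "OHT"))
  expect_true(all(tab$max_iop >= tab$mean_iop - 1e-12))
})

test_that("zero slopes and zero trajectory noise freeze MRW and LCD", {
  p <- cohort_params(iop_structure_slope_mrw = 0, iop_structure_slope_lcd = 0,
                     mrw_traj_noise_sd = 0, lcd_traj_noise_sd = 0, seed = 9)
  tab <- generate_cohort(p)
  for (k in split(tab, paste(tab$primate_id, tab$eye))) {
    expect_equal(k$mrw, rep(k$mrw[1], nrow(k)))
    expect_equal(k$lcd, rep(k$lcd[1], nrow(k)))
  }
})

test_that("identical seeds give bit-identical cohorts", {
  a <- generate_cohort(cohort_params(seed = 7))
  b <- generate_cohort(cohort_params(seed = 7))
  expect_identical(a, b)
  c <- generate_cohort(cohort_params(seed = 8))
  expect_false(identical(a$mean_iop, c$mean_iop))
})

test_that("interval change means telescope to the overall change", {
  tab <- generate_cohort(cohort_params(seed = 3))
  ch <- monthly_change(tab, "mrw", arm = "oht_right")
  arm <- cohort_arm(tab, "oht_right")
  overall <- mean(arm$mrw[arm$month == 7] - arm$mrw[arm$month == 0])
  expect_equal(sum(ch$mean_change), overall, tolerance = 1e-9)
})

test_that("arm selection matches the design", {
  tab <- generate_cohort(cohort_params(seed = 5))
  expect_equal(length(unique(paste(cohort_arm(tab, "oht_right")$primate_id,
                                   cohort_arm(tab, "oht_right")$eye))), 16)
  expect_equal(length(unique(cohort_arm(tab, "control")$primate_id)), 10)
  expect_equal(length(unique(cohort_arm(tab, "oht_left")$primate_id)), 6)
})
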