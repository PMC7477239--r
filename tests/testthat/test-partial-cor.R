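test_that("single-subject partial correlation reduces to Pearson", {
  x <- 1:7
  y <- 2 * x + 1
  res <- partial_correlation(x, y, rep("a", 7))
  expect_equal(res$rho_hat, 1)
  expect_equal(res$df, 5L)          # n - 2 with one subject
  expect_equal(res$p_value, 0)      # |rho| = 1: flagged infinite z

  set.seed(2)
  x <- rnorm(20); y <- 0.5 * x + rnorm(20)
  res <- partial_correlation(x, y, rep("a", 20))
  expect_equal(res$rho_hat, cor(x, y), tolerance = 1e-12)
  expect_equal(res$df, 18L)
})

test_that("subject control removes offsets that flip the pooled correlation", {
  x <- c(1:5, 11:15)
  y <- c(1:5 + 100, 11:15 - 100)
  s <- rep(c("a", "b"), each = 5)
  expect_lte(cor(x, y), 0)
  res <- partial_correlation(x, y, s)
  expect_equal(res$rho_hat, 1)
  # independent route: residuals from explicit indicator regressions
  set.seed(31)
  x <- rnorm(40) + rep(c(0, 8, -4, 2), each = 10)
  y <- 0.6 * x + rnorm(40) + rep(c(10, -20, 5, 0), each = 10)
  s <- rep(letters[1:4], each = 10)
  res <- partial_correlation(x, y, s)
  oracle <- cor(resid(lm(x ~ factor(s))), resid(lm(y ~ factor(s))))
  expect_equal(res$rho_hat, oracle, tolerance = 1e-12)
})

test_that("partial correlation is invariant to subject-specific shifts", {
  set.seed(5)
  x <- rnorm(30); y <- rnorm(30)
  s <- rep(c("a", "b", "c"), each = 10)
  base <- partial_correlation(x, y, s)$rho_hat
  shift_x <- rep(c(100, -50, 7), each = 10)
  shift_y <- rep(c(-3, 40, 1000), each = 10)
  shifted <- partial_correlation(x + shift_x, y + shift_y, s)$rho_hat
  expect_lt(abs(shifted - base), 1e-12)
})

test_that("within-subject permutation null is centred at zero", {
  set.seed(17)
  x <- rnorm(48); y <- rnorm(48)
  s <- rep(sprintf("s%d", 1:6), each = 8)
  rhos <- vapply(1:1000, function(i) {
    xp <- unlist(lapply(split(x, s), sample), use.names = FALSE)
    partial_correlation(xp, y, s)$rho_hat
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 0.02)
})

test_that("degenerate inputs raise errors", {
  expect_error(partial_correlation(1:2, 1:2, c("a", "a")), "at least 3")
  expect_error(partial_correlation(rep(1, 6), rnorm(6), rep(c("a", "b"), 3)),
               "zero within-subject variance")
  # one observation per subject: everything centred away
  expect_error(partial_correlation(rnorm(4), rnorm(4), letters[1:4]),
               "variance|degrees")
})

test_that("Fisher z inference behaves at the reference points", {
  res <- list(rho_hat = 0, n_obs = 40, n_subjects = 4)
  zt <- fisher_z_test(res)
  expect_equal(zt$z_stat, 0)
  expect_equal(zt$p_value, 1)

  # study-scale check: rho 0.413 over 112 observations from 16 subjects is
  # overwhelmingly significant
  zt <- fisher_z_test(list(rho_hat = 0.413, n_obs = 112, n_subjects = 16))
  expect_lt(zt$p_value, 1e-4)
  expect_equal(zt$z_stat, atanh(0.413) * sqrt(112 - 15 - 3))

  zt <- fisher_z_test(list(rho_hat = 1, n_obs = 20, n_subjects = 2))
  expect_true(zt$infinite)
  expect_equal(zt$p_value, 0)
})
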