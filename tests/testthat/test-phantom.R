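test_that("phantom truth matches closed-form geometry for exact cases", {
  # flat LC parallel to the BMO plane
  ph <- make_phantom_volume(
    phantom_params(lc_shape = "flat", lc_depth = 250, bmo_tilt_deg = 0,
                   surface_noise_sd = 0),
    truth_oversample = 2L)
  expect_identical(ph$truth$true_mean_lcd, 250)

  # circular BMO of radius 900 um
  ph <- make_phantom_volume(
    phantom_params(bmo_semi_axis_major = 900, bmo_semi_axis_minor = 900),
    truth_oversample = 2L)
  expect_equal(ph$truth$true_bmo_area, pi * 0.9^2)

  # visibility fraction by construction
  ph <- make_phantom_volume(phantom_params(lc_visible_fraction = 0.9),
                            truth_oversample = 2L)
  expect_identical(ph$truth$true_lc_visibility, 90)

  # tilted LC over the full ellipse: odd term integrates out
  ph <- make_phantom_volume(
    phantom_params(lc_shape = "tilted", lc_visible_fraction = 1),
    truth_oversample = 2L)
  expect_identical(ph$truth$true_mean_lcd, 200)

  # bowl over the full ellipse: mean of sag * (1 - rho^2) is sag / 2
  ph <- make_phantom_volume(
    phantom_params(lc_shape = "bowl", lc_bowl_sag = 60,
                   lc_visible_fraction = 1),
    truth_oversample = 2L)
  expect_identical(ph$truth$true_mean_lcd, 230)

  # flat untilted ILM: MRW equals the rim height exactly
  ph <- make_phantom_volume(
    phantom_params(rim_height = 150, cup_depth = -150), truth_oversample = 2L)
  expect_identical(ph$truth$true_mean_mrw, 150)
})

test_that("bowl-phantom truth agrees with an independent brute-force oracle", {
  p <- phantom_params(lc_shape = "bowl", rim_height = 150, cup_depth = 400,
                      seed = 7)
  g <- scan_geometry()
  ph <- make_phantom_volume(p, g)
  # independent dense evaluation, written from the surface definitions
  os <- 8L
  gx <- seq(0, (g$n_ascans - 1) * g$ascan_spacing, by = g$ascan_spacing / os)
  gy <- seq(0, (g$n_bscans - 1) * g$bscan_spacing, by = g$bscan_spacing / os)
  cx <- (g$n_ascans - 1) * g$ascan_spacing / 2
  cy <- (g$n_bscans - 1) * g$bscan_spacing / 2
  xm <- matrix(gx, length(gy), length(gx), byrow = TRUE)
  ym <- matrix(gy, length(gy), length(gx))
  rho <- sqrt(((xm - cx) / 950)^2 + ((ym - cy) / 880)^2)
  wedge <- onhmorph:::phantom_wedge(p)
  tang <- atan2((ym - cy) / 880, (xm - cx) / 950)
  vis <- rho <= 1 & !onhmorph:::in_wedge(tang, wedge)
  depth <- 200 + 60 * (1 - rho^2)
  expect_equal(ph$truth$true_mean_lcd, mean(depth[vis]), tolerance = 0.005)

  # MRW truth vs dense cloud of the analytic ILM inside the BMO
  sstep <- function(t) { t <- pmin(1, pmax(0, t)); t^3 * (t * (t * 6 - 15) + 10) }
  ilm <- 1000 + 400 - (400 + 150) * sstep(rho)
  inb <- rho <= 1
  px <- xm[inb]; py <- ym[inb]; pz <- ilm[inb]
  ring <- ph$volume$bmo_points
  per <- vapply(seq_len(nrow(ring)), function(i)
    sqrt(min((px - ring[i, 1])^2 + (py - ring[i, 2])^2 + (pz - ring[i, 3])^2)),
    numeric(1))
  expect_equal(ph$truth$true_mean_mrw, mean(per), tolerance = 0.005)
})

test_that("phantom construction is deterministic and validated", {
  p <- phantom_params(surface_noise_sd = 4, seed = 99)
  a <- make_phantom_volume(p, truth_oversample = 2L)
  b <- make_phantom_volume(p, truth_oversample = 2L)
  expect_identical(a$volume, b$volume)
  expect_identical(a$truth, b$truth)

  expect_error(phantom_params(bmo_semi_axis_major = -5), "semi-axes")
  expect_error(phantom_params(lc_visible_fraction = 1.2), "lc_visible_fraction")
  expect_error(phantom_params(surface_noise_sd = -1), "surface_noise_sd")
  # ellipse larger than the scanned field
  expect_error(
    make_phantom_volume(phantom_params(bmo_semi_axis_major = 5000)),
    "exceeds the scanned field")
})

test_that("controlled LC-depth perturbation moves mean LCD only", {
  p1 <- phantom_params(lc_shape = "flat", lc_depth = 250)
  p2 <- phantom_params(lc_shape = "flat", lc_depth = 350)
  m1 <- measure_volume(make_phantom_volume(p1, truth_oversample = 2L)$volume)
  m2 <- measure_volume(make_phantom_volume(p2, truth_oversample = 2L)$volume)
  expect_equal(m2$mean_lcd - m1$mean_lcd, 100, tolerance = 0.01)
  expect_equal(m2$mean_mrw, m1$mean_mrw, tolerance = 1e-3)
  expect_equal(m2$bmo_area, m1$bmo_area, tolerance = 1e-9)
  expect_equal(m2$lc_visibility, m1$lc_visibility, tolerance = 1e-9)
})

test_that("measures are stable when the grid resolution doubles", {
  p <- phantom_params(lc_shape = "bowl", seed = 13)
  m1 <- measure_volume(make_phantom_volume(p, scan_geometry(),
                                           truth_oversample = 2L)$volume)
  g2 <- scan_geometry(145L, 767L, 31, 5.8)
  m2 <- measure_volume(make_phantom_volume(p, g2, truth_oversample = 2L)$volume)
  expect_equal(m2$mean_mrw, m1$mean_mrw, tolerance = 0.005)
  expect_equal(m2$mean_lcd, m1$mean_lcd, tolerance = 0.005)
  expect_equal(m2$bmo_area, m1$bmo_area, tolerance = 0.005)
  expect_equal(m2$lc_visibility, m1$lc_visibility, tolerance = 0.005)
})
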