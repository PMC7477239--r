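test_that("exact point-to-triangle distance agrees with dense sampling", {
  # brute force: min distance over a fine barycentric lattice on the triangle
  brute <- function(p, a, b, c, k = 200L) {
    s <- rep(0:k, times = k + 1L)
    t <- rep(0:k, each = k + 1L)
    keep <- s + t <= k
    s <- s[keep] / k
    t <- t[keep] / k
    q <- outer(1 - s - t, a) + outer(s, b) + outer(t, c)
    sqrt(min(rowSums(sweep(q, 2, p)^2)))
  }
  set.seed(7)
  for (i in 1:40) {
    a <- runif(3, -1, 1); b <- runif(3, -1, 1); c <- runif(3, -1, 1)
    p <- runif(3, -2, 2)
    d <- onhmorph:::dist_point_triangles(p, rbind(a), rbind(b), rbind(c))
    db <- brute(p, a, b, c)
    expect_gte(db + 1e-12, d)             # lattice min can never beat the exact min
    expect_lt(db - d, 5e-4)               # and converges to it
  }
})

test_that("flat ILM gives per-point MRW equal to the rim height", {
  v <- flat_volume(rim = 150, lc_depth = 250)
  res <- compute_mrw(v)
  # the rim-constraint admissibility is resolved at grid-cell granularity, so
  # a per-point deviation up to ~(cell/2)^2 / (2 * rim) can remain
  expect_lt(max(abs(res$per_point_mrw - 150)), 0.5)
  expect_equal(res$mean_mrw, 150, tolerance = 0.002)
})

test_that("MRW is invariant under rigid motion of all inputs", {
  ph <- make_phantom_volume(phantom_params(lc_shape = "bowl", seed = 5),
                            truth_oversample = 2L)
  v <- ph$volume
  base <- compute_mrw(v)
  R <- rotation_matrix()
  tr <- c(1234, -567, 890)
  move <- function(p) sweep(p %*% t(R), 2, tr, "+")
  # rigid motion breaks the lattice alignment, so rebuild via explicit points:
  # rotate the BMO ring and the ILM triangle soup by comparing against the
  # oracle on moved points is circular; instead check the primitive directly.
  tri <- onhmorph:::admissible_ilm_triangles(v, v$bmo_points,
                                             fit_bmo_plane(v$bmo_points))
  p <- v$bmo_points[1, ]
  d0 <- min(onhmorph:::dist_point_triangles(p, tri$A, tri$B, tri$C))
  d1 <- min(onhmorph:::dist_point_triangles(drop(move(rbind(p))),
                                            move(tri$A), move(tri$B),
                                            move(tri$C)))
  expect_equal(d1, d0, tolerance = 1e-9)
  expect_equal(base$per_point_mrw[1], d0, tolerance = 1e-12)
})

test_that("conical cup MRW matches the brute-force point-cloud oracle", {
  g <- scan_geometry(41L, 41L, 50, 50)
  ext <- field_extent(g)
  cx <- ext[["x"]] / 2; cy <- ext[["y"]] / 2
  z0 <- 500
  gx <- (seq_len(g$n_ascans) - 1) * g$ascan_spacing
  gy <- (seq_len(g$n_bscans) - 1) * g$bscan_spacing
  xm <- matrix(gx, g$n_bscans, g$n_ascans, byrow = TRUE)
  ym <- matrix(gy, g$n_bscans, g$n_ascans)
  r <- sqrt((xm - cx)^2 + (ym - cy)^2)
  # cone: apex 400 um posterior at the centre, rim 150 um anterior beyond 800
  ilm <- z0 + pmin(pmax(400 - 550 * r / 800, -150), 400)
  lc <- matrix(z0 + 250, g$n_bscans, g$n_ascans)
  v <- segmented_onh_volume(g, ilm, lc, circle_ring(800, 32L, z0, cx, cy))
  est <- compute_mrw(v)
  orc <- mrw_pointcloud_oracle(v, oversample = 10L)
  expect_lt(max(abs(est$per_point_mrw / orc$per_point_mrw - 1)), 0.005)
})

test_that("missing ILM handling: exclusion, warning flag and constraint error", {
  v <- flat_volume()
  # poke holes outside the BMO: harmless
  v1 <- v
  v1$ilm_height[1:2, ] <- NA
  expect_equal(compute_mrw(v1)$mean_mrw, compute_mrw(v)$mean_mrw,
               tolerance = 1e-12)
  # remove all ILM inside the BMO: no admissible triangle left
  g <- v$geometry
  gx <- (seq_len(g$n_ascans) - 1) * g$ascan_spacing
  gy <- (seq_len(g$n_bscans) - 1) * g$bscan_spacing
  xm <- matrix(gx, g$n_bscans, g$n_ascans, byrow = TRUE)
  ym <- matrix(gy, g$n_bscans, g$n_ascans)
  cx <- max(gx) / 2; cy <- max(gy) / 2
  inside <- sqrt((xm - cx)^2 + (ym - cy)^2) <= 600 + 100
  v2 <- v
  v2$ilm_height[inside] <- NA
  expect_error(compute_mrw(v2), "no admissible ILM triangles")
  # > 25% of within-BMO ILM missing flags the result
  v3 <- v
  v3$ilm_height[inside & ym < cy] <- NA
  res <- compute_mrw(v3)
  expect_true(isTRUE(attr(res, "high_missing_ilm")))
})
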