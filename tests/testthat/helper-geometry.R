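# Shared fixture builders (all constructed in code at test time).

# Ring of n points on a circle of radius r in the plane z = z0.
circle_ring <- function(r = 900, n = 48L, z0 = 0, cx = 0, cy = 0) {
  t <- 2 * pi * (seq_len(n) - 1L) / n
  cbind(cx + r * cos(t), cy + r * sin(t), z0)
}

# Ellipse ring (semi-axes a, b) tilted by `tilt_deg` about the x axis.
ellipse_ring <- function(a = 1000, b = 800, n = 64L, tilt_deg = 0, z0 = 0,
                         cx = 0, cy = 0) {
  t <- 2 * pi * (seq_len(n) - 1L) / n
  th <- tilt_deg * pi / 180
  cbind(cx + a * cos(t), cy + b * sin(t) * cos(th), z0 + b * sin(t) * sin(th))
}

# Small volume with analytic surfaces for targeted morphometry tests:
# flat ILM at z0 - rim above the BMO plane z = z0, flat LC at z0 + depth.
flat_volume <- function(rim = 150, lc_depth = 250, r = 600, n_ring = 48L,
                        geometry = scan_geometry(61L, 81L, 30, 22.5)) {
  ext <- field_extent(geometry)
  cx <- ext[["x"]] / 2
  cy <- ext[["y"]] / 2
  z0 <- 500
  ilm <- matrix(z0 - rim, geometry$n_bscans, geometry$n_ascans)
  lc <- matrix(z0 + lc_depth, geometry$n_bscans, geometry$n_ascans)
  ring <- circle_ring(r, n_ring, z0, cx, cy)
  segmented_onh_volume(geometry, ilm, lc, ring)
}

# Apply a rigid motion (rotation matrix R, translation t) to a volume's
# geometry-independent point sets; returns transformed BMO ring and a
# function transforming arbitrary points.
rotation_matrix <- function(ax = 0.3, ay = -0.2, az = 0.5) {
  rx <- rbind(c(1, 0, 0), c(0, cos(ax), -sin(ax)), c(0, sin(ax), cos(ax)))
  ry <- rbind(c(cos(ay), 0, sin(ay)), c(0, 1, 0), c(-sin(ay), 0, cos(ay)))
  rz <- rbind(c(cos(az), -sin(az), 0), c(sin(az), cos(az), 0), c(0, 0, 1))
  rz %*% ry %*% rx
}
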