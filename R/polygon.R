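# Planar polygon primitives used by the morphometry module.
# All polygon tests count on-boundary points as inside (deterministic
# tie-break, tolerance 1e-9 um).

# Shoelace area of a planar polygon given as n x 2 matrix (absolute value).
polygon_area_xy <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  n <- nrow(xy)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Vectorised point-in-polygon (even-odd rule), boundary counted inside.
# px, py: point coordinates; vx, vy: polygon vertices in order.
point_in_polygon <- function(px, py, vx, vy, tol = 1e-9) {
  n <- length(vx)
  inside <- logical(length(px))
  on_bd <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- vx[i]; yi <- vy[i]
    xj <- vx[j]; yj <- vy[j]
    dx <- xj - xi; dy <- yj - yi
    l2 <- dx * dx + dy * dy
    t <- if (l2 > 0) pmin(1, pmax(0, ((px - xi) * dx + (py - yi) * dy) / l2)) else 0
    ex <- px - (xi + t * dx); ey <- py - (yi + t * dy)
    on_bd <- on_bd | (ex * ex + ey * ey <= tol * tol)
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_bd
}

# Do segments p1-p2 and p3-p4 properly intersect (shared endpoints ignored)?
segments_cross <- function(p1, p2, p3, p4, tol = 1e-12) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > tol & d2 < -tol) | (d1 < -tol & d2 > tol)) &
     ((d3 > tol & d4 < -tol) | (d3 < -tol & d4 > tol)))
}

# Is the closed polygon (n x 2 matrix, ordered vertices) simple?
is_simple_polygon <- function(xy) {
  n <- nrow(xy)
  if (n < 3L) return(FALSE)
  idx <- function(i) ((i - 1L) %% n) + 1L
  for (i in seq_len(n - 1L)) {
    for (k in seq(i + 1L, n)) {
      # skip adjacent edges (share a vertex), including the wrap pair
      if (k == i + 1L || (i == 1L && k == n)) next
      if (segments_cross(xy[i, ], xy[idx(i + 1L), ],
                         xy[k, ], xy[idx(k + 1L), ]))
        return(FALSE)
    }
  }
  TRUE
}

# Order 2-d points counter-clockwise by angle about their centroid.
order_by_angle <- function(xy) {
  cx <- mean(xy[, 1]); cy <- mean(xy[, 2])
  order(atan2(xy[, 2] - cy, xy[, 1] - cx))
}
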