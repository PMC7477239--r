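#' Minimum rim width (BMO-MRW)
#'
#' The MRW at each BMO point is the shortest Euclidean distance from that
#' point to the ILM surface, constrained to remain within the neuroretinal
#' rim: the ILM grid is triangulated (two triangles per grid cell, cells with
#' any missing corner skipped) and only triangles whose centroid projects
#' inside the BMO polygon on the reference plane are admissible. Distances to
#' admissible triangles use the exact closest-point computation (face, edge
#' and vertex cases), no approximation.
#'
#' If more than 25% of the ILM nodes inside the (enface) BMO polygon are
#' missing, the result carries attribute `high_missing_ilm = TRUE`.
#'
#' @param volume A [segmented_onh_volume()].
#' @param bmo_points Optional n x 3 ring overriding the volume's BMO ring.
#' @param plane Optional [fit_bmo_plane()] result.
#' @return List with `mean_mrw` (um) and `per_point_mrw` (one distance per
#'   BMO point).
#' @export
compute_mrw <- function(volume, bmo_points = NULL, plane = NULL) {
  stopifnot(inherits(volume, "segmented_onh_volume"))
  pts <- if (is.null(bmo_points)) volume$bmo_points else as_points_matrix(bmo_points)
  if (is.null(plane)) plane <- fit_bmo_plane(pts)
  tri <- admissible_ilm_triangles(volume, pts, plane)
  if (tri$n_admissible == 0L)
    stop("compute_mrw: no admissible ILM triangles within the neuroretinal rim for BMO point 1",
         call. = FALSE)
  per_point <- vapply(seq_len(nrow(pts)), function(k) {
    min(dist_point_triangles(pts[k, ], tri$A, tri$B, tri$C))
  }, numeric(1))
  out <- list(mean_mrw = mean(per_point), per_point_mrw = per_point)
  if (tri$high_missing_ilm) attr(out, "high_missing_ilm") <- TRUE
  out
}

#' Brute-force MRW oracle on a dense surface point cloud
#'
#' Reference computation for [compute_mrw()]: each admissible ILM triangle is
#' subsampled on a barycentric lattice (`oversample` points per edge) and the
#' minimum point-to-point distance over the resulting dense cloud is taken.
#' Converges to the exact point-to-triangle minimum from above; used as the
#' independent check of the closest-point computation.
#'
#' @inheritParams compute_mrw
#' @param oversample Lattice subdivisions per triangle edge (default 10).
#' @return List with `mean_mrw` and `per_point_mrw`.
#' @export
mrw_pointcloud_oracle <- function(volume, bmo_points = NULL, plane = NULL,
                                  oversample = 10L) {
  stopifnot(inherits(volume, "segmented_onh_volume"), oversample >= 1L)
  pts <- if (is.null(bmo_points)) volume$bmo_points else as_points_matrix(bmo_points)
  if (is.null(plane)) plane <- fit_bmo_plane(pts)
  tri <- admissible_ilm_triangles(volume, pts, plane)
  if (tri$n_admissible == 0L)
    stop("mrw_pointcloud_oracle: no admissible ILM triangles", call. = FALSE)
  k <- as.integer(oversample)
  ab <- tri$B - tri$A
  ac <- tri$C - tri$A
  cloud <- vector("list", (k + 1L) * (k + 2L) / 2L)
  idx <- 1L
  for (s in 0:k) {
    for (t in 0:(k - s)) {
      cloud[[idx]] <- tri$A + (s / k) * ab + (t / k) * ac
      idx <- idx + 1L
    }
  }
  cloud <- do.call(rbind, cloud)
  per_point <- vapply(seq_len(nrow(pts)), function(i) {
    d2 <- (cloud[, 1L] - pts[i, 1L])^2 + (cloud[, 2L] - pts[i, 2L])^2 +
      (cloud[, 3L] - pts[i, 3L])^2
    sqrt(min(d2))
  }, numeric(1))
  list(mean_mrw = mean(per_point), per_point_mrw = per_point)
}

# Triangulate the ILM grid and keep triangles whose centroid projects inside
# the BMO polygon on the reference plane. Also flags heavy ILM missingness
# inside the enface BMO polygon.
admissible_ilm_triangles <- function(volume, bmo_points, plane) {
  g <- volume$geometry
  h <- volume$ilm_height
  gc <- grid_coords(g)
  nb <- g$n_bscans
  nc <- g$n_ascans
  i <- rep(seq_len(nb - 1L), times = nc - 1L)
  j <- rep(seq_len(nc - 1L), each = nb - 1L)
  z11 <- h[cbind(i, j)]
  z21 <- h[cbind(i + 1L, j)]
  z12 <- h[cbind(i, j + 1L)]
  z22 <- h[cbind(i + 1L, j + 1L)]
  ok <- is.finite(z11) & is.finite(z21) & is.finite(z12) & is.finite(z22)
  p11 <- cbind(gc$x[j], gc$y[i], z11)[ok, , drop = FALSE]
  p21 <- cbind(gc$x[j], gc$y[i + 1L], z21)[ok, , drop = FALSE]
  p12 <- cbind(gc$x[j + 1L], gc$y[i], z12)[ok, , drop = FALSE]
  p22 <- cbind(gc$x[j + 1L], gc$y[i + 1L], z22)[ok, , drop = FALSE]
  a <- rbind(p11, p21)
  b <- rbind(p21, p22)
  c_ <- rbind(p12, p12)

  poly <- project_to_plane(bmo_points, plane)
  poly <- poly[order_by_angle(poly), , drop = FALSE]
  cen <- (a + b + c_) / 3
  uv <- project_to_plane(cen, plane)
  adm <- point_in_polygon(uv[, 1L], uv[, 2L], poly[, 1L], poly[, 2L])

  # missingness of ILM nodes inside the enface BMO polygon
  ring_xy <- bmo_points[, 1:2, drop = FALSE]
  ring_xy <- ring_xy[order_by_angle(ring_xy), , drop = FALSE]
  nx <- rep(gc$x, each = nb)
  ny <- rep(gc$y, times = nc)
  inside <- point_in_polygon(nx, ny, ring_xy[, 1L], ring_xy[, 2L])
  frac_missing <- if (any(inside)) mean(!is.finite(h[inside])) else 0

  list(A = a[adm, , drop = FALSE], B = b[adm, , drop = FALSE],
       C = c_[adm, , drop = FALSE], n_admissible = sum(adm),
       high_missing_ilm = frac_missing > 0.25)
}

# Exact minimum distances from point p to each triangle (A[i,], B[i,], C[i,]).
# Vectorised closest-point-on-triangle with face/edge/vertex case analysis.
dist_point_triangles <- function(p, A, B, C) {
  m <- nrow(A)
  px <- matrix(p, m, 3L, byrow = TRUE)
  ab <- B - A
  ac <- C - A
  ap <- px - A
  d1 <- rowSums(ab * ap)
  d2 <- rowSums(ac * ap)
  bp <- px - B
  d3 <- rowSums(ab * bp)
  d4 <- rowSums(ac * bp)
  cp <- px - C
  d5 <- rowSums(ab * cp)
  d6 <- rowSums(ac * cp)
  va <- d3 * d6 - d5 * d4
  vb <- d5 * d2 - d1 * d6
  vc <- d1 * d4 - d3 * d2

  q <- matrix(NA_real_, m, 3L)
  done <- logical(m)
  claim <- function(mask, val) {
    mask <- mask & !done
    mask[is.na(mask)] <- FALSE
    if (any(mask)) {
      q[mask, ] <<- val[mask, , drop = FALSE]
      done[mask] <<- TRUE
    }
  }
  claim(d1 <= 0 & d2 <= 0, A)                                   # vertex A
  claim(d3 >= 0 & d4 <= d3, B)                                  # vertex B
  claim(d6 >= 0 & d5 <= d6, C)                                  # vertex C
  claim(vc <= 0 & d1 >= 0 & d3 <= 0, A + (d1 / (d1 - d3)) * ab) # edge AB
  claim(vb <= 0 & d2 >= 0 & d6 <= 0, A + (d2 / (d2 - d6)) * ac) # edge AC
  claim(va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0,
        B + ((d4 - d3) / ((d4 - d3) + (d5 - d6))) * (C - B))    # edge BC
  denom <- va + vb + vc
  claim(rep(TRUE, m), A + (vb / denom) * ab + (vc / denom) * ac) # face
  sqrt(rowSums((px - q)^2))
}
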