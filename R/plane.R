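#' Fit the BMO reference plane
#'
#' Orthogonal least-squares (total least squares) plane through the BMO
#' points: the plane through their centroid whose normal is the smallest
#' principal direction of the centred point cloud. This minimises the sum of
#' squared perpendicular distances. The normal is oriented posteriorly
#' (positive axial z component; ties broken toward +z).
#'
#' @param bmo_points Numeric n x 3 matrix of BMO ring points (x, y, z in um),
#'   n >= 3, not all collinear.
#' @return Object of class `bmo_plane` with fields `centroid` (3-vector),
#'   `normal` (unit 3-vector, posterior-pointing), `rms_fit_residual` (um)
#'   and `basis` (3 x 2 in-plane orthonormal basis).
#' @export
#' @examples
#' ring <- cbind(cos(seq(0, 2 * pi, length.out = 49)[-49]) * 900,
#'               sin(seq(0, 2 * pi, length.out = 49)[-49]) * 900, 100)
#' fit_bmo_plane(ring)$centroid
fit_bmo_plane <- function(bmo_points) {
  pts <- as_points_matrix(bmo_points)
  if (nrow(pts) < 3L)
    stop("fit_bmo_plane: need at least 3 points", call. = FALSE)
  centroid <- colMeans(pts)
  x <- sweep(pts, 2L, centroid)
  sv <- svd(x)
  scale <- max(sv$d[1L], sqrt(.Machine$double.eps))
  if (sv$d[2L] <= scale * 1e-10)
    stop("fit_bmo_plane: points are collinear (degenerate geometry)",
         call. = FALSE)
  normal <- sv$v[, 3L]
  if (normal[3L] < 0) {
    normal <- -normal
  } else if (normal[3L] == 0) {
    # plane parallel to z: orient deterministically by first nonzero component
    nz <- which(normal != 0)[1L]
    if (normal[nz] < 0) normal <- -normal
  }
  e1 <- sv$v[, 1L]
  if (e1[which.max(abs(e1))] < 0) e1 <- -e1
  e2 <- c(normal[2L] * e1[3L] - normal[3L] * e1[2L],
          normal[3L] * e1[1L] - normal[1L] * e1[3L],
          normal[1L] * e1[2L] - normal[2L] * e1[1L])
  rms <- sqrt(mean((x %*% normal)^2))
  structure(
    list(centroid = centroid, normal = normal,
         rms_fit_residual = rms, basis = cbind(e1 = e1, e2 = e2)),
    class = "bmo_plane"
  )
}

#' Project 3-d points into the in-plane coordinates of a BMO plane
#'
#' @param points Numeric n x 3 matrix.
#' @param plane A [fit_bmo_plane()] result.
#' @return n x 2 matrix of coordinates in the plane's orthonormal basis.
#' @export
project_to_plane <- function(points, plane) {
  stopifnot(inherits(plane, "bmo_plane"))
  pts <- as_points_matrix(points)
  sweep(pts, 2L, plane$centroid) %*% plane$basis
}

#' Signed perpendicular distance of points from a BMO plane
#'
#' Positive distances are posterior (deeper) by the plane's orientation.
#'
#' @inheritParams project_to_plane
#' @return Numeric vector of signed distances in um.
#' @export
signed_plane_distance <- function(points, plane) {
  stopifnot(inherits(plane, "bmo_plane"))
  pts <- as_points_matrix(points)
  drop(sweep(pts, 2L, plane$centroid) %*% plane$normal)
}

#' @export
print.bmo_plane <- function(x, ...) {
  cat(sprintf("BMO reference plane: centroid (%.1f, %.1f, %.1f) um, normal (%.4f, %.4f, %.4f), rms residual %.3f um\n",
              x$centroid[1], x$centroid[2], x$centroid[3],
              x$normal[1], x$normal[2], x$normal[3], x$rms_fit_residual))
  invisible(x)
}

# Coerce to an n x 3 numeric matrix.
as_points_matrix <- function(points) {
  pts <- as.matrix(points)
  if (!is.numeric(pts) || ncol(pts) != 3L)
    stop("points must be an n x 3 numeric matrix", call. = FALSE)
  storage.mode(pts) <- "double"
  pts
}
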