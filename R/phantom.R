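#' Parameters of a synthetic ONH phantom
#'
#' The phantom replaces manual OCT delineation with analytically constructed
#' surfaces: an elliptical BMO ring on a (possibly tilted) plane, a smooth
#' rim-plus-cup ILM, and an anterior LC surface at a controlled perpendicular
#' depth, with an optional contiguous angular wedge of the LC removed to
#' emulate shadowing-limited LC visibility.
#'
#' Default dimensions follow healthy primate ONH anatomy: BMO semi-axes
#' 950 x 880 um (area ~2.63 mm^2), rim height 280 um (baseline MRW scale),
#' LC depth 200 um, LC visible over 90% of the BMO.
#'
#' @param bmo_semi_axis_major Semi-axis along x (um), > 0.
#' @param bmo_semi_axis_minor Semi-axis along y (um), > 0.
#' @param bmo_tilt_deg Tilt of the BMO plane about the x (A-scan) axis,
#'   degrees.
#' @param rim_height ILM elevation anterior to the BMO plane at the rim (um).
#' @param cup_depth ILM depth posterior to the BMO plane at the cup centre
#'   (um). Setting `cup_depth = -rim_height` yields a flat ILM at
#'   `rim_height` anterior to the plane.
#' @param lc_depth Perpendicular LC offset posterior to the BMO plane (um).
#' @param lc_shape One of `"flat"` (LC parallel to the BMO plane),
#'   `"tilted"` (depth varies linearly along x) or `"bowl"` (paraboloid,
#'   deepest centrally).
#' @param lc_tilt_deg Extra LC tilt for `lc_shape = "tilted"`, degrees.
#' @param lc_bowl_sag Central extra sag for `lc_shape = "bowl"`, um.
#' @param surface_noise_sd Gaussian axial noise SD added to both surfaces
#'   (um); ground truth always refers to the noise-free surfaces.
#' @param lc_visible_fraction Fraction of the BMO area over which the LC is
#'   delineated, in `[0, 1]`. The invisible part is a contiguous angular
#'   wedge (in the elliptic parametric angle, so the removed area fraction is
#'   exact), positioned deterministically from `seed`.
#' @param lc_extent LC delineation extent in normalised elliptical radius
#'   (default 1.05: slightly beyond the BMO).
#' @param n_bmo_points Number of ring vertices (default 64).
#' @param seed Integer seed for the wedge position and surface noise.
#' @return Object of class `phantom_params`.
#' @export
phantom_params <- function(bmo_semi_axis_major = 950, bmo_semi_axis_minor = 880,
                           bmo_tilt_deg = 0, rim_height = 280, cup_depth = 350,
                           lc_depth = 200,
                           lc_shape = c("flat", "tilted", "bowl"),
                           lc_tilt_deg = 8, lc_bowl_sag = 60,
                           surface_noise_sd = 0, lc_visible_fraction = 0.9,
                           lc_extent = 1.05, n_bmo_points = 64L, seed = 1L) {
  lc_shape <- match.arg(lc_shape)
  if (!is.finite(bmo_semi_axis_major) || bmo_semi_axis_major <= 0 ||
      !is.finite(bmo_semi_axis_minor) || bmo_semi_axis_minor <= 0)
    stop("phantom_params: BMO semi-axes must be > 0", call. = FALSE)
  if (!is.finite(lc_visible_fraction) || lc_visible_fraction < 0 ||
      lc_visible_fraction > 1)
    stop("phantom_params: lc_visible_fraction must be in [0, 1]",
         call. = FALSE)
  if (!is.finite(surface_noise_sd) || surface_noise_sd < 0)
    stop("phantom_params: surface_noise_sd must be >= 0", call. = FALSE)
  if (!is.finite(lc_extent) || lc_extent <= 0)
    stop("phantom_params: lc_extent must be > 0", call. = FALSE)
  if (n_bmo_points < 8L)
    stop("phantom_params: need at least 8 BMO ring points", call. = FALSE)
  structure(
    list(bmo_semi_axis_major = bmo_semi_axis_major,
         bmo_semi_axis_minor = bmo_semi_axis_minor,
         bmo_tilt_deg = bmo_tilt_deg, rim_height = rim_height,
         cup_depth = cup_depth, lc_depth = lc_depth, lc_shape = lc_shape,
         lc_tilt_deg = lc_tilt_deg, lc_bowl_sag = lc_bowl_sag,
         surface_noise_sd = surface_noise_sd,
         lc_visible_fraction = lc_visible_fraction, lc_extent = lc_extent,
         n_bmo_points = as.integer(n_bmo_points), seed = as.integer(seed)),
    class = "phantom_params"
  )
}

#' Generate a phantom segmented ONH volume with known ground truth
#'
#' Constructs a [segmented_onh_volume()] whose BMO ring lies exactly on the
#' parameterised (possibly tilted) ellipse, with a smooth rim-and-cup ILM and
#' an LC surface at a controlled perpendicular depth, and returns it together
#' with the analytically known morphometry (`phantom_truth`).
#'
#' Truth values are closed-form where possible (flat LC: `lc_depth` exactly;
#' tilted or bowl LC with full visibility: exact ellipse integrals; circular
#' or elliptic BMO area: `pi * a * b`) and are otherwise computed by dense
#' numerical integration of the analytic surfaces on an `truth_oversample`-x
#' finer lateral lattice. Truth always refers to the noise-free surfaces.
#'
#' @param params A [phantom_params()].
#' @param geometry A [scan_geometry()].
#' @param truth_oversample Lateral oversampling factor for numerically
#'   integrated truth values (default 10).
#' @return List of class `onh_phantom` with elements `volume`
#'   ([segmented_onh_volume()]) and `truth` (class `phantom_truth` with
#'   `true_mean_mrw`, `true_mean_lcd` in um, `true_bmo_area` in mm^2,
#'   `true_lc_visibility` in percent).
#' @export
#' @examples
#' ph <- make_phantom_volume(phantom_params(lc_shape = "flat"))
#' ph$truth$true_mean_lcd  # equals lc_depth exactly
make_phantom_volume <- function(params, geometry = scan_geometry(),
                                truth_oversample = 10L) {
  stopifnot(inherits(params, "phantom_params"),
            inherits(geometry, "scan_geometry"))
  a <- params$bmo_semi_axis_major
  b <- params$bmo_semi_axis_minor
  theta <- params$bmo_tilt_deg * pi / 180
  ext <- field_extent(geometry)
  cx <- ext[["x"]] / 2
  cy <- ext[["y"]] / 2
  z0 <- 1000
  if (a > cx || b * cos(theta) > cy)
    stop("make_phantom_volume: BMO ellipse exceeds the scanned field",
         call. = FALSE)

  # BMO ring exactly on the tilted ellipse
  tt <- 2 * pi * (seq_len(params$n_bmo_points) - 1L) / params$n_bmo_points
  ring <- cbind(x = cx + a * cos(tt),
                y = cy + b * sin(tt) * cos(theta),
                z = z0 + b * sin(tt) * sin(theta))

  gc <- grid_coords(geometry)
  nb <- geometry$n_bscans
  nc <- geometry$n_ascans
  xm <- matrix(gc$x, nb, nc, byrow = TRUE)
  ym <- matrix(gc$y, nb, nc)

  surf <- phantom_surfaces(params, xm, ym, cx, cy, z0, theta)
  ilm <- surf$ilm
  lc <- surf$lc

  # LC visibility wedge: contiguous interval of the elliptic parametric
  # angle; removed BMO-area fraction is exactly 1 - lc_visible_fraction.
  wedge <- phantom_wedge(params)
  if (wedge$width > 0) {
    tang <- atan2((ym - cy) / (b * cos(theta)), (xm - cx) / a)
    lc[in_wedge(tang, wedge)] <- NA_real_
  }

  if (params$surface_noise_sd > 0) {
    with_seed(derive_seed(params$seed, "phantom-surface-noise"), {
      ilm <- ilm + matrix(stats::rnorm(nb * nc, 0, params$surface_noise_sd), nb, nc)
      nn <- matrix(stats::rnorm(nb * nc, 0, params$surface_noise_sd), nb, nc)
      lc <- lc + nn  # NA + noise stays NA
    })
  }

  volume <- segmented_onh_volume(geometry, ilm, lc, ring)
  truth <- phantom_truth(params, geometry, cx, cy, z0, theta, ring,
                         truth_oversample)
  structure(list(volume = volume, truth = truth, params = params),
            class = "onh_phantom")
}

# Noise-free analytic surfaces evaluated on lateral coordinate matrices.
phantom_surfaces <- function(params, xm, ym, cx, cy, z0, theta) {
  a <- params$bmo_semi_axis_major
  bp <- params$bmo_semi_axis_minor * cos(theta)
  zpl <- z0 + tan(theta) * (ym - cy)
  rho <- sqrt(((xm - cx) / a)^2 + ((ym - cy) / bp)^2)
  # ILM: cup_depth posterior at the centre, rim_height anterior at/beyond the
  # ring, quintic-smooth in between (flat with zero curvature at both ends).
  ilm <- zpl + params$cup_depth -
    (params$cup_depth + params$rim_height) * smootherstep(rho)
  d <- lc_perp_depth(params, xm, ym, cx, rho)
  lc <- zpl + d / cos(theta)
  lc[rho > params$lc_extent] <- NA_real_
  list(ilm = ilm, lc = lc, rho = rho, zpl = zpl)
}

# Perpendicular LC depth field (um, positive = posterior).
lc_perp_depth <- function(params, xm, ym, cx, rho) {
  switch(params$lc_shape,
    flat = rho * 0 + params$lc_depth,
    tilted = params$lc_depth + tan(params$lc_tilt_deg * pi / 180) * (xm - cx),
    bowl = params$lc_depth + params$lc_bowl_sag * (1 - rho^2)
  )
}

phantom_wedge <- function(params) {
  width <- 2 * pi * (1 - params$lc_visible_fraction)
  start <- if (width > 0)
    with_seed(derive_seed(params$seed, "lc-wedge"), stats::runif(1, 0, 2 * pi))
  else 0
  list(start = start, width = width)
}

in_wedge <- function(tang, wedge) {
  ((tang - wedge$start) %% (2 * pi)) < wedge$width
}

# Ground-truth morphometry of the noise-free phantom.
phantom_truth <- function(params, geometry, cx, cy, z0, theta, ring,
                          oversample) {
  a <- params$bmo_semi_axis_major
  b <- params$bmo_semi_axis_minor
  bp <- b * cos(theta)
  f <- params$lc_visible_fraction
  true_area <- pi * a * b * 1e-6
  true_vis <- 100 * f

  # dense lateral lattice (oversample x finer in both directions)
  os <- as.integer(oversample)
  gx <- seq(0, (geometry$n_ascans - 1L) * geometry$ascan_spacing,
            by = geometry$ascan_spacing / os)
  gy <- seq(0, (geometry$n_bscans - 1L) * geometry$bscan_spacing,
            by = geometry$bscan_spacing / os)
  xm <- matrix(gx, length(gy), length(gx), byrow = TRUE)
  ym <- matrix(gy, length(gy), length(gx))
  rho <- sqrt(((xm - cx) / a)^2 + ((ym - cy) / bp)^2)
  in_bmo <- rho <= 1
  wedge <- phantom_wedge(params)
  visible <- in_bmo
  if (wedge$width > 0) {
    tang <- atan2((ym - cy) / bp, (xm - cx) / a)
    visible <- visible & !in_wedge(tang, wedge)
  }

  # mean LCD: closed form where exact, dense integration otherwise
  if (f == 0) {
    true_lcd <- NA_real_
  } else if (params$lc_shape == "flat") {
    true_lcd <- params$lc_depth
  } else if (f == 1 && params$lc_shape == "tilted") {
    true_lcd <- params$lc_depth        # odd term integrates to zero
  } else if (f == 1 && params$lc_shape == "bowl") {
    true_lcd <- params$lc_depth + params$lc_bowl_sag / 2  # E[1 - rho^2] = 1/2
  } else {
    d <- lc_perp_depth(params, xm, ym, cx, rho)
    true_lcd <- mean(d[visible])
  }

  # mean MRW: flat untilted ILM is exactly rim_height above the plane;
  # otherwise brute-force over a dense cloud of the analytic ILM inside the
  # BMO (the rim region admissible under the rim constraint).
  if (theta == 0 && params$cup_depth == -params$rim_height) {
    true_mrw <- params$rim_height
  } else {
    surf <- phantom_surfaces(params, xm, ym, cx, cy, z0, theta)
    px <- xm[in_bmo]; py <- ym[in_bmo]; pz <- surf$ilm[in_bmo]
    per <- vapply(seq_len(nrow(ring)), function(i) {
      sqrt(min((px - ring[i, 1L])^2 + (py - ring[i, 2L])^2 +
                 (pz - ring[i, 3L])^2))
    }, numeric(1))
    true_mrw <- mean(per)
  }

  structure(
    list(true_mean_mrw = true_mrw, true_mean_lcd = true_lcd,
         true_bmo_area = true_area, true_lc_visibility = true_vis),
    class = "phantom_truth"
  )
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf(
    "Phantom truth: MRW %.2f um, LCD %.2f um, BMO area %.4f mm^2, LC visibility %.1f%%\n",
    x$true_mean_mrw, x$true_mean_lcd, x$true_bmo_area, x$true_lc_visibility))
  invisible(x)
}
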