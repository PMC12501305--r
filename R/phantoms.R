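#' Single-point reference phantom
#'
#' One unit-RCS scatterer 6 cm from the centre at azimuth 180 deg (cartesian
#' (0, -0.06) m) in water (eps_r = 80) inside the 17 cm diameter container —
#' the canonical single-target simulation scenario.
#'
#' @param radius Scatterer radius in metres (default 0.06).
#' @param azimuth_deg Azimuth in degrees (default 180).
#' @param rcs RCS in m^2 (default 1).
#' @param medium_eps_r Medium permittivity (default 80).
#' @param container_radius Container radius in metres (default 0.085).
#' @return A [scene()].
#' @export
#' @examples
#' single_point_scene()
single_point_scene <- function(radius = 0.06, azimuth_deg = 180, rcs = 1,
                               medium_eps_r = 80, container_radius = 0.085) {
  scene(list(scatterer(scene_point(radius, azimuth_deg), rcs)),
        medium_eps_r = medium_eps_r, container_radius = container_radius)
}

#' Nine-point reference phantom
#'
#' Nine unit-RCS scatterers: a pair on the x axis at radius `r_x`, a pair on
#' the y axis at radius `r_y`, four on the quadrant diagonals (45, 135, 225,
#' 315 deg) at radius `r_diag`, and one at the centre. The default radii
#' honour the ordering `r_x > r_y > r_diag`: the diagonal points sit closer
#' to the centre than either axis pair.
#'
#' @param r_x,r_y,r_diag Radii in metres, `r_x > r_y > r_diag > 0` (defaults
#'   0.07, 0.06, 0.045), all inside the container.
#' @param medium_eps_r Medium permittivity (default 80).
#' @param container_radius Container radius in metres (default 0.085).
#' @return A [scene()] with 9 scatterers.
#' @export
nine_point_scene <- function(r_x = 0.07, r_y = 0.06, r_diag = 0.045,
                             medium_eps_r = 80, container_radius = 0.085) {
  if (!(r_x > r_y && r_y > r_diag && r_diag > 0)) {
    stop("nine_point_scene: radii must satisfy r_x > r_y > r_diag > 0 ",
         "(diagonal points closest to the centre)")
  }
  if (r_x >= container_radius) {
    stop("nine_point_scene: r_x must be inside the container")
  }
  ang_x <- c(90, 270)            # +x and -x (azimuth from +y toward +x)
  ang_y <- c(0, 180)             # +y and -y
  ang_d <- c(45, 135, 225, 315)
  pts <- c(lapply(ang_x, function(a) scatterer(scene_point(r_x, a))),
           lapply(ang_y, function(a) scatterer(scene_point(r_y, a))),
           lapply(ang_d, function(a) scatterer(scene_point(r_diag, a))),
           list(scatterer(scene_point(0, 0))))
  scene(pts, medium_eps_r = medium_eps_r, container_radius = container_radius)
}

#' Elliptical extended phantom with cylindrical inserts
#'
#' Emulates a vegetable phantom (default: an 8 cm x 12 cm potato with two
#' 1 cm diameter wooden inserts) as a point-scatterer cloud: a boundary ring
#' at high contrast, an interior fill at low contrast, and insert disks at a
#' distinct contrast. The discretization pitch defaults to a quarter of the
#' in-medium wavelength at the top frequency.
#'
#' @param a,b Ellipse semi-axes in metres (defaults 0.04, 0.06).
#' @param insert_positions List of [scene_point()] insert centres (default:
#'   two inserts at (0, +/-0.025) m).
#' @param insert_diameter Insert diameter in metres (default 0.01).
#' @param contrasts Named list of RCS contrasts for `boundary`, `interior`,
#'   `insert` (all > 0).
#' @param pitch Scatterer spacing in metres; default
#'   `c0 / (4 f_max sqrt(eps_r))` with `f_max` = 4.8 GHz.
#' @param f_max Top frequency used for the default pitch (Hz).
#' @param medium_eps_r Medium permittivity (default 80).
#' @param container_radius Container radius in metres (default 0.085).
#' @return A [scene()].
#' @export
ellipse_with_inserts_scene <- function(
    a = 0.04, b = 0.06,
    insert_positions = list(scene_point(0.025, 0), scene_point(0.025, 180)),
    insert_diameter = 0.01,
    contrasts = list(boundary = 1, interior = 0.05, insert = 0.5),
    pitch = NULL, f_max = 4.8e9,
    medium_eps_r = 80, container_radius = 0.085) {
  if (a <= 0 || b <= 0) stop("ellipse_with_inserts_scene: semi-axes must be > 0")
  if (sqrt(max(a, b)^2) >= container_radius) {
    stop("ellipse_with_inserts_scene: ellipse extends outside the container")
  }
  if (any(unlist(contrasts) <= 0)) {
    stop("ellipse_with_inserts_scene: contrasts must be > 0")
  }
  rins <- insert_diameter / 2
  ins_xy <- lapply(insert_positions, point_to_cart)
  for (c0i in ins_xy) {
    # insert circle must fit inside the ellipse
    th <- seq(0, 2 * pi, length.out = 64)
    ex <- c0i[1] + rins * cos(th); ey <- c0i[2] + rins * sin(th)
    if (any((ex / a)^2 + (ey / b)^2 > 1)) {
      stop("ellipse_with_inserts_scene: an insert extends outside the ellipse")
    }
  }
  if (is.null(pitch)) pitch <- .c0 / (4 * f_max * sqrt(Re(medium_eps_r)))
  pts <- list()
  add <- function(x, y, rcs) {
    pts[[length(pts) + 1]] <<- scatterer(cart_to_point(x, y), rcs)
  }
  # boundary ring along the ellipse perimeter at ~pitch arc spacing
  perim <- pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))  # Ramanujan
  nb <- max(8, ceiling(perim / pitch))
  th <- seq(0, 2 * pi, length.out = nb + 1)[-(nb + 1)]
  for (t in th) add(a * cos(t), b * sin(t), contrasts$boundary)
  # interior fill on a square lattice, skipping insert disks
  gx <- seq(-a, a, by = pitch)
  gy <- seq(-b, b, by = pitch)
  for (x in gx) for (y in gy) {
    if ((x / a)^2 + (y / b)^2 >= 1) next
    in_insert <- FALSE
    for (c0i in ins_xy) {
      if ((x - c0i[1])^2 + (y - c0i[2])^2 <= rins^2) { in_insert <- TRUE; break }
    }
    add(x, y, if (in_insert) contrasts$insert else contrasts$interior)
  }
  scene(pts, medium_eps_r = medium_eps_r, container_radius = container_radius)
}

#' Single-rod calibration phantom
#'
#' One strong scatterer at a known position, standing in for the thin
#' aluminium calibration rod (default diameter metadata 5 mm) used to
#' estimate the coupling medium's propagation speed.
#'
#' @param position A [scene_point()] inside the container.
#' @param rcs RCS in m^2 (default 1).
#' @param diameter Rod diameter in metres, metadata only (default 0.005).
#' @param medium_eps_r Medium permittivity (default 80).
#' @param container_radius Container radius in metres (default 0.085).
#' @return A [scene()]; the rod diameter is stored as `attr(, "rod_diameter")`.
#' @export
rod_calibration_scene <- function(position, rcs = 1, diameter = 0.005,
                                  medium_eps_r = 80,
                                  container_radius = 0.085) {
  sc <- scene(list(scatterer(position, rcs)), medium_eps_r = medium_eps_r,
              container_radius = container_radius)
  attr(sc, "rod_diameter") <- diameter
  sc
}

#' Add complex white Gaussian noise to a sinogram
#'
#' Adds circularly symmetric complex Gaussian noise scaled so that the mean
#' signal power divided by the noise power equals `10^(snr_db/10)`.
#' Reproducible for a fixed seed; `snr_db = Inf` returns the input
#' bit-identically.
#'
#' @param sg A [sinogram()].
#' @param snr_db Target signal-to-noise ratio in dB.
#' @param seed Integer RNG seed (required for finite SNR).
#' @return A [sinogram()] with noise added; metadata records `snr_db` and
#'   `seed`.
#' @export
#' @examples
#' cfg <- forward_config(antenna_config(0.085),
#'                       frequency_sweep(0.1e9, 4.8e9, 16), angular_sweep(12))
#' sg <- simulate_sinogram(single_point_scene(), cfg)
#' noisy <- add_noise(sg, 20, seed = 1)
add_noise <- function(sg, snr_db, seed) {
  stopifnot(inherits(sg, "sinogram"))
  if (is.infinite(snr_db) && snr_db > 0) return(sg)
  if (missing(seed) || is.null(seed)) stop("add_noise: seed is required")
  psig <- mean(Mod(sg$values)^2)
  pnoise <- psig * 10^(-snr_db / 10)
  sd1 <- sqrt(pnoise / 2)
  n <- length(sg$values)
  vals <- withr::with_seed(as.integer(seed), {
    sg$values + complex(real = stats::rnorm(n, 0, sd1),
                        imaginary = stats::rnorm(n, 0, sd1))
  })
  md <- sg$metadata
  md$snr_db <- snr_db
  md$noise_seed <- as.integer(seed)
  sinogram(vals, sg$sweep, sg$rotation, md)
}
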