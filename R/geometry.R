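#' Physical constants used throughout the package
#'
#' Speed of light in vacuum `c0` (m/s), vacuum permittivity `eps0` (F/m) and
#' free-space impedance `Z0` (Ohm), fixed to CODATA values.
#'
#' @return Named list with elements `c0`, `eps0`, `Z0`.
#' @export
#' @examples
#' isar_constants()$c0
isar_constants <- function() {
  list(c0 = 299792458, eps0 = 8.8541878128e-12, Z0 = 376.730)
}

.c0 <- 299792458
.eps0 <- 8.8541878128e-12
.Z0 <- 376.730

#' Scene point in the polar imaging plane
#'
#' A scatterer location given by radius and azimuth. Azimuth is measured in
#' degrees from the +y axis toward +x, so the cartesian position is
#' `(R sin(phi), R cos(phi))`; `phi = 180` maps to `(0, -R)`.
#'
#' @param radius Distance from the container centre in metres (>= 0).
#' @param azimuth_deg Azimuth angle in degrees; reduced to `[0, 360)`.
#' @return Object of class `scene_point` with fields `radius`, `azimuth_deg`.
#' @export
#' @examples
#' p <- scene_point(0.06, 180)
#' point_to_cart(p) # (0, -0.06)
scene_point <- function(radius, azimuth_deg) {
  stopifnot(is.numeric(radius), length(radius) == 1, is.finite(radius))
  if (radius < 0) stop("scene_point: radius must be >= 0")
  structure(list(radius = radius, azimuth_deg = azimuth_deg %% 360),
            class = "scene_point")
}

#' @export
print.scene_point <- function(x, ...) {
  xy <- point_to_cart(x)
  cat(sprintf("scene_point: R = %.4g m, phi = %.4g deg  [x = %.4g, y = %.4g]\n",
              x$radius, x$azimuth_deg, xy[1], xy[2]))
  invisible(x)
}

#' Convert a scene point to cartesian coordinates
#'
#' @param p A [scene_point()].
#' @return Numeric length-2 vector `c(x, y)` in metres.
#' @export
point_to_cart <- function(p) {
  a <- p$azimuth_deg * pi / 180
  c(p$radius * sin(a), p$radius * cos(a))
}

#' Convert cartesian coordinates to a scene point
#'
#' Inverse of [point_to_cart()]; the azimuth of the origin is taken as 0.
#'
#' @param x,y Cartesian coordinates in metres.
#' @return A [scene_point()].
#' @export
cart_to_point <- function(x, y) {
  r <- sqrt(x^2 + y^2)
  phi <- if (r == 0) 0 else (atan2(x, y) * 180 / pi) %% 360
  scene_point(r, phi)
}

#' Rotate a scene point in azimuth
#'
#' @param p A [scene_point()].
#' @param dphi_deg Rotation angle in degrees (positive: +y toward +x).
#' @return The rotated [scene_point()].
#' @export
rotate_point <- function(p, dphi_deg) {
  scene_point(p$radius, p$azimuth_deg + dphi_deg)
}

#' Bistatic antenna-pair configuration
#'
#' Two antenna placements on the ring of radius `ring_radius` are supported.
#' `"antipodal"`: Tx at `(R0 sin(theta), R0 cos(theta))` and Rx diametrically
#' opposite — the transmission layout. `"adjacent"`: both antennas on one
#' side of the container, straddling the -y axis at `(+/- R0 sin(theta),
#' -R0 cos(theta))` — the quasi-monostatic backscatter layout of a turntable
#' testbed where the pair is mounted on a single support; its half-separation
#' is `w = R0 sin(theta)` and `theta = 0` collapses to a co-located
#' monostatic pair. An exactly antipodal pair with identical beam patterns
#' cannot distinguish a scene from its point inversion (the measurement is
#' invariant under swapping d1/d2 and delta1/delta2), so imaging runs use the
#' adjacent placement by default.
#'
#' @param ring_radius Ring radius R0 in metres (> 0).
#' @param opening_angle_deg Pair half-angle theta from the y axis in degrees
#'   (default 0).
#' @param element_halfspacing Element half-spacing w in metres (>= 0),
#'   informational; for the adjacent placement it corresponds to
#'   `R0 sin(theta)`.
#' @param placement `"antipodal"` (default) or `"adjacent"`.
#' @return Object of class `antenna_config`.
#' @export
antenna_config <- function(ring_radius, opening_angle_deg = 0,
                           element_halfspacing = 0,
                           placement = c("antipodal", "adjacent")) {
  if (!is.numeric(ring_radius) || length(ring_radius) != 1 ||
      !is.finite(ring_radius) || ring_radius <= 0) {
    stop("antenna_config: ring_radius must be a positive finite number")
  }
  if (element_halfspacing < 0) {
    stop("antenna_config: element_halfspacing must be >= 0")
  }
  placement <- match.arg(placement)
  structure(list(ring_radius = ring_radius,
                 opening_angle_deg = opening_angle_deg,
                 element_halfspacing = element_halfspacing,
                 placement = placement),
            class = "antenna_config")
}

#' @export
print.antenna_config <- function(x, ...) {
  cat(sprintf("antenna_config: R0 = %.4g m, theta = %.4g deg, w = %.4g m (%s)\n",
              x$ring_radius, x$opening_angle_deg, x$element_halfspacing,
              x$placement))
  invisible(x)
}

#' Cartesian positions of the Tx and Rx antennas
#'
#' For the `"antipodal"` placement Tx sits at `(R0 sin(theta), R0
#' cos(theta))` and Rx diametrically opposite at `(-R0 sin(theta), -R0
#' cos(theta))`. For the `"adjacent"` placement the pair straddles the -y
#' axis: Rx at `(R0 sin(theta), -R0 cos(theta))`, Tx at `(-R0 sin(theta),
#' -R0 cos(theta))`.
#'
#' @param cfg An [antenna_config()].
#' @return List with numeric length-2 vectors `tx` and `rx` (metres).
#' @export
#' @examples
#' antenna_positions(antenna_config(0.085))
antenna_positions <- function(cfg) {
  stopifnot(inherits(cfg, "antenna_config"))
  th <- cfg$opening_angle_deg * pi / 180
  r0 <- cfg$ring_radius
  if (identical(cfg$placement, "adjacent")) {
    list(tx = c(-r0 * sin(th), -r0 * cos(th)),
         rx = c(r0 * sin(th), -r0 * cos(th)))
  } else {
    list(tx = c(r0 * sin(th), r0 * cos(th)),
         rx = c(-r0 * sin(th), -r0 * cos(th)))
  }
}

# Vectorised bistatic distances from cartesian target coordinates.
# d1: target -> Rx, d2: target -> Tx.
.bistatic_distances_xy <- function(x, y, tx, rx) {
  list(d1 = sqrt((x - rx[1])^2 + (y - rx[2])^2),
       d2 = sqrt((x - tx[1])^2 + (y - tx[2])^2))
}

# Vectorised boresight-offset angles. Each antenna's boresight points at the
# origin; the offset is the angle between boresight and the antenna->target
# vector, in [0, pi].
.boresight_angles_xy <- function(x, y, tx, rx) {
  ang <- function(a) {
    bx <- -a[1]; by <- -a[2]                  # boresight: antenna -> origin
    vx <- x - a[1]; vy <- y - a[2]            # antenna -> target
    nb <- sqrt(bx^2 + by^2)
    nv <- sqrt(vx^2 + vy^2)
    if (any(nv == 0)) stop("boresight angle undefined: target at an antenna position")
    cosd <- (bx * vx + by * vy) / (nb * nv)
    acos(pmin(1, pmax(-1, cosd)))
  }
  list(delta1 = ang(rx), delta2 = ang(tx))
}

#' Bistatic distances from a scene point to the antennas
#'
#' Euclidean distances `d1` (target to receive antenna) and `d2` (target to
#' transmit antenna), computed from the explicit cartesian antenna coordinates.
#'
#' @param p A [scene_point()], strictly inside the antenna ring.
#' @param cfg An [antenna_config()].
#' @return Named numeric vector `c(d1, d2)` in metres.
#' @export
#' @examples
#' bistatic_distances(scene_point(0, 0), antenna_config(0.085)) # both 0.085
bistatic_distances <- function(p, cfg) {
  stopifnot(inherits(p, "scene_point"), inherits(cfg, "antenna_config"))
  if (p$radius >= cfg$ring_radius) {
    stop("bistatic_distances: point lies outside the container (Ri >= R0)")
  }
  ap <- antenna_positions(cfg)
  xy <- point_to_cart(p)
  d <- .bistatic_distances_xy(xy[1], xy[2], ap$tx, ap$rx)
  c(d1 = d$d1, d2 = d$d2)
}

#' Boresight-offset angles from the antennas to a scene point
#'
#' Each antenna's boresight points at the container centre. The returned
#' angles `delta1` (receive) and `delta2` (transmit) are the angles between
#' boresight and the antenna-to-target direction, in radians in `[0, pi]`.
#'
#' @inheritParams bistatic_distances
#' @return Named numeric vector `c(delta1, delta2)` in radians.
#' @export
boresight_angles <- function(p, cfg) {
  stopifnot(inherits(p, "scene_point"), inherits(cfg, "antenna_config"))
  if (p$radius >= cfg$ring_radius) {
    stop("boresight_angles: point lies outside the container (Ri >= R0)")
  }
  ap <- antenna_positions(cfg)
  xy <- point_to_cart(p)
  d <- .boresight_angles_xy(xy[1], xy[2], ap$tx, ap$rx)
  c(delta1 = d$delta1, delta2 = d$delta2)
}

#' One-way propagation delay over a bistatic path
#'
#' Delay of a wave travelling `d1 + d2` metres in a medium of relative
#' permittivity `eps_r`: `(d1 + d2) sqrt(eps_r) / c0`.
#'
#' @param d1,d2 Path lengths in metres (>= 0).
#' @param eps_r Relative permittivity of the medium (> 0).
#' @return Delay in seconds.
#' @export
#' @examples
#' path_delay(0.085, 0.085, 80)
path_delay <- function(d1, d2, eps_r) {
  if (any(d1 < 0) || any(d2 < 0)) stop("path_delay: distances must be >= 0")
  if (any(eps_r <= 0)) stop("path_delay: eps_r must be > 0")
  (d1 + d2) * sqrt(eps_r) / .c0
}
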