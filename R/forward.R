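#' Uniform frequency sweep
#'
#' @param f_start,f_stop Sweep limits in Hz, `0 < f_start < f_stop`.
#' @param n_points Number of frequency bins M (>= 2).
#' @return Object of class `frequency_sweep` with fields `f` (Hz, ascending,
#'   uniform), `f_start`, `f_stop`, `n_points`, `df` (bin width).
#' @export
#' @examples
#' frequency_sweep(0.1e9, 4.8e9, 200)
frequency_sweep <- function(f_start, f_stop, n_points) {
  if (!(f_start > 0 && f_stop > f_start)) {
    stop("frequency_sweep: need 0 < f_start < f_stop")
  }
  if (n_points < 2) stop("frequency_sweep: n_points must be >= 2")
  f <- seq(f_start, f_stop, length.out = n_points)
  structure(list(f = f, f_start = f_start, f_stop = f_stop,
                 n_points = as.integer(n_points), df = f[2] - f[1]),
            class = "frequency_sweep")
}

#' Uniform angular (turntable) sweep
#'
#' N uniformly spaced scene rotation angles covering `[start_deg,
#' start_deg + 360)`.
#'
#' @param n_positions Number of rotation steps N (>= 1).
#' @param start_deg First angle in degrees (default 0).
#' @return Object of class `angular_sweep` with fields `angles` (degrees) and
#'   `n_positions`.
#' @export
#' @examples
#' angular_sweep(360)
angular_sweep <- function(n_positions, start_deg = 0) {
  if (n_positions < 1) stop("angular_sweep: n_positions must be >= 1")
  angles <- start_deg + (seq_len(n_positions) - 1) * 360 / n_positions
  structure(list(angles = angles, n_positions = as.integer(n_positions)),
            class = "angular_sweep")
}

#' Point scatterer
#'
#' @param position A [scene_point()].
#' @param rcs Radar cross-section sigma in m^2 (> 0, default 1).
#' @return Object of class `scatterer`.
#' @export
scatterer <- function(position, rcs = 1) {
  stopifnot(inherits(position, "scene_point"))
  if (rcs <= 0) stop("scatterer: rcs must be > 0")
  structure(list(position = position, rcs = rcs), class = "scatterer")
}

#' Scene: scatterers in a homogeneous matching medium
#'
#' @param scatterers List of [scatterer()] objects (may be empty).
#' @param medium_eps_r Relative permittivity of the coupling medium (> 0,
#'   default 80 for water).
#' @param container_radius Container radius in metres (default 0.085, the
#'   17 cm diameter tank).
#' @return Object of class `scene`.
#' @export
scene <- function(scatterers = list(), medium_eps_r = 80,
                  container_radius = 0.085) {
  if (Re(medium_eps_r[1]) <= 0) stop("scene: medium_eps_r real part must be > 0")
  for (s in scatterers) {
    stopifnot(inherits(s, "scatterer"))
    if (s$position$radius >= container_radius) {
      stop("scene: scatterer at radius ", s$position$radius,
           " m lies outside the container (radius ", container_radius, " m)")
    }
  }
  structure(list(scatterers = scatterers, medium_eps_r = medium_eps_r,
                 container_radius = container_radius), class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("scene: %d scatterer(s), eps_r = %s, container radius %.3g m\n",
              length(x$scatterers), format(x$medium_eps_r),
              x$container_radius))
  invisible(x)
}

# Scene -> matrix of cartesian positions and RCS values.
.scene_table <- function(sc) {
  if (!length(sc$scatterers)) {
    return(data.frame(x = numeric(0), y = numeric(0), rcs = numeric(0)))
  }
  xy <- t(vapply(sc$scatterers, function(s) point_to_cart(s$position),
                 numeric(2)))
  data.frame(x = xy[, 1], y = xy[, 2],
             rcs = vapply(sc$scatterers, function(s) s$rcs, numeric(1)))
}

#' Export a scene to CSV (x_m, y_m, rcs_m2)
#'
#' @param sc A [scene()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_scene_csv <- function(sc, path) {
  tab <- .scene_table(sc)
  names(tab) <- c("x_m", "y_m", "rcs_m2")
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Antenna gain model
#'
#' Normalised gain as a function of boresight offset delta (radians).
#' `"isotropic"` is G = 1 everywhere (the default: results are reproducible
#' without invented antenna parameters); `"cosine_power"` is
#' `cos(delta)^n` within the forward hemisphere, 0 behind; `"gaussian"` is
#' `exp(-4 ln 2 (delta/beamwidth)^2)` with `beamwidth` the full width at
#' half maximum in radians.
#'
#' @param model One of `"isotropic"`, `"cosine_power"`, `"gaussian"`.
#' @param n Exponent for `cosine_power` (default 2).
#' @param beamwidth_rad FWHM for `gaussian` in radians (default `pi/3`).
#' @return Object of class `gain_model`; callable via [gain()].
#' @export
gain_model <- function(model = c("isotropic", "cosine_power", "gaussian"),
                       n = 2, beamwidth_rad = pi / 3) {
  model <- match.arg(model)
  structure(list(model = model, n = n, beamwidth_rad = beamwidth_rad),
            class = "gain_model")
}

#' Evaluate a gain model
#'
#' @param g A [gain_model()].
#' @param delta Boresight offset angle(s) in radians.
#' @return Gain values, `>= 0`, maximal at `delta = 0`.
#' @export
gain <- function(g, delta) {
  stopifnot(inherits(g, "gain_model"))
  switch(g$model,
    isotropic = rep(1, length(delta)),
    cosine_power = ifelse(abs(delta) <= pi / 2, cos(delta)^g$n, 0),
    gaussian = exp(-4 * log(2) * (delta / g$beamwidth_rad)^2)
  )
}

#' Forward-model configuration
#'
#' Bundles antenna geometry, frequency sweep, turntable rotation, transmit
#' power, free-space impedance and the antenna gain model.
#'
#' @param antenna An [antenna_config()].
#' @param sweep A [frequency_sweep()].
#' @param rotation An [angular_sweep()].
#' @param tx_power Transmit power Pt in W (> 0, default 1).
#' @param z0 Free-space impedance in Ohm (default 376.730).
#' @param gain A [gain_model()] (default isotropic).
#' @param alpha_fun Optional attenuation hook: a function of frequency (Hz)
#'   returning an amplitude attenuation coefficient in Np/m, applied as
#'   `exp(-alpha(f) (d1 + d2))`. `NULL` (default) means a lossless medium.
#' @return Object of class `forward_config`.
#' @export
forward_config <- function(antenna, sweep, rotation, tx_power = 1,
                           z0 = 376.730, gain = gain_model("isotropic"),
                           alpha_fun = NULL) {
  stopifnot(inherits(antenna, "antenna_config"),
            inherits(sweep, "frequency_sweep"),
            inherits(rotation, "angular_sweep"),
            inherits(gain, "gain_model"))
  if (tx_power <= 0 || z0 <= 0) {
    stop("forward_config: tx_power and z0 must be > 0")
  }
  if (!is.null(alpha_fun) && !is.function(alpha_fun)) {
    stop("forward_config: alpha_fun must be NULL or a function of frequency")
  }
  structure(list(antenna = antenna, sweep = sweep, rotation = rotation,
                 tx_power = tx_power, z0 = z0, gain = gain,
                 alpha_fun = alpha_fun),
            class = "forward_config")
}

#' Effective aperture of the receiving antenna
#'
#' `A0 = sqrt(Z0 Pt / (4 pi)) * lambda / (4 pi)` — linear in wavelength,
#' square-root in transmit power.
#'
#' @param Pt Transmit power in W (> 0).
#' @param lambda Wavelength in metres (> 0); may be a vector.
#' @param Z0 Free-space impedance in Ohm (> 0, default 376.730).
#' @return Effective aperture values.
#' @export
effective_aperture <- function(Pt, lambda, Z0 = 376.730) {
  if (Pt <= 0 || Z0 <= 0 || any(lambda <= 0)) {
    stop("effective_aperture: all arguments must be > 0")
  }
  sqrt(Z0 * Pt / (4 * pi)) * lambda / (4 * pi)
}

# Core of the forward model, vectorised over frequencies x positions.
# x, y: cartesian scatterer coordinates already rotated into the antenna
# frame (vectors of length P); returns M x P complex matrix of unit-RCS
# responses: A0(f) * sqrt(G1 G2) / (d1 d2) * exp(+i (w sqrt(eps)/c0)(d1+d2)).
.unit_response_matrix <- function(x, y, f, eps_r, cfg) {
  ap <- antenna_positions(cfg$antenna)
  d <- .bistatic_distances_xy(x, y, ap$tx, ap$rx)
  if (any(d$d1 == 0) || any(d$d2 == 0)) {
    stop("forward model: scatterer coincides with an antenna (singular geometry)")
  }
  del <- .boresight_angles_xy(x, y, ap$tx, ap$rx)
  g <- sqrt(gain(cfg$gain, del$delta1) * gain(cfg$gain, del$delta2))
  amp <- g / (d$d1 * d$d2)                        # length P
  er <- Re(eps_r)                                 # phase uses the real part
  lambda_med <- .c0 / (f * sqrt(er))              # in-medium wavelength
  a0 <- effective_aperture(cfg$tx_power, lambda_med, cfg$z0)  # length M
  k <- 2 * pi * f * sqrt(er) / .c0                # length M
  L <- d$d1 + d$d2
  ph <- exp(1i * outer(k, L))                     # M x P
  if (!is.null(cfg$alpha_fun)) {
    ph <- ph * exp(-outer(cfg$alpha_fun(f), L))
  }
  (a0 * ph) * rep(amp, each = length(f))
}

#' Bistatic response of a single scatterer
#'
#' The received signal of one point scatterer at frequency `f` with the scene
#' rotated by `rotation_angle` relative to the fixed antenna pair:
#' `A0 sqrt(G(delta1) G(delta2) sigma) / (d1 d2) *
#'  exp(+i (omega sqrt(eps_r)/c0) (d1 + d2))`.
#'
#' @param s A [scatterer()].
#' @param f Frequency in Hz; may be a vector.
#' @param rotation_angle Scene rotation in degrees.
#' @param sc The [scene()] providing the medium.
#' @param cfg A [forward_config()].
#' @return Complex response, same length as `f`.
#' @export
point_response <- function(s, f, rotation_angle, sc, cfg) {
  stopifnot(inherits(s, "scatterer"), inherits(sc, "scene"),
            inherits(cfg, "forward_config"))
  p <- rotate_point(s$position, rotation_angle)
  if (p$radius >= sc$container_radius) {
    stop("point_response: scatterer outside the container")
  }
  xy <- point_to_cart(p)
  drop(.unit_response_matrix(xy[1], xy[2], f, sc$medium_eps_r, cfg)) *
    sqrt(s$rcs)
}

#' Sinogram container
#'
#' Complex S21 matrix with M frequency rows and N angle columns plus
#' acquisition metadata.
#'
#' @param values Complex M x N matrix.
#' @param sweep A [frequency_sweep()].
#' @param rotation An [angular_sweep()].
#' @param metadata Named list (medium, geometry, provenance); free-form.
#' @return Object of class `sinogram`.
#' @export
sinogram <- function(values, sweep, rotation, metadata = list()) {
  stopifnot(inherits(sweep, "frequency_sweep"),
            inherits(rotation, "angular_sweep"))
  values <- as.matrix(values)
  if (nrow(values) != sweep$n_points || ncol(values) != rotation$n_positions) {
    stop("sinogram: values must be ", sweep$n_points, " x ",
         rotation$n_positions)
  }
  if (!all(is.finite(Re(values))) || !all(is.finite(Im(values)))) {
    stop("sinogram: all entries must be finite")
  }
  structure(list(values = values, sweep = sweep, rotation = rotation,
                 metadata = metadata), class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf(
    "sinogram: %d frequencies (%.3g-%.3g GHz) x %d angles; |S21| in [%.3g, %.3g]\n",
    x$sweep$n_points, x$sweep$f_start / 1e9, x$sweep$f_stop / 1e9,
    x$rotation$n_positions, min(Mod(x$values)), max(Mod(x$values))))
  invisible(x)
}

#' Simulate the sinogram of a scene
#'
#' Entry `(m, n)` is the coherent sum over scatterers of [point_response()]
#' at frequency `f_m` with the scene rotated by `phi_n` — the turntable
#' acquisition in the frequency domain.
#'
#' @param sc A [scene()].
#' @param cfg A [forward_config()].
#' @return A [sinogram()].
#' @export
#' @examples
#' cfg <- forward_config(antenna_config(0.085),
#'                       frequency_sweep(0.1e9, 4.8e9, 16), angular_sweep(12))
#' sg <- simulate_sinogram(single_point_scene(), cfg)
simulate_sinogram <- function(sc, cfg) {
  stopifnot(inherits(sc, "scene"), inherits(cfg, "forward_config"))
  M <- cfg$sweep$n_points
  N <- cfg$rotation$n_positions
  vals <- matrix(0 + 0i, M, N)
  if (length(sc$scatterers)) {
    tab <- .scene_table(sc)
    a <- cfg$rotation$angles * pi / 180
    ca <- cos(a); sa <- sin(a)
    for (i in seq_len(nrow(tab))) {
      # rotate scatterer i into each turntable position
      xr <- tab$x[i] * ca + tab$y[i] * sa
      yr <- -tab$x[i] * sa + tab$y[i] * ca
      vals <- vals + sqrt(tab$rcs[i]) *
        .unit_response_matrix(xr, yr, cfg$sweep$f, sc$medium_eps_r, cfg)
    }
  }
  sinogram(vals, cfg$sweep, cfg$rotation,
           metadata = list(eps_r = sc$medium_eps_r,
                           container_radius = sc$container_radius,
                           R0 = cfg$antenna$ring_radius,
                           provenance = "simulate_sinogram"))
}

#' Range compression of a sinogram (windowed IFFT)
#'
#' Transforms each per-angle frequency sweep into a delay profile. Under the
#' forward model's `exp(+i omega tau)` phase convention, the matching inverse
#' transform is the unitary DFT `sum_m w_m S_m exp(-2 pi i m k / M) / sqrt(M)`,
#' which places a scatterer with delay `tau` at the bin nearest
#' `tau * M * df`. Windowing (default Hann) suppresses range sidelobes at the
#' cost of slight mainlobe broadening.
#'
#' @param sg A [sinogram()].
#' @param window One of `"hann"` (default), `"hamming"`, `"rect"`.
#' @return Object of class `range_profile_set`: complex matrix (delay bins x
#'   angles), `delay` axis in seconds starting at 0, and the window label.
#' @export
range_compress <- function(sg, window = c("hann", "hamming", "rect")) {
  stopifnot(inherits(sg, "sinogram"))
  window <- match.arg(window)
  M <- sg$sweep$n_points
  w <- switch(window,
    rect = rep(1, M),
    hann = as.numeric(signal::hanning(M)),
    hamming = as.numeric(signal::hamming(M))
  )
  delay <- (seq_len(M) - 1) / (M * sg$sweep$df)
  # reference the profile to absolute delay: the index-space DFT is phased by
  # the sweep start frequency so that profile(tau_k) = sum_m w_m S_m
  # exp(-2 pi i f_m tau_k) / sqrt(M)
  profiles <- stats::mvfft(sg$values * w) *
    exp(-2i * pi * sg$sweep$f_start * delay) / sqrt(M)
  structure(list(profiles = profiles, delay = delay,
                 angles = sg$rotation$angles, window = window),
            class = "range_profile_set")
}

#' Export range profiles to CSV
#'
#' Rows are delay bins; columns are `delay_s` then interleaved
#' `re_<angle>`/`im_<angle>` pairs.
#'
#' @param rp A range profile set from [range_compress()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_range_profiles_csv <- function(rp, path) {
  stopifnot(inherits(rp, "range_profile_set"))
  out <- data.frame(delay_s = rp$delay)
  for (j in seq_along(rp$angles)) {
    out[[sprintf("re_%g", rp$angles[j])]] <- Re(rp$profiles[, j])
    out[[sprintf("im_%g", rp$angles[j])]] <- Im(rp$profiles[, j])
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Assemble the sensitivity matrix
#'
#' Column r holds the vectorised sinogram of a unit-RCS scatterer at the
#' centre of pixel r (row-major grid order); row k = (n-1) M + m stacks
#' measurements angle-major with frequency fastest — the same ordering as
#' [vectorize_sinogram()]. Pixels outside the circular imaging mask get
#' all-zero columns.
#'
#' @param grid An [imaging_grid()].
#' @param medium_eps_r Relative permittivity of the medium.
#' @param cfg A [forward_config()].
#' @param container_radius Container radius in metres (default 0.085); any
#'   masked-in pixel centre must lie inside it.
#' @return Object of class `sensitivity_matrix` with fields `J` (complex
#'   (M N) x (p q) matrix), `grid`, `sweep`, `rotation`, `eps_r`, `ordering`.
#' @export
build_sensitivity <- function(grid, medium_eps_r, cfg,
                              container_radius = 0.085) {
  stopifnot(inherits(grid, "imaging_grid"), inherits(cfg, "forward_config"))
  M <- cfg$sweep$n_points
  N <- cfg$rotation$n_positions
  px <- grid_pixel_centers(grid)
  P <- nrow(px)
  if (M * N < P) {
    stop("build_sensitivity: under-determined system: measurements (M*N = ",
         M * N, ") must be >= pixels (p*q = ", P, ")")
  }
  if (any(px$mask & sqrt(px$x^2 + px$y^2) >= container_radius)) {
    stop("build_sensitivity: imaging mask extends outside the container")
  }
  a <- cfg$rotation$angles * pi / 180
  ca <- cos(a); sa <- sin(a)
  J <- matrix(0 + 0i, M * N, P)
  for (r in which(px$mask)) {
    xr <- px$x[r] * ca + px$y[r] * sa
    yr <- -px$x[r] * sa + px$y[r] * ca
    # M x N unit-RCS sinogram; column-major vectorisation = frequency fastest
    J[, r] <- as.vector(
      .unit_response_matrix(xr, yr, cfg$sweep$f, medium_eps_r, cfg))
  }
  structure(list(J = J, grid = grid, sweep = cfg$sweep,
                 rotation = cfg$rotation, eps_r = medium_eps_r,
                 ordering = "rows: angle-major, frequency fastest; columns: row-major pixels"),
            class = "sensitivity_matrix")
}

#' @export
print.sensitivity_matrix <- function(x, ...) {
  cat(sprintf("sensitivity_matrix: %d x %d complex (%s)\n",
              nrow(x$J), ncol(x$J), x$ordering))
  invisible(x)
}

#' Vectorise a sinogram in sensitivity-matrix row order
#'
#' Stacks the M x N sinogram into a length-(M N) vector, angle-major with
#' frequency fastest — index k = (n-1) M + m. This is the single shared
#' ordering used for the rows of [build_sensitivity()].
#'
#' @param sg A [sinogram()].
#' @return Complex vector of length M N.
#' @export
vectorize_sinogram <- function(sg) {
  stopifnot(inherits(sg, "sinogram"))
  as.vector(sg$values)
}
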