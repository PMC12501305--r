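# Independent oracles and small fixture builders shared across test files.

# Brute-force cartesian positions, bypassing antenna_positions().
oracle_antennas <- function(r0, theta_deg, placement = "antipodal") {
  th <- theta_deg * pi / 180
  if (placement == "adjacent") {
    list(tx = c(-r0 * sin(th), -r0 * cos(th)),
         rx = c(r0 * sin(th), -r0 * cos(th)))
  } else {
    list(tx = c(r0 * sin(th), r0 * cos(th)),
         rx = c(-r0 * sin(th), -r0 * cos(th)))
  }
}

oracle_point_cart <- function(ri, phi_deg) {
  a <- phi_deg * pi / 180
  c(ri * sin(a), ri * cos(a))
}

oracle_dist <- function(a, b) sqrt(sum((a - b)^2))

# Angle between two vectors via normalized dot product.
oracle_angle <- function(u, v) {
  acos(min(1, max(-1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
}

# Dense DFT evaluation of a windowed spectrum on an arbitrary delay axis.
oracle_dft_profile <- function(spectrum, f, tau) {
  E <- exp(-2i * pi * outer(tau, f))
  drop(E %*% spectrum)
}

# Small forward configuration for fast tests.
tiny_cfg <- function(M = 16, N = 12, placement = "adjacent", theta = 0,
                     r0 = 0.085, gain = gain_model("isotropic")) {
  forward_config(antenna_config(r0, theta, placement = placement),
                 frequency_sweep(0.1e9, 4.8e9, M), angular_sweep(N),
                 gain = gain)
}
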