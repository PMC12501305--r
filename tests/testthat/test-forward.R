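test_that("effective aperture scales linearly in wavelength, sqrt in power", {
  a <- effective_aperture(1, 0.0335)
  expect_equal(effective_aperture(1, 0.067), 2 * a, tolerance = 1e-12)
  expect_equal(effective_aperture(4, 0.0335), 2 * a, tolerance = 1e-12)
  expect_equal(a, sqrt(376.73 * 1 / (4 * pi)) * 0.0335 / (4 * pi),
               tolerance = 1e-12)
  expect_error(effective_aperture(0, 1), "> 0")
})

test_that("point response scales with sqrt(RCS) and has the delay phase", {
  cfg <- tiny_cfg(M = 8, N = 6)
  sc <- single_point_scene()
  s1 <- scatterer(scene_point(0.05, 120), rcs = 1)
  s4 <- scatterer(scene_point(0.05, 120), rcs = 4)
  f <- cfg$sweep$f
  r1 <- point_response(s1, f, 33, sc, cfg)
  r4 <- point_response(s4, f, 33, sc, cfg)
  expect_equal(Mod(r4), 2 * Mod(r1), tolerance = 1e-12)
  expect_equal(Arg(r4), Arg(r1), tolerance = 1e-10)
  # phase equals the geometric delay phase mod 2 pi
  p <- rotate_point(s1$position, 33)
  d <- bistatic_distances(p, cfg$antenna)
  c0 <- isar_constants()$c0
  expected <- (2 * pi * f * sqrt(80) / c0) * sum(d)
  expect_lt(max(Mod(exp(1i * (Arg(r1) - expected)) - 1)), 1e-8)
  # scatterer at the origin: response independent of rotation angle
  s0 <- scatterer(scene_point(0, 0))
  r_a <- point_response(s0, f, 0, sc, cfg)
  r_b <- point_response(s0, f, 123.4, sc, cfg)
  expect_equal(r_a, r_b, tolerance = 1e-12)
})

test_that("sinogram synthesis is superposition of per-scatterer responses", {
  cfg <- tiny_cfg(M = 12, N = 10)
  empty <- simulate_sinogram(scene(), cfg)
  expect_true(all(empty$values == 0))
  sA <- scene(list(scatterer(scene_point(0.03, 40))))
  sB <- scene(list(scatterer(scene_point(0.06, 200), rcs = 2)))
  sAB <- scene(c(sA$scatterers, sB$scatterers))
  expect_equal(simulate_sinogram(sAB, cfg)$values,
               simulate_sinogram(sA, cfg)$values +
                 simulate_sinogram(sB, cfg)$values, tolerance = 1e-12)
  # homogeneity of degree 1/2 in a uniform RCS scaling
  sA9 <- scene(list(scatterer(scene_point(0.03, 40), rcs = 9)))
  expect_equal(simulate_sinogram(sA9, cfg)$values,
               3 * simulate_sinogram(sA, cfg)$values, tolerance = 1e-12)
})

test_that("rotating the scene shifts the sinogram columns", {
  cfg <- tiny_cfg(M = 10, N = 12)
  dstep <- 360 / 12
  sc <- scene(list(scatterer(scene_point(0.05, 77)),
                   scatterer(scene_point(0.02, 300), rcs = 0.5)))
  rot <- scene(lapply(sc$scatterers, function(s) {
    scatterer(rotate_point(s$position, 3 * dstep), s$rcs)
  }))
  a <- simulate_sinogram(sc, cfg)$values
  b <- simulate_sinogram(rot, cfg)$values
  # rotating the scene by 3 steps advances which column sees which geometry
  perm <- c(10:12, 1:9)
  expect_lt(max(Mod(b[, perm] - a)), 1e-10 * max(Mod(a)))
})

test_that("swapping Tx and Rx leaves the sinogram magnitude unchanged", {
  sc <- scene(list(scatterer(scene_point(0.05, 10)),
                   scatterer(scene_point(0.03, 250), rcs = 2)))
  mk <- function(th) forward_config(antenna_config(0.085, th),
                                    frequency_sweep(0.1e9, 4.8e9, 10),
                                    angular_sweep(8),
                                    gain = gain_model("cosine_power", n = 2))
  a <- simulate_sinogram(sc, mk(0))$values
  b <- simulate_sinogram(sc, mk(180))$values   # antipodal pair exchanged
  expect_lt(max(abs(Mod(a) - Mod(b))), 1e-10 * max(Mod(a)))
})

test_that("gain models are maximal at boresight and non-negative", {
  d <- seq(0, pi, length.out = 50)
  for (g in list(gain_model("isotropic"), gain_model("cosine_power", n = 3),
                 gain_model("gaussian", beamwidth_rad = pi / 4))) {
    v <- gain(g, d)
    expect_true(all(v >= 0))
    expect_equal(max(v), gain(g, 0))
  }
  expect_equal(gain(gain_model("cosine_power", n = 2), 2), 0) # behind
})

test_that("range compression places delays in the right bins", {
  sw <- frequency_sweep(0.1e9, 4.8e9, 64)
  rot <- angular_sweep(1)
  # flat unit spectrum: impulse in delay bin 0
  sg <- sinogram(matrix(1 + 0i, 64, 1), sw, rot)
  rp <- range_compress(sg, "rect")
  expect_equal(which.max(Mod(rp$profiles[, 1])), 1)
  expect_equal(rp$delay[1], 0)
  expect_equal(diff(rp$delay), rep(1 / (64 * sw$df), 63), tolerance = 1e-12)
  # oscillating spectrum with a bin-centred delay peaks at that bin
  k0 <- 17
  tau0 <- k0 / (64 * sw$df)
  sg2 <- sinogram(matrix(exp(2i * pi * sw$f * tau0), 64, 1), sw, rot)
  rp2 <- range_compress(sg2, "rect")
  expect_equal(which.max(Mod(rp2$profiles[, 1])), k0 + 1)
  # matches the dense DFT oracle on the bin grid (unitary scaling)
  oracle <- oracle_dft_profile(sg2$values[, 1], sw$f, rp2$delay) / sqrt(64)
  expect_equal(rp2$profiles[, 1], oracle, tolerance = 1e-10)
  expect_error(range_compress(sg, "blackman"), "arg")
})

test_that("range compression is unitary (Parseval) for every window", {
  cfg <- tiny_cfg(M = 32, N = 5)
  sg <- simulate_sinogram(single_point_scene(), cfg)
  for (w in c("rect", "hann", "hamming")) {
    rp <- range_compress(sg, w)
    win <- switch(w, rect = rep(1, 32),
                  hann = as.numeric(signal::hanning(32)),
                  hamming = as.numeric(signal::hamming(32)))
    expect_equal(sum(Mod(rp$profiles)^2), sum(Mod(sg$values * win)^2),
                 tolerance = 1e-9)
  }
})

test_that("per-angle peak delay tracks the geometry of the rotating target", {
  cfg <- tiny_cfg(M = 200, N = 36, placement = "adjacent")
  sg <- simulate_sinogram(single_point_scene(), cfg)
  rp <- range_compress(sg, "hann")
  peak_bins <- apply(Mod(rp$profiles), 2, which.max)
  meas_delay <- rp$delay[peak_bins]
  # oracle: geometric two-way delay per rotation angle
  truth <- vapply(cfg$rotation$angles, function(a) {
    d <- bistatic_distances(rotate_point(scene_point(0.06, 180), a),
                            cfg$antenna)
    path_delay(d[["d1"]], d[["d2"]], 80)
  }, numeric(1))
  bin <- diff(rp$delay)[1]
  expect_true(all(abs(meas_delay - truth) <= 2 * bin))
  # minimum where the rotation brings the target nearest the receive antenna
  expect_lt(abs(truth[which.min(meas_delay)] - min(truth)), 2 * bin)
  ap <- antenna_positions(cfg$antenna)
  best <- cfg$rotation$angles[which.min(meas_delay)]
  xy <- point_to_cart(rotate_point(scene_point(0.06, 180), best))
  dists <- vapply(cfg$rotation$angles, function(a) {
    q <- point_to_cart(rotate_point(scene_point(0.06, 180), a))
    sqrt(sum((q - ap$rx)^2))
  }, numeric(1))
  # the best rotation is (close to) the closest approach to Rx
  expect_lt(sqrt(sum((xy - ap$rx)^2)) - min(dists), 0.01)
})

test_that("sensitivity matrix columns equal single-scatterer sinograms", {
  cfg <- tiny_cfg(M = 16, N = 20)
  grid <- imaging_grid(8, 0.06)
  J <- build_sensitivity(grid, 80, cfg)
  expect_equal(dim(J$J), c(16 * 20, 64))
  px <- grid_pixel_centers(grid)
  set.seed(21)
  for (r in sample(which(px$mask), 6)) {
    sc <- scene(list(scatterer(cart_to_point(px$x[r], px$y[r]), rcs = 1)))
    sgv <- vectorize_sinogram(simulate_sinogram(sc, cfg))
    expect_equal(J$J[, r], sgv, tolerance = 1e-12)
  }
  # in-mask columns are nonzero and finite; masked-out columns are zero
  nrm <- sqrt(colSums(Mod(J$J)^2))
  expect_true(all(nrm[px$mask] > 0))
  expect_true(all(is.finite(nrm)))
  expect_true(all(nrm[!px$mask] == 0))
})

test_that("J applied to pixel-aligned sqrt-RCS weights reproduces the sinogram", {
  cfg <- tiny_cfg(M = 16, N = 20)
  grid <- imaging_grid(8, 0.06)
  J <- build_sensitivity(grid, 80, cfg)
  px <- grid_pixel_centers(grid)
  set.seed(33)
  idx <- sample(which(px$mask), 5)
  rcs <- runif(5, 0.5, 2)
  sc <- scene(mapply(function(r, s) scatterer(cart_to_point(px$x[r], px$y[r]), s),
                     idx, rcs, SIMPLIFY = FALSE))
  w <- rep(0, nrow(px)); w[idx] <- sqrt(rcs)
  sgv <- vectorize_sinogram(simulate_sinogram(sc, cfg))
  expect_equal(drop(J$J %*% w), sgv, tolerance = 1e-10)
})

test_that("under-determined imaging configurations are refused", {
  cfg <- tiny_cfg(M = 4, N = 4)
  expect_error(build_sensitivity(imaging_grid(8, 0.06), 80, cfg),
               "under-determined")
})
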