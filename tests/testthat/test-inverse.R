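test_that("imaging grid pixel centres, pitch and mask are consistent", {
  g <- imaging_grid(8, 0.06)
  px <- grid_pixel_centers(g)
  expect_equal(nrow(px), 64)
  expect_equal(g$pitch, 0.015)
  expect_equal(sort(unique(px$x)), -0.06 + (1:8 - 0.5) * 0.015)
  # row-major linear order: first row spans x at the top y
  expect_equal(px$row[1:8], rep(1, 8))
  expect_equal(px$y[1], max(px$y))
  expect_equal(px$mask, sqrt(px$x^2 + px$y^2) <= 0.06)
  expect_false(px$mask[1])  # corner pixel outside the circle
  expect_error(imaging_grid(0), ">= 1")
})

test_that("pinv_svd reproduces closed-form pseudo-inverses", {
  expect_equal(pinv_svd(diag(3))$pinv, diag(3), tolerance = 1e-12)
  p <- pinv_svd(diag(c(2, 1, 0)))
  expect_equal(p$pinv, diag(c(0.5, 1, 0)), tolerance = 1e-12)
  expect_equal(p$rank, 2)
  expect_error(pinv_svd(matrix(0, 3, 3)), "rank zero")
  expect_error(pinv_svd(matrix(c(1, NA, 0, 1), 2)), "finite")
})

test_that("pinv_svd satisfies the Moore-Penrose identities on complex input", {
  set.seed(101)
  for (dims in list(c(40, 15), c(25, 25), c(15, 40))) {
    A <- matrix(complex(real = rnorm(prod(dims)),
                        imaginary = rnorm(prod(dims))), dims[1], dims[2])
    Ap <- pinv_svd(A)$pinv
    H <- function(m) Conj(t(m))
    expect_lt(max(Mod(A %*% Ap %*% A - A)), 1e-8)
    expect_lt(max(Mod(Ap %*% A %*% Ap - Ap)), 1e-8)
    expect_lt(max(Mod(A %*% Ap - H(A %*% Ap))), 1e-8)
    expect_lt(max(Mod(Ap %*% A - H(Ap %*% A))), 1e-8)
  }
  # full-column-rank: left inverse
  A <- matrix(complex(real = rnorm(200 * 50), imaginary = rnorm(200 * 50)),
              200, 50)
  expect_lt(max(Mod(pinv_svd(A)$pinv %*% A - diag(50))), 1e-8)
})

test_that("tolerance thresholding matches a dense SVD oracle", {
  # matrix with a known SVD and deliberately tiny trailing singular values
  set.seed(55)
  m <- 30; n <- 12
  d <- c(10, 5, 2, 1, rep(1e-10, n - 4))
  qa <- qr.Q(qr(matrix(rnorm(m * m), m)))[, 1:n]
  qb <- qr.Q(qr(matrix(rnorm(n * n), n)))
  A <- qa %*% (d * t(qb))
  rt <- 1e-6
  p <- pinv_svd(A, rtol = rt)
  expect_equal(p$rank, 4)
  oracle <- qb[, 1:4] %*% ((1 / d[1:4]) * t(qa[, 1:4]))
  expect_lt(max(abs(p$pinv - oracle)), 1e-8)
  # rtol = 0 keeps everything
  expect_equal(pinv_svd(A, rtol = 0)$rank, n)
})

test_that("scatterer map is the least-squares solution", {
  set.seed(77)
  m <- 120; n <- 40
  J <- matrix(complex(real = rnorm(m * n), imaginary = rnorm(m * n)), m, n)
  x0 <- complex(real = rnorm(n), imaginary = rnorm(n))
  S <- drop(J %*% x0) + 0.01 * complex(real = rnorm(m), imaginary = rnorm(m))
  P <- solve_scatterer_map(S, J)$P
  # independent oracle: Hermitian normal equations
  H <- Conj(t(J))
  P_ne <- drop(solve(H %*% J, H %*% S))
  expect_equal(P, P_ne, tolerance = 1e-8)
  # optimality against random competitors
  r0 <- sqrt(sum(Mod(J %*% P - S)^2))
  for (i in 1:100) {
    x <- P + 0.1 * complex(real = rnorm(n), imaginary = rnorm(n))
    expect_gte(sqrt(sum(Mod(J %*% x - S)^2)), r0 - 1e-10)
  }
  expect_equal(solve_scatterer_map(complex(m), J)$P, rep(0 + 0i, n))
  expect_error(solve_scatterer_map(S[-1], J), "angle-major")
})

test_that("noiseless pixel-aligned sources are recovered exactly", {
  cfg <- tiny_cfg(M = 24, N = 18)
  grid <- imaging_grid(8, 0.06)
  J <- build_sensitivity(grid, 80, cfg)
  px <- grid_pixel_centers(grid)
  pv <- pinv_svd(J$J, rtol = 1e-10)
  set.seed(9)
  for (k in sample(which(px$mask), 4)) {
    S <- J$J[, k]
    P <- solve_scatterer_map(S, J, pinv = pv)$P
    expect_equal(which.max(Mod(P)), k)
    expect_lt(max(Mod(P)[-k]) / Mod(P)[k], 1e-6)
  }
})

test_that("image assembly handles scales, masking and degenerate input", {
  grid <- imaging_grid(8, 0.06)
  px <- grid_pixel_centers(grid)
  P <- rep(0 + 0i, 64)
  k <- which(px$mask)[10]
  P[k] <- 3 + 4i
  img <- assemble_image(P, grid)
  expect_equal(sum(img$pixels > 0), 1)
  expect_equal(img$pixels[px$row[k], px$col[k]], 5)
  # dB image: peak-normalized maximum of 0, masked corners at the floor
  P[which(px$mask)[20]] <- 1i
  imdb <- assemble_image(P, grid, scale = "db")
  expect_equal(max(imdb$pixels), 0)
  expect_equal(imdb$pixels[1, 1], imdb$floor_db)
  # out-of-mask content is suppressed regardless of P
  P2 <- P; P2[!px$mask] <- 100
  expect_equal(assemble_image(P2, grid)$pixels[1, 1], 0)
  # dB and linear argmax agree
  expect_equal(which.max(assemble_image(P, grid)$pixels),
               which.max(imdb$pixels))
  expect_warning(assemble_image(rep(0 + 0i, 64), grid, scale = "db"),
                 "all-zero")
})

test_that("bilinear presentation upsampling preserves nodes and constants", {
  grid <- imaging_grid(8, 0.06)
  set.seed(2)
  img <- assemble_image(complex(real = runif(64), imaginary = runif(64)), grid)
  # doubling minus one puts original nodes at odd output indices
  up <- interpolate_presentation(img, 15)
  expect_equal(up$pixels[seq(1, 15, 2), seq(1, 15, 2)], img$pixels,
               tolerance = 1e-12)
  const <- img; const$pixels[] <- 3.25
  upc <- interpolate_presentation(const, 31)
  expect_true(all(abs(upc$pixels - 3.25) < 1e-12))
  # default presentation size
  up2401 <- interpolate_presentation(img, 2401)
  expect_equal(dim(up2401$pixels), c(2401, 2401))
  expect_error(interpolate_presentation(img, 4), ">=")
})

test_that("peak localization finds separated maxima in order", {
  grid <- imaging_grid(32, 0.08)
  px <- grid_pixel_centers(grid)
  z <- exp(-((px$x - 0.0325)^2 + (px$y - 0.0025)^2) / 2e-5) +
    0.6 * exp(-((px$x + 0.0325)^2 + (px$y + 0.0225)^2) / 2e-5)
  img <- assemble_image(complex(real = z), grid)
  pk <- localize_peaks(img, 2)
  expect_equal(nrow(pk), 2)
  expect_gte(pk$value[1], pk$value[2])
  expect_lt(abs(pk$x[1] - 0.0325) + abs(pk$y[1] - 0.0025), 2 * grid$pitch)
  expect_lt(abs(pk$x[2] + 0.0325) + abs(pk$y[2] + 0.0225), 2 * grid$pitch)
  # constant image has no strict local maxima
  cimg <- img; cimg$pixels[] <- 1
  expect_warning(pks <- localize_peaks(cimg, 1), "no local maxima")
  expect_equal(nrow(pks), 0)
  # asking for more peaks than exist warns and returns the shorter list
  expect_warning(pk1 <- localize_peaks(img, 5), "of 5 peaks")
  expect_lt(nrow(pk1), 5)
})

test_that("rtol sweep reports rank and peak stability", {
  cfg <- tiny_cfg(M = 24, N = 18)
  grid <- imaging_grid(8, 0.06)
  J <- build_sensitivity(grid, 80, cfg)
  sg <- simulate_sinogram(
    scene(list(scatterer(scene_point(0.03, 180)))), cfg)
  sw <- rtol_sweep(sg, J, rtols = c(1e-8, 1e-4))
  expect_equal(nrow(sw), 2)
  expect_true(all(sw$rank > 0))
  expect_true(all(is.finite(sw$peak_x)))
})
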