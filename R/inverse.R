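#' Cartesian imaging grid with circular mask
#'
#' A `n_side x n_side` lattice of square pixels spanning
#' `[-radius, +radius]^2`. Pixel pitch is `2 radius / n_side`; pixel centres
#' sit at `-radius + (j - 1/2) pitch`. Pixels whose centre falls outside the
#' circle of `radius` are masked out, reproducing the square images with
#' circular support typical of turntable acquisitions.
#'
#' @param n_side Pixels per side p = q (default 64).
#' @param radius Imaging radius in metres (default 0.08; 0.10 is the other
#'   standard preset).
#' @return Object of class `imaging_grid`.
#' @export
#' @examples
#' g <- imaging_grid(32, 0.08)
#' sum(grid_pixel_centers(g)$mask) # pixels inside the circle
imaging_grid <- function(n_side = 64, radius = 0.08) {
  if (n_side < 1) stop("imaging_grid: n_side must be >= 1")
  if (radius <= 0) stop("imaging_grid: radius must be > 0")
  structure(list(n_side = as.integer(n_side), radius = radius,
                 pitch = 2 * radius / n_side),
            class = "imaging_grid")
}

#' @export
print.imaging_grid <- function(x, ...) {
  cat(sprintf("imaging_grid: %d x %d over radius %.3g m (pitch %.3g m)\n",
              x$n_side, x$n_side, x$radius, x$pitch))
  invisible(x)
}

#' Pixel centres and mask of an imaging grid
#'
#' The single shared pixel ordering used everywhere: row-major, rows running
#' top to bottom (y from `+radius` to `-radius`), columns left to right
#' (x from `-radius` to `+radius`); linear index `r = (row - 1) p + col`.
#'
#' @param grid An [imaging_grid()].
#' @return data.frame with columns `row`, `col`, `x`, `y`, `mask`, one row
#'   per pixel in linear-index order.
#' @export
grid_pixel_centers <- function(grid) {
  stopifnot(inherits(grid, "imaging_grid"))
  p <- grid$n_side
  ax <- -grid$radius + (seq_len(p) - 0.5) * grid$pitch
  row <- rep(seq_len(p), each = p)
  col <- rep(seq_len(p), times = p)
  x <- ax[col]
  y <- rev(ax)[row]
  data.frame(row = row, col = col, x = x, y = y,
             mask = sqrt(x^2 + y^2) <= grid$radius)
}

#' Moore-Penrose pseudo-inverse via truncated SVD
#'
#' Computes `J+ = V S+ U^H` from the singular value decomposition, zeroing
#' singular values below `rtol * s_max`. Works for real and complex matrices
#' (conjugate transposes throughout).
#'
#' @param J Numeric or complex matrix, all entries finite.
#' @param rtol Relative truncation tolerance (>= 0). Default
#'   `max(dim(J)) * .Machine$double.eps`.
#' @return Object of class `pinv` with fields `pinv` (the pseudo-inverse
#'   matrix), `rank`, `d` (singular values), `rtol`.
#' @export
#' @examples
#' p <- pinv_svd(diag(c(2, 1, 0)))
#' p$pinv # diag(0.5, 1, 0)
pinv_svd <- function(J, rtol = NULL) {
  if (inherits(J, "sensitivity_matrix")) J <- J$J
  J <- as.matrix(J)
  if (!all(is.finite(Re(J))) || (is.complex(J) && !all(is.finite(Im(J))))) {
    stop("pinv_svd: J must be finite")
  }
  if (is.null(rtol)) rtol <- max(dim(J)) * .Machine$double.eps
  if (rtol < 0) stop("pinv_svd: rtol must be >= 0")
  k <- min(dim(J))
  s <- La.svd(J, nu = k, nv = k)
  keep <- s$d > rtol * s$d[1]
  if (!any(keep)) stop("pinv_svd: rank zero: all singular values below tolerance")
  r <- sum(keep)
  # La.svd returns vt (the conjugate-transposed right factor for complex input)
  vt <- s$vt[seq_len(r), , drop = FALSE]
  u <- s$u[, seq_len(r), drop = FALSE]
  pj <- Conj(t(vt)) %*% ((1 / s$d[seq_len(r)]) * Conj(t(u)))
  structure(list(pinv = pj, rank = r, d = s$d, rtol = rtol), class = "pinv")
}

#' @export
print.pinv <- function(x, ...) {
  cat(sprintf("pinv: %d x %d, rank %d (rtol %.3g, s_max %.3g)\n",
              nrow(x$pinv), ncol(x$pinv), x$rank, x$rtol, x$d[1]))
  invisible(x)
}

#' Least-squares scatterer map from a measurement vector
#'
#' Solves `S = J P` in the least-squares sense, `P = J+ S`, over the retained
#' singular subspace. The measurement vector must use the same stacking as
#' the sensitivity-matrix rows ([vectorize_sinogram()]).
#'
#' @param S_vec Complex measurement vector of length `nrow(J)`, or a
#'   [sinogram()] (vectorised automatically).
#' @param J A [build_sensitivity()] result (or plain matrix).
#' @param rtol SVD truncation tolerance passed to [pinv_svd()].
#' @param pinv Optional precomputed [pinv_svd()] object for repeated solves.
#' @return Object of class `scatterer_map` with fields `P` (complex vector,
#'   length p q) and `grid`.
#' @export
solve_scatterer_map <- function(S_vec, J, rtol = NULL, pinv = NULL) {
  grid <- NULL
  if (inherits(J, "sensitivity_matrix")) {
    grid <- J$grid
    Jm <- J$J
  } else {
    Jm <- as.matrix(J)
  }
  if (inherits(S_vec, "sinogram")) S_vec <- vectorize_sinogram(S_vec)
  if (length(S_vec) != nrow(Jm)) {
    stop("solve_scatterer_map: measurement vector length (", length(S_vec),
         ") does not match sensitivity rows (", nrow(Jm),
         "); both must be stacked angle-major with frequency fastest")
  }
  if (is.null(pinv)) pinv <- pinv_svd(Jm, rtol)
  stopifnot(inherits(pinv, "pinv"))
  structure(list(P = drop(pinv$pinv %*% S_vec), grid = grid),
            class = "scatterer_map")
}

#' Export a scatterer map to CSV
#'
#' Columns: pixel centre `x_m`, `y_m`, magnitude `abs_P` and phase `arg_P`.
#'
#' @param map A [solve_scatterer_map()] result carrying its grid.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_scatterer_map_csv <- function(map, path) {
  stopifnot(inherits(map, "scatterer_map"), !is.null(map$grid))
  px <- grid_pixel_centers(map$grid)
  utils::write.csv(
    data.frame(x_m = px$x, y_m = px$y, abs_P = Mod(map$P),
               arg_P = Arg(map$P)),
    path, row.names = FALSE)
  invisible(path)
}

#' Assemble a displayable image from a scatterer map
#'
#' Linear scale shows `|P_r|`; dB scale shows `20 log10(|P_r| / max |P|)`
#' floored at `floor_db`. Masked (out-of-circle) pixels carry the background
#' value: 0 on the linear scale, the floor on the dB scale.
#'
#' @param map A [scatterer_map] (or complex vector with `grid` supplied).
#' @param grid The [imaging_grid()]; defaults to the map's own grid.
#' @param scale `"linear"` (default) or `"db"`.
#' @param floor_db dB floor for the logarithmic scale (default -60).
#' @return Object of class `recon_image` with fields `pixels` (p x q real
#'   matrix, rows top to bottom), `grid`, `scale`, `floor_db`.
#' @export
assemble_image <- function(map, grid = NULL, scale = c("linear", "db"),
                           floor_db = -60) {
  scale <- match.arg(scale)
  if (inherits(map, "scatterer_map")) {
    if (is.null(grid)) grid <- map$grid
    P <- map$P
  } else {
    P <- map
  }
  stopifnot(inherits(grid, "imaging_grid"))
  p <- grid$n_side
  if (length(P) != p * p) stop("assemble_image: map length does not match grid")
  px <- grid_pixel_centers(grid)
  mag <- Mod(P)
  mag[!px$mask] <- 0
  if (scale == "db") {
    peak <- max(mag)
    if (peak == 0) {
      warning("assemble_image: all-zero map; dB image set to the floor")
      vals <- rep(floor_db, length(mag))
    } else {
      vals <- pmax(20 * log10(pmax(mag / peak, 10^((floor_db - 20) / 20))),
                   floor_db)
      vals[!px$mask] <- floor_db
    }
  } else {
    vals <- mag
  }
  structure(list(pixels = matrix(vals, p, p, byrow = TRUE), grid = grid,
                 scale = scale, floor_db = floor_db),
            class = "recon_image")
}

#' @export
print.recon_image <- function(x, ...) {
  cat(sprintf("recon_image: %d x %d (%s scale), range [%.3g, %.3g]\n",
              nrow(x$pixels), ncol(x$pixels), x$scale,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Bilinear upsampling to a presentation image
#'
#' Interpolates the pixel-centre lattice bilinearly onto an `n_out x n_out`
#' lattice spanning the same extent; values at the original nodes are
#' preserved by construction.
#'
#' @param img A [recon_image].
#' @param n_out Output side length (default 2401); must be >= the input side.
#' @return A `recon_image` with an `n_out x n_out` pixel matrix.
#' @export
interpolate_presentation <- function(img, n_out = 2401) {
  stopifnot(inherits(img, "recon_image"))
  p <- nrow(img$pixels)
  if (n_out < p) stop("interpolate_presentation: n_out must be >= input side")
  ax <- seq_len(p)                       # node coordinates (pixel index)
  axo <- seq(1, p, length.out = n_out)
  grd <- pracma::meshgrid(axo, axo)
  z <- pracma::interp2(ax, ax, img$pixels, grd$X, grd$Y, method = "linear")
  structure(list(pixels = matrix(z, n_out, n_out), grid = img$grid,
                 scale = img$scale, floor_db = img$floor_db,
                 upsampled_from = p),
            class = "recon_image")
}

#' Locate the strongest peaks in a reconstructed image
#'
#' Finds strict local maxima over the 8-neighbourhood, enforces a minimum
#' separation (in pixels) between reported peaks, and returns the `k`
#' strongest in decreasing magnitude with their pixel and cartesian
#' coordinates.
#'
#' @param img A [recon_image] (linear or dB; peak set is scale-invariant).
#' @param k Number of peaks requested (>= 1).
#' @param min_separation Minimum Chebyshev distance between peaks in pixels
#'   (default 2).
#' @return data.frame with columns `row`, `col`, `x`, `y`, `value`; fewer
#'   than `k` rows (with a warning) if the image has fewer local maxima.
#' @export
localize_peaks <- function(img, k, min_separation = 2) {
  stopifnot(inherits(img, "recon_image"))
  if (k < 1) stop("localize_peaks: k must be >= 1")
  z <- img$pixels
  p <- nrow(z); q <- ncol(z)
  # strict local maximum over available 8-neighbours
  is_peak <- matrix(TRUE, p, q)
  shifts <- expand.grid(dr = -1:1, dc = -1:1)
  shifts <- shifts[!(shifts$dr == 0 & shifts$dc == 0), ]
  for (s in seq_len(nrow(shifts))) {
    dr <- shifts$dr[s]; dc <- shifts$dc[s]
    rs <- seq_len(p) + dr; cs <- seq_len(q) + dc
    ok_r <- rs >= 1 & rs <= p; ok_c <- cs >= 1 & cs <= q
    nb <- matrix(-Inf, p, q)
    nb[ok_r, ok_c] <- z[rs[ok_r], cs[ok_c]]
    is_peak <- is_peak & (z > nb)
  }
  idx <- which(is_peak, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    if (k > 0) warning("localize_peaks: no local maxima found")
    return(data.frame(row = integer(0), col = integer(0), x = numeric(0),
                      y = numeric(0), value = numeric(0)))
  }
  ord <- order(z[idx], decreasing = TRUE)
  idx <- idx[ord, , drop = FALSE]
  sel <- matrix(NA_integer_, 0, 2)
  for (i in seq_len(nrow(idx))) {
    if (nrow(sel) == 0 ||
        all(pmax(abs(sel[, 1] - idx[i, 1]),
                 abs(sel[, 2] - idx[i, 2])) >= min_separation)) {
      sel <- rbind(sel, idx[i, , drop = FALSE])
      if (nrow(sel) == k) break
    }
  }
  if (nrow(sel) < k) {
    warning("localize_peaks: only ", nrow(sel), " of ", k, " peaks found")
  }
  g <- img$grid
  ps <- if (!is.null(g)) g$n_side else p
  ax <- if (!is.null(g)) -g$radius + (seq_len(ps) - 0.5) * g$pitch else seq_len(p)
  # presentation images: map row/col back to the original extent
  rowpos <- if (p == ps) rev(ax)[sel[, 1]] else {
    stats::approx(seq_len(p), rev(seq(min(ax), max(ax), length.out = p)),
                  sel[, 1])$y
  }
  colpos <- if (q == ps) ax[sel[, 2]] else {
    stats::approx(seq_len(q), seq(min(ax), max(ax), length.out = q),
                  sel[, 2])$y
  }
  data.frame(row = sel[, 1], col = sel[, 2], x = colpos, y = rowpos,
             value = z[sel])
}

#' Localization quality versus SVD truncation
#'
#' Utility sweep: reconstructs one measurement vector at several truncation
#' tolerances and reports the retained rank and the top-peak location for
#' each, to guide `rtol` selection.
#'
#' @param S_vec Measurement vector or [sinogram()].
#' @param J A [build_sensitivity()] result.
#' @param rtols Vector of relative tolerances to try.
#' @return data.frame with columns `rtol`, `rank`, `peak_x`, `peak_y`.
#' @export
rtol_sweep <- function(S_vec, J, rtols = 10^seq(-12, -2, by = 2)) {
  stopifnot(inherits(J, "sensitivity_matrix"))
  out <- lapply(rtols, function(rt) {
    pv <- pinv_svd(J$J, rt)
    m <- solve_scatterer_map(S_vec, J, pinv = pv)
    img <- assemble_image(m)
    pk <- localize_peaks(img, 1)
    data.frame(rtol = rt, rank = pv$rank,
               peak_x = if (nrow(pk)) pk$x[1] else NA_real_,
               peak_y = if (nrow(pk)) pk$y[1] else NA_real_)
  })
  do.call(rbind, out)
}

#' Write a reconstructed image as PNG
#'
#' Greyscale presentation export; values are min-max scaled to `[0, 1]`.
#'
#' @param img A [recon_image].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(img, path) {
  stopifnot(inherits(img, "recon_image"))
  z <- img$pixels
  rng <- range(z)
  z <- if (diff(rng) > 0) (z - rng[1]) / diff(rng) else z * 0
  png::writePNG(z, path)
  invisible(path)
}
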