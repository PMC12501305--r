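#' Measurement set: per-angle complex S21 spectra
#'
#' The ingestion container for VNA acquisitions: an M x N complex matrix of
#' S21 values over a shared frequency grid (rows) and azimuth positions
#' (columns), plus acquisition metadata. Losslessly convertible to and from
#' [sinogram()].
#'
#' @param values Complex M x N matrix.
#' @param f Frequency grid in Hz (length M, strictly ascending).
#' @param angles Azimuth angles in degrees (length N).
#' @param metadata Named list (R0, container radius, nominal eps_r,
#'   calibration notes, ...).
#' @return Object of class `measurement_set`.
#' @export
measurement_set <- function(values, f, angles, metadata = list()) {
  values <- as.matrix(values)
  if (nrow(values) != length(f) || ncol(values) != length(angles)) {
    stop("measurement_set: values must be length(f) x length(angles)")
  }
  if (any(diff(f) <= 0)) stop("measurement_set: frequency grid must be strictly ascending")
  structure(list(values = values, f = f, angles = angles,
                 metadata = metadata), class = "measurement_set")
}

#' @export
print.measurement_set <- function(x, ...) {
  cat(sprintf("measurement_set: %d frequencies (%.3g-%.3g GHz) x %d angles\n",
              length(x$f), min(x$f) / 1e9, max(x$f) / 1e9, length(x$angles)))
  invisible(x)
}

#' Convert a measurement set to a sinogram
#'
#' Requires a uniform frequency grid and uniform angle coverage.
#'
#' @param ms A [measurement_set()].
#' @return A [sinogram()].
#' @export
as_sinogram <- function(ms) {
  stopifnot(inherits(ms, "measurement_set"))
  df <- diff(ms$f)
  if (max(abs(df - df[1])) > 1e-6 * df[1]) {
    stop("as_sinogram: frequency grid must be uniform")
  }
  sw <- frequency_sweep(ms$f[1], ms$f[length(ms$f)], length(ms$f))
  rot <- angular_sweep(length(ms$angles), start_deg = ms$angles[1])
  if (max(abs(rot$angles - ms$angles)) > 1e-6) {
    stop("as_sinogram: angles must be uniform over [start, start + 360)")
  }
  sinogram(ms$values, sw, rot, ms$metadata)
}

#' Convert a sinogram to a measurement set
#'
#' @param sg A [sinogram()].
#' @return A [measurement_set()].
#' @export
as_measurement_set <- function(sg) {
  stopifnot(inherits(sg, "sinogram"))
  measurement_set(sg$values, sg$sweep$f, sg$rotation$angles, sg$metadata)
}

#' Write a sinogram (or measurement set) as a CSV matrix
#'
#' Dialect: first column `f_Hz`, then two columns per angle,
#' `re_<angle>` and `im_<angle>`, with angles in the header. Lossless
#' round trip via [read_measurements()] with `dialect = "csv_matrix"`.
#'
#' @param x A [sinogram()] or [measurement_set()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sinogram_csv <- function(x, path) {
  if (inherits(x, "sinogram")) x <- as_measurement_set(x)
  stopifnot(inherits(x, "measurement_set"))
  out <- data.frame(f_Hz = x$f)
  for (j in seq_along(x$angles)) {
    out[[sprintf("re_%g", x$angles[j])]] <- Re(x$values[, j])
    out[[sprintf("im_%g", x$angles[j])]] <- Im(x$values[, j])
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

# Parse one Touchstone .s2p file; returns list(f, s21).
.read_s2p <- function(path) {
  lines <- readLines(path, warn = FALSE)
  fmt <- "RI"; funit <- 1e9   # Touchstone defaults to GHz
  data <- list()
  for (ln in seq_along(lines)) {
    s <- trimws(lines[ln])
    if (s == "" || startsWith(s, "!")) next
    if (startsWith(s, "#")) {
      tok <- toupper(strsplit(sub("^#\\s*", "", s), "\\s+")[[1]])
      if (length(tok) >= 1 && tok[1] %in% c("HZ", "KHZ", "MHZ", "GHZ")) {
        funit <- c(HZ = 1, KHZ = 1e3, MHZ = 1e6, GHZ = 1e9)[[tok[1]]]
      }
      if ("MA" %in% tok) fmt <- "MA"
      if ("RI" %in% tok) fmt <- "RI"
      if ("DB" %in% tok) fmt <- "DB"
      next
    }
    v <- suppressWarnings(as.numeric(strsplit(s, "\\s+")[[1]]))
    if (length(v) != 9 || any(is.na(v))) {
      stop("Touchstone parse error in '", basename(path), "' at line ", ln,
           ": expected 9 numeric fields, got '", s, "'")
    }
    data[[length(data) + 1]] <- v
  }
  if (!length(data)) stop("Touchstone parse error: no data rows in '", path, "'")
  m <- do.call(rbind, data)
  f <- m[, 1] * funit
  a <- m[, 4]; b <- m[, 5]          # S21 = third/fourth fields after f (port 2<-1)
  s21 <- switch(fmt,
    RI = complex(real = a, imaginary = b),
    MA = a * exp(1i * b * pi / 180),
    DB = 10^(a / 20) * exp(1i * b * pi / 180)
  )
  list(f = f, s21 = s21)
}

#' Read VNA measurements
#'
#' Two dialects: `"touchstone_per_angle"` reads a directory of two-port
#' `.s2p` files, one per azimuth position, with the angle encoded as a
#' zero-padded integer-degree filename suffix (`name_a237.s2p`); S21 (the
#' forward-transmission term) is extracted. `"csv_matrix"` reads the CSV
#' matrix written by [write_sinogram_csv()] (header carries the angles).
#'
#' @param path Directory (`touchstone_per_angle`) or CSV file
#'   (`csv_matrix`).
#' @param dialect `"touchstone_per_angle"` or `"csv_matrix"`.
#' @param metadata Optional named list merged into the result's metadata.
#' @return A [measurement_set()].
#' @export
read_measurements <- function(path,
                              dialect = c("touchstone_per_angle", "csv_matrix"),
                              metadata = list()) {
  dialect <- match.arg(dialect)
  if (dialect == "csv_matrix") {
    tab <- utils::read.csv(path, check.names = FALSE)
    if (names(tab)[1] != "f_Hz") stop("read_measurements: first column must be f_Hz")
    cn <- names(tab)[-1]
    re_cols <- grep("^re_", cn, value = TRUE)
    angles <- as.numeric(sub("^re_", "", re_cols))
    vals <- sapply(re_cols, function(rc) {
      ic <- sub("^re_", "im_", rc)
      if (!ic %in% cn) stop("read_measurements: missing column ", ic)
      complex(real = tab[[rc]], imaginary = tab[[ic]])
    })
    return(measurement_set(matrix(vals, nrow(tab), length(angles)),
                           tab$f_Hz, angles, metadata))
  }
  files <- list.files(path, pattern = "_a[0-9]+\\.s2p$", full.names = TRUE)
  if (!length(files)) {
    stop("read_measurements: no *_a<deg>.s2p files found in ", path)
  }
  angles <- as.numeric(sub(".*_a([0-9]+)\\.s2p$", "\\1", files))
  ord <- order(angles)
  files <- files[ord]; angles <- angles[ord]
  recs <- lapply(files, .read_s2p)
  f0 <- recs[[1]]$f
  bad <- vapply(recs, function(r) {
    length(r$f) != length(f0) || max(abs(r$f - f0)) > 1e-3
  }, logical(1))
  if (any(bad)) {
    stop("read_measurements: inconsistent frequency grids in: ",
         paste(basename(files[bad]), collapse = ", "))
  }
  vals <- vapply(recs, function(r) r$s21, complex(length(f0)))
  measurement_set(matrix(vals, length(f0), length(angles)), f0, angles,
                  metadata)
}

#' Write a measurement set as per-angle Touchstone files
#'
#' One two-port `.s2p` file per angle, named `<prefix>_a<deg>.s2p` with the
#' angle zero-padded to three digits. S21 carries the data; S12 is set equal
#' (reciprocity) and S11 = S22 = 0.
#'
#' @param ms A [measurement_set()]; angles must be integer degrees.
#' @param dir Output directory (created if needed).
#' @param prefix Filename prefix (default `"meas"`).
#' @param format `"RI"` (default) or `"MA"`.
#' @return Character vector of file paths, invisibly.
#' @export
write_touchstone_dir <- function(ms, dir, prefix = "meas",
                                 format = c("RI", "MA")) {
  stopifnot(inherits(ms, "measurement_set"))
  format <- match.arg(format)
  if (max(abs(ms$angles - round(ms$angles))) > 1e-9) {
    stop("write_touchstone_dir: angles must be integer degrees")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(ms$angles))
  for (j in seq_along(ms$angles)) {
    p <- file.path(dir, sprintf("%s_a%03d.s2p", prefix, round(ms$angles[j])))
    s21 <- ms$values[, j]
    ab <- if (format == "RI") cbind(Re(s21), Im(s21))
          else cbind(Mod(s21), Arg(s21) * 180 / pi)
    con <- file(p, "w")
    writeLines(sprintf("! mwisar export, angle %g deg", ms$angles[j]), con)
    writeLines(sprintf("# HZ S %s R 50", format), con)
    writeLines(sprintf("%.10e 0 0 %.10e %.10e %.10e %.10e 0 0",
                       ms$f, ab[, 1], ab[, 2], ab[, 1], ab[, 2]), con)
    close(con)
    paths[j] <- p
  }
  invisible(paths)
}

#' Reference (background) subtraction
#'
#' Elementwise complex difference of a target acquisition and a reference
#' acquisition on identical frequency/angle grids — the standard
#' differential step that removes static clutter.
#'
#' @param ms Target [measurement_set()].
#' @param ref Reference [measurement_set()] (e.g. empty tank).
#' @return A [measurement_set()]; metadata gains a `reference` note.
#' @export
subtract_reference <- function(ms, ref) {
  stopifnot(inherits(ms, "measurement_set"), inherits(ref, "measurement_set"))
  if (length(ms$f) != length(ref$f) || max(abs(ms$f - ref$f)) > 1e-3 ||
      length(ms$angles) != length(ref$angles) ||
      max(abs(ms$angles - ref$angles)) > 1e-9) {
    stop("subtract_reference: frequency/angle grids do not match")
  }
  md <- ms$metadata
  md$reference <- "subtracted"
  measurement_set(ms$values - ref$values, ms$f, ms$angles, md)
}

# Sub-bin peak delay per angle via a dense delay-domain evaluation of the
# windowed spectrum (matched-filter style); returns a vector of delays (s).
.peak_delays <- function(ms, window = "hann", oversample = 20) {
  sg <- as_sinogram(ms)
  M <- sg$sweep$n_points
  w <- switch(window,
    rect = rep(1, M),
    hann = as.numeric(signal::hanning(M)),
    hamming = as.numeric(signal::hamming(M))
  )
  tmax <- 1 / sg$sweep$df
  tau <- seq(0, tmax, length.out = M * oversample)
  E <- exp(-2i * pi * outer(tau, sg$sweep$f))     # K x M
  prof <- Mod(E %*% (sg$values * w))              # K x N
  tau[apply(prof, 2, which.max)]
}

#' Estimate the medium permittivity from rod measurements
#'
#' Rod-based calibration: for each acquisition of a thin rod at a known
#' position, range-compressed per-angle peak delays are regressed (through
#' the origin) against the geometric bistatic path length `d1 + d2` at each
#' rotation; the slope is `sqrt(eps_r)/c0`.
#'
#' @param rod_sets List of `list(ms = measurement_set, point = scene_point)`
#'   entries; at least two rod positions with distinct path lengths.
#' @param antenna The [antenna_config()] used for the acquisition.
#' @param window Range-compression window (default `"hann"`).
#' @return List with `eps_r` (estimate), `slope` (s/m), `residual_rms` (s),
#'   `n_points`, and the pooled `fit` data.frame (path_m, delay_s).
#' @export
calibrate_medium <- function(rod_sets, antenna, window = "hann") {
  if (length(rod_sets) < 2) {
    stop("calibrate_medium: need at least 2 rod positions with distinct path lengths")
  }
  stopifnot(inherits(antenna, "antenna_config"))
  ap <- antenna_positions(antenna)
  Ls <- c(); taus <- c()
  for (rs in rod_sets) {
    stopifnot(inherits(rs$ms, "measurement_set"),
              inherits(rs$point, "scene_point"))
    tau <- .peak_delays(rs$ms, window)
    a <- rs$ms$angles * pi / 180
    xy <- point_to_cart(rs$point)
    xr <- xy[1] * cos(a) + xy[2] * sin(a)
    yr <- -xy[1] * sin(a) + xy[2] * cos(a)
    d <- .bistatic_distances_xy(xr, yr, ap$tx, ap$rx)
    Ls <- c(Ls, d$d1 + d$d2)
    taus <- c(taus, tau)
  }
  slope <- sum(Ls * taus) / sum(Ls^2)
  if (slope <= 0) {
    warning("calibrate_medium: non-physical (non-positive) delay/path slope")
  }
  res <- taus - slope * Ls
  list(eps_r = (slope * .c0)^2, slope = slope,
       residual_rms = sqrt(mean(res^2)), n_points = length(Ls),
       fit = data.frame(path_m = Ls, delay_s = taus))
}
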