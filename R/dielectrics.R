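#' Loss tangent of a conductive dielectric
#'
#' `tan(delta) = sigma / (omega eps0 eps_r)` with `omega = 2 pi f` — the ratio
#' of conduction to displacement current in the medium.
#'
#' @param sigma Conductivity in S/m (>= 0).
#' @param eps_r Relative permittivity (> 0).
#' @param f Frequency in Hz (> 0).
#' @return Dimensionless loss tangent.
#' @export
#' @examples
#' loss_tangent(1.58, 61.07, 1e9) # blood at 1 GHz, ~0.466
loss_tangent <- function(sigma, eps_r, f) {
  if (any(f <= 0)) stop("loss_tangent: f must be > 0")
  if (any(eps_r <= 0)) stop("loss_tangent: eps_r must be > 0")
  if (any(sigma < 0)) stop("loss_tangent: sigma must be >= 0")
  sigma / (2 * pi * f * .eps0 * eps_r)
}

#' Wavelength in a lossy dielectric
#'
#' `lambda = c0 / (f Re{sqrt(eps_r (1 - i tan(delta)))})`. Reduces to
#' `c0/(f sqrt(eps_r))` in the lossless limit and shortens as loss increases.
#'
#' @param eps_r Relative permittivity (> 0).
#' @param tan_delta Loss tangent (>= 0).
#' @param f Frequency in Hz (> 0).
#' @return Wavelength in metres.
#' @export
#' @examples
#' wavelength_lossy(61.07, loss_tangent(1.58, 61.07, 1e9), 1e9) # ~0.0374 m
wavelength_lossy <- function(eps_r, tan_delta, f) {
  if (any(f <= 0)) stop("wavelength_lossy: f must be > 0")
  if (any(eps_r <= 0)) stop("wavelength_lossy: eps_r must be > 0")
  if (any(tan_delta < 0)) stop("wavelength_lossy: tan_delta must be >= 0")
  .c0 / (f * Re(sqrt(eps_r * complex(real = 1, imaginary = -tan_delta))))
}

#' Two-way (or one-way) attenuation through a tissue layer
#'
#' Signed dB loss of a signal crossing a layer of given thickness with a
#' per-centimetre attenuation coefficient; `passes = 2` for the radar
#' round trip. Losses are negative by convention.
#'
#' @param thickness_cm Layer thickness in cm (>= 0).
#' @param coeff_db_per_cm Attenuation coefficient in dB/cm (>= 0).
#' @param passes Number of traversals, 1 or 2 (default 2).
#' @return Signed loss in dB (<= 0).
#' @export
#' @examples
#' attenuation_loss(1, 1)      # skull bone, round trip: -2 dB
#' attenuation_loss(3, 2.1)    # grey matter, round trip: -12.6 dB
attenuation_loss <- function(thickness_cm, coeff_db_per_cm, passes = 2) {
  if (any(thickness_cm < 0) || any(coeff_db_per_cm < 0)) {
    stop("attenuation_loss: thickness and coefficient must be >= 0")
  }
  if (!all(passes %in% c(1, 2))) stop("attenuation_loss: passes must be 1 or 2")
  -(thickness_cm * passes * coeff_db_per_cm)
}

#' Link-budget total from individual loss terms
#'
#' Sums signed dB contributions (attenuation, interface return loss, target
#' RCS, spreading) into a total expected signal level.
#'
#' @param terms Numeric vector of signed dB terms; names are kept as labels.
#' @return Object of class `loss_budget` with fields `terms` and `total_db`.
#' @export
#' @examples
#' b <- loss_budget(c(skull = -2, grey_matter = -12.6, return_loss = -13,
#'                    coupling = -2, rcs = -30, spreading = -8))
#' b$total_db # -67.6
loss_budget <- function(terms) {
  terms <- unlist(terms)
  if (length(terms) && !all(is.finite(terms))) {
    stop("loss_budget: all terms must be finite")
  }
  structure(list(terms = terms, total_db = sum(terms)), class = "loss_budget")
}

#' @export
print.loss_budget <- function(x, ...) {
  cat("Link budget (dB):\n")
  if (length(x$terms)) {
    lab <- if (is.null(names(x$terms))) seq_along(x$terms) else names(x$terms)
    for (i in seq_along(x$terms)) {
      cat(sprintf("  %-28s %8.1f\n", lab[i], x$terms[i]))
    }
  }
  cat(sprintf("  %-28s %8.1f\n", "TOTAL", x$total_db))
  invisible(x)
}

#' Reference head link budget at 1 GHz
#'
#' The six-term first-order budget for a blood target 5 cm beneath the scalp
#' through a water coupling layer: skull bone (1 cm, two passes, 1 dB/cm),
#' grey matter (3 cm, two passes, 2.1 dB/cm), grey-matter-to-blood return
#' loss, additional coupling losses, RCS of a 3 cm blood sphere, and
#' spreading loss at 5 cm.
#'
#' @return A [loss_budget()] totalling -67.6 dB.
#' @export
head_budget_1GHz <- function() {
  loss_budget(c(
    skull_bone_1cm   = attenuation_loss(1, 1, 2),
    grey_matter_3cm  = attenuation_loss(3, 2.1, 2),
    return_loss_gm_blood = -13.0,
    coupling_losses  = -2.0,
    rcs_blood_3cm    = -30.0,
    spreading_5cm    = -8.0
  ))
}

#' Cole-Cole dispersion parameters
#'
#' Single-pole Cole-Cole parameter set: `eps_inf` (optical permittivity),
#' `eps_static` (static permittivity), relaxation time `tau` (s), broadening
#' exponent `alpha` in `[0, 1)` (`alpha = 0` gives Debye relaxation), and a
#' static ionic conductivity term (S/m).
#'
#' @param eps_inf,eps_static Dimensionless permittivities, `eps_static >= eps_inf > 0`.
#' @param tau Relaxation time in seconds (> 0).
#' @param alpha Broadening exponent in `[0, 1)`.
#' @param ionic_conductivity Static conductivity in S/m (>= 0).
#' @return Object of class `cole_cole_params`.
#' @export
cole_cole_params <- function(eps_inf, eps_static, tau, alpha = 0,
                             ionic_conductivity = 0) {
  if (eps_static < eps_inf) stop("cole_cole_params: eps_static must be >= eps_inf")
  if (tau <= 0) stop("cole_cole_params: tau must be > 0")
  if (alpha < 0 || alpha >= 1) stop("cole_cole_params: alpha must be in [0, 1)")
  if (ionic_conductivity < 0) stop("cole_cole_params: ionic_conductivity must be >= 0")
  structure(list(eps_inf = eps_inf, eps_static = eps_static, tau = tau,
                 alpha = alpha, ionic_conductivity = ionic_conductivity),
            class = "cole_cole_params")
}

# Named presets are data, not code: matching-media parameter sets.
.cole_cole_presets <- list(
  # Tap water near 25 C: Debye parameters for water with a small ionic
  # conductivity accounting for dissolved salts, giving ~78 - j5 at 1 GHz.
  tap_water_25C = list(eps_inf = 5.2, eps_static = 78.4, tau = 8.27e-12,
                       alpha = 0.0, ionic_conductivity = 0.05),
  # Distilled water: same relaxation, negligible ionic term.
  distilled_water_25C = list(eps_inf = 5.2, eps_static = 78.4, tau = 8.27e-12,
                             alpha = 0.0, ionic_conductivity = 0.0)
)

#' Named Cole-Cole presets for matching media
#'
#' @param name Preset name, one of `"tap_water_25C"` (default) or
#'   `"distilled_water_25C"`. The tap-water preset carries a small ionic
#'   conductivity (0.05 S/m) representative of dissolved salts; override via
#'   `ionic_conductivity` for other salinities.
#' @param ionic_conductivity Optional override of the preset's ionic
#'   conductivity in S/m.
#' @return A [cole_cole_params()] object.
#' @export
#' @examples
#' cole_cole(1e9, cole_cole_preset("tap_water_25C")) # ~ 78 - 4.7i
cole_cole_preset <- function(name = "tap_water_25C", ionic_conductivity = NULL) {
  if (!name %in% names(.cole_cole_presets)) {
    stop("cole_cole_preset: unknown preset '", name, "'; available: ",
         paste(names(.cole_cole_presets), collapse = ", "))
  }
  p <- .cole_cole_presets[[name]]
  if (!is.null(ionic_conductivity)) p$ionic_conductivity <- ionic_conductivity
  cole_cole_params(p$eps_inf, p$eps_static, p$tau, p$alpha, p$ionic_conductivity)
}

#' Complex relative permittivity from the Cole-Cole model
#'
#' `eps(omega) = eps_inf + (eps_s - eps_inf) / (1 + (i omega tau)^(1-alpha))
#'  - i sigma_i / (omega eps0)` under the `exp(+i omega t)` time convention,
#' so the imaginary part is `<= 0` for a passive medium.
#'
#' @param f Frequency in Hz (> 0); may be a vector.
#' @param params A [cole_cole_params()] object.
#' @return Complex relative permittivity, same length as `f`.
#' @export
cole_cole <- function(f, params) {
  stopifnot(inherits(params, "cole_cole_params"))
  if (any(f <= 0)) stop("cole_cole: f must be > 0")
  w <- 2 * pi * f
  jwt <- complex(real = 0, imaginary = 1) * w * params$tau
  eps <- params$eps_inf +
    (params$eps_static - params$eps_inf) / (1 + jwt^(1 - params$alpha))
  eps - complex(real = 0, imaginary = 1) * params$ionic_conductivity / (w * .eps0)
}

#' Wave propagation speed in a dielectric
#'
#' `v = c0 / sqrt(eps_r)`.
#'
#' @param eps_r Relative permittivity (> 0).
#' @return Speed in m/s.
#' @export
propagation_speed <- function(eps_r) {
  if (any(eps_r <= 0)) stop("propagation_speed: eps_r must be > 0")
  .c0 / sqrt(eps_r)
}

#' Theoretical range resolution of a swept-frequency radar
#'
#' `Delta R = v / (2 B) = c0 / (2 B sqrt(eps_r))` for sweep bandwidth `B` in a
#' medium of relative permittivity `eps_r`. With B = 4.8 GHz this is about
#' 31 mm in air and 3.5 mm in water (eps_r = 80); windowing for sidelobe
#' suppression broadens it slightly.
#'
#' @param B Sweep bandwidth in Hz (> 0).
#' @param eps_r Relative permittivity of the medium (> 0, default 1).
#' @return Range resolution in metres.
#' @export
#' @examples
#' range_resolution(4.8e9)      # ~0.031 m in air
#' range_resolution(4.8e9, 80)  # ~0.0035 m in water
range_resolution <- function(B, eps_r = 1) {
  if (any(B <= 0)) stop("range_resolution: B must be > 0")
  if (any(eps_r <= 0)) stop("range_resolution: eps_r must be > 0")
  .c0 / (2 * B * sqrt(eps_r))
}

#' Cross-range resolution estimate for a rotational aperture
#'
#' Standard turntable-ISAR estimate `Delta x = lambda_c / (4 sin(Delta
#' theta / 2))` at centre wavelength `lambda_c` in the medium, for a total
#' angular aperture `Delta theta`. This is an order-of-magnitude guide; the
#' realised cross-range width also depends on windowing and processing.
#'
#' @param f_center Centre frequency in Hz (> 0).
#' @param eps_r Relative permittivity of the medium (> 0, default 1).
#' @param aperture_deg Total synthetic aperture in degrees (default 180).
#' @return Cross-range resolution estimate in metres.
#' @export
cross_range_resolution <- function(f_center, eps_r = 1, aperture_deg = 180) {
  if (f_center <= 0 || eps_r <= 0 || aperture_deg <= 0) {
    stop("cross_range_resolution: all arguments must be > 0")
  }
  lambda_c <- .c0 / (f_center * sqrt(eps_r))
  lambda_c / (4 * sin(min(aperture_deg, 360) * pi / 360))
}

#' Dielectric record for a tissue at a spot frequency
#'
#' Builds a one-row record from conductivity and permittivity; loss tangent
#' and in-medium wavelength are derived via [loss_tangent()] and
#' [wavelength_lossy()].
#'
#' @param name Tissue label.
#' @param f Frequency in Hz.
#' @param sigma Conductivity in S/m.
#' @param eps_r Relative permittivity (> 1 for tissues).
#' @return One-row data.frame with columns `name`, `f_Hz`, `sigma_Sm`,
#'   `eps_r`, `tan_delta`, `lambda_m`.
#' @export
tissue_dielectric <- function(name, f, sigma, eps_r) {
  td <- loss_tangent(sigma, eps_r, f)
  data.frame(name = name, f_Hz = f, sigma_Sm = sigma, eps_r = eps_r,
             tan_delta = td, lambda_m = wavelength_lossy(eps_r, td, f),
             stringsAsFactors = FALSE)
}

#' Dielectric properties of head tissues at 1 GHz
#'
#' Conductivity and relative permittivity of blood, cortical bone,
#' cerebrospinal fluid, grey matter and white matter at 1 GHz (Gabriel
#' tissue database values), with derived loss tangent and in-medium
#' wavelength. Values are read from the CSV shipped in `extdata`.
#'
#' @param recompute If `TRUE` (default) derive `tan_delta` and `lambda_m`
#'   from `(sigma, eps_r, f)`; if `FALSE` return the stored columns.
#' @return data.frame with columns `name`, `f_Hz`, `sigma_Sm`, `eps_r`,
#'   `tan_delta`, `lambda_m`.
#' @export
#' @examples
#' head_tissues_1GHz()
head_tissues_1GHz <- function(recompute = TRUE) {
  path <- system.file("extdata", "head_tissues_1GHz.csv", package = "mwisar")
  tab <- read_tissue_table(path, validate = !recompute)
  if (recompute) {
    tab$tan_delta <- loss_tangent(tab$sigma_Sm, tab$eps_r, tab$f_Hz)
    tab$lambda_m <- wavelength_lossy(tab$eps_r, tab$tan_delta, tab$f_Hz)
  }
  tab
}

#' Read a tissue dielectric table from CSV
#'
#' Expects columns `name, f_Hz, sigma_Sm, eps_r, tan_delta, lambda_m`.
#' When `validate = TRUE`, checks that the stored loss tangent agrees with
#' `sigma/(2 pi f eps0 eps_r)` within 1%.
#'
#' @param path CSV file path.
#' @param validate Check internal consistency (default `TRUE`).
#' @return data.frame.
#' @export
read_tissue_table <- function(path, validate = TRUE) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "f_Hz", "sigma_Sm", "eps_r", "tan_delta", "lambda_m")
  if (!all(need %in% names(tab))) {
    stop("read_tissue_table: missing columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  }
  if (validate) {
    td <- loss_tangent(tab$sigma_Sm, tab$eps_r, tab$f_Hz)
    bad <- abs(td - tab$tan_delta) > 0.01 * pmax(td, .Machine$double.eps)
    if (any(bad)) {
      stop("read_tissue_table: loss tangent inconsistent with (sigma, eps_r, f) for: ",
           paste(tab$name[bad], collapse = ", "))
    }
  }
  tab
}

#' Write a tissue dielectric table to CSV
#'
#' @param tab data.frame as returned by [head_tissues_1GHz()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tissue_table <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
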