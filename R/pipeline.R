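#' Validate a run configuration
#'
#' Checks a nested configuration list against the pipeline schema; unknown
#' keys at any level are rejected so typos fail before any compute.
#'
#' @param config Named list (typically from [read_run_config()]).
#' @return The validated config with defaults filled in.
#' @export
validate_run_config <- function(config) {
  chk <- function(x, allowed, where) {
    unknown <- setdiff(names(x), allowed)
    if (length(unknown)) {
      stop("run config: unknown key(s) in ", where, ": ",
           paste(unknown, collapse = ", "))
    }
  }
  chk(config, c("seed", "geometry", "sweep", "rotation", "medium", "grid",
                "phantom", "solver", "output"), "top level")
  g <- config$geometry %||% list()
  chk(g, c("ring_radius_m", "opening_angle_deg", "element_halfspacing_m",
           "container_radius_m", "placement"), "geometry")
  sw <- config$sweep %||% list()
  chk(sw, c("f_start_hz", "f_stop_hz", "n_points"), "sweep")
  rot <- config$rotation %||% list()
  chk(rot, c("n_positions", "start_deg"), "rotation")
  med <- config$medium %||% list()
  chk(med, c("eps_r"), "medium")
  gr <- config$grid %||% list()
  chk(gr, c("n_side", "radius_m"), "grid")
  ph <- config$phantom %||% list()
  chk(ph, c("kind", "radius_m", "azimuth_deg", "r_x_m", "r_y_m", "r_diag_m",
            "a_m", "b_m", "insert_diameter_m", "snr_db"), "phantom")
  sol <- config$solver %||% list()
  chk(sol, c("rtol", "window", "gain_model", "gain_n", "gain_beamwidth_rad"),
      "solver")
  out <- config$output %||% list()
  chk(out, c("dir", "write_png", "upsample"), "output")

  num <- function(x) if (is.null(x)) NULL else as.numeric(x)

  list(
    seed = config$seed %||% 1L,
    geometry = list(
      ring_radius_m = g$ring_radius_m %||% 0.085,
      opening_angle_deg = g$opening_angle_deg %||% 0,
      element_halfspacing_m = g$element_halfspacing_m %||% 0,
      container_radius_m = g$container_radius_m %||% 0.085,
      placement = g$placement %||% "adjacent"),
    sweep = list(f_start_hz = num(sw$f_start_hz) %||% 0.1e9,
                 f_stop_hz = num(sw$f_stop_hz) %||% 4.8e9,
                 n_points = num(sw$n_points) %||% 200L),
    rotation = list(n_positions = rot$n_positions %||% 360L,
                    start_deg = rot$start_deg %||% 0),
    medium = list(eps_r = med$eps_r %||% 80),
    grid = list(n_side = gr$n_side %||% 64L, radius_m = gr$radius_m %||% 0.08),
    phantom = ph,
    solver = list(rtol = sol$rtol %||% NULL,
                  window = sol$window %||% "hann",
                  gain_model = sol$gain_model %||% "isotropic",
                  gain_n = sol$gain_n %||% 2,
                  gain_beamwidth_rad = sol$gain_beamwidth_rad %||% pi / 3),
    output = list(dir = out$dir %||% NULL,
                  write_png = out$write_png %||% FALSE,
                  upsample = out$upsample %||% 0L)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and validate a YAML run configuration
#'
#' @param path YAML file path.
#' @return Validated config list (see [validate_run_config()]).
#' @export
read_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path))
}

# Build a scene from the phantom section of a validated config.
.phantom_scene <- function(cfg) {
  ph <- cfg$phantom
  kind <- ph$kind %||% "single_point"
  er <- cfg$medium$eps_r
  cr <- cfg$geometry$container_radius_m
  switch(kind,
    single_point = single_point_scene(
      radius = ph$radius_m %||% 0.06, azimuth_deg = ph$azimuth_deg %||% 180,
      medium_eps_r = er, container_radius = cr),
    nine_point = nine_point_scene(
      r_x = ph$r_x_m %||% 0.07, r_y = ph$r_y_m %||% 0.06,
      r_diag = ph$r_diag_m %||% 0.045,
      medium_eps_r = er, container_radius = cr),
    ellipse_with_inserts = , potato = ellipse_with_inserts_scene(
      a = ph$a_m %||% 0.04, b = ph$b_m %||% 0.06,
      insert_diameter = ph$insert_diameter_m %||% 0.01,
      medium_eps_r = er, container_radius = cr),
    rod = rod_calibration_scene(
      scene_point(ph$radius_m %||% 0.04, ph$azimuth_deg %||% 0),
      medium_eps_r = er, container_radius = cr),
    stop("run config: unknown phantom kind '", kind, "'")
  )
}

#' Run the full simulate-and-reconstruct pipeline
#'
#' From a validated configuration: builds the phantom scene, simulates its
#' sinogram (optionally adding noise at `phantom$snr_db`), assembles the
#' sensitivity matrix, solves the least-squares scatterer map, assembles
#' linear and dB images (optionally upsampled), localizes peaks, and writes
#' artefacts plus a JSON run report if an output directory is configured.
#' Deterministic for a fixed seed.
#'
#' @param config Run configuration (list or YAML path); validated first.
#' @param quiet Suppress progress messages (default `TRUE`).
#' @return List with `scene`, `sinogram`, `sensitivity`, `map`,
#'   `image_linear`, `image_db`, `image_presentation` (or `NULL`), `peaks`,
#'   `report`, and `files` (paths written, possibly empty).
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- validate_run_config(config)
  say <- function(...) if (!quiet) message(...)
  t0 <- proc.time()[["elapsed"]]

  M <- cfg$sweep$n_points; N <- cfg$rotation$n_positions
  p <- cfg$grid$n_side
  if (M * N < p * p) {
    stop("run_pipeline: solvability condition violated: measurements ",
         "(M*N = ", M * N, ") must be >= pixels (p*q = ", p * p, ")")
  }

  ant <- antenna_config(cfg$geometry$ring_radius_m,
                        cfg$geometry$opening_angle_deg,
                        cfg$geometry$element_halfspacing_m,
                        placement = cfg$geometry$placement)
  fsw <- frequency_sweep(cfg$sweep$f_start_hz, cfg$sweep$f_stop_hz,
                         cfg$sweep$n_points)
  rot <- angular_sweep(cfg$rotation$n_positions, cfg$rotation$start_deg)
  gm <- gain_model(cfg$solver$gain_model, n = cfg$solver$gain_n,
                   beamwidth_rad = cfg$solver$gain_beamwidth_rad)
  fcfg <- forward_config(ant, fsw, rot, gain = gm)

  say("stage: phantom")
  sc <- .phantom_scene(cfg)
  say("stage: forward")
  sg <- simulate_sinogram(sc, fcfg)
  snr <- cfg$phantom$snr_db %||% Inf
  if (is.finite(snr)) sg <- add_noise(sg, snr, seed = cfg$seed)

  say("stage: sensitivity")
  grid <- imaging_grid(cfg$grid$n_side, cfg$grid$radius_m)
  J <- build_sensitivity(grid, cfg$medium$eps_r, fcfg,
                         container_radius = cfg$geometry$container_radius_m)
  say("stage: inverse")
  pv <- pinv_svd(J$J, cfg$solver$rtol)
  map <- solve_scatterer_map(sg, J, pinv = pv)
  img_lin <- assemble_image(map, scale = "linear")
  img_db <- assemble_image(map, scale = "db")
  img_pres <- if (cfg$output$upsample >= p && cfg$output$upsample > 0) {
    interpolate_presentation(img_lin, cfg$output$upsample)
  } else NULL
  peaks <- localize_peaks(img_lin, k = max(1, length(sc$scatterers)))

  report <- list(
    parameters = cfg,
    rtol_used = pv$rtol,
    rank = pv$rank,
    window = cfg$solver$window,
    gain_model = cfg$solver$gain_model,
    ordering = J$ordering,
    peaks = peaks,
    timings = list(elapsed_s = proc.time()[["elapsed"]] - t0)
  )

  files <- character(0)
  if (!is.null(cfg$output$dir)) {
    dir.create(cfg$output$dir, showWarnings = FALSE, recursive = TRUE)
    fp <- function(x) file.path(cfg$output$dir, x)
    write_sinogram_csv(sg, fp("sinogram.csv"))
    write_scatterer_map_csv(map, fp("scatterer_map.csv"))
    jsonlite::write_json(report, fp("report.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
    files <- c(fp("sinogram.csv"), fp("scatterer_map.csv"), fp("report.json"))
    if (isTRUE(cfg$output$write_png)) {
      img_out <- if (!is.null(img_pres)) img_pres else img_lin
      write_image_png(img_out, fp("image.png"))
      files <- c(files, fp("image.png"))
    }
  }

  list(scene = sc, sinogram = sg, sensitivity = J, map = map,
       image_linear = img_lin, image_db = img_db,
       image_presentation = img_pres, peaks = peaks, report = report,
       files = files)
}
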