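# Offline pipeline driver tying the modules together:
# simulate -> process -> screen / export. Each command writes its
# artifacts under an output directory and records the fully resolved
# configuration beside them for provenance. With a fixed seed every
# artifact (timestamps aside) is reproducible byte for byte.

#' Default run configuration
#'
#' Nested named list of every tunable the pipeline commands accept.
#' Values supplied through `...` (or a YAML config file via
#' [read_run_config()]) override these defaults field by field.
#'
#' @param ... Named overrides, possibly nested lists (e.g.
#'   `schedule = list(n_data = 100)`).
#' @return A `run_config` list.
#' @export
cred_config <- function(...) {
  base <- list(
    seed = 1L,
    schedule = list(n_data = 20L, n_interval = 10L, frame_time = 0.512,
                    exposure = 0.5, defocus_exposure = 0.01,
                    start_angle = -10, rotation_speed = 0.45,
                    start_delay = 0.2),
    beam = list(voltage = 200, camera_length = 250, pixel_pitch = 55),
    center = list(method = "gaussian_max", sigma = 10),
    distortion = list(eccentricity = 0, azimuth = 0),
    simulate = list(cell = c(10, 10, 10, 90, 90, 90), d_min = 1.0,
                    excitation_tol = 0.002, spot_peak = 400,
                    background = 0.5, aperture_radius = 0.75,
                    crystal_radius = 0.25, drift_rate = 0),
    screen = list(n_per_class = 40L, pattern_size = 256L,
                  neighbor_min = 1.5, edge_min = 0.5, score_cutoff = 0.5,
                  area = 200, n_crystals = 60L,
                  cnn = list(filters = c(4L, 8L), dense = 16L,
                             epochs = 4L, batch_size = 75L)),
    qc = list(beam_exclusion_radius = 30, dip_threshold = 0.5,
              run_length = 5L, cv_cutoff = 0.3)
  )
  .merge_config(base, list(...))
}

.merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read a YAML run configuration
#'
#' @param path YAML file of overrides.
#' @return A `run_config` with file values layered over the defaults.
#' @export
read_run_config <- function(path) {
  do.call(cred_config, yaml::read_yaml(path))
}

.log_msg <- function(...) {
  message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...)))
}

#' Run a pipeline command
#'
#' * `simulate`: build the acquisition schedule, simulate the rotation
#'   series, and write the SMV data frames (`data/`), defocused tracking
#'   snapshots (`tracking/`) and a JSON truth sidecar.
#' * `process`: read the SMV stack back, estimate per-frame beam centres
#'   and their median, compute the QC scale series, and write
#'   `beam_center.csv`, `qc.csv` and `process.json`.
#' * `screen`: simulate a crystal field and still patterns, train the
#'   (small, config-sized) screening CNN, apply the isolation filter and
#'   score cutoff, and write `candidates.csv`.
#' * `export`: from `process.json`, write `XDS.INP`, DIALS parameters, a
#'   REDp angle table, GEO_CORR tables when distortion is configured, and
#'   the YAML experiment log. Refuses to run without a beam-centre
#'   estimate.
#'
#' @param command One of `"simulate"`, `"process"`, `"screen"`,
#'   `"export"`.
#' @param config A [cred_config()] list (or path to a YAML file).
#' @param out_dir Output directory for this run's artifacts.
#' @param seed Optional override of `config$seed`.
#' @return Invisibly, a list of the artifacts produced.
#' @export
cred_run <- function(command = c("simulate", "process", "screen", "export"),
                     config = cred_config(), out_dir, seed = NULL) {
  command <- match.arg(command)
  if (is.character(config)) config <- read_run_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(config, file.path(out_dir, "run_config.yaml"))
  switch(command,
         simulate = .run_simulate(config, out_dir),
         process = .run_process(config, out_dir),
         screen = .run_screen(config, out_dir),
         export = .run_export(config, out_dir))
}

.build_schedule_from <- function(config) {
  s <- config$schedule
  build_schedule(n_data = s$n_data, n_interval = s$n_interval,
                 frame_time = s$frame_time, start_angle = s$start_angle,
                 rotation_speed = s$rotation_speed, exposure = s$exposure,
                 defocus_exposure = s$defocus_exposure,
                 start_delay = s$start_delay)
}

.run_simulate <- function(config, out_dir) {
  .log_msg("simulate: building schedule and rendering frames")
  sched <- .build_schedule_from(config)
  sim_cfg <- config$simulate
  n_slots <- nrow(sched$slots)
  drift <- if (sim_cfg$drift_rate > 0)
    function(i) c(sim_cfg$drift_rate * (i - 1), 0) else NULL
  exp <- synthetic_experiment(
    cell = sim_cfg$cell, voltage = config$beam$voltage,
    camera_length = config$beam$camera_length,
    pixel_pitch = config$beam$pixel_pitch, d_min = sim_cfg$d_min,
    excitation_tol = sim_cfg$excitation_tol, spot_peak = sim_cfg$spot_peak,
    background = sim_cfg$background,
    aperture_radius = sim_cfg$aperture_radius,
    crystal_radius = sim_cfg$crystal_radius, drift = drift,
    seed = config$seed)
  sim <- simulate_rotation_series(exp, sched)
  data_dir <- file.path(out_dir, "data")
  trk_dir <- file.path(out_dir, "tracking")
  dir.create(data_dir, showWarnings = FALSE)
  dir.create(trk_dir, showWarnings = FALSE)
  osc <- sched$rotation_speed * sched$frame_time
  for (i in seq_along(sim$frames)) {
    f <- sim$frames[[i]]
    hdr <- smv_header(pixel_size = config$beam$pixel_pitch / 1000,
                      distance = config$beam$camera_length,
                      wavelength = electron_wavelength(config$beam$voltage),
                      beam_center = sim$truth$beam_center,
                      osc_start = sched$slots$angle_start[i],
                      osc_range = osc, exposure = f$exposure)
    dest <- if (f$kind == "data") data_dir else trk_dir
    write_smv(f, hdr, file.path(dest, sprintf("%05d.img", i)))
  }
  truth_path <- file.path(out_dir, "truth.json")
  jsonlite::write_json(
    list(beam_center = sim$truth$beam_center,
         attenuation = sim$truth$attenuation,
         n_slots = n_slots,
         n_data = sched$n_data, n_defocus = sched$n_defocus,
         kind = sched$slots$kind),
    truth_path, auto_unbox = TRUE, digits = NA)
  .log_msg("simulate: wrote %d frames to %s", n_slots, out_dir)
  invisible(list(schedule = sched, truth = truth_path, data_dir = data_dir))
}

.run_process <- function(config, out_dir) {
  data_dir <- file.path(out_dir, "data")
  files <- sort(list.files(data_dir, pattern = "\\.img$", full.names = TRUE))
  if (length(files) == 0)
    stop("process: no SMV frames under ", data_dir, " (run simulate first)")
  .log_msg("process: reading %d frames", length(files))
  frames <- lapply(files, function(p) {
    sm <- read_smv(p)
    idx <- as.integer(sub("\\.img$", "", basename(p)))
    detector_frame(sm$pixels, kind = "data", frame_index = idx,
                   timestamp = NA_real_, exposure = sm$header$TIME)
  })
  ests <- lapply(frames, center_gaussian_max, sigma = config$center$sigma)
  med <- median_center(ests)
  utils::write.csv(beam_center_table(ests),
                   file.path(out_dir, "beam_center.csv"), row.names = FALSE)
  qc <- scale_series(frames, med,
                     beam_exclusion_radius = config$qc$beam_exclusion_radius)
  fl <- tracking_flags(qc, dip_threshold = config$qc$dip_threshold,
                       run_length = config$qc$run_length,
                       cv_cutoff = config$qc$cv_cutoff)
  write_scale_series(qc, file.path(out_dir, "qc.csv"), fl)
  jsonlite::write_json(
    list(beam_center = as.numeric(med), n_frames = length(frames),
         verdict = fl$verdict),
    file.path(out_dir, "process.json"), auto_unbox = TRUE, digits = NA)
  .log_msg("process: median beam centre (%.2f, %.2f), verdict: %s",
           med[1], med[2], fl$verdict)
  invisible(list(beam_center = med, qc = qc, verdict = fl$verdict))
}

.run_screen <- function(config, out_dir) {
  sc <- config$screen
  .log_msg("screen: generating %d patterns/class and training CNN",
           sc$n_per_class)
  pats <- simulate_pattern_classes(sc$n_per_class,
                                   classes = c("spots", "rings", "blank"),
                                   seed = config$seed,
                                   size = sc$pattern_size, preprocess = TRUE)
  n <- length(pats$labels)
  set.seed(config$seed)
  idx <- sample.int(n)
  n_tr <- floor(0.8 * n)
  arch <- cnn_architecture(filters = sc$cnn$filters, dense = sc$cnn$dense)
  model <- cred_cnn(pats$images[, , idx[1:n_tr]], pats$labels[idx[1:n_tr]],
                    architecture = arch, epochs = sc$cnn$epochs,
                    batch_size = sc$cnn$batch_size, seed = config$seed)
  field <- simulate_crystal_field(area = sc$area, n_crystals = sc$n_crystals,
                                  seed = config$seed)
  keep <- isolation_filter(field[, c("x", "y")], attr(field, "frame"),
                           neighbor_min = sc$neighbor_min,
                           edge_min = sc$edge_min)
  iso <- field[keep, , drop = FALSE]
  # score each isolated crystal with a fresh simulated pattern:
  # crystals get a spots or blank pattern at random (quality unknown
  # upstream), the CNN provides the prediction score
  cls <- sample(c("spots", "blank"), nrow(iso), replace = TRUE)
  scores <- numeric(nrow(iso))
  for (i in seq_len(nrow(iso))) {
    img <- preprocess_pattern(.render_pattern_class(cls[i], sc$pattern_size))
    scores[i] <- predict_score(model, img)
  }
  cand <- crystal_candidates(
    image_path = sprintf("images/%04d.tiff", seq_len(nrow(iso))),
    image_seq = seq_len(nrow(iso)), crystal_seq = seq_len(nrow(iso)),
    score = scores, object_size = iso$size,
    stage_x = iso$x, stage_y = iso$y)
  path <- file.path(out_dir, "candidates.csv")
  write_candidates(cand, path)
  n_good <- sum(scores > sc$score_cutoff)
  .log_msg("screen: %d isolated candidates, %d above score %.2f",
           nrow(iso), n_good, sc$score_cutoff)
  invisible(list(candidates = cand, model = model, path = path))
}

.run_export <- function(config, out_dir) {
  pj <- file.path(out_dir, "process.json")
  if (!file.exists(pj))
    stop("export: no beam-centre estimate (", pj,
         " missing) — run process first")
  proc <- jsonlite::fromJSON(pj)
  sched <- .build_schedule_from(config)
  beam <- beam_parameters(config$beam$voltage, config$beam$camera_length,
                          config$beam$pixel_pitch)
  dm <- distortion_model(config$distortion$eccentricity,
                         config$distortion$azimuth,
                         center = proc$beam_center)
  geo_files <- c("geo_corr_x.img", "geo_corr_y.img")
  if (dm$eccentricity > 0)
    write_geo_corr_smv(geo_corr_tables(dm), out_dir, "geo_corr")
  write_xds_inp(sched, proc$beam_center, beam,
                file.path(out_dir, "XDS.INP"), distortion = dm,
                geo_corr_files = geo_files)
  write_dials_params(sched, file.path(out_dir, "dials_params.phil"))
  write_redp(sched, file.path(out_dir, "redp_angles.txt"))
  md <- rotation_metadata(sched, camera_length = config$beam$camera_length,
                          aperture_radius = config$simulate$aperture_radius)
  write_experiment_log(md, file.path(out_dir, "cRED_log.yaml"),
                       extra = list(written = format(Sys.time())))
  .log_msg("export: wrote XDS.INP, DIALS parameters, REDp table and log")
  invisible(list(xds = file.path(out_dir, "XDS.INP"),
                 dials = file.path(out_dir, "dials_params.phil"),
                 redp = file.path(out_dir, "redp_angles.txt"),
                 log = file.path(out_dir, "cRED_log.yaml")))
}
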