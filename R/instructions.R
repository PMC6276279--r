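# Instruction-file generation for downstream processing software
# (XDS, DIALS, REDp) and the experiment log.
#
# Defocus-tracking slots are represented by placeholder frame numbers in
# DATA_RANGE so the EXCLUDE_DATA_RANGE indices align with slot indices;
# the defocused snapshots themselves live in a sibling directory.
# Print precision follows the conventions of the acquisition logs:
# 4 decimals for angles, 5 significant figures for the wavelength.

#' Write an XDS input file
#'
#' Emits the geometry, schedule and masking instructions XDS needs:
#' `OSCILLATION_RANGE`, `STARTING_ANGLE`, `DATA_RANGE`, `ORGX/ORGY`,
#' `NX/NY/QX/QY`, `WAVELENGTH`, the two `UNTRUSTED_RECTANGLE` strips
#' masking the Timepix module cross, one `EXCLUDE_DATA_RANGE` line per
#' defocus gap, and `X-GEO_CORR`/`Y-GEO_CORR` references when the
#' distortion model is non-trivial.
#'
#' @param schedule An [build_schedule()] result.
#' @param beam_center `(x, y)` beam centre in pixels (required).
#' @param beam A [beam_parameters()] object.
#' @param path Output path (conventionally `XDS.INP`).
#' @param distortion Optional [distortion_model()]; `e > 0` adds GEO_CORR
#'   references.
#' @param name_template `NAME_TEMPLATE_OF_DATA_FRAMES` value.
#' @param rotation_axis Laboratory rotation axis, 3-vector.
#' @param geo_corr_files Paths referenced by the GEO_CORR instructions.
#' @return `path`, invisibly.
#' @export
write_xds_inp <- function(schedule, beam_center, beam, path,
                          distortion = NULL,
                          name_template = "data/?????.img",
                          rotation_axis = c(-1, 0, 0),
                          geo_corr_files = c("geo_corr_x.img", "geo_corr_y.img")) {
  stopifnot(inherits(schedule, "acquisition_schedule"))
  if (missing(beam_center) || is.null(beam_center) ||
      any(!is.finite(beam_center)))
    stop("cannot write XDS.INP: no beam-centre estimate available")
  n_slots <- nrow(schedule$slots)
  osc <- schedule$rotation_speed * schedule$frame_time
  lines <- c(
    "! XDS.INP generated by credkit",
    "JOB= XYCORR INIT COLSPOT IDXREF DEFPIX INTEGRATE CORRECT",
    sprintf("NAME_TEMPLATE_OF_DATA_FRAMES= %s", name_template),
    sprintf("DATA_RANGE= 1 %d", n_slots),
    "STARTING_FRAME= 1",
    sprintf("STARTING_ANGLE= %.4f", schedule$start_angle),
    sprintf("OSCILLATION_RANGE= %.4f", osc),
    sprintf("ROTATION_AXIS= %g %g %g", rotation_axis[1], rotation_axis[2],
            rotation_axis[3]),
    sprintf("WAVELENGTH= %.5f", beam$wavelength),
    sprintf("DETECTOR_DISTANCE= %.4f", beam$camera_length),
    sprintf("ORGX= %.2f ORGY= %.2f", beam_center[1], beam_center[2]),
    "DETECTOR= PILATUS  MINIMUM_VALID_PIXEL_VALUE= 0  OVERLOAD= 65000",
    sprintf("NX= %d NY= %d QX= %.4f QY= %.4f", 516L, 516L,
            beam$pixel_pitch / 1000, beam$pixel_pitch / 1000),
    vapply(cross_untrusted_rectangles(), function(r)
      sprintf("UNTRUSTED_RECTANGLE= %d %d %d %d", r[1], r[2], r[3], r[4]),
      character(1))
  )
  exc <- excluded_ranges(schedule)
  if (nrow(exc) > 0)
    lines <- c(lines, sprintf("EXCLUDE_DATA_RANGE= %d %d",
                              exc[, "first"], exc[, "last"]))
  if (!is.null(distortion) && distortion$eccentricity > 0)
    lines <- c(lines,
               sprintf("X-GEO_CORR= %s", geo_corr_files[1]),
               sprintf("Y-GEO_CORR= %s", geo_corr_files[2]))
  writeLines(lines, path)
  invisible(path)
}

#' Write DIALS frame-selection parameters
#'
#' One `scan_range=first,last` token per run of data frames (for
#' dials.find_spots) and one `exclude_images=first,last` token per
#' defocus gap (for dials.integrate), one token per line. Together the
#' two sets partition `[1, n_slots]`.
#'
#' @param schedule An [build_schedule()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dials_params <- function(schedule, path) {
  ex <- dials_exclusions(schedule)
  lines <- c(
    sprintf("scan_range=%d,%d", ex$scan_range[, "first"],
            ex$scan_range[, "last"]),
    if (nrow(ex$exclude_images) > 0)
      sprintf("exclude_images=%d,%d", ex$exclude_images[, "first"],
              ex$exclude_images[, "last"])
  )
  writeLines(lines, path)
  invisible(path)
}

#' Parse a DIALS parameter file back into ranges
#'
#' @param path File written by [write_dials_params()].
#' @return List with integer range matrices `scan_range` and
#'   `exclude_images`.
#' @export
parse_dials_params <- function(path) {
  lines <- readLines(path)
  grab <- function(key) {
    sel <- grep(paste0("^", key, "="), lines, value = TRUE)
    if (length(sel) == 0)
      return(matrix(integer(0), ncol = 2,
                    dimnames = list(NULL, c("first", "last"))))
    m <- do.call(rbind, lapply(strsplit(sub(".*=", "", sel), ","),
                               as.integer))
    colnames(m) <- c("first", "last")
    m
  }
  list(scan_range = grab("scan_range"), exclude_images = grab("exclude_images"))
}

#' Write a REDp tilt-angle table
#'
#' One line per data frame with its index and mid-slot tilt angle; the
#' minimal per-frame geometry REDp needs.
#'
#' @param schedule An [build_schedule()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_redp <- function(schedule, path) {
  slots <- schedule$slots[schedule$slots$kind == "data", ]
  lines <- c("# frame  tilt_angle_deg",
             if (nrow(slots) > 0)
               sprintf("%6d  %10.4f", slots$index,
                       (slots$angle_start + slots$angle_end) / 2))
  writeLines(lines, path)
  invisible(path)
}

#' Create the next experiment output directory
#'
#' Directories are named `<prefix><NNNNNN>` with an incrementing numeric
#' suffix; an existing directory is never reused, so previous
#' acquisitions are never overwritten.
#'
#' @param root Parent directory (created if needed).
#' @param prefix Directory-name prefix.
#' @param width Zero-padded suffix width.
#' @return Path of the newly created directory.
#' @export
new_experiment_dir <- function(root, prefix = "exp_", width = 6L) {
  dir.create(root, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(10^width - 1L)) {
    cand <- file.path(root, sprintf(paste0(prefix, "%0", width, "d"), i))
    if (!dir.exists(cand) && !file.exists(cand)) {
      dir.create(cand)
      return(cand)
    }
  }
  stop("exhausted experiment directory suffixes under ", root)
}

#' Write the experiment log
#'
#' YAML log of all experimental parameters (exposure time, spot number,
#' camera length, rotation speed, frame counts, timestamps, ...), the
#' machine-readable record each acquisition leaves behind.
#'
#' @param metadata A [rotation_metadata()] object (or named list).
#' @param path Output path (conventionally `cRED_log.yaml`).
#' @param extra Optional named list appended to the log (e.g. timestamps).
#' @return `path`, invisibly.
#' @export
write_experiment_log <- function(metadata, path, extra = list()) {
  rec <- c(unclass(metadata), extra)
  yaml::write_yaml(rec, path, precision = 12L)
  invisible(path)
}

#' Read an experiment log
#'
#' @param path File written by [write_experiment_log()].
#' @return Named list of logged fields.
#' @export
read_experiment_log <- function(path) yaml::read_yaml(path)
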