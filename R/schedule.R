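# cRED acquisition schedule: the slot-by-slot timeline of data frames and
# defocused crystal-tracking frames, and every integration-geometry number
# derived from it.
#
# Cycle convention: n_interval DATA frames followed by one defocus slot.
# With the typical n = 10 this interleaves one tracking image per ten
# diffraction patterns (554 data frames -> 55 tracking images, 430 -> 43).
# Defocus slots occupy a full frame slot even though their exposure is
# ~0.01 s; the goniometer keeps rotating, so each gap sweeps exactly one
# frame's oscillation and the oscillation angle stays consistent for the
# integration software.

#' Total tilt range of a rotation experiment
#'
#' @param start,end Goniometer angles at the start and end of the run,
#'   degrees.
#' @return `abs(end - start)`, degrees.
#' @examples
#' tilt_range(-64.06, 63.91)  # 127.97
#' @export
tilt_range <- function(start, end) abs(end - start)

#' Oscillation angle per frame
#'
#' The per-frame angular increment used for integration: the rotation
#' range divided by the data-collection time, times the duration of one
#' frame slot.
#'
#' @param tilt_range Total rotation range, degrees.
#' @param total_time Total acquisition time, s.
#' @param frame_time Duration of one frame slot, s.
#' @return Oscillation angle, degrees per frame.
#' @examples
#' oscillation_angle(102.55, 224.7, 0.512)  # 0.2336
#' @export
oscillation_angle <- function(tilt_range, total_time, frame_time) {
  if (total_time <= 0 || frame_time <= 0)
    stop("`total_time` and `frame_time` must be positive")
  tilt_range / total_time * frame_time
}

#' Build a defocus-interleaved acquisition schedule
#'
#' Lays out `n_data` data frames in cycles of `n_interval` data slots
#' followed by one defocus-tracking slot; a trailing partial cycle gets
#' no defocus slot. All slots share the same duration `frame_time` and
#' sweep the same rotation range, so gaps cover exactly one frame
#' oscillation. A start delay (default 0.2 s) avoids goniometer
#' acceleration/backlash and shifts the time origin only.
#'
#' @param n_data Number of data frames (>= 1).
#' @param n_interval Data frames per defocus cycle (>= 1, typically 10).
#' @param frame_time Slot duration, s (exposure + readout + overhead).
#' @param start_angle Goniometer angle at the first slot, degrees.
#' @param rotation_speed Signed rotation speed, degrees/s.
#' @param exposure Data-frame exposure, s.
#' @param defocus_exposure Defocused-snapshot exposure, s.
#' @param start_delay Delay before the first slot, s.
#' @return An `acquisition_schedule` with a `slots` data.frame
#'   (`index`, `kind`, `angle_start`, `angle_end`, `time_start`) and the
#'   scalar parameters.
#' @export
build_schedule <- function(n_data, n_interval = 10L, frame_time = 0.512,
                           start_angle = 0, rotation_speed = 0.45,
                           exposure = 0.5, defocus_exposure = 0.01,
                           start_delay = 0.2) {
  n_data <- as.integer(n_data); n_interval <- as.integer(n_interval)
  if (is.na(n_data) || n_data < 1L) stop("`n_data` must be >= 1")
  if (is.na(n_interval) || n_interval < 1L) stop("`n_interval` must be >= 1")
  if (frame_time <= 0) stop("`frame_time` must be positive")
  n_defocus <- n_data %/% n_interval
  n_slots <- n_data + n_defocus
  kind <- rep("data", n_slots)
  defocus_at <- (n_interval + 1L) * seq_len(n_defocus)
  kind[defocus_at] <- "defocus_tracking"
  osc <- rotation_speed * frame_time
  idx <- seq_len(n_slots)
  slots <- data.frame(
    index = idx,
    kind = kind,
    angle_start = start_angle + (idx - 1L) * osc,
    angle_end = start_angle + idx * osc,
    time_start = start_delay + (idx - 1L) * frame_time,
    stringsAsFactors = FALSE
  )
  structure(
    list(slots = slots, n_data = n_data, n_defocus = n_defocus,
         n_interval = n_interval, frame_time = frame_time,
         exposure = exposure, defocus_exposure = defocus_exposure,
         start_angle = start_angle, rotation_speed = rotation_speed,
         start_delay = start_delay,
         end_angle = start_angle + n_slots * osc),
    class = "acquisition_schedule"
  )
}

#' @export
print.acquisition_schedule <- function(x, ...) {
  cat(sprintf(
    paste0("Acquisition schedule: %d data + %d defocus-tracking slots ",
           "(n_interval = %d)\n  %.4f deg/frame at %.3f deg/s, angles %.2f",
           " to %.2f deg, slot %.3f s (delay %.1f s)\n"),
    x$n_data, x$n_defocus, x$n_interval,
    x$rotation_speed * x$frame_time, x$rotation_speed,
    x$start_angle, x$end_angle, x$frame_time, x$start_delay))
  invisible(x)
}

#' Frame ranges to exclude from integration
#'
#' Maximal runs of defocus-tracking slot indices, as 1-based inclusive
#' `(first, last)` ranges suitable for the XDS `EXCLUDE_DATA_RANGE`
#' instruction. Their complement over `[1, n_slots]` is exactly the data
#' slots.
#'
#' @param schedule An [build_schedule()] result.
#' @return Integer matrix with columns `first`, `last` (zero rows if the
#'   schedule has no defocus slots).
#' @export
excluded_ranges <- function(schedule) {
  stopifnot(inherits(schedule, "acquisition_schedule"))
  runs_to_ranges(schedule$slots$index[schedule$slots$kind == "defocus_tracking"])
}

#' Frame-exclusion strings for DIALS
#'
#' The same bookkeeping as [excluded_ranges()] in the form DIALS wants:
#' `scan_range` (the data runs, for dials.find_spots) and
#' `exclude_images` (the defocus runs, for dials.integrate). The two
#' partitions tile `[1, n_slots]` exactly.
#'
#' @param schedule An [build_schedule()] result.
#' @return List with integer range matrices `scan_range` and
#'   `exclude_images`.
#' @export
dials_exclusions <- function(schedule) {
  stopifnot(inherits(schedule, "acquisition_schedule"))
  list(
    scan_range = runs_to_ranges(schedule$slots$index[schedule$slots$kind == "data"]),
    exclude_images = excluded_ranges(schedule)
  )
}

#' Derived rotation metadata for an experiment
#'
#' Collects the integration-geometry numbers and acquisition metadata a
#' processing-software input file needs.
#'
#' @param schedule An [build_schedule()] result.
#' @param total_time Total acquisition time, s; defaults to
#'   `n_slots * frame_time`.
#' @param spot_size,camera_length,aperture_radius Acquisition metadata
#'   passed through to logs.
#' @return A `rotation_metadata` list.
#' @export
rotation_metadata <- function(schedule, total_time = NULL, spot_size = 2,
                              camera_length = 250, aperture_radius = 0.75) {
  stopifnot(inherits(schedule, "acquisition_schedule"))
  n_slots <- nrow(schedule$slots)
  if (is.null(total_time)) total_time <- n_slots * schedule$frame_time
  tr <- tilt_range(schedule$start_angle, schedule$end_angle)
  structure(
    list(
      tilt_range = tr,
      total_time = total_time,
      rotation_speed = schedule$rotation_speed,
      oscillation_angle = oscillation_angle(tr, total_time, schedule$frame_time),
      n_data_frames = schedule$n_data,
      n_defocus_frames = schedule$n_defocus,
      frame_time = schedule$frame_time,
      exposure = schedule$exposure,
      spot_size = spot_size,
      camera_length = camera_length,
      aperture_radius = aperture_radius
    ),
    class = "rotation_metadata"
  )
}

#' @export
print.rotation_metadata <- function(x, ...) {
  cat(sprintf(
    paste0("Rotation metadata: tilt range %.2f deg in %.1f s, ",
           "%.4f deg/frame\n  %d data frames, %d tracking images, ",
           "camera length %g mm\n"),
    x$tilt_range, x$total_time, x$oscillation_angle,
    x$n_data_frames, x$n_defocus_frames, x$camera_length))
  invisible(x)
}
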