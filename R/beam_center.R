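# Primary-beam position estimation.
#
# Two estimators are used at different points of the workflow:
#  - processing (cRED): arg-max of the Gaussian-smoothed frame, robust to
#    single hot pixels because of the smoothing;
#  - screening (SerialED): centroid of the top few percent brightest
#    pixels, cheap enough to run on every still pattern.
# For integration the per-frame estimates are reduced to a component-wise
# median, since XDS/DIALS expect a stationary beam.

#' Beam centre by Gaussian-smoothed arg-max
#'
#' Smooths the frame with a Gaussian of standard deviation `sigma`
#' (typically 10--30 px for Timepix diffraction data) and returns the
#' position of the maximum. Ties are broken deterministically towards the
#' lowest row, then lowest column.
#'
#' @param frame `detector_frame` or numeric matrix.
#' @param sigma Smoothing standard deviation, px. Default 10 (the sharp
#'   end of the usual range, best localization on clean data).
#' @return A `beam_center_estimate`: list with `position` `(x, y)` in
#'   1-based pixels (x = column, y = row), `method`, `frame_index`.
#' @export
center_gaussian_max <- function(frame, sigma = 10) {
  px <- frame_pixels(frame)
  if (all(px == 0)) stop("no signal: frame is all zero")
  sm <- gaussian_smooth(px, sigma)
  rc <- argmax_rc(sm)
  .bc_estimate(c(rc["col"], rc["row"]), "gaussian_max",
               if (inherits(frame, "detector_frame")) frame$frame_index else NA_integer_)
}

#' Beam centre by top-percentile centroid
#'
#' Mean position of the brightest `ceil(fraction * N)` pixels (default:
#' top 5%); every pixel tied at the threshold intensity is included, so
#' on a constant frame all pixels tie and the estimate is the geometric
#' centre.
#'
#' @param frame `detector_frame` or numeric matrix.
#' @param fraction Fraction of pixels to average over, in (0, 1].
#' @return A `beam_center_estimate` (see [center_gaussian_max()]).
#' @export
center_top_percentile <- function(frame, fraction = 0.05) {
  px <- frame_pixels(frame)
  if (length(px) == 0) stop("empty frame")
  if (fraction <= 0 || fraction > 1) stop("`fraction` must be in (0, 1]")
  n <- ceiling(fraction * length(px))
  k <- length(px) - n + 1L   # n-th largest via partial selection
  thr <- sort(px, partial = k)[k]
  sel <- which(px >= thr)   # every pixel tied at the threshold is included
  rows <- (sel - 1L) %% nrow(px) + 1L
  cols <- (sel - 1L) %/% nrow(px) + 1L
  .bc_estimate(c(mean(cols), mean(rows)), "top_percentile",
               if (inherits(frame, "detector_frame")) frame$frame_index else NA_integer_)
}

.bc_estimate <- function(position, method, frame_index) {
  structure(list(position = as.numeric(position), method = method,
                 frame_index = frame_index),
            class = "beam_center_estimate")
}

#' @export
print.beam_center_estimate <- function(x, ...) {
  cat(sprintf("Beam centre (%s): x = %.2f, y = %.2f px\n",
              x$method, x$position[1], x$position[2]))
  invisible(x)
}

#' Median beam centre over a series of frames
#'
#' Component-wise median of per-frame estimates; with an even number of
#' frames the average of the two middle values is used. Robust to fewer
#' than half the frames being outliers.
#'
#' @param estimates List of `beam_center_estimate` objects, or a
#'   two-column matrix of positions.
#' @return Numeric `(x, y)` pair.
#' @export
median_center <- function(estimates) {
  if (is.list(estimates) && !is.data.frame(estimates))
    pos <- do.call(rbind, lapply(estimates, function(e)
      if (inherits(e, "beam_center_estimate")) e$position else as.numeric(e)))
  else pos <- as.matrix(estimates)
  if (is.null(pos) || nrow(pos) == 0) stop("no estimates supplied")
  c(x = stats::median(pos[, 1]), y = stats::median(pos[, 2]))
}

#' Tabulate beam-centre estimates
#'
#' @param estimates List of `beam_center_estimate` objects.
#' @return `data.frame` with columns `frame_index`, `x`, `y`, `method`.
#' @export
beam_center_table <- function(estimates) {
  data.frame(
    frame_index = vapply(estimates, function(e) as.integer(e$frame_index), integer(1)),
    x = vapply(estimates, function(e) e$position[1], numeric(1)),
    y = vapply(estimates, function(e) e$position[2], numeric(1)),
    method = vapply(estimates, function(e) e$method, character(1)),
    stringsAsFactors = FALSE
  )
}
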