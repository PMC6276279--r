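# Timepix detector-frame model and geometry corrections.
#
# The Timepix detector is a 2x2 tiling of 256x256 modules. The single row
# and column of pixels at each module boundary are physically three times
# wider (165 um vs 55 um), so a raw 512x512 readout must be expanded to a
# 516x516 logical grid of uniform 55 um pixels before integration software
# can use it.

RAW_SIZE <- 512L
CORRECTED_SIZE <- 516L
# 0-based raw indices of the wide boundary pixels in each dimension
.BIG_PIXELS_RAW <- c(255L, 256L)

#' Detector frame
#'
#' A single 2-D diffraction (or defocused tracking) frame together with
#' its geometry state and per-frame acquisition metadata. Geometry is
#' inferred from the array shape: 512x512 is `raw512`, 516x516 is
#' `corrected516`.
#'
#' @param pixels Numeric matrix of non-negative counts, 512x512 or 516x516.
#' @param kind `"data"` or `"defocus_tracking"`.
#' @param frame_index 1-based frame number within the acquisition.
#' @param timestamp Acquisition time, s (relative to run start).
#' @param exposure Exposure time, s.
#' @return A `detector_frame` object.
#' @export
detector_frame <- function(pixels, kind = c("data", "defocus_tracking"),
                           frame_index = 1L, timestamp = NA_real_,
                           exposure = NA_real_) {
  kind <- match.arg(kind)
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  geom <- frame_geometry(pixels)
  if (any(pixels < 0)) stop("counts must be non-negative")
  structure(
    list(pixels = pixels, geometry = geom, kind = kind,
         frame_index = as.integer(frame_index),
         timestamp = timestamp, exposure = exposure),
    class = "detector_frame"
  )
}

frame_geometry <- function(pixels) {
  d <- dim(pixels)
  if (all(d == RAW_SIZE)) "raw512"
  else if (all(d == CORRECTED_SIZE)) "corrected516"
  else "generic"   # simulator/test frames of other sizes
}

#' @export
print.detector_frame <- function(x, ...) {
  cat(sprintf("Detector frame #%d (%s, %s): %dx%d, total counts %.6g\n",
              x$frame_index, x$kind, x$geometry,
              nrow(x$pixels), ncol(x$pixels), sum(x$pixels)))
  invisible(x)
}

# accept either a detector_frame or a bare matrix; return the matrix
frame_pixels <- function(frame) {
  if (inherits(frame, "detector_frame")) frame$pixels
  else if (is.matrix(frame)) frame
  else stop("expected a detector_frame or a matrix")
}

# Per-dimension expansion operator: 516x512 matrix whose columns sum to 1.
# Raw 0-based indices 255 and 256 each expand to three logical pixels with
# weight 1/3; all other raw pixels map one-to-one.
.expansion_operator <- local({
  E <- NULL
  function() {
    if (is.null(E)) {
      M <- matrix(0, CORRECTED_SIZE, RAW_SIZE)
      out <- 1L
      for (raw0 in 0:(RAW_SIZE - 1L)) {
        if (raw0 %in% .BIG_PIXELS_RAW) {
          M[out:(out + 2L), raw0 + 1L] <- 1 / 3
          out <- out + 3L
        } else {
          M[out, raw0 + 1L] <- 1
          out <- out + 1L
        }
      }
      stopifnot(out == CORRECTED_SIZE + 1L)
      E <<- M
    }
    E
  }
})

#' Expand a raw Timepix frame to the 516x516 logical grid
#'
#' Each of the two wide module-boundary pixels per dimension is expanded
#' into three logical 55 um pixels, splitting its counts equally (/3)
#' among them; corner pixels wide in both dimensions split /9 over a 3x3
#' block. The expansion conserves total counts exactly — the expanded
#' strips are masked for integration anyway (see
#' [cross_untrusted_rectangles()]), but conservation keeps quality-control
#' sums meaningful.
#'
#' @param frame A `detector_frame` in `raw512` geometry, or a bare 512x512
#'   matrix.
#' @return The same type as the input, in `corrected516` geometry.
#' @export
expand_timepix <- function(frame) {
  px <- frame_pixels(frame)
  if (!all(dim(px) == RAW_SIZE))
    stop("expand_timepix() requires a raw 512x512 frame")
  E <- .expansion_operator()
  out <- E %*% px %*% t(E)
  if (inherits(frame, "detector_frame")) {
    frame$pixels <- out
    frame$geometry <- "corrected516"
    frame
  } else out
}

#' Logical pixel indices covered by the expanded module cross
#'
#' The two wide raw pixels per dimension expand to logical 0-based
#' indices 255..260, a 6-pixel-wide strip across each axis.
#'
#' @return Integer vector of 0-based logical indices.
#' @export
cross_pixel_indices <- function() 255:260

#' Untrusted rectangles masking the Timepix module cross
#'
#' Returns the two strips covering the expanded module-boundary pixels in
#' the XDS `UNTRUSTED_RECTANGLE` convention: each rectangle is
#' `(x1, x2, y1, y2)` masking pixels with `x1 < x < x2` and `y1 < y < y2`
#' in 1-based pixel numbering (an open interval, so the masked interior
#' is `x1+1 .. x2-1`).
#'
#' @return List of two numeric vectors `c(x1, x2, y1, y2)`: the vertical
#'   strip (columns) then the horizontal strip (rows).
#' @export
cross_untrusted_rectangles <- function() {
  idx0 <- cross_pixel_indices()            # 0-based logical 255..260
  lo1 <- min(idx0) + 1L                    # 1-based first masked pixel: 256
  hi1 <- max(idx0) + 1L                    # 1-based last masked pixel: 261
  full <- c(0L, CORRECTED_SIZE + 1L)       # open interval covering 1..516
  list(
    c(x1 = lo1 - 1L, x2 = hi1 + 1L, y1 = full[1], y2 = full[2]),
    c(x1 = full[1], x2 = full[2], y1 = lo1 - 1L, y2 = hi1 + 1L)
  )
}

#' Logical mask of trusted pixels on the corrected grid
#'
#' @return 516x516 logical matrix, `FALSE` on the expanded module cross.
#' @export
cross_mask <- function() {
  m <- matrix(TRUE, CORRECTED_SIZE, CORRECTED_SIZE)
  idx <- cross_pixel_indices() + 1L
  m[idx, ] <- FALSE
  m[, idx] <- FALSE
  m
}

#' Flatfield response map
#'
#' Normalizes a per-pixel detector response so that its mean over live
#' (response > 0) pixels is 1. Pixels with non-positive response are
#' flagged dead.
#'
#' @param response Positive numeric matrix matching a frame geometry.
#' @return A `flat_field` object with fields `response` (normalized) and
#'   `dead` (logical matrix).
#' @export
flat_field <- function(response) {
  if (!is.matrix(response)) stop("`response` must be a matrix")
  dead <- !(response > 0) | !is.finite(response)
  if (all(dead)) stop("flatfield has no live pixels")
  norm <- response / mean(response[!dead])
  norm[dead] <- 0
  structure(list(response = norm, dead = dead), class = "flat_field")
}

#' Apply a flatfield correction to a frame
#'
#' Divides counts by the mean-normalized response; dead pixels
#' (response <= 0) are set to 0. With a uniform response the frame is
#' unchanged. Note the correction is not idempotent: applying the same
#' non-uniform field twice divides twice.
#'
#' @param frame `detector_frame` or matrix; geometry must match `ff`.
#' @param ff A [flat_field()] object (or raw response matrix).
#' @return Corrected frame of the same type as the input.
#' @export
apply_flatfield <- function(frame, ff) {
  if (!inherits(ff, "flat_field")) ff <- flat_field(ff)
  px <- frame_pixels(frame)
  if (!all(dim(px) == dim(ff$response)))
    stop("frame and flatfield dimensions differ")
  out <- px / ff$response
  out[ff$dead] <- 0
  if (inherits(frame, "detector_frame")) { frame$pixels <- out; frame }
  else out
}
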