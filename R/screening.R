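# SerialED crystal screening: diffraction-pattern preprocessing for the
# CNN, isolated-crystal selection, and the candidate CSV.

#' Cap intensities at mean + k standard deviations
#'
#' The central beam dwarfs the diffraction spots, so pixel values `z` are
#' clipped at `mu + n_sigma * sigma`, with the moments computed on the
#' image being capped.
#'
#' @param z Numeric matrix.
#' @param n_sigma Number of standard deviations above the mean (default 4).
#' @return Capped matrix.
#' @export
cap_intensity <- function(z, n_sigma = 4) {
  mu <- mean(z)
  sdev <- stats::sd(as.vector(z))
  if (!is.finite(sdev)) sdev <- 0
  pmin(z, mu + n_sigma * sdev)
}

#' Feature-scale an image to `[0, 1]`
#'
#' `(z - z_min) / (z_max - z_min)`; if the largest and smallest values are
#' identical (no contrast) every value is set to zero.
#'
#' @param z Numeric matrix.
#' @return Matrix with values in `[0, 1]`.
#' @export
feature_scale <- function(z) {
  zmin <- min(z); zmax <- max(z)
  if (zmax == zmin) return(array(0, dim = dim(z)))
  (z - zmin) / (zmax - zmin)
}

#' Crop a window centred on the primary beam
#'
#' Extracts a `size x size` window centred on the (rounded) beam
#' position; parts of the window falling outside the pattern are
#' zero-padded, so the beam stays at the window centre even near frame
#' borders.
#'
#' @param z Numeric matrix.
#' @param center `(x, y)` beam position, 1-based pixels.
#' @param size Window side, pixels (default 400).
#' @return `size x size` matrix.
#' @export
crop_about_beam <- function(z, center, size = 400L) {
  size <- as.integer(size)
  cx <- as.integer(round(center[1])); cy <- as.integer(round(center[2]))
  half <- size %/% 2L
  rows <- (cy - half):(cy + half - 1L + size %% 2L)
  cols <- (cx - half):(cx + half - 1L + size %% 2L)
  out <- matrix(0, size, size)
  rok <- rows >= 1L & rows <= nrow(z)
  cok <- cols >= 1L & cols <= ncol(z)
  out[which(rok), which(cok)] <- z[rows[rok], cols[cok]]
  out
}

#' Preprocess a diffraction pattern for the CNN
#'
#' The screening pipeline: locate the primary beam as the centroid of the
#' top 5% brightest pixels, crop 400x400 pixels around it (zero-padding
#' outside the frame), cap intensities at the crop's mean plus four
#' standard deviations, feature-scale to `[0, 1]` (all zeros if the image
#' has no contrast), and shrink to 150x150 by area averaging.
#'
#' @param pattern Numeric matrix of counts (a still diffraction pattern).
#' @param crop_size Window side around the beam, px.
#' @param out_size Final image side, px.
#' @param cap_nsigma Capping threshold in standard deviations.
#' @param beam_fraction Top-pixel fraction for beam location.
#' @return `out_size x out_size` matrix with values in `[0, 1]`, with
#'   attribute `"beam_center"` holding the located beam position.
#' @export
preprocess_pattern <- function(pattern, crop_size = 400L, out_size = 150L,
                               cap_nsigma = 4, beam_fraction = 0.05) {
  if (length(pattern) == 0) stop("empty pattern")
  pattern <- frame_pixels(pattern)
  bc <- center_top_percentile(pattern, beam_fraction)
  z <- crop_about_beam(pattern, bc$position, crop_size)
  z <- cap_intensity(z, cap_nsigma)
  z <- feature_scale(z)
  z <- resize_area(z, c(out_size, out_size))
  # area averaging of a [0,1] image stays in [0,1]; clamp rounding dust
  z[z < 0] <- 0; z[z > 1] <- 1
  attr(z, "beam_center") <- bc$position
  z
}

#' Select isolated crystals
#'
#' Keeps crystals at least `neighbor_min` from every other crystal
#' (both members of a too-close pair are discarded) and at least
#' `edge_min` from every edge of the image frame.
#'
#' @param positions Two-column matrix/data.frame of crystal `(x, y)`
#'   stage positions, um.
#' @param frame Frame rectangle `c(xmin, xmax, ymin, ymax)`, um.
#' @param neighbor_min Minimum nearest-neighbour distance, um.
#' @param edge_min Minimum distance to any frame edge, um.
#' @return Logical vector: `TRUE` for kept crystals.
#' @export
isolation_filter <- function(positions, frame,
                             neighbor_min = 1.5, edge_min = 0.5) {
  pos <- as.matrix(positions)
  n <- nrow(pos)
  if (is.null(n) || n == 0L) return(logical(0))
  if (any(!is.finite(pos))) stop("crystal positions must be finite")
  keep_edge <- pos[, 1] - frame[1] >= edge_min &
    frame[2] - pos[, 1] >= edge_min &
    pos[, 2] - frame[3] >= edge_min &
    frame[4] - pos[, 2] >= edge_min
  keep_edge <- unname(keep_edge)
  if (n == 1L) return(keep_edge)
  dm <- as.matrix(stats::dist(pos))
  diag(dm) <- Inf
  keep_nn <- unname(apply(dm, 1, min) >= neighbor_min)
  keep_edge & keep_nn
}

#' Crystal candidate table
#'
#' @param image_path Path of the low-magnification image the crystal was
#'   found on.
#' @param image_seq,crystal_seq Sequence numbers of image and crystal.
#' @param score CNN prediction score in `[0, 1]`.
#' @param object_size Crystal size, um.
#' @param stage_x,stage_y Sample-stage coordinates, um.
#' @return `data.frame` of class `crystal_candidates` with the columns in
#'   the canonical CSV order.
#' @export
crystal_candidates <- function(image_path, image_seq, crystal_seq, score,
                               object_size, stage_x, stage_y) {
  if (any(score < 0 | score > 1)) stop("scores must lie in [0, 1]")
  out <- data.frame(
    image_path = as.character(image_path),
    image_seq = as.integer(image_seq),
    crystal_seq = as.integer(crystal_seq),
    score = as.numeric(score),
    object_size = as.numeric(object_size),
    stage_x = as.numeric(stage_x),
    stage_y = as.numeric(stage_y),
    stringsAsFactors = FALSE
  )
  class(out) <- c("crystal_candidates", "data.frame")
  out
}

#' Write the candidate CSV
#'
#' One row per candidate crystal, columns in the order `image_path,
#' image_seq, crystal_seq, score, object_size, stage_x, stage_y`.
#' Scores are written with 4 decimals; stage coordinates and sizes keep
#' full precision so the file round-trips through [read_candidates()].
#'
#' @param candidates A [crystal_candidates()] data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(candidates, path) {
  cols <- c("image_path", "image_seq", "crystal_seq", "score",
            "object_size", "stage_x", "stage_y")
  stopifnot(all(cols %in% names(candidates)))
  out <- candidates[, cols]
  num <- function(x) vapply(x, function(v)
    format(v, digits = 15, trim = TRUE, scientific = FALSE), character(1))
  lines <- c(paste(cols, collapse = ","),
             sprintf("%s,%d,%d,%.4f,%s,%s,%s",
                     out$image_path, out$image_seq, out$crystal_seq,
                     out$score, num(out$object_size), num(out$stage_x),
                     num(out$stage_y)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a candidate CSV back
#'
#' @param path File written by [write_candidates()].
#' @return A [crystal_candidates()] data.frame.
#' @export
read_candidates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  crystal_candidates(df$image_path, df$image_seq, df$crystal_seq,
                     df$score, df$object_size, df$stage_x, df$stage_y)
}
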