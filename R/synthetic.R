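# Ground-truth simulator: rotating-crystal frame series, screening
# pattern classes and SerialED crystal-field maps. Everything is seeded
# and emits a truth record, so the other modules can be tested without a
# microscope.
#
# The diffraction model is kinematic: reciprocal-lattice points within an
# excitation tolerance of the Ewald sphere at the slot's angular midpoint
# are projected to the detector with the small-angle relation
# r = L * lambda / d (valid to better than a percent at electron
# wavelengths) and rendered as Gaussian spots with Poisson counting
# noise. Crystal drift attenuates the diffracted (not the primary) beam
# through the overlap of the crystal with the selected-area aperture.

#' Reciprocal-space basis matrix of a unit cell
#'
#' Columns are the reciprocal basis vectors a*, b*, c* (1/Angstrom) in a
#' Cartesian frame with a along x and b in the xy plane.
#'
#' @param cell Numeric vector `(a, b, c, alpha, beta, gamma)`, Angstrom
#'   and degrees.
#' @return 3x3 matrix `B` such that `s = B %*% hkl`.
#' @export
cell_bmatrix <- function(cell) {
  a <- cell[1]; b <- cell[2]; c <- cell[3]
  al <- cell[4] * pi / 180; be <- cell[5] * pi / 180; ga <- cell[6] * pi / 180
  av <- c(a, 0, 0)
  bv <- c(b * cos(ga), b * sin(ga), 0)
  cx <- c * cos(be)
  cy <- c * (cos(al) - cos(be) * cos(ga)) / sin(ga)
  cz <- sqrt(c^2 - cx^2 - cy^2)
  cv <- c(cx, cy, cz)
  A <- cbind(av, bv, cv)
  V <- det(A)
  B <- cbind(crossv(bv, cv), crossv(cv, av), crossv(av, bv)) / V
  B
}

crossv <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                           u[3] * v[1] - u[1] * v[3],
                           u[1] * v[2] - u[2] * v[1])

# rotation matrix about a unit axis by theta (radians), Rodrigues form
rotation_about <- function(axis, theta) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Describe a synthetic rotating-crystal experiment
#'
#' Ground-truth description consumed by [simulate_rotation_series()].
#' Defaults describe a small-cell inorganic crystal on a 200 kV
#' instrument with a 55 um-pitch hybrid pixel detector.
#'
#' @param cell Unit cell `(a, b, c, alpha, beta, gamma)`.
#' @param orientation 3x3 orientation matrix (default: identity).
#' @param rotation_axis In-plane goniometer axis (default x).
#' @param voltage Accelerating voltage, kV.
#' @param camera_length Effective camera length, mm.
#' @param pixel_pitch Detector pixel pitch, um.
#' @param d_min Resolution cutoff for generated reflections, Angstrom.
#' @param excitation_tol Excitation-error tolerance, 1/Angstrom.
#' @param beam_center True beam centre `(x, y)`, pixels.
#' @param beam_counts Peak counts of the primary-beam blob.
#' @param spot_peak Nominal peak counts of a full spot.
#' @param spot_sigma Spot width, px.
#' @param background Flat instrument background level, counts per pixel
#'   (independent of the crystal).
#' @param diffuse Diffuse crystal scatter level, counts per pixel: the
#'   inelastic/amorphous halo a real crystal adds, which scales with the
#'   illuminated crystal volume and therefore with the aperture-overlap
#'   attenuation. This is what makes the per-frame intensity scale a
#'   usable tracking diagnostic.
#' @param b_iso Overall displacement damping (Angstrom^2) applied as
#'   `exp(-b_iso * |s|^2)`.
#' @param aperture_radius Selected-area aperture radius, um (0.75 and
#'   0.35 are the usual first/second apertures).
#' @param crystal_radius Crystal radius, um.
#' @param drift Per-slot crystal offset, um: a function `(slot index) ->
#'   c(dx, dy)`, an n x 2 matrix, or `NULL` for no drift.
#' @param seed Integer seed for the Poisson noise.
#' @return A `synthetic_experiment` object.
#' @export
synthetic_experiment <- function(cell = c(10, 10, 10, 90, 90, 90),
                                 orientation = diag(3),
                                 rotation_axis = c(1, 0, 0),
                                 voltage = 200, camera_length = 250,
                                 pixel_pitch = 55, d_min = 1.0,
                                 excitation_tol = 0.002,
                                 beam_center = c(258, 258),
                                 beam_counts = 5000, spot_peak = 400,
                                 spot_sigma = 1.5, background = 0.5,
                                 diffuse = 2, b_iso = 2,
                                 aperture_radius = 0.75,
                                 crystal_radius = 0.25, drift = NULL,
                                 seed = 1L) {
  structure(
    list(cell = cell, orientation = orientation,
         rotation_axis = rotation_axis, voltage = voltage,
         wavelength = electron_wavelength(voltage),
         camera_length = camera_length, pixel_pitch = pixel_pitch,
         d_min = d_min, excitation_tol = excitation_tol,
         beam_center = as.numeric(beam_center), beam_counts = beam_counts,
         spot_peak = spot_peak, spot_sigma = spot_sigma,
         background = background, diffuse = diffuse, b_iso = b_iso,
         aperture_radius = aperture_radius, crystal_radius = crystal_radius,
         drift = drift, seed = as.integer(seed)),
    class = "synthetic_experiment"
  )
}

.drift_offset <- function(exp, slot) {
  d <- exp$drift
  if (is.null(d)) return(c(0, 0))
  if (is.function(d)) return(as.numeric(d(slot)))
  as.numeric(d[slot, ])
}

# additive Gaussian blob on a local window of lambda map
.add_blob <- function(img, x0, y0, amp, sigma) {
  n <- nrow(img); m <- ncol(img)
  r <- ceiling(4 * sigma)
  xlo <- max(1, floor(x0 - r)); xhi <- min(m, ceiling(x0 + r))
  ylo <- max(1, floor(y0 - r)); yhi <- min(n, ceiling(y0 + r))
  if (xlo > xhi || ylo > yhi) return(img)   # blob entirely off-frame
  xs <- xlo:xhi
  ys <- ylo:yhi
  gx <- exp(-((xs - x0)^2) / (2 * sigma^2))
  gy <- exp(-((ys - y0)^2) / (2 * sigma^2))
  img[ys, xs] <- img[ys, xs] + amp * (gy %o% gx)
  img
}

#' Simulate a cRED rotation series
#'
#' Renders one frame per schedule slot. Data slots get the diffraction
#' pattern excited at the slot's angular midpoint; defocus-tracking slots
#' get a crystal-silhouette image at the drifted position. Alongside the
#' frames a truth record is returned with the per-frame spot lists
#' (hkl, position, intensity) and aperture-overlap attenuation factors.
#'
#' @param exp A [synthetic_experiment()].
#' @param schedule An [build_schedule()] result.
#' @param size Frame side, pixels (default 516, corrected geometry).
#' @return List with `frames` (list of [detector_frame()]) and `truth`
#'   (list: `beam_center`, `attenuation` per slot, `spots` per slot,
#'   `experiment`, `schedule` parameters).
#' @export
simulate_rotation_series <- function(exp, schedule, size = 516L) {
  stopifnot(inherits(exp, "synthetic_experiment"),
            inherits(schedule, "acquisition_schedule"))
  set.seed(exp$seed)
  B <- cell_bmatrix(exp$cell)
  UB <- exp$orientation %*% B
  hmax <- ceiling(max(exp$cell[1:3]) / exp$d_min)
  H <- as.matrix(expand.grid(h = -hmax:hmax, k = -hmax:hmax, l = -hmax:hmax))
  H <- H[rowSums(H^2) > 0, , drop = FALSE]
  S0 <- UB %*% t(H)                       # 3 x nrefl at zero rotation
  slen0 <- sqrt(colSums(S0^2))
  keep <- slen0 <= 1 / exp$d_min
  H <- H[keep, , drop = FALSE]; S0 <- S0[, keep, drop = FALSE]
  if (ncol(S0) == 0)
    warning("no reciprocal-lattice points within the resolution limit; frames will be blank")
  kmag <- 1 / exp$wavelength
  px_per_mm <- 1000 / exp$pixel_pitch
  slots <- schedule$slots
  frames <- vector("list", nrow(slots))
  spots <- vector("list", nrow(slots))
  attenuation <- rep(NA_real_, nrow(slots))
  for (i in seq_len(nrow(slots))) {
    off <- .drift_offset(exp, i)
    att <- disc_overlap_fraction(sqrt(sum(off^2)), exp$crystal_radius,
                                 exp$aperture_radius)
    attenuation[i] <- att
    if (slots$kind[i] == "defocus_tracking") {
      frames[[i]] <- .render_silhouette(exp, off, size, slots, i)
      next
    }
    theta <- (slots$angle_start[i] + slots$angle_end[i]) / 2 * pi / 180
    R <- rotation_about(exp$rotation_axis, theta)
    S <- R %*% S0
    zeta <- kmag - sqrt(S[1, ]^2 + S[2, ]^2 + (S[3, ] + kmag)^2)
    sel <- which(abs(zeta) < exp$excitation_tol)
    lam <- matrix(exp$background + exp$diffuse * att, size, size)
    slist <- NULL
    if (length(sel) > 0) {
      sx <- S[1, sel]; sy <- S[2, sel]
      slen <- sqrt(colSums(S[, sel, drop = FALSE]^2))
      xpix <- exp$beam_center[1] + exp$camera_length * exp$wavelength * sx * px_per_mm
      ypix <- exp$beam_center[2] + exp$camera_length * exp$wavelength * sy * px_per_mm
      part <- 1 - abs(zeta[sel]) / exp$excitation_tol
      inten <- exp$spot_peak * exp(-exp$b_iso * slen^2) * part * att
      ok <- xpix > 1 & xpix < size & ypix > 1 & ypix < size & inten > 0
      for (j in which(ok))
        lam <- .add_blob(lam, xpix[j], ypix[j], inten[j], exp$spot_sigma)
      slist <- data.frame(h = H[sel, 1][ok], k = H[sel, 2][ok],
                          l = H[sel, 3][ok], x = xpix[ok], y = ypix[ok],
                          intensity = inten[ok])
    }
    lam <- .add_blob(lam, exp$beam_center[1], exp$beam_center[2],
                     exp$beam_counts, 3)
    counts <- matrix(stats::rpois(size * size, lam), size, size)
    frames[[i]] <- detector_frame(counts, kind = "data", frame_index = i,
                                  timestamp = slots$time_start[i],
                                  exposure = schedule$exposure)
    spots[[i]] <- slist
  }
  list(
    frames = frames,
    truth = list(
      beam_center = exp$beam_center,
      attenuation = attenuation,
      spots = spots,
      experiment = exp,
      n_slots = nrow(slots)
    )
  )
}

# defocused snapshot: bright illuminated disc with the crystal as a
# darker silhouette at the drifted position
.render_silhouette <- function(exp, off, size, slots, i,
                               px_per_um = 40, bg = 100) {
  lam <- matrix(1, size, size)
  cx <- exp$beam_center[1]; cy <- exp$beam_center[2]
  xs <- seq_len(size); ys <- seq_len(size)
  rr_ap <- exp$aperture_radius * px_per_um * 6   # illuminated field
  d2 <- outer((ys - cy)^2, (xs - cx)^2, "+")
  lam[d2 <= rr_ap^2] <- bg
  ccx <- cx + off[1] * px_per_um
  ccy <- cy + off[2] * px_per_um
  rr_cr <- exp$crystal_radius * px_per_um
  d2c <- outer((ys - ccy)^2, (xs - ccx)^2, "+")
  lam[d2c <= rr_cr^2] <- bg * 0.25
  counts <- matrix(stats::rpois(size * size, lam), size, size)
  detector_frame(counts, kind = "defocus_tracking", frame_index = i,
                 timestamp = slots$time_start[i], exposure = 0.01)
}

#' Generate labelled screening-pattern classes
#'
#' Produces class-separable synthetic still patterns: `spots` (sparse
#' sharp Bragg spots — the "good" class), `rings` (azimuthally uniform
#' powder annuli, emulating computer-generated powder rings), `blank`
#' (primary beam and noise only) and `diffuse` (broad amorphous blobs).
#' All classes share a bright primary-beam blob and Poisson counting
#' noise. Deterministic for a fixed seed.
#'
#' @param n_per_class Images per class.
#' @param classes Subset of `c("spots", "rings", "blank", "diffuse")`.
#' @param seed Integer seed.
#' @param size Raw pattern side, pixels (default 516).
#' @param good_classes Classes labelled 1 ("good"); by default only
#'   `spots` — powder rings are treated as a bad-class option.
#' @param preprocess If `TRUE`, each raw pattern is run through
#'   [preprocess_pattern()] and the 150x150 result is returned instead.
#' @return List with `images` (3-D array, `size x size x n` or
#'   `150 x 150 x n`), `labels` (0/1) and `class` (character).
#' @export
simulate_pattern_classes <- function(n_per_class,
                                     classes = c("spots", "rings", "blank",
                                                 "diffuse"),
                                     seed = 1L, size = 516L,
                                     good_classes = "spots",
                                     preprocess = FALSE) {
  known <- c("spots", "rings", "blank", "diffuse")
  if (!all(classes %in% known))
    stop("unknown class: ", paste(setdiff(classes, known), collapse = ", "))
  set.seed(as.integer(seed))
  n_total <- n_per_class * length(classes)
  out_side <- if (preprocess) 150L else as.integer(size)
  images <- array(0, c(out_side, out_side, n_total))
  labels <- integer(n_total)
  cls <- character(n_total)
  k <- 0L
  for (cl in classes) {
    for (i in seq_len(n_per_class)) {
      k <- k + 1L
      img <- .render_pattern_class(cl, size)
      if (preprocess) img <- preprocess_pattern(img)
      images[, , k] <- img
      labels[k] <- as.integer(cl %in% good_classes)
      cls[k] <- cl
    }
  }
  list(images = images, labels = labels, class = cls)
}

.render_pattern_class <- function(class, size) {
  cx <- size / 2 + stats::runif(1, -4, 4)
  cy <- size / 2 + stats::runif(1, -4, 4)
  lam <- matrix(1, size, size)
  rmax <- size / 2 - 30
  if (class == "spots") {
    n_spots <- 8L + stats::rpois(1, 20)
    rad <- sqrt(stats::runif(n_spots)) * (rmax - 30) + 30
    ang <- stats::runif(n_spots, 0, 2 * pi)
    amp <- stats::rgamma(n_spots, shape = 2, scale = 200)
    sig <- stats::runif(n_spots, 1.2, 2.5)
    for (j in seq_len(n_spots))
      lam <- .add_blob(lam, cx + rad[j] * cos(ang[j]),
                       cy + rad[j] * sin(ang[j]), amp[j], sig[j])
  } else if (class == "rings") {
    n_rings <- sample(2:4, 1)
    r0 <- stats::runif(n_rings, 40, rmax)
    amp <- stats::runif(n_rings, 60, 200)
    sg <- stats::runif(n_rings, 1.5, 3)
    xs <- seq_len(size); ys <- seq_len(size)
    rr <- sqrt(outer((ys - cy)^2, (xs - cx)^2, "+"))
    for (j in seq_len(n_rings)) {
      # annulus support only: the Gaussian profile is negligible beyond 5 sigma
      band <- which(abs(rr - r0[j]) < 5 * sg[j])
      lam[band] <- lam[band] + amp[j] * exp(-(rr[band] - r0[j])^2 / (2 * sg[j]^2))
    }
  } else if (class == "diffuse") {
    n_blobs <- sample(3:6, 1)
    for (j in seq_len(n_blobs))
      lam <- .add_blob(lam, stats::runif(1, 60, size - 60),
                       stats::runif(1, 60, size - 60),
                       stats::runif(1, 30, 120), stats::runif(1, 12, 30))
  }
  # all classes: primary beam
  lam <- .add_blob(lam, cx, cy, stats::runif(1, 3000, 6000), 3)
  matrix(stats::rpois(size * size, lam), size, size)
}

#' Generate a SerialED crystal field
#'
#' Uniform crystal positions over a square stage area with lognormal
#' sizes; a configurable number of close pairs is planted below the
#' isolation distance to exercise the selection filter.
#'
#' @param area Side of the surveyed stage area, um (default 200, the
#'   usual screening raster).
#' @param n_crystals Number of isolated-candidate crystals to draw.
#' @param seed Integer seed.
#' @param n_pairs Number of planted too-close pairs.
#' @param pair_distance Separation of planted pairs, um (below the
#'   1.5 um isolation rule by default).
#' @return `data.frame` with columns `x`, `y`, `size`, `planted_pair`,
#'   plus attribute `frame = c(0, area, 0, area)`.
#' @export
simulate_crystal_field <- function(area = 200, n_crystals = 100, seed = 1L,
                                   n_pairs = 2L, pair_distance = 1.0) {
  set.seed(as.integer(seed))
  if (n_crystals == 0L && n_pairs == 0L) {
    out <- data.frame(x = numeric(0), y = numeric(0), size = numeric(0),
                      planted_pair = logical(0))
    attr(out, "frame") <- c(0, area, 0, area)
    return(out)
  }
  x <- stats::runif(n_crystals, 0, area)
  y <- stats::runif(n_crystals, 0, area)
  planted <- rep(FALSE, n_crystals)
  for (p in seq_len(n_pairs)) {
    bx <- stats::runif(1, 5, area - 5); by <- stats::runif(1, 5, area - 5)
    th <- stats::runif(1, 0, 2 * pi)
    x <- c(x, bx, bx + pair_distance * cos(th))
    y <- c(y, by, by + pair_distance * sin(th))
    planted <- c(planted, TRUE, TRUE)
  }
  out <- data.frame(
    x = x, y = y,
    size = stats::rlnorm(length(x), meanlog = log(0.5), sdlog = 0.4),
    planted_pair = planted
  )
  attr(out, "frame") <- c(0, area, 0, area)
  out
}
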