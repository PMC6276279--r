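# Elliptical lens-distortion model: fitting, point mapping and the
# per-pixel correction tables consumed by integration software.
#
# The post-specimen lenses map a true circle of diffraction spots into an
# ellipse; the model is the affine stretch that undoes this. It is
# parameterized by the eccentricity e = sqrt(1 - (b/a)^2) of the observed
# ellipse, the azimuth of its major axis, and its centre.

#' Construct an elliptical distortion model
#'
#' @param eccentricity Eccentricity `e` in `[0, 1)` of the ellipse into
#'   which the distortion maps a true circle; `e = 0` is the identity.
#' @param azimuth Orientation of the ellipse major axis, degrees.
#' @param center Centre of the distortion `(x, y)`, pixels.
#' @return A `distortion_model` object.
#' @export
distortion_model <- function(eccentricity = 0, azimuth = 0,
                             center = c(258, 258)) {
  if (eccentricity < 0 || eccentricity >= 1)
    stop("`eccentricity` must lie in [0, 1)")
  structure(
    list(eccentricity = eccentricity, azimuth = azimuth,
         center = as.numeric(center),
         axis_ratio = sqrt(1 - eccentricity^2)),  # b/a
    class = "distortion_model"
  )
}

#' @export
print.distortion_model <- function(x, ...) {
  cat(sprintf(
    "Elliptical distortion: e = %.4f (b/a = %.4f), azimuth %.2f deg, centre (%.2f, %.2f)\n",
    x$eccentricity, x$axis_ratio, x$azimuth, x$center[1], x$center[2]))
  invisible(x)
}

#' Fit an elliptical distortion model to ring points
#'
#' Direct least-squares ellipse fit (stable Halir--Flusser formulation of
#' the Fitzgibbon method) to point positions sampled on a distorted
#' powder ring or spot circle. Noiseless points on a true ellipse are
#' recovered to better than 1e-3 in eccentricity.
#'
#' @param points Two-column matrix (or data.frame) of `(x, y)` positions.
#' @return A [distortion_model()] with additional fields `semi_major`,
#'   `semi_minor` (pixels) and `n_points`.
#' @export
fit_elliptical_distortion <- function(points) {
  pts <- as.matrix(points)
  if (ncol(pts) != 2) stop("`points` must have two columns (x, y)")
  pts <- pts[stats::complete.cases(pts), , drop = FALSE]
  if (nrow(pts) < 5) stop("ellipse fit needs at least 5 points")
  x <- pts[, 1]; y <- pts[, 2]
  # centre/scale for conditioning
  mx <- mean(x); my <- mean(y)
  s <- max(stats::sd(x), stats::sd(y))
  if (!is.finite(s) || s == 0) stop("degenerate point set: no spatial extent")
  xs <- (x - mx) / s; ys <- (y - my) / s
  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  T1 <- tryCatch(-solve(S3, t(S2)), error = function(e)
    stop("ellipse fit failed: degenerate (collinear?) points"))
  M <- S1 + S2 %*% T1
  # apply inverse constraint matrix C1^-1 (constraint 4ac - b^2 = 1)
  M2 <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M2)
  V <- Re(ev$vectors)
  cond <- 4 * V[1, ] * V[3, ] - V[2, ]^2
  ok <- which(cond > 0)
  if (length(ok) == 0) stop("ellipse fit failed: no elliptical solution")
  a1 <- V[, ok[1]]
  conic_s <- c(a1, as.vector(T1 %*% a1))    # A B C D E F in scaled coords
  # undo the conditioning transform: substitute xs = (x-mx)/s etc.
  A <- conic_s[1] / s^2
  B <- conic_s[2] / s^2
  C <- conic_s[3] / s^2
  D <- conic_s[4] / s - (2 * conic_s[1] * mx + conic_s[2] * my) / s^2
  E <- conic_s[5] / s - (2 * conic_s[3] * my + conic_s[2] * mx) / s^2
  F <- conic_s[6] - (conic_s[4] * mx + conic_s[5] * my) / s +
    (conic_s[1] * mx^2 + conic_s[2] * mx * my + conic_s[3] * my^2) / s^2
  # geometric parameters from the conic
  den <- B^2 - 4 * A * C
  if (den >= 0) stop("ellipse fit failed: conic is not an ellipse")
  x0 <- (2 * C * D - B * E) / den
  y0 <- (2 * A * E - B * D) / den
  Q <- matrix(c(A, B / 2, B / 2, C), 2)
  if (A + C < 0) { Q <- -Q; A <- -A; B <- -B; C <- -C; D <- -D; E <- -E; F <- -F }
  g <- A * x0^2 + B * x0 * y0 + C * y0^2 + D * x0 + E * y0 + F   # conic at centre, < 0
  eg <- eigen(Q, symmetric = TRUE)
  if (any(eg$values <= 0) || g >= 0) stop("ellipse fit failed: degenerate conic")
  semi <- sqrt(-g / eg$values)              # descending eigenvalue -> minor first
  semi_major <- max(semi); semi_minor <- min(semi)
  vmaj <- eg$vectors[, which.min(eg$values)]
  azimuth <- atan2(vmaj[2], vmaj[1]) * 180 / pi
  azimuth <- azimuth %% 180
  e <- sqrt(max(0, 1 - (semi_minor / semi_major)^2))
  if (e < 1e-8) azimuth <- 0               # circle: orientation undefined
  m <- distortion_model(eccentricity = e, azimuth = azimuth,
                        center = c(x0, y0))
  m$semi_major <- semi_major
  m$semi_minor <- semi_minor
  m$n_points <- nrow(pts)
  m
}

# rotate (x,y) decomposition helpers: returns list(u = major unit, v = minor unit)
.axes_of <- function(model) {
  phi <- model$azimuth * pi / 180
  list(u = c(cos(phi), sin(phi)), v = c(-sin(phi), cos(phi)))
}

#' Apply the forward distortion to ideal points
#'
#' Maps undistorted positions to what the detector observes: the
#' component along the ellipse minor axis is compressed by `b/a`.
#'
#' @param model A [distortion_model()].
#' @param points Two-column matrix of `(x, y)` positions.
#' @return Matrix of distorted positions.
#' @export
distort_points <- function(model, points) {
  .map_points(model, points, model$axis_ratio)
}

#' Undo the distortion on observed points
#'
#' Maps observed (distorted) positions to corrected positions by
#' stretching the minor-axis component by `a/b`. Exact inverse of
#' [distort_points()].
#'
#' @inheritParams distort_points
#' @return Matrix of corrected positions.
#' @export
correct_points <- function(model, points) {
  .map_points(model, points, 1 / model$axis_ratio)
}

.map_points <- function(model, points, minor_scale) {
  pts <- as.matrix(points)
  ax <- .axes_of(model)
  dc <- sweep(pts, 2, model$center)
  xi <- dc %*% ax$u
  eta <- dc %*% ax$v
  out <- cbind(model$center[1] + xi * ax$u[1] + minor_scale * eta * ax$v[1],
               model$center[2] + xi * ax$u[2] + minor_scale * eta * ax$v[2])
  colnames(out) <- c("x", "y")
  out
}

#' Per-pixel geometric correction tables (GEO_CORR convention)
#'
#' Builds the x- and y-offset tables XDS consumes through the
#' `X-GEO_CORR`/`Y-GEO_CORR` instructions: for every pixel of the
#' corrected grid, the displacement from the observed (distorted)
#' position to the corrected position, in integer hundredths of a pixel.
#' An identity model (`e = 0`) yields all-zero tables.
#'
#' @param model A [distortion_model()].
#' @param shape Integer pair, detector size in pixels (default 516x516).
#' @return List with integer matrices `x` and `y` (offsets x 100,
#'   `[row, col]` layout; `x` offsets act on the column coordinate).
#' @export
geo_corr_tables <- function(model, shape = c(516L, 516L)) {
  shape <- as.integer(shape)
  xs <- seq_len(shape[2]); ys <- seq_len(shape[1])
  grid <- cbind(x = rep(xs, each = shape[1]), y = rep(ys, times = shape[2]))
  corr <- correct_points(model, grid)
  dx <- matrix(corr[, 1] - grid[, 1], shape[1], shape[2])
  dy <- matrix(corr[, 2] - grid[, 2], shape[1], shape[2])
  list(x = matrix(as.integer(round(100 * dx)), shape[1], shape[2]),
       y = matrix(as.integer(round(100 * dy)), shape[1], shape[2]))
}
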