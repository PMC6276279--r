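# Shared numerical helpers (image smoothing, resizing, run-length utilities).

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Gaussian smoothing with reflective borders
#'
#' Separable Gaussian convolution of a matrix. Borders are handled by
#' reflect padding so the smoothed maximum of a near-border feature is
#' not pulled inwards. Kernel is truncated at 4 standard deviations.
#'
#' @param x Numeric matrix.
#' @param sigma Standard deviation of the kernel, pixels.
#' @return Smoothed matrix of the same dimensions.
#' @export
gaussian_smooth <- function(x, sigma) {
  if (!is.matrix(x)) stop("`x` must be a matrix")
  if (sigma <= 0) stop("`sigma` must be positive")
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  n <- nrow(x); m <- ncol(x)
  # reflect-pad index vector for a dimension of length len
  pad_idx <- function(len) {
    idx <- c(rev(seq_len(min(r, len))), seq_len(len),
             len + 1 - rev(seq_len(min(r, len))))
    if (r > len) { # pathological small images: recycle reflection
      while (length(idx) < len + 2 * r) idx <- c(idx[1], idx, idx[length(idx)])
    }
    idx
  }
  # smooth along rows (dimension 1) via band-operator matrix product
  op <- function(len) {
    idx <- pad_idx(len)
    A <- matrix(0, len, length(idx))
    for (j in seq_along(k)) {
      rows <- seq_len(len)
      A[cbind(rows, rows + j - 1L)] <- A[cbind(rows, rows + j - 1L)] + k[j]
    }
    list(A = A, idx = idx)
  }
  o1 <- op(n)
  y <- o1$A %*% x[o1$idx, , drop = FALSE]
  o2 <- op(m)
  t(o2$A %*% t(y)[o2$idx, , drop = FALSE])
}

#' Area-average (local mean) image resize
#'
#' Resizes a matrix by averaging over the exact fractional source area
#' covered by each destination pixel. Preserves the mean intensity and
#' keeps values within the input range, so a feature-scaled image stays
#' in [0, 1].
#'
#' @param x Numeric matrix.
#' @param out_dim Integer pair `(rows, cols)` of the output.
#' @return Resized matrix.
#' @export
.resize_wcache <- new.env(parent = emptyenv())

resize_area <- function(x, out_dim) {
  out_dim <- as.integer(out_dim)
  if (length(out_dim) == 1L) out_dim <- c(out_dim, out_dim)
  wmat <- function(n_in, n_out) {
    key <- paste(n_in, n_out, sep = ">")
    hit <- .resize_wcache[[key]]
    if (!is.null(hit)) return(hit)
    # W[i, j] = overlap of destination cell i with source cell j, / cell width
    scale <- n_in / n_out
    W <- matrix(0, n_out, n_in)
    for (i in seq_len(n_out)) {
      lo <- (i - 1) * scale
      hi <- i * scale
      j0 <- floor(lo) + 1L
      j1 <- min(ceiling(hi), n_in)
      js <- j0:j1
      w <- pmin(hi, js) - pmax(lo, js - 1)
      W[i, js] <- w / sum(w)
    }
    .resize_wcache[[key]] <- W
    W
  }
  L <- wmat(nrow(x), out_dim[1])
  R <- wmat(ncol(x), out_dim[2])
  L %*% x %*% t(R)
}

# Collapse a sorted integer vector into maximal runs; returns a 2-column
# matrix (first, last), zero rows for empty input.
runs_to_ranges <- function(idx) {
  idx <- sort(unique(as.integer(idx)))
  if (length(idx) == 0L)
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("first", "last"))))
  brk <- which(diff(idx) > 1L)
  first <- idx[c(1L, brk + 1L)]
  last <- idx[c(brk, length(idx))]
  cbind(first = first, last = last)
}

# Overlap area fraction of a disc of radius r_small centred at distance d
# from a disc of radius r_big, relative to the small disc's area.
disc_overlap_fraction <- function(d, r_small, r_big) {
  stopifnot(r_small > 0, r_big > 0)
  f <- function(d) {
    if (d >= r_small + r_big) return(0)
    if (d <= abs(r_big - r_small))
      return(if (r_small <= r_big) 1 else (r_big / r_small)^2)
    r1 <- r_small; r2 <- r_big
    a1 <- r1^2 * acos((d^2 + r1^2 - r2^2) / (2 * d * r1))
    a2 <- r2^2 * acos((d^2 + r2^2 - r1^2) / (2 * d * r2))
    a3 <- 0.5 * sqrt((-d + r1 + r2) * (d + r1 - r2) * (d - r1 + r2) * (d + r1 + r2))
    (a1 + a2 - a3) / (pi * r1^2)
  }
  vapply(d, f, numeric(1))
}

# Deterministic arg-max with (lowest row, then lowest column) tie-break.
argmax_rc <- function(x) {
  m <- max(x)
  hits <- which(x == m, arr.ind = TRUE)
  r <- min(hits[, 1])
  c <- min(hits[hits[, 1] == r, 2])
  c(row = r, col = c)
}
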