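# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Relativistic electron wavelength via the energy form
# lambda = h*c / sqrt(E * (E + 2*E0)), E = e*V in joules — an independent
# rearrangement of the de Broglie relation.
oracle_wavelength <- function(kv) {
  h <- 6.62607015e-34; c <- 299792458
  e <- 1.602176634e-19; m0 <- 9.1093837015e-31
  E <- e * kv * 1e3
  E0 <- m0 * c^2
  (h * c / sqrt(E * (E + 2 * E0))) * 1e10
}

# Contract a 516x516 logical frame back to 512x512 by summing each
# boundary triplet — the exact inverse of the module-gap expansion.
oracle_contract_516 <- function(px516) {
  collapse <- function(m, margin) {
    # logical index i (1..516) -> raw index
    raw_of <- integer(516)
    raw_of[1:255] <- 1:255
    raw_of[256:258] <- 256L
    raw_of[259:261] <- 257L
    raw_of[262:516] <- 258:512
    out <- matrix(0, if (margin == 1) 512 else nrow(m),
                  if (margin == 1) ncol(m) else 512)
    if (margin == 1) {
      for (i in 1:516) out[raw_of[i], ] <- out[raw_of[i], ] + m[i, ]
    } else {
      for (i in 1:516) out[, raw_of[i]] <- out[, raw_of[i]] + m[, i]
    }
    out
  }
  collapse(collapse(px516, 1), 2)
}

# O(n^2) brute-force isolation filter.
oracle_isolation <- function(pos, frame, neighbor_min = 1.5, edge_min = 0.5) {
  n <- nrow(pos)
  keep <- logical(n)
  for (i in seq_len(n)) {
    ok <- pos[i, 1] - frame[1] >= edge_min && frame[2] - pos[i, 1] >= edge_min &&
      pos[i, 2] - frame[3] >= edge_min && frame[4] - pos[i, 2] >= edge_min
    if (ok && n > 1) {
      for (j in seq_len(n)) {
        if (j == i) next
        if (sqrt(sum((pos[i, ] - pos[j, ])^2)) < neighbor_min) {
          ok <- FALSE
          break
        }
      }
    }
    keep[i] <- ok
  }
  keep
}

# Sample points on an ellipse (semi-axes a, b, azimuth degrees).
ellipse_points <- function(n, a, b, center = c(0, 0), azimuth = 0,
                           jitter = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  phi <- azimuth * pi / 180
  x0 <- a * cos(th); y0 <- b * sin(th)
  x <- center[1] + cos(phi) * x0 - sin(phi) * y0
  y <- center[2] + sin(phi) * x0 + cos(phi) * y0
  if (jitter > 0) {
    x <- x + rnorm(n, 0, jitter)
    y <- y + rnorm(n, 0, jitter)
  }
  cbind(x, y)
}
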