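# Convolutional neural network for good/bad diffraction-pattern
# classification.
#
# No deep-learning framework is assumed: the network is implemented
# directly on BLAS matrix products (im2col convolutions), which is fast
# enough for the small architectures this screening task needs. The
# training protocol is fixed by the screening method: batches of 75
# images, 20 epochs, dropout rate 0.15, binary cross-entropy loss and the
# RMSprop optimizer; rectifier activations everywhere except the logistic
# output unit. Given a seed, training is fully deterministic.

#' CNN architecture description
#'
#' A stack of 3x3 convolution blocks (each followed by a 2x2 max-pool)
#' feeding a dense rectifier layer with dropout and a single logistic
#' output unit. The nominal screening network uses four blocks of
#' 32/64/128/128 filters with a 128-unit dense layer on 150x150 input;
#' narrower variants train orders of magnitude faster on a CPU and are
#' adequate for well-separated synthetic classes.
#'
#' @param filters Integer vector: filters per convolution block.
#' @param dense Width of the dense hidden layer.
#' @param input Input image side, pixels.
#' @return A `cnn_architecture` list.
#' @export
cnn_architecture <- function(filters = c(32L, 64L, 128L, 128L),
                             dense = 128L, input = 150L) {
  stopifnot(length(filters) >= 1, all(filters >= 1), dense >= 1, input >= 4)
  structure(list(filters = as.integer(filters), dense = as.integer(dense),
                 input = as.integer(input)),
            class = "cnn_architecture")
}

relu <- function(x) { x[x < 0] <- 0; x }
sigmoid <- function(x) 1 / (1 + exp(-x))

.init_params <- function(arch) {
  glorot <- function(nr, nc, fan_in, fan_out) {
    lim <- sqrt(6 / (fan_in + fan_out))
    matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
  }
  C <- 1L
  side <- arch$input
  conv <- list()
  for (l in seq_along(arch$filters)) {
    F <- arch$filters[l]
    conv[[l]] <- list(W = glorot(F, 9L * C, 9L * C, 9L * F), b = numeric(F))
    C <- F
    side <- side %/% 2L
  }
  nfeat <- C * side * side
  list(conv = conv,
       d1 = list(W = glorot(arch$dense, nfeat, nfeat, arch$dense),
                 b = numeric(arch$dense)),
       d2 = list(W = glorot(1L, arch$dense, arch$dense, 1L), b = 0),
       nfeat = nfeat, out_side = side)
}

# full forward pass (conv/pool blocks run in compiled code); when `train`
# the dropout mask is sampled from the RNG
.cnn_forward <- function(params, X, dropout, train = FALSE) {
  n_conv <- length(params$conv)
  caches <- vector("list", n_conv)
  cur <- X  # (H, W, C, N)
  for (l in seq_len(n_conv)) {
    d <- dim(cur)
    A <- .cpp_conv_relu_forward(cur, params$conv[[l]]$W,
                                params$conv[[l]]$b, d)
    pool <- .cpp_maxpool_forward(A, dim(A))
    caches[[l]] <- list(X = cur, A = A, which = pool$which, dims = d)
    cur <- pool$P                        # (h, w, F, N): channel-last layout
  }
  N <- dim(cur)[4]
  flat <- cur
  dim(flat) <- c(params$nfeat, N)
  Z1 <- params$d1$W %*% flat + params$d1$b
  H1 <- relu(Z1)
  if (train && dropout > 0) {
    keep <- 1 - dropout
    dmask <- matrix((stats::runif(length(H1)) < keep) / keep, nrow(H1), ncol(H1))
    H1d <- H1 * dmask
  } else { dmask <- NULL; H1d <- H1 }
  Z2 <- as.vector(params$d2$W %*% H1d + params$d2$b)
  list(p = sigmoid(Z2), caches = caches, flat = flat,
       m1 = Z1 > 0, H1d = H1d, dmask = dmask)
}

.cnn_backward <- function(params, fwd, y) {
  N <- length(y)
  grads <- list(conv = vector("list", length(params$conv)))
  dZ2 <- matrix((fwd$p - y) / N, nrow = 1)          # BCE + sigmoid
  grads$d2 <- list(W = dZ2 %*% t(fwd$H1d), b = sum(dZ2))
  dH1 <- t(params$d2$W) %*% dZ2
  if (!is.null(fwd$dmask)) dH1 <- dH1 * fwd$dmask
  dZ1 <- dH1 * fwd$m1
  grads$d1 <- list(W = tcrossprod(dZ1, fwd$flat), b = rowSums(dZ1))
  dflat <- crossprod(params$d1$W, dZ1)
  side <- params$out_side
  C <- nrow(params$conv[[length(params$conv)]]$W)
  dim(dflat) <- c(side, side, C, N)      # pooled layout (h, w, F, N)
  dP <- dflat
  for (l in rev(seq_along(params$conv))) {
    cache <- fwd$caches[[l]]
    dA <- .cpp_maxpool_backward(dP, cache$which, dim(cache$A))
    bk <- .cpp_conv_relu_backward(cache$X, params$conv[[l]]$W, cache$A, dA,
                                  cache$dims, l > 1L)
    grads$conv[[l]] <- list(W = bk$W, b = as.vector(bk$b))
    if (l > 1L) dP <- bk$X               # already (H, W, C, N) of this input
  }
  grads
}

# RMSprop state and update (cache v = rho v + (1-rho) g^2)
.rmsprop_update <- function(params, grads, state, lr, rho, eps) {
  upd <- function(p, g, v) {
    v <- rho * v + (1 - rho) * g * g
    list(p = p - lr * g / (sqrt(v) + eps), v = v)
  }
  for (l in seq_along(params$conv)) {
    u <- upd(params$conv[[l]]$W, grads$conv[[l]]$W, state$conv[[l]]$W)
    params$conv[[l]]$W <- u$p; state$conv[[l]]$W <- u$v
    u <- upd(params$conv[[l]]$b, grads$conv[[l]]$b, state$conv[[l]]$b)
    params$conv[[l]]$b <- u$p; state$conv[[l]]$b <- u$v
  }
  for (nm in c("d1", "d2")) {
    u <- upd(params[[nm]]$W, grads[[nm]]$W, state[[nm]]$W)
    params[[nm]]$W <- u$p; state[[nm]]$W <- u$v
    u <- upd(params[[nm]]$b, grads[[nm]]$b, state[[nm]]$b)
    params[[nm]]$b <- u$p; state[[nm]]$b <- u$v
  }
  list(params = params, state = state)
}

.zero_like <- function(params) {
  z <- function(p) lapply(p, function(x) x * 0)   # keeps shape (matrix/vector)
  list(conv = lapply(params$conv, z), d1 = z(params$d1), d2 = z(params$d2))
}

# coerce images to an (H, W, 1, N) array
.as_image_array <- function(x, side) {
  if (is.list(x) && !is.array(x)) x <- simplify2array(x)
  d <- dim(x)
  if (length(d) == 2L) dim(x) <- c(d, 1L)
  d <- dim(x)
  if (length(d) == 3L) x <- array(x, c(d[1], d[2], 1L, d[3]))
  d <- dim(x)
  if (d[1] != side || d[2] != side)
    stop(sprintf("images must be %dx%d for this architecture, got %dx%d",
                 side, side, d[1], d[2]))
  x
}

#' Fit the diffraction-pattern screening CNN
#'
#' Trains a good/bad pattern classifier with the screening protocol:
#' batches of 75 images, 20 epochs, dropout rate 0.15, binary
#' cross-entropy loss and RMSprop. All randomness (weight init, epoch
#' shuffling, dropout) comes from the R RNG, so a fixed `seed` makes
#' training deterministic.
#'
#' @param x Training images: `(side, side, n)` array (or list of
#'   matrices), values in `[0, 1]` as produced by [preprocess_pattern()].
#' @param y Labels, 0 (bad) / 1 (good); both classes must be present.
#' @param x_val,y_val Optional validation set, evaluated every epoch.
#' @param architecture A [cnn_architecture()].
#' @param epochs,batch_size,dropout,learning_rate,rho Training protocol;
#'   defaults are the screening protocol.
#' @param seed Integer seed; mandatory for reproducibility.
#' @param verbose Print a line per epoch.
#' @return A `cred_cnn` model with `history` (per-epoch loss/accuracy
#'   trace) usable with `predict()`, `print()`, `summary()` and `plot()`.
#' @export
cred_cnn <- function(x, y, x_val = NULL, y_val = NULL,
                     architecture = cnn_architecture(),
                     epochs = 20L, batch_size = 75L, dropout = 0.15,
                     learning_rate = 1e-3, rho = 0.9, seed = 1L,
                     verbose = FALSE) {
  X <- .as_image_array(x, architecture$input)
  y <- as.numeric(y)
  n <- dim(X)[4]
  if (length(y) != n) stop("length(y) must match the number of images")
  if (length(unique(y)) < 2L)
    stop("training set must contain both classes")
  has_val <- !is.null(x_val)
  if (has_val) {
    XV <- .as_image_array(x_val, architecture$input)
    y_val <- as.numeric(y_val)
  }
  set.seed(as.integer(seed))
  params <- .init_params(architecture)
  state <- .zero_like(params)
  eps <- 1e-7
  hist <- data.frame(epoch = integer(0), loss = numeric(0),
                     accuracy = numeric(0), val_loss = numeric(0),
                     val_accuracy = numeric(0))
  bce <- function(p, y) {
    p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
    -mean(y * log(p) + (1 - y) * log(1 - p))
  }
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; ep_hits <- 0
    for (b0 in seq(1L, n, by = batch_size)) {
      bi <- ord[b0:min(b0 + batch_size - 1L, n)]
      Xb <- X[, , , bi, drop = FALSE]
      yb <- y[bi]
      fwd <- .cnn_forward(params, Xb, dropout, train = TRUE)
      ep_loss <- ep_loss + bce(fwd$p, yb) * length(bi)
      ep_hits <- ep_hits + sum((fwd$p > 0.5) == (yb > 0.5))
      grads <- .cnn_backward(params, fwd, yb)
      u <- .rmsprop_update(params, grads, state, learning_rate, rho, eps)
      params <- u$params; state <- u$state
    }
    row <- data.frame(epoch = ep, loss = ep_loss / n, accuracy = ep_hits / n,
                      val_loss = NA_real_, val_accuracy = NA_real_)
    if (has_val) {
      pv <- .cnn_predict_scores(params, architecture, XV, dropout)
      row$val_loss <- bce(pv, y_val)
      row$val_accuracy <- mean((pv > 0.5) == (y_val > 0.5))
    }
    hist <- rbind(hist, row)
    if (verbose)
      cat(sprintf("epoch %2d  loss %.4f  acc %.4f%s\n", ep, row$loss,
                  row$accuracy,
                  if (has_val) sprintf("  val_acc %.4f", row$val_accuracy) else ""))
  }
  structure(
    list(architecture = architecture, params = params, history = hist,
         protocol = list(epochs = epochs, batch_size = batch_size,
                         dropout = dropout, learning_rate = learning_rate,
                         rho = rho, seed = as.integer(seed)),
         n_train = n),
    class = "cred_cnn"
  )
}

.cnn_predict_scores <- function(params, arch, X, dropout, batch = 128L) {
  n <- dim(X)[4]
  out <- numeric(n)
  for (b0 in seq(1L, n, by = batch)) {
    bi <- b0:min(b0 + batch - 1L, n)
    out[bi] <- .cnn_forward(params, X[, , , bi, drop = FALSE],
                            dropout, train = FALSE)$p
  }
  out
}

#' Predict screening scores
#'
#' @param object A fitted [cred_cnn()] model.
#' @param newdata Images as in [cred_cnn()].
#' @param type `"score"` for the logistic output in `[0, 1]`, `"class"`
#'   for the good/bad decision (good iff score strictly greater than 0.5).
#' @param ... Unused.
#' @return Numeric scores or integer 0/1 classes.
#' @export
predict.cred_cnn <- function(object, newdata, type = c("score", "class"), ...) {
  type <- match.arg(type)
  X <- .as_image_array(newdata, object$architecture$input)
  p <- .cnn_predict_scores(object$params, object$architecture, X,
                           object$protocol$dropout)
  if (type == "class") as.integer(p > 0.5) else p
}

#' Score a single preprocessed pattern
#'
#' Convenience wrapper over [predict.cred_cnn()] for one image.
#'
#' @param model A fitted [cred_cnn()].
#' @param img A single preprocessed image matrix.
#' @return Score in `[0, 1]`; values strictly above 0.5 mean "good".
#' @export
predict_score <- function(model, img) {
  if (!is.matrix(img)) stop("`img` must be a single image matrix")
  as.numeric(predict(model, array(img, c(dim(img), 1L))))
}

#' @rdname cred_cnn
#' @param train,val Lists with elements `x` and `y` (alternative calling
#'   convention mirroring a train/validation split).
#' @param ... Passed on to [cred_cnn()].
#' @export
train_classifier <- function(train, val = NULL, seed = 1L, ...) {
  cred_cnn(train$x, train$y, x_val = val$x, y_val = val$y, seed = seed, ...)
}

#' @export
print.cred_cnn <- function(x, ...) {
  a <- x$architecture
  last <- x$history[nrow(x$history), ]
  cat(sprintf(
    paste0("Screening CNN: conv blocks [%s] + dense %d on %dx%d input\n",
           "  trained %d epochs on %d images (batch %d, dropout %.2f, RMSprop)\n",
           "  final loss %.4f, accuracy %.3f%s\n"),
    paste(a$filters, collapse = ", "), a$dense, a$input, a$input,
    nrow(x$history), x$n_train, x$protocol$batch_size, x$protocol$dropout,
    last$loss, last$accuracy,
    if (!is.na(last$val_accuracy))
      sprintf(", validation accuracy %.3f", last$val_accuracy) else ""))
  invisible(x)
}

#' @export
summary.cred_cnn <- function(object, ...) {
  print(object)
  cat("\nTraining history:\n")
  print(object$history, row.names = FALSE)
  invisible(object$history)
}

#' @export
plot.cred_cnn <- function(x, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$accuracy, type = "b", ylim = c(0, 1),
                 xlab = "epoch", ylab = "accuracy",
                 main = "Screening CNN training", ...)
  if (any(!is.na(h$val_accuracy)))
    graphics::lines(h$epoch, h$val_accuracy, type = "b", lty = 2, pch = 2)
  invisible(x)
}
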