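#' Hyperparameter configuration for the 1D convolutional network
#'
#' A network is `depth` convolutional groups (convolution + average
#' pooling) followed by a fully connected hidden layer and a linear
#' 4-score output layer.  All activations are ELU.  Training is plain
#' mini-batch stochastic gradient descent on the sum-of-squares loss
#' against one-hot targets.
#'
#' @param depth Number of convolutional groups (>= 1).
#' @param kernel_size Odd kernel length (taps per filter).
#' @param learning_rate SGD step size (> 0).
#' @param activation Activation function; only `"elu"` is supported.
#' @param pool_factor Average-pooling factor `tt` (>= 1).  Pooling in a
#'   group is skipped when the signal is shorter than `2 * tt`.
#' @param n_filters Filters per convolutional group.
#' @param mlp_hidden Width of the fully connected hidden layer.
#' @param epochs Maximum training epochs.
#' @param batch_size Mini-batch size.
#' @param padding `"same"` (zero padding, length-preserving; default) or
#'   `"valid"`.
#' @param seed Integer seed for weight initialization and batch shuffling.
#' @param plateau_tol,plateau_window Early stopping: training stops when
#'   the mean epoch loss changes by less than `plateau_tol` (relative)
#'   over `plateau_window` epochs.
#' @return Object of class `odcnn_config`.
#' @export
odcnn_config <- function(depth = 5L, kernel_size = 7L,
                         learning_rate = 5e-4, activation = "elu",
                         pool_factor = 1L, n_filters = 16L,
                         mlp_hidden = 32L, epochs = 100L,
                         batch_size = 32L, padding = c("same", "valid"),
                         seed = 1L, plateau_tol = 1e-6,
                         plateau_window = 20L) {
  padding <- match.arg(padding)
  depth <- as.integer(depth); kernel_size <- as.integer(kernel_size)
  if (depth < 1) stop("`depth` must be >= 1")
  if (kernel_size < 1 || kernel_size %% 2 == 0)
    stop("`kernel_size` must be odd and >= 1")
  if (learning_rate <= 0) stop("`learning_rate` must be > 0")
  if (pool_factor < 1) stop("`pool_factor` must be >= 1")
  if (activation != "elu") stop("only the ELU activation is supported")
  structure(list(depth = depth, kernel_size = kernel_size,
                 learning_rate = learning_rate, activation = activation,
                 pool_factor = as.integer(pool_factor),
                 n_filters = as.integer(n_filters),
                 mlp_hidden = as.integer(mlp_hidden),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 padding = padding, seed = seed,
                 plateau_tol = plateau_tol,
                 plateau_window = as.integer(plateau_window)),
            class = "odcnn_config")
}

# Signal length after each convolutional group; errors if the configured
# depth/kernel/pooling would shrink the signal away (the guard is proven
# before any training starts).
odcnn_layer_lengths <- function(config, input_dim) {
  L <- input_dim
  pad <- if (config$padding == "same") (config$kernel_size - 1L) %/% 2L else 0L
  out <- integer(config$depth)
  for (g in seq_len(config$depth)) {
    L <- L - config$kernel_size + 1L + 2L * pad
    if (L < 1)
      stop(sprintf(
        "configuration infeasible: group %d reduces the signal to %d %s",
        g, L, "values; use `same` padding or a smaller kernel/depth"))
    if (config$pool_factor > 1 && L >= 2L * config$pool_factor)
      L <- L %/% config$pool_factor
    out[g] <- L
  }
  out
}

glorot <- function(nr, nc, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Initialize network weights
#'
#' Scaled-uniform (Glorot) initialization, seeded.  The returned object is
#' an untrained model of class `odcnn`.
#'
#' @param config An [odcnn_config()].
#' @param input_dim Input signal length (13 for the employee features).
#' @param n_classes Number of output scores (4 emotions).
#' @param seed Optional override of `config$seed`.
#' @return Object of class `odcnn`.
#' @export
odcnn_init <- function(config, input_dim = 13L, n_classes = 4L,
                       seed = config$seed) {
  lens <- odcnn_layer_lengths(config, input_dim)
  with_seed(seed, {
    k <- config$kernel_size; F_ <- config$n_filters
    conv <- vector("list", config$depth)
    C_in <- 1L
    for (g in seq_len(config$depth)) {
      fan_in <- k * C_in; fan_out <- k * F_
      conv[[g]] <- list(
        W = array(stats::runif(k * C_in * F_,
                               -sqrt(6 / (fan_in + fan_out)),
                               sqrt(6 / (fan_in + fan_out))),
                  dim = c(k, C_in, F_)),
        b = numeric(F_))
      C_in <- F_
    }
    flat <- lens[config$depth] * F_
    H <- config$mlp_hidden
    model <- list(config = config, input_dim = as.integer(input_dim),
                  n_classes = as.integer(n_classes),
                  layer_lengths = lens,
                  conv = conv,
                  W1 = glorot(flat, H, flat, H), b1 = numeric(H),
                  W2 = glorot(H, n_classes, H, n_classes),
                  b2 = numeric(n_classes),
                  loss_curve = numeric(0), epochs_run = 0L,
                  trained = FALSE)
    class(model) <- "odcnn"
    model
  })
}

# --- batched forward/backward ------------------------------------------
# Internal layout: a layer's activation for a batch of B signals of length
# L with C channels is a (B*L) x C matrix whose row index is
# (b - 1) * L + i (position i fastest).  Convolution is im2col + one
# matrix product; this keeps the whole training loop in BLAS calls.

odcnn_forward_batch <- function(model, X, keep_cache = FALSE) {
  cfg <- model$config
  B <- nrow(X); L <- model$input_dim
  k <- cfg$kernel_size
  pad <- if (cfg$padding == "same") (k - 1L) %/% 2L else 0L
  Tc <- matrix(as.vector(t(X)), ncol = 1L)
  C <- 1L
  cache <- if (keep_cache) vector("list", cfg$depth)
  for (g in seq_len(cfg$depth)) {
    Lp <- L + 2L * pad
    Lout <- L - k + 1L + 2L * pad
    Mp <- matrix(0, B * Lp, C)
    in_rows <- as.vector(outer(seq_len(L) + pad, (seq_len(B) - 1L) * Lp, "+"))
    Mp[in_rows, ] <- Tc
    rbase <- as.vector(outer(seq_len(Lout), (seq_len(B) - 1L) * Lp, "+"))
    Z <- matrix(0, B * Lout, k * C)
    for (j in seq_len(k))
      Z[, j + (seq_len(C) - 1L) * k] <- Mp[rbase + (j - 1L), ]
    lay <- model$conv[[g]]
    F_ <- length(lay$b)
    Wmat <- matrix(lay$W, k * C, F_)
    Y <- Z %*% Wmat
    Y <- Y + rep(lay$b, each = B * Lout)
    Zact <- elu(Y)
    tt <- cfg$pool_factor
    pooled <- tt > 1L && Lout >= 2L * tt
    if (pooled) {
      Lnew <- Lout %/% tt
      A <- array(Zact, c(Lout, B, F_))
      A2 <- array(A[seq_len(Lnew * tt), , , drop = FALSE],
                  c(tt, Lnew, B, F_))
      P <- colMeans(A2)                       # (Lnew, B, F_)
      Tnext <- matrix(P, Lnew * B, F_)
    } else {
      Lnew <- Lout
      Tnext <- Zact
    }
    if (keep_cache)
      cache[[g]] <- list(Z = Z, Y = Y, L_in = L, L_conv = Lout,
                         L_out = Lnew, C_in = C, pooled = pooled,
                         in_rows = in_rows, rbase = rbase, Lp = Lp)
    Tc <- Tnext; L <- Lnew; C <- F_
  }
  A <- array(Tc, c(L, B, C))
  Xflat <- t(matrix(aperm(A, c(1, 3, 2)), L * C, B))
  Yh <- Xflat %*% model$W1
  Yh <- Yh + rep(model$b1, each = B)
  Hact <- elu(Yh)
  scores <- Hact %*% model$W2
  scores <- scores + rep(model$b2, each = B)
  if (keep_cache)
    list(scores = scores,
         cache = list(conv = cache, Xflat = Xflat, Yh = Yh, Hact = Hact,
                      L_last = L, C_last = C, B = B, scores = scores))
  else scores
}

# Gradients of the summed (over the batch) sum-of-squares loss: one
# mini-batch step applies the accumulated per-sample updates, so batch
# size 1 reduces exactly to per-presentation SGD.
odcnn_backward_batch <- function(model, cache, U) {
  cfg <- model$config
  B <- cache$B
  dscores <- 2 * (cache$scores - U)
  dW2 <- crossprod(cache$Hact, dscores)
  db2 <- colSums(dscores)
  dH <- dscores %*% t(model$W2)
  dYh <- dH * elu_prime(cache$Yh)
  dW1 <- crossprod(cache$Xflat, dYh)
  db1 <- colSums(dYh)
  dXflat <- dYh %*% t(model$W1)
  L <- cache$L_last; C <- cache$C_last
  tmp <- array(t(dXflat), c(L, C, B))
  dT <- matrix(aperm(tmp, c(1, 3, 2)), L * B, C)
  k <- cfg$kernel_size
  dconv <- vector("list", cfg$depth)
  for (g in rev(seq_len(cfg$depth))) {
    cc <- cache$conv[[g]]
    lay <- model$conv[[g]]
    F_ <- length(lay$b)
    if (cc$pooled) {
      tt <- cfg$pool_factor
      Lnew <- cc$L_out
      dP <- array(dT, c(Lnew, B, F_))
      dZact <- array(0, c(cc$L_conv, B, F_))
      idx <- rep(seq_len(Lnew), each = tt)
      dZact[seq_len(Lnew * tt), , ] <- dP[idx, , , drop = FALSE] / tt
      dZact <- matrix(dZact, cc$L_conv * B, F_)
    } else {
      dZact <- dT
    }
    dY <- dZact * elu_prime(cc$Y)
    Cin <- cc$C_in
    Wmat <- matrix(lay$W, k * Cin, F_)
    dWmat <- crossprod(cc$Z, dY)
    db <- colSums(dY)
    dZ <- dY %*% t(Wmat)
    dMp <- matrix(0, B * cc$Lp, Cin)
    for (j in seq_len(k)) {
      rows_j <- cc$rbase + (j - 1L)
      dMp[rows_j, ] <- dMp[rows_j, ] + dZ[, j + (seq_len(Cin) - 1L) * k]
    }
    dT <- dMp[cc$in_rows, , drop = FALSE]
    dconv[[g]] <- list(W = array(dWmat, dim(lay$W)), b = db)
  }
  list(conv = dconv, W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
}

#' Forward propagation for a single feature vector
#'
#' Runs one input through the network and returns the four class scores
#' together with all cached intermediate states needed by
#' [odcnn_backward()].
#'
#' @param model An `odcnn` model.
#' @param features Numeric vector of length `model$input_dim`.
#' @return List with `scores` (length-4 numeric) and `cache`.
#' @export
odcnn_forward <- function(model, features) {
  if (length(features) != model$input_dim)
    stop("feature length ", length(features), " does not match input layer ",
         model$input_dim)
  fb <- odcnn_forward_batch(model, matrix(features, nrow = 1), TRUE)
  list(scores = as.vector(fb$scores), cache = fb$cache)
}

#' Backward propagation (gradients) for a single input
#'
#' Computes the gradient of the sum-of-squares loss with respect to every
#' kernel, weight matrix and bias, using the states cached by
#' [odcnn_forward()].
#'
#' @param model An `odcnn` model.
#' @param cache Cache from [odcnn_forward()].
#' @param target One-hot target vector (length `model$n_classes`).
#' @return List of gradients mirroring the model structure
#'   (`conv[[g]]$W`, `conv[[g]]$b`, `W1`, `b1`, `W2`, `b2`).
#' @export
odcnn_backward <- function(model, cache, target) {
  if (is.null(cache$scores)) stop("missing or stale forward cache")
  odcnn_backward_batch(model, cache, matrix(target, nrow = 1))
}

#' One stochastic-gradient-descent update
#'
#' `w <- w - eps * dF/dw` for every weight and bias.  Non-finite gradients
#' abort with a diagnostic rather than silently corrupting the model.
#'
#' @param model An `odcnn` model.
#' @param grads Gradient list from [odcnn_backward()].
#' @param eps Learning rate.
#' @return Updated model.
#' @export
odcnn_sgd_step <- function(model, grads, eps) {
  finite <- all(vapply(grads$conv, function(g)
    all(is.finite(g$W)) && all(is.finite(g$b)), logical(1))) &&
    all(is.finite(grads$W1)) && all(is.finite(grads$b1)) &&
    all(is.finite(grads$W2)) && all(is.finite(grads$b2))
  if (!finite) stop("non-finite gradients; training diverged")
  for (g in seq_along(model$conv)) {
    model$conv[[g]]$W <- model$conv[[g]]$W - eps * grads$conv[[g]]$W
    model$conv[[g]]$b <- model$conv[[g]]$b - eps * grads$conv[[g]]$b
  }
  model$W1 <- model$W1 - eps * grads$W1
  model$b1 <- model$b1 - eps * grads$b1
  model$W2 <- model$W2 - eps * grads$W2
  model$b2 <- model$b2 - eps * grads$b2
  model
}

#' Fit the 1D convolutional emotion classifier
#'
#' Trains the network with seeded mini-batch SGD on the sum-of-squares
#' loss against one-hot class targets, recording the mean per-sample loss
#' for every epoch and stopping early on a loss plateau.
#'
#' @param x Numeric feature matrix (rows = observations), e.g. from
#'   [emotion_feature_matrix()].
#' @param y Integer class labels 0..(n_classes - 1), or a factor.
#' @param config An [odcnn_config()].
#' @param n_classes Number of classes (default: inferred, at least 4 when
#'   labels are 0-based integers in 0..3).
#' @param verbose Print a line every 25 epochs.
#' @return A fitted model of class `odcnn` with a `loss_curve` component.
#' @examples
#' d <- simulate_employees(emotion_sim_config(n_base = 120, seed = 3))
#' fm <- emotion_feature_matrix(d)
#' fit <- odcnn(fm$x, fm$y, odcnn_config(depth = 2, epochs = 30, seed = 3))
#' print(fit)
#' @export
odcnn <- function(x, y, config = odcnn_config(), n_classes = NULL,
                  verbose = FALSE) {
  x <- as.matrix(x)
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("need at least 2 classes to train")
  if (is.null(n_classes)) n_classes <- max(max(y) + 1L, 4L)
  n <- nrow(x)
  U <- matrix(0, n, n_classes)
  U[cbind(seq_len(n), y + 1L)] <- 1
  model <- odcnn_init(config, input_dim = ncol(x), n_classes = n_classes)
  eps <- config$learning_rate
  bs <- config$batch_size
  loss_curve <- numeric(config$epochs)
  epochs_done <- 0L
  with_seed(derive_seed(config$seed, 7L), {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      tot <- 0
      for (s in seq(1L, n, by = bs)) {
        idx <- ord[s:min(s + bs - 1L, n)]
        fb <- odcnn_forward_batch(model, x[idx, , drop = FALSE], TRUE)
        Ub <- U[idx, , drop = FALSE]
        tot <- tot + sum((fb$scores - Ub)^2)
        grads <- odcnn_backward_batch(model, fb$cache, Ub)
        model <- odcnn_sgd_step(model, grads, eps)
      }
      loss_curve[epoch] <- tot / n
      epochs_done <- epoch
      if (!is.finite(loss_curve[epoch]))
        stop("training diverged (non-finite loss) at epoch ", epoch)
      if (verbose && epoch %% 25L == 0L)
        message(sprintf("epoch %d  mean loss %.6f", epoch,
                        loss_curve[epoch]))
      w <- config$plateau_window
      if (epoch > w) {
        prev <- loss_curve[epoch - w]
        if (abs(prev - loss_curve[epoch]) <
            config$plateau_tol * max(prev, .Machine$double.eps))
          break
      }
    }
  })
  model$loss_curve <- loss_curve[seq_len(epochs_done)]
  model$epochs_run <- epochs_done
  model$trained <- TRUE
  model
}

#' Predict emotion labels and class scores
#'
#' @param object A fitted `odcnn` model.
#' @param newdata Feature matrix with `object$input_dim` columns.
#' @param type `"class"` for labels (default) or `"score"` for the raw
#'   score matrix used for ROC analysis.
#' @param ... Unused.
#' @return Integer labels 0..3 (`type = "class"`) or an n x 4 score
#'   matrix.  The predicted label maximizes the score; ties go to the
#'   lowest class index.
#' @export
predict.odcnn <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$input_dim)
    stop("newdata has ", ncol(newdata), " features; model expects ",
         object$input_dim)
  scores <- odcnn_forward_batch(object, newdata, FALSE)
  colnames(scores) <- emotion_levels()[seq_len(ncol(scores))]
  if (type == "score") return(scores)
  as.integer(max.col(scores, ties.method = "first") - 1L)
}

#' @export
print.odcnn <- function(x, ...) {
  cfg <- x$config
  cat("1D convolutional emotion classifier (odcnn)\n")
  cat(sprintf("  depth %d | kernel %d | %d filters | padding %s | pool %d\n",
              cfg$depth, cfg$kernel_size, cfg$n_filters, cfg$padding,
              cfg$pool_factor))
  cat(sprintf("  input %d -> conv groups -> flatten %d -> hidden %d -> %d scores\n",
              x$input_dim, x$layer_lengths[cfg$depth] * cfg$n_filters,
              cfg$mlp_hidden, x$n_classes))
  if (x$trained)
    cat(sprintf("  trained %d epochs (lr %g); final mean loss %.6f\n",
                x$epochs_run, cfg$learning_rate,
                x$loss_curve[length(x$loss_curve)]))
  else cat("  untrained\n")
  invisible(x)
}

#' @export
summary.odcnn <- function(object, ...) {
  np <- sum(vapply(object$conv, function(l) length(l$W) + length(l$b),
                   double(1))) +
    length(object$W1) + length(object$b1) +
    length(object$W2) + length(object$b2)
  out <- list(config = object$config, n_parameters = np,
              layer_lengths = object$layer_lengths,
              epochs_run = object$epochs_run,
              final_loss = if (object$trained)
                object$loss_curve[length(object$loss_curve)] else NA_real_)
  class(out) <- "summary.odcnn"
  out
}

#' @export
print.summary.odcnn <- function(x, ...) {
  cat(sprintf("odcnn: %d parameters, signal lengths after each group: %s\n",
              x$n_parameters, paste(x$layer_lengths, collapse = " ")))
  cat(sprintf("epochs run: %d, final mean loss: %s\n", x$epochs_run,
              format(x$final_loss)))
  invisible(x)
}

#' @export
coef.odcnn <- function(object, ...) {
  list(conv = object$conv, W1 = object$W1, b1 = object$b1,
       W2 = object$W2, b2 = object$b2)
}

#' @export
plot.odcnn <- function(x, ...) {
  if (!x$trained) stop("model is untrained; nothing to plot")
  graphics::plot(seq_along(x$loss_curve), x$loss_curve, type = "l",
                 xlab = "epoch", ylab = "mean per-sample loss",
                 main = "ODCNN training loss", ...)
  invisible(x)
}

#' Serialize / restore a fitted model
#'
#' The container carries a format version tag and the full configuration;
#' the round trip is exact.
#'
#' @param model An `odcnn` model.
#' @param path File path.
#' @return `read_odcnn` returns the model; `write_odcnn` the path,
#'   invisibly.
#' @export
write_odcnn <- function(model, path) {
  stopifnot(inherits(model, "odcnn"))
  saveRDS(list(format = "emocomp-odcnn", version = 1L, model = model), path)
  invisible(path)
}

#' @rdname write_odcnn
#' @export
read_odcnn <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "emocomp-odcnn"))
    stop("not an emocomp odcnn container")
  obj$model
}
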