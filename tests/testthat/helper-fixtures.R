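# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# Small generated dataset (240 records) for fast structural tests.
small_dataset <- function() {
  if (is.null(.fixtures$small))
    .fixtures$small <- simulate_employees(
      emotion_sim_config(n_base = 240L, seed = 404L))
  .fixtures$small
}

# A linearly separable 2-feature, 2-class toy problem embedded in the
# 13-feature input layout (padded with zeros).
separable_toy <- function(n_per = 40, gap = 4, seed = 99) {
  set.seed(seed)
  x <- rbind(cbind(rnorm(n_per, -gap / 2, 0.3), rnorm(n_per, 0, 0.3)),
             cbind(rnorm(n_per, gap / 2, 0.3), rnorm(n_per, 0, 0.3)))
  x13 <- cbind(x, matrix(0, 2 * n_per, 11))
  list(x = x13, y = rep(0:1, each = n_per))
}

# Exhaustive pair-counting AUC oracle: P(score_pos > score_neg) + tie/2.
auc_pair_oracle <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Eigendecompose-clip-renormalize oracle for the PSD projection.
psd_clip_oracle <- function(R) {
  e <- eigen(R, symmetric = TRUE)
  X <- e$vectors %*% (pmax(e$values, 0) * t(e$vectors))
  d <- sqrt(diag(X))
  X <- X / outer(d, d)
  diag(X) <- 1
  X
}

# Central finite-difference gradient of the single-sample loss wrt one
# scalar parameter addressed by getter/setter closures.
fd_grad <- function(model, x, u, get, set, h = 1e-5) {
  loss_at <- function(m) mse_loss(odcnn_forward(m, x)$scores, u)
  (loss_at(set(model, get(model) + h)) -
     loss_at(set(model, get(model) - h))) / (2 * h)
}
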