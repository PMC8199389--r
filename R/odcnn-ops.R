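#' Valid (unpadded) 1D convolution
#'
#' Cross-correlation orientation: `out[i] = sum_k signal[i + k - 1] * kernel[k]`.
#' Output length is `length(signal) - length(kernel) + 1`.
#'
#' @param signal Numeric vector.
#' @param kernel Numeric vector, no longer than `signal`.
#' @return Numeric vector.
#' @export
conv1d_valid <- function(signal, kernel) {
  n <- length(signal); k <- length(kernel)
  if (k > n) stop("kernel longer than signal")
  out <- numeric(n - k + 1)
  for (j in seq_len(k)) out <- out + kernel[j] * signal[j:(n - k + j)]
  out
}

#' Full (zero-padded) 1D convolution
#'
#' True convolution (the kernel is reversed relative to [conv1d_valid()]),
#' with zero padding so the output has length
#' `length(signal) + length(kernel) - 1`.  This is the operation used to
#' backpropagate delta errors through a convolutional layer.
#'
#' @param signal Numeric vector.
#' @param kernel Numeric vector.
#' @return Numeric vector.
#' @export
conv1d_full <- function(signal, kernel) {
  n <- length(signal); k <- length(kernel)
  if (n == 0 || k == 0) stop("empty input")
  padded <- c(numeric(k - 1), signal, numeric(k - 1))
  conv1d_valid(padded, rev(kernel))
}

#' Exponential linear unit and its derivative
#'
#' `elu(x) = x` for `x >= 0` and `exp(x) - 1` otherwise; the derivative is
#' 1 for `x >= 0` and `exp(x)` otherwise.  Both are continuous at 0.
#'
#' @param x Numeric vector/matrix.
#' @return Numeric object of the same shape.
#' @export
elu <- function(x) pmax(x, 0) + expm1(pmin(x, 0))

#' @rdname elu
#' @export
elu_prime <- function(x) exp(pmin(x, 0))

#' Average-pooling downsample and its adjoint zero-order upsample
#'
#' `downsample` averages consecutive non-overlapping windows of length
#' `tt` (a trailing partial window is dropped); `upsample_zero_order`
#' repeats each entry `tt` times scaled by `1/tt`, which makes the pair
#' adjoint: `sum(downsample(z, tt) * d) == sum(z * upsample_zero_order(d, tt))`
#' whenever `length(z)` is a multiple of `tt`.
#'
#' @param z,d Numeric vectors.
#' @param tt Integer pooling factor `>= 1`.
#' @return Numeric vector.
#' @export
downsample <- function(z, tt) {
  tt <- as.integer(tt)
  if (tt < 1) stop("`tt` must be >= 1")
  if (tt == 1) return(z)
  m <- length(z) %/% tt
  if (m == 0) stop("signal shorter than pooling window")
  colMeans(matrix(z[seq_len(m * tt)], nrow = tt))
}

#' @rdname downsample
#' @export
upsample_zero_order <- function(d, tt) {
  tt <- as.integer(tt)
  if (tt < 1) stop("`tt` must be >= 1")
  if (tt == 1) return(d)
  rep(d, each = tt) / tt
}

#' Sum-of-squares loss between output scores and a one-hot target
#'
#' `F = sum_j (z_j - u_j)^2`; zero iff the output equals the target.
#'
#' @param output Numeric score vector.
#' @param target One-hot target vector of the same length.
#' @return Non-negative scalar.
#' @export
mse_loss <- function(output, target) {
  if (length(output) != length(target)) stop("length mismatch")
  sum((output - target)^2)
}
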