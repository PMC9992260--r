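# Evaluation metrics and the training objective. SSIM follows the
# Gaussian-weighted convention: an 11x11 window with sigma = 1.5,
# K1 = 0.01, K2 = 0.03, local statistics normalized by the window weights
# (no sample-covariance correction), averaged over the valid interior.

gauss_kernel <- function(size = 11L, sigma = 1.5) {
  r <- (size - 1L) / 2
  g <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# Valid-mode 2-D correlation of a matrix with a small kernel (im2col reuse).
filter2_valid <- function(x, k) {
  d <- dim(x); dk <- dim(k)
  ii <- im2col_index(d[1], d[2], dk[1], dk[2], 1L, 1L)
  P <- x[as.vector(ii$idx)]
  dim(P) <- c(ii$ho * ii$wo, dk[1] * dk[2])
  out <- P %*% as.vector(k)
  dim(out) <- c(ii$ho, ii$wo)
  out
}

ssim_constants <- function(data_range, K1 = 0.01, K2 = 0.03) {
  list(C1 = (K1 * data_range)^2, C2 = (K2 * data_range)^2)
}

#' Gaussian-weighted structural similarity index (SSIM)
#'
#' Mean SSIM between two magnitude images using a Gaussian window
#' (11x11, sigma 1.5) and the standard stabilizing constants
#' `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2` with `L = data_range`. Symmetric in
#' its arguments and equal to 1 exactly when the images coincide.
#'
#' @param x,y real matrices of identical shape.
#' @param data_range dynamic range `L` of the reference (e.g. the maximum of
#'   the reference volume).
#' @param win_size,sigma Gaussian window size and width.
#' @return scalar in `[-1, 1]`.
#' @export
ssim <- function(x, y, data_range, win_size = 11L, sigma = 1.5) {
  if (!all(dim(x) == dim(y))) stop("ssim: shape mismatch")
  if (data_range <= 0) stop("ssim: data_range must be positive")
  K <- gauss_kernel(win_size, sigma)
  cs <- ssim_constants(data_range)
  mx <- filter2_valid(x, K); my <- filter2_valid(y, K)
  sxx <- filter2_valid(x * x, K) - mx^2
  syy <- filter2_valid(y * y, K) - my^2
  sxy <- filter2_valid(x * y, K) - mx * my
  num <- (2 * mx * my + cs$C1) * (2 * sxy + cs$C2)
  den <- (mx^2 + my^2 + cs$C1) * (sxx + syy + cs$C2)
  mean(num / den)
}

#' Normalized mean square error
#'
#' `||pred - ref||^2 / ||ref||^2` over the whole array (image or volume).
#'
#' @param pred,ref arrays of identical shape; `ref` must not be all zero.
#' @return nonnegative scalar.
#' @export
nmse <- function(pred, ref) {
  if (!all(dim(pred) == dim(ref))) stop("nmse: shape mismatch")
  denom <- sum(ref^2)
  if (denom == 0) stop("nmse: reference is identically zero")
  sum((pred - ref)^2) / denom
}

#' Peak signal-to-noise ratio (dB)
#'
#' `20 log10(data_range) - 10 log10(MSE)`. Exact matches (zero MSE) return
#' the sentinel value `20 log10(data_range) + 160` (the double-precision
#' floor) rather than infinity.
#'
#' @param pred,ref arrays of identical shape.
#' @param data_range dynamic range of the reference.
#' @return PSNR in decibels.
#' @export
psnr <- function(pred, ref, data_range) {
  if (!all(dim(pred) == dim(ref))) stop("psnr: shape mismatch")
  mse <- mean((pred - ref)^2)
  if (mse == 0) return(20 * log10(data_range) + 160)
  20 * log10(data_range) - 10 * log10(mse)
}

#' Training loss: (1 - SSIM) + L1
#'
#' Equally weighted combination of the Gaussian-weighted structural
#' dissimilarity and the mean absolute error:
#' `(1 - ssim(pred, ref, data_range)) + mean(|pred - ref|)`. Zero exactly
#' when the images coincide.
#'
#' @inheritParams psnr
#' @return nonnegative scalar.
#' @export
training_loss <- function(pred, ref, data_range) {
  (1 - ssim(pred, ref, data_range)) + mean(abs(pred - ref))
}

# Differentiable SSIM on graph tensors; x is a tensor (h, w), ref a plain
# matrix. Mirrors ssim() exactly (same kernel, constants, valid crop).
ssim_graph <- function(x, ref, data_range, win_size = 11L, sigma = 1.5) {
  K <- gauss_kernel(win_size, sigma)
  cs <- ssim_constants(data_range)
  d <- dim(ref)
  kt <- ag_const(array(K, c(win_size, win_size, 1L, 1L)))
  conv_valid <- function(t) ag_conv2d(t, kt, NULL, stride = 1L, pad = 0L)
  x4 <- ag_reshape(x, c(d[1], d[2], 1L, 1L))
  r4 <- ag_const(array(ref, c(d[1], d[2], 1L, 1L)))
  mx <- conv_valid(x4)
  my <- conv_valid(r4)
  sxx <- ag_sub(conv_valid(ag_mul(x4, x4)), ag_mul(mx, mx))
  syy <- ag_sub(conv_valid(ag_mul(r4, r4)), ag_mul(my, my))
  sxy <- ag_sub(conv_valid(ag_mul(x4, r4)), ag_mul(mx, my))
  num <- ag_mul(ag_add_const(ag_mul_const(ag_mul(mx, my), 2), cs$C1),
                ag_add_const(ag_mul_const(sxy, 2), cs$C2))
  den <- ag_mul(ag_add_const(ag_add(ag_mul(mx, mx), ag_mul(my, my)), cs$C1),
                ag_add_const(ag_add(sxx, syy), cs$C2))
  ag_mean(ag_div(num, den))
}

# Differentiable (1 - SSIM) + L1 against a constant reference.
training_loss_graph <- function(pred, ref, data_range) {
  s <- ssim_graph(pred, ref, data_range)
  l1 <- ag_mean(ag_abs(ag_sub(pred, ag_const(ref))))
  ag_add(ag_add_const(ag_mul_const(s, -1), 1), l1)
}
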