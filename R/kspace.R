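#' Centered orthonormal 2-D Fourier transform
#'
#' Transforms the first two array dimensions with the zero-frequency (DC)
#' component placed at the array center, using orthonormal `1/sqrt(n)` scaling
#' so that Parseval's identity holds exactly and `ifft2c(fft2c(x)) == x`.
#' Any trailing dimensions (coils, slices) are transformed independently.
#'
#' The center index convention follows the usual half-spectrum roll: for an
#' axis of length `n` the DC component lands at index `floor(n / 2) + 1`.
#'
#' @param x complex (or numeric) array with at least 2 dimensions; a plain
#'   matrix is treated as a single image.
#' @return complex array of the same shape.
#' @seealso [ifft2c()], [coil_reduce()], [apply_mask()]
#' @export
fft2c <- function(x) .fft2c_impl(x, inverse = FALSE)

#' Centered orthonormal inverse 2-D Fourier transform
#'
#' Inverse of [fft2c()]; maps centered k-space back to the image domain.
#'
#' @inheritParams fft2c
#' @return complex array of the same shape.
#' @export
ifft2c <- function(x) .fft2c_impl(x, inverse = TRUE)

.roll_idx <- function(n, k) ((seq_len(n) - 1L - k) %% n) + 1L

.fft2c_impl <- function(x, inverse) {
  d <- dim(x)
  if (is.null(d) || length(d) < 2L) stop("fft2c/ifft2c need an array with 2 spatial dims")
  h <- d[1]; w <- d[2]
  sh <- h %/% 2L; sw <- w %/% 2L
  pre_r <- .roll_idx(h, -sh); pre_c <- .roll_idx(w, -sw)   # ifftshift
  post_r <- .roll_idx(h, sh); post_c <- .roll_idx(w, sw)   # fftshift
  scale <- sqrt(h * w)
  n_rest <- if (length(d) > 2L) prod(d[-(1:2)]) else 1L
  xm <- x
  dim(xm) <- c(h, w, n_rest)
  out <- array(0i, c(h, w, n_rest))
  for (k in seq_len(n_rest)) {
    s <- xm[, , k][pre_r, pre_c]
    f <- stats::fft(s, inverse = inverse)
    out[, , k] <- f[post_r, post_c] / if (inverse) (h * w / scale) else scale
  }
  dim(out) <- d
  out
}

#' Combine coil k-space into a single complex image
#'
#' SENSE-style coil reduction: `I_red = sum_i ifft2c(k[, , i]) * Conj(S_i)`.
#' With sensitivities normalized to unit pixelwise energy this inverts
#' [coil_expand()] exactly.
#'
#' @param ku complex k-space array `(kx, ky, coil)`.
#' @param S complex coil sensitivity array `(h, w, coil)`.
#' @return complex matrix `(h, w)`.
#' @export
coil_reduce <- function(ku, S) {
  dk <- dim(ku); ds <- dim(S)
  if (length(dk) == 2L) { dim(ku) <- c(dk, 1L); dk <- dim(ku) }
  if (length(ds) == 2L) { dim(S) <- c(ds, 1L); ds <- dim(S) }
  if (!all(dk == ds)) stop("coil_reduce: k-space ", paste(dk, collapse = "x"),
                           " and sensitivities ", paste(ds, collapse = "x"), " differ")
  rowSums(ifft2c(ku) * Conj(S), dims = 2L)
}

#' Expand a single complex image to per-coil images
#'
#' Coil `i` of the result is the elementwise product `I * S[, , i]`.
#'
#' @param I complex matrix `(h, w)`.
#' @param S complex coil sensitivity array `(h, w, coil)`.
#' @return complex array `(h, w, coil)`.
#' @export
coil_expand <- function(I, S) {
  ds <- dim(S)
  if (length(ds) == 2L) { dim(S) <- c(ds, 1L); ds <- dim(S) }
  if (!all(dim(I) == ds[1:2])) stop("coil_expand: image and sensitivity shapes differ")
  S * as.vector(I)
}

#' Root-sum-of-squares coil combination
#'
#' Pixelwise `sqrt(sum_i |image_i|^2)`, the standard magnitude reference for
#' multi-coil MRI. Invariant under any global phase of the coil images.
#'
#' @param images complex (or real) array `(h, w, coil)`; a matrix is treated
#'   as a single coil.
#' @return nonnegative real matrix `(h, w)`.
#' @export
rss <- function(images) {
  d <- dim(images)
  if (length(d) == 2L) dim(images) <- c(d, 1L)
  if (dim(images)[3] < 1L) stop("rss: empty coil dimension")
  sqrt(rowSums(Re(images)^2 + Im(images)^2, dims = 2L))
}

#' Normalize coil sensitivities to unit pixelwise energy
#'
#' Divides each pixel's coil vector by `sqrt(sum_i |S_i|^2 + eps)` so that
#' `sum_i Conj(S_i) S_i = 1` wherever the raw maps carry energy. The relative
#' phases and magnitude ratios between coils are preserved. Pixels with zero
#' total energy map to zero (the regularizer prevents division by zero); the
#' attached `"valid"` attribute is a logical matrix flagging pixels with
#' energy above `eps`.
#'
#' @param raw complex array `(h, w, coil)` of unnormalized maps.
#' @param eps regularizer added inside the square root (default `1e-12`).
#' @return normalized complex array `(h, w, coil)` with a `"valid"` attribute.
#' @export
normalize_sensitivities <- function(raw, eps = 1e-12) {
  d <- dim(raw)
  if (length(d) == 2L) { dim(raw) <- c(d, 1L); d <- dim(raw) }
  energy <- rowSums(Re(raw)^2 + Im(raw)^2, dims = 2L)
  S <- raw / as.vector(sqrt(energy + eps))
  structure(S, valid = energy > eps)
}

#' Centered square crop of the spatial dimensions
#'
#' Crops the first two dimensions to a `target x target` block centered with
#' the floor convention: the first retained index is `floor((dim - target)/2)`
#' in 0-based terms. Used to remove frequency oversampling in the image
#' domain before re-transforming to k-space.
#'
#' @param x array with at least 2 dimensions (image, coil stack or volume).
#' @param target side length of the square crop; must not exceed either
#'   spatial dimension.
#' @return array of the same trailing shape with spatial dims `target x target`.
#' @export
crop_quadratic <- function(x, target) {
  d <- dim(x)
  if (is.null(d) || length(d) < 2L) stop("crop_quadratic needs an array")
  if (target > d[1] || target > d[2])
    stop("crop_quadratic: target ", target, " exceeds spatial dims ",
         d[1], "x", d[2])
  ri <- (d[1] - target) %/% 2L + seq_len(target)
  ci <- (d[2] - target) %/% 2L + seq_len(target)
  switch(length(d) - 1L,
    x[ri, ci, drop = FALSE],
    x[ri, ci, , drop = FALSE],
    x[ri, ci, , , drop = FALSE],
    stop("crop_quadratic supports up to 4-d arrays"))
}
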