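#' Equidistant Cartesian undersampling mask with a fully sampled center
#'
#' Builds a binary per-phase-encoding-line pattern: a contiguous central block
#' of `round(center_fraction * n_ky)` lines is always acquired (the
#' autocalibration region), and outside the center every `acceleration`-th
#' line is kept, i.e. 0-based line index `j` is sampled iff
#' `j %% acceleration == offset`. Fourfold acceleration pairs with an 8%
#' center and eightfold with a 4% center in the standard evaluation setup.
#'
#' With `exact_rate = TRUE` the spacing outside the center is widened instead
#' so that the total number of sampled lines is approximately
#' `n_ky / acceleration` (the convention of the fastMRI leaderboard masks);
#' the default keeps the literal every-n-th-line rule.
#'
#' @param n_ky number of phase-encoding lines (>= 8).
#' @param acceleration nominal acceleration factor R (>= 1).
#' @param center_fraction fraction of lines in the fully sampled center,
#'   in (0, 1).
#' @param offset 0-based residue of the sampled lines outside the center;
#'   must lie in `[0, acceleration)`.
#' @param exact_rate widen spacing so sampled lines total about `n_ky / R`.
#' @return object of class `"undersampling_mask"`: a list with `lines`
#'   (binary integer vector), `acceleration`, `center_fraction`, `offset`,
#'   `n_center`.
#' @examples
#' m <- make_equidistant_mask(100, 4, 0.08)
#' mask_stats(m)
#' @export
make_equidistant_mask <- function(n_ky, acceleration, center_fraction,
                                  offset = 0L, exact_rate = FALSE) {
  if (n_ky < 8L) stop("n_ky must be >= 8")
  if (acceleration < 1L) stop("acceleration must be >= 1")
  if (center_fraction <= 0 || center_fraction >= 1)
    stop("center_fraction must be in (0, 1)")
  n_center <- as.integer(round(center_fraction * n_ky))
  if (n_center < 1L) stop("center_fraction too small: no center lines")
  if (n_center > n_ky) stop("center wider than n_ky")
  if (offset < 0L || offset >= acceleration) stop("offset must be in [0, acceleration)")
  lines <- integer(n_ky)
  c0 <- (n_ky - n_center) %/% 2L
  center_idx <- c0 + seq_len(n_center)
  lines[center_idx] <- 1L
  if (!exact_rate) {
    j <- seq_len(n_ky) - 1L
    lines[j %% acceleration == offset] <- 1L
  } else {
    target_total <- max(n_center, as.integer(round(n_ky / acceleration)))
    extra <- target_total - n_center
    outside <- setdiff(seq_len(n_ky), center_idx)
    if (extra > 0L && length(outside) > 0L) {
      pick <- unique(as.integer(round(seq(1L, length(outside), length.out = extra))))
      lines[outside[pick]] <- 1L
    }
  }
  structure(list(lines = lines, acceleration = as.integer(acceleration),
                 center_fraction = center_fraction, offset = as.integer(offset),
                 n_center = n_center),
            class = "undersampling_mask")
}

#' Summary statistics of an undersampling mask
#'
#' Reports the center width, sampled-line count and fraction, and the
#' effective acceleration `n_ky / sampled_lines` (the conventional
#' total-over-sampled ratio; descriptions of the acceleration factor as a
#' masked-over-total ratio are its reciprocal complement and are not used
#' here).
#'
#' @param mask an `"undersampling_mask"`.
#' @return list with `n_ky`, `center_lines`, `sampled_lines`,
#'   `sampled_fraction`, `effective_acceleration`.
#' @export
mask_stats <- function(mask) {
  stopifnot(inherits(mask, "undersampling_mask"))
  n <- length(mask$lines)
  s <- sum(mask$lines)
  list(n_ky = n, center_lines = mask$n_center, sampled_lines = as.integer(s),
       sampled_fraction = s / n, effective_acceleration = n / s)
}

#' Apply an undersampling mask to k-space
#'
#' Zeroes the unsampled phase-encoding lines (axis 2) of a k-space array;
#' sampled lines pass through unchanged. Idempotent.
#'
#' @param k complex k-space array `(kx, ky)` or `(kx, ky, coil)`.
#' @param mask an `"undersampling_mask"` whose length matches `dim(k)[2]`.
#' @return masked k-space of the same shape.
#' @export
apply_mask <- function(k, mask) {
  stopifnot(inherits(mask, "undersampling_mask"))
  d <- dim(k)
  if (is.null(d)) stop("apply_mask: k must be an array")
  if (d[2] != length(mask$lines))
    stop("apply_mask: mask length ", length(mask$lines),
         " does not match n_ky ", d[2])
  m2 <- matrix(rep(mask$lines, each = d[1]), d[1], d[2])
  k * as.vector(m2)
}

# Binary (kx, ky) matrix form of a mask, broadcastable over coils.
mask_matrix <- function(mask, n_kx) {
  matrix(rep(mask$lines, each = n_kx), n_kx, length(mask$lines))
}

#' @export
print.undersampling_mask <- function(x, ...) {
  st <- mask_stats(x)
  cat(sprintf(
    "Equidistant undersampling mask: %d lines, R=%d, center %d lines (%.1f%%), sampled %d (effective R %.2f)\n",
    st$n_ky, x$acceleration, st$center_lines, 100 * x$center_fraction,
    st$sampled_lines, st$effective_acceleration))
  invisible(x)
}

# Center fraction conventionally paired with an acceleration factor.
default_center_fraction <- function(acceleration) {
  if (acceleration >= 8) 0.04 else 0.08
}
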