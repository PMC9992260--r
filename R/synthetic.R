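# Seeded multi-coil phantom simulator. The object is a piecewise-constant
# complex ellipse composite under a smooth phase field; per-coil complex
# sensitivity lobes with Gaussian magnitude and linear phase are normalized
# to unit pixelwise energy; fully sampled k-space is the centered orthonormal
# transform of each sensitivity-weighted coil image plus i.i.d. complex
# Gaussian noise. Frequency oversampling is emulated by generating a wider
# field of view and cropping in the image domain before re-transforming.

#' Specification of a synthetic multi-coil acquisition
#'
#' Draws a reproducible phantom description: ellipses (center, axes, angle,
#' complex amplitude), smooth phase-field coefficients, coil geometry and the
#' k-space noise level. Everything downstream ([make_phantom()],
#' [simulate_acquisition()]) is fully determined by this spec.
#'
#' @param seed integer seed; the returned specification is a pure function
#'   of it and the arguments.
#' @param size reconstructed image side (>= 16).
#' @param coils number of receiver coils.
#' @param n_ellipses number of ellipses (drawn `3:6` if `NULL`).
#' @param noise_sigma standard deviation of the real and imaginary parts of
#'   the additive complex Gaussian k-space noise.
#' @param oversample extra readout columns emulating frequency oversampling,
#'   removed by an image-domain quadratic crop.
#' @param coil_width Gaussian coil-profile width as a fraction of the image
#'   size.
#' @param ellipses explicit ellipse list (each with `cx`, `cy`, `a`, `b`,
#'   `angle`, `amp`) overriding the random draw.
#' @param phase_coef explicit length-4 phase-field coefficients overriding
#'   the random draw.
#' @return a `"phantom_spec"` list.
#' @export
phantom_spec <- function(seed, size = 64L, coils = 4L, n_ellipses = NULL,
                         noise_sigma = 0.01, oversample = 16L,
                         coil_width = 0.45, ellipses = NULL,
                         phase_coef = NULL) {
  if (size < 16L) stop("size must be >= 16")
  if (coils < 1L) stop("coils must be >= 1")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  old <- save_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  n_ell <- n_ellipses %||% sample(3:6, 1L)
  if (is.null(ellipses)) ellipses <- lapply(seq_len(n_ell), function(i) {
    list(cx = stats::runif(1, -0.45, 0.45), cy = stats::runif(1, -0.45, 0.45),
         a = stats::runif(1, 0.08, 0.45), b = stats::runif(1, 0.08, 0.45),
         angle = stats::runif(1, 0, pi),
         amp = complex(modulus = stats::runif(1, 0.3, 1),
                       argument = stats::runif(1, -pi / 4, pi / 4)))
  })
  structure(list(seed = as.integer(seed), size = as.integer(size),
                 coils = as.integer(coils), ellipses = ellipses,
                 phase_coef = phase_coef %||% stats::rnorm(4L, sd = 1.2),
                 noise_sigma = noise_sigma,
                 oversample = as.integer(oversample),
                 coil_width = coil_width),
            class = "phantom_spec")
}

save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv())
}
restore_rng_state <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Render the complex-valued phantom image
#'
#' Superposes the ellipse indicator functions weighted by their complex
#' amplitudes and multiplies by a smooth unit-magnitude phase field (a
#' low-order polynomial phase), at the oversampled width
#' `size x (size + oversample)`.
#'
#' @param spec a [phantom_spec()].
#' @return complex matrix `(size, size + oversample)`.
#' @export
make_phantom <- function(spec) {
  h <- spec$size; w <- spec$size + spec$oversample
  yy <- matrix(seq(-1, 1, length.out = h), h, w)
  xx <- matrix(rep(seq(-w / h, w / h, length.out = w), each = h), h, w)
  img <- matrix(0i, h, w)
  for (e in spec$ellipses) {
    if (e$a <= 0 || e$b <= 0) stop("degenerate ellipse axes")
    dx <- xx - e$cx; dy <- yy - e$cy
    u <- cos(e$angle) * dx + sin(e$angle) * dy
    v <- -sin(e$angle) * dx + cos(e$angle) * dy
    img <- img + e$amp * ((u / e$a)^2 + (v / e$b)^2 <= 1)
  }
  p <- spec$phase_coef
  phase <- p[1] * xx + p[2] * yy + p[3] * xx * yy + p[4] * (xx^2 - yy^2)
  img * exp(1i * phase)
}

#' Smooth complex coil sensitivity maps
#'
#' Places `c` Gaussian magnitude lobes at points spread around the field of
#' view, each with a coil-specific linear phase ramp, and normalizes the
#' stack to unit pixelwise energy with [normalize_sensitivities()].
#'
#' @param coils number of coils.
#' @param h,w spatial dimensions.
#' @param profile_width Gaussian width as a fraction of `min(h, w)`.
#' @param seed seed for the per-coil phase-ramp coefficients.
#' @return normalized complex array `(h, w, coils)`.
#' @export
make_coil_maps <- function(coils, h, w, profile_width = 0.45, seed = 0L) {
  old <- save_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(rep(seq_len(w), each = h), h, w)
  sig <- profile_width * min(h, w)
  raw <- array(0i, c(h, w, coils))
  for (k in seq_len(coils)) {
    th <- 2 * pi * (k - 1) / coils
    cx <- (w + 1) / 2 + 0.45 * w * cos(th)
    cy <- (h + 1) / 2 + 0.45 * h * sin(th)
    mag <- exp(-((xx - cx)^2 + (yy - cy)^2) / (2 * sig^2))
    ramp <- stats::rnorm(2L, sd = 2 * pi / max(h, w))
    raw[, , k] <- mag * exp(1i * (ramp[1] * xx + ramp[2] * yy))
  }
  normalize_sensitivities(raw)
}

#' Simulate a fully sampled multi-coil acquisition
#'
#' Per coil: `k_i = fft2c(S_i * x) + eps` with i.i.d. complex Gaussian noise
#' (`noise_sigma` per real/imaginary component).
#'
#' @param phantom complex image `(h, w)`.
#' @param S normalized coil sensitivities `(h, w, coil)`.
#' @param noise_sigma noise standard deviation per component.
#' @param seed seed for the noise draw.
#' @return complex k-space array `(h, w, coil)`.
#' @export
simulate_acquisition <- function(phantom, S, noise_sigma = 0, seed = 0L) {
  if (!all(dim(phantom) == dim(S)[1:2]))
    stop("simulate_acquisition: phantom and sensitivity shapes differ")
  k <- fft2c(coil_expand(phantom, S))
  if (noise_sigma > 0) {
    old <- save_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
    n <- length(k)
    k <- k + complex(real = stats::rnorm(n, sd = noise_sigma),
                     imaginary = stats::rnorm(n, sd = noise_sigma))
  }
  k
}

# One volume: k-space (kx, ky, coil, slice), ground truth (h, w, slice).
# coil_seed fixes the receive-array geometry: one scanner's coil maps are
# shared by every slice and volume of a dataset.
simulate_volume <- function(seed, slices, size, coils, noise_sigma, contrast,
                            coil_seed = seed) {
  ks <- array(0i, c(size, size, coils, slices))
  gt <- array(0, c(size, size, slices))
  for (s in seq_len(slices)) {
    spec <- phantom_spec(seed + 7919L * s, size = size, coils = coils,
                         noise_sigma = noise_sigma)
    ph <- make_phantom(spec)
    S_full <- make_coil_maps(coils, nrow(ph), ncol(ph),
                             profile_width = spec$coil_width,
                             seed = coil_seed)
    # image-domain quadratic crop removes the oversampled columns,
    # then transform back to k-space (preprocessing path)
    coil_imgs <- crop_quadratic(coil_expand(ph, S_full), size)
    gt[, , s] <- rss(coil_imgs)
    k <- fft2c(coil_imgs)
    if (noise_sigma > 0) {
      old <- save_rng_state()
      set.seed(spec$seed + 2L)
      n <- length(k)
      k <- k + complex(real = stats::rnorm(n, sd = noise_sigma),
                       imaginary = stats::rnorm(n, sd = noise_sigma))
      restore_rng_state(old)
    }
    ks[, , , s] <- k
  }
  structure(list(kspace = ks, reconstruction_rss = gt, contrast = contrast,
                 noise_sigma = noise_sigma, seed = seed),
            class = "mri_volume")
}

#' Generate a directory of synthetic multi-coil volumes
#'
#' Writes `n_volumes` files (`vol_001.rds`, ...), each holding fully sampled
#' complex k-space `(kx, ky, coil, slice)` and the ground-truth
#' root-sum-of-squares magnitude volume of the noiseless coil images,
#' with contrast labels cycling through T1, T2 and FLAIR. Fully reproducible
#' from `seed`.
#'
#' @param path output directory (created if needed).
#' @param n_volumes number of volumes (>= 1).
#' @param slices_per_volume slices per volume.
#' @param size image side length.
#' @param coils receiver coils.
#' @param noise_sigma k-space noise level per component.
#' @param seed master seed for phantoms and noise.
#' @param coil_seed seed of the receive-array geometry. All slices and
#'   volumes of a dataset share one coil array (a single emulated scanner);
#'   the default is the same for every dataset, so training and held-out
#'   splits are acquired on the same array, as in a single-site study.
#' @return invisibly, the vector of file paths.
#' @export
make_dataset <- function(path, n_volumes, slices_per_volume = 4L, size = 64L,
                         coils = 4L, noise_sigma = 0.01, seed = 0L,
                         coil_seed = 0L) {
  if (n_volumes < 1L) stop("n_volumes must be >= 1")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  contrasts <- c("T1", "T2", "FLAIR")
  files <- character(n_volumes)
  for (v in seq_len(n_volumes)) {
    vol <- simulate_volume(seed + 104729L * v, slices_per_volume, size, coils,
                           noise_sigma, contrasts[(v - 1L) %% 3L + 1L],
                           coil_seed = coil_seed)
    files[v] <- file.path(path, sprintf("vol_%03d.rds", v))
    saveRDS(vol, files[v])
  }
  invisible(files)
}

#' Read a stored synthetic volume
#'
#' @param path path to a volume file written by [make_dataset()].
#' @return an `"mri_volume"` list with `kspace`, `reconstruction_rss`,
#'   `contrast`.
#' @export
read_volume <- function(path) {
  vol <- readRDS(path)
  if (!inherits(vol, "mri_volume")) stop("not an mri_volume file: ", path)
  vol
}
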