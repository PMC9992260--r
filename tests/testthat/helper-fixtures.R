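# Shared helpers: random complex arrays, numeric gradients, tiny fixtures.

rand_complex <- function(...) {
  d <- c(...)
  array(complex(real = rnorm(prod(d)), imaginary = rnorm(prod(d))), d)
}

rand_real <- function(...) {
  d <- c(...)
  array(rnorm(prod(d)), d)
}

# Central finite differences of a scalar function of an array.
num_grad <- function(fn, x, eps = 1e-5) {
  g <- array(0, dim(x) %||% length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (fn(xp) - fn(xm)) / (2 * eps)
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Analytic-vs-numeric gradient comparison for a scalar-valued graph function.
expect_gradcheck <- function(fn_ag, x0, tol = 1e-4) {
  dircn:::ag_tape_reset()
  xt <- dircn:::ag_param(x0)
  loss <- fn_ag(xt)
  dircn:::ag_backward(loss)
  ga <- xt$grad
  gn <- num_grad(function(x) dircn:::ag_no_grad(fn_ag(dircn:::ag_const(x))$value), x0)
  expect_lt(max(abs(ga - gn)) / max(1e-8, max(abs(gn))), tol)
}

# A small undersampled slice plus ground truth from the simulator.
tiny_slice <- function(seed = 1, size = 32L, coils = 3L, R = 4L) {
  dir <- file.path(tempdir(), paste0("vols_", seed, "_", size, "_", coils))
  if (!dir.exists(dir))
    make_dataset(dir, 1, slices_per_volume = 1L, size = size, coils = coils,
                 noise_sigma = 0.005, seed = seed)
  vol <- read_volume(list.files(dir, full.names = TRUE)[1])
  mask <- make_equidistant_mask(size, R, default_center_fraction_(R))
  list(ku = apply_mask(vol$kspace[, , , 1], mask), mask = mask,
       gt = vol$reconstruction_rss[, , 1], kfull = vol$kspace[, , , 1])
}

default_center_fraction_ <- function(R) if (R >= 8) 0.04 else 0.08

tiny_model <- function(preset = "reference", seed = 1, m = 1L, base = 4L,
                       depth = 2L, ...) {
  set.seed(seed)
  build_model(model_config(preset, m = m, base = base, depth = depth,
                           sens_base = 4L, ...))
}
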