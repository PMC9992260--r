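# Finite-difference validation of the reverse-mode engine on every operation
# the reconstruction network uses, including the complex-valued chain through
# the Fourier and data-consistency layers.

ag <- function(name) get(name, envir = asNamespace("dircn"))

test_that("convolution gradients match finite differences", {
  set.seed(31)
  x0 <- rand_real(5, 5, 4, 2)
  w0 <- rand_real(3, 3, 4, 3)
  b0 <- rnorm(3)
  conv <- ag("ag_conv2d"); amean <- ag("ag_mean"); amul <- ag("ag_mul")
  cst <- ag("ag_const")
  expect_gradcheck(function(x) {
    y <- conv(x, cst(w0), cst(b0))
    amean(amul(y, y))
  }, x0)
  expect_gradcheck(function(w) {
    y <- conv(cst(x0), w, cst(b0))
    amean(amul(y, y))
  }, w0)
  expect_gradcheck(function(b) {
    y <- conv(cst(x0), cst(w0), b)
    amean(amul(y, y))
  }, b0)
  # grouped, strided
  w2 <- rand_real(3, 3, 2, 6)
  expect_gradcheck(function(x) {
    y <- conv(x, cst(w2), NULL, stride = 2L, groups = 2L)
    amean(amul(y, y))
  }, x0)
  expect_gradcheck(function(w) {
    y <- conv(cst(x0), w, NULL, stride = 2L, groups = 2L)
    amean(amul(y, y))
  }, w2)
})

test_that("normalization, activation and pooling gradients are exact", {
  set.seed(32)
  x0 <- rand_real(5, 5, 3, 2)
  g0 <- rnorm(3); b0 <- rnorm(3)
  instnorm <- ag("ag_instnorm"); amean <- ag("ag_mean"); amul <- ag("ag_mul")
  cst <- ag("ag_const")
  expect_gradcheck(function(x) {
    y <- instnorm(x, cst(g0), cst(b0))
    amean(amul(y, y))
  }, x0, tol = 5e-4)
  expect_gradcheck(function(g) amean(amul(instnorm(cst(x0), g, cst(b0)),
                                          instnorm(cst(x0), g, cst(b0)))), g0)
  v0 <- rnorm(15)
  asum <- ag("ag_sum")
  expect_gradcheck(function(x) asum(amul(ag("ag_silu")(x), ag("ag_silu")(x))), v0)
  expect_gradcheck(function(x) asum(ag("ag_sigmoid")(x)), v0)
  expect_gradcheck(function(x) asum(ag("ag_relu")(amul(x, x))), v0)
  expect_gradcheck(function(x) asum(ag("ag_sqrt")(ag("ag_add_const")(amul(x, x), 0.1))), v0)
  expect_gradcheck(function(x) asum(amul(ag("ag_global_mean")(x), ag("ag_global_mean")(x))), x0)
})

test_that("shape ops (upsample, pad, crop, concat) backpropagate correctly", {
  set.seed(33)
  x0 <- rand_real(6, 6, 3, 2)
  amean <- ag("ag_mean"); amul <- ag("ag_mul")
  up <- ag("ag_upsample2"); padr <- ag("ag_pad_reflect")
  cropo <- ag("ag_crop_offset"); cat3 <- ag("ag_concat_ch")
  expect_gradcheck(function(x) amean(amul(up(x), up(x))), x0)
  expect_gradcheck(function(x) amean(amul(padr(x, 2L, 3L), padr(x, 2L, 3L))), x0)
  expect_gradcheck(function(x) amean(amul(cropo(x, 1L, 2L, 4L, 3L),
                                          cropo(x, 1L, 2L, 4L, 3L))), x0)
  expect_gradcheck(function(x) {
    y <- cat3(list(x, amul(x, x)))
    amean(amul(y, y))
  }, x0)
})

test_that("complex chain through FFT, masking and data consistency is exact", {
  set.seed(34)
  ku <- rand_complex(6, 6, 2)
  mk <- matrix(rbinom(36, 1, 0.5), 6, 6)
  xr <- rand_real(6, 6, 2, 2)
  c2x <- ag("ag_channels_to_complex"); fft <- ag("ag_fft2c")
  iff <- ag("ag_ifft2c"); dc <- ag("ag_dc"); modsq <- ag("ag_cmodsq")
  sumc <- ag("ag_sum_coils"); sq <- ag("ag_sqrt"); addc <- ag("ag_add_const")
  amean <- ag("ag_mean"); cst <- ag("ag_const")
  expect_gradcheck(function(x) {
    z <- c2x(x)
    k2 <- dc(fft(z), cst(0.3), ku, mk)
    amean(sq(addc(sumc(modsq(iff(k2))), 1e-12)))
  }, xr)
  # gradient w.r.t. the data-consistency weight itself
  expect_gradcheck(function(l) {
    k2 <- dc(fft(c2x(cst(xr))), l, ku, mk)
    amean(modsq(k2))
  }, 0.3)
})

test_that("coil broadcast ops carry conjugate-correct adjoints", {
  set.seed(35)
  S0 <- rand_complex(6, 6, 3)
  Sr <- rand_real(6, 6, 2, 3)
  rr <- matrix(abs(rnorm(36)) + 0.5, 6, 6)
  c2x <- ag("ag_channels_to_complex"); amean <- ag("ag_mean")
  modsq <- ag("ag_cmodsq"); cst <- ag("ag_const")
  expandc <- ag("ag_expand_coils"); cws <- ag("ag_coilwise_scale")
  z0 <- matrix(complex(real = rnorm(36), imaginary = rnorm(36)), 6, 6)
  expect_gradcheck(function(x) {
    z <- ag("ag_reshape")(c2x(x), c(6, 6))
    amean(modsq(expandc(z, cst(S0))))
  }, rand_real(6, 6, 2, 1))
  expect_gradcheck(function(x) amean(modsq(expandc(cst(z0), c2x(x)))), Sr)
  expect_gradcheck(function(x) amean(modsq(cws(c2x(x), cst(rr)))), Sr)
  expect_gradcheck(function(r) amean(modsq(cws(cst(S0), r))), rr)
  # full sensitivity-normalization chain
  sumc <- ag("ag_sum_coils"); sq <- ag("ag_sqrt"); addc <- ag("ag_add_const")
  dv <- ag("ag_div"); aim <- ag("ag_im")
  expect_gradcheck(function(x) {
    S <- c2x(x)
    inv <- dv(cst(matrix(1, 6, 6)), sq(addc(sumc(modsq(S)), 1e-12)))
    amean(aim(cws(S, inv)))
  }, Sr)
})

test_that("inference mode records no tape and training mode frees it", {
  set.seed(36)
  tape_len <- function() get(".ag", envir = asNamespace("dircn"))$n
  cst <- ag("ag_const"); amul <- ag("ag_mul")
  dircn:::ag_tape_reset()
  p <- dircn:::ag_param(rand_real(3, 3, 1, 1))
  dircn:::ag_no_grad(amul(p, p))
  expect_equal(tape_len(), 0L)
  y <- ag("ag_mean")(amul(p, p))
  expect_gt(tape_len(), 0L)
  dircn:::ag_backward(y)
  expect_equal(tape_len(), 0L)
  expect_equal(p$grad, 2 * p$value / 9, tolerance = 1e-12)
})
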