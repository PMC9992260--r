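ag_c <- function(x) dircn:::ag_const(x)

test_that("se_block matches a hand computation and can only shrink channels", {
  set.seed(41)
  blk <- new_se_block(2L, reduction = 1L)
  # force tiny, known excitation weights
  blk$fc1$W$value <- matrix(c(0.1, -0.2, 0.3, 0.05), 2, 2)
  blk$fc1$b$value <- c(0.01, -0.02)
  blk$fc2$W$value <- matrix(c(0.2, 0.1, -0.1, 0.4), 2, 2)
  blk$fc2$b$value <- c(0.05, 0)
  x <- array(c(1.5, -0.5), c(1, 1, 2, 1))
  y <- dircn:::ag_no_grad(forward(blk, ag_c(x))$value)
  # by hand: squeeze = (1.5, -0.5); silu(W1 s + b1); sigmoid(W2 h + b2); scale
  s <- c(1.5, -0.5)
  h <- blk$fc1$W$value %*% s + blk$fc1$b$value
  h <- h / (1 + exp(-h))
  e <- 1 / (1 + exp(-(blk$fc2$W$value %*% h + blk$fc2$b$value)))
  expect_equal(as.vector(y), s * as.vector(e), tolerance = 1e-12)
  # saturation: huge excitation bias drives the gate to 1, y -> x
  blk$fc2$b$value <- c(50, 50)
  x2 <- rand_real(4, 4, 2, 1)
  y2 <- dircn:::ag_no_grad(forward(blk, ag_c(x2))$value)
  expect_lt(max(abs(y2 - x2)), 1e-8)
  # the sigmoid gate is at most 1: never amplifies a channel
  set.seed(42)
  blk2 <- new_se_block(4L, reduction = 2L)
  x3 <- rand_real(5, 5, 4, 2)
  y3 <- dircn:::ag_no_grad(forward(blk2, ag_c(x3))$value)
  expect_true(all(abs(y3) <= abs(x3) + 1e-12))
  expect_error(forward(blk2, ag_c(rand_real(5, 5, 3, 1))), "channel")
})

test_that("residual block is the exact identity when its branch is zeroed", {
  set.seed(43)
  blk <- new_res_block(4L, cardinality = 2L, se_reduction = 2L)
  for (nm in c("conv1", "conv2")) {
    blk[[nm]]$w$value[] <- 0
    blk[[nm]]$b$value[] <- 0
  }
  x <- rand_real(6, 6, 4, 2)
  y <- dircn:::ag_no_grad(forward(blk, ag_c(x))$value)
  expect_identical(dim(y), dim(x))
  expect_lt(max(abs(y - x)), 1e-12)
  # with the branch zeroed the loss gradient passes through unchanged
  dircn:::ag_tape_reset()
  xt <- dircn:::ag_param(x)
  loss <- dircn:::ag_mean(dircn:::ag_mul(forward(blk, xt), ag_c(x)))
  dircn:::ag_backward(loss)
  expect_equal(xt$grad, array(x / length(x), dim(x)), tolerance = 1e-12)
})

test_that("subnet forward preserves shape and emits per-resolution packets", {
  set.seed(44)
  net <- resxunet(base = 4L, depth = 3L, cardinality = 2L, se_reduction = 2L)
  x <- rand_real(32, 32, 2, 1)
  res <- dircn:::ag_no_grad(forward(net, ag_c(x)))
  expect_identical(dim(res$out$value), c(32L, 32L, 2L, 1L))
  expect_length(res$interconnect_out, 3L)
  dims <- vapply(res$interconnect_out, function(t) dim(t$value)[1], 0L)
  expect_equal(dims, c(32L, 16L, 8L))
  chans <- vapply(res$interconnect_out, function(t) dim(t$value)[3], 0L)
  expect_equal(chans, c(4L, 8L, 16L))
  # determinism
  res2 <- dircn:::ag_no_grad(forward(net, ag_c(x)))
  expect_identical(res$out$value, res2$out$value)
  # non-dyadic sizes are padded internally and cropped back
  x2 <- rand_real(30, 26, 2, 1)
  out2 <- dircn:::ag_no_grad(forward(net, ag_c(x2))$out$value)
  expect_identical(dim(out2), c(30L, 26L, 2L, 1L))
})

test_that("interconnect packets are consumed at matching resolutions", {
  set.seed(45)
  a <- resxunet(base = 4L, depth = 3L, cardinality = 2L, se_reduction = 2L)
  b <- resxunet(base = 4L, depth = 3L, cardinality = 2L, se_reduction = 2L,
                interconnect = TRUE)
  x <- rand_real(16, 16, 2, 1)
  pk <- dircn:::ag_no_grad(forward(a, ag_c(x)))$interconnect_out
  out <- dircn:::ag_no_grad(forward(b, ag_c(x), interconnect_in = pk)$out$value)
  expect_identical(dim(out), c(16L, 16L, 2L, 1L))
  expect_error(forward(b, ag_c(x), interconnect_in = pk[1:2]), "resolution")
  expect_error(forward(a, ag_c(x), interconnect_in = pk), "without interconnect")
})

test_that("plain U-Net has strictly fewer parameters than ResXUNet", {
  set.seed(46)
  u <- unet(base = 8L, depth = 3L)
  r <- resxunet(base = 8L, depth = 3L, cardinality = 2L, se_reduction = 4L)
  expect_lt(count_parameters(u), count_parameters(r))
  # determinism of construction given the seed
  set.seed(46)
  u2 <- unet(base = 8L, depth = 3L)
  expect_identical(parameters(u)[["p.stem.conv.w"]]$value,
                   parameters(u2)[["p.stem.conv.w"]]$value)
})

test_that("every subnet parameter receives gradient from a generic loss", {
  set.seed(47)
  net <- resxunet(base = 4L, depth = 2L, cardinality = 2L, se_reduction = 2L,
                  interconnect = TRUE)
  x <- rand_real(8, 8, 2, 1)
  pk_src <- resxunet(base = 4L, depth = 2L, cardinality = 2L, se_reduction = 2L)
  pk <- forward(pk_src, ag_c(x))$interconnect_out
  params <- parameters(net)
  dircn:::zero_grads(params)
  dircn:::ag_tape_reset()
  out <- forward(net, ag_c(x), interconnect_in = pk)$out
  loss <- dircn:::ag_mean(dircn:::ag_mul(out, out))
  dircn:::ag_backward(loss)
  got <- vapply(params, function(p) !is.null(p$grad) && any(p$grad != 0), TRUE)
  expect_true(all(got))
})

test_that("batched forward equals per-sample forwards (no cross-talk)", {
  set.seed(48)
  net <- resxunet(base = 4L, depth = 2L, cardinality = 2L, se_reduction = 2L)
  x1 <- rand_real(8, 8, 2, 1)
  x2 <- rand_real(8, 8, 2, 1)
  xb <- array(c(x1, x2), c(8, 8, 2, 2))
  yb <- dircn:::ag_no_grad(forward(net, ag_c(xb))$out$value)
  y1 <- dircn:::ag_no_grad(forward(net, ag_c(x1))$out$value)
  y2 <- dircn:::ag_no_grad(forward(net, ag_c(x2))$out$value)
  expect_lt(max(abs(yb[, , , 1] - y1[, , , 1])), 1e-10)
  expect_lt(max(abs(yb[, , , 2] - y2[, , , 1])), 1e-10)
})

test_that("sensitivity estimation reduces to the center-crop oracle", {
  set.seed(49)
  sl <- tiny_slice(seed = 3, size = 32L, coils = 3L)
  S <- estimate_sensitivities(sl$ku, sl$mask)  # identity refinement
  # oracle: zero all but the center block, per-coil ifft, normalize
  nc <- sl$mask$n_center
  c0 <- (32L - nc) %/% 2L
  kc <- array(0i, dim(sl$ku))
  kc[, c0 + seq_len(nc), ] <- sl$ku[, c0 + seq_len(nc), ]
  Sref <- normalize_sensitivities(ifft2c(kc))
  expect_lt(max(Mod(S - Sref)), 1e-10)
  energy <- rowSums(Mod(S)^2, dims = 2)
  expect_lt(max(abs(energy - 1)), 1e-5)
  # refined estimation also returns unit-energy maps for any coil count
  set.seed(50)
  net <- resxunet(base = 4L, depth = 2L, cardinality = 2L, se_reduction = 2L)
  S2 <- estimate_sensitivities(sl$ku, sl$mask, net)
  expect_lt(max(abs(rowSums(Mod(S2)^2, dims = 2) - 1)), 1e-5)
  # single coil: unit magnitude (up to the division regularizer, which only
  # bites at pixels whose center-reconstruction energy is itself vanishing)
  s1 <- estimate_sensitivities(sl$ku[, , 1, drop = FALSE], sl$mask)
  expect_lt(max(abs(Mod(s1) - 1)), 1e-3)
  expect_lt(stats::median(abs(Mod(s1) - 1)), 1e-7)
})
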