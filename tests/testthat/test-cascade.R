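test_that("data consistency blends sampled lines and passes unsampled ones", {
  set.seed(51)
  m <- make_equidistant_mask(16, 4, 0.25)
  kp <- rand_complex(16, 16, 2)
  ku <- rand_complex(16, 16, 2)
  # the lam -> 0 limit restores the measurements exactly
  out0 <- data_consistency(kp, ku, m, 0)
  on <- m$lines == 1
  expect_equal(out0[, on, ], ku[, on, ])
  expect_equal(out0[, !on, ], kp[, !on, ])
  # fixed point: a prediction equal to the measurement is untouched
  expect_equal(data_consistency(ku, ku, m, 0.37), ku, tolerance = 1e-12)
  # printed blend value at lambda = 0.01: (1 + 0.01*0)/1.01
  one <- matrix(1 + 0i, 16, 16)
  blend <- data_consistency(matrix(0i, 16, 16), one, m, 0.01)
  expect_equal(Re(blend[1, which(on)[1]]), 1 / 1.01, tolerance = 1e-12)
  expect_equal(Re(blend[1, which(on)[1]]), 0.990099, tolerance = 1e-6)
  # idempotence at lam = 0
  expect_equal(data_consistency(out0, ku, m, 0), out0, tolerance = 1e-12)
  expect_error(data_consistency(kp[, , 1], ku, m, 0.01), "mismatch")
})

test_that("run_cascade equals the manually chained five-step composition", {
  set.seed(52)
  sl <- tiny_slice(seed = 4, size = 32L, coils = 3L)
  model <- tiny_model("reference", seed = 52, m = 1L, base = 4L, depth = 2L)
  S <- estimate_sensitivities(sl$ku, sl$mask, model$sens_net)
  st <- run_cascade(new_cascade_state(sl$ku), S, sl$ku, sl$mask,
                    model$cascades[[1]], model$config)
  # manual chain: reduce -> CNN -> expand -> transform -> data consistency
  I_red <- coil_reduce(sl$ku, S)
  x <- array(0, c(32, 32, 2, 1))
  x[, , 1, 1] <- Re(I_red); x[, , 2, 1] <- Im(I_red)
  out <- dircn:::ag_no_grad(
    forward(model$cascades[[1]]$subnet, dircn:::ag_const(x))$out$value)
  I_rec <- out[, , 1, 1] + 1i * out[, , 2, 1]
  kp <- fft2c(coil_expand(I_rec, S))
  kdc <- data_consistency(kp, sl$ku, sl$mask, model$cascades[[1]]$lam$value)
  expect_lt(max(Mod(st$k_current - kdc)), 1e-10)
  expect_lt(max(Mod(st$kp - kp)), 1e-10)
  expect_length(st$reduced_history, 1L)
  expect_lt(max(Mod(st$reduced_history[[1]] - I_red)), 1e-10)
})

test_that("dense connections concatenate the full coil-reduced history", {
  model <- tiny_model("dense", seed = 53, m = 3L, base = 4L, depth = 2L)
  expect_equal(vapply(model$cascades, function(cs) cs$subnet$in_ch, 0L),
               c(2L, 4L, 6L))
  sl <- tiny_slice(seed = 5, size = 16L, coils = 2L)
  S <- estimate_sensitivities(sl$ku, sl$mask, model$sens_net)
  st <- new_cascade_state(sl$ku)
  for (k in 1:3)
    st <- run_cascade(st, S, sl$ku, sl$mask, model$cascades[[k]], model$config)
  expect_length(st$reduced_history, 3L)
})

test_that("presets resolve to the documented flag combinations", {
  expect_equal(model_config("reference")[c("subnet", "dense", "interconnect")],
               list(subnet = "unet", dense = FALSE, interconnect = FALSE))
  expect_equal(model_config("dircn")[c("subnet", "dense", "interconnect")],
               list(subnet = "resxunet", dense = TRUE, interconnect = TRUE))
  expect_equal(model_config("dense")$dense, TRUE)
  expect_equal(model_config("interconnections")$interconnect, TRUE)
  expect_equal(model_config("resxunet")$subnet, "resxunet")
  # the study-scale preset unrolls 12 cascades
  expect_equal(model_config("reference", scale = "full")$m, 12L)
  expect_error(model_config("nope"), "unknown preset")
  # switching all flags off reproduces the reference architecture exactly
  set.seed(54)
  ref <- build_model(model_config("reference", m = 2L, base = 4L, depth = 2L,
                                  sens_base = 4L))
  set.seed(54)
  manual <- build_model(model_config(subnet = "unet", dense = FALSE,
                                     interconnect = FALSE, m = 2L, base = 4L,
                                     depth = 2L, sens_base = 4L))
  expect_identical(names(parameters(ref)), names(parameters(manual)))
  expect_identical(parameters(ref)[[10]]$value, parameters(manual)[[10]]$value)
})

test_that("parameter counts match closed-form layer arithmetic", {
  cv <- dircn:::new_conv(2L, 4L, 3L)
  expect_equal(count_parameters(cv), 3 * 3 * 2 * 4 + 4)  # = 76
  # tiny U-Net, closed form per layer
  set.seed(55)
  u <- unet(in_ch = 2L, out_ch = 2L, base = 4L, depth = 2L)
  conv_n <- function(cin, cout, k) k * k * cin * cout + cout
  norm_n <- function(c) 2 * c
  dc_n <- function(cin, cout) conv_n(cin, cout, 3) + norm_n(cout) +
    conv_n(cout, cout, 3) + norm_n(cout)
  expected <- conv_n(2, 4, 3) + norm_n(4) +          # stem
    dc_n(4, 4) + dc_n(8, 8) +                        # encoder levels
    conv_n(4, 8, 3) + norm_n(8) +                    # downsample
    conv_n(8, 4, 3) + norm_n(4) +                    # up projection
    conv_n(8, 4, 3) + norm_n(4) +                    # skip fusion
    dc_n(4, 4) +                                     # decoder level
    conv_n(4, 2, 1)                                  # head
  expect_equal(count_parameters(u), expected)
  # interconnections can only add parameters at matched width
  set.seed(56)
  rx <- build_model(model_config("resxunet", m = 2L, base = 4L, depth = 2L,
                                 cardinality = 2L, se_reduction = 2L,
                                 sens_base = 4L))
  set.seed(56)
  dx <- build_model(model_config("dircn", m = 2L, base = 4L, depth = 2L,
                                 cardinality = 2L, se_reduction = 2L,
                                 sens_base = 4L))
  expect_gte(count_parameters(dx), count_parameters(rx))
  # every learnable data-consistency weight is counted
  expect_equal(count_parameters(rx) -
                 sum(vapply(parameters(rx), function(p) length(p$value), 0)), 0)
})

test_that("reconstruct returns a nonnegative image obeying the DC blend", {
  set.seed(57)
  sl <- tiny_slice(seed = 6, size = 32L, coils = 3L)
  model <- tiny_model("reference", seed = 57, m = 2L, base = 4L, depth = 2L)
  img <- reconstruct(model, sl$ku, sl$mask)
  expect_identical(dim(img), c(32L, 32L))
  expect_true(all(img >= 0))
  # untrained model, lambda = 0.01: the final k-space at sampled lines is the
  # Eq-style blend of the measurement and the cascade's pre-DC prediction
  fm <- dircn:::ag_no_grad(dircn:::forward_model(model, sl$ku, sl$mask))
  kdc <- fm$k_dc$value
  kp <- fm$kp_last$value
  lam <- model$cascades[[2]]$lam$value
  on <- sl$mask$lines == 1
  blend <- (sl$ku[, on, ] + lam * kp[, on, ]) / (1 + lam)
  expect_lt(max(Mod(kdc[, on, ] - blend)), 1e-10)
  expect_lt(max(Mod(kdc[, !on, ] - kp[, !on, ])), 1e-10)
})

test_that("one built model reconstructs any coil count", {
  model <- tiny_model("dircn", seed = 58, m = 2L, base = 4L, depth = 2L,
                      cardinality = 2L, se_reduction = 2L)
  for (coils in c(2L, 6L)) {
    sl <- tiny_slice(seed = 60 + coils, size = 16L, coils = coils)
    img <- reconstruct(model, sl$ku, sl$mask)
    expect_identical(dim(img), c(16L, 16L))
    expect_true(all(is.finite(img)))
  }
})
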