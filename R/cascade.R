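#' Soft k-space data consistency
#'
#' Blends a predicted k-space with the measured samples: at sampled lines the
#' output is `(ku + lambda * kp) / (1 + lambda)`, at unsampled lines the
#' prediction passes through. As `lambda -> 0` the sampled lines are replaced
#' by the measurements exactly; `lambda` is a learnable scalar inside a built
#' model, initialized to 0.01.
#'
#' @param kp predicted complex k-space `(kx, ky[, coil])`.
#' @param ku measured (masked) complex k-space, same shape.
#' @param mask the `"undersampling_mask"` marking the measured lines.
#' @param lam nonnegative blending weight.
#' @return complex array of the same shape.
#' @export
data_consistency <- function(kp, ku, mask, lam) {
  if (!identical(dim(kp), dim(ku))) stop("data_consistency: shape mismatch")
  d <- dim(kp)
  m <- as.vector(mask_matrix(mask, d[1]))
  blend <- (ku + lam * kp) / (1 + lam)
  kp * (1 - m) + blend * m
}

#' Model configuration for the cascading reconstruction network
#'
#' Assembles the variant flags and sub-network hyperparameters. The five
#' named presets map onto the ablation grid: `"reference"` (plain U-Net
#' cascades), `"dense"` (U-Net + input-level dense connections),
#' `"resxunet"` (SE residual U-Net sub-networks), `"interconnections"`
#' (U-Net + long-range skip connections between sub-networks) and `"dircn"`
#' (all three extensions). Flags are strictly additive: switching them all
#' off recovers the reference composition.
#'
#' `scale = "tiny"` (2 cascades, depth 3, 8 base channels) is sized for CPU
#' experiments; `scale = "full"` uses 12 cascades, depth 4 and widths that
#' bring the total parameter budget to roughly 45 million (the study-scale
#' configuration).
#'
#' @param preset one of `"reference"`, `"dense"`, `"resxunet"`,
#'   `"interconnections"`, `"dircn"`, or `NULL` to set flags manually.
#' @param m number of cascades.
#' @param subnet `"unet"` or `"resxunet"`.
#' @param dense enable input-level dense connections (the k-th sub-network
#'   sees the concatenated coil-reduced inputs of all prior cascades, newest
#'   first: 2k real channels).
#' @param interconnect enable per-resolution feature-map hand-over between
#'   consecutive sub-networks.
#' @param lambda_init initial data-consistency weight (> 0).
#' @param base,depth,cardinality,se_reduction sub-network width, number of
#'   resolutions, aggregated-convolution groups and SE reduction.
#' @param sens_base width of the sensitivity-estimation network (defaults to
#'   half `base`; same architecture, fewer parameters).
#' @param scale `"tiny"` or `"full"`; sets defaults for any of `m`, `base`,
#'   `depth`, `cardinality`, `se_reduction` not given explicitly.
#' @return a `"model_config"` list.
#' @export
model_config <- function(preset = NULL, m = NULL, subnet = NULL, dense = NULL,
                         interconnect = NULL, lambda_init = 0.01,
                         base = NULL, depth = NULL, cardinality = NULL,
                         se_reduction = NULL, sens_base = NULL,
                         scale = c("tiny", "full")) {
  scale <- match.arg(scale)
  if (!is.null(preset)) {
    flags <- switch(preset,
      reference = list(subnet = "unet", dense = FALSE, interconnect = FALSE),
      dense = list(subnet = "unet", dense = TRUE, interconnect = FALSE),
      resxunet = list(subnet = "resxunet", dense = FALSE, interconnect = FALSE),
      interconnections = list(subnet = "unet", dense = FALSE, interconnect = TRUE),
      dircn = list(subnet = "resxunet", dense = TRUE, interconnect = TRUE),
      stop("unknown preset '", preset, "'"))
    if (is.null(subnet)) subnet <- flags$subnet
    if (is.null(dense)) dense <- flags$dense
    if (is.null(interconnect)) interconnect <- flags$interconnect
  }
  subnet <- match.arg(subnet %||% "unet", c("unet", "resxunet"))
  # full-scale widths land each configuration near the ~45M budget: grouped
  # convolutions make the ResXUNet leaner per channel, so it runs wider
  defaults <- if (scale == "tiny")
    list(m = 2L, base = 8L, depth = 3L, cardinality = 2L, se_reduction = 4L)
  else if (subnet == "resxunet")
    list(m = 12L, base = 48L, depth = 4L, cardinality = 12L, se_reduction = 16L)
  else
    list(m = 12L, base = 36L, depth = 4L, cardinality = 1L, se_reduction = 16L)
  m <- as.integer(m %||% defaults$m)
  base <- as.integer(base %||% defaults$base)
  depth <- as.integer(depth %||% defaults$depth)
  cardinality <- as.integer(cardinality %||% defaults$cardinality)
  se_reduction <- as.integer(se_reduction %||% defaults$se_reduction)
  dense <- isTRUE(dense)
  interconnect <- isTRUE(interconnect)
  sens_base <- as.integer(sens_base %||% max(4L, base %/% 2L))
  if (m < 1L) stop("m must be >= 1")
  if (lambda_init <= 0) stop("lambda_init must be > 0")
  structure(list(preset = preset, m = m, subnet = subnet, dense = dense,
                 interconnect = interconnect, lambda_init = lambda_init,
                 base = base, depth = depth, cardinality = cardinality,
                 se_reduction = se_reduction, sens_base = sens_base,
                 scale = scale),
            class = "model_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_subnet <- function(config, in_ch, interconnect) {
  if (config$subnet == "resxunet")
    resxunet(in_ch = in_ch, out_ch = 2L, base = config$base,
             depth = config$depth, cardinality = config$cardinality,
             se_reduction = config$se_reduction, interconnect = interconnect)
  else
    unet(in_ch = in_ch, out_ch = 2L, base = config$base,
         depth = config$depth, interconnect = interconnect)
}

#' Build an unrolled cascading reconstruction model
#'
#' Constructs `m` cascades (each a refinement sub-network plus a soft
#' data-consistency step with its own learnable weight) and one
#' coil-sensitivity estimation network. Sub-network parameters are not
#' shared between cascades; under dense connections the k-th sub-network has
#' `2k` input channels. Weight initialization draws from R's RNG: call
#' `set.seed()` first for reproducible models.
#'
#' @param config a [model_config()]; alternatively a preset name.
#' @return object of class `"dircn_model"`.
#' @examples
#' set.seed(1)
#' model <- build_model(model_config("reference", m = 1, base = 4, depth = 2))
#' count_parameters(model)
#' @export
build_model <- function(config = model_config("reference")) {
  if (is.character(config)) config <- model_config(config)
  stopifnot(inherits(config, "model_config"))
  sens_cfg <- config
  sens_cfg$base <- config$sens_base
  sens_net <- make_subnet(sens_cfg, 2L, interconnect = FALSE)
  # zero head: the residual sensitivity refinement starts at the classical
  # center-crop estimate
  sens_net$head$w$value[] <- 0
  sens_net$head$b$value[] <- 0
  cascades <- lapply(seq_len(config$m), function(k) {
    in_ch <- if (config$dense) 2L * k else 2L
    list(subnet = make_subnet(config, in_ch,
                              interconnect = config$interconnect && k > 1L),
         lam = ag_param(config$lambda_init))
  })
  structure(list(config = config,
                 sens_net = sens_net,
                 cascades = cascades),
            class = "dircn_model")
}

#' @export
print.dircn_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Cascading MRI reconstruction model: %d cascades of %s (dense=%s, interconnect=%s), %s parameters\n",
    cfg$m, cfg$subnet, cfg$dense, cfg$interconnect,
    format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

# One cascade on graph tensors. state: list(k_current = complex tensor,
# reduced_history = list of (h, w) complex tensors (newest first),
# carry = interconnect packet or NULL). Returns the updated state.
cascade_step <- function(state, S, ku, maskmat, cascade, config) {
  d <- dim(ku)
  I_red <- ag_sum_coils(ag_mul(ag_ifft2c(state$k_current), ag_conj(S)))
  history <- c(list(I_red), state$reduced_history)
  inputs <- if (config$dense) history else list(I_red)
  x <- ag_concat_ch(lapply(inputs, ag_complex_to_channels))
  use_carry <- config$interconnect && !is.null(state$carry)
  res <- forward(cascade$subnet, x,
                 interconnect_in = if (use_carry) state$carry)
  I_rec <- ag_reshape(ag_channels_to_complex(res$out), d[1:2])
  I_ep <- ag_expand_coils(I_rec, S)
  kp <- ag_fft2c(I_ep)
  k_dc <- ag_dc(kp, cascade$lam, ku, maskmat)
  list(k_current = k_dc,
       reduced_history = history,
       carry = if (config$interconnect) res$interconnect_out else NULL,
       kp = kp)
}

#' Run a single cascade of the unrolled network
#'
#' Executes the five-step cascade procedure on plain arrays (no gradient
#' recording): coil-reduce the current k-space estimate, refine with the
#' cascade's sub-network (with dense-history concatenation and interconnect
#' packets according to the model configuration), coil-expand, transform to
#' k-space and apply data consistency against the measured lines.
#'
#' @param state list with `k_current` (complex `(kx, ky, coil)`),
#'   `reduced_history` (list of complex matrices, newest first) and `carry`
#'   (interconnect packet or `NULL`); use [new_cascade_state()] to start.
#' @param S normalized coil sensitivities `(h, w, coil)`.
#' @param ku measured masked k-space `(kx, ky, coil)`.
#' @param mask the `"undersampling_mask"`.
#' @param cascade one element of `model$cascades`.
#' @param config the model's `"model_config"`.
#' @return updated state (plain arrays), with the post-refinement prediction
#'   in `kp`.
#' @export
run_cascade <- function(state, S, ku, mask, cascade, config) {
  ag_no_grad({
    st <- list(k_current = ag_const(state$k_current),
               reduced_history = lapply(state$reduced_history, ag_const),
               carry = if (!is.null(state$carry))
                 lapply(state$carry, ag_const))
    out <- cascade_step(st, ag_const(S), ku, mask_matrix(mask, dim(ku)[1]),
                        cascade, config)
    list(k_current = out$k_current$value,
         reduced_history = lapply(out$reduced_history, function(t) t$value),
         carry = if (!is.null(out$carry))
           lapply(out$carry, function(t) t$value),
         kp = out$kp$value)
  })
}

#' Initial cascade state
#'
#' @param ku measured masked k-space; the initial estimate.
#' @return state list for [run_cascade()].
#' @export
new_cascade_state <- function(ku) {
  list(k_current = ku, reduced_history = list(), carry = NULL)
}

# Full forward pass on graph tensors; returns the final data-consistent
# k-space and the RSS magnitude tensor.
forward_model <- function(model, ku, mask) {
  d <- dim(ku)
  maskmat <- mask_matrix(mask, d[1])
  S <- estimate_sensitivities_graph(ku, mask, model$sens_net)
  state <- list(k_current = ag_const(ku), reduced_history = list(), carry = NULL)
  for (cascade in model$cascades)
    state <- cascade_step(state, S, ku, maskmat, cascade, model$config)
  coil_imgs <- ag_ifft2c(state$k_current)
  mag <- ag_sqrt(ag_add_const(ag_sum_coils(ag_cmodsq(coil_imgs)), 1e-12))
  list(k_dc = state$k_current, magnitude = mag, kp_last = state$kp,
       sensitivities = S)
}

#' Reconstruct a magnitude image from undersampled multi-coil k-space
#'
#' Runs sensitivity estimation, all cascades and a final root-sum-of-squares
#' coil combination of the data-consistent k-space. No gradients are
#' recorded.
#'
#' @param model a built `"dircn_model"`.
#' @param ku masked complex k-space `(kx, ky, coil)`.
#' @param mask the `"undersampling_mask"` used to produce `ku`.
#' @return nonnegative magnitude image `(kx, ky)`.
#' @export
reconstruct <- function(model, ku, mask) {
  d <- dim(ku)
  if (length(d) == 2L) dim(ku) <- c(d, 1L)
  ag_no_grad(forward_model(model, ku, mask)$magnitude$value)
}

#' Zero-filled baseline reconstruction
#'
#' Root-sum-of-squares of the inverse transform of the masked k-space with
#' zeros at unsampled lines; the standard aliased baseline.
#'
#' @param ku masked complex k-space `(kx, ky, coil)`.
#' @return magnitude image `(kx, ky)`.
#' @export
zero_filled <- function(ku) {
  d <- dim(ku)
  if (length(d) == 2L) dim(ku) <- c(d, 1L)
  rss(ifft2c(ku))
}
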