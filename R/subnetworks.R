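# Image-domain refinement networks. Both U-Net variants share the same
# encoder/decoder skeleton: a stem, per-resolution blocks, stride-2
# downsampling convolutions, nearest-neighbour upsampling with skip
# concatenation, and a 1x1 output head. They differ in the level block
# (plain double convolution vs aggregated SE residual blocks) and in the
# activation (ReLU vs SiLU). Inputs of any rectangular size are reflect-padded
# to a multiple of 2^(depth-1) and cropped back.

subnet_channels <- function(base, depth) base * 2L^(seq_len(depth) - 1L)

build_subnet_skeleton <- function(kind, in_ch, out_ch, base, depth,
                                  cardinality, se_reduction, interconnect) {
  ch <- subnet_channels(base, depth)
  act <- if (kind == "resxunet") "silu" else "relu"
  level_block <- function(c) {
    if (kind == "resxunet")
      list(new_res_block(c, cardinality, se_reduction),
           new_res_block(c, cardinality, se_reduction))
    else
      list(new_double_conv(c, c))
  }
  net <- list(
    kind = kind, in_ch = in_ch, out_ch = out_ch, base = base, depth = depth,
    interconnect = interconnect,
    stem = new_conv_act(in_ch, ch[1], act = act),
    enc = lapply(ch, level_block),
    down = lapply(seq_len(depth - 1L), function(r)
      new_conv_act(ch[r], ch[r + 1L], stride = 2L, act = act)),
    fuse_ic = if (interconnect) lapply(ch, function(c)
      new_conv_act(2L * c, c, k = 1L, act = act)),
    up = lapply(seq_len(depth - 1L), function(r)
      new_conv_act(ch[r + 1L], ch[r], act = act)),
    fuse_skip = lapply(seq_len(depth - 1L), function(r)
      new_conv_act(2L * ch[r], ch[r], act = act)),
    dec = lapply(seq_len(depth - 1L), function(r) level_block(ch[r])),
    head = new_conv(ch[1], out_ch, k = 1L, pad = 0L)
  )
  net
}

#' Squeeze-and-excitation residual U-Net (ResXUNet)
#'
#' U-Net-shaped refinement network whose level blocks are aggregated residual
#' blocks (grouped 3x3 convolutions of the given cardinality) with
#' squeeze-and-excitation gating, SiLU activations and instance
#' normalization. Channel width doubles at each of `depth` resolutions.
#' When `interconnect = TRUE` the network accepts a per-resolution packet of
#' feature maps from the preceding sub-network (concatenated onto its encoder
#' features through 1x1 fusion convolutions) and always emits the final
#' feature map of each resolution for the next sub-network.
#'
#' @param in_ch input channels (2 per complex image: real, imaginary).
#' @param out_ch output channels (2: real, imaginary).
#' @param base channels at the finest resolution.
#' @param depth number of resolutions (>= 2).
#' @param cardinality groups of the aggregated residual convolutions; must
#'   divide all level widths.
#' @param se_reduction squeeze-and-excitation reduction ratio.
#' @param interconnect whether the network consumes an interconnect packet.
#' @return module of class `c("resxunet", "subnet")`; apply with
#'   `forward(net, x, interconnect_in = )`, which returns
#'   `list(out, interconnect_out)`.
#' @export
resxunet <- function(in_ch = 2L, out_ch = 2L, base = 8L, depth = 3L,
                     cardinality = 2L, se_reduction = 4L, interconnect = FALSE) {
  if (depth < 2L) stop("depth must be >= 2")
  if (base %% cardinality != 0L)
    stop("cardinality must divide the base channel count")
  structure(build_subnet_skeleton("resxunet", in_ch, out_ch, base, depth,
                                  cardinality, se_reduction, interconnect),
            class = c("resxunet", "subnet"))
}

#' Plain U-Net baseline sub-network
#'
#' The baseline refinement network: identical skeleton to [resxunet()] but
#' with ungrouped double-convolution level blocks, ReLU activations and no
#' squeeze-and-excitation, so it has strictly fewer parameters at matched
#' width and depth.
#'
#' @inheritParams resxunet
#' @return module of class `c("unet", "subnet")`.
#' @export
unet <- function(in_ch = 2L, out_ch = 2L, base = 8L, depth = 3L,
                 interconnect = FALSE) {
  if (depth < 2L) stop("depth must be >= 2")
  structure(build_subnet_skeleton("unet", in_ch, out_ch, base, depth,
                                  cardinality = 1L, se_reduction = NULL,
                                  interconnect = interconnect),
            class = c("unet", "subnet"))
}

run_blocks <- function(blocks, x) {
  for (b in blocks) x <- forward(b, x)
  x
}

#' @export
forward.subnet <- function(module, x, interconnect_in = NULL, ...) {
  d <- dim(x$value)
  if (d[3] != module$in_ch)
    stop("subnet: expected ", module$in_ch, " input channels, got ", d[3])
  div <- 2L^(module$depth - 1L)
  ph <- (div - d[1] %% div) %% div
  pw <- (div - d[2] %% div) %% div
  x <- ag_pad_reflect(x, ph, pw)
  if (!is.null(interconnect_in)) {
    if (!module$interconnect)
      stop("subnet built without interconnect support received a packet")
    if (length(interconnect_in) != module$depth)
      stop("interconnect packet must have one entry per resolution")
  }
  skips <- vector("list", module$depth)
  h <- forward(module$stem, x)
  for (r in seq_len(module$depth)) {
    if (!is.null(interconnect_in))
      h <- forward(module$fuse_ic[[r]], ag_concat_ch(list(h, interconnect_in[[r]])))
    h <- run_blocks(module$enc[[r]], h)
    skips[[r]] <- h
    if (r < module$depth) h <- forward(module$down[[r]], h)
  }
  packet <- vector("list", module$depth)
  packet[[module$depth]] <- skips[[module$depth]]
  h <- skips[[module$depth]]
  for (r in seq.int(module$depth - 1L, 1L)) {
    h <- forward(module$up[[r]], ag_upsample2(h))
    h <- forward(module$fuse_skip[[r]], ag_concat_ch(list(h, skips[[r]])))
    h <- run_blocks(module$dec[[r]], h)
    packet[[r]] <- h
  }
  out <- ag_conv2d(h, module$head$w, module$head$b, stride = 1L, pad = 0L)
  out <- ag_crop_offset(out, 0L, 0L, d[1], d[2])  # undo bottom/right padding
  list(out = out, interconnect_out = packet)
}

# Graph-mode sensitivity estimation: center-only k-space -> per-coil images
# (coils on the batch axis, 2 real channels) -> residual CNN refinement ->
# unit-energy normalization. The refinement is additive on top of the
# center-crop estimate and its output head is zero-initialized, so an
# untrained network reproduces the classical autocalibration maps exactly.
# net = NULL skips the CNN refinement.
estimate_sensitivities_graph <- function(ku, mask, net = NULL) {
  d <- dim(ku)
  if (mask$n_center < 1L) stop("mask has an empty fully sampled center")
  c0 <- (length(mask$lines) - mask$n_center) %/% 2L
  keep <- c0 + seq_len(mask$n_center)
  kc <- array(0i, d)
  kc[, keep, ] <- ku[, keep, ]
  coil_imgs <- ifft2c(kc)                       # (h, w, c) complex, constant
  if (!is.null(net)) {
    x <- ag_complex_to_channels(ag_const(coil_imgs))   # (h, w, 2, c)
    x <- forward(net, x)$out
    S <- ag_add(ag_const(coil_imgs), ag_channels_to_complex(x))
  } else {
    S <- ag_const(coil_imgs)
  }
  energy <- ag_sum_coils(ag_cmodsq(S))
  inv <- ag_div(ag_const(matrix(1, d[1], d[2])),
                ag_sqrt(ag_add_const(energy, 1e-12)))
  ag_coilwise_scale(S, inv)
}

#' Estimate coil sensitivity maps from the autocalibration region
#'
#' Extracts the fully sampled central phase-encoding lines of the
#' undersampled k-space, inverse-transforms each coil, optionally applies a
#' residual CNN refinement to each low-resolution coil image (the coil index
#' rides the batch axis, so any coil count is supported), and normalizes the
#' result to unit pixelwise energy (`sum_i Conj(S_i) S_i = 1`). Inside a
#' built model the refinement head starts at zero, so an untrained model
#' reproduces the classical center-crop estimate.
#'
#' @param ku complex undersampled k-space `(kx, ky, coil)`.
#' @param mask the `"undersampling_mask"` that produced `ku` (its center
#'   width defines the autocalibration region).
#' @param net optional refinement sub-network ([resxunet()] or [unet()] with
#'   2 input/output channels); `NULL` uses the unrefined center
#'   reconstruction.
#' @return normalized complex sensitivity array `(h, w, coil)`.
#' @export
estimate_sensitivities <- function(ku, mask, net = NULL) {
  d <- dim(ku)
  if (length(d) == 2L) { dim(ku) <- c(d, 1L) }
  ag_no_grad(estimate_sensitivities_graph(ku, mask, net)$value)
}
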