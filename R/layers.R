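# Learnable building blocks. Each constructor returns a plain list of
# parameter tensors plus metadata; forward() dispatches on its class and
# returns an ag tensor so gradients flow through the autodiff tape.
# Feature maps are real arrays (h, w, channels, batch).

#' Forward pass of a network module
#'
#' S3 generic dispatching on the module class (convolution, normalization,
#' squeeze-and-excitation block, residual block, U-Net variants, ...).
#' Inputs and outputs are autodiff tensors; wrap plain arrays with the
#' internal constructors or use the higher-level entry points
#' ([reconstruct()], [estimate_sensitivities()]).
#'
#' @param module a module created by one of the `new_*` constructors,
#'   [resxunet()] or [unet()].
#' @param x input tensor (real, `(h, w, channels, batch)`).
#' @param ... module-specific arguments (e.g. `interconnect_in`).
#' @return output tensor, or a list for modules with auxiliary outputs.
#' @export
forward <- function(module, x, ...) UseMethod("forward")

rnorm_array <- function(dims, sd) array(stats::rnorm(prod(dims), sd = sd), dims)

new_conv <- function(cin, cout, k = 3L, stride = 1L, pad = k %/% 2L,
                     groups = 1L, bias = TRUE) {
  if (cin %% groups != 0L || cout %% groups != 0L)
    stop("conv: groups must divide both channel counts")
  cpg <- cin %/% groups
  w <- ag_param(rnorm_array(c(k, k, cpg, cout), sd = sqrt(2 / (k * k * cpg))))
  b <- if (bias) ag_param(numeric(cout)) else NULL
  structure(list(w = w, b = b, stride = stride, pad = pad, groups = groups),
            class = "cv_layer")
}

#' @export
forward.cv_layer <- function(module, x, ...) {
  ag_conv2d(x, module$w, module$b, stride = module$stride,
            pad = module$pad, groups = module$groups)
}

new_norm <- function(channels) {
  structure(list(gamma = ag_param(rep(1, channels)),
                 beta = ag_param(numeric(channels))),
            class = "in_layer")
}

#' @export
forward.in_layer <- function(module, x, ...) ag_instnorm(x, module$gamma, module$beta)

new_linear <- function(cin, cout, bias = TRUE) {
  structure(list(W = ag_param(rnorm_array(c(cout, cin), sd = sqrt(2 / cin))),
                 b = if (bias) ag_param(numeric(cout)) else NULL),
            class = "fc_layer")
}

#' @export
forward.fc_layer <- function(module, x, ...) ag_linear(x, module$W, module$b)

#' Squeeze-and-excitation block
#'
#' Learnable channel-wise gating: global average pooling (squeeze) feeds a
#' two-layer excitation network whose sigmoid output `s` in `[0, 1]` rescales
#' every channel multiplicatively, `y = x * s`. Scaling can only shrink a
#' channel, never amplify it.
#'
#' @param channels number of feature channels.
#' @param reduction bottleneck reduction ratio of the excitation MLP.
#' @return module of class `"se_block"`; apply with [forward()].
#' @export
new_se_block <- function(channels, reduction = 4L) {
  hidden <- max(1L, channels %/% reduction)
  structure(list(fc1 = new_linear(channels, hidden),
                 fc2 = new_linear(hidden, channels),
                 channels = channels),
            class = "se_block")
}

#' @export
forward.se_block <- function(module, x, ...) {
  if (dim(x$value)[3] != module$channels)
    stop("se_block: channel mismatch (", dim(x$value)[3], " vs ", module$channels, ")")
  s <- ag_global_mean(x)
  s <- ag_silu(forward(module$fc1, s))
  s <- ag_sigmoid(forward(module$fc2, s))
  ag_channel_scale(x, s)
}

#' Aggregated residual block with squeeze-and-excitation
#'
#' `y = SE(F(x)) + x` where `F` is conv-norm-SiLU-conv-norm with grouped
#' (aggregated) 3x3 convolutions of the given cardinality, and the
#' squeeze-and-excitation gate is the final operation of the residual branch,
#' before the identity addition. A trailing SiLU follows the addition.
#' Channel count is preserved; with all branch weights at zero the block is
#' the identity followed by SiLU.
#'
#' @param channels feature channels (must be divisible by `cardinality`).
#' @param cardinality number of parallel convolution groups.
#' @param se_reduction reduction ratio of the SE gate; `NULL` disables SE,
#'   leaving a plain aggregated residual block.
#' @return module of class `"res_block"`; apply with [forward()].
#' @export
new_res_block <- function(channels, cardinality = 2L, se_reduction = 4L) {
  structure(list(
    conv1 = new_conv(channels, channels, 3L, groups = cardinality),
    n1 = new_norm(channels),
    conv2 = new_conv(channels, channels, 3L, groups = cardinality),
    n2 = new_norm(channels),
    se = if (!is.null(se_reduction)) new_se_block(channels, se_reduction),
    channels = channels),
    class = "res_block")
}

#' @export
forward.res_block <- function(module, x, ...) {
  if (dim(x$value)[3] != module$channels)
    stop("res_block: channel mismatch")
  f <- ag_silu(forward(module$n1, forward(module$conv1, x)))
  f <- forward(module$n2, forward(module$conv2, f))
  if (!is.null(module$se)) f <- forward(module$se, f)
  ag_add(f, x)
}

# conv-norm-act applied twice; the plain U-Net level block.
new_double_conv <- function(cin, cout) {
  structure(list(conv1 = new_conv(cin, cout, 3L), n1 = new_norm(cout),
                 conv2 = new_conv(cout, cout, 3L), n2 = new_norm(cout)),
            class = "double_conv")
}

#' @export
forward.double_conv <- function(module, x, ...) {
  x <- ag_relu(forward(module$n1, forward(module$conv1, x)))
  ag_relu(forward(module$n2, forward(module$conv2, x)))
}

# conv-norm-SiLU stage used for stems / downsampling / fusion.
new_conv_act <- function(cin, cout, k = 3L, stride = 1L, act = "silu") {
  structure(list(conv = new_conv(cin, cout, k, stride = stride),
                 n = new_norm(cout), act = act),
            class = "conv_act")
}

#' @export
forward.conv_act <- function(module, x, ...) {
  y <- forward(module$n, forward(module$conv, x))
  switch(module$act, silu = ag_silu(y), relu = ag_relu(y), none = y)
}

## ---- parameter bookkeeping -------------------------------------------------

#' Collect the learnable parameters of a model or module
#'
#' Recursively walks the module tree and returns a named list of parameter
#' tensors; names encode the path (e.g. `cascades.1.subnet.stem.conv.w`).
#'
#' @param module any module or model built by this package.
#' @return named list of parameter tensors.
#' @export
parameters <- function(module) {
  out <- list()
  walk <- function(x, path) {
    if (ag_is_tensor(x)) {
      if (isTRUE(x$is_param)) out[[path]] <<- x
    } else if (is.list(x)) {
      nm <- names(x)
      for (i in seq_along(x)) {
        if (is.null(x[[i]]) || is.function(x[[i]])) next
        tag <- if (!is.null(nm) && nzchar(nm[i])) nm[i] else as.character(i)
        walk(x[[i]], paste(path, tag, sep = "."))
      }
    }
  }
  walk(module, "p")
  out
}

#' Count learnable scalars
#'
#' Total number of learnable scalar parameters (convolution and linear
#' weights and biases, normalization affine terms, data-consistency weights).
#'
#' @param module a module or built model.
#' @return integer count.
#' @examples
#' cv <- dircn:::new_conv(2L, 4L, 3L)
#' count_parameters(cv)  # 3*3*2*4 + 4 = 76
#' @export
count_parameters <- function(module) {
  sum(vapply(parameters(module), function(p) length(p$value), 0))
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}
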