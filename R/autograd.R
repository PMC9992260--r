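# Reverse-mode automatic differentiation on dense R arrays.
#
# A tensor is an environment holding a numeric (possibly complex) array, an
# accumulated gradient, and a backward closure; operations append nodes to a
# global tape which is replayed in reverse by ag_backward().  Complex arrays
# are first-class: the "gradient" of a complex tensor packs (dL/dRe, dL/dIm)
# as Re and Im parts of one complex array, which makes the adjoint of a
# unitary FFT simply the inverse FFT and the adjoint of elementwise
# multiplication a multiplication by the complex conjugate.

.ag <- new.env(parent = emptyenv())
.ag$tape <- list()
.ag$n <- 0L
.ag$on <- TRUE
.ag$im2col <- new.env(parent = emptyenv())

ag_tape_reset <- function() {
  .ag$tape <- vector("list", 256L)
  .ag$n <- 0L
  invisible(NULL)
}

#' @keywords internal
ag_is_tensor <- function(x) inherits(x, "ag_tensor")

ag_new <- function(value, parents = list(), backward = NULL, extras = NULL) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$is_param <- FALSE
  req <- FALSE
  if (.ag$on && length(parents)) {
    for (p in parents) if (p$requires) { req <- TRUE; break }
  }
  node$requires <- req
  if (req) {
    node$parents <- parents
    node$backward <- backward
    node$extras <- extras
    .ag$n <- .ag$n + 1L
    if (.ag$n > length(.ag$tape)) length(.ag$tape) <- 2L * length(.ag$tape) + 16L
    .ag$tape[[.ag$n]] <- node
  }
  class(node) <- "ag_tensor"
  node
}

ag_param <- function(value, name = NULL) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$requires <- TRUE
  node$is_param <- TRUE
  node$name <- name
  class(node) <- "ag_tensor"
  node
}

ag_const <- function(value) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$requires <- FALSE
  node$is_param <- FALSE
  class(node) <- "ag_tensor"
  node
}

as_ag <- function(x) if (ag_is_tensor(x)) x else ag_const(x)

ag_value <- function(x) x$value

# Evaluate fn() with gradient recording switched off (inference mode).
ag_no_grad <- function(expr) {
  old <- .ag$on
  .ag$on <- FALSE
  on.exit(.ag$on <- old)
  force(expr)
}

acc_grad <- function(p, g) {
  if (!p$requires) return(invisible(NULL))
  dim(g) <- dim(p$value)
  p$grad <- if (is.null(p$grad)) g else p$grad + g
  invisible(NULL)
}

# Backpropagate from a scalar loss through the current tape.
ag_backward <- function(loss) {
  stopifnot(length(loss$value) == 1L)
  loss$grad <- 1
  if (.ag$n > 0L) {
    for (i in seq.int(.ag$n, 1L)) {
      node <- .ag$tape[[i]]
      if (!is.null(node$grad) && !is.null(node$backward)) node$backward(node)
      node$grad <- NULL  # free
    }
  }
  ag_tape_reset()
  invisible(NULL)
}

## ---- elementwise arithmetic ------------------------------------------------

ag_add <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  ag_new(a$value + b$value, list(a, b), function(node) {
    acc_grad(node$parents[[1]], node$grad)
    acc_grad(node$parents[[2]], node$grad)
  })
}

ag_sub <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  ag_new(a$value - b$value, list(a, b), function(node) {
    acc_grad(node$parents[[1]], node$grad)
    acc_grad(node$parents[[2]], -node$grad)
  })
}

# Elementwise product; valid for real and complex operands (the adjoint of
# multiplication by z, viewed as a real-linear map, is multiplication by
# Conj(z)).
ag_mul <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  ag_new(a$value * b$value, list(a, b), function(node) {
    acc_grad(node$parents[[1]], Conj(node$parents[[2]]$value) * node$grad)
    acc_grad(node$parents[[2]], Conj(node$parents[[1]]$value) * node$grad)
  })
}

ag_div <- function(a, b) {  # real only
  a <- as_ag(a); b <- as_ag(b)
  ag_new(a$value / b$value, list(a, b), function(node) {
    bv <- node$parents[[2]]$value
    acc_grad(node$parents[[1]], node$grad / bv)
    acc_grad(node$parents[[2]], -node$grad * node$parents[[1]]$value / bv^2)
  })
}

ag_add_const <- function(x, k) {
  x <- as_ag(x)
  ag_new(x$value + k, list(x), function(node) acc_grad(node$parents[[1]], node$grad))
}

ag_mul_const <- function(x, k) {
  x <- as_ag(x)
  ag_new(x$value * k, list(x), function(node)
    acc_grad(node$parents[[1]], Conj(k) * node$grad))
}

# y = s * x with s a real scalar tensor (e.g. a learnable weight).
ag_scale <- function(x, s) {
  x <- as_ag(x); s <- as_ag(s)
  ag_new(s$value[1] * x$value, list(x, s), function(node) {
    sv <- node$parents[[2]]$value[1]
    acc_grad(node$parents[[1]], sv * node$grad)
    gs <- sum(Re(Conj(node$grad) * node$parents[[1]]$value))
    acc_grad(node$parents[[2]], gs)
  })
}

## ---- real nonlinearities ---------------------------------------------------

ag_relu <- function(x) {
  x <- as_ag(x)
  ag_new(pmax(x$value, 0), list(x), function(node)
    acc_grad(node$parents[[1]], node$grad * (node$parents[[1]]$value > 0)))
}

ag_sigmoid <- function(x) {
  x <- as_ag(x)
  s <- 1 / (1 + exp(-x$value))
  ag_new(s, list(x), function(node) {
    sv <- node$extras$s
    acc_grad(node$parents[[1]], node$grad * sv * (1 - sv))
  }, extras = list(s = s))
}

ag_silu <- function(x) {
  x <- as_ag(x)
  s <- 1 / (1 + exp(-x$value))
  ag_new(x$value * s, list(x), function(node) {
    sv <- node$extras$s
    xv <- node$parents[[1]]$value
    acc_grad(node$parents[[1]], node$grad * (sv + xv * sv * (1 - sv)))
  }, extras = list(s = s))
}

ag_sqrt <- function(x) {
  x <- as_ag(x)
  r <- sqrt(x$value)
  ag_new(r, list(x), function(node)
    acc_grad(node$parents[[1]], node$grad / (2 * node$extras$r)),
    extras = list(r = r))
}

ag_abs <- function(x) {  # real; subgradient 0 at 0
  x <- as_ag(x)
  ag_new(abs(x$value), list(x), function(node)
    acc_grad(node$parents[[1]], node$grad * sign(node$parents[[1]]$value)))
}

ag_sum <- function(x) {
  x <- as_ag(x)
  ag_new(sum(x$value), list(x), function(node) {
    v <- node$parents[[1]]$value
    g <- array(node$grad, dim = if (is.null(dim(v))) length(v) else dim(v))
    acc_grad(node$parents[[1]], g)
  })
}

ag_mean <- function(x) {
  x <- as_ag(x)
  n <- length(x$value)
  ag_new(sum(x$value) / n, list(x), function(node) {
    v <- node$parents[[1]]$value
    g <- array(node$grad / node$extras$n,
               dim = if (is.null(dim(v))) length(v) else dim(v))
    acc_grad(node$parents[[1]], g)
  }, extras = list(n = n))
}

## ---- complex packing and Fourier ops --------------------------------------

ag_re <- function(z) {
  z <- as_ag(z)
  ag_new(Re(z$value), list(z), function(node)
    acc_grad(node$parents[[1]], node$grad + 0i))
}

ag_im <- function(z) {
  z <- as_ag(z)
  ag_new(Im(z$value), list(z), function(node)
    acc_grad(node$parents[[1]], 1i * node$grad))
}

ag_complex <- function(re, im) {
  re <- as_ag(re); im <- as_ag(im)
  ag_new(re$value + 1i * im$value, list(re, im), function(node) {
    acc_grad(node$parents[[1]], Re(node$grad))
    acc_grad(node$parents[[2]], Im(node$grad))
  })
}

ag_conj <- function(z) {
  z <- as_ag(z)
  ag_new(Conj(z$value), list(z), function(node)
    acc_grad(node$parents[[1]], Conj(node$grad)))
}

# |z|^2, a real array; d/d(Re,Im) packs to 2 * g * z.
ag_cmodsq <- function(z) {
  z <- as_ag(z)
  ag_new(Re(z$value)^2 + Im(z$value)^2, list(z), function(node)
    acc_grad(node$parents[[1]], 2 * node$grad * node$parents[[1]]$value))
}

# Centered orthonormal 2-D FFT over the first two dims (coil slices looped).
# Unitary, so the adjoint (= transpose of the real-linear map) is the inverse.
ag_fft2c <- function(z) {
  z <- as_ag(z)
  ag_new(fft2c(z$value), list(z), function(node)
    acc_grad(node$parents[[1]], ifft2c(node$grad)))
}

ag_ifft2c <- function(z) {
  z <- as_ag(z)
  ag_new(ifft2c(z$value), list(z), function(node)
    acc_grad(node$parents[[1]], fft2c(node$grad)))
}

# Sum over the coil axis (dim 3): (h, w, c) -> (h, w).
ag_sum_coils <- function(x) {
  x <- as_ag(x)
  v <- rowSums(x$value, dims = 2L)
  ag_new(v, list(x), function(node) {
    d <- dim(node$parents[[1]]$value)
    g <- array(rep(as.vector(node$grad), d[3]), dim = d)
    acc_grad(node$parents[[1]], g)
  })
}

# y[, , k] = z * S[, , k]: broadcast a single complex image over coils.
ag_expand_coils <- function(z, S) {
  z <- as_ag(z); S <- as_ag(S)
  ag_new(S$value * as.vector(z$value), list(z, S), function(node) {
    zv <- node$parents[[1]]$value
    Sv <- node$parents[[2]]$value
    gz <- rowSums(Conj(Sv) * node$grad, dims = 2L)
    acc_grad(node$parents[[1]], gz)
    acc_grad(node$parents[[2]], node$grad * as.vector(Conj(zv)))
  })
}

# y[, , k] = z[, , k] * r with r a real (h, w) map (e.g. 1/sqrt(energy)).
ag_coilwise_scale <- function(z, r) {
  z <- as_ag(z); r <- as_ag(r)
  ag_new(z$value * as.vector(r$value), list(z, r), function(node) {
    zv <- node$parents[[1]]$value
    rv <- node$parents[[2]]$value
    acc_grad(node$parents[[1]], node$grad * as.vector(rv))
    gr <- rowSums(Re(Conj(node$grad) * zv), dims = 2L)
    acc_grad(node$parents[[2]], gr)
  })
}

# Complex (h, w[, c]) -> real channel stack (h, w, 2, c): ch 1 = Re, ch 2 = Im.
ag_complex_to_channels <- function(z) {
  z <- as_ag(z)
  d <- dim(z$value)
  cc <- if (length(d) == 2L) 1L else d[3]
  v <- array(0, c(d[1], d[2], 2L, cc))
  v[, , 1L, ] <- Re(z$value)
  v[, , 2L, ] <- Im(z$value)
  ag_new(v, list(z), function(node) {
    g <- node$grad
    gi <- g[, , 1L, , drop = FALSE] + 1i * g[, , 2L, , drop = FALSE]
    acc_grad(node$parents[[1]], gi)
  })
}

# Real channel stack (h, w, 2, c) -> complex (h, w, c) (c = 1 gives h x w x 1).
ag_channels_to_complex <- function(x) {
  x <- as_ag(x)
  d <- dim(x$value)
  v <- x$value[, , 1L, , drop = FALSE] + 1i * x$value[, , 2L, , drop = FALSE]
  dim(v) <- c(d[1], d[2], d[4])
  ag_new(v, list(x), function(node) {
    d0 <- dim(node$parents[[1]]$value)
    g <- array(0, d0)
    gg <- node$grad
    dim(gg) <- c(d0[1], d0[2], 1L, d0[4])
    g[, , 1L, ] <- Re(gg)
    g[, , 2L, ] <- Im(gg)
    acc_grad(node$parents[[1]], g)
  })
}

## ---- soft data consistency -------------------------------------------------

# Sampled lines: (ku + lam * kp) / (1 + lam); unsampled: kp.  mask is a binary
# (h, w) array broadcast over coils; lam a real scalar parameter tensor.
ag_dc <- function(kp, lam, ku, mask) {
  kp <- as_ag(kp); lam <- as_ag(lam)
  lv <- lam$value[1]
  mvec <- as.vector(mask)
  blend <- (ku + lv * kp$value) / (1 + lv)
  y <- kp$value * (1 - mvec) + blend * mvec
  ag_new(y, list(kp, lam), function(node) {
    ex <- node$extras
    lv <- node$parents[[2]]$value[1]
    g <- node$grad
    gkp <- g * (1 - ex$mvec) + g * ex$mvec * (lv / (1 + lv))
    acc_grad(node$parents[[1]], gkp)
    diff <- (node$parents[[1]]$value - ex$ku) * ex$mvec
    glam <- sum(Re(Conj(g) * diff)) / (1 + lv)^2
    acc_grad(node$parents[[2]], glam)
  }, extras = list(ku = ku, mvec = mvec))
}

## ---- shape ops -------------------------------------------------------------

ag_reshape <- function(x, dims) {
  x <- as_ag(x)
  v <- x$value
  dim(v) <- dims
  ag_new(v, list(x), function(node) {
    g <- node$grad
    dim(g) <- dim(node$parents[[1]]$value)
    acc_grad(node$parents[[1]], g)
  })
}

# Concatenate 4-d feature maps (h, w, c, n) along the channel axis.
ag_concat_ch <- function(xs) {
  xs <- lapply(xs, as_ag)
  dims <- lapply(xs, function(x) dim(x$value))
  chs <- vapply(dims, function(d) d[3], 0)
  d1 <- dims[[1]]
  out <- array(0, c(d1[1], d1[2], sum(chs), d1[4]))
  at <- 0L
  for (i in seq_along(xs)) {
    out[, , at + seq_len(chs[i]), ] <- xs[[i]]$value
    at <- at + chs[i]
  }
  ag_new(out, xs, function(node) {
    at <- 0L
    for (i in seq_along(node$parents)) {
      ci <- dim(node$parents[[i]]$value)[3]
      acc_grad(node$parents[[i]], node$grad[, , at + seq_len(ci), , drop = FALSE])
      at <- at + ci
    }
  })
}

# Centered crop of the first two dims; works for 2-, 3- and 4-d arrays.
ag_crop_center <- function(x, th, tw) {
  d <- dim(as_ag(x)$value)
  ag_crop_offset(x, (d[1] - th) %/% 2L, (d[2] - tw) %/% 2L, th, tw)
}

# Crop starting at 0-based offset (r0, c0).
ag_crop_offset <- function(x, r0, c0, th, tw) {
  x <- as_ag(x)
  d <- dim(x$value)
  ri <- r0 + seq_len(th); ci <- c0 + seq_len(tw)
  v <- switch(length(d) - 1L,
    x$value[ri, ci, drop = FALSE],
    x$value[ri, ci, , drop = FALSE],
    x$value[ri, ci, , , drop = FALSE])
  ag_new(v, list(x), function(node) {
    ex <- node$extras
    g <- array(if (is.complex(node$grad)) 0i else 0, dim(node$parents[[1]]$value))
    nd <- length(dim(g))
    if (nd == 2L) g[ex$ri, ex$ci] <- node$grad
    else if (nd == 3L) g[ex$ri, ex$ci, ] <- node$grad
    else g[ex$ri, ex$ci, , ] <- node$grad
    acc_grad(node$parents[[1]], g)
  }, extras = list(ri = ri, ci = ci))
}

# Reflect-pad the bottom/right spatial borders of a 4-d map (no edge repeat).
ag_pad_reflect <- function(x, ph, pw) {
  x <- as_ag(x)
  if (ph == 0L && pw == 0L) return(x)
  d <- dim(x$value)
  ir <- c(seq_len(d[1]), d[1] - seq_len(ph))
  ic <- c(seq_len(d[2]), d[2] - seq_len(pw))
  v <- x$value[ir, ic, , , drop = FALSE]
  ag_new(v, list(x), function(node) {
    ex <- node$extras
    g <- node$grad
    dg <- dim(g)
    m <- g; dim(m) <- c(dg[1], prod(dg[-1]))
    m <- rowsum(m, group = ex$ir)
    dim(m) <- c(nrow(m), dg[2], dg[3], dg[4])
    m <- aperm(m, c(2, 1, 3, 4))
    dm <- dim(m); dim(m) <- c(dm[1], prod(dm[-1]))
    m <- rowsum(m, group = ex$ic)
    dim(m) <- c(nrow(m), dm[2], dm[3], dm[4])
    m <- aperm(m, c(2, 1, 3, 4))
    acc_grad(node$parents[[1]], m)
  }, extras = list(ir = ir, ic = ic))
}

# Nearest-neighbour x2 upsampling of (h, w, c, n).
ag_upsample2 <- function(x) {
  x <- as_ag(x)
  d <- dim(x$value)
  v <- x$value[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , , drop = FALSE]
  ag_new(v, list(x), function(node) {
    g <- node$grad
    dg <- dim(g)
    odd_r <- seq.int(1L, dg[1], 2L)
    g <- g[odd_r, , , , drop = FALSE] + g[odd_r + 1L, , , , drop = FALSE]
    odd_c <- seq.int(1L, dg[2], 2L)
    g <- g[, odd_c, , , drop = FALSE] + g[, odd_c + 1L, , , drop = FALSE]
    acc_grad(node$parents[[1]], g)
  })
}

## ---- dense / pooling / normalization ---------------------------------------

# Global average pool: (h, w, c, n) -> (c, n).
ag_global_mean <- function(x) {
  x <- as_ag(x)
  d <- dim(x$value)
  hw <- d[1] * d[2]
  m <- x$value; dim(m) <- c(hw, d[3] * d[4])
  v <- colMeans(m); dim(v) <- c(d[3], d[4])
  ag_new(v, list(x), function(node) {
    d <- dim(node$parents[[1]]$value)
    hw <- d[1] * d[2]
    g <- array(rep(as.vector(node$grad), each = hw) / hw, dim = d)
    acc_grad(node$parents[[1]], g)
  })
}

# Fully connected: x (cin, n), W (cout, cin), b length cout.
ag_linear <- function(x, W, b = NULL) {
  x <- as_ag(x); W <- as_ag(W)
  v <- W$value %*% x$value
  if (!is.null(b)) { b <- as_ag(b); v <- v + b$value }
  parents <- if (is.null(b)) list(x, W) else list(x, W, b)
  ag_new(v, parents, function(node) {
    g <- node$grad
    xv <- node$parents[[1]]$value
    Wv <- node$parents[[2]]$value
    acc_grad(node$parents[[1]], crossprod(Wv, g))
    acc_grad(node$parents[[2]], tcrossprod(g, xv))
    if (length(node$parents) == 3L) acc_grad(node$parents[[3]], rowSums(g))
  })
}

# Per-(channel, sample) scaling: x (h, w, c, n) * s (c, n).
ag_channel_scale <- function(x, s) {
  x <- as_ag(x); s <- as_ag(s)
  d <- dim(x$value)
  hw <- d[1] * d[2]
  v <- x$value * rep(as.vector(s$value), each = hw)
  ag_new(v, list(x, s), function(node) {
    d <- dim(node$parents[[1]]$value)
    hw <- d[1] * d[2]
    sv <- as.vector(node$parents[[2]]$value)
    acc_grad(node$parents[[1]], node$grad * rep(sv, each = hw))
    gs <- node$grad * node$parents[[1]]$value
    dim(gs) <- c(hw, d[3] * d[4])
    gs <- colSums(gs); dim(gs) <- c(d[3], d[4])
    acc_grad(node$parents[[2]], gs)
  })
}

# Instance normalization over the spatial dims of (h, w, c, n), with
# per-channel affine parameters gamma, beta (length c), biased variance.
ag_instnorm <- function(x, gamma, beta, eps = 1e-5) {
  x <- as_ag(x); gamma <- as_ag(gamma); beta <- as_ag(beta)
  d <- dim(x$value)
  hw <- d[1] * d[2]; cn <- d[3] * d[4]
  m <- x$value; dim(m) <- c(hw, cn)
  mu <- colMeans(m)
  v <- colMeans(m * m) - mu^2
  sdv <- sqrt(v + eps)
  xhat <- (m - rep(mu, each = hw)) / rep(sdv, each = hw)
  gvec <- rep(gamma$value, times = d[4])
  bvec <- rep(beta$value, times = d[4])
  y <- xhat * rep(gvec, each = hw) + rep(bvec, each = hw)
  dim(y) <- d
  ag_new(y, list(x, gamma, beta), function(node) {
    ex <- node$extras
    d <- dim(node$parents[[1]]$value)
    hw <- d[1] * d[2]
    g <- node$grad; dim(g) <- c(hw, d[3] * d[4])
    gg_cn <- colSums(g * ex$xhat)
    gb_cn <- colSums(g)
    acc_grad(node$parents[[2]], rowSums(matrix(gg_cn, d[3], d[4])))
    acc_grad(node$parents[[3]], rowSums(matrix(gb_cn, d[3], d[4])))
    gvec <- rep(node$parents[[2]]$value, times = d[4])
    gxh <- g * rep(gvec, each = hw)
    t1 <- rep(colMeans(gxh), each = hw)
    t2 <- ex$xhat * rep(colMeans(gxh * ex$xhat), each = hw)
    gx <- (gxh - t1 - t2) / rep(ex$sdv, each = hw)
    dim(gx) <- d
    acc_grad(node$parents[[1]], gx)
  }, extras = list(xhat = xhat, sdv = sdv))
}

## ---- convolution -----------------------------------------------------------

im2col_index <- function(hp, wp, kh, kw, cin, stride, n = 1L) {
  key <- paste(hp, wp, kh, kw, cin, stride, n, sep = "_")
  hit <- .ag$im2col[[key]]
  if (!is.null(hit)) return(hit)
  ho <- (hp - kh) %/% stride + 1L
  wo <- (wp - kw) %/% stride + 1L
  base <- outer(seq.int(0L, by = stride, length.out = ho),
                seq.int(0L, by = stride, length.out = wo) * hp, "+")
  off <- as.vector(outer(seq_len(kh) - 1L, (seq_len(kw) - 1L) * hp, "+"))
  idx <- outer(as.vector(base), off, "+") + 1L
  idx <- outer(as.vector(idx), (seq_len(cin) - 1L) * (hp * wp), "+")
  dim(idx) <- c(ho * wo, kh * kw * cin)
  idxS <- if (n == 1L) as.vector(idx) else
    as.vector(idx[rep(seq_len(ho * wo), times = n), ] +
                rep((seq_len(n) - 1L) * (hp * wp * cin), each = ho * wo))
  out <- list(idx = idx, idxS = idxS, ho = ho, wo = wo)
  assign(key, out, envir = .ag$im2col)
  out
}

# 2-D convolution on (h, w, cin, n) with weights (kh, kw, cin/groups, cout)
# and optional bias (length cout); zero padding, grouped when groups > 1.
# The im2col patch matrix is stacked over the batch so each call does one
# BLAS multiply per group.
ag_conv2d <- function(x, w, b = NULL, stride = 1L, pad = 1L, groups = 1L) {
  x <- as_ag(x); w <- as_ag(w)
  if (!is.null(b)) b <- as_ag(b)
  d <- dim(x$value)
  dw <- dim(w$value)
  kh <- dw[1]; kw <- dw[2]; cpg <- dw[3]; cout <- dw[4]
  cin <- d[3]; n <- d[4]
  if (cin != cpg * groups) stop("conv2d: input channels ", cin,
                                " incompatible with weight (", cpg, " x ", groups, " groups)")
  hp <- d[1] + 2L * pad; wp2 <- d[2] + 2L * pad
  ii <- im2col_index(hp, wp2, kh, kw, cin, stride, n)
  ho <- ii$ho; wo <- ii$wo
  kk <- kh * kw
  cog <- cout %/% groups
  wm <- w$value; dim(wm) <- c(kk * cpg, cout)
  if (pad > 0L) {
    xp <- array(0, c(hp, wp2, cin, n))
    xp[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x$value
  } else xp <- x$value
  P <- xp[ii$idxS]
  dim(P) <- c(ho * wo * n, kk * cin)
  Y <- matrix(0, ho * wo * n, cout)
  for (g in seq_len(groups)) {
    cols <- (g - 1L) * cpg * kk + seq_len(cpg * kk)
    og <- (g - 1L) * cog + seq_len(cog)
    Y[, og] <- P[, cols, drop = FALSE] %*% wm[, og, drop = FALSE]
  }
  if (!is.null(b)) Y <- Y + rep(b$value, each = ho * wo * n)
  dim(Y) <- c(ho, wo, n, cout)
  out <- aperm(Y, c(1L, 2L, 4L, 3L))
  keepP <- .ag$on && w$requires
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  ag_new(out, parents, function(node) {
    ex <- node$extras
    xT <- node$parents[[1]]; wT <- node$parents[[2]]
    d <- dim(xT$value)
    kh <- ex$kh; kw <- ex$kw; kk <- kh * kw
    cpg <- ex$cpg; cout <- ex$cout; cog <- cout %/% ex$groups
    stride <- ex$stride; pad <- ex$pad
    ho <- ex$ho; wo <- ex$wo; n <- d[4]
    wm <- wT$value; dim(wm) <- c(kk * cpg, cout)
    gm <- aperm(node$grad, c(1L, 2L, 4L, 3L))
    dim(gm) <- c(ho * wo * n, cout)
    need_gw <- wT$requires
    need_gx <- xT$requires
    gW <- if (need_gw) matrix(0, kk * cpg, cout) else NULL
    gP <- if (need_gx) matrix(0, ho * wo * n, kk * d[3]) else NULL
    for (g in seq_len(ex$groups)) {
      cols <- (g - 1L) * cpg * kk + seq_len(cpg * kk)
      og <- (g - 1L) * cog + seq_len(cog)
      if (need_gw)
        gW[, og] <- crossprod(ex$P[, cols, drop = FALSE], gm[, og, drop = FALSE])
      if (need_gx)
        gP[, cols] <- tcrossprod(gm[, og, drop = FALSE], wm[, og, drop = FALSE])
    }
    if (need_gx) {
      hp <- d[1] + 2L * pad; wp2 <- d[2] + 2L * pad
      dim(gP) <- c(ho, wo, n, kh, kw, d[3])
      gxp <- array(0, c(hp, wp2, n, d[3]))
      for (kj in seq_len(kw)) for (ki in seq_len(kh)) {
        rr <- ki + stride * (seq_len(ho) - 1L)
        cc <- kj + stride * (seq_len(wo) - 1L)
        gxp[rr, cc, , ] <- gxp[rr, cc, , ] + gP[, , , ki, kj, ]
      }
      gx <- gxp[pad + seq_len(d[1]), pad + seq_len(d[2]), , , drop = FALSE]
      acc_grad(xT, aperm(gx, c(1L, 2L, 4L, 3L)))
    }
    if (need_gw) { dim(gW) <- dim(wT$value); acc_grad(wT, gW) }
    if (length(node$parents) == 3L && node$parents[[3]]$requires)
      acc_grad(node$parents[[3]], colSums(gm))
  }, extras = list(P = if (keepP) P, kh = kh, kw = kw, cpg = cpg, cout = cout,
                   groups = groups, stride = stride, pad = pad, ho = ho, wo = wo))
}
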