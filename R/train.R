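# Training loop, AMSGrad Adam, per-cascade gradient profiling, evaluation.

#' Training configuration
#'
#' Defaults follow the reference training schedule: Adam with AMSGrad,
#' initial learning rate 0.002, stepwise decay by `lr_gamma = 0.1` every
#' `lr_step = 60` iterations, 120 iterations of 10,000 randomly drawn slices
#' at mini-batch size one, each slice undersampled by four- or eightfold
#' acceleration with equal probability. Tiny CPU runs shrink `iterations`
#' and `steps_per_iteration` but keep the schedule semantics: an "iteration"
#' is an epoch-like pass of `steps_per_iteration` gradient steps.
#'
#' @param lr initial learning rate.
#' @param lr_step decay the learning rate every this many iterations.
#' @param lr_gamma multiplicative decay factor.
#' @param iterations number of iterations (epochs).
#' @param steps_per_iteration gradient steps per iteration.
#' @param accelerations acceleration factors drawn uniformly per step.
#' @param random_offset draw the equidistant mask offset uniformly from
#'   `[0, R)` per step instead of fixing it at 0.
#' @param val_slices number of held-out slices scored after each iteration
#'   (0 disables validation).
#' @param seed RNG seed for sampling, masks and noise order.
#' @return a `"train_config"` list.
#' @export
train_config <- function(lr = 0.002, lr_step = 60L, lr_gamma = 0.1,
                         iterations = 120L, steps_per_iteration = 10000L,
                         accelerations = c(4L, 8L), random_offset = FALSE,
                         val_slices = 0L, seed = 0L) {
  stopifnot(lr > 0, lr_gamma > 0, lr_gamma <= 1, iterations >= 1,
            steps_per_iteration >= 1)
  structure(list(lr = lr, lr_step = as.integer(lr_step), lr_gamma = lr_gamma,
                 iterations = as.integer(iterations),
                 steps_per_iteration = as.integer(steps_per_iteration),
                 accelerations = as.integer(accelerations),
                 random_offset = isTRUE(random_offset),
                 val_slices = as.integer(val_slices),
                 seed = as.integer(seed)),
            class = "train_config")
}

## ---- AMSGrad Adam ----------------------------------------------------------

adam_init <- function(params, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      amsgrad = TRUE) {
  st <- new.env(parent = emptyenv())
  st$m <- lapply(params, function(p) { z <- p$value; z[] <- 0; z })
  st$v <- st$m
  st$vhat <- st$m
  st$t <- 0L
  st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps; st$amsgrad <- amsgrad
  st
}

adam_step <- function(st, params, lr) {
  st$t <- st$t + 1L
  b1 <- st$beta1; b2 <- st$beta2
  bc1 <- 1 - b1^st$t; bc2 <- 1 - b2^st$t
  for (i in seq_along(params)) {
    p <- params[[i]]
    g <- p$grad
    if (is.null(g)) next
    st$m[[i]] <- b1 * st$m[[i]] + (1 - b1) * g
    st$v[[i]] <- b2 * st$v[[i]] + (1 - b2) * g * g
    vv <- if (st$amsgrad) {
      st$vhat[[i]] <- pmax(st$vhat[[i]], st$v[[i]])
      st$vhat[[i]]
    } else st$v[[i]]
    p$value <- p$value - lr * (st$m[[i]] / bc1) / (sqrt(vv / bc2) + st$eps)
  }
  invisible(NULL)
}

## ---- gradient bookkeeping --------------------------------------------------

cascade_param_groups <- function(model) {
  lapply(model$cascades, parameters)
}

mean_abs_grads <- function(groups) {
  vapply(groups, function(ps) {
    tot <- 0; n <- 0
    for (p in ps) if (!is.null(p$grad)) {
      tot <- tot + sum(abs(p$grad)); n <- n + length(p$grad)
    }
    if (n == 0) 0 else tot / n
  }, 0)
}

#' Per-cascade mean absolute gradient
#'
#' Runs one forward and backward pass of the training loss on a single
#' undersampled slice and reports, for each cascade, the mean absolute
#' gradient over that cascade's parameters (sub-network weights and the
#' data-consistency weight). A healthy unrolled network has strictly
#' positive values in every cascade, including the first.
#'
#' @param model a built `"dircn_model"`.
#' @param ku masked complex k-space `(kx, ky, coil)`.
#' @param mask the corresponding `"undersampling_mask"`.
#' @param target ground-truth magnitude image.
#' @param data_range dynamic range for the SSIM term (default `max(target)`).
#' @return numeric vector of length `m` (the cascade count).
#' @export
gradient_profile <- function(model, ku, mask, target,
                             data_range = max(target)) {
  params <- parameters(model)
  zero_grads(params)
  ag_tape_reset()
  fm <- forward_model(model, ku, mask)
  loss <- training_loss_graph(fm$magnitude, target, data_range)
  ag_backward(loss)
  prof <- mean_abs_grads(cascade_param_groups(model))
  zero_grads(params)
  prof
}

## ---- training --------------------------------------------------------------

#' Train a reconstruction model on a synthetic dataset
#'
#' Optimizes the (1 - SSIM) + L1 objective over randomly drawn slices with
#' AMSGrad Adam and the stepwise learning-rate schedule. Each step draws a
#' volume and slice uniformly, an acceleration factor from
#' `config$accelerations`, builds the equidistant mask (8% center for
#' fourfold, 4% for eightfold), masks the stored k-space and backpropagates
#' through sensitivity estimation and all cascades. Fully deterministic
#' given the config seed.
#'
#' @param model a built `"dircn_model"` (modified in place and returned).
#' @param data_path directory of volumes written by [make_dataset()].
#' @param config a [train_config()].
#' @param val_path optional directory of validation volumes; its first
#'   `config$val_slices` slices are scored with the training loss after each
#'   iteration.
#' @param record_gradients record the per-cascade mean absolute gradient at
#'   every step (the gradient profile).
#' @param verbose print per-iteration progress.
#' @return a `"dircn_fit"` list: `model`, `history` (per-step data frame with
#'   iteration, step, lr, loss), `grad_profile` (steps x m matrix or NULL),
#'   `val` (per-iteration data frame or NULL).
#' @export
train_model <- function(model, data_path, config = train_config(),
                        val_path = NULL, record_gradients = TRUE,
                        verbose = FALSE) {
  files <- sort(list.files(data_path, pattern = "\\.rds$", full.names = TRUE))
  if (length(files) == 0L) stop("no volumes found in ", data_path)
  vols <- lapply(files, read_volume)
  val_vols <- if (!is.null(val_path))
    lapply(sort(list.files(val_path, pattern = "\\.rds$", full.names = TRUE)),
           read_volume)
  params <- parameters(model)
  opt <- adam_init(params)
  set.seed(config$seed)
  total_steps <- config$iterations * config$steps_per_iteration
  hist <- data.frame(step = seq_len(total_steps), iteration = 0L,
                     lr = 0, loss = NA_real_)
  gprof <- if (record_gradients)
    matrix(0, total_steps, model$config$m) else NULL
  step <- 0L
  for (it in seq_len(config$iterations)) {
    lr <- config$lr * config$lr_gamma^((it - 1L) %/% config$lr_step)
    for (s in seq_len(config$steps_per_iteration)) {
      step <- step + 1L
      vi <- sample.int(length(vols), 1L)
      vol <- vols[[vi]]
      si <- sample.int(dim(vol$kspace)[4], 1L)
      R <- config$accelerations[sample.int(length(config$accelerations), 1L)]
      off <- if (config$random_offset) sample.int(R, 1L) - 1L else 0L
      mask <- make_equidistant_mask(dim(vol$kspace)[2], R,
                                    default_center_fraction(R), offset = off)
      ku <- apply_mask(vol$kspace[, , , si], mask)
      gt <- vol$reconstruction_rss[, , si]
      zero_grads(params)
      ag_tape_reset()
      fm <- forward_model(model, ku, mask)
      loss <- training_loss_graph(fm$magnitude, gt, max(gt))
      lv <- loss$value
      if (!is.finite(lv)) stop("non-finite training loss at step ", step)
      ag_backward(loss)
      if (record_gradients)
        gprof[step, ] <- mean_abs_grads(cascade_param_groups(model))
      adam_step(opt, params, lr)
      hist$iteration[step] <- it
      hist$lr[step] <- lr
      hist$loss[step] <- lv
    }
    if (verbose)
      message(sprintf("iteration %d/%d  lr %.2e  mean loss %.4f", it,
                      config$iterations, lr,
                      mean(hist$loss[hist$iteration == it])))
  }
  val <- NULL
  if (!is.null(val_vols) && config$val_slices > 0L)
    val <- data.frame(loss = validation_loss(model, val_vols, config))
  zero_grads(params)
  structure(list(model = model, history = hist, grad_profile = gprof,
                 val = val, config = config),
            class = "dircn_fit")
}

validation_loss <- function(model, vols, config) {
  losses <- c()
  n <- 0L
  for (vol in vols) for (si in seq_len(dim(vol$kspace)[4])) {
    if (n >= config$val_slices) break
    R <- config$accelerations[(n %% length(config$accelerations)) + 1L]
    mask <- make_equidistant_mask(dim(vol$kspace)[2], R,
                                  default_center_fraction(R))
    ku <- apply_mask(vol$kspace[, , , si], mask)
    gt <- vol$reconstruction_rss[, , si]
    pred <- reconstruct(model, ku, mask)
    losses <- c(losses, training_loss(pred, gt, max(gt)))
    n <- n + 1L
  }
  mean(losses)
}

## ---- evaluation ------------------------------------------------------------

#' Evaluate reconstructions on a dataset
#'
#' Reconstructs every volume at each requested acceleration with fixed
#' (offset-0) equidistant masks and reports per-volume SSIM (mean over
#' slices, volume-level data range), NMSE and PSNR (volume-level), plus the
#' zero-filled baseline when requested. Aggregates are unweighted means over
#' volumes.
#'
#' @param model a `"dircn_model"`, or `NULL` to score only the zero-filled
#'   baseline.
#' @param data_path directory of volumes from [make_dataset()].
#' @param accelerations acceleration factors to evaluate.
#' @param include_zero_filled also score the zero-filled baseline.
#' @return a `"metrics_report"`: list with `per_volume` (data frame with
#'   columns file, contrast, acceleration, method, ssim, nmse, psnr) and
#'   `summary` (means by method, acceleration and contrast, plus overall
#'   rows with contrast `"all"`).
#' @export
evaluate_model <- function(model, data_path, accelerations = c(4L, 8L),
                           include_zero_filled = TRUE) {
  files <- sort(list.files(data_path, pattern = "\\.rds$", full.names = TRUE))
  if (length(files) == 0L) stop("no volumes found in ", data_path)
  rows <- list()
  for (f in files) {
    vol <- read_volume(f)
    d <- dim(vol$kspace)
    for (R in accelerations) {
      mask <- make_equidistant_mask(d[2], R, default_center_fraction(R))
      gt <- vol$reconstruction_rss
      dr <- max(gt)
      methods <- c(if (!is.null(model)) "model", if (include_zero_filled) "zero_filled")
      for (method in methods) {
        pred <- array(0, dim(gt))
        for (si in seq_len(d[4])) {
          ku <- apply_mask(vol$kspace[, , , si], mask)
          pred[, , si] <- if (method == "model") reconstruct(model, ku, mask)
                          else zero_filled(ku)
        }
        s <- mean(vapply(seq_len(d[4]), function(si)
          ssim(pred[, , si], gt[, , si], dr), 0))
        rows[[length(rows) + 1L]] <- data.frame(
          file = basename(f), contrast = vol$contrast, acceleration = R,
          method = method, ssim = s, nmse = nmse(pred, gt),
          psnr = psnr(pred, gt, dr))
      }
    }
  }
  per_volume <- do.call(rbind, rows)
  agg <- function(df) data.frame(ssim = mean(df$ssim), nmse = mean(df$nmse),
                                 psnr = mean(df$psnr))
  keys <- unique(per_volume[c("method", "acceleration", "contrast")])
  summ <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    sel <- per_volume$method == k$method &
      per_volume$acceleration == k$acceleration &
      per_volume$contrast == k$contrast
    cbind(k, agg(per_volume[sel, ]))
  }))
  overall_keys <- unique(per_volume[c("method", "acceleration")])
  overall <- do.call(rbind, lapply(seq_len(nrow(overall_keys)), function(i) {
    k <- overall_keys[i, ]
    sel <- per_volume$method == k$method &
      per_volume$acceleration == k$acceleration
    cbind(k, contrast = "all", agg(per_volume[sel, ]))
  }))
  summary <- rbind(summ, overall[names(summ)])
  rownames(summary) <- NULL
  structure(list(per_volume = per_volume, summary = summary),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Reconstruction metrics (aggregate rows have contrast 'all'):\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write the per-volume metrics table to CSV
#'
#' @param report a `"metrics_report"` from [evaluate_model()].
#' @param path output CSV path.
#' @export
write_metrics_csv <- function(report, path) {
  utils::write.csv(report$per_volume, path, row.names = FALSE)
  invisible(path)
}

## ---- checkpoints -----------------------------------------------------------

#' Save model parameters and configuration
#'
#' Stores the `"model_config"` plus a named list of all parameter values;
#' [load_checkpoint()] rebuilds the model and restores them.
#'
#' @param model a `"dircn_model"`.
#' @param path output file.
#' @export
save_checkpoint <- function(model, path) {
  values <- lapply(parameters(model), function(p) p$value)
  saveRDS(list(config = model$config, values = values), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint` returns the restored `"dircn_model"`.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_model(ck$config)
  params <- parameters(model)
  if (!identical(sort(names(params)), sort(names(ck$values))))
    stop("checkpoint parameter names do not match the rebuilt model")
  for (nm in names(params)) params[[nm]]$value <- ck$values[[nm]]
  model
}
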