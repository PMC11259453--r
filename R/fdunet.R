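#' FDU-net architecture configuration
#'
#' The adapted FDU-net maps the measurement vector to the two-channel
#' optical volume in three modules: a fully connected layer with tanh
#' activation (the learned inverse operator, Y = WX + B then tanh), a 3D
#' convolutional encoder--decoder (kernel 3^3, relu, dropout after each
#' hidden layer, last layer linear with 2 output channels), and a two-level
#' 3D U-Net refiner (max-pooling down, transposed-convolution up, skip
#' concatenation).
#'
#' @param input_dim measurement channel count.
#' @param output_dim spatial target dimensions (x, y, z).
#' @param n_encoder_decoder_conv_layers encoder--decoder depth.
#' @param filters_per_layer filters in the hidden encoder--decoder layers.
#' @param unet_filters length-2: filters at the two U-Net levels.
#' @param dropout_rate dropout after each hidden encoder--decoder layer.
#' @param fc_activation,conv_activation activation names (documentation of
#'   the architecture; `"tanh"` and `"relu"` are what is implemented).
#' @return an object of class `"fdunet_config"`.
#' @export
fdunet_config <- function(input_dim = 1152L,
                          output_dim = c(16L, 16L, 8L),
                          n_encoder_decoder_conv_layers = 4L,
                          filters_per_layer = 64L,
                          unet_filters = c(32L, 64L),
                          dropout_rate = 0.2,
                          fc_activation = "tanh",
                          conv_activation = "relu") {
  stopifnot(input_dim >= 1, length(output_dim) == 3,
            n_encoder_decoder_conv_layers >= 2, filters_per_layer >= 1,
            length(unet_filters) == 2, dropout_rate >= 0, dropout_rate < 1,
            fc_activation == "tanh", conv_activation == "relu")
  structure(list(input_dim = as.integer(input_dim),
                 output_dim = as.integer(output_dim),
                 n_encoder_decoder_conv_layers =
                   as.integer(n_encoder_decoder_conv_layers),
                 filters_per_layer = as.integer(filters_per_layer),
                 unet_filters = as.integer(unet_filters),
                 dropout_rate = dropout_rate,
                 fc_activation = fc_activation,
                 conv_activation = conv_activation),
            class = "fdunet_config")
}

#' Training configuration for the FDU-net
#'
#' @param roi_weight weight of the anomaly region in the ROI loss (0.5, 1).
#' @param learning_rate Adamax learning rate.
#' @param max_epochs epoch cap per training stage.
#' @param early_stop_patience epochs without validation improvement before
#'   stopping.
#' @param batch_size minibatch size.
#' @param validation_fraction fraction of examples held out for validation
#'   when no explicit split is given.
#' @param seed RNG seed for initialization, shuffling and dropout.
#' @return an object of class `"fdunet_train_config"`.
#' @export
fdunet_train_config <- function(roi_weight = 0.887,
                                learning_rate = 0.001,
                                max_epochs = 500L,
                                early_stop_patience = 50L,
                                batch_size = 32L,
                                validation_fraction = 1 / 11,
                                seed = 1L) {
  stopifnot(roi_weight > 0.5, roi_weight < 1,
            early_stop_patience < max_epochs,
            learning_rate > 0, batch_size >= 1,
            validation_fraction > 0, validation_fraction < 1)
  structure(list(roi_weight = roi_weight, learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 batch_size = as.integer(batch_size),
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "fdunet_train_config")
}

#' Initialize FDU-net weights
#'
#' Glorot-uniform initialization of all modules, deterministic given the
#' seed.
#'
#' @param config a [fdunet_config()].
#' @param seed integer seed.
#' @return nested parameter list (class `"fdunet_params"`).
#' @export
build_fdu_net <- function(config = fdunet_config(), seed = 1L) {
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  od <- config$output_dim
  nvox_out <- prod(od) * 2L
  F <- config$filters_per_layer
  L <- config$n_encoder_decoder_conv_layers
  chans <- c(2L, rep(F, L - 1L), 2L)
  ed <- lapply(seq_len(L), function(l) init_conv3(chans[l], chans[l + 1]))
  f1 <- config$unet_filters[1]; f2 <- config$unet_filters[2]
  params <- list(
    fc = init_dense(config$input_dim, nvox_out),
    ed = ed,
    un = list(c1 = init_conv3(2L, f1),
              c2 = init_conv3(f1, f2),
              up = init_convtrans(f2, f1),
              c3 = init_conv3(2L * f1, f1),
              out = init_conv3(f1, 2L)))
  structure(params, class = "fdunet_params", config = config)
}

# forward through FC + encoder-decoder; returns activations for backprop
fdnet_forward <- function(params, X, config, training = FALSE) {
  n <- nrow(X)
  od <- config$output_dim
  a_fc <- X %*% params$fc$w + matrix(params$fc$b, n, length(params$fc$b),
                                     byrow = TRUE)
  z_fc <- tanh(a_fc)
  t0 <- array(t(z_fc), c(od, 2L, n))
  acts <- list(z_fc = z_fc, t0 = t0)
  h <- t0
  L <- length(params$ed)
  drops <- vector("list", L)
  hs <- vector("list", L)
  for (l in seq_len(L)) {
    h <- conv3d_forward(h, params$ed[[l]]$w, params$ed[[l]]$b)
    if (l < L) {
      h <- relu_fw(h)
      if (training && config$dropout_rate > 0) {
        drops[[l]] <- dropout_mask(h, config$dropout_rate)
        h <- h * drops[[l]]
      }
    }
    hs[[l]] <- h
  }
  acts$hs <- hs
  acts$drops <- drops
  acts$out <- h
  acts
}

fdnet_backward <- function(params, X, acts, dout, config) {
  L <- length(params$ed)
  g_ed <- vector("list", L)
  dh <- dout
  for (l in rev(seq_len(L))) {
    inp <- if (l == 1) acts$t0 else acts$hs[[l - 1]]
    bk <- conv3d_backward(inp, params$ed[[l]]$w, dh)
    g_ed[[l]] <- list(w = bk$dw, b = bk$db)
    dh <- bk$dx
    if (l > 1) {
      if (!is.null(acts$drops[[l - 1]])) dh <- dh * acts$drops[[l - 1]]
      dh <- relu_bw(dh, acts$hs[[l - 1]])
    }
  }
  n <- nrow(X)
  dz_fc <- matrix(dh, ncol = n)    # (4096 x n): t0 layout is voxels x n
  dz_fc <- t(dz_fc)
  da_fc <- tanh_bw(dz_fc, acts$z_fc)
  list(fc = list(w = crossprod(X, da_fc), b = colSums(da_fc)), ed = g_ed)
}

unet_forward <- function(un, E, training = FALSE, dropout_rate = 0) {
  u1 <- relu_fw(conv3d_forward(E, un$c1$w, un$c1$b))
  p1 <- maxpool3d_forward(u1)
  u2 <- relu_fw(conv3d_forward(p1$y, un$c2$w, un$c2$b))
  t1 <- convtrans3d_forward(u2, un$up$w, un$up$b)
  c1 <- concat_channels(t1, u1)
  u3 <- relu_fw(conv3d_forward(c1, un$c3$w, un$c3$b))
  out <- conv3d_forward(u3, un$out$w, un$out$b)
  list(u1 = u1, p1 = p1, u2 = u2, t1 = t1, c1 = c1, u3 = u3, out = out)
}

unet_backward <- function(un, E, acts, dout) {
  bk_out <- conv3d_backward(acts$u3, un$out$w, dout)
  du3 <- relu_bw(bk_out$dx, acts$u3)
  bk_c3 <- conv3d_backward(acts$c1, un$c3$w, du3)
  sp <- split_channels(bk_c3$dx, dim(acts$t1)[4])
  dt1 <- sp$first; du1_skip <- sp$second
  bk_up <- convtrans3d_backward(acts$u2, un$up$w, dt1)
  du2 <- relu_bw(bk_up$dx, acts$u2)
  bk_c2 <- conv3d_backward(acts$p1$y, un$c2$w, du2)
  dp1 <- maxpool3d_backward(bk_c2$dx, acts$p1$argmax, dim(acts$u1))
  du1 <- relu_bw(dp1 + du1_skip, acts$u1)
  bk_c1 <- conv3d_backward(E, un$c1$w, du1)
  list(grads = list(c1 = list(w = bk_c1$dw, b = bk_c1$db),
                    c2 = list(w = bk_c2$dw, b = bk_c2$db),
                    up = list(w = bk_up$dw, b = bk_up$db),
                    c3 = list(w = bk_c3$dw, b = bk_c3$db),
                    out = list(w = bk_out$dw, b = bk_out$db)),
       dE = bk_c1$dx)
}

#' Combine per-parameter ROI masks
#'
#' Voxel-wise logical OR of the absorption and scattering anomaly masks; the
#' combined mask is applied to both output channels of the loss, penalizing
#' crosstalk between the parameters inside anomalies.
#'
#' @param mask_mua,mask_musp logical arrays of equal shape.
#' @return logical array.
#' @export
combine_roi_masks <- function(mask_mua, mask_musp) {
  if (!identical(dim(mask_mua), dim(mask_musp)))
    stop("mask shape mismatch")
  mask_mua | mask_musp
}

#' Region-of-interest weighted mean-squared-error loss
#'
#' `W_ROI * mean((pred - target)^2)` over mask-true voxels (both channels)
#' plus `(1 - W_ROI) * mean(...)` over mask-false voxels.  When the mask is
#' empty (or full) only the populated term contributes.
#'
#' @param pred,target arrays `[nx, ny, nz, 2, n]` (or without the batch
#'   dimension).
#' @param mask logical array `[nx, ny, nz, n]` (or `[nx, ny, nz]`), applied
#'   to both channels.
#' @param w_roi ROI weight in (0.5, 1).
#' @param gradient if `TRUE` also return d loss / d pred.
#' @return scalar loss, or list `loss`, `grad`.
#' @export
mse_roi_loss <- function(pred, target, mask, w_roi = 0.887, gradient = FALSE) {
  if (!identical(dim(pred), dim(target))) stop("pred/target shape mismatch")
  nd <- length(dim(pred))
  if (nd == 4) { dim(pred) <- c(dim(pred), 1L); dim(target) <- dim(pred) }
  d <- dim(pred)
  if (length(dim(mask)) == 3) dim(mask) <- c(dim(mask), 1L)
  if (!identical(as.integer(dim(mask)), as.integer(d[c(1:3, 5)])))
    stop("mask shape mismatch")
  # expand mask over the channel dimension
  mfull <- array(FALSE, d)
  mfull[, , , 1, ] <- mask
  mfull[, , , 2, ] <- mask
  err2 <- (pred - target)^2
  n_roi <- sum(mfull); n_bg <- length(mfull) - n_roi
  loss <- 0
  if (n_roi > 0) loss <- loss + w_roi * sum(err2[mfull]) / n_roi
  if (n_bg > 0) loss <- loss + (1 - w_roi) * sum(err2[!mfull]) / n_bg
  if (!gradient) return(loss)
  grad <- 2 * (pred - target)
  if (n_roi > 0) grad[mfull] <- grad[mfull] * (w_roi / n_roi)
  if (n_bg > 0) grad[!mfull] <- grad[!mfull] * ((1 - w_roi) / n_bg)
  list(loss = loss, grad = grad)
}

#' Fit the FDU-net
#'
#' Two-stage training: the fully connected + encoder--decoder modules are
#' trained first on (normalized measurements -> normalized targets) with the
#' ROI-weighted loss and then frozen; the U-Net refiner is trained second on
#' the frozen first-stage outputs with the same loss.  Both stages use
#' Adamax with early stopping on the validation loss (weights are restored
#' to the best validation epoch).  Fully deterministic given the training
#' seed.
#'
#' @param x numeric matrix of raw measurements, examples in rows.
#' @param y target array `[nx, ny, nz, 2, n]` in mm^-1 (raw, not yet
#'   normalized).
#' @param mask logical combined-ROI array `[nx, ny, nz, n]`.
#' @param config a [fdunet_config()].
#' @param train a [fdunet_train_config()].
#' @param input_stats,target_stats optional pre-fitted
#'   [fit_input_stats()] / [fit_target_stats()]; fitted on the training
#'   split when `NULL`.
#' @param validation_idx optional explicit validation example indices.
#' @param protocol_hash optional provenance hash of the scan protocol.
#' @param verbose print per-epoch losses.
#' @return an object of class `"fdu_net"` with elements `params`,
#'   `config`, `train`, `history` (per stage), `input_stats`,
#'   `target_stats`, `elapsed_s`.
#' @export
fdu_net <- function(x, y, mask, config = NULL,
                    train = fdunet_train_config(),
                    input_stats = NULL, target_stats = NULL,
                    validation_idx = NULL, protocol_hash = NULL,
                    verbose = FALSE) {
  t_start <- proc.time()[3]
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2) stop("empty or degenerate dataset")
  if (is.null(config)) config <- fdunet_config(input_dim = ncol(x),
                                               output_dim = dim(y)[1:3])
  stopifnot(ncol(x) == config$input_dim,
            identical(as.integer(dim(y)[1:3]), config$output_dim),
            dim(y)[5] == n, dim(mask)[4] == n)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(train$seed)
  if (is.null(validation_idx)) {
    n_val <- max(1L, round(n * train$validation_fraction))
    validation_idx <- sample(n, n_val)
  }
  tr_idx <- setdiff(seq_len(n), validation_idx)
  if (is.null(input_stats))
    input_stats <- fit_input_stats(x[tr_idx, , drop = FALSE],
                                   protocol_hash = protocol_hash)
  if (is.null(target_stats))
    target_stats <- fit_target_stats(y[, , , , tr_idx, drop = FALSE])
  Xn <- apply_input_stats(x, input_stats)
  Yn <- normalize_targets(y, target_stats)
  params <- build_fdu_net(config, seed = train$seed)
  run_stage <- function(stage, params) {
    if (stage == 1) {
      sub <- params[c("fc", "ed")]
      with_sub <- function(p) { full <- params; full$fc <- p$fc; full$ed <- p$ed; full }
      fw_tr <- function(p, idx) {
        a <- fdnet_forward(with_sub(p), Xn[idx, , drop = FALSE],
                           config, training = TRUE)
        list(out = a$out, ctx = a, idx = idx)
      }
      bw <- function(p, f, dout)
        fdnet_backward(with_sub(p), Xn[f$idx, , drop = FALSE],
                       f$ctx, dout, config)
      fw_ev <- function(p, idx)
        fdnet_forward(with_sub(p), Xn[idx, , drop = FALSE],
                      config, training = FALSE)$out
    } else {
      E_all <- stage1_outputs(params, Xn, config, batch = 64L)
      sub <- params["un"]
      fw_tr <- function(p, idx) {
        E <- E_all[, , , , idx, drop = FALSE]
        a <- unet_forward(p$un, E)
        list(out = a$out, ctx = a, E = E, idx = idx)
      }
      bw <- function(p, f, dout)
        list(un = unet_backward(p$un, f$E, f$ctx, dout)$grads)
      fw_ev <- function(p, idx)
        unet_forward(p$un, E_all[, , , , idx, drop = FALSE])$out
    }
    opt <- adamax_init(sub)
    best <- list(loss = Inf, params = sub, epoch = 0L)
    hist <- data.frame(epoch = integer(), train_loss = numeric(),
                       val_loss = numeric())
    tstep <- 0L
    for (ep in seq_len(train$max_epochs)) {
      ord <- sample(tr_idx)
      tl <- 0; nb <- 0L
      for (b0 in seq(1, length(ord), by = train$batch_size)) {
        idx <- ord[b0:min(b0 + train$batch_size - 1L, length(ord))]
        f <- fw_tr(sub, idx)
        lg <- mse_roi_loss(f$out, Yn[, , , , idx, drop = FALSE],
                           mask[, , , idx, drop = FALSE],
                           train$roi_weight, gradient = TRUE)
        g <- bw(sub, f, lg$grad)
        tstep <- tstep + 1L
        st <- adamax_step(sub, g, opt, train$learning_rate, tstep)
        sub <- st$p; opt <- st$s
        tl <- tl + lg$loss; nb <- nb + 1L
      }
      vl <- eval_loss(fw_ev, sub, validation_idx, Yn, mask, train,
                      batch = 64L)
      hist <- rbind(hist, data.frame(epoch = ep, train_loss = tl / nb,
                                     val_loss = vl))
      if (verbose)
        message(sprintf("stage %d epoch %3d train %.5g val %.5g",
                        stage, ep, tl / nb, vl))
      if (vl < best$loss) best <- list(loss = vl, params = sub, epoch = ep)
      if (ep - best$epoch >= train$early_stop_patience) break
    }
    list(params = best$params, history = hist, best_epoch = best$epoch)
  }
  s1 <- run_stage(1, params)
  params[c("fc", "ed")] <- s1$params[c("fc", "ed")]
  s2 <- run_stage(2, params)
  params["un"] <- s2$params["un"]
  structure(list(params = params, config = config, train = train,
                 history = list(stage1 = s1$history, stage2 = s2$history),
                 best_epochs = c(stage1 = s1$best_epoch,
                                 stage2 = s2$best_epoch),
                 input_stats = input_stats, target_stats = target_stats,
                 protocol_hash = protocol_hash,
                 validation_idx = sort(validation_idx),
                 elapsed_s = proc.time()[3] - t_start),
            class = "fdu_net")
}

# frozen stage-1 outputs for the whole dataset, batched
stage1_outputs <- function(params, Xn, config, batch = 64L) {
  n <- nrow(Xn)
  out <- NULL
  for (b0 in seq(1, n, by = batch)) {
    idx <- b0:min(b0 + batch - 1L, n)
    o <- fdnet_forward(params, Xn[idx, , drop = FALSE], config,
                       training = FALSE)$out
    if (is.null(out)) out <- array(0, c(dim(o)[1:4], n))
    out[, , , , idx] <- o
  }
  out
}

eval_loss <- function(fw_ev, sub, idx_all, Yn, mask, train, batch = 64L) {
  tot <- 0; m <- 0L
  for (b0 in seq(1, length(idx_all), by = batch)) {
    idx <- idx_all[b0:min(b0 + batch - 1L, length(idx_all))]
    out <- fw_ev(sub, idx)
    tot <- tot + mse_roi_loss(out, Yn[, , , , idx, drop = FALSE],
                              mask[, , , idx, drop = FALSE],
                              train$roi_weight) * length(idx)
    m <- m + length(idx)
  }
  tot / m
}

#' Predict optical volumes from measurements
#'
#' Applies the stored input z-score transform, the full network forward pass
#' (dropout disabled), and the inverse target min-max transform, returning
#' physical-unit volumes.  Values are clamped at a small positive floor with
#' a warning if the denormalized prediction is non-positive.
#'
#' @param object a fitted [fdu_net()].
#' @param newdata measurement matrix (examples x channels) or vector.
#' @param protocol_hash optional hash of the protocol the measurements were
#'   acquired with; must match the model's when both are non-`NULL`.
#' @param ... unused.
#' @return list with arrays `mua`, `musp` `[nx, ny, nz, n]` (mm^-1) and
#'   `elapsed_s` (forward-pass wall clock).
#' @export
predict.fdu_net <- function(object, newdata, protocol_hash = NULL, ...) {
  if (!is.null(protocol_hash) && !is.null(object$protocol_hash) &&
      !identical(protocol_hash, object$protocol_hash))
    stop("protocol hash mismatch between model and measurements")
  X <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1) else as.matrix(newdata)
  t0 <- proc.time()[3]
  Xn <- apply_input_stats(X, object$input_stats)
  E <- fdnet_forward(object$params, Xn, object$config, training = FALSE)$out
  out_n <- unet_forward(object$params$un, E)$out
  elapsed <- proc.time()[3] - t0
  out <- denormalize_predictions(out_n, object$target_stats)
  if (any(out <= 0)) {
    warning("non-positive predicted optical properties; clamped")
    out[out <= 0] <- 1e-6
  }
  list(mua = out[, , , 1, , drop = TRUE],
       musp = out[, , , 2, , drop = TRUE],
       normalized = out_n,
       elapsed_s = elapsed)
}

#' @export
print.fdu_net <- function(x, ...) {
  cfg <- x$config
  np <- sum(unlist(rapply(x$params, length, how = "list", classes = "ANY")))
  cat("FDU-net (FC + 3D conv encoder-decoder + U-Net)\n")
  cat(sprintf("  input %d channels -> output %s x 2 parameters\n",
              cfg$input_dim, paste(cfg$output_dim, collapse = "x")))
  cat(sprintf("  %d encoder-decoder layers (%d filters), U-Net filters %s, dropout %.1f\n",
              cfg$n_encoder_decoder_conv_layers, cfg$filters_per_layer,
              paste(cfg$unet_filters, collapse = "/"), cfg$dropout_rate))
  cat(sprintf("  %d trainable values; best epochs %d (stage 1) / %d (stage 2); trained in %.1f s\n",
              np, x$best_epochs[1], x$best_epochs[2], x$elapsed_s))
  invisible(x)
}

#' @export
summary.fdu_net <- function(object, ...) {
  print(object)
  h1 <- object$history$stage1; h2 <- object$history$stage2
  cat(sprintf("  stage 1: %d epochs, final val loss %.5g\n",
              nrow(h1), h1$val_loss[nrow(h1)]))
  cat(sprintf("  stage 2: %d epochs, final val loss %.5g\n",
              nrow(h2), h2$val_loss[nrow(h2)]))
  invisible(object)
}

#' @export
plot.fdu_net <- function(x, ...) {
  h1 <- x$history$stage1; h2 <- x$history$stage2
  graphics::par(mfrow = c(1, 2))
  for (h in list(h1, h2)) {
    graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                      lty = 1, col = c("grey40", "firebrick"),
                      xlab = "epoch", ylab = "ROI-weighted MSE", log = "y", ...)
    graphics::legend("topright", c("train", "validation"), lty = 1,
                     col = c("grey40", "firebrick"), bty = "n")
  }
  graphics::par(mfrow = c(1, 1))
  invisible(x)
}

#' @export
coef.fdu_net <- function(object, ...) object$params
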