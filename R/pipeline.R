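#' Experiment scale presets
#'
#' Bundles every stage configuration of the end-to-end study at a given
#' scale.  `"full"` declares the headline study conditions (10,000 training
#' + 1,000 validation examples, the complete 12 x 16 linescan lattice, the
#' 64-filter network, 500-epoch training); `"desk"` is a reduced study that
#' runs end-to-end on a single CPU core (500 + 50 examples, a 2 x 3 probe
#' lattice, a narrower network, shorter training); `"tiny"` is a smoke-test
#' scale.  Geometry, optical-property randomization and physics are
#' identical across presets; only the probe lattice, dataset size and
#' network capacity change.
#'
#' @param preset `"tiny"`, `"desk"` or `"full"`.
#' @param seed global experiment seed.
#' @return an object of class `"dot_experiment_config"`.
#' @export
experiment_config <- function(preset = c("desk", "tiny", "full"), seed = 1L) {
  preset <- match.arg(preset)
  geometry <- volume_geometry()
  probe <- probe_layout()
  p <- switch(preset,
    tiny = list(n_train = 200L, n_val = 40L, step_mm = 16, n_x = 3L, n_y = 3L,
                depths_mm = c(5, 10, 15), n_per_depth = 10L,
                filters = 8L, unet_filters = c(8L, 16L), dropout = 0.2,
                max_epochs = 25L, patience = 6L, batch = 16L,
                lr = 0.003, fem_cap = 8L, n_calib = 3L),
    desk = list(n_train = 500L, n_val = 25L, step_mm = 16, n_x = 2L, n_y = 4L,
                depths_mm = c(5, 10, 15), n_per_depth = 17L,
                filters = 8L, unet_filters = c(8L, 16L), dropout = 0.2,
                max_epochs = 25L, patience = 6L, batch = 32L,
                lr = 0.003, fem_cap = 8L, n_calib = 4L),
    full = list(n_train = 10000L, n_val = 1000L, step_mm = 4, n_x = NULL,
                n_y = NULL,
                depths_mm = c(2.5, 5, 7.5, 10, 15), n_per_depth = 30L,
                filters = 64L, unet_filters = c(32L, 64L), dropout = 0.2,
                max_epochs = 500L, patience = 50L, batch = 32L,
                lr = 0.001, fem_cap = 25L, n_calib = 10L))
  protocol <- build_scan_protocol(geometry, probe, step_mm = p$step_mm,
                                  n_x = p$n_x, n_y = p$n_y)
  structure(list(
    preset = preset, seed = as.integer(seed),
    geometry = geometry, probe = probe, protocol = protocol,
    dataset = dataset_spec(),
    solver = fd_solver_config(tol = 1e-6),
    noise = noise_model(),
    fem = fem_recon_config(max_iterations = p$fem_cap),
    net = fdunet_config(input_dim = protocol$n_channels,
                        output_dim = coarse_target_grid(geometry)$dim,
                        filters_per_layer = p$filters,
                        unet_filters = p$unet_filters,
                        dropout_rate = p$dropout),
    train = fdunet_train_config(
      learning_rate = p$lr,
      max_epochs = p$max_epochs,
      early_stop_patience = p$patience,
      batch_size = p$batch,
      validation_fraction = p$n_val / (p$n_train + p$n_val),
      seed = as.integer(seed)),
    n_train = p$n_train, n_val = p$n_val, n_calib = p$n_calib,
    depths_mm = p$depths_mm, n_per_depth = p$n_per_depth),
    class = "dot_experiment_config")
}

#' Simulate a training set of randomized phantoms
#'
#' Samples phantoms, rasterizes them on the fine simulation grid, runs the
#' forward model (reusing one homogeneous-background solver factorization as
#' preconditioner), adds noise, and assembles network-ready tensors.  Seeded
#' and reproducible: phantom i uses seed `seed + i`, its noise realization
#' `seed + 500000 + i`.
#'
#' @param n number of examples.
#' @param config a [experiment_config()].
#' @param seed base seed (defaults to the experiment seed).
#' @param progress print progress every 100 examples.
#' @return list with `x` (n x channels), `y` (targets, mm^-1,
#'   `[16,16,8,2,n]`), `mask` (combined ROI, `[16,16,8,n]`), `masks_mua`,
#'   `masks_musp`, `phantoms`, `protocol_hash`.
#' @export
simulate_training_set <- function(n, config, seed = config$seed,
                                  progress = FALSE) {
  geometry <- config$geometry
  protocol <- config$protocol
  tg <- coarse_target_grid(geometry)
  fg <- fine_grid(geometry)
  ref <- list(mua = array(config$dataset$bg_mua_mean, geometry$fine_dim),
              musp = array(config$dataset$bg_musp_mean, geometry$fine_dim))
  ctx <- solver_context(ref, geometry, config$solver, type = "direct")
  X <- matrix(0, n, protocol$n_channels)
  Y <- array(0, c(tg$dim, 2L, n))
  M <- array(FALSE, c(tg$dim, n))
  Mm <- array(FALSE, c(tg$dim, n)); Ms <- array(FALSE, c(tg$dim, n))
  phantoms <- vector("list", n)
  for (i in seq_len(n)) {
    ph <- sample_phantom(config$dataset, geometry, seed = seed + i)
    phantoms[[i]] <- ph
    fine <- rasterize_phantom(ph, fg)
    meas <- simulate_scan(fine, protocol, config$solver, precond = ctx)
    meas <- add_noise(meas, config$noise, seed = seed + 500000L + i)
    X[i, ] <- meas$values
    Y[, , , , i] <- prepare_target(fine, geometry)
    coarse <- rasterize_phantom(ph, tg)
    M[, , , i] <- coarse$mask_combined
    Mm[, , , i] <- coarse$mask_mua; Ms[, , , i] <- coarse$mask_musp
    if (progress && i %% 100 == 0) message(sprintf("  simulated %d/%d", i, n))
  }
  list(x = X, y = Y, mask = M, masks_mua = Mm, masks_musp = Ms,
       phantoms = phantoms, protocol_hash = protocol$hash)
}

#' Simulate measurements for a prepared depth test set
#'
#' @param examples output of [make_depth_test_set()].
#' @param config a [experiment_config()].
#' @param seed base seed for the noise realizations.
#' @return `examples` with a `measurements` element added to each.
#' @export
simulate_test_measurements <- function(examples, config,
                                       seed = config$seed + 900000L) {
  geometry <- config$geometry
  fg <- fine_grid(geometry)
  ref <- list(mua = array(config$dataset$bg_mua_mean, geometry$fine_dim),
              musp = array(config$dataset$bg_musp_mean, geometry$fine_dim))
  ctx <- solver_context(ref, geometry, config$solver, type = "direct")
  for (i in seq_along(examples)) {
    fine <- rasterize_phantom(examples[[i]]$phantom, fg)
    meas <- simulate_scan(fine, config$protocol, config$solver, precond = ctx)
    examples[[i]]$measurements <- add_noise(meas, config$noise,
                                            seed = seed + i)
  }
  examples
}

#' Run the end-to-end study
#'
#' Generate -> simulate -> train -> reconstruct (network and model-based) ->
#' evaluate, at the scale of the chosen preset, writing metric and
#' comparison CSVs plus a YAML manifest when `out_dir` is given.
#'
#' @param config a [experiment_config()], or a preset name.
#' @param out_dir optional output directory for artifacts.
#' @param verbose print stage progress.
#' @return list with the trained `model`, `reports` (per method),
#'   `comparison`, `timing`, `manifest`.
#' @export
run_pipeline <- function(config = experiment_config("tiny"), out_dir = NULL,
                         verbose = TRUE) {
  if (is.character(config)) config <- experiment_config(config)
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- proc.time()[3]
  n_total <- config$n_train + config$n_val
  say("[1/5] simulating %d training examples", n_total)
  ds <- simulate_training_set(n_total, config, progress = verbose)
  say("[2/5] training the FDU-net")
  tcfg <- config$train
  model <- fdu_net(ds$x, ds$y, ds$mask, config = config$net, train = tcfg,
                   validation_idx = config$n_train + seq_len(config$n_val),
                   protocol_hash = ds$protocol_hash)
  say("[3/5] calibrating the reconstruction regularization on validation examples")
  calib_idx <- config$n_train + seq_len(min(config$n_calib, config$n_val))
  calib <- lapply(calib_idx, function(i) {
    list(measurements = structure(list(values = ds$x[i, ],
                                       noise_applied = TRUE,
                                       protocol_hash = ds$protocol_hash,
                                       n_channels = ncol(ds$x)),
                                  class = "measurement_set"),
         volume = list(mua = ds$y[, , , 1, i], musp = ds$y[, , , 2, i]))
  })
  cal <- calibrate_lambda_factor(
    calib, config$protocol, config$fem, config$solver,
    initial_background = c(config$dataset$bg_mua_mean,
                           config$dataset$bg_musp_mean))
  fem_cfg <- cal$config
  say("  selected lambda factor: %g", cal$factor)
  say("[3/5] building the %d-volume depth test set",
      length(config$depths_mm) * config$n_per_depth)
  tests <- make_depth_test_set(config$depths_mm, config$n_per_depth,
                               config$dataset, config$geometry,
                               seed = config$seed + 700000L)
  tests <- simulate_test_measurements(tests, config)
  say("[4/5] reconstructing with both methods")
  n_test <- length(tests)
  dl_time <- fem_time <- numeric(n_test)
  dl_recons <- fem_recons <- vector("list", n_test)
  Xtest <- do.call(rbind, lapply(tests, function(e) e$measurements$values))
  t_dl <- proc.time()[3]
  pred <- predict(model, Xtest, protocol_hash = config$protocol$hash)
  dl_time[] <- pred$elapsed_s / n_test
  for (i in seq_len(n_test))
    dl_recons[[i]] <- list(mua = pred$mua[, , , i], musp = pred$musp[, , , i])
  say("  network: %d volumes in %.2f s", n_test, proc.time()[3] - t_dl)
  for (i in seq_len(n_test)) {
    t1 <- proc.time()[3]
    r <- dot_reconstruct(tests[[i]]$measurements, config$protocol,
                         fem_cfg, config$solver,
                         initial_background = c(config$dataset$bg_mua_mean,
                                                config$dataset$bg_musp_mean))
    fem_time[i] <- proc.time()[3] - t1
    fem_recons[[i]] <- list(mua = r$mua, musp = r$musp)
  }
  say("  iterative: %d volumes in %.1f s", n_test, sum(fem_time))
  say("[5/5] scoring")
  rep_dl <- evaluate_recons(dl_recons, tests, method = "dl")
  rep_fem <- evaluate_recons(fem_recons, tests, method = "fem")
  comparison <- compare_methods(rep_dl, rep_fem)
  timing <- timing_report(list(dl = dl_time, fem = fem_time))
  manifest <- list(preset = config$preset, seed = config$seed,
                   lambda_factor = cal$factor,
                   n_train = config$n_train, n_val = config$n_val,
                   n_test = n_test, depths_mm = config$depths_mm,
                   protocol_hash = config$protocol$hash,
                   channels = config$protocol$n_channels,
                   elapsed_s = proc.time()[3] - t0)
  out <- list(model = model, reports = list(dl = rep_dl, fem = rep_fem),
              comparison = comparison, timing = timing, manifest = manifest,
              calibration = cal$table,
              tests = tests, recons = list(dl = dl_recons, fem = fem_recons))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(rbind(rep_dl, rep_fem),
                     file.path(out_dir, "metrics.csv"), row.names = FALSE)
    utils::write.csv(comparison$tests,
                     file.path(out_dir, "comparison.csv"), row.names = FALSE)
    utils::write.csv(comparison$by_depth,
                     file.path(out_dir, "metrics_by_depth.csv"),
                     row.names = FALSE)
    utils::write.csv(timing, file.path(out_dir, "timing.csv"),
                     row.names = FALSE)
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
    write_protocol(config$protocol, file.path(out_dir, "protocol.yaml"))
    saveRDS(model, file.path(out_dir, "model.rds"))
  }
  out
}

#' Wall-clock summary of reconstruction methods
#'
#' @param times named list of per-reconstruction wall-clock vectors
#'   (seconds), e.g. `list(dl = ..., fem = ...)`.
#' @return data frame with one row per method (n, mean, sd seconds) and the
#'   slowest/fastest mean ratio in the `ratio_to_fastest` column.
#' @export
timing_report <- function(times) {
  stopifnot(length(times) >= 1, !is.null(names(times)))
  df <- do.call(rbind, lapply(names(times), function(nm) {
    v <- times[[nm]]
    if (length(v) == 0) stop(sprintf("missing timing for method '%s'", nm))
    data.frame(method = nm, n = length(v), mean_s = mean(v),
               sd_s = stats::sd(v))
  }))
  df$ratio_to_fastest <- df$mean_s / min(df$mean_s)
  df
}
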