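# Shared end-to-end study for the acceptance checks: the desk study
# conditions (2 x 4 probe lattice, calibrated regularization, 8-iteration
# reconstruction cap, identical physics and randomization) at reduced sample
# counts so the suite completes on one CPU; fully seeded, so the result is
# reproducible bit-for-bit.  Run once per session and reused.
.desk_env <- new.env(parent = emptyenv())

desk_study <- function() {
  if (is.null(.desk_env$res)) {
    cfg <- experiment_config("desk", seed = 1L)
    cfg$n_train <- 160L
    cfg$n_val <- 16L
    cfg$n_per_depth <- 10L
    cfg$n_calib <- 3L
    cfg$train$validation_fraction <- 16 / 176
    .desk_env$res <- run_pipeline(cfg, verbose = FALSE)
  }
  .desk_env$res
}
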