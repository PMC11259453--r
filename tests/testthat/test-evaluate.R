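toy_pair <- function() {
  set.seed(12)
  truth <- list(mua = array(0.005, c(4, 4, 2)), musp = array(1.0, c(4, 4, 2)))
  pred <- list(mua = truth$mua + rnorm(32, 0, 1e-4),
               musp = truth$musp + rnorm(32, 0, 1e-2))
  list(pred = pred, truth = truth)
}

test_that("RMSE matches a loop-and-accumulate oracle", {
  tp <- toy_pair()
  r <- metric_rmse(tp$pred, tp$truth)
  acc <- 0
  for (i in seq_along(tp$pred$mua))
    acc <- acc + (tp$pred$mua[i] - tp$truth$mua[i])^2
  expect_equal(unname(r["mua"]), sqrt(acc / 32), tolerance = 1e-12)
  expect_equal(unname(metric_rmse(tp$truth, tp$truth)), c(0, 0))
  off <- list(mua = tp$truth$mua + 0.001, musp = tp$truth$musp + 0.001)
  expect_equal(unname(metric_rmse(off, tp$truth)), c(0.001, 0.001))
})

test_that("Dice coefficient follows the overlap formula and its conventions", {
  d <- c(4, 4, 2)
  truth_mask <- array(FALSE, d); truth_mask[1:2, 1:2, 1] <- TRUE  # 4 voxels
  pred <- array(0, d); pred[1:2, 1:3, 1] <- 1                      # 6 above 0.5
  expect_equal(metric_sdc(pred, truth_mask), 2 * 4 / (6 + 4))
  # identical masks
  pred2 <- array(0, d); pred2[truth_mask] <- 1
  expect_equal(metric_sdc(pred2, truth_mask), 1)
  # disjoint masks
  pred3 <- array(0, d); pred3[3:4, 3:4, 2] <- 1
  expect_equal(metric_sdc(pred3, truth_mask), 0)
  # conventions for empty masks
  expect_equal(metric_sdc(array(0, d), array(FALSE, d)), 1)
  expect_equal(metric_sdc(array(0, d), truth_mask), 0)
  # sizes 4 and 6 with intersection 3
  t2 <- array(FALSE, d); t2[1:4, 1, 1] <- TRUE                    # 4
  p2 <- array(0, d); p2[2:4, 1, 1] <- 1; p2[1:3, 2, 1] <- 1        # 6, cap 3
  expect_equal(metric_sdc(p2, t2), 2 * 3 / (4 + 6))
})

test_that("contrast ratio and crosstalk match hand-evaluated cases", {
  d <- c(4, 4, 2)
  mask <- array(FALSE, d); mask[1:2, 1:2, 1] <- TRUE
  truth <- list(mua = array(0.005, d), musp = array(0.98, d))
  truth$mua[mask] <- 0.010
  pred <- list(mua = array(0.005, d), musp = array(0.98, d))
  pred$mua[mask] <- 0.008
  expect_equal(metric_contrast_ratio(pred, truth, mask, mask, "mua"),
               (0.008 / 0.005) / (0.010 / 0.005))
  expect_equal(metric_contrast_ratio(truth, truth, mask, mask, "mua"), 1)
  # a flat prediction yields 1 / (true contrast)
  flat <- list(mua = array(0.005, d), musp = array(0.98, d))
  expect_equal(metric_contrast_ratio(flat, truth, mask, mask, "mua"), 1 / 2)
  # crosstalk: spurious musp contrast over a mua-only anomaly
  pred$musp[mask] <- 1.078
  expect_equal(metric_crosstalk(pred, truth, mask, "mua"),
               abs(1.078 / 0.98 - 1), tolerance = 1e-12)
  expect_equal(metric_crosstalk(truth, truth, mask, "mua"), 0)
  half <- list(mua = truth$mua, musp = truth$musp * 0)
  half$musp[] <- 0.49
  expect_equal(metric_crosstalk(half, truth, mask, "mua"), 0.5)
  # contract violation: the anomaly also perturbs the other parameter
  masks <- list(mask_mua = mask, mask_musp = mask)
  expect_error(metric_crosstalk(pred, truth, mask, "mua", truth_masks = masks),
               "both-parameter")
})

test_that("CR and CT are invariant to a global rescaling of both volumes", {
  d <- c(4, 4, 2)
  mask <- array(FALSE, d); mask[1:2, 1:2, 1] <- TRUE
  set.seed(5)
  truth <- list(mua = array(runif(32, 0.004, 0.02), d),
                musp = array(runif(32, 0.8, 2), d))
  pred <- list(mua = truth$mua * runif(32, 0.5, 1.5),
               musp = truth$musp * runif(32, 0.5, 1.5))
  s <- 7.3
  scale2 <- function(v) list(mua = v$mua * s, musp = v$musp * s)
  expect_equal(metric_contrast_ratio(pred, truth, mask, mask, "mua"),
               metric_contrast_ratio(scale2(pred), scale2(truth), mask, mask,
                                     "mua"), tolerance = 1e-12)
  expect_equal(metric_crosstalk(pred, truth, mask, "mua"),
               metric_crosstalk(scale2(pred), scale2(truth), mask, "mua"),
               tolerance = 1e-12)
})

test_that("paired comparison recovers a constant shift and a textbook t", {
  ts <- make_depth_test_set(c(5, 10), 3L, seed = 13)
  base <- lapply(ts, function(e) list(mua = e$volume$mua, musp = e$volume$musp))
  ra <- evaluate_recons(base, ts, "a")
  rb <- ra; rb$method <- "b"
  cmp0 <- compare_methods(ra, rb)
  expect_true(all(cmp0$tests$mean_diff == 0))
  expect_true(all(cmp0$tests$t == 0))
  # B = A + 0.001 on every RMSE
  rb2 <- ra; rb2$method <- "b"; rb2$rmse <- rb2$rmse + 0.001
  cmp1 <- compare_methods(ra, rb2)
  rr <- cmp1$tests[cmp1$tests$metric == "rmse", ]
  expect_equal(rr$mean_diff, rep(-0.001, 2), tolerance = 1e-12)
  expect_true(all(rr$p < 0.05))
  # hand-computed paired t on 5 pairs
  a <- c(1.1, 0.9, 1.3, 1.0, 1.2); b <- c(1.0, 0.8, 1.1, 1.1, 1.0)
  dd <- a - b
  t_hand <- mean(dd) / (sd(dd) / sqrt(5))
  tt <- t.test(a, b, paired = TRUE)
  expect_equal(unname(tt$statistic), t_hand, tolerance = 1e-9)
})

test_that("report rows carry method, depth and four metrics per parameter", {
  ts <- make_depth_test_set(5, 2L, seed = 31)
  recs <- lapply(ts, function(e) list(mua = e$volume$mua, musp = e$volume$musp))
  rep_ <- evaluate_recons(recs, ts, "oracle")
  expect_equal(nrow(rep_), 2L * 2L)
  expect_setequal(rep_$parameter, c("mua", "musp"))
  # perfect reconstruction scores perfectly
  expect_true(all(rep_$rmse == 0))
  expect_true(all(rep_$sdc == 1))
  expect_true(all(abs(rep_$cr - 1) < 1e-12))
  expect_true(all(rep_$ct == 0))
})
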