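#' Root mean squared error per optical parameter
#'
#' @param pred,truth lists with 3D arrays `mua`, `musp` (mm^-1) on the same
#'   grid.
#' @return named numeric: `mua`, `musp`.
#' @export
metric_rmse <- function(pred, truth) {
  stopifnot(identical(dim(pred$mua), dim(truth$mua)),
            identical(dim(pred$musp), dim(truth$musp)))
  c(mua = sqrt(mean((pred$mua - truth$mua)^2)),
    musp = sqrt(mean((pred$musp - truth$musp)^2)))
}

#' Sorensen-Dice coefficient of the reconstructed anomaly mask
#'
#' The prediction's anomaly mask is taken as the voxels above 0.5 after
#' min-max normalizing that parameter channel over the volume itself; the
#' truth mask is the rasterized ROI mask.  Conventions: 1 when both masks
#' are empty, 0 when exactly one is empty.
#'
#' @param pred_channel 3D array, one parameter channel of the
#'   reconstruction.
#' @param truth_mask logical 3D array.
#' @return scalar in `[0, 1]`.
#' @export
metric_sdc <- function(pred_channel, truth_mask) {
  stopifnot(identical(dim(pred_channel), dim(truth_mask)))
  rng <- max(pred_channel) - min(pred_channel)
  pmask <- if (rng > 0) (pred_channel - min(pred_channel)) / rng > 0.5
           else array(FALSE, dim(pred_channel))
  np <- sum(pmask); nt <- sum(truth_mask)
  if (np == 0 && nt == 0) return(1)
  if (np == 0 || nt == 0) return(0)
  2 * sum(pmask & truth_mask) / (np + nt)
}

#' Contrast ratio of a reconstructed anomaly
#'
#' Ratio of the reconstructed anomaly/background contrast to the true
#' contrast for one parameter; 1 is perfect.  The background is the
#' complement of the combined anomaly mask, so co-located anomalies of the
#' other parameter never contaminate the background mean.
#'
#' @param pred,truth lists with `mua`, `musp` arrays.
#' @param mask logical array: the anomaly ROI of `parameter`.
#' @param combined_mask logical array: OR of both parameter masks.
#' @param parameter `"mua"` or `"musp"`.
#' @return scalar, or `NA` with a warning if the mask is empty.
#' @export
metric_contrast_ratio <- function(pred, truth, mask, combined_mask,
                                  parameter = c("mua", "musp")) {
  parameter <- match.arg(parameter)
  if (!any(mask)) {
    warning("empty anomaly mask: contrast ratio undefined")
    return(NA_real_)
  }
  bg <- !combined_mask
  p <- pred[[parameter]]; y <- truth[[parameter]]
  (mean(p[mask]) / mean(p[bg])) / (mean(y[mask]) / mean(y[bg]))
}

#' Crosstalk into the unperturbed parameter
#'
#' For an anomaly that perturbs only `parameter`, measures the spurious
#' contrast appearing in the *other* parameter channel:
#' `| mean(pred_other[mask]) / mean(truth_other[mask]) - 1 |`; 0 is perfect
#' separation.
#'
#' @param pred,truth lists with `mua`, `musp` arrays.
#' @param mask logical array: ROI of a single-parameter anomaly perturbing
#'   `parameter`.
#' @param parameter the perturbed parameter of the anomaly.
#' @param truth_masks optional list with `mask_mua`, `mask_musp`; when
#'   supplied the single-parameter contract is verified and a violation is
#'   an error.
#' @return scalar `>= 0`.
#' @export
metric_crosstalk <- function(pred, truth, mask, parameter = c("mua", "musp"),
                             truth_masks = NULL) {
  parameter <- match.arg(parameter)
  other <- if (parameter == "mua") "musp" else "mua"
  if (!is.null(truth_masks)) {
    other_mask <- truth_masks[[paste0("mask_", other)]]
    if (any(mask & other_mask))
      stop("crosstalk mask belongs to a both-parameter anomaly")
  }
  if (!any(mask)) {
    warning("empty anomaly mask: crosstalk undefined")
    return(NA_real_)
  }
  abs(mean(pred[[other]][mask]) / mean(truth[[other]][mask]) - 1)
}

#' Score reconstructions of the depth test set
#'
#' Computes, for every reconstructed example, per-parameter RMSE and SDC,
#' the contrast ratio over each parameter's ROI, and the crosstalk over the
#' single-parameter anomaly regions, tagged with method and anomaly depth.
#'
#' @param recons list of reconstructions, each a list with `mua`, `musp`
#'   arrays on the target grid.
#' @param examples the matching [make_depth_test_set()] examples.
#' @param method label stored in the report.
#' @return data frame (one row per example x parameter) of class
#'   `"dot_metric_report"`.
#' @export
evaluate_recons <- function(recons, examples, method = "method") {
  stopifnot(length(recons) == length(examples))
  rows <- list()
  for (i in seq_along(examples)) {
    ex <- examples[[i]]; pred <- recons[[i]]; tv <- ex$volume
    truth <- list(mua = tv$mua, musp = tv$musp)
    masks <- list(mask_mua = tv$mask_mua, mask_musp = tv$mask_musp)
    rm_ <- metric_rmse(pred, truth)
    for (par in c("mua", "musp")) {
      other <- if (par == "mua") "musp" else "mua"
      pmask <- tv[[paste0("mask_", par)]]
      only_other <- tv[[paste0("mask_", other)]] & !pmask
      ct <- if (any(only_other))
        metric_crosstalk(pred, truth, only_other, parameter = other,
                         truth_masks = masks)
      else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        example = i, method = method, depth_mm = ex$depth_mm,
        parameter = par,
        rmse = unname(rm_[par]),
        sdc = metric_sdc(pred[[par]], pmask),
        cr = if (any(pmask))
          metric_contrast_ratio(pred, truth, pmask, tv$mask_combined, par)
        else NA_real_,
        ct = ct)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("dot_metric_report", class(out))
  out
}

#' Paired comparison of two metric reports
#'
#' For each parameter and metric, a paired t-test across the matched
#' examples of the two methods, with group means by anomaly depth.
#' `rel_change` is the mean improvement of method A relative to method B,
#' as a fraction of B's mean (positive = A smaller for error-like metrics).
#'
#' @param report_a,report_b `"dot_metric_report"`s over the same examples.
#' @param alpha significance level.
#' @return list with `tests` (per parameter x metric data frame) and
#'   `by_depth` (group means).
#' @export
compare_methods <- function(report_a, report_b, alpha = 0.05) {
  key <- function(r) paste(r$example, r$parameter)
  if (!identical(sort(key(report_a)), sort(key(report_b))))
    stop("reports do not cover the same example set")
  b <- report_b[match(key(report_a), key(report_b)), ]
  a <- report_a
  tests <- list()
  for (par in c("mua", "musp")) {
    for (metric in c("rmse", "sdc", "cr", "ct")) {
      va <- a[[metric]][a$parameter == par]
      vb <- b[[metric]][b$parameter == par]
      ok <- is.finite(va) & is.finite(vb)
      va <- va[ok]; vb <- vb[ok]
      if (length(va) < 2 || stats::sd(va - vb) == 0) {
        # degenerate paired test: zero-variance differences
        tt <- if (all(va == vb)) list(statistic = 0, p.value = 1)
              else list(statistic = sign(mean(va - vb)) * Inf, p.value = 0)
      } else tt <- stats::t.test(va, vb, paired = TRUE)
      tests[[length(tests) + 1L]] <- data.frame(
        parameter = par, metric = metric, n = length(va),
        mean_a = mean(va), mean_b = mean(vb),
        mean_diff = mean(va - vb),
        sd_diff = if (length(va) > 1) stats::sd(va - vb) else NA_real_,
        rel_change = if (mean(vb) != 0) (mean(vb) - mean(va)) / mean(vb)
                     else NA_real_,
        t = unname(tt$statistic), p = tt$p.value,
        significant = is.finite(tt$p.value) && tt$p.value < alpha)
    }
  }
  tests <- do.call(rbind, tests)
  both <- rbind(a, b)
  agg <- stats::aggregate(
    both[, c("rmse", "sdc", "cr", "ct")],
    by = list(method = both$method, depth_mm = both$depth_mm,
              parameter = both$parameter),
    FUN = function(v) mean(v, na.rm = TRUE))
  list(tests = tests, by_depth = agg[order(agg$parameter, agg$method,
                                           agg$depth_mm), ])
}
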