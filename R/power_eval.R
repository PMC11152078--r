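#' Window scores for the ROC protocol
#'
#' Tiles the region with nonoverlapping 100-bp windows from position 1 and
#' scores each window by the maximum per-SNP score inside it. The true
#' window is the one containing a SNP within `truth_radius` (50 bp) of the
#' balanced site; its score is the maximum over such qualifying SNPs, and
#' every window containing a qualifying SNP is removed from the negatives.
#' If no SNP lies within the radius the true score is missing and the
#' replicate contributes no true positive at any threshold.
#'
#' @param scan a `scan_result` (data.frame with `position`, `score`).
#' @param balanced_site balanced-site position in bp.
#' @param region_length region length in bp.
#' @param window window width (100 bp).
#' @param truth_radius truth rule radius (50 bp).
#' @return list with `true_score` (scalar or NA) and `negative_scores`.
#' @export
window_scores <- function(scan, balanced_site, region_length,
                          window = 100L, truth_radius = 50L) {
  scan <- scan[!is.na(scan$score), , drop = FALSE]
  if (nrow(scan) == 0)
    return(list(true_score = NA_real_, negative_scores = numeric(0)))
  win <- floor((scan$position - 1) / window)
  qualifying <- abs(scan$position - balanced_site) <= truth_radius
  true_score <- if (any(qualifying)) max(scan$score[qualifying]) else NA_real_
  true_wins <- unique(win[qualifying])
  agg <- tapply(scan$score, win, max)
  keep <- !(as.numeric(names(agg)) %in% true_wins)
  list(true_score = true_score,
       negative_scores = as.numeric(agg[keep]))
}

#' ROC curve from per-replicate window scores
#'
#' `TPR(t)` is the fraction of replicates whose true-window score is `>= t`
#' (replicates with a missing true window stay in the denominator);
#' `FPR(t)` is the fraction of pooled negative windows with score `>= t`.
#' Thresholds are either the sorted union of observed scores
#' (`thresholds = "all-observed"`) or `n_even` evenly spaced values from 0
#' to the global maximum.
#'
#' @param window_list list of [window_scores()] results, one per replicate.
#' @param thresholds "all-observed" or a count of evenly spaced thresholds.
#' @param negative_pool optional vector of negative window scores (e.g.
#'   from matched neutral replicates); when supplied it replaces the
#'   negatives pooled from `window_list`.
#' @return a `roc_result`: data.frame with `threshold`, `tpr`, `fpr` and
#'   attributes `n_replicates`, `method`.
#' @export
roc <- function(window_list, thresholds = "all-observed",
                negative_pool = NULL) {
  true_scores <- vapply(window_list, function(w) {
    if (is.na(w$true_score)) -Inf else w$true_score
  }, numeric(1))
  negs <- if (is.null(negative_pool))
    unlist(lapply(window_list, `[[`, "negative_scores"))
  else negative_pool
  all_scores <- c(true_scores[is.finite(true_scores)], negs)
  if (identical(thresholds, "all-observed")) {
    th <- sort(unique(c(0, all_scores)))
  } else {
    th <- seq(0, max(all_scores, 0), length.out = as.integer(thresholds))
  }
  tpr <- vapply(th, function(t) mean(true_scores >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(negs >= t), numeric(1))
  structure(data.frame(threshold = th, tpr = tpr, fpr = fpr),
            n_replicates = length(window_list), class = c("roc_result",
                                                          "data.frame"))
}

#' TPR at a fixed FPR level
#'
#' Conservative step interpolation: the TPR at the largest threshold whose
#' FPR is `<= fpr_level`.
#'
#' @param roc a `roc_result`.
#' @param fpr_level FPR level in (0, 1).
#' @return the TPR (NA if no threshold attains the level).
#' @export
tpr_at_fpr <- function(roc, fpr_level = 0.05) {
  if (fpr_level <= 0 || fpr_level >= 1) stop("fpr_level must be in (0, 1)")
  ok <- roc$fpr <= fpr_level
  if (!any(ok)) return(NA_real_)
  # FPR is non-increasing in threshold: the smallest qualifying threshold
  # is the most liberal one still at or below the level
  i <- which(ok)[which.min(roc$threshold[ok])]
  roc$tpr[i]
}

#' Area under an ROC curve
#' @param roc a `roc_result`.
#' @return AUC in `[0, 1]` (trapezoid over the FPR axis).
#' @export
roc_auc <- function(roc) {
  o <- order(roc$fpr, roc$tpr)
  x <- c(0, roc$fpr[o], 1)
  y <- c(min(roc$tpr), roc$tpr[o], 1)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Maximum per-SNP score of every 100-bp window of a scan
#'
#' Used to build negative pools from scans of null (no balanced site)
#' replicates, where every window is a potential false positive.
#'
#' @param scan a `scan_result`.
#' @param window window width in bp.
#' @return numeric vector of window scores.
#' @export
all_window_scores <- function(scan, window = 100L) {
  scan <- scan[!is.na(scan$score), , drop = FALSE]
  if (nrow(scan) == 0) return(numeric(0))
  win <- floor((scan$position - 1) / window)
  as.numeric(tapply(scan$score, win, max))
}

#' Normalized-threshold FPR curve (null / structure scenarios)
#'
#' All window scores of a scenario are min-max normalized to `[0, 1]`;
#' the FPR (fraction of windows called) is computed at `n_thresholds`
#' evenly spaced normalized thresholds. Used for scenarios without a
#' balanced site, where every window is a potential false positive.
#'
#' @param scans list of `scan_result`s (one per replicate).
#' @param region_length region length in bp.
#' @param n_thresholds number of thresholds (100).
#' @param window window width (100 bp).
#' @return data.frame with `threshold` (normalized) and `fpr`; NULL if the
#'   scores are degenerate (constant).
#' @export
normalized_fpr_curve <- function(scans, region_length, n_thresholds = 100L,
                                 window = 100L) {
  ws <- unlist(lapply(scans, function(scan) {
    scan <- scan[!is.na(scan$score), , drop = FALSE]
    if (nrow(scan) == 0) return(numeric(0))
    win <- floor((scan$position - 1) / window)
    as.numeric(tapply(scan$score, win, max))
  }))
  rng <- range(ws)
  if (diff(rng) == 0) return(NULL)
  norm <- (ws - rng[1]) / diff(rng)
  th <- seq(0, 1, length.out = as.integer(n_thresholds))
  data.frame(threshold = th,
             fpr = vapply(th, function(t) mean(norm >= t), numeric(1)))
}

#' Normalized FPR curves of several scenarios on a common scale
#'
#' Ranking scenarios by their false-positive behaviour requires one
#' normalization per method: window scores of all scenarios are pooled and
#' min-max scaled jointly (thresholds run from 0 to the maximum score
#' across all replicates of all scenarios), then each scenario's FPR curve
#' is computed on that common axis. Per-scenario normalization (see
#' [normalized_fpr_curve()]) cannot rank scenarios, since a scenario with
#' a heavier score tail has its own curve compressed.
#'
#' @param scan_sets named list; each element a list of `scan_result`s for
#'   one scenario.
#' @param region_length region length in bp.
#' @param n_thresholds number of thresholds (100).
#' @param window window width (100 bp).
#' @return data.frame with `scenario`, `threshold` (normalized), `fpr`.
#' @export
normalized_fpr_curves <- function(scan_sets, region_length,
                                  n_thresholds = 100L, window = 100L) {
  ws <- lapply(scan_sets, function(scans)
    unlist(lapply(scans, all_window_scores, window = window)))
  rng <- range(unlist(ws))
  if (diff(rng) == 0) return(NULL)
  th <- seq(0, 1, length.out = as.integer(n_thresholds))
  do.call(rbind, lapply(names(ws), function(nm) {
    norm <- (ws[[nm]] - rng[1]) / diff(rng)
    data.frame(scenario = nm, threshold = th,
               fpr = vapply(th, function(t) mean(norm >= t), numeric(1)))
  }))
}
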