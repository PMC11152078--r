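#' Extended haplotype homozygosity curve
#'
#' EHH at a target SNP is the probability that two randomly chosen carriers
#' of the core allele are identical over the whole interval from the core
#' to the target. The curve is 1 at the core, non-increasing outward, and
#' is truncated when it falls below `cutoff` or the region edge is reached
#' (flagged).
#'
#' @param sample a `haplotype_sample` (or any list with `matrix` and
#'   `positions`).
#' @param core_pos physical position of the core SNP.
#' @param allele 0 (ancestral) or 1 (derived).
#' @param cutoff truncation threshold (0.05).
#' @return an `ehh_curve`: positions, EHH values (core included), iHH
#'   (trapezoidal integral in bp), carrier count and truncation flags;
#'   `NULL` if the core allele has fewer than 2 carriers.
#' @export
ehh <- function(sample, core_pos, allele = 1L, cutoff = 0.05) {
  core0 <- match(core_pos, sample$positions)
  if (is.na(core0)) stop("core position is not a SNP in this sample")
  res <- ehh_curve_cpp(sample$matrix, as.numeric(sample$positions),
                       core0 - 1L, as.integer(allele), cutoff)
  if (!isTRUE(res$ok)) return(NULL)
  structure(list(core_pos = core_pos, allele = allele,
                 positions = res$positions, ehh = res$ehh,
                 ihh = res$ihh, n_carriers = res$n_carriers,
                 left_edge = res$left_edge, right_edge = res$right_edge,
                 left_cutoff = res$left_cutoff,
                 right_cutoff = res$right_cutoff),
            class = "ehh_curve")
}

#' Trapezoidal integral of an EHH curve (iHH, in bp)
#' @param curve an `ehh_curve`.
#' @return area under the curve, left plus right of the core.
#' @export
integrated_ehh <- function(curve) {
  p <- curve$positions; e <- curve$ehh
  if (length(p) < 2) return(0)
  sum(diff(p) * (utils::head(e, -1) + utils::tail(e, -1)) / 2)
}

#' Unstandardized iHS
#' @param ihh_a,ihh_d integrated EHH for the ancestral and derived allele.
#' @return `ln(iHH_A / iHH_D)`; `NA` when either integral is not positive.
#' @export
unstandardized_ihs <- function(ihh_a, ihh_d) {
  ifelse(ihh_a > 0 & ihh_d > 0, log(ihh_a / ihh_d), NA_real_)
}

merge_small_bins <- function(bin, min_bin) {
  repeat {
    tab <- table(bin)
    ids <- as.numeric(names(tab))
    small <- ids[tab < min_bin]
    if (length(small) == 0 || length(ids) == 1) break
    b <- small[1]
    others <- setdiff(ids, b)
    nearest <- others[which.min(abs(others - b))]
    bin[bin == b] <- nearest
  }
  bin
}

#' Estimate frequency-bin standardization parameters
#'
#' Groups scores into derived-frequency bins of width `bin_width` (bins
#' with fewer than `min_bin` scores merged with the nearest neighbour) and
#' records each merged bin's mean and sample SD. Estimating these on a
#' neutral reference pool emulates genome-wide standardization, where the
#' genomic background is predominantly neutral.
#'
#' @param uihs unstandardized scores (NA allowed).
#' @param p_derived derived allele frequencies.
#' @param bin_width frequency bin width (0.02).
#' @param min_bin minimum scores per retained bin (20).
#' @return an `ihs_bin_params` data.frame with `bin`, `mean`, `sd`.
#' @export
ihs_bin_params <- function(uihs, p_derived, bin_width = 0.02, min_bin = 20L) {
  ok <- !is.na(uihs)
  if (sum(ok) < 2) stop("need at least 2 scores to standardize")
  raw_bin <- pmin(floor(p_derived[ok] / bin_width), 1 / bin_width - 1)
  bin <- merge_small_bins(raw_bin, min_bin)
  x <- uihs[ok]
  ub <- sort(unique(bin))
  stats <- vapply(ub, function(b) {
    xi <- x[bin == b]
    c(mean(xi), stats::sd(xi))
  }, numeric(2))
  # map every raw bin (merged or not) to its merged bin's statistics
  map <- vapply(sort(unique(raw_bin)), function(rb)
    bin[which(raw_bin == rb)[1]], numeric(1))
  structure(data.frame(raw_bin = sort(unique(raw_bin)), bin = map,
                       mean = stats[1, match(map, ub)],
                       sd = stats[2, match(map, ub)]),
            bin_width = bin_width, class = c("ihs_bin_params", "data.frame"))
}

#' Standardize iHS scores within derived-frequency bins
#'
#' With `params = NULL` the bin means and SDs are estimated from the
#' scores themselves; otherwise the supplied [ihs_bin_params()] (e.g. from
#' a neutral reference pool) are applied, scores outside any estimated bin
#' using the nearest one.
#'
#' @param uihs unstandardized scores.
#' @param p_derived derived allele frequencies (same length).
#' @param bin_width frequency bin width (0.02).
#' @param min_bin minimum scores per retained bin (20).
#' @param params optional pre-estimated `ihs_bin_params`.
#' @return numeric vector of standardized scores (NA where input was NA).
#' @export
standardize_ihs <- function(uihs, p_derived, bin_width = 0.02, min_bin = 20L,
                            params = NULL) {
  if (is.null(params))
    params <- ihs_bin_params(uihs, p_derived, bin_width, min_bin)
  bw <- attr(params, "bin_width")
  ok <- !is.na(uihs)
  out <- rep(NA_real_, length(uihs))
  rb <- pmin(floor(p_derived[ok] / bw), 1 / bw - 1)
  idx <- vapply(rb, function(b) which.min(abs(params$raw_bin - b)),
                integer(1))
  m <- params$mean[idx]; s <- params$sd[idx]
  z <- ifelse(is.na(s) | s == 0, 0, (uihs[ok] - m) / s)
  out[ok] <- z
  out
}

#' iHS scan of one sample
#'
#' Computes both EHH curves at every SNP with at least 2 carriers of each
#' allele (no frequency exclusion; edge-truncated curves are retained),
#' takes `ln(iHH_A / iHH_D)` and, if `standardize = TRUE`, standardizes
#' within frequency bins of this sample alone. For scenario-level power
#' analyses use [ihs_scan_set()], which pools the standardization across
#' replicates. The detection score is |standardized iHS|.
#'
#' @param sample a `haplotype_sample`.
#' @param cutoff EHH truncation threshold.
#' @param standardize standardize within this sample.
#' @return a `scan_result` data.frame: position, p_derived, ihh_a, ihh_d,
#'   uihs, (ihs, score).
#' @export
ihs_scan <- function(sample, cutoff = 0.05, standardize = TRUE) {
  df <- ihs_components_cpp(sample$matrix, as.numeric(sample$positions),
                           cutoff)
  df <- df[!is.na(df$uihs), , drop = FALSE]
  if (standardize && nrow(df) >= 2) {
    df$ihs <- standardize_ihs(df$uihs, df$p_derived)
    df$score <- abs(df$ihs)
  }
  attr(df, "method") <- "ihs"
  class(df) <- c("scan_result", class(df))
  df
}

#' iHS scan of a replicate set with pooled standardization
#'
#' Runs [ihs_scan()] without standardization on every sample, then
#' standardizes the pooled unstandardized scores across all replicates in
#' shared frequency bins (stable bins require pooling at a few hundred
#' replicates).
#'
#' @param samples list of `haplotype_sample`s.
#' @param cutoff EHH truncation threshold.
#' @param params optional [ihs_bin_params()] from a reference pool (e.g.
#'   matched neutral replicates); `NULL` estimates them from these samples.
#' @return list of `scan_result`s, one per sample.
#' @export
ihs_scan_set <- function(samples, cutoff = 0.05, params = NULL) {
  raw <- lapply(samples, ihs_scan, cutoff = cutoff, standardize = FALSE)
  sizes <- vapply(raw, nrow, integer(1))
  all_u <- unlist(lapply(raw, `[[`, "uihs"))
  all_p <- unlist(lapply(raw, `[[`, "p_derived"))
  std <- if (length(all_u) >= 2)
    standardize_ihs(all_u, all_p, params = params) else all_u
  idx <- cumsum(c(0, sizes))
  for (i in seq_along(raw)) {
    if (sizes[i] > 0) {
      raw[[i]]$ihs <- std[(idx[i] + 1):idx[i + 1]]
      raw[[i]]$score <- abs(raw[[i]]$ihs)
    } else {
      raw[[i]]$ihs <- numeric(0)
      raw[[i]]$score <- numeric(0)
    }
    attr(raw[[i]], "method") <- "ihs"
  }
  raw
}
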