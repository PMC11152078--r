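#' Background site frequency spectrum
#'
#' Pools derived-allele counts over all polymorphic sites plus
#' substitutions (class `k = n`) across the provided samples, and
#' normalizes with a pseudocount per class so that no class has zero
#' probability.
#'
#' @param samples list of `haplotype_sample`s with a common sample size.
#' @param pseudocount added to every class (1).
#' @return a `spectrum_model`: list with `n` and probabilities `g` over
#'   `k = 1..n`.
#' @export
background_sfs <- function(samples, pseudocount = 1) {
  if (inherits(samples, "haplotype_sample")) samples <- list(samples)
  if (!length(samples)) stop("need at least one sample")
  ns <- vapply(samples, function(s) s$n, numeric(1))
  if (length(unique(ns)) != 1) stop("samples have mixed sample sizes")
  n <- ns[1]
  counts <- numeric(n)
  for (s in samples) {
    tb <- tabulate(s$k, nbins = n)
    counts <- counts + tb
    counts[n] <- counts[n] + nrow(s$substitutions)
  }
  counts <- counts + pseudocount
  structure(list(n = as.integer(n), g = counts / sum(counts)),
            class = "spectrum_model")
}

#' Expected spectrum at a balanced site
#'
#' `h_beta(k) = Binomial(k; n, beta)` renormalized over `k = 1..n` (the
#' mass at `k = 0` is dropped): allele frequencies concentrated around the
#' equilibrium frequency, with `k = n` the substitution-like limit.
#'
#' @param beta equilibrium frequency in (0, 1).
#' @param n sample size.
#' @return probabilities over `k = 1..n`.
#' @export
balanced_component <- function(beta, n) {
  if (beta <= 0 || beta >= 1) stop("beta must be in (0, 1)")
  p <- stats::dbinom(1:n, n, beta)
  p / sum(p)
}

#' CLR scan configuration
#'
#' @param beta_grid candidate equilibrium frequencies.
#' @param footprint_grid decay scales A in bp (log-spaced decades by
#'   default); the degenerate no-signal point is always included.
#' @return a `b2_config`.
#' @export
b2_config <- function(beta_grid = seq(0.05, 0.95, by = 0.05),
                      footprint_grid = 10^(2:6)) {
  if (any(beta_grid <= 0 | beta_grid >= 1)) stop("beta grid must be in (0,1)")
  if (any(footprint_grid <= 0)) stop("footprints must be > 0")
  structure(list(beta_grid = beta_grid, footprint_grid = footprint_grid),
            class = "b2_config")
}

#' Composite likelihood ratio at one test position
#'
#' `CLR = 2 max_(beta, A) sum_l ln[(a_l h_beta(k_l) + (1 - a_l) g(k_l)) /
#' g(k_l)]` with `a_l = exp(-d_l / A)`, maximized over the grid including
#' the degenerate no-signal point, hence `CLR >= 0`.
#'
#' @param test_pos physical test position(s).
#' @param sites data.frame with `position` and derived count `k`
#'   (substitutions as `k = n`).
#' @param model a `spectrum_model`.
#' @param config a `b2_config`.
#' @return data.frame with `position`, `clr`, `beta_hat`, `A_hat`.
#' @export
b2_clr <- function(test_pos, sites, model, config = b2_config()) {
  ord <- order(sites$position)
  res <- b2_clr_cpp(as.numeric(sites$position[ord]),
                    as.integer(sites$k[ord]), model$n, model$g,
                    config$beta_grid, config$footprint_grid,
                    as.numeric(test_pos))
  data.frame(position = test_pos, clr = res$clr, beta_hat = res$beta_hat,
             A_hat = res$A_hat)
}

#' CLR scan of one sample
#'
#' Evaluates [b2_clr()] with the test position at every SNP, using all
#' polymorphic sites and recorded substitutions as informative sites. The
#' detection score is the CLR.
#'
#' @param sample a `haplotype_sample`.
#' @param model a `spectrum_model` (typically [background_sfs()] pooled over
#'   the scenario's replicates).
#' @param config a `b2_config`.
#' @return a `scan_result` data.frame: position, clr, beta_hat, A_hat,
#'   score.
#' @export
b2_scan <- function(sample, model, config = b2_config()) {
  sites <- data.frame(position = sample$positions, k = sample$k)
  if (nrow(sample$substitutions))
    sites <- rbind(sites, data.frame(position = sample$substitutions$position,
                                     k = sample$n))
  df <- b2_clr(sample$positions, sites, model, config)
  df$score <- df$clr
  attr(df, "method") <- "b2"
  class(df) <- c("scan_result", class(df))
  df
}
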