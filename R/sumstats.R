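#' Nucleotide diversity (pi) per site
#'
#' Mean pairwise Hamming distance over all C(n,2) haplotype pairs, divided
#' by the window length. Computed from per-column derived counts:
#' `sum_j 2 k_j (n - k_j) / (n (n - 1)) / L`.
#'
#' @param mat n x S 0/1 haplotype matrix (possibly with 0 columns).
#' @param L window length in bp.
#' @return pi per site.
#' @export
nucleotide_diversity <- function(mat, L) {
  n <- nrow(mat)
  if (is.null(n) || n < 2) stop("need at least 2 haplotypes")
  if (ncol(mat) == 0) return(0)
  k <- colSums(mat)
  sum(2 * k * (n - k)) / (n * (n - 1)) / L
}

tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D
#'
#' `D = (pi_total - S / a1) / sqrt(e1 S + e2 S (S - 1))` with the standard
#' constants. Undefined (NA) when `S = 0`.
#'
#' @param n sample size.
#' @param S segregating sites.
#' @param pi_total total (not per-site) mean pairwise differences.
#' @return D, or `NA_real_` when undefined.
#' @export
tajimas_d <- function(n, S, pi_total) {
  if (S < 1) return(NA_real_)
  if (n < 2) stop("need n >= 2")
  cst <- tajima_constants(n)
  v <- cst$e1 * S + cst$e2 * S * (S - 1)
  if (v <= 0) return(NA_real_)
  (pi_total - S / cst$a1) / sqrt(v)
}

#' Haplotype diversity
#'
#' Unbiased estimator `H = n/(n-1) (1 - sum p_h^2)` over distinct haplotype
#' strings within the window.
#'
#' @param mat n x S 0/1 haplotype matrix.
#' @return H in `[0, 1]`.
#' @export
haplotype_diversity <- function(mat) {
  n <- nrow(mat)
  if (is.null(n) || n < 2) stop("need at least 2 haplotypes")
  if (ncol(mat) == 0) return(0)
  key <- apply(mat, 1, paste, collapse = "")
  p <- table(key) / n
  (n / (n - 1)) * (1 - sum(p^2))
}

#' Mean absolute D' over all biallelic site pairs
#'
#' For each pair, `D = p_AB - p_A p_B`; `D' = D / D_max` with
#' `D_max = min(p_A (1 - p_B), (1 - p_A) p_B)` when `D > 0` and
#' `min(p_A p_B, (1 - p_A)(1 - p_B))` when `D < 0`. Returns the mean of
#' `|D'|`; monomorphic columns are skipped and fewer than two polymorphic
#' sites give `NA`.
#'
#' @param mat n x S 0/1 haplotype matrix.
#' @return mean |D'| in `[0, 1]`, or `NA_real_`.
#' @export
mean_d_prime <- function(mat) {
  n <- nrow(mat)
  k <- colSums(mat)
  poly <- which(k > 0 & k < n)
  if (length(poly) < 2) return(NA_real_)
  m <- mat[, poly, drop = FALSE]
  pa <- colMeans(m)
  tot <- 0; cnt <- 0
  for (i in seq_len(ncol(m) - 1)) {
    for (j in (i + 1):ncol(m)) {
      pab <- mean(m[, i] * m[, j])
      D <- pab - pa[i] * pa[j]
      if (D == 0) { cnt <- cnt + 1; next }
      dmax <- if (D > 0) min(pa[i] * (1 - pa[j]), (1 - pa[i]) * pa[j])
              else min(pa[i] * pa[j], (1 - pa[i]) * (1 - pa[j]))
      tot <- tot + abs(D / dmax)
      cnt <- cnt + 1
    }
  }
  tot / cnt
}

#' Windowed summary-statistic table
#'
#' Computes S, per-site pi, Watterson's theta, Tajima's D, haplotype
#' diversity, and mean |D'| in sliding windows (2 kb width, 1 kb step by
#' default; windows extending past the region end are dropped). Undefined
#' statistics propagate as NA, never as 0.
#'
#' @param sample a `haplotype_sample`.
#' @param window window width in bp.
#' @param step step in bp.
#' @return data.frame with one row per window.
#' @export
sliding_window_table <- function(sample, window = 2000L, step = 1000L) {
  if (step < 1 || window < step) stop("need window >= step >= 1")
  L <- sample$region_length
  if (window > L) stop("window wider than the region")
  starts <- seq(1L, L - window + 1L, by = step)
  n <- sample$n
  cst_cache <- tajima_constants(n)
  out <- lapply(starts, function(s0) {
    e0 <- s0 + window - 1L
    idx <- which(sample$positions >= s0 & sample$positions <= e0)
    m <- sample$matrix[, idx, drop = FALSE]
    S <- length(idx)
    k <- if (S) colSums(m) else integer(0)
    pi_tot <- if (S) sum(2 * k * (n - k)) / (n * (n - 1)) else 0
    data.frame(start = s0, end = e0, n = n, S = S,
               pi = pi_tot / window,
               theta_w = S / cst_cache$a1 / window,
               tajimas_d = if (S >= 1) tajimas_d(n, S, pi_tot) else NA_real_,
               hap_diversity = haplotype_diversity(m),
               mean_d_prime = if (S >= 2) mean_d_prime(m) else NA_real_)
  })
  do.call(rbind, out)
}
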