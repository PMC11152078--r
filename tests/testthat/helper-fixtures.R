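# Small in-code fixtures shared across tests.

# a haplotype_sample built directly from a matrix
make_sample <- function(mat, positions, region_length = max(positions) + 10,
                        substitutions = NULL, balanced_site = NA,
                        tau = NA_real_) {
  subs <- if (is.null(substitutions))
    data.frame(position = integer(0), gen = integer(0), kind = integer(0))
  else data.frame(position = substitutions, gen = 0L, kind = 0L)
  structure(list(matrix = mat, positions = as.numeric(positions),
                 k = colSums(mat), n = nrow(mat), substitutions = subs,
                 balanced_col = NA_integer_, deme_of_row = rep(1L, nrow(mat)),
                 tau = tau, region_length = region_length,
                 balanced_site = balanced_site, generation = 0L),
            class = "haplotype_sample")
}

random_sample <- function(n, S, L = 10000) {
  mat <- matrix(0L, n, S)
  for (j in seq_len(S)) {
    k <- sample.int(n - 1, 1)
    mat[sample.int(n, k), j] <- 1L
  }
  make_sample(mat, sort(sample.int(L, S)), region_length = L)
}

# a desk-scale neutral config (N = 100 via Q = 100)
small_neutral_config <- function(N = 100, n = 100, seed = 1) {
  balsel:::neutral_scenario(N, n = n, seed = seed)
}

# brute-force oracles -------------------------------------------------------

pi_oracle <- function(mat, L) {
  n <- nrow(mat)
  tot <- 0
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      tot <- tot + sum(mat[i, ] != mat[j, ])
  tot / choose(n, 2) / L
}

hapdiv_oracle <- function(mat) {
  n <- nrow(mat)
  key <- apply(mat, 1, paste, collapse = "")
  (n / (n - 1)) * (1 - sum((table(key) / n)^2))
}

dprime_oracle <- function(mat) {
  n <- nrow(mat)
  k <- colSums(mat)
  poly <- which(k > 0 & k < n)
  if (length(poly) < 2) return(NA_real_)
  vals <- c()
  for (a in seq_along(poly)[-length(poly)]) {
    for (b in (a + 1):length(poly)) {
      i <- poly[a]; j <- poly[b]
      pA <- mean(mat[, i]); pB <- mean(mat[, j])
      pAB <- mean(mat[, i] == 1 & mat[, j] == 1)
      D <- pAB - pA * pB
      if (D == 0) { vals <- c(vals, 0); next }
      dmax <- if (D > 0) min(pA * (1 - pB), (1 - pA) * pB)
              else min(pA * pB, (1 - pA) * (1 - pB))
      vals <- c(vals, abs(D / dmax))
    }
  }
  mean(vals)
}

# EHH by explicit pair enumeration: fraction of carrier pairs identical on
# every SNP between the core and the target (inclusive)
ehh_oracle <- function(mat, core, target, allele) {
  carriers <- which(mat[, core] == allele)
  if (length(carriers) < 2) return(NA_real_)
  rng <- sort(c(core, target))
  cols <- rng[1]:rng[2]
  same <- 0; tot <- 0
  for (a in seq_along(carriers)[-length(carriers)]) {
    for (b in (a + 1):length(carriers)) {
      tot <- tot + 1
      if (all(mat[carriers[a], cols] == mat[carriers[b], cols]))
        same <- same + 1
    }
  }
  same / tot
}

# ROC by explicit enumeration over all (threshold, window) pairs
roc_oracle <- function(window_list, thresholds) {
  negs <- unlist(lapply(window_list, `[[`, "negative_scores"))
  trues <- vapply(window_list, function(w)
    if (is.na(w$true_score)) -Inf else w$true_score, numeric(1))
  data.frame(threshold = thresholds,
             tpr = vapply(thresholds, function(t) sum(trues >= t) /
                            length(trues), numeric(1)),
             fpr = vapply(thresholds, function(t) sum(negs >= t) /
                            length(negs), numeric(1)))
}
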