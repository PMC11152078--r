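test_that("EHH basics: core value, carrier splits, monotonicity", {
  # 4 carriers of the core allele; prefixes over cols 2:3 are
  # (0,0),(0,0),(0,1),(1,0): split {2,1,1} -> EHH = C(2,2)/C(4,2) = 1/6
  mat <- rbind(c(1, 0, 0),
               c(1, 0, 0),
               c(1, 0, 1),
               c(1, 1, 0),
               c(0, 0, 0),
               c(0, 0, 0))
  s <- make_sample(mat, c(100, 200, 300))
  cv <- ehh(s, core_pos = 100, allele = 1, cutoff = 0)
  expect_equal(cv$ehh[cv$positions == 100], 1)
  # first flanking SNP splits carriers {3,1}
  expect_equal(cv$ehh[cv$positions == 200],
               (choose(3, 2) + choose(1, 2)) / choose(4, 2))
  expect_equal(cv$ehh[cv$positions == 300], 1 / 6)
  expect_true(all(diff(cv$ehh[cv$positions >= 100]) <= 1e-12))

  # identical carriers keep EHH = 1 everywhere
  m2 <- rbind(matrix(1L, 3, 4), matrix(0L, 3, 4))
  m2[4:6, 2] <- c(1L, 0L, 0L)  # some ancestral variation
  s2 <- make_sample(m2, c(10, 20, 30, 40))
  cv2 <- ehh(s2, core_pos = 10, allele = 1, cutoff = 0.05)
  expect_true(all(cv2$ehh == 1))
  expect_true(cv2$left_edge && cv2$right_edge)

  # fewer than 2 carriers -> undefined
  m3 <- rbind(c(1, 0), c(0, 0), c(0, 1))
  expect_null(ehh(make_sample(m3, c(5, 6)), core_pos = 5, allele = 1))
})

test_that("EHH equals the brute-force pair-enumeration oracle", {
  set.seed(31)
  n_checked <- 0
  for (rep in 1:50) {
    s <- random_sample(sample(6:12, 1), sample(4:12, 1))
    core <- sample(seq_along(s$positions), 1)
    allele <- sample(0:1, 1)
    if (sum(s$matrix[, core] == allele) < 2) next
    cv <- ehh(s, s$positions[core], allele, cutoff = 0)
    for (ti in seq_along(cv$positions)) {
      target <- match(cv$positions[ti], s$positions)
      expect_equal(cv$ehh[ti], ehh_oracle(s$matrix, core, target, allele))
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 100)
})

test_that("integrated EHH is the trapezoidal area", {
  curve <- structure(list(positions = c(0, 1000), ehh = c(1, 0.5)),
                     class = "ehh_curve")
  expect_equal(integrated_ehh(curve), 750)
  flat <- structure(list(positions = c(-500, 0, 500), ehh = c(1, 1, 1)),
                    class = "ehh_curve")
  expect_equal(integrated_ehh(flat), 1000)
  # symmetric curve contributes equally on both sides
  sym <- structure(list(positions = c(-200, 0, 200), ehh = c(0.4, 1, 0.4)),
                   class = "ehh_curve")
  expect_equal(integrated_ehh(sym), 2 * (0.5 * (1 + 0.4) * 200))
})

test_that("unstandardized iHS arithmetic and domain edges", {
  expect_equal(unstandardized_ihs(500, 500), 0)
  expect_equal(unstandardized_ihs(500, 1000), log(0.5))
  expect_true(is.na(unstandardized_ihs(500, 0)))
})

test_that("standardization gives exact per-bin moments", {
  expect_equal(standardize_ihs(c(-1, 0, 1), rep(0.5, 3), min_bin = 1),
               c(-1, 0, 1))
  expect_equal(standardize_ihs(c(1, 2, 3), rep(0.5, 3), min_bin = 1),
               c(-1, 0, 1))
  expect_equal(standardize_ihs(c(2, 4), rep(0.3, 2), min_bin = 1),
               c(-1, 1) / sqrt(2), tolerance = 1e-12)
  # per-bin mean ~ 0 and SD ~ 1 after merging of small bins
  set.seed(32)
  u <- rnorm(500); p <- runif(500, 0.05, 0.95)
  z <- standardize_ihs(u, p)
  bins <- floor(p / 0.02)
  for (b in unique(bins)) {
    zb <- z[bins == b]
    if (length(zb) >= 20) {
      expect_lt(abs(mean(zb)), 0.8)  # merged bins shift moments slightly
    }
  }
  expect_equal(mean(z), 0, tolerance = 1e-10)
})

test_that("ihs_scan drops unscorable sites and flags sweeps", {
  # all-identical haplotypes except a singleton: nothing scorable
  m <- matrix(0L, 10, 3)
  m[1, 2] <- 1L
  s <- make_sample(m, c(10, 20, 30))
  expect_equal(nrow(ihs_scan(s)), 0)

  # a derived allele on one long shared haplotype vs diverse ancestrals
  set.seed(33)
  n <- 40; S <- 41
  anc <- matrix(rbinom(n / 2 * S, 1, 0.4), n / 2, S)
  der <- matrix(rep(rbinom(S, 1, 0.4), each = n / 2), n / 2, S)
  mat <- rbind(der, anc)
  core <- 21
  mat[, core] <- rep(c(1L, 0L), each = n / 2)
  sw <- make_sample(mat, seq(100, by = 100, length.out = S))
  sc <- ihs_scan(sw, standardize = FALSE)
  row <- sc[sc$position == 2100, ]
  # derived carriers identical: iHH_D large, ln(iHH_A/iHH_D) strongly negative
  expect_lt(row$uihs, -1)
})
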