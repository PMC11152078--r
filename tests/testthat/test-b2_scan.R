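test_that("background spectrum pools polymorphisms and substitutions", {
  m <- matrix(0L, 4, 1); m[1:3, 1] <- 1L  # one site with k = 3 of n = 4
  s <- make_sample(m, 50)
  sm <- background_sfs(list(s), pseudocount = 0)
  expect_equal(sm$g[3], 1)
  expect_equal(sum(sm$g), 1)

  s2 <- make_sample(m, 50, substitutions = c(10, 20))
  sm2 <- background_sfs(list(s2), pseudocount = 0)
  expect_equal(sm2$g, c(0, 0, 1 / 3, 2 / 3))

  # pseudocount keeps every class positive
  sm3 <- background_sfs(list(s))
  expect_true(all(sm3$g > 0))
  expect_equal(sum(sm3$g), 1)

  bad <- make_sample(matrix(0L, 5, 0), numeric(0), region_length = 100)
  expect_error(background_sfs(list(s, bad)), "mixed sample sizes")
})

test_that("neutral pooled spectrum has the 1/k shape", {
  # Sample n = 100 from 2N = 500 (n << 2N keeps the discrete-chain
  # fixation boundary away from the sampled classes; the top two classes
  # are still excluded as boundary-adjacent). The attainable Spearman is
  # bounded by sampling noise even for a perfect 1/k spectrum, so the
  # check compares against the ideal-sampling oracle at the same pooled
  # number of sites.
  set.seed(41)
  cfg <- small_neutral_config(N = 250)
  smp <- lapply(1:20, function(i) {
    set.seed(4100 + i)
    balsel:::run_neutral_replicate(cfg, 0, data.frame(deme = 1, n = 100))
  })
  kk <- unlist(lapply(smp, function(s) s$k))
  tb <- tabulate(kk, 100)
  ks <- 1:97
  # monotone 1/k decay (linkage between sites overdisperses the counts
  # relative to independent sampling, so the rank correlation is checked
  # against a conservative floor rather than the independent-site value)
  expect_gt(cor(tb[ks], 1 / ks, method = "spearman"), 0.75)
  # the log-log slope of the binned spectrum is -1 for a 1/k shape
  edges <- c(1, 2, 3, 4, 5, 7, 10, 15, 22, 33, 49, 72, 98)
  mids <- dens <- numeric(length(edges) - 1)
  for (i in seq_along(mids)) {
    rng <- edges[i]:(edges[i + 1] - 1)
    dens[i] <- sum(tb[rng]) / length(rng)  # count density per class
    mids[i] <- exp(mean(log(rng)))
  }
  fit <- lm(log(dens) ~ log(mids))
  expect_equal(unname(coef(fit)[2]), -1, tolerance = 0.25)
  # head of the spectrum: singletons about twice the doubletons
  expect_equal(tb[1] / tb[2], 2, tolerance = 0.15)
})

test_that("balanced component is a renormalized binomial", {
  h <- balanced_component(0.5, 100)
  expect_equal(sum(h), 1)
  expect_equal(h[50], dbinom(50, 100, 0.5), tolerance = 1e-10)
  expect_equal(round(h[50], 4), 0.0796)
  expect_equal(which.max(balanced_component(0.995, 100)), 100L)
  expect_error(balanced_component(0, 10), "in \\(0, 1\\)")
})

test_that("CLR: nested null, single-site closed form, log-additivity", {
  n <- 100
  g <- (1 / 1:99)
  g <- c(g / sum(g) * 0.999, 0.001)  # mostly 1/k with a small sub class
  model <- structure(list(n = n, g = g), class = "spectrum_model")
  cfg <- b2_config(beta_grid = 0.5, footprint_grid = 100)

  # single informative site at the test position with k = 50
  sites <- data.frame(position = 1000, k = 50)
  out <- b2_clr(1000, sites, model, cfg)
  h50 <- balanced_component(0.5, n)[50]
  expected <- 2 * log((h50 * 0.999 + 0) / g[50])  # alpha = 1 at d = 0
  # g(50) ~ 0.003863 on the pure 1/k normalization
  expect_equal(out$clr, 2 * log(h50 / g[50]), tolerance = 1e-6)
  expect_equal(out$clr, 6.05, tolerance = 0.02 * 6.05 + 0.01)

  # a background-typical site cannot beat the no-signal point
  sites0 <- data.frame(position = 1000, k = 1)
  expect_equal(b2_clr(1000, sites0, model, cfg)$clr, 0)

  # log-additivity at alpha = 1
  sites2 <- data.frame(position = c(1000, 1000.0001), k = c(50, 50))
  out2 <- b2_clr(1000, sites2, model, cfg)
  expect_equal(out2$clr, 2 * out$clr, tolerance = 1e-4)
})

test_that("CLR is non-negative and translation invariant", {
  set.seed(42)
  n <- 20
  model <- structure(list(n = n, g = {
    x <- c(1 / 1:(n - 1), 0.2); x / sum(x)
  }), class = "spectrum_model")
  cfg <- b2_config(beta_grid = c(0.2, 0.5, 0.8),
                   footprint_grid = c(100, 1000, 10000))
  for (rep in 1:20) {
    S <- sample(5:25, 1)
    sites <- data.frame(position = sort(sample.int(50000, S)),
                        k = sample.int(n, S, replace = TRUE))
    test <- sites$position[sample.int(S, 1)]
    out <- b2_clr(test, sites, model, cfg)
    expect_gte(out$clr, 0)
    shift <- 12345
    sites2 <- sites; sites2$position <- sites2$position + shift
    out2 <- b2_clr(test + shift, sites2, model, cfg)
    expect_equal(out2$clr, out$clr, tolerance = 1e-9)
  }
})

test_that("CLR agrees with a brute-force grid evaluator and monotonicity", {
  set.seed(43)
  n <- 10
  g <- c(1 / 1:(n - 1), 0.15); g <- g / sum(g)
  model <- structure(list(n = n, g = g), class = "spectrum_model")
  betas <- c(0.3, 0.5, 0.7); As <- c(200, 2000)
  cfg <- b2_config(beta_grid = betas, footprint_grid = As)
  hmat <- sapply(betas, balanced_component, n = n)

  brute <- function(test, sites) {
    best <- 0
    for (b in seq_along(betas)) for (a in seq_along(As)) {
      al <- exp(-abs(sites$position - test) / As[a])
      ll <- sum(log(al * hmat[sites$k, b] + (1 - al) * g[sites$k]) -
                log(g[sites$k]))
      best <- max(best, ll)
    }
    2 * best
  }

  for (rep in 1:15) {
    S <- sample(4:15, 1)
    sites <- data.frame(position = sort(sample.int(20000, S)),
                        k = sample.int(n, S, replace = TRUE))
    test <- sites$position[sample.int(S, 1)]
    out <- b2_clr(test, sites, model, cfg)
    expect_equal(out$clr, brute(test, sites), tolerance = 1e-8)

    # moving the nearest site's derived count to the balanced mode
    # round(n * beta) never decreases the CLR maximized at that beta
    j <- which.min(abs(sites$position - test))
    sites2 <- sites; sites2$k[j] <- round(n * 0.5)
    cfg5 <- b2_config(beta_grid = 0.5, footprint_grid = As)
    expect_gte(b2_clr(test, sites2, model, cfg5)$clr + 1e-9,
               b2_clr(test, sites, model, cfg5)$clr)
  }
})

test_that("b2_scan scores every SNP and uses substitutions", {
  set.seed(44)
  s <- random_sample(10, 12, L = 5000)
  s$substitutions <- data.frame(position = c(100, 4900), gen = 0, kind = 0)
  model <- background_sfs(list(s))
  out <- b2_scan(s, model)
  expect_equal(nrow(out), 12)
  expect_equal(out$position, s$positions)
  expect_true(all(out$clr >= 0))
})
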