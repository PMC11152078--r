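test_that("generation-to-year conversion matches the human calibration", {
  expect_equal(generations_to_years(25, 10000, 26.9), 6.725e6)
  expect_equal(generations_to_years(1, 1, 1), 1)
})

test_that("neutral establishment follows the martingale identity", {
  set.seed(81)
  N <- 1000; q <- 0.1
  est <- establishment_chain(N, 1e5, copies = 1, threshold = q, s = 0)
  p <- 1 / (2 * N * q)
  se <- sqrt(p * (1 - p) / 1e5)
  expect_lt(abs(mean(est) - p), 3 * se)
})

test_that("semidominant establishment matches the diffusion formula", {
  set.seed(82)
  N <- 10000; s <- 100 / (2 * N); h <- 0.5; q <- 0.1
  out <- establishment_experiment(N = N, n_replicates = 10000, s = s, h = h,
                                  threshold = q)
  alpha <- 4 * N * h * s
  pred <- (1 - exp(-alpha / (2 * N))) / (1 - exp(-alpha * q))
  se <- sqrt(pred * (1 - pred) / out$n_replicates)
  expect_lt(abs(out$proportion - pred), 3 * se)
  expect_true(out$ci_lo <= out$proportion && out$proportion <= out$ci_hi)
})

test_that("balanced establishment lies between the two analytic oracles", {
  set.seed(83)
  N <- 1000; feq <- 0.5; q <- 0.1; h <- 0.5
  out <- establishment_experiment(N = N, n_replicates = 10000, f_eq = feq,
                                  threshold = q)
  # Diffusion (Kolmogorov backward) hitting probability with drift
  # m(p) = h S(p) p(1-p), S(p) = feq - p: psi(x) = exp(-2N(feq x - x^2/2)),
  # u(p0) = int_0^p0 psi / int_0^q psi. The initial advantage h S ~ 0.25 is
  # strong, where the diffusion slightly overshoots; the branching-process
  # survival probability (Poisson offspring, mean 1 + h S(0)) is the
  # strong-selection limit from below. The exact WF value sits in between.
  psi <- function(x) exp(-2 * N * (feq * x - x^2 / 2))
  p0 <- 1 / (2 * N)
  diff_pred <- stats::integrate(psi, 0, p0, rel.tol = 1e-10)$value /
    stats::integrate(psi, 0, q, rel.tol = 1e-10)$value
  lam <- 1 + h * feq
  branch_pred <- 1 - stats::uniroot(function(x) exp(lam * (x - 1)) - x,
                                    c(1e-12, 1 - 1e-9))$root
  se <- sqrt(diff_pred * (1 - diff_pred) / 10000)
  expect_gt(out$proportion, branch_pred - 3 * se)
  expect_lt(out$proportion, diff_pred + 3 * se)
})

test_that("structure presets build the documented models", {
  cfg <- balsel:::neutral_scenario(100)
  expect_null(cfg$f_eq)
  expect_equal(cfg$demography$N_ancestral, 100)
  # hidden structure samples 50 + 50 after a 5N-generation split
  # (structural check on the event list; the heavy FPR runs live in the
  # acceptance suite)
  ev_split <- list(time = 0, kind = "split", deme = 1, N = 100)
  cfg$demography$events <- list(ev_split)
  pop <- run_burn_in(cfg)
  balsel:::wf_evolve(pop$ptr, 500)
  st <- population_status(pop)
  expect_equal(st$deme_sizes, c(100L, 100L))
  s <- sample_haplotypes(pop, sample_demes = data.frame(deme = 1:2,
                                                        n = c(50, 50)))
  expect_equal(s$n, 100L)
  expect_equal(unname(table(s$deme_of_row)), unname(table(rep(1:2, 50))))
})

test_that("migration homogenizes demes but isolation differentiates", {
  set.seed(84)
  # two demes isolated for 5N generations develop frequency differences;
  # strong migration prevents them
  fst_like <- function(m) {
    cfg <- balsel:::neutral_scenario(60)
    N <- 60
    ev <- list(list(time = 0, kind = "split", deme = 1, N = N))
    if (m > 0)
      ev <- c(ev, list(list(time = 0, kind = "set_migration",
                            matrix = c(1 - m, m, m, 1 - m))))
    cfg$demography$events <- ev
    pop <- run_burn_in(cfg)
    balsel:::wf_evolve(pop$ptr, as.integer(5 * N))
    s <- sample_haplotypes(pop, sample_demes = data.frame(deme = 1:2,
                                                          n = c(30, 30)))
    p1 <- colMeans(s$matrix[s$deme_of_row == 1, , drop = FALSE])
    p2 <- colMeans(s$matrix[s$deme_of_row == 2, , drop = FALSE])
    mean((p1 - p2)^2)
  }
  expect_gt(fst_like(0), fst_like(0.1) * 1.5)
})

test_that("run_scenario is deterministic given its seed", {
  cfg <- preset_scenario("neutral", Q = 100, n_replicates = 2, seed = 19,
                         sampling_times = 0.1)
  d1 <- tempfile(); d2 <- tempfile()
  run_scenario(cfg, methods = "b2", out_dir = d1)
  run_scenario(cfg, methods = "b2", out_dir = d2)
  f1 <- file.path(d1, "roc_b2_tau0.1.tsv")
  f2 <- file.path(d2, "roc_b2_tau0.1.tsv")
  expect_true(file.exists(f1))
  expect_identical(readLines(f1), readLines(f2))
  expect_true(file.exists(file.path(d1, "manifest.yaml")))
})
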