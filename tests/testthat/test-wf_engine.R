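# engine-level model contracts and small Monte-Carlo checks

bare_population <- function(N, L = 1000) {
  layout <- build_neutral_layout(L)
  cfg <- scenario_config(
    layout, demography_plan(N),
    mutation_map = draw_rate_map("mutation", layout, "fixed", fixed_rate = 0),
    recombination_map = draw_rate_map("recombination", layout, "fixed",
                                      fixed_rate = 0),
    f_eq = NULL, burn_in_N = 0)
  wf_population(cfg)
}

test_that("frequency-dependent coefficient follows f_eq - f", {
  expect_equal(balanced_selection_coefficient(0.5, 0.5), 0)
  expect_equal(balanced_selection_coefficient(0.5, 0.1), 0.4)
  expect_equal(balanced_selection_coefficient(0.5, 0.75), -0.25)
  expect_error(balanced_selection_coefficient(1.2, 0.5), "\\[0, 1\\]")
})

test_that("genotype fitness is multiplicative with the stated contributions", {
  del1 <- data.frame(s = 0.1, h = 0.5, kind = "deleterious")
  expect_equal(individual_fitness(het = del1), 0.95)
  bal <- data.frame(s = NA, h = 0.5, kind = "balanced")
  expect_equal(individual_fitness(het = bal,
                                  S_bp = balanced_selection_coefficient(0.5, 0.1)),
               1.2)
  del2 <- data.frame(s = c(0.1, 0.1), h = c(0.5, 0.5),
                     kind = c("deleterious", "deleterious"))
  expect_equal(individual_fitness(het = del2), 0.95^2)
  expect_equal(individual_fitness(hom = del1), 0.9)
  # the engine agrees: a deme where one individual carries one het
  # deleterious mutation
  pop <- bare_population(10)
  seed_mutation(pop, 500, 1, s = 0.1, h = 0.5, kind = "deleterious")
  w <- sort(balsel:::wf_fitness_vector(pop$ptr, 1))
  expect_equal(w[1], 0.95)
  expect_true(all(w[-1] == 1))
})

test_that("one neutral WF generation is binomial sampling of alleles", {
  set.seed(51)
  N <- 50; k0 <- 40  # p = 0.4
  draws <- replicate(4000, {
    pop <- bare_population(N)
    id <- seed_mutation(pop, 500, k0)
    step_generation(pop)
    round(mutation_frequency(pop, id) * 2 * N)
  })
  # chi-square GOF against Binomial(2N, 0.4), pooling sparse tails
  br <- 0:(2 * N)
  p <- dbinom(br, 2 * N, k0 / (2 * N))
  keep <- p * length(draws) >= 5
  lo <- min(br[keep]); hi <- max(br[keep])
  cats <- pmin(pmax(draws, lo), hi)
  obs <- tabulate(cats - lo + 1, hi - lo + 1)
  pr <- dbinom(lo:hi, 2 * N, 0.4)
  pr[1] <- pbinom(lo, 2 * N, 0.4)
  pr[length(pr)] <- 1 - pbinom(hi - 1, 2 * N, 0.4)
  gof <- chisq.test(obs, p = pr / sum(pr))
  expect_gt(gof$p.value, 0.001)
})

test_that("neutral heterozygosity decays as (1 - 1/2N)^t", {
  set.seed(52)
  N <- 50; t <- 50
  H <- replicate(1500, {
    pop <- bare_population(N)
    id <- seed_mutation(pop, 500, N)  # p = 0.5
    step_generation(pop, t)
    p <- mutation_frequency(pop, id)
    2 * p * (1 - p)
  })
  expected <- 0.5 * (1 - 1 / (2 * N))^t
  se <- sd(H) / sqrt(length(H))
  expect_lt(abs(mean(H) - expected), 3 * se)
})

test_that("fixation moves mutations to the substitution record", {
  pop <- bare_population(20)
  seed_mutation(pop, 500, 40)  # all 2N chromosomes
  st <- population_status(pop)
  expect_equal(st$n_substitutions, 1L)
  expect_equal(st$n_active, 0L)
})

test_that("introduction preconditions: occupied positions and copy range", {
  pop <- bare_population(20)
  seed_mutation(pop, 500, 5)
  expect_error(seed_mutation(pop, 500, 1), "occupied")
  expect_error(seed_mutation(pop, 600, 0), "copies out of range")
  expect_error(seed_mutation(pop, 600, 41), "copies out of range")
  id <- seed_mutation(pop, 600, 1)
  expect_equal(mutation_frequency(pop, id), 1 / 40)
})

test_that("burn-in length, determinism, and reproducible samples", {
  cfg <- small_neutral_config(N = 60, n = 20)
  set.seed(53)
  pop1 <- run_burn_in(cfg)
  expect_equal(population_status(pop1)$generation, 600L)
  s1 <- sample_haplotypes(pop1)
  set.seed(53)
  pop2 <- run_burn_in(cfg)
  s2 <- sample_haplotypes(pop2)
  expect_identical(s1$positions, s2$positions)
  expect_identical(s1$matrix, s2$matrix)
})

test_that("frequency dependence pushes the allele toward equilibrium", {
  set.seed(54)
  N <- 100
  shift <- function(p0) {
    mean(replicate(400, {
      pop <- bare_population(N)
      balsel:::wf_introduce(pop$ptr, 500L, as.integer(p0 * 2 * N), 2L, 0.5, 0.5, TRUE)
      step_generation(pop)
      f <- focal_frequency(pop)
      (if (is.na(f)) if (p0 < 0.5) 0 else 1 else f) - p0
    }))
  }
  expect_gt(shift(0.1), 0)
  expect_lt(shift(0.9), 0)
})

test_that("the balanced allele hovers near f_eq over long runs", {
  set.seed(55)
  means <- replicate(3, {
    pop <- bare_population(100)
    balsel:::wf_introduce(pop$ptr, 500L, 100L, 2L, 0.5, 0.5, TRUE)
    freqs <- replicate(20, {
      step_generation(pop, 50)
      focal_frequency(pop)
    })
    mean(freqs)
  })
  expect_lt(abs(mean(means) - 0.5), 0.05)
})

test_that("rescaling preserves population-scaled parameters", {
  cfg <- preset_scenario("functional", dfe_name = "DFE4", Q = 1,
                         n_replicates = 1)
  expect_identical(rescale_scenario(cfg, 1), cfg)
  r20 <- rescale_scenario(cfg, 20)
  expect_equal(r20$demography$N_ancestral, 500)
  expect_equal(r20$mutation_map$block_rates[1], 2.5e-8 * 20)
  expect_equal(r20$recombination_map$block_rates[1], 1e-8 * 20)
  # 4 N mu invariant
  expect_equal(4 * 500 * r20$mutation_map$block_rates[1],
               4 * 10000 * cfg$mutation_map$block_rates[1])
  # the DFE stays on the same 2Ns scale through its reference size
  expect_equal(r20$dfe$N_ancestral, 500)
  set.seed(56)
  s <- sample_selection_coefficient(discrete_dfe(c(0, 0, 1, 0), 500), 2000)
  expect_true(all(2 * 500 * s >= 10 & 2 * 500 * s < 100))
  expect_error(rescale_scenario(cfg, 300), "N < 50")
})

test_that("replicates condition on establishment and emit n chromosomes", {
  cfg <- preset_scenario("neutral", Q = 100, n_replicates = 1,
                         sampling_times = c(0.01, 0.1))
  rep1 <- run_replicate(cfg, replicate_seed = 57)
  expect_gte(rep1$n_attempts, 1)
  for (s in rep1$samples) expect_equal(s$n, 100L)
  # checkpoints never precede the first attainment of f_eq
  expect_true(all(rep1$trajectory$gen >= rep1$feq_hit_gen))
  # conditioned on establishment, frequency stays near f_eq at 0.1N
  expect_gt(rep1$trajectory$freq[2], 0.15)
})

test_that("partial-sweep replicates sample at the target frequency", {
  cfg <- preset_scenario("neutral", Q = 100, n_replicates = 1, f_eq = NULL,
                         sweep_s = 100 / (2 * 10000))
  rep1 <- run_replicate(cfg, replicate_seed = 58)
  s <- rep1$samples$sweep
  focal <- s$k[s$balanced_col] / s$n
  # at Q = 100 the rescaled s = 0.5, so one generation overshoots the 0.5
  # stopping rule by about p(1-p)hs ~ 0.06 plus drift and sampling noise
  expect_gt(focal, 0.4)
  expect_lt(focal, 0.75)
  expect_equal(s$n, 100L)
})

test_that("diversity is invariant to the rescaling factor", {
  set.seed(59)
  pis <- lapply(c(50, 100), function(N) {
    cfg <- small_neutral_config(N = N)
    replicate(12, {
      pop <- run_burn_in(cfg)
      s <- sample_haplotypes(pop)
      nucleotide_diversity(s$matrix, 50000)
    })
  })
  d <- abs(mean(pis[[1]]) - mean(pis[[2]]))
  se <- sqrt(var(pis[[1]]) / 12 + var(pis[[2]]) / 12)
  expect_lt(d, 3 * se)
})
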