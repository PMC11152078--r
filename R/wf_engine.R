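#' @useDynLib balsel, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Frequency-dependent selection coefficient of the balanced allele
#'
#' Negative frequency dependence: `S = f_eq - f_bp`, positive (favouring the
#' balanced allele) below the equilibrium frequency and negative above it.
#'
#' @param f_eq equilibrium frequency in `[0, 1]`.
#' @param f_bp current frequency of the balanced allele in `[0, 1]`.
#' @return the selection coefficient `S`.
#' @export
balanced_selection_coefficient <- function(f_eq, f_bp) {
  if (any(f_eq < 0 | f_eq > 1) || any(f_bp < 0 | f_bp > 1))
    stop("frequencies must be in [0, 1]")
  f_eq - f_bp
}

#' Multiplicative fitness of a genotype
#'
#' Deleterious mutations contribute `1 - h s` when heterozygous and `1 - s`
#' when homozygous; balanced or beneficial mutations contribute `1 + h S`
#' and `1 + S`. Fitness is multiplicative across mutations and floored at 0.
#'
#' @param het data.frame of heterozygous mutations with columns `s`, `h`,
#'   `kind` ("neutral", "deleterious", "balanced", "beneficial").
#' @param hom data.frame of homozygous mutations, same columns.
#' @param S_bp current selection coefficient of the balanced allele.
#' @return fitness weight (>= 0).
#' @export
individual_fitness <- function(het = NULL, hom = NULL, S_bp = 0) {
  contrib <- function(df, homo) {
    if (is.null(df) || nrow(df) == 0) return(1)
    f <- vapply(seq_len(nrow(df)), function(i) {
      k <- df$kind[i]
      if (k == "neutral") return(1)
      if (k == "deleterious")
        return(if (homo) 1 - df$s[i] else 1 - df$h[i] * df$s[i])
      s <- if (k == "balanced") S_bp else df$s[i]
      if (homo) 1 + s else 1 + df$h[i] * s
    }, numeric(1))
    prod(f)
  }
  max(contrib(het, FALSE) * contrib(hom, TRUE), 0)
}

#' Demography plan
#'
#' @param N_ancestral diploid size of the single ancestral deme.
#' @param events list of events, each a list with `time` (generations
#'   relative to the introduction of the balanced allele; negative = before),
#'   `kind` ("size_change", "split", "set_migration") and parameters:
#'   `deme`/`N` for size_change and split, `matrix` (row-stochastic backward
#'   migration probabilities) for set_migration.
#' @return a `demography_plan`.
#' @export
demography_plan <- function(N_ancestral, events = list()) {
  if (N_ancestral < 1) stop("N_ancestral must be >= 1")
  times <- vapply(events, function(e) as.numeric(e$time), numeric(1))
  if (length(times) > 1 && any(diff(sort(times)) < 0))
    stop("event times must be orderable")
  structure(list(N_ancestral = N_ancestral, events = events),
            class = "demography_plan")
}

#' Scenario configuration
#'
#' Full description of one simulation experiment: chromosome layout, DFE,
#' rate maps, demography, balanced-allele model, sampling grid and seeds.
#' Sampling times `tau_b` are in units of `N_ancestral` generations since
#' the introduction of the focal variant.
#'
#' @param layout `chromosome_layout`.
#' @param demography `demography_plan`.
#' @param mutation_map,recombination_map `rate_map`s (defaults: fixed
#'   2.5e-8 and 1e-8 per bp per generation).
#' @param dfe optional `discrete_dfe` applied to exonic sites.
#' @param f_eq equilibrium frequency of the balanced allele, or `NULL` for
#'   neutral / partial-sweep runs.
#' @param balanced_h dominance of the focal variant.
#' @param intro_copies chromosomes carrying the variant at introduction.
#' @param establishment_threshold frequency defining establishment (0.1).
#' @param sampling_times vector of tau_b values (units of N_ancestral
#'   generations).
#' @param sample_size chromosomes per sample.
#' @param sample_demes data.frame with columns `deme`, `n` (defaults to all
#'   of `sample_size` from deme 1).
#' @param n_replicates replicates per scenario.
#' @param seed master seed.
#' @param rescale_Q rescaling factor already applied (bookkeeping).
#' @param sweep_s fixed beneficial coefficient for partial-sweep /
#'   stochastic-loss mode (no frequency dependence).
#' @param sweep_target sampling frequency for partial sweeps (0.5).
#' @param burn_in_N burn-in duration in units of N_ancestral (10).
#' @param retry_budget maximum establishment retries per replicate.
#' @return a `scenario_config`.
#' @export
scenario_config <- function(layout, demography,
                            mutation_map = NULL, recombination_map = NULL,
                            dfe = NULL, f_eq = 0.5, balanced_h = 0.5,
                            intro_copies = 1L, establishment_threshold = 0.1,
                            sampling_times = c(0.01, 0.1, 1, 10, 25, 50, 75, 100),
                            sample_size = 100L, sample_demes = NULL,
                            n_replicates = 200L, seed = 1L, rescale_Q = 1L,
                            sweep_s = NULL, sweep_target = 0.5,
                            burn_in_N = 10, retry_budget = 1000L) {
  if (is.null(mutation_map))
    mutation_map <- draw_rate_map("mutation", layout, "fixed",
                                  fixed_rate = 2.5e-8)
  if (is.null(recombination_map))
    recombination_map <- draw_rate_map("recombination", layout, "fixed",
                                       fixed_rate = 1e-8)
  if (!is.null(f_eq) && (f_eq <= 0 || f_eq >= 1))
    stop("f_eq must be in (0, 1)")
  if (establishment_threshold <= 0 || establishment_threshold >= 1)
    stop("establishment_threshold must be in (0, 1)")
  if (any(sampling_times <= 0)) stop("sampling times must be positive")
  if (rescale_Q < 1) stop("rescale_Q must be >= 1")
  if (is.null(sample_demes))
    sample_demes <- data.frame(deme = 1L, n = as.integer(sample_size))
  structure(list(layout = layout, demography = demography,
                 mutation_map = mutation_map,
                 recombination_map = recombination_map, dfe = dfe,
                 f_eq = f_eq, balanced_h = balanced_h,
                 intro_copies = as.integer(intro_copies),
                 establishment_threshold = establishment_threshold,
                 sampling_times = sort(unique(sampling_times)),
                 sample_size = as.integer(sample_size),
                 sample_demes = sample_demes,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed), rescale_Q = as.integer(rescale_Q),
                 sweep_s = sweep_s, sweep_target = sweep_target,
                 burn_in_N = burn_in_N,
                 retry_budget = as.integer(retry_budget)),
            class = "scenario_config")
}

#' Rescale a scenario by a factor Q
#'
#' Shrinks the population (`N -> N/Q`) while preserving the population-scaled
#' parameters: `mu -> Q mu`, `r -> Q r`, fixed selection coefficients
#' `s -> Q s` (the DFE is defined on the 2Ns scale and rescales through its
#' reference size), times in generations `-> /Q`; times already in units of
#' N are unchanged. The frequency-dependent coefficient `S = f_eq - F` is
#' O(1) and is deliberately not multiplied by Q.
#'
#' @param config a `scenario_config` (unscaled, `rescale_Q == 1`).
#' @param Q integer rescaling factor; the scaled N must stay >= 50.
#' @return a rescaled `scenario_config`.
#' @export
rescale_scenario <- function(config, Q) {
  if (Q < 1) stop("Q must be >= 1")
  if (Q == 1) return(config)
  N <- config$demography$N_ancestral
  N2 <- round(N / Q)
  if (N2 < 50) stop("rescaling would give N < 50; choose a smaller Q")
  cfg <- config
  cfg$demography$N_ancestral <- N2
  cfg$demography$events <- lapply(config$demography$events, function(e) {
    e$time <- e$time / Q
    if (!is.null(e$N)) e$N <- max(1L, round(e$N / Q))
    e
  })
  cfg$mutation_map$block_rates <- config$mutation_map$block_rates * Q
  cfg$recombination_map$block_rates <- config$recombination_map$block_rates * Q
  if (!is.null(config$dfe)) {
    cfg$dfe <- discrete_dfe(config$dfe$class_probs, N_ancestral = N2,
                            h = config$dfe$h)
  }
  if (!is.null(config$sweep_s)) cfg$sweep_s <- min(config$sweep_s * Q, 1)
  cfg$rescale_Q <- as.integer(config$rescale_Q * Q)
  cfg
}

rate_map_args <- function(map) {
  list(starts = as.integer(map$block_edges), ends = as.integer(map$block_ends),
       rates = as.numeric(map$block_rates))
}

#' Create a live Wright-Fisher population from a scenario
#'
#' Low-level constructor; most users want [run_burn_in()] / [run_replicate()].
#' Event times are converted to absolute generations using the burn-in
#' length (`burn_in_N * N_ancestral` generations; the introduction happens
#' at the end of burn-in).
#'
#' @param config a `scenario_config`.
#' @return a `wf_population` handle.
#' @export
wf_population <- function(config) {
  N <- config$demography$N_ancestral
  burn_end <- round(config$burn_in_N * N)
  ev <- lapply(config$demography$events, function(e) {
    e$gen <- as.integer(round(burn_end + e$time))
    e
  })
  dfe <- config$dfe
  dfe_list <- if (is.null(dfe)) list() else
    list(class_probs = dfe$class_probs, class_bounds_2Ns = dfe$class_bounds_2Ns,
         h = dfe$h, N_ancestral = dfe$N_ancestral)
  mu <- rate_map_args(config$mutation_map)
  rec <- rate_map_args(config$recombination_map)
  cls <- if (is.null(dfe)) integer(config$layout$total_length) else
    site_classes(config$layout)
  ptr <- wf_create(config$layout$total_length, cls,
                   mu$starts, mu$ends, mu$rates,
                   rec$starts, rec$ends, rec$rates,
                   as.integer(N), matrix(1, 1, 1), dfe_list, ev)
  structure(list(ptr = ptr, config = config, burn_in_end = burn_end),
            class = "wf_population")
}

#' Evolve a population through the burn-in period
#'
#' Evolves a mutation-free ancestral deme for `burn_in_N * N_ancestral`
#' generations, leaving the population at neutral (or mutation-selection)
#' equilibrium, poised for the introduction of the focal variant.
#'
#' @param config a `scenario_config`.
#' @return a `wf_population` at the end of burn-in.
#' @export
run_burn_in <- function(config) {
  pop <- wf_population(config)
  wf_evolve(pop$ptr, pop$burn_in_end)
  pop
}

#' Advance a population by one (or more) Wright-Fisher generations
#' @param pop a `wf_population`.
#' @param n generations to step.
#' @return the population, invisibly.
#' @export
step_generation <- function(pop, n = 1L) {
  wf_evolve(pop$ptr, as.integer(n))
  invisible(pop)
}

#' Snapshot (deep-copy) a population
#' @param pop a `wf_population`.
#' @return an independent copy.
#' @export
clone_population <- function(pop) {
  structure(list(ptr = wf_clone_cpp(pop$ptr), config = pop$config,
                 burn_in_end = pop$burn_in_end),
            class = "wf_population")
}

#' Introduce the focal variant
#'
#' Places the variant on `copies` distinct randomly chosen chromosomes.
#' An occupied position (active mutation or substitution) is an error.
#'
#' @param pop a `wf_population`.
#' @param position 1-based bp.
#' @param copies number of carrier chromosomes.
#' @param kind "balanced" or "beneficial".
#' @param s_or_feq equilibrium frequency (balanced) or selection
#'   coefficient (beneficial).
#' @param h dominance.
#' @return the population, invisibly.
#' @export
introduce_variant <- function(pop, position, copies = 1L,
                              kind = c("balanced", "beneficial"),
                              s_or_feq, h = 0.5) {
  kind <- match.arg(kind)
  wf_introduce(pop$ptr, as.integer(position), as.integer(copies),
               if (kind == "balanced") 2L else 3L, s_or_feq, h, TRUE)
  invisible(pop)
}

#' Population status
#' @param pop a `wf_population`.
#' @return list with generation, deme sizes, active mutation count,
#'   substitution count, and focal-allele frequency.
#' @export
population_status <- function(pop) wf_status(pop$ptr)

#' Current focal-allele frequency
#' @param pop a `wf_population`.
#' @return frequency in `[0, 1]` (`NA` if no focal variant).
#' @export
focal_frequency <- function(pop) wf_focal_freq(pop$ptr)

#' Draw a sample of chromosomes
#'
#' Samples without replacement according to `sample_demes` and returns a
#' `haplotype_sample`: an n x S 0/1 matrix over sample-polymorphic sites
#' (columns ordered by position), derived counts, substitutions since
#' `min_sub_gen` (population fixations plus sample-fixed columns), and the
#' focal column if the focal variant is segregating in the sample.
#'
#' @param pop a `wf_population`.
#' @param sample_demes data.frame with `deme`, `n`; defaults to the config's.
#' @param min_sub_gen earliest substitution generation to report (defaults
#'   to the introduction generation, i.e. the end of burn-in).
#' @param tau label for the sampling time (units of N generations).
#' @return a `haplotype_sample`.
#' @export
sample_haplotypes <- function(pop, sample_demes = NULL, min_sub_gen = NULL,
                              tau = NA_real_) {
  if (is.null(sample_demes)) sample_demes <- pop$config$sample_demes
  if (is.null(min_sub_gen)) min_sub_gen <- pop$burn_in_end
  raw <- wf_sample(pop$ptr, as.integer(sample_demes$deme),
                   as.integer(sample_demes$n), as.integer(min_sub_gen))
  subs <- data.frame(position = raw$sub_pos, gen = raw$sub_gen,
                     kind = raw$sub_kind)
  subs <- subs[order(subs$position), , drop = FALSE]
  focal_col <- NA_integer_
  if (!is.na(raw$focal_pos) && length(raw$positions))
    focal_col <- match(raw$focal_pos, raw$positions)
  structure(list(matrix = raw$matrix, positions = as.numeric(raw$positions),
                 k = raw$k, n = nrow(raw$matrix),
                 substitutions = subs, balanced_col = focal_col,
                 deme_of_row = raw$deme_of_row, tau = tau,
                 region_length = pop$config$layout$total_length,
                 balanced_site = pop$config$layout$balanced_site_position,
                 generation = raw$generation),
            class = "haplotype_sample")
}

#' @export
print.haplotype_sample <- function(x, ...) {
  cat("haplotype_sample: n =", x$n, "chromosomes, S =", length(x$positions),
      "SNPs,", nrow(x$substitutions), "substitutions; tau =", x$tau, "\n")
  invisible(x)
}

#' Run one simulation replicate
#'
#' Burn-in, introduction of the focal variant, conditioning on establishment
#' (a variant lost before reaching the establishment threshold triggers a
#' restart from the saved post-burn-in state with a fresh introduction),
#' then sampling at each requested tau_b. Checkpoints that would fall before
#' the balanced allele first reaches its equilibrium frequency are deferred
#' to that generation, so that "young allele" samples are taken as soon as
#' the initial sweep completes (the sweep lasts about ln(2N)/(h f_eq)
#' generations, which does not shrink under rescaling).
#'
#' In partial-sweep mode (`sweep_s` set) a single sample is drawn when the
#' beneficial variant first reaches `sweep_target`.
#'
#' @param config a `scenario_config`.
#' @param replicate_seed integer seed for this replicate.
#' @param burned_in optional pre-computed post-burn-in `wf_population`
#'   (it is cloned, never modified).
#' @return list with `samples` (named by tau), `trajectory` (data.frame of
#'   checkpoint generations and focal frequency), `n_attempts`,
#'   `established_gen`, `feq_hit_gen`.
#' @export
run_replicate <- function(config, replicate_seed = NULL, burned_in = NULL) {
  if (!is.null(replicate_seed)) set.seed(replicate_seed)
  if (is.null(burned_in)) burned_in <- run_burn_in(config)
  N <- config$demography$N_ancestral
  site <- config$layout$balanced_site_position
  sweep_mode <- !is.null(config$sweep_s)
  thr <- config$establishment_threshold

  attempt <- 0L
  repeat {
    attempt <- attempt + 1L
    if (attempt > config$retry_budget)
      stop("establishment not achieved within the retry budget")
    pop <- clone_population(burned_in)
    if (sweep_mode) {
      introduce_variant(pop, site, config$intro_copies, "beneficial",
                        config$sweep_s, h = config$balanced_h)
      target <- config$sweep_target
    } else {
      introduce_variant(pop, site, config$intro_copies, "balanced",
                        config$f_eq, h = config$balanced_h)
      target <- thr
    }
    res <- wf_evolve_track(pop$ptr, as.integer(200 * N), 0, target)
    if (res$status == "high") break
  }
  intro_gen <- pop$burn_in_end
  gens_elapsed <- population_status(pop)$generation - intro_gen

  if (sweep_mode) {
    s <- sample_haplotypes(pop, min_sub_gen = intro_gen, tau = NA_real_)
    return(list(samples = list(sweep = s),
                trajectory = data.frame(gen = gens_elapsed,
                                        freq = focal_frequency(pop)),
                n_attempts = attempt, established_gen = gens_elapsed,
                feq_hit_gen = gens_elapsed))
  }

  established_gen <- gens_elapsed
  # first attainment of the equilibrium frequency
  res <- wf_evolve_track(pop$ptr, as.integer(200 * N), 0, config$f_eq)
  feq_hit <- population_status(pop)$generation - intro_gen
  if (res$status %in% c("low", "nofocal")) feq_hit <- established_gen

  checkpoints <- pmax(round(config$sampling_times * N), feq_hit)
  ord <- order(checkpoints)
  samples <- vector("list", length(checkpoints))
  names(samples) <- as.character(config$sampling_times)
  traj <- data.frame(gen = numeric(0), freq = numeric(0))
  for (i in ord) {
    now <- population_status(pop)$generation - intro_gen
    if (checkpoints[i] > now) wf_evolve(pop$ptr, as.integer(checkpoints[i] - now))
    samples[[i]] <- sample_haplotypes(pop, min_sub_gen = intro_gen,
                                      tau = config$sampling_times[i])
    f <- focal_frequency(pop)
    traj <- rbind(traj, data.frame(gen = checkpoints[i],
                                   freq = if (is.na(f)) 0 else f))
  }
  list(samples = samples, trajectory = traj, n_attempts = attempt,
       established_gen = established_gen, feq_hit_gen = feq_hit)
}

# low-level helpers used by tests ------------------------------------------

#' Seed a mutation at an exact carrier count (testing/diagnostics)
#' @param pop a `wf_population`.
#' @param position bp.
#' @param copies carriers.
#' @param s selection coefficient; `kind` as in [introduce_variant()] plus
#'   "neutral"/"deleterious".
#' @param h dominance.
#' @param kind mutation kind.
#' @return the internal mutation id.
#' @export
seed_mutation <- function(pop, position, copies, s = 0, h = 0.5,
                          kind = c("neutral", "deleterious", "balanced",
                                   "beneficial")) {
  kind <- match.arg(kind)
  code <- match(kind, c("neutral", "deleterious", "balanced", "beneficial")) - 1L
  wf_introduce(pop$ptr, as.integer(position), as.integer(copies), code,
               s, h, code >= 2L)
}

#' Frequency of a mutation by internal id (testing/diagnostics)
#' @param pop a `wf_population`.
#' @param id internal mutation id from [seed_mutation()].
#' @return frequency in `[0, 1]`.
#' @export
mutation_frequency <- function(pop, id) wf_mut_freq(pop$ptr, id)

#' Population allele frequencies of all active mutations (diagnostics)
#' @param pop a `wf_population`.
#' @return numeric vector of frequencies.
#' @export
active_frequencies <- function(pop) wf_site_freqs(pop$ptr)
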