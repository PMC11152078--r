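#' Convert a sampling time to years
#'
#' `tau` (in units of N generations) times `N` times the generation time.
#' With human parameters (N = 10,000, 26.9 years per generation), 25N
#' generations is 6.725 million years.
#'
#' @param tau time in units of N generations.
#' @param N diploid population size.
#' @param generation_time years per generation.
#' @return time in years.
#' @export
generations_to_years <- function(tau, N = 10000, generation_time = 26.9) {
  tau * N * generation_time
}

#' Run a full scenario: replicates, scans, ROC curves
#'
#' Simulates `config$n_replicates` replicates (each with burn-in,
#' conditioned establishment and the tau_b sampling grid), applies the
#' requested scan methods at every checkpoint, and builds one ROC table
#' per method per tau_b using the 100-bp window protocol. The CLR scan's
#' background spectrum is pooled across the replicates of each tau_b;
#' iHS standardization is pooled the same way.
#'
#' @param config a `scenario_config`.
#' @param methods subset of `c("b2", "ihs")` (empty: simulation only).
#' @param b2_cfg a `b2_config`.
#' @param fpr_mode "matched_neutral" (default): negatives are all windows
#'   of matched neutral replicates of the same baseline model, and iHS
#'   standardization is calibrated on the neutral pool (emulating a
#'   predominantly neutral genome-wide background); "within_replicate":
#'   negatives are the non-true windows of the selection scans themselves.
#' @param n_null_replicates neutral replicates for the negative pool
#'   (defaults to `n_replicates`).
#' @param share_burnin pair each selection replicate with a matched
#'   neutral control grown from a clone of the same post-burn-in state
#'   (halves simulation cost; requires equal replicate counts).
#' @param keep_samples retain the raw samples in the result.
#' @param sumstats also compute the 2-kb/1-kb sliding-window summary table.
#' @param out_dir optional directory for TSV outputs and a manifest.
#' @param verbose print progress.
#' @return a `scenario_result`: list with `rocs[[method]][[tau]]`,
#'   `window_scores`, `power` (TPR at 5 and 10 percent FPR), `trajectories`,
#'   `n_attempts`, and optionally `samples`, `sumstats`.
#' @export
run_scenario <- function(config, methods = c("b2", "ihs"),
                         b2_cfg = b2_config(),
                         fpr_mode = c("matched_neutral", "within_replicate"),
                         n_null_replicates = NULL, share_burnin = TRUE,
                         keep_samples = FALSE,
                         sumstats = FALSE, out_dir = NULL, verbose = FALSE) {
  fpr_mode <- match.arg(fpr_mode)
  matched <- fpr_mode == "matched_neutral" && length(methods) > 0
  if (is.null(n_null_replicates)) n_null_replicates <- config$n_replicates
  share <- matched && share_burnin &&
    n_null_replicates == config$n_replicates
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max, config$n_replicates)
  null_seeds <- sample.int(.Machine$integer.max, n_null_replicates)
  reps <- vector("list", config$n_replicates)
  nulls <- if (matched) vector("list", n_null_replicates)
  for (r in seq_len(config$n_replicates)) {
    if (share) {
      set.seed(seeds[r])
      base <- run_burn_in(config)
      nulls[[r]] <- run_null_replicate(config,
                                       burned_in = clone_population(base))
      reps[[r]] <- run_replicate(config, burned_in = base)
    } else {
      reps[[r]] <- run_replicate(config, replicate_seed = seeds[r])
    }
    if (r %% 5 == 0) gc(FALSE)  # free finished engine states promptly
    if (verbose && r %% 10 == 0) message("replicate ", r)
  }
  if (matched && !share) {
    for (r in seq_len(n_null_replicates)) {
      nulls[[r]] <- run_null_replicate(config, replicate_seed = null_seeds[r])
      if (verbose && r %% 10 == 0) message("null replicate ", r)
    }
  }
  taus <- as.character(config$sampling_times)
  sweep_mode <- !is.null(config$sweep_s)
  if (sweep_mode) taus <- "sweep"

  res <- list(config = config, seeds = seeds, fpr_mode = fpr_mode,
              n_attempts = vapply(reps, `[[`, numeric(1), "n_attempts"),
              trajectories = lapply(reps, `[[`, "trajectory"),
              rocs = list(), window_scores = list(), scans = list(),
              null_scans = list())
  if (keep_samples) res$samples <- lapply(reps, `[[`, "samples")

  site <- config$layout$balanced_site_position
  L <- config$layout$total_length
  for (tau in taus) {
    smp <- lapply(reps, function(rp) rp$samples[[tau]])
    nul <- if (matched) lapply(nulls, function(rp) rp$samples[[tau]])
    if (sumstats)
      res$sumstats[[tau]] <- do.call(rbind, lapply(seq_along(smp), function(i) {
        cbind(replicate = i, tau = tau, sliding_window_table(smp[[i]]))
      }))
    if ("b2" %in% methods) {
      model <- background_sfs(smp)
      scans <- lapply(smp, b2_scan, model = model, config = b2_cfg)
      pool <- NULL
      if (matched) {
        null_model <- background_sfs(nul)
        nscans <- lapply(nul, b2_scan, model = null_model, config = b2_cfg)
        pool <- unlist(lapply(nscans, all_window_scores))
        res$null_scans[["b2"]][[tau]] <- nscans
      }
      ws <- lapply(scans, window_scores, balanced_site = site,
                   region_length = L)
      res$window_scores[["b2"]][[tau]] <- ws
      res$rocs[["b2"]][[tau]] <- roc(ws, negative_pool = pool)
      res$scans[["b2"]][[tau]] <- scans
    }
    if ("ihs" %in% methods) {
      pool <- NULL
      if (matched) {
        nraw <- lapply(nul, ihs_scan, standardize = FALSE)
        pars <- ihs_bin_params(unlist(lapply(nraw, `[[`, "uihs")),
                               unlist(lapply(nraw, `[[`, "p_derived")))
        nscans <- lapply(nraw, function(df) {
          df$ihs <- standardize_ihs(df$uihs, df$p_derived, params = pars)
          df$score <- abs(df$ihs)
          df
        })
        pool <- unlist(lapply(nscans, all_window_scores))
        res$null_scans[["ihs"]][[tau]] <- nscans
        res$ihs_params[[tau]] <- pars
        scans <- ihs_scan_set(smp, params = pars)
      } else {
        scans <- ihs_scan_set(smp)
      }
      ws <- lapply(scans, window_scores, balanced_site = site,
                   region_length = L)
      res$window_scores[["ihs"]][[tau]] <- ws
      res$rocs[["ihs"]][[tau]] <- roc(ws, negative_pool = pool)
      res$scans[["ihs"]][[tau]] <- scans
    }
  }
  pw <- list()
  for (m in names(res$rocs))
    for (tau in names(res$rocs[[m]]))
      pw[[length(pw) + 1]] <- data.frame(
        method = m, tau = tau,
        tpr_fpr05 = tpr_at_fpr(res$rocs[[m]][[tau]], 0.05),
        tpr_fpr10 = tpr_at_fpr(res$rocs[[m]][[tau]], 0.10))
  res$power <- if (length(pw)) do.call(rbind, pw) else NULL
  class(res) <- "scenario_result"
  if (!is.null(out_dir)) write_scenario_result(res, out_dir)
  res
}

write_scenario_result <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (m in names(res$rocs))
    for (tau in names(res$rocs[[m]]))
      utils::write.table(res$rocs[[m]][[tau]],
                         file.path(out_dir, paste0("roc_", m, "_tau", tau,
                                                   ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$power))
    utils::write.table(res$power, file.path(out_dir, "power.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  write_scenario_yaml(res$config, file.path(out_dir, "config.yaml"))
  yaml::write_yaml(list(seeds = res$seeds,
                        n_attempts = res$n_attempts,
                        package_version =
                          as.character(utils::packageVersion("balsel"))),
                   file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}

#' Marginal allele-frequency establishment chain
#'
#' Exact Wright-Fisher binomial chain for a single focal allele on a
#' neutral background (no linked sites): deterministic selection update of
#' the expected frequency followed by binomial sampling of 2N alleles,
#' iterated until the allele reaches the establishment threshold or is
#' lost. Equivalent to the full engine when no other selected variation
#' segregates, and fast enough for 10^5 replicates.
#'
#' @param N diploid size.
#' @param n_replicates replicates.
#' @param copies initial carrier chromosomes.
#' @param threshold establishment frequency (0.1).
#' @param s fixed beneficial coefficient (ignored when `f_eq` given).
#' @param h dominance.
#' @param f_eq if non-NULL, frequency-dependent coefficient `f_eq - p`.
#' @return logical vector: established or lost, per replicate.
#' @export
establishment_chain <- function(N, n_replicates, copies = 1L, threshold = 0.1,
                                s = 0, h = 0.5, f_eq = NULL) {
  p <- rep(copies / (2 * N), n_replicates)
  alive <- rep(TRUE, n_replicates)
  established <- rep(FALSE, n_replicates)
  while (any(alive)) {
    pa <- p[alive]
    S <- if (!is.null(f_eq)) f_eq - pa else rep(s, length(pa))
    whom <- 1 + S; whet <- 1 + h * S
    wbar <- pa^2 * whom + 2 * pa * (1 - pa) * whet + (1 - pa)^2
    pexp <- (pa^2 * whom + pa * (1 - pa) * whet) / wbar
    k <- stats::rbinom(length(pexp), 2 * N, pexp)
    pa <- k / (2 * N)
    idx <- which(alive)
    est <- pa >= threshold
    dead <- pa <= 0
    p[idx] <- pa
    established[idx[est]] <- TRUE
    alive[idx] <- !(est | dead)
  }
  established
}

#' Establishment-probability experiment
#'
#' Counts replicates in which a newly introduced beneficial (or balanced)
#' variant reaches the establishment threshold before loss. On a neutral
#' background the focal-allele trajectory is simulated as a standalone
#' frequency process ([establishment_chain()]); with a DFE the full engine
#' is used, amortizing a small number of independent burn-ins across many
#' introduction trials.
#'
#' @param N diploid size (chain mode).
#' @param n_replicates total introduction trials.
#' @param s beneficial selection coefficient (2Ns / 2N).
#' @param h dominance.
#' @param f_eq equilibrium frequency for a balanced variant (chain mode).
#' @param copies introduction copies.
#' @param threshold establishment frequency.
#' @param config full-engine mode: a `scenario_config` with `sweep_s` (and
#'   usually a DFE); overrides the chain.
#' @param n_burnins independent burn-ins to amortize (full-engine mode).
#' @param scenario_id label.
#' @return an `establishment_result`: data.frame with counts, proportion
#'   and exact binomial 95 percent CI.
#' @export
establishment_experiment <- function(N = NULL, n_replicates = 10000L,
                                     s = 0, h = 0.5, f_eq = NULL,
                                     copies = 1L, threshold = 0.1,
                                     config = NULL, n_burnins = 5L,
                                     scenario_id = "establishment") {
  if (is.null(config)) {
    est <- establishment_chain(N, n_replicates, copies, threshold, s, h, f_eq)
    n_est <- sum(est)
    twoNs <- 2 * N * s
  } else {
    N <- config$demography$N_ancestral
    site <- config$layout$balanced_site_position
    per <- ceiling(n_replicates / n_burnins)
    n_est <- 0L; n_run <- 0L
    for (b in seq_len(n_burnins)) {
      base <- run_burn_in(config)
      for (i in seq_len(per)) {
        if (n_run >= n_replicates) break
        # engine state lives outside R's heap; collect stale clones
        if (i %% 25 == 0) gc(FALSE)
        pop <- clone_population(base)
        if (!is.null(config$sweep_s))
          introduce_variant(pop, site, copies, "beneficial", config$sweep_s,
                            h = config$balanced_h)
        else
          introduce_variant(pop, site, copies, "balanced", config$f_eq,
                            h = config$balanced_h)
        out <- wf_evolve_track(pop$ptr, as.integer(1000 * N), 0, threshold)
        n_run <- n_run + 1L
        if (out$status == "high") n_est <- n_est + 1L
      }
    }
    n_replicates <- n_run
    twoNs <- if (!is.null(config$sweep_s)) 2 * N * config$sweep_s else NA_real_
  }
  ci <- stats::binom.test(n_est, n_replicates)$conf.int
  structure(data.frame(scenario = scenario_id, two_Ns = twoNs,
                       intro_copies = copies, n_replicates = n_replicates,
                       n_established = n_est,
                       proportion = n_est / n_replicates,
                       ci_lo = ci[1], ci_hi = ci[2]),
            class = c("establishment_result", "data.frame"))
}

neutral_scenario <- function(N, length = 50000L, n = 100L, seed = 1L,
                             Q = 1L, mu = 2.5e-8, r = 1e-8) {
  layout <- build_neutral_layout(length)
  cfg <- scenario_config(
    layout, demography_plan(10000),
    mutation_map = draw_rate_map("mutation", layout, "fixed", fixed_rate = mu),
    recombination_map = draw_rate_map("recombination", layout, "fixed",
                                      fixed_rate = r),
    f_eq = NULL, sample_size = n, seed = seed)
  cfg$demography$N_ancestral <- 10000
  cfg <- rescale_scenario(cfg, round(10000 / N))
  cfg
}

# a matched neutral replicate: same baseline model, no focal variant,
# sampled at the same checkpoint generations as the selection replicates
run_null_replicate <- function(config, replicate_seed = NULL,
                               burned_in = NULL) {
  if (!is.null(replicate_seed)) set.seed(replicate_seed)
  pop <- if (is.null(burned_in)) run_burn_in(config) else burned_in
  N <- config$demography$N_ancestral
  intro_gen <- pop$burn_in_end
  if (!is.null(config$sweep_s)) {
    return(list(samples = list(
      sweep = sample_haplotypes(pop, min_sub_gen = intro_gen))))
  }
  checkpoints <- round(config$sampling_times * N)
  samples <- vector("list", length(checkpoints))
  names(samples) <- as.character(config$sampling_times)
  for (i in order(checkpoints)) {
    now <- population_status(pop)$generation - intro_gen
    if (checkpoints[i] > now)
      wf_evolve(pop$ptr, as.integer(checkpoints[i] - now))
    samples[[i]] <- sample_haplotypes(pop, min_sub_gen = intro_gen,
                                      tau = config$sampling_times[i])
  }
  list(samples = samples)
}

run_neutral_replicate <- function(config, forward_gens, sample_demes) {
  pop <- run_burn_in(config)
  if (forward_gens > 0) wf_evolve(pop$ptr, as.integer(forward_gens))
  sample_haplotypes(pop, sample_demes = sample_demes,
                    min_sub_gen = pop$burn_in_end)
}

#' Structure / admixture false-positive experiment
#'
#' Simulates a neutral model forward-in-time (no balanced allele), scans
#' every replicate with both methods, and returns normalized-threshold FPR
#' curves. Models:
#' \describe{
#'   \item{panmictic}{single equilibrium deme, 100 chromosomes (the null).}
#'   \item{two_deme_geneflow}{split into two demes of size N with symmetric
#'     migration `m = Nm / N` for 10N generations; one deme sampled.}
#'   \item{admixture}{split, strong migration (Nm = 0.25) for 5N
#'     generations, then 5N generations of isolation; one deme sampled.}
#'   \item{hidden_structure}{split, complete isolation for 5N generations,
#'     then 50 chromosomes sampled from each deme.}
#' }
#'
#' Scans can be calibrated against an external reference (typically the
#' panmictic scenario): `b2_model` replaces the scenario's own pooled
#' background spectrum and `ihs_params` the scenario's own
#' standardization bins. This emulates an analyst whose null model
#' assumes panmixia — the situation in which unacknowledged structure
#' confounds the scans; self-calibrated scans absorb a genome-wide
#' structure signal into their own background and show little excess.
#'
#' @param model model name.
#' @param N scaled diploid deme size.
#' @param Nm population-scaled migration rate (two_deme_geneflow).
#' @param n_replicates replicates.
#' @param seed master seed.
#' @param methods scan methods.
#' @param n_thresholds normalized thresholds.
#' @param b2_model optional reference `spectrum_model`.
#' @param ihs_params optional reference `ihs_bin_params`.
#' @return list with `model`, per-method `curves` (per-scenario
#'   normalization; see [normalized_fpr_curves()] for cross-scenario
#'   comparison), the pooled `scans`, and the calibration objects used
#'   (`b2_model`, `ihs_params`) for reuse as a reference.
#' @export
structure_fpr_experiment <- function(model = c("panmictic",
                                               "two_deme_geneflow",
                                               "admixture",
                                               "hidden_structure"),
                                     N = 500, Nm = 0.1, n_replicates = 200L,
                                     seed = 1L, methods = c("b2", "ihs"),
                                     n_thresholds = 100L, b2_model = NULL,
                                     ihs_params = NULL) {
  model <- match.arg(model)
  cfg <- neutral_scenario(N, seed = seed)
  N <- cfg$demography$N_ancestral
  m <- if (model == "two_deme_geneflow") Nm / N else 0.25 / N
  ev <- switch(model,
    panmictic = list(),
    two_deme_geneflow = c(list(list(time = 0, kind = "split", deme = 1, N = N)),
      if (Nm > 0) list(list(time = 0, kind = "set_migration",
                            matrix = c(1 - m, m, m, 1 - m)))),
    admixture = list(
      list(time = 0, kind = "split", deme = 1, N = N),
      list(time = 0, kind = "set_migration", matrix = c(1 - m, m, m, 1 - m)),
      list(time = 5 * N, kind = "set_migration", matrix = c(1, 0, 0, 1))),
    hidden_structure = list(list(time = 0, kind = "split", deme = 1, N = N)))
  cfg$demography$events <- ev
  forward <- switch(model, panmictic = 0, two_deme_geneflow = 10 * N,
                    admixture = 10 * N, hidden_structure = 5 * N)
  demes <- if (model == "hidden_structure")
    data.frame(deme = c(1L, 2L), n = c(50L, 50L))
  else data.frame(deme = 1L, n = 100L)

  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, n_replicates)
  smp <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    set.seed(seeds[r])
    smp[[r]] <- run_neutral_replicate(cfg, forward, demes)
  }
  out <- list(model = model, Nm = if (model == "two_deme_geneflow") Nm else NA,
              curves = list(), scans = list())
  L <- cfg$layout$total_length
  if ("b2" %in% methods) {
    mod <- if (is.null(b2_model)) background_sfs(smp) else b2_model
    scans <- lapply(smp, b2_scan, model = mod)
    out$scans$b2 <- scans
    out$b2_model <- mod
    out$curves$b2 <- normalized_fpr_curve(scans, L,
                                          n_thresholds = n_thresholds)
  }
  if ("ihs" %in% methods) {
    if (is.null(ihs_params)) {
      raw <- lapply(smp, ihs_scan, standardize = FALSE)
      ihs_params <- ihs_bin_params(unlist(lapply(raw, `[[`, "uihs")),
                                   unlist(lapply(raw, `[[`, "p_derived")))
    }
    scans <- ihs_scan_set(smp, params = ihs_params)
    out$scans$ihs <- scans
    out$ihs_params <- ihs_params
    out$curves$ihs <- normalized_fpr_curve(scans, L,
                                           n_thresholds = n_thresholds)
  }
  out
}

#' Standard scenario presets
#'
#' Builds the named scenario grid: neutral or functional background,
#' optional DFE archetype, instantaneous size changes (timed at the
#' introduction of the balanced allele or 74N generations after it, i.e.
#' 1N before the 75N sampling point), fixed or variable per-kb rates, and
#' the equilibrium-frequency sweep. All parameters can be overridden
#' afterwards; `Q` rescales for desk-scale runs.
#'
#' @param background "neutral" (50 kb) or "functional" (85,005 bp with
#'   exon/intron/intergenic structure).
#' @param dfe_name optional "DFE1".."DFE6" (functional background).
#' @param demography "equilibrium", "expansion2x", "contraction0.5x" or
#'   "contraction0.01x".
#' @param timing "at_introduction" or "1N_before_sampling".
#' @param mu_mode,r_mode "fixed" or "variable".
#' @param f_eq equilibrium frequency (NULL for sweeps/neutral runs).
#' @param sweep_s fixed beneficial coefficient (partial-sweep mode).
#' @param Q rescaling factor.
#' @param n_replicates,seed,sampling_times passed to [scenario_config()].
#' @return a `scenario_config`.
#' @export
preset_scenario <- function(background = c("neutral", "functional"),
                            dfe_name = NULL,
                            demography = c("equilibrium", "expansion2x",
                                           "contraction0.5x",
                                           "contraction0.01x"),
                            timing = c("at_introduction",
                                       "1N_before_sampling"),
                            mu_mode = c("fixed", "variable"),
                            r_mode = c("fixed", "variable"),
                            f_eq = 0.5, sweep_s = NULL, Q = 1L,
                            n_replicates = 200L, seed = 1L,
                            sampling_times = c(0.01, 0.1, 1, 10, 25, 50,
                                               75, 100)) {
  background <- match.arg(background)
  demography <- match.arg(demography)
  timing <- match.arg(timing)
  mu_mode <- match.arg(mu_mode)
  r_mode <- match.arg(r_mode)
  N <- 10000
  layout <- if (background == "functional") build_functional_layout()
            else build_neutral_layout(50000L)
  dfe <- if (!is.null(dfe_name)) dfe_preset(dfe_name, N_ancestral = N)
  set.seed(seed)
  mu_map <- if (mu_mode == "fixed")
    draw_rate_map("mutation", layout, "fixed", fixed_rate = 2.5e-8)
  else draw_rate_map("mutation", layout, "variable", lo = 1.3e-8, hi = 3.4e-8)
  r_map <- if (r_mode == "fixed")
    draw_rate_map("recombination", layout, "fixed", fixed_rate = 1e-8)
  else draw_rate_map("recombination", layout, "variable",
                     lo = cm_per_mb(0.124), hi = cm_per_mb(4.930))
  ev <- if (demography != "equilibrium") {
    newN <- switch(demography, expansion2x = 2 * N,
                   contraction0.5x = round(0.5 * N),
                   contraction0.01x = round(0.01 * N))
    t0 <- if (timing == "at_introduction") 0 else 74 * N
    list(list(time = t0, kind = "size_change", deme = 1, N = newN))
  } else list()
  cfg <- scenario_config(layout, demography_plan(N, ev),
                         mutation_map = mu_map, recombination_map = r_map,
                         dfe = dfe, f_eq = f_eq, sweep_s = sweep_s,
                         n_replicates = n_replicates, seed = seed,
                         sampling_times = sampling_times)
  rescale_scenario(cfg, Q)
}
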