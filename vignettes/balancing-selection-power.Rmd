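---
title: "Temporal power to detect balancing selection: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal power to detect balancing selection: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

A balanced polymorphism — an allele held at intermediate frequency by
selection — leaves different genomic footprints at different ages. While
the allele is sweeping up from a single copy it looks exactly like a
partial selective sweep: long shared haplotypes and elevated linkage
disequilibrium (LD). Once it has sat near its equilibrium frequency for
many coalescent times, it accumulates an excess of intermediate-frequency
variants around it, visible in the site frequency spectrum (SFS). `balsel`
quantifies, by forward simulation, how much power an LD-based scan (the
integrated haplotype score, iHS) and an SFS-based composite likelihood
ratio scan (a B2-style CLR) have at each age, and how badly neutral
confounders (population structure, admixture) and selective confounders
(partial sweeps) mimic the signal.

# The simulation model

The generator is a discrete-generation diploid Wright–Fisher engine:

* **Chromosomes.** Either a 50-kb strictly neutral region, or an 85,005-bp
  human-like region of three functional blocks (9 exons of 1,317 bp
  alternating with 8 introns of 1,520 bp, i.e. 24,013 bp per block)
  separated by 4,322-bp intergenic segments. Every third exonic site is
  treated as synonymous (neutral). The balanced site sits at the centre of
  the region: position 25,000 (neutral) or 40,342 (centre of the middle
  functional block).
* **Rates.** Mutation mu = 2.5e-8 and recombination r = 1e-8 per bp per
  generation, either uniform or varying per 1-kb block with
  block rates drawn from Uniform(1.3e-8, 3.4e-8) for mutation and
  Uniform(0.124, 4.930) cM/Mb for recombination. (The printed
  recombination bounds average ~2.5 cM/Mb rather than the 1 cM/Mb fixed
  rate; we reproduce the bounds as stated and note the inconsistency.)
* **Fitness.** Multiplicative across loci. Exonic (non-synonymous)
  mutations draw a selection coefficient from a discrete DFE with four
  bins on the 2Ns scale — [0,1), [1,10), [10,100), [100, 2N] — uniform
  within a bin, semi-dominant (h = 0.5); `s` is the homozygote's fitness
  reduction, so the strong bin is capped at s = 1. Six labelled archetypes
  (excess-weak, excess-moderate, excess-strong, uniform, two bimodal
  shapes) stand in for DFE shapes whose exact proportions are
  user-configurable.
* **Balancing selection.** Negative frequency dependence:
  `S = f_eq - F`, recomputed once per generation from the parental
  frequency, applied semi-dominantly (heterozygote `1 + 0.5 S`,
  homozygote `1 + S`). With f_eq = 0.5 the allele is introduced as a
  single copy after a 10N-generation burn-in of an N = 10,000 ancestral
  population, and replicates in which it is lost before reaching
  frequency 0.1 are restarted from the saved post-burn-in state (the
  conditioning-on-establishment rule).
* **Sampling.** 100 chromosomes at tau_b in {0.01, 0.1, 1, 10, 25, 50,
  75, 100} x N generations after introduction, 200 replicates per
  scenario at full scale.
* **Demography and structure.** Instantaneous size changes (2x expansion,
  0.5x and 0.01x contractions) timed either at the introduction or 74N
  generations after it; two-deme splits with symmetric backward migration
  (offspring pick a parental deme by the migration row), used for the
  gene-flow (Nm in {0, 0.01, 0.05, 0.1, 0.2}), admixture (Nm = 0.25 for
  5N generations, then isolation for 5N) and hidden-structure (isolation
  for 5N, then 50 + 50 sampling) experiments. Published multi-epoch human
  histories are supported as user-supplied piecewise configurations; no
  parameter values are hard-coded.

The engine uses an infinite-sites rule on discrete positions (a mutation
landing on an occupied position is redrawn), records fixations as
substitutions with timestamps (the CLR scan uses them as the k = n
frequency class), and floors fitness at zero.

# The two scans

**iHS.** At each SNP with at least two carriers of each allele, the
extended haplotype homozygosity (EHH) — the probability that two random
carriers of the core allele are identical from the core out to a target
SNP — is computed outward until it falls below 0.05 or the region edge is
reached (edge-truncated curves are kept, and no frequency filter is
applied, matching the truncation-tolerant, keep-low-frequency options of
the reference tool). The score is `ln(iHH_A / iHH_D)` of the two
trapezoidal integrals, standardized within derived-frequency bins of
width 0.02 (bins under 20 scores merged with their nearest neighbour);
the detection score is the absolute standardized value.

**B2-style CLR.** The reference publication does not print the B2
likelihood, so the scan here is a faithful reconstruction of its verbal
description, labelled B2-style rather than a bit-exact clone: at a test
position, each informative site (polymorphism with derived count k, or
substitution with k = n) contributes
`ln[(a h_beta(k) + (1 - a) g(k)) / g(k)]`, where `g` is the pooled
background spectrum (pseudocount 1 per class), `h_beta` a binomial
spectrum centred on a candidate equilibrium frequency beta, and
`a = exp(-d / A)` decays with physical distance d over a footprint A. The
CLR is twice the maximum over beta in {0.05, ..., 0.95} and A log-spaced
over 10^2..10^6 bp plus a degenerate no-signal point, hence CLR >= 0.
Absolute CLR magnitudes are not comparable to the reference tool — only
rankings and ROC behaviour are, and those are what every analysis here
uses.

# The ROC protocol

The region is tiled by non-overlapping 100-bp windows scored by their
maximum per-SNP score. A window is eligible as the true positive only via
SNPs within 50 bp of the balanced site; the true-positive rate at a
threshold is the fraction of replicates whose true-window score reaches
it (replicates without a qualifying SNP count in the denominator — the
conservative reading).

The negative side is the one genuinely open design point. Two
constructions are provided:

* `fpr_mode = "matched_neutral"` (default): the false-positive rate pools
  all windows of matched neutral replicates — the same baseline model
  without the balanced mutation — and iHS standardization parameters are
  estimated on that neutral pool. This emulates the practice the study
  follows (its human-demography runs are explicitly re-run "in the
  absence of balancing selection to obtain false-positive rates"), and it
  is the only construction under which a young balanced allele is
  detectable at all: shortly after establishment the *entire* simulated
  region is swept, so windows of the same replicate are elevated together
  with the true window and carry no contrast.
* `fpr_mode = "within_replicate"`: negatives are the non-true windows of
  the selection scans themselves. Useful for the old-allele regime, where
  the CLR signal is localized.

For null-only scenarios (structure, admixture) there is no true window;
window scores are reported as FPR at 100 evenly spaced normalized
thresholds. Two conventions matter here and both are implemented:

* *Cross-scenario comparison needs a common scale.* Normalizing each
  scenario by its own minimum and maximum compresses precisely the
  scenarios with the heaviest score tails, so per-scenario curves cannot
  rank scenarios; `normalized_fpr_curves()` therefore pools all
  scenarios of a method and scales thresholds from 0 to the global
  maximum before computing each scenario's curve. The single-scenario
  `normalized_fpr_curve()` remains for self-contained null calibration.
* *Confounding requires a mis-specified null.* A scan calibrated on the
  structured data themselves — background spectrum and standardization
  bins estimated from the same scenario — absorbs a genome-wide
  structure signal into its own null and reports little excess, because
  unacknowledged structure shifts the whole genome, not one locus. The
  structure experiments therefore score every scenario against the
  *panmictic* reference calibration (the analyst's null model assumes
  panmixia), which is the situation the false-positive question is
  about. Self-calibration is available by simply not passing a
  reference.

# Rescaling and its limits

Full-scale runs (N = 10,000) need no rescaling but are not desk-scale. A
factor Q shrinks N to N/Q while multiplying mu, r and fixed s by Q and
dividing times in generations by Q, preserving 4N·mu, 4N·r, 2Ns and times
in units of N. Two deliberate choices:

* The frequency-dependent coefficient `S = f_eq - F` is **not**
  multiplied by Q: it is already O(0.5), and scaling it would change the
  model rather than rescale it.
* The initial sweep of the balanced allele lasts roughly
  `ln(2N) / (h f_eq)` **generations** — a quantity that does not shrink
  with Q. Two consequences follow. First, checkpoints scheduled before
  the allele first reaches f_eq (e.g. tau_b = 0.01N = 5 generations at
  Q = 20) are deferred to that first-attainment generation, so
  "young allele" samples mean what they mean at full scale: an allele
  that has just completed its initial sweep. Second, haplotype erosion
  during the sweep scales with Q·r·t_sweep, so LD-based power at small
  tau_b degrades as Q grows. The analyses therefore use the smallest
  feasible Q per question: long-horizon CLR power (diffusion-timescale
  dynamics, insensitive to Q once 4N-scaled parameters are fixed; the
  test suite checks diversity is invariant across Q) runs at Q = 100
  (N = 100), while young-allele iHS and partial-sweep comparisons run at
  Q = 20 (N = 500). Even at Q = 20 the sweep experiences several-fold
  more recombination than at full scale, so desk-scale iHS power at
  tau_b = 0.01N is expected to undershoot the near-perfect full-scale
  value; the temporal *ordering* (high power at 0.01N, none at 1N) is the
  robust, and asserted, property.

Establishment probabilities are *not* invariant under rescaling (the
single-copy starting frequency 1/(2N) changes, and a rescaled beneficial
coefficient saturates the survival probability), so establishment
experiments run at the sizes stated in their results, using the exact
marginal Wright–Fisher binomial chain on neutral backgrounds (equivalent
to the full engine when nothing else is selected, and fast enough for
10^5 replicates) and the full engine when a DFE provides linked
interference. The interference itself is also scale-sensitive: a
rescaled strongly deleterious allele (s near 1) is purged within a
couple of generations and cannot interfere with anything, so the
suppression channel that survives desk scaling is standing *weakly*
deleterious variation. The shipped suppression experiment therefore uses
the excess-weak DFE archetype at a moderate Q; the full-scale ranking of
archetypes (strongest suppression under a strong-deleterious excess) is
not asserted at desk scale.

# Problem sizes used by the shipped analyses

The test suite and the acceptance script run the whole pipeline at
reduced scale, chosen once as a compromise between Monte-Carlo error and
desk-scale runtimes: the CLR temporal sweep at Q = 100 with about 22
selection replicates (each with a burn-in-sharing matched neutral
control) over tau_b in {1, 25, 50, 75}N; iHS young-allele runs at Q = 20
with about 16 replicate pairs and 12 partial-sweep replicates;
structure and admixture false-positive runs at Q = 100 with 30
replicates per model; establishment checks with 10^4-10^5 replicates of
the marginal chain and a few hundred full-engine introductions amortized
over shared burn-ins. At these sizes a TPR carries a binomial standard
error of roughly 0.08-0.12, which is the resolution at which the shipped
numbers should be read.

# Numerical and degenerate-input conventions

* Coordinates are 1-based inclusive; printed positions are taken
  verbatim (25,000 and 40,342); windows tile from position 1.
* Undefined statistics (Tajima's D with S = 0, D' with fewer than two
  polymorphic sites, iHS with a zero integral or fewer than two carriers
  of either allele) propagate as missing values, never as zeros; sites
  failing scan preconditions are dropped.
* pi and Watterson's theta are reported per site; D' is averaged as
  |D'| over all biallelic pairs with no frequency filter.
* The balanced component of the CLR keeps the k = n class (the
  substitution-like limit of beta near 1) and drops k = 0.
* Ties in the ROC are handled by the >= threshold rule on both axes;
  TPR at an FPR level uses conservative step interpolation (the largest
  threshold whose FPR does not exceed the level).
* All randomness flows through R's RNG (a single master seed derives
  per-replicate seeds), so every run is reproducible from its manifest.

# What the generator does and does not emulate

Passing tests show that the pipeline reproduces the qualitative physics
of the model: drift at the right rate, diversity at 4N·mu, a balanced
allele that hovers at f_eq, CLR power that grows with allele age, iHS
power confined to young alleles, establishment probabilities matching
branching/diffusion theory, and structure-driven false positives. Real
data differ in ways the generator does not attempt: no gene conversion,
no overlapping generations, no hotspot-scale recombination structure
(only 1-kb uniform blocks), no sequencing error or missing data, no
ascertainment bias, and an infinite-sites mutation model. Conclusions
about absolute power in real genomes should therefore lean on the
orderings and contrasts, not the third decimal of any TPR.

# Known limitations

* Desk-scale (rescaled) runs systematically understate LD-based power on
  young alleles, as explained above; full-scale runs (Q = 1) are
  supported but take cluster-scale time.
* The B2-style CLR is a reconstruction; its absolute values differ from
  the reference implementation by design.
* Establishment probabilities reported by the reference publication's
  table are an order of magnitude above every single-copy analytic
  expectation and could not be reproduced from the stated protocol under
  any interpretation we tried; the package asserts only the qualitative
  effects (suppression by linked deleterious variation, strongest under
  a strong-deleterious-excess DFE) and exposes the introduction copy
  number as a configuration knob.
* Two-deme models interpret printed migration intensities as N·m per
  generation (the Methods convention); the figure-caption 4Nm convention
  differs by a factor of 4, and the per-generation m is what configs
  take.
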