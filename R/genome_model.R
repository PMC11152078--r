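#' Build the human-like functional chromosome layout
#'
#' Tiles a chromosome as alternating functional regions and intergenic blocks
#' (functional region first: F-I-F-I-F-I). Each functional region alternates
#' exons and introns, starting and ending with an exon. The balanced site is
#' placed at the centre of the middle functional region. With the defaults
#' (3 regions of 9 x 1,317-bp exons and 8 x 1,520-bp introns, separated by
#' 4,322-bp intergenic blocks) the chromosome is 85,005 bp long, each
#' functional region spans 24,013 bp, and the balanced site sits at 40,342.
#'
#' @param n_regions number of functional regions.
#' @param exons_per_region exons per functional region.
#' @param exon_len exon length in bp.
#' @param introns_per_region introns per functional region (one fewer than
#'   exons in the default human-like architecture).
#' @param intron_len intron length in bp.
#' @param intergenic_len intergenic block length in bp.
#' @return A `chromosome_layout` object: list with `total_length`, `elements`
#'   (data.frame of kind/start/end, 1-based inclusive), `balanced_site_position`
#'   and `synonymous_rule` (every third exonic site neutral).
#' @export
build_functional_layout <- function(n_regions = 3L, exons_per_region = 9L,
                                    exon_len = 1317L, introns_per_region = 8L,
                                    intron_len = 1520L, intergenic_len = 4322L) {
  vals <- c(n_regions, exons_per_region, exon_len, introns_per_region,
            intron_len, intergenic_len)
  if (any(!is.finite(vals)) || any(vals < 1))
    stop("all counts and lengths must be >= 1")

  kinds <- character(0); lens <- integer(0)
  region_starts <- integer(n_regions)
  pos <- 1L
  for (r in seq_len(n_regions)) {
    region_starts[r] <- pos
    for (e in seq_len(exons_per_region)) {
      kinds <- c(kinds, "exon"); lens <- c(lens, as.integer(exon_len))
      pos <- pos + as.integer(exon_len)
      if (e <= introns_per_region) {
        kinds <- c(kinds, "intron"); lens <- c(lens, as.integer(intron_len))
        pos <- pos + as.integer(intron_len)
      }
    }
    kinds <- c(kinds, "intergenic"); lens <- c(lens, as.integer(intergenic_len))
    pos <- pos + as.integer(intergenic_len)
  }
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  total <- ends[length(ends)]

  region_len <- exons_per_region * exon_len + introns_per_region * intron_len
  mid <- as.integer(ceiling(n_regions / 2))
  mid_start <- region_starts[mid]
  balanced <- as.integer(floor((mid_start + (mid_start + region_len - 1L)) / 2))

  new_layout(total, data.frame(kind = kinds, start = starts, end = ends,
                               stringsAsFactors = FALSE),
             balanced, synonymous_rule = TRUE)
}

#' Build a strictly neutral single-region layout
#'
#' @param length region length in bp (>= 2).
#' @return A `chromosome_layout` with one neutral element spanning
#'   `[1, length]` and the balanced site at `floor(length / 2)`.
#' @export
build_neutral_layout <- function(length = 50000L) {
  if (!is.finite(length) || length < 2) stop("length must be >= 2")
  length <- as.integer(length)
  new_layout(length,
             data.frame(kind = "neutral", start = 1L, end = length,
                        stringsAsFactors = FALSE),
             as.integer(floor(length / 2)), synonymous_rule = FALSE)
}

new_layout <- function(total, elements, balanced, synonymous_rule) {
  stopifnot(all(elements$start <= elements$end),
            elements$start[1] == 1L,
            elements$end[nrow(elements)] == total,
            balanced >= 1L, balanced <= total)
  if (nrow(elements) > 1)
    stopifnot(all(elements$start[-1] == elements$end[-nrow(elements)] + 1L))
  structure(list(total_length = total, elements = elements,
                 balanced_site_position = balanced,
                 synonymous_rule = synonymous_rule),
            class = "chromosome_layout")
}

#' @export
print.chromosome_layout <- function(x, ...) {
  cat("chromosome_layout:", x$total_length, "bp,",
      nrow(x$elements), "elements; balanced site at",
      x$balanced_site_position, "\n")
  invisible(x)
}

#' Per-site selection classes for a layout
#'
#' Integer vector over positions 1..total_length: 0 for neutral sites
#' (intergenic, intronic, neutral regions, and synonymous exonic sites),
#' 1 for exonic sites subject to the DFE. Under the synonymous rule every
#' third site within each exon (offset divisible by 3, counting from the
#' exon start) is neutral.
#'
#' @param layout a `chromosome_layout`.
#' @return integer vector of length `layout$total_length`.
#' @export
site_classes <- function(layout) {
  cls <- integer(layout$total_length)
  ex <- layout$elements[layout$elements$kind == "exon", , drop = FALSE]
  if (nrow(ex)) {
    for (i in seq_len(nrow(ex))) {
      idx <- ex$start[i]:ex$end[i]
      sel <- rep(1L, length(idx))
      if (isTRUE(layout$synonymous_rule)) {
        off <- seq_along(idx)
        sel[off %% 3L == 0L] <- 0L
      }
      cls[idx] <- sel
    }
  }
  cls
}

#' Discrete distribution of fitness effects
#'
#' Four fixed bins on the population-scaled scale 2\eqn{N s}:
#' effectively neutral `[0, 1)`, weakly deleterious `[1, 10)`, moderately
#' deleterious `[10, 100)` and strongly deleterious `[100, upper_cap]`.
#' Within a bin the scaled coefficient is uniform. `s` is the fitness
#' reduction of the mutant homozygote; the strong bin is capped at
#' `2 N_ancestral` so that `s <= 1` (lethal homozygote).
#'
#' @param class_probs length-4 non-negative vector summing to 1
#'   (f0, f1, f2, f3).
#' @param N_ancestral diploid reference population size converting 2Ns to s.
#' @param h dominance coefficient (0.5 = semi-dominant).
#' @param upper_cap upper edge of the strong bin on the 2Ns scale; defaults
#'   to `2 * N_ancestral`.
#' @return a `discrete_dfe` object.
#' @export
discrete_dfe <- function(class_probs, N_ancestral = 10000, h = 0.5,
                         upper_cap = 2 * N_ancestral) {
  class_probs <- as.numeric(class_probs)
  if (length(class_probs) != 4 || any(class_probs < 0) ||
      abs(sum(class_probs) - 1) > 1e-8)
    stop("class_probs must be 4 non-negative proportions summing to 1")
  edges <- c(0, 1, 10, 100, upper_cap)
  if (any(diff(edges) <= 0)) stop("bin edges must be strictly increasing")
  structure(list(class_probs = class_probs,
                 class_bounds_2Ns = edges,
                 h = h, N_ancestral = N_ancestral),
            class = "discrete_dfe")
}

#' Named DFE archetypes
#'
#' Six labelled archetypes spanning the shapes commonly inferred for new
#' mutations: DFE1 excess of weakly deleterious, DFE2 excess of moderately
#' deleterious, DFE3 excess of strongly deleterious, DFE4 equal proportions,
#' DFE5 and DFE6 bimodal (weak + strong modes). Proportions are
#' user-overridable via [discrete_dfe()].
#'
#' @param name one of "DFE1".."DFE6".
#' @param N_ancestral diploid reference size.
#' @return a `discrete_dfe`.
#' @export
dfe_preset <- function(name, N_ancestral = 10000) {
  probs <- switch(name,
    DFE1 = c(0.20, 0.60, 0.10, 0.10),
    DFE2 = c(0.20, 0.10, 0.60, 0.10),
    DFE3 = c(0.20, 0.10, 0.10, 0.60),
    DFE4 = c(0.25, 0.25, 0.25, 0.25),
    DFE5 = c(0.40, 0.10, 0.10, 0.40),
    DFE6 = c(0.45, 0.05, 0.05, 0.45),
    stop("unknown DFE preset: ", name))
  discrete_dfe(probs, N_ancestral = N_ancestral)
}

#' Draw one selection coefficient from a discrete DFE
#'
#' A bin is chosen with the DFE's class probabilities and 2Ns is drawn
#' uniformly within the bin; the returned `s` (fitness reduction of the
#' mutant homozygote) is `2Ns / (2 N_ancestral)`, always in `[0, 1]`.
#'
#' @param dfe a `discrete_dfe`.
#' @param n number of draws.
#' @return numeric vector of deleterious selection coefficients.
#' @export
sample_selection_coefficient <- function(dfe, n = 1L) {
  stopifnot(inherits(dfe, "discrete_dfe"))
  cls <- sample.int(4L, n, replace = TRUE, prob = dfe$class_probs)
  lo <- dfe$class_bounds_2Ns[cls]
  hi <- dfe$class_bounds_2Ns[cls + 1L]
  scaled <- stats::runif(n, lo, hi)
  pmin(scaled / (2 * dfe$N_ancestral), 1)
}

#' Per-kilobase mutation or recombination rate map
#'
#' Fixed mode gives every 1-kb block the same rate; variable mode draws each
#' block's per-bp rate from Uniform(lo, hi). A final partial block inherits
#' the last full block's rate.
#'
#' @param kind "mutation" or "recombination".
#' @param layout a `chromosome_layout`.
#' @param mode "fixed" or "variable".
#' @param fixed_rate per-bp per-generation rate (fixed mode).
#' @param lo,hi uniform bounds for variable mode (per-bp per-generation).
#' @param block_size block width in bp (1 kb as in the rate-heterogeneity
#'   scenarios).
#' @return a `rate_map`: list with `kind`, `block_edges` (starts, 1-based),
#'   `block_rates`.
#' @export
draw_rate_map <- function(kind = c("mutation", "recombination"), layout,
                          mode = c("fixed", "variable"), fixed_rate = NULL,
                          lo = NULL, hi = NULL, block_size = 1000L) {
  kind <- match.arg(kind); mode <- match.arg(mode)
  L <- layout$total_length
  starts <- seq(1L, L, by = as.integer(block_size))
  ends <- pmin(starts + as.integer(block_size) - 1L, L)
  nb <- length(starts)
  if (mode == "fixed") {
    if (is.null(fixed_rate) || fixed_rate < 0) stop("need fixed_rate >= 0")
    rates <- rep(fixed_rate, nb)
  } else {
    if (is.null(lo) || is.null(hi)) stop("need lo and hi for variable mode")
    if (hi < lo) stop("hi must be >= lo")
    if (lo < 0) stop("rates must be >= 0")
    n_full <- sum(ends - starts + 1L == as.integer(block_size))
    drawn <- stats::runif(max(n_full, 1L), lo, hi)
    rates <- c(drawn, rep(drawn[length(drawn)], nb - length(drawn)))[seq_len(nb)]
  }
  structure(list(kind = kind, block_edges = starts, block_ends = ends,
                 block_rates = rates, total_length = L),
            class = "rate_map")
}

#' Convert cM/Mb to per-bp per-generation recombination rate
#' @param x rate in centimorgans per megabase.
#' @return rate in Morgans per bp per generation.
#' @export
cm_per_mb <- function(x) x * 1e-8

#' Mean rate of a map, weighted by block length
#' @param map a `rate_map`.
#' @return per-bp rate averaged over the chromosome.
#' @export
rate_map_mean <- function(map) {
  w <- map$block_ends - map$block_edges + 1
  sum(map$block_rates * w) / sum(w)
}

#' Write / read a layout or rate map as TSV
#'
#' Layouts serialize as (kind, start, end, rate=NA); rate maps as
#' (kind, start, end, rate).
#' @param x a `chromosome_layout` or `rate_map`.
#' @param path output file.
#' @export
write_layout_tsv <- function(x, path) {
  if (inherits(x, "chromosome_layout")) {
    df <- data.frame(kind = x$elements$kind, start = x$elements$start,
                     end = x$elements$end, rate = NA_real_)
  } else if (inherits(x, "rate_map")) {
    df <- data.frame(kind = x$kind, start = x$block_edges,
                     end = x$block_ends, rate = x$block_rates)
  } else stop("unsupported object")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_layout_tsv
#' @export
read_rate_map_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  structure(list(kind = df$kind[1], block_edges = df$start,
                 block_ends = df$end, block_rates = df$rate,
                 total_length = df$end[nrow(df)]),
            class = "rate_map")
}
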