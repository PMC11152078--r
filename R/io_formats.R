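#' Write haplotype samples in ms dialect
#'
#' Standard ms output: a `//` line per replicate, `segsites:`, a
#' `positions:` line of fractions of the region length (12 decimals), then
#' one 0/1 row per haplotype. Zero-SNP samples emit `segsites: 0` with no
#' positions line.
#'
#' @param samples a `haplotype_sample` or list of them.
#' @param region_length region length in bp.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ms <- function(samples, region_length, path) {
  if (inherits(samples, "haplotype_sample")) samples <- list(samples)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("balsel ms output", ""), con)
  for (s in samples) {
    writeLines("//", con)
    S <- length(s$positions)
    writeLines(paste("segsites:", S), con)
    if (S > 0) {
      fr <- sprintf("%.12f", s$positions / region_length)
      writeLines(paste("positions:", paste(fr, collapse = " ")), con)
      rows <- apply(s$matrix, 1, paste, collapse = "")
      writeLines(rows, con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Read ms-dialect haplotype blocks
#'
#' @param path ms file.
#' @param region_length region length in bp used to de-normalize positions.
#' @return list of `haplotype_sample`-like lists (matrix, positions, n).
#' @export
read_ms <- function(path, region_length) {
  lines <- readLines(path)
  starts <- which(lines == "//")
  lapply(starts, function(i) {
    S <- as.integer(sub("segsites: *", "", lines[i + 1]))
    if (S == 0) {
      return(structure(list(matrix = matrix(0L, 0, 0), positions = numeric(0),
                            k = integer(0), n = 0L,
                            region_length = region_length),
                       class = "haplotype_sample"))
    }
    pos <- as.numeric(strsplit(sub("positions: *", "", lines[i + 2]),
                               " ")[[1]]) * region_length
    j <- i + 3
    rows <- character(0)
    while (j <= length(lines) && grepl("^[01]+$", lines[j])) {
      rows <- c(rows, lines[j])
      j <- j + 1
    }
    mat <- do.call(rbind, lapply(strsplit(rows, ""), as.integer))
    structure(list(matrix = mat, positions = pos, k = colSums(mat),
                   n = nrow(mat), region_length = region_length),
              class = "haplotype_sample")
  })
}

#' Write selscan-style .hap and .map files
#'
#' `.hap`: one haplotype per row, space-separated 0/1. `.map`: one row per
#' SNP with chromosome, locus id, genetic position (cumulative Morgans from
#' the recombination map; `bp * r` for a fixed-rate map) and physical
#' position, ordered by position.
#'
#' @param sample a `haplotype_sample`.
#' @param chrom chromosome label.
#' @param path_stem output stem; writes `<stem>.hap` and `<stem>.map`.
#' @param recombination_map optional `rate_map` for genetic positions;
#'   defaults to a fixed 1e-8 per bp.
#' @return character vector of the two paths, invisibly.
#' @export
write_hap_map <- function(sample, chrom = "1", path_stem,
                          recombination_map = NULL) {
  hap_path <- paste0(path_stem, ".hap")
  map_path <- paste0(path_stem, ".map")
  rows <- apply(sample$matrix, 1, paste, collapse = " ")
  writeLines(rows, hap_path)
  gpos <- genetic_position(sample$positions, recombination_map)
  df <- data.frame(chrom = chrom,
                   id = paste0("snp", seq_along(sample$positions)),
                   gpos = formatC(gpos, format = "g", digits = 12),
                   ppos = as.integer(sample$positions))
  utils::write.table(df, map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(hap_path, map_path))
}

#' Read selscan-style .hap and .map files
#' @param path_stem stem such that `<stem>.hap` and `<stem>.map` exist.
#' @return a `haplotype_sample`-like list (matrix, positions, k, n).
#' @export
read_hap_map <- function(path_stem) {
  rows <- strsplit(readLines(paste0(path_stem, ".hap")), " ")
  mat <- do.call(rbind, lapply(rows, as.integer))
  map <- utils::read.table(paste0(path_stem, ".map"))
  structure(list(matrix = mat, positions = as.numeric(map$V4),
                 k = colSums(mat), n = nrow(mat),
                 region_length = max(map$V4)),
            class = "haplotype_sample")
}

genetic_position <- function(pos, recombination_map = NULL) {
  if (is.null(recombination_map)) return(pos * 1e-8)
  m <- recombination_map
  w <- m$block_ends - m$block_edges + 1
  cum <- c(0, cumsum(m$block_rates * w))
  b <- findInterval(pos, m$block_edges)
  cum[b] + (pos - m$block_edges[b]) * m$block_rates[b]
}

#' Write the allele-frequency table used by the CLR scan
#'
#' TSV with columns position, derived count `k`, sample size `n`,
#' substitution flag; substitutions are rows with `k = n`, flag 1. Rows are
#' sorted by position with no duplicates.
#'
#' @param sample a `haplotype_sample`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_freq_table <- function(sample, path) {
  n <- sample$n
  df <- data.frame(position = sample$positions, k = sample$k, n = n, sub = 0L)
  if (nrow(sample$substitutions)) {
    df <- rbind(df, data.frame(position = sample$substitutions$position,
                               k = n, n = n, sub = 1L))
  }
  df <- df[order(df$position), , drop = FALSE]
  df <- df[!duplicated(df$position), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_freq_table
#' @export
read_freq_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE)
}

#' Serialize a scenario config to YAML
#' @param config a `scenario_config`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_scenario_yaml <- function(config, path) {
  x <- list(
    layout = list(total_length = config$layout$total_length,
                  balanced_site_position = config$layout$balanced_site_position,
                  synonymous_rule = config$layout$synonymous_rule,
                  elements = lapply(seq_len(nrow(config$layout$elements)),
                                    function(i) as.list(config$layout$elements[i, ]))),
    dfe = if (is.null(config$dfe)) NULL else
      list(class_probs = config$dfe$class_probs,
           N_ancestral = config$dfe$N_ancestral, h = config$dfe$h),
    mutation_map = list(rates = config$mutation_map$block_rates,
                        starts = config$mutation_map$block_edges),
    recombination_map = list(rates = config$recombination_map$block_rates,
                             starts = config$recombination_map$block_edges),
    demography = list(N_ancestral = config$demography$N_ancestral,
                      events = config$demography$events),
    f_eq = config$f_eq, balanced_h = config$balanced_h,
    intro_copies = config$intro_copies,
    establishment_threshold = config$establishment_threshold,
    sampling_times = config$sampling_times,
    sample_size = config$sample_size, n_replicates = config$n_replicates,
    seed = config$seed, rescale_Q = config$rescale_Q,
    sweep_s = config$sweep_s, burn_in_N = config$burn_in_N)
  yaml::write_yaml(x, path)
  invisible(path)
}
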