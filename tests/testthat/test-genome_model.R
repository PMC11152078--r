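test_that("functional layout reproduces the human-like architecture", {
  l <- build_functional_layout()
  expect_equal(l$total_length, 85005L)
  expect_equal(l$balanced_site_position, 40342L)
  # per-region span and the F-I alternation
  expect_equal(9 * 1317 + 8 * 1520, 24013)
  expect_equal(3 * 24013 + 3 * 4322, 85005)
  el <- l$elements
  expect_equal(sum(el$end - el$start + 1), l$total_length)
  expect_true(all(el$start[-1] == el$end[-nrow(el)] + 1))
  expect_equal(el$kind[1], "exon")
  expect_equal(sum(el$kind == "exon"), 27)
  expect_equal(sum(el$kind == "intron"), 24)
  expect_equal(sum(el$kind == "intergenic"), 3)
  expect_error(build_functional_layout(exon_len = 0), "must be >= 1")
})

test_that("neutral layout centres the balanced site", {
  l <- build_neutral_layout(50000)
  expect_equal(l$balanced_site_position, 25000L)
  expect_equal(l$elements$kind, "neutral")
  expect_equal(c(l$elements$start, l$elements$end), c(1L, 50000L))
  expect_equal(build_neutral_layout(2)$balanced_site_position, 1L)
  expect_error(build_neutral_layout(1), ">= 2")
})

test_that("site classes follow the synonymous rule", {
  l <- build_functional_layout()
  cls <- site_classes(l)
  expect_length(cls, l$total_length)
  ex1 <- l$elements[l$elements$kind == "exon", ][1, ]
  off <- seq_len(ex1$end - ex1$start + 1)
  expect_true(all(cls[ex1$start:ex1$end][off %% 3 == 0] == 0L))
  expect_true(all(cls[ex1$start:ex1$end][off %% 3 != 0] == 1L))
  ig <- l$elements[l$elements$kind == "intergenic", ][1, ]
  expect_true(all(cls[ig$start:ig$end] == 0L))
  # a third of exonic sites are synonymous
  expect_equal(sum(cls == 1), 27 * 1317 * 2 / 3)
})

test_that("rate maps: fixed, variable bounds, reproducibility, partial block", {
  l <- build_neutral_layout(50000)
  fx <- draw_rate_map("recombination", l, "fixed", fixed_rate = 1e-8)
  expect_true(all(fx$block_rates == 1e-8))
  expect_equal(fx$block_edges[1], 1L)
  expect_equal(fx$block_ends[length(fx$block_ends)], 50000L)

  set.seed(11)
  v1 <- draw_rate_map("recombination", l, "variable",
                      lo = cm_per_mb(0.124), hi = cm_per_mb(4.930))
  set.seed(11)
  v2 <- draw_rate_map("recombination", l, "variable",
                      lo = cm_per_mb(0.124), hi = cm_per_mb(4.930))
  expect_identical(v1$block_rates, v2$block_rates)
  expect_true(all(v1$block_rates >= 1.24e-9 & v1$block_rates <= 4.93e-8))

  # a partial final block inherits the last drawn rate
  lp <- build_neutral_layout(1500)
  set.seed(2)
  vp <- draw_rate_map("mutation", lp, "variable", lo = 1e-8, hi = 2e-8)
  expect_equal(length(vp$block_rates), 2L)
  expect_equal(vp$block_rates[2], vp$block_rates[1])
  expect_error(draw_rate_map("mutation", l, "variable", lo = 2, hi = 1),
               "hi must be >= lo")
})

test_that("variable mutation-rate draws average to the midpoint", {
  big <- build_neutral_layout(1e7)  # 10^4 blocks
  set.seed(3)
  v <- draw_rate_map("mutation", big, "variable", lo = 1.3e-8, hi = 3.4e-8)
  expect_equal(rate_map_mean(v), 2.35e-8, tolerance = 0.02)
})

test_that("DFE draws respect bins and class probabilities", {
  set.seed(4)
  d0 <- discrete_dfe(c(1, 0, 0, 0), N_ancestral = 10000)
  s0 <- sample_selection_coefficient(d0, 1000)
  expect_true(all(2 * 10000 * s0 >= 0 & 2 * 10000 * s0 < 1))

  d3 <- discrete_dfe(c(0, 0, 0, 1), N_ancestral = 10000)
  s3 <- sample_selection_coefficient(d3, 1000)
  expect_true(all(2 * 10000 * s3 >= 100 & s3 <= 1))

  d2 <- discrete_dfe(c(0, 0, 1, 0), N_ancestral = 10000)
  s2 <- sample_selection_coefficient(d2, 1e5)
  expect_equal(mean(2 * 10000 * s2), 55, tolerance = 0.01)

  # class frequencies within 3 Monte-Carlo SE
  probs <- c(0.2, 0.3, 0.4, 0.1)
  dm <- discrete_dfe(probs, N_ancestral = 10000)
  sm <- sample_selection_coefficient(dm, 1e5)
  scaled <- 2 * 10000 * sm
  cls <- findInterval(scaled, c(0, 1, 10, 100), rightmost.closed = FALSE)
  obs <- tabulate(cls, 4) / 1e5
  se <- sqrt(probs * (1 - probs) / 1e5)
  expect_true(all(abs(obs - probs) <= 3 * se))

  expect_error(discrete_dfe(c(0.5, 0.5, 0.5, 0.5)), "summing to 1")
})

test_that("layouts and rate maps round-trip through TSV", {
  l <- build_neutral_layout(5000)
  set.seed(9)
  v <- draw_rate_map("mutation", l, "variable", lo = 1e-8, hi = 3e-8)
  path <- tempfile(fileext = ".tsv")
  write_layout_tsv(v, path)
  v2 <- read_rate_map_tsv(path)
  expect_equal(v2$block_rates, v$block_rates)
  expect_equal(v2$block_edges, v$block_edges)
})
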