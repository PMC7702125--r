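test_that("fourfold-site classification follows the standard genetic code", {
  expect_equal(classify_fourfold_sites("GGA", "GGG"), 3L)   # Gly family
  expect_equal(length(classify_fourfold_sites("TTT", "TTC")), 0L)  # Phe, twofold
  expect_equal(length(classify_fourfold_sites("AGA", "CGA")), 0L)  # prefix differs
  expect_equal(length(classify_fourfold_sites("GG-", "GGA")), 0L)  # gap
  expect_equal(length(classify_fourfold_sites("GGN", "GGA")), 0L)  # ambiguity
  expect_error(classify_fourfold_sites("GGAA", "GGAA"), "divisible by 3")
  expect_error(classify_fourfold_sites("GGA", "GGAGGA"), "length")
})

test_that("the fourfold prefix set matches the genetic code exactly", {
  gc_table <- Biostrings::GENETIC_CODE
  all_prefixes <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0))
  is_4d <- vapply(all_prefixes, function(p) {
    length(unique(gc_table[paste0(p, c("A", "C", "G", "T"))])) == 1L
  }, logical(1))
  expect_setequal(fourfold_prefixes, all_prefixes[is_4d])
})

test_that("worked six-codon alignment yields 6 sites, 2 transversions, 3 transitions", {
  a <- "GGACTTCCAGTAACCGCG"
  b <- "GGTCTCCCGGTTACCGCA"
  sites <- classify_fourfold_sites(a, b)
  expect_equal(length(sites), 6L)
  subs <- count_substitutions_4d(a, b, sites)
  expect_equal(subs$n_transversion, 2L)
  expect_equal(subs$n_transition, 3L)
  expect_equal(raw_4dtv(subs$n_transversion, length(sites)), 1 / 3)
  oracle <- oracle_4d_counts(a, b)
  expect_equal(subs$n_transversion, oracle$n_transversion)
  expect_equal(subs$n_transition, oracle$n_transition)
})

test_that("substitution counting matches the brute-force per-column oracle", {
  set.seed(42)
  for (i in 1:30) {
    pr <- random_codon_pair(n_codons = 40L)
    sites <- classify_fourfold_sites(pr$seq_a, pr$seq_b)
    got <- count_substitutions_4d(pr$seq_a, pr$seq_b, sites)
    want <- oracle_4d_counts(pr$seq_a, pr$seq_b)
    expect_equal(length(sites), want$n_4d)
    expect_equal(got$n_transversion, want$n_transversion)
    expect_equal(got$n_transition, want$n_transition)
  }
})

test_that("raw 4DTv handles edge counts and undefined denominators", {
  expect_equal(raw_4dtv(0L, 10L), 0)
  expect_equal(raw_4dtv(10L, 10L), 1)
  expect_true(is.na(raw_4dtv(0L, 0L)))
  a <- strrep("GGA", 4)   # identical pair
  sites <- classify_fourfold_sites(a, a)
  subs <- count_substitutions_4d(a, a, sites)
  expect_equal(c(subs$n_transversion, subs$n_transition), c(0L, 0L))
})

test_that("HKY-consistent correction has the right closed form and domain", {
  expect_equal(corrected_4dtv(0), 0)
  expect_equal(corrected_4dtv(0.2), -0.5 * log(0.6), tolerance = 1e-12)
  expect_equal(round(corrected_4dtv(0.2), 5), 0.25541)
  expect_true(is.na(corrected_4dtv(0.5)))   # boundary 2*piR*piY at equal freqs
  # unequal frequencies: matches -2 piR piY log(1 - Q/(2 piR piY))
  freqs <- c(0.4, 0.1, 0.2, 0.3)
  piR <- 0.6; piY <- 0.4
  q <- 0.3
  expect_equal(corrected_4dtv(q, freqs),
               -2 * piR * piY * log(1 - q / (2 * piR * piY)), tolerance = 1e-12)
})

test_that("correction is monotone, bounded below by raw, and equal-freq reduces", {
  q <- seq(0, 0.49, by = 0.01)
  corr <- corrected_4dtv(q)
  expect_true(all(diff(corr) > 0))
  expect_true(all(corr[-1] > q[-1]))
  expect_equal(corr[1], 0)
  expect_equal(corr, -0.5 * log(1 - 2 * q), tolerance = 1e-12)
})

test_that("HKY transition matrix agrees with an independent matrix exponential", {
  for (d in c(0.1, 0.5, 1.2)) {
    kappa <- 2.5; freqs <- c(0.3, 0.2, 0.2, 0.3)
    expect_equal(hky_transversion_prob(d, kappa, freqs),
                 oracle_hky_tv_prob(d, kappa, freqs), tolerance = 1e-10)
  }
})

test_that("paranome scan reports modal bin, ties and exclusions", {
  # single usable pair: peak is that pair's bin midpoint
  sim <- simulate_codon_pair_set(1L, 100L, 0.3, seed = 2)
  scan <- paranome_4dtv(sim$pairs)
  v <- tidy(scan)$corrected_4dtv[[1L]]
  expect_equal(scan$peak, (floor(v / 0.02) + 0.5) * 0.02)

  # two equal modes: leftmost reported and flagged
  pairs <- tibble::tibble(
    pair_id = c("p1", "p2"),
    seq_a = c(strrep("GGA", 40), strrep("GGA", 40)),
    seq_b = c(paste0(strrep("GGA", 20), strrep("GGT", 20)),  # raw 0.5 -> huge
              strrep("GGA", 40))                             # raw 0
  )
  scan2 <- paranome_4dtv(pairs, min_4d_sites = 10L, value = "raw")
  expect_true(scan2$peak_tied)
  expect_equal(scan2$peak, 0.01)  # leftmost of the two modal bins

  # short pairs excluded and counted; all excluded errors
  short <- tibble::tibble(pair_id = "s", seq_a = "GGA", seq_b = "GGA")
  expect_error(paranome_4dtv(short, min_4d_sites = 10L), "no usable pairs")
  g <- glance(paranome_4dtv(dplyr::bind_rows(short, sim$pairs), min_4d_sites = 10L))
  expect_equal(g$n_too_few_sites, 1L)
  expect_equal(g$n_used, 1L)
})

test_that("paranome peak recovers the simulated transversion distance", {
  sim <- simulate_codon_pair_set(300L, 300L, 0.5,
                                 distance_scale = "transversion", seed = 7)
  scan <- paranome_4dtv(sim$pairs)
  expect_lt(abs(scan$peak - 0.5), 1.5 * scan$bin_width + 1e-9)
  # mean raw 4DTv within 3 SE of the exact P-matrix transversion probability
  raw <- tidy(scan)$raw_4dtv
  expected <- oracle_hky_tv_prob(sim$truth$distance_total)
  se <- sd(raw) / sqrt(length(raw))
  expect_lt(abs(mean(raw) - expected), 3 * se)
})

test_that("paranome autoplot returns a ggplot", {
  sim <- simulate_codon_pair_set(5L, 100L, 0.3, seed = 2)
  p <- ggplot2::autoplot(paranome_4dtv(sim$pairs))
  expect_s3_class(p, "ggplot")
})
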