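test_that("all generators are pure functions of parameters and seed", {
  a <- simulate_codon_pair_set(5L, 30L, 0.4, seed = 7)
  b <- simulate_codon_pair_set(5L, 30L, 0.4, seed = 7)
  expect_identical(a, b)
  expect_false(identical(
    a$pairs, simulate_codon_pair_set(5L, 30L, 0.4, seed = 8)$pairs))

  expect_identical(simulate_ltr_cohort(5L, 1.5, seed = 3),
                   simulate_ltr_cohort(5L, 1.5, seed = 3))
  expect_identical(plant_satellite_chromosome(50000L, n_copies = 20L,
                                              locus_start = 10001L, seed = 3),
                   plant_satellite_chromosome(50000L, n_copies = 20L,
                                              locus_start = 10001L, seed = 3))
  expect_identical(make_family_fixture(seed = 2), make_family_fixture(seed = 2))
  expect_identical(make_expression_fixture(n_genes = 50L, seed = 2),
                   make_expression_fixture(n_genes = 50L, seed = 2))
})

test_that("generators do not disturb the global random stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(simulate_codon_pair_set(2L, 10L, 0.1, seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("codon pairs at distance zero are identical with raw 4DTv zero", {
  sim <- simulate_codon_pair_set(10L, 50L, 0, seed = 1)
  expect_identical(sim$pairs$seq_a, sim$pairs$seq_b)
  scan <- paranome_4dtv(sim$pairs, value = "raw")
  expect_true(all(tidy(scan)$raw_4dtv == 0))
  expect_error(simulate_codon_pair_set(5L, 10L, -0.1, seed = 1), "distance")
})

test_that("codon-pair transversion rate matches the exact HKY oracle", {
  sim <- simulate_codon_pair_set(300L, 300L, 0.6, kappa = 2, seed = 7)
  res <- dplyr::bind_rows(purrr::pmap(
    list(sim$pairs$seq_a, sim$pairs$seq_b, sim$pairs$pair_id), pair_4dtv))
  expected <- oracle_hky_tv_prob(0.6, kappa = 2)
  expect_equal(sim$truth$expected_raw_4dtv, expected, tolerance = 1e-10)
  se <- sd(res$raw_4dtv) / sqrt(nrow(res))
  expect_lt(abs(mean(res$raw_4dtv) - expected), 3 * se)
  # roughly the configured fraction of codons is fourfold degenerate
  expect_equal(mean(res$n_4d / 300), 0.8, tolerance = 0.05)
})

test_that("LTR cohorts recover their true age and mixtures stay bimodal", {
  expect_error(simulate_ltr_cohort(5L, -1, seed = 1), "ages")
  expect_error(simulate_ltr_cohort(5L, 1, rate = 0, seed = 1), "rate")
  zero <- simulate_ltr_cohort(5L, 0, seed = 1)
  expect_identical(zero$pairs$ltr5, zero$pairs$ltr3)

  sim <- simulate_ltr_cohort(200L, 1.5, ltr_length = 1000L, seed = 1)
  ages <- ltr_ages(sim$pairs)
  se <- sd(ages$t_mya) / sqrt(nrow(ages))
  expect_lt(abs(mean(ages$t_mya) - 1.5), 3 * se)

  mix <- simulate_ltr_cohort(200L, c(1.0, 4.5), ltr_length = 1000L, seed = 2)
  expect_setequal(unique(mix$truth$age_mya), c(1.0, 4.5))
})

test_that("satellite planting obeys the stated arithmetic and bounds", {
  sat <- plant_satellite_chromosome(500000L, n_copies = 100L,
                                    locus_start = 30001L, seed = 3)
  expect_equal(sat$truth$locus_end - sat$truth$locus_start + 1L, 100L * 161L)
  expect_equal(nchar(sat$genome$seq), 500000L)
  planted_row <- sat$repeats[sat$repeats$copy_number == 100, ]
  expect_equal(planted_row$start, 30001L)
  expect_equal(planted_row$monomer, sat$truth$monomer)

  none <- plant_satellite_chromosome(50000L, n_copies = 0L, seed = 3)
  expect_true(is.na(none$truth$locus_start))
  expect_false(any(none$repeats$copy_number > 8))
  expect_error(
    plant_satellite_chromosome(1000L, n_copies = 100L, locus_start = 1L, seed = 1),
    "exceeds chromosome"
  )
})

test_that("family fixture decoys each violate exactly one criterion", {
  fam <- make_family_fixture(n_genes = 50L, n_true_members = 12L, seed = 9)
  hits <- fam$hits |>
    dplyr::mutate(query_length = unname(fam$query_lengths[query_id]),
                  coverage = 100 * aln_length / query_length)
  domain_genes <- unique(fam$domains$gene_id)
  for (k in seq_len(nrow(fam$truth))) {
    g <- fam$truth$gene_id[[k]]
    h <- hits[hits$query_id == g, ]
    checks <- c(
      evalue = h$evalue <= 1e-5,
      identity = h$pct_identity >= 50,
      coverage = h$coverage >= 50,
      domain = g %in% domain_genes
    )
    if (fam$truth$is_member[[k]]) {
      expect_true(all(checks))
    } else {
      expect_equal(sum(!checks), 1L)
      failed <- names(checks)[!checks]
      expect_equal(paste0("decoy_", failed), fam$truth$role[[k]])
    }
  }
  empty <- make_family_fixture(n_genes = 20L, n_true_members = 0L,
                               tandem_cluster_spec = list(chrom = "chr4", n = 0L,
                                                          span_bp = 0L),
                               seed = 1)
  hits0 <- empty$hits |>
    dplyr::mutate(query_length = unname(empty$query_lengths[query_id]),
                  coverage = 100 * aln_length / query_length)
  res <- screen_family(hits0, empty$domains, empty$query_domain, empty$genes)
  expect_length(res$members, 0L)
})

test_that("expression fixture plants recoverable fold changes", {
  flat <- make_expression_fixture(n_genes = 200L,
                                  upregulated = list(n = 3L, fold = 1,
                                                     stage_pair = c("85DAF", "100DAF")),
                                  seed = 5)
  r <- rpkm(flat$counts, flat$gene_lengths, flat$library_sizes)
  fc <- stage_fold_change(r, flat$sample_stages, "85DAF", "100DAF")
  expect_lt(max(fc$fold), 2)

  expect_error(
    make_expression_fixture(upregulated = list(n = 2L, fold = 4,
                                               stage_pair = c("85DAF", "999DAF")),
                            seed = 1),
    "unknown stage"
  )
  expect_error(
    make_expression_fixture(upregulated = list(n = 2L, fold = -1,
                                               stage_pair = c("85DAF", "100DAF")),
                            seed = 1),
    "fold"
  )
})
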