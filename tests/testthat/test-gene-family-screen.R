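mk_hits <- function(...) {
  rows <- list(...)
  tibble::tibble(
    query_id = vapply(rows, `[[`, "", 1L),
    evalue = as.numeric(vapply(rows, `[[`, "", 2L)),
    pct_identity = as.numeric(vapply(rows, `[[`, "", 3L)),
    coverage = as.numeric(vapply(rows, `[[`, "", 4L))
  )
}

test_that("homology filter applies inclusive thresholds per hit", {
  hits <- mk_hits(
    c("pass", "1e-6", "55", "60"),
    c("fail_e", "1e-4", "90", "90"),
    c("fail_id", "1e-8", "40", "90"),
    c("fail_cov", "1e-8", "90", "40"),
    c("boundary", "1e-5", "50", "50")
  )
  expect_equal(filter_homology(hits), c("boundary", "pass"))
  # a gene passes if any one of its hits passes
  multi <- dplyr::bind_rows(hits, mk_hits(c("fail_e", "1e-9", "60", "60")))
  expect_true("fail_e" %in% filter_homology(multi))
})

test_that("homology filter equals brute-force row-wise evaluation", {
  set.seed(13)
  for (i in 1:20) {
    n <- 40L
    hits <- tibble::tibble(
      query_id = sample(sprintf("g%02d", 1:15), n, TRUE),
      evalue = 10^runif(n, -12, 0),
      pct_identity = runif(n, 0, 100),
      coverage = runif(n, 0, 100)
    )
    brute <- sort(unique(unlist(lapply(seq_len(n), function(k) {
      if (hits$evalue[k] <= 1e-5 && hits$pct_identity[k] >= 50 &&
          hits$coverage[k] >= 50) hits$query_id[k] else NULL
    }))))
    expect_identical(filter_homology(hits), brute)
  }
})

test_that("relaxing any threshold never shrinks the passing set", {
  set.seed(17)
  hits <- tibble::tibble(
    query_id = sprintf("g%03d", 1:200),
    evalue = 10^runif(200, -12, 0),
    pct_identity = runif(200, 0, 100),
    coverage = runif(200, 0, 100)
  )
  base <- filter_homology(hits)
  expect_true(all(base %in% filter_homology(hits, max_evalue = 1e-3)))
  expect_true(all(base %in% filter_homology(hits, min_identity = 30)))
  expect_true(all(base %in% filter_homology(hits, min_coverage = 30)))
})

test_that("domain requirement keeps supersets and supports exact mode", {
  domains <- tibble::tibble(
    gene_id = c("g1", "g1", "g2", "g3"),
    pfam_acc = c("PF00001", "PF00002", "PF00001", "PF00009"),
    domain_evalue = 1e-6
  )
  cand <- c("g1", "g2", "g3", "g4")
  expect_equal(require_shared_domains(cand, domains, "PF00001"), c("g1", "g2"))
  expect_equal(require_shared_domains(cand, domains, c("PF00001", "PF00002")), "g1")
  expect_equal(require_shared_domains(cand, domains, "PF00001", mode = "exact"), "g2")
  expect_error(require_shared_domains(cand, domains, character()), "non-empty")
})

test_that("LEA classification maps the seven diagnostic domains with strict threshold", {
  domains <- tibble::tibble(
    gene_id = c("geneX", "geneY", "geneZ", "geneZ"),
    pfam_acc = c("PF00257", "PF03168", "PF03760", "PF04927"),
    domain_evalue = c(0.005, 0.02, 0.001, 0.0001)
  )
  res <- suppressWarnings(classify_lea(domains))
  expect_equal(res$family[res$gene_id == "geneX"], "dehydrin")
  expect_false("geneY" %in% res$gene_id)   # 0.02 fails strict < 0.01
  z <- res[res$gene_id == "geneZ", ]
  expect_setequal(z$family, c("LEA1", "SMP"))
  expect_true(all(z$ambiguous))
  # boundary: exactly 0.01 fails (strict <)
  at <- tibble::tibble(gene_id = "g", pfam_acc = "PF00257", domain_evalue = 0.01)
  expect_equal(nrow(classify_lea(at)), 0L)
  expect_warning(
    classify_lea(tibble::tibble(gene_id = "g", pfam_acc = "PF99999",
                                domain_evalue = 1e-5)),
    "PF99999"
  )
})

test_that("tandem arrays chain nearby members and split on interlopers", {
  fam <- make_family_fixture(seed = 9)
  members <- fam$genes[fam$genes$gene_id %in% fam$cluster$gene_ids, ]
  arrays <- detect_tandem_arrays(members, fam$genes)
  expect_equal(nrow(arrays), 1L)
  expect_equal(arrays$n_genes, 10L)
  expect_equal(arrays$span_bp, 270000L)

  # two members 5 Mb apart: no array
  far <- tibble::tibble(gene_id = c("a", "b"), chrom = "chr1",
                        start = c(1e6, 6e6), end = c(1e6, 6e6) + 2000)
  expect_equal(nrow(detect_tandem_arrays(far, far)), 0L)

  # interlopers beyond max_intervening split the chain
  mem <- tibble::tibble(gene_id = c("m1", "m2"), chrom = "chr1",
                        start = c(10000L, 60000L), end = c(12000L, 62000L))
  inter <- tibble::tibble(gene_id = sprintf("x%d", 1:6), chrom = "chr1",
                          start = seq(20000L, 45000L, length.out = 6L))
  inter$end <- inter$start + 1000L
  all_genes <- dplyr::bind_rows(mem, inter)
  expect_equal(nrow(detect_tandem_arrays(mem, all_genes)), 0L)
  expect_equal(nrow(detect_tandem_arrays(mem, all_genes, max_intervening = 6L)), 1L)

  expect_error(
    detect_tandem_arrays(dplyr::mutate(mem, chrom = "chrZ"), all_genes),
    "chrZ"
  )
})

test_that("the full screen recovers the fixture truth exactly", {
  fam <- make_family_fixture(n_genes = 50L, n_true_members = 12L, seed = 9)
  hits <- fam$hits |>
    dplyr::mutate(query_length = unname(fam$query_lengths[query_id]),
                  coverage = 100 * aln_length / query_length)
  res <- screen_family(hits, fam$domains, fam$query_domain, fam$genes)
  expect_identical(res$members, sort(fam$truth$gene_id[fam$truth$is_member]))
  expect_equal(nrow(res$arrays), 1L)
  expect_equal(res$arrays$span_bp, fam$cluster$span_bp)
  expect_setequal(res$arrays$gene_ids[[1L]], fam$cluster$gene_ids)
})
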