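rotate <- function(s, k) {
  n <- nchar(s)
  paste0(substr(s, k + 1L, n), substr(s, 1L, k))
}

test_that("monomer identity is invariant to rotation and strand", {
  set.seed(1)
  m <- random_dna(161)
  expect_equal(monomer_identity(m, m), 1)
  expect_equal(monomer_identity(m, rotate(m, 47)), 1)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(m)))
  expect_equal(monomer_identity(m, rc), 1)
  expect_equal(monomer_identity(m, rotate(rc, 90)), 1)
  unrelated <- random_dna(161)
  expect_lt(monomer_identity(m, unrelated), 0.8)
})

test_that("clustering joins rotated/reverse-complemented monomers and is order-invariant", {
  set.seed(2)
  m <- random_dna(120)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(m)))
  reps <- tibble::tibble(
    chrom = "c1",
    start = c(1L, 1000L, 5000L, 9000L),
    end = c(600L, 1600L, 5600L, 9360L),
    period = c(120L, 120L, 120L, 90L),
    copy_number = c(5, 5, 5, 4),
    monomer = c(m, rotate(m, 33), rc, random_dna(90))
  )
  cl <- cluster_monomers(reps)
  expect_equal(nrow(cl), 2L)
  expect_equal(cl$n_members[[1L]], 3L)
  shuffled <- cluster_monomers(reps[c(3, 1, 4, 2), ])
  expect_equal(shuffled$total_bases, cl$total_bases)
  expect_equal(shuffled$n_members, cl$n_members)
})

test_that("clustering respects the period band", {
  reps <- tibble::tibble(chrom = "c1", start = 1L, end = 100L, period = 10L,
                         copy_number = 10, monomer = strrep("AC", 5))
  expect_error(cluster_monomers(reps), "period_range")
})

test_that("the planted satellite wins base-repeat selection over decoys", {
  sat <- plant_satellite_chromosome(200000L, n_copies = 120L,
                                    locus_start = 50001L, seed = 3)
  cl <- cluster_monomers(sat$repeats)
  base <- base_repeat(cl)
  expect_equal(base$monomer_length[[1L]], 161L)
  expect_equal(base$members[[1L]]$start, sat$truth$locus_start)
  # tie on total bases resolves to the longer representative
  tie <- tibble::tibble(
    cluster_id = c("a", "b"), representative_monomer = c(strrep("A", 100), strrep("C", 161)),
    monomer_length = c(100L, 161L), n_members = 1L,
    total_copies = 5, total_bases = c(1000L, 1000L), members = list(NULL, NULL)
  )
  expect_equal(base_repeat(tie)$monomer_length[[1L]], 161L)
})

test_that("monomer mapping finds exact, mutated and reverse-complement copies", {
  set.seed(5)
  mono <- random_dna(60)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(mono)))
  genome <- c(chrA = paste0(random_dna(500), mono, random_dna(500)),
              chrB = paste0(random_dna(300), rc, random_dna(300)))
  hits <- map_monomer(genome, mono)
  expect_equal(nrow(hits), 2L)
  fwd <- hits[hits$chrom == "chrA", ]
  expect_equal(fwd$start, 501L)
  expect_equal(fwd$end, 560L)
  expect_equal(fwd$strand, "+")
  expect_equal(hits$strand[hits$chrom == "chrB"], "-")
  expect_error(map_monomer(genome, "ACGTACGT"), "seed length")
})

test_that("a planted mutated array is recovered nearly copy for copy", {
  sat <- plant_satellite_chromosome(300000L, n_copies = 100L,
                                    locus_start = 100001L,
                                    per_copy_mutation = 0.05, seed = 6)
  hits <- map_monomer(Biostrings::DNAStringSet(
    setNames(sat$genome$seq, sat$genome$id)), sat$truth$monomer)
  in_locus <- hits$start >= sat$truth$locus_start - 161L &
    hits$end <= sat$truth$locus_end + 161L
  expect_gte(sum(in_locus), 95L)
})

test_that("window densities conserve total satellite bp", {
  sat <- plant_satellite_chromosome(300000L, n_copies = 100L,
                                    locus_start = 100001L, seed = 6)
  hits <- map_monomer(sat$genome, sat$truth$monomer)
  calls <- call_centromeres(hits, c(chr_sim = 300000L), window = 50000L,
                            monomer = sat$truth$monomer)
  dens <- evoscan:::window_densities(hits, 300000L, 50000L)
  expect_equal(sum(dens), sum(hits$end - hits$start + 1L))
})

test_that("centromere calls localise the planted array and report no_call elsewhere", {
  sat <- plant_satellite_chromosome(900000L, n_copies = 200L,
                                    locus_start = 400001L, seed = 8)
  res <- scan_centromeres(sat$genome, sat$repeats, window = 300000L)
  calls <- res$calls
  expect_equal(calls$status, "called")
  expect_lte(calls$start, sat$truth$locus_start)
  expect_gte(calls$end, sat$truth$locus_end)
  expect_equal(calls$monomer_length, 161L)
  expect_equal(calls$monomer_gc, gc_content(res$base_repeat$representative_monomer[[1L]]))

  # second chromosome without satellite: no_call
  hits <- map_monomer(sat$genome, res$base_repeat$representative_monomer[[1L]])
  two <- call_centromeres(hits, c(chr_sim = 900000L, chr_empty = 600000L),
                          monomer = sat$truth$monomer)
  expect_equal(two$status[two$chrom == "chr_empty"], "no_call")
  expect_equal(sum(two$status == "called"), 1L)
  expect_error(call_centromeres(hits, c(other = 1000L)), "absent from chrom_lengths")
})
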