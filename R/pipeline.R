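default_config <- function() {
  list(
    rate = 1.3e-8,
    window = 300000L,
    min_fraction = 0.05,
    max_evalue = 1e-5,
    min_identity = 50,
    min_coverage = 50,
    lea_max_evalue = 0.01,
    min_4d_sites = 10L,
    bin_4dtv = 0.02,
    bin_mya = 0.25,
    monomer_min_identity = 0.80,
    period_range = c(50, 500),
    pseudocount = 1,
    seed = 1L
  )
}

#' Validate and normalise a pipeline configuration
#'
#' Fills defaults (substitution rate 1.3e-8/site/year, 300-kb density window,
#' homology thresholds 1e-5 / 50% / 50%, LEA domain E-value 0.01, ...),
#' rejects unknown keys, and checks every value against its documented
#' domain, naming the offending key.
#'
#' @param cfg Named list of overrides (possibly empty), or a path to a YAML
#'   file containing one.
#' @return The fully populated configuration list.
#' @export
validate_config <- function(cfg = list()) {
  if (is.character(cfg) && length(cfg) == 1L) cfg <- yaml::read_yaml(cfg)
  if (is.null(cfg)) cfg <- list()
  defaults <- default_config()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown) > 0L) {
    abort(paste0("unknown config key: ", unknown[[1L]]))
  }
  out <- utils::modifyList(defaults, cfg)
  check_pos <- function(key) {
    if (!is.numeric(out[[key]]) || any(out[[key]] <= 0)) {
      abort(paste0("config value out of domain: ", key, " must be > 0"))
    }
  }
  for (key in c("rate", "window", "bin_4dtv", "bin_mya", "pseudocount")) check_pos(key)
  if (out$min_fraction < 0 || out$min_fraction > 1) {
    abort("config value out of domain: min_fraction must be in [0, 1]")
  }
  if (out$max_evalue < 0) abort("config value out of domain: max_evalue must be >= 0")
  for (key in c("min_identity", "min_coverage")) {
    if (out[[key]] < 0 || out[[key]] > 100) {
      abort(paste0("config value out of domain: ", key, " must be in [0, 100]"))
    }
  }
  if (out$monomer_min_identity < 0 || out$monomer_min_identity > 1) {
    abort("config value out of domain: monomer_min_identity must be in [0, 1]")
  }
  if (out$lea_max_evalue <= 0) {
    abort("config value out of domain: lea_max_evalue must be > 0")
  }
  if (out$min_4d_sites < 1) {
    abort("config value out of domain: min_4d_sites must be >= 1")
  }
  if (length(out$period_range) != 2L || out$period_range[[1L]] > out$period_range[[2L]]) {
    abort("config value out of domain: period_range must be (min, max)")
  }
  out
}

#' Run the full pipeline on seeded synthetic data
#'
#' Generates every synthetic fixture, writes them to disk in their external
#' formats, reads them back through the format readers, runs all analysis
#' stages, and writes a machine-readable report comparing each estimate with
#' the generator's recorded truth. All outputs are byte-stable functions of
#' the seed (no timestamps).
#'
#' @param seed Integer seed driving every fixture.
#' @param outdir Writable output directory (created if absent).
#' @param config Optional configuration overrides (see [validate_config()]).
#' @return The report, invisibly (also written to `report.json` in `outdir`).
#' @export
run_demo <- function(seed = 42L, outdir, config = list()) {
  cfg <- validate_config(config)
  cfg$seed <- as.integer(seed)
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("cannot create output directory: ", outdir))
  }
  if (file.access(outdir, 2L) != 0L) {
    abort(paste0("output directory not writable: ", outdir))
  }
  report <- list(seed = cfg$seed)
  p <- function(...) file.path(outdir, ...)

  # --- whole-genome duplication: 4DTv on simulated paralog pairs ----------
  message("stage: 4dtv")
  sim <- simulate_codon_pair_set(300L, 200L, distance = 0.5,
                                 distance_scale = "transversion",
                                 seed = seed)
  fasta <- tibble(
    id = c(rbind(paste0(sim$pairs$pair_id, "_a"), paste0(sim$pairs$pair_id, "_b"))),
    seq = c(rbind(sim$pairs$seq_a, sim$pairs$seq_b))
  )
  write_fasta(fasta, p("paralog_pairs.fasta"))
  rec <- read_fasta(p("paralog_pairs.fasta"))
  pairs <- tibble(
    pair_id = sub("_a$", "", rec$id[c(TRUE, FALSE)]),
    seq_a = rec$seq[c(TRUE, FALSE)],
    seq_b = rec$seq[c(FALSE, TRUE)]
  )
  scan <- paranome_4dtv(pairs, min_4d_sites = cfg$min_4d_sites,
                        bin_width = cfg$bin_4dtv)
  readr::write_tsv(tidy(scan), p("4dtv_pairs.tsv"))
  report$wgd_4dtv <- list(
    true_transversion_distance = sim$truth$transversion_distance,
    peak = scan$peak,
    pass = abs(scan$peak - sim$truth$transversion_distance) <= 1.5 * cfg$bin_4dtv
  )

  # --- LTR insertion-age dating ------------------------------------------
  message("stage: ltr-age")
  ltr <- simulate_ltr_cohort(150L, ages_mya = 1.5, rate = cfg$rate,
                             ltr_length = 800L, seed = seed + 1L)
  ages <- ltr_ages(ltr$pairs, rate = cfg$rate)
  prof <- age_profile(ages, bin_mya = cfg$bin_mya)
  readr::write_tsv(ages, p("ltr_ages.tsv"))
  mean_age <- mean(ages$t_mya[ages$status == "ok"])
  report$ltr_dating <- list(
    true_age_mya = 1.5,
    mean_estimated_age_mya = mean_age,
    burst_peak_mya = prof$burst_peak_mya,
    pass = abs(mean_age - 1.5) < 0.15
  )

  # --- centromeric satellite recovery ------------------------------------
  message("stage: censcan")
  sat <- plant_satellite_chromosome(1500000L, n_copies = 300L,
                                    locus_start = 600001L, seed = seed + 2L)
  write_fasta(sat$genome, p("satellite_chrom.fasta"))
  write_trf_dat(sat$repeats, p("satellite_repeats.dat"))
  genome <- read_fasta(p("satellite_chrom.fasta"))
  repeats <- read_trf_dat(p("satellite_repeats.dat"))
  cen <- scan_centromeres(genome, repeats,
                          min_identity = cfg$monomer_min_identity,
                          period_range = cfg$period_range,
                          window = cfg$window,
                          min_fraction = cfg$min_fraction)
  readr::write_tsv(cen$calls, p("centromeres.tsv"))
  call <- cen$calls[cen$calls$status == "called", , drop = FALSE]
  locus_ok <- nrow(call) == 1L &&
    call$start[[1L]] <= sat$truth$locus_start + cfg$window &&
    call$end[[1L]] >= sat$truth$locus_end - cfg$window
  report$centromere <- list(
    true_locus = c(sat$truth$locus_start, sat$truth$locus_end),
    monomer_length = cen$base_repeat$monomer_length[[1L]],
    call = if (nrow(call) == 1L) c(call$start[[1L]], call$end[[1L]]) else NULL,
    pass = locus_ok &&
      cen$base_repeat$monomer_length[[1L]] == nchar(sat$truth$monomer)
  )

  # --- gene-family screen -------------------------------------------------
  message("stage: famscreen")
  fam <- make_family_fixture(seed = seed + 3L)
  write_gff3_genes(fam$genes, p("genes.gff3"))
  write_blast_tab(fam$hits, p("family_hits.tsv"))
  write_domtbl(fam$domains, p("family_domains.domtbl"))
  genes <- read_gff3_genes(p("genes.gff3"))
  hits <- read_blast_tab(p("family_hits.tsv"), fam$query_lengths)
  domains <- read_domtbl(p("family_domains.domtbl"))
  screen <- screen_family(hits, domains, fam$query_domain, genes,
                          max_evalue = cfg$max_evalue,
                          min_identity = cfg$min_identity,
                          min_coverage = cfg$min_coverage)
  truth_members <- sort(fam$truth$gene_id[fam$truth$is_member])
  readr::write_tsv(tibble(gene_id = screen$members), p("family_members.tsv"))
  report$family_screen <- list(
    n_members = length(screen$members),
    n_arrays = nrow(screen$arrays),
    pass = identical(screen$members, truth_members) && nrow(screen$arrays) >= 1L
  )

  # --- expression summaries ----------------------------------------------
  message("stage: expr")
  expr <- make_expression_fixture(n_genes = 500L, seed = seed + 4L)
  readr::write_tsv(expr$counts, p("counts.tsv"))
  readr::write_tsv(expr$gene_lengths, p("gene_lengths.tsv"))
  counts <- readr::read_tsv(p("counts.tsv"), show_col_types = FALSE)
  r <- rpkm(counts, expr$gene_lengths, expr$library_sizes)
  fc <- stage_fold_change(r, expr$sample_stages,
                          expr$truth$stage_pair[[1L]], expr$truth$stage_pair[[2L]],
                          pseudocount = cfg$pseudocount)
  readr::write_tsv(fc, p("fold_changes.tsv"))
  topk <- fc$gene_id[seq_along(expr$truth$genes)]
  report$expression <- list(
    planted_fold = expr$truth$fold,
    top_ranked = topk,
    pass = setequal(topk, expr$truth$genes)
  )

  # --- assembly statistics ------------------------------------------------
  message("stage: stats")
  stats_tbl <- assembly_stats(c(8, 5, 4, 3) * 1e6)
  report$assembly_stats <- list(
    n50_bp = stats_tbl$n50[[1L]],
    pass = stats_tbl$n50[[1L]] == 5e6
  )

  report$all_pass <- all(vapply(
    report[c("wgd_4dtv", "ltr_dating", "centromere", "family_screen",
             "expression", "assembly_stats")],
    function(x) isTRUE(x$pass), logical(1)
  ))
  jsonlite::write_json(cfg, p("config.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(report, p("report.json"), auto_unbox = TRUE, digits = NA)
  invisible(report)
}
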