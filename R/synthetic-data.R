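with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("seed must be a single integer")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

BASES <- c("A", "C", "G", "T")
NON4D_PREFIXES <- c("TT", "AT", "TA", "AA", "AG", "GA", "CA", "TG")

sample_bases <- function(n, freqs = rep(0.25, 4)) {
  sample(BASES, n, replace = TRUE, prob = freqs)
}

evolve_bases <- function(anc, P) {
  out <- character(length(anc))
  for (b in BASES) {
    idx <- which(anc == b)
    if (length(idx) > 0L) {
      out[idx] <- sample(BASES, length(idx), replace = TRUE, prob = P[b, ])
    }
  }
  out
}

#' Simulate codon-aligned paralog pairs of known divergence
#'
#' Each pair descends from a common ancestor whose codons are drawn mostly
#' from fourfold-degenerate families (a `decoy_fraction` of non-fourfold
#' codons exercises site classification). Codon positions 1-2 are copied
#' unchanged to both descendants; third positions evolve independently down
#' two branches of length `distance/2` under the exact HKY85
#' transition-probability matrix, so the expected transversion fraction at 4D
#' sites is computable in closed form ([hky_transversion_prob()]).
#'
#' @param n_pairs Number of pairs.
#' @param n_codons Codons per sequence.
#' @param distance Expected substitutions per third-position site separating
#'   the two descendants (>= 0). With `distance_scale = "transversion"` the
#'   value is instead the expected number of *transversions* per site and the
#'   total divergence is scaled up accordingly.
#' @param kappa,freqs HKY85 parameters (see [hky_rate_matrix()]).
#' @param decoy_fraction Fraction of codons drawn from non-fourfold families
#'   (default 0.2).
#' @param distance_scale `"total"` (default) or `"transversion"`.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments.
#' @return List with `pairs` (tibble `pair_id`, `seq_a`, `seq_b`) and `truth`
#'   (list with the realised `distance_total`, the target
#'   `transversion_distance`, the exact `expected_raw_4dtv`, parameters and
#'   seed).
#' @export
simulate_codon_pair_set <- function(n_pairs, n_codons, distance, kappa = 2,
                                    freqs = rep(0.25, 4), decoy_fraction = 0.2,
                                    distance_scale = c("total", "transversion"),
                                    seed = 1L) {
  distance_scale <- match.arg(distance_scale)
  if (distance < 0) abort("distance must be >= 0")
  if (n_codons < 1L) abort("n_codons must be >= 1")
  check_hky(kappa, freqs)
  tv_frac <- hky_transversion_fraction(kappa, freqs)
  d_total <- if (distance_scale == "transversion") distance / tv_frac else distance
  P <- hky_pmatrix(d_total / 2, kappa, freqs)
  with_seed(seed, {
    pairs <- purrr::map(seq_len(n_pairs), function(k) {
      is_4d <- runif(n_codons) >= decoy_fraction
      prefixes <- ifelse(is_4d,
                         sample(fourfold_prefixes, n_codons, replace = TRUE),
                         sample(NON4D_PREFIXES, n_codons, replace = TRUE))
      anc3 <- sample_bases(n_codons, freqs)
      a3 <- evolve_bases(anc3, P)
      b3 <- evolve_bases(anc3, P)
      tibble(
        pair_id = sprintf("pair_%04d", k),
        seq_a = paste0(paste0(prefixes, a3), collapse = ""),
        seq_b = paste0(paste0(prefixes, b3), collapse = "")
      )
    }) |> bind_rows()
    list(
      pairs = pairs,
      truth = list(
        distance_total = d_total,
        transversion_distance = d_total * tv_frac,
        expected_raw_4dtv = hky_transversion_prob(d_total, kappa, freqs),
        kappa = kappa, freqs = freqs,
        decoy_fraction = decoy_fraction, seed = seed
      )
    )
  })
}

#' Simulate a cohort of LTR retrotransposons of known insertion ages
#'
#' For each element one ancestral LTR is generated (uniform random ACGT) and
#' two descendant copies each accumulate substitutions under exact
#' Jukes-Cantor site dynamics for `age` years at rate `rate`, emulating the
#' divergence of the two LTRs since insertion.
#'
#' @param n Number of elements.
#' @param ages_mya A single age, or a vector of `n` ages, in Mya (>= 0); a
#'   vector shorter than `n` is sampled from with replacement (a mixture).
#' @param rate Substitution rate per site per year (> 0; default 1.3e-8).
#' @param ltr_length LTR length in bp (default 1000).
#' @param seed Integer seed.
#' @return List with `pairs` (tibble `element_id`, `ltr5`, `ltr3`) and
#'   `truth` (tibble `element_id`, `age_mya`, plus attributes in a list).
#' @export
simulate_ltr_cohort <- function(n, ages_mya, rate = 1.3e-8, ltr_length = 1000L,
                                seed = 1L) {
  if (any(ages_mya < 0)) abort("ages must be >= 0")
  if (rate <= 0) abort("rate must be > 0")
  with_seed(seed, {
    ages <- if (length(ages_mya) == n) ages_mya
            else if (length(ages_mya) == 1L) rep(ages_mya, n)
            else sample(ages_mya, n, replace = TRUE)
    rows <- purrr::map(seq_len(n), function(k) {
      anc <- sample_bases(ltr_length)
      d <- rate * ages[[k]] * 1e6  # per-branch expected substitutions/site
      p_same <- 0.25 + 0.75 * exp(-4 * d / 3)
      Pjc <- matrix((1 - p_same) / 3, 4, 4, dimnames = list(BASES, BASES))
      diag(Pjc) <- p_same
      tibble(
        element_id = sprintf("ltr_%04d", k),
        ltr5 = paste0(evolve_bases(anc, Pjc), collapse = ""),
        ltr3 = paste0(evolve_bases(anc, Pjc), collapse = "")
      )
    })
    list(
      pairs = bind_rows(rows),
      truth = tibble(element_id = sprintf("ltr_%04d", seq_len(n)),
                     age_mya = ages)
    )
  })
}

mutate_monomer <- function(monomer, per_base_rate) {
  v <- strsplit(monomer, "")[[1L]]
  hit <- runif(length(v)) < per_base_rate
  if (any(hit)) {
    v[hit] <- vapply(v[hit], function(b) sample(setdiff(BASES, b), 1L), "")
  }
  paste0(v, collapse = "")
}

#' Plant a centromeric satellite array on a synthetic chromosome
#'
#' Builds a uniform-random background chromosome and inserts `n_copies`
#' tandem copies of `monomer` at `locus_start`, each copy independently
#' mutated at `per_copy_mutation` per base. A matching Tandem Repeats Finder
#' table is emitted listing the array plus `n_decoys` planted low-copy decoy
#' repeats.
#'
#' @param chrom_length Chromosome length in bp.
#' @param monomer Monomer string, or `NULL` to draw a random monomer of
#'   `monomer_length` bp.
#' @param n_copies Number of tandem copies (0 plants nothing).
#' @param locus_start 1-based start of the array.
#' @param per_copy_mutation Per-base substitution probability per copy
#'   (default 0.05).
#' @param n_decoys Number of decoy low-copy tandem repeats (default 5).
#' @param monomer_length Length of the random monomer when `monomer` is NULL
#'   (default 161 bp, a typical plant centromeric satellite period).
#' @param chrom_name Chromosome name (default `"chr_sim"`).
#' @param seed Integer seed.
#' @return List with `genome` (tibble `id`, `seq` compatible with
#'   [write_fasta()]), `repeats` (tibble in [read_trf_dat()] form) and
#'   `truth` (list with `locus_start`, `locus_end`, `monomer`, `n_copies`;
#'   empty locus fields when `n_copies = 0`).
#' @export
plant_satellite_chromosome <- function(chrom_length, monomer = NULL,
                                       n_copies = 500L, locus_start = NULL,
                                       per_copy_mutation = 0.05, n_decoys = 5L,
                                       monomer_length = 161L,
                                       chrom_name = "chr_sim", seed = 1L) {
  with_seed(seed, {
    if (is.null(monomer)) monomer <- paste0(sample_bases(monomer_length), collapse = "")
    mlen <- nchar(monomer)
    if (is.null(locus_start)) locus_start <- floor(chrom_length / 2)
    if (n_copies > 0L && locus_start + n_copies * mlen - 1L > chrom_length) {
      abort("satellite array exceeds chromosome length")
    }
    chrom <- sample_bases(chrom_length)
    records <- list()
    if (n_copies > 0L) {
      copies <- vapply(seq_len(n_copies),
                       function(i) mutate_monomer(monomer, per_copy_mutation), "")
      array_seq <- strsplit(paste0(copies, collapse = ""), "")[[1L]]
      locus_end <- locus_start + length(array_seq) - 1L
      chrom[locus_start:locus_end] <- array_seq
      records[[1L]] <- tibble(
        chrom = chrom_name, start = as.integer(locus_start),
        end = as.integer(locus_end), period = as.integer(mlen),
        copy_number = as.numeric(n_copies), monomer = monomer
      )
    } else {
      locus_end <- NA_integer_
    }
    # decoy low-copy repeats, placed clear of the array
    guard <- function(s, e) {
      n_copies > 0L && s <= locus_end + mlen && e >= locus_start - mlen
    }
    d <- 0L
    while (d < n_decoys) {
      dper <- sample(60:320, 1L)
      dcop <- sample(3:8, 1L)
      dlen <- dper * dcop
      s <- sample.int(chrom_length - dlen, 1L)
      e <- s + dlen - 1L
      if (guard(s, e)) next
      dmono <- paste0(sample_bases(dper), collapse = "")
      dseq <- strsplit(paste0(rep(dmono, dcop), collapse = ""), "")[[1L]]
      chrom[s:e] <- dseq
      records[[length(records) + 1L]] <- tibble(
        chrom = chrom_name, start = as.integer(s), end = as.integer(e),
        period = as.integer(dper), copy_number = as.numeric(dcop),
        monomer = dmono
      )
      d <- d + 1L
    }
    repeats <- if (length(records) > 0L) bind_rows(records) |> arrange(.data$start)
               else tibble(chrom = character(), start = integer(),
                           end = integer(), period = integer(),
                           copy_number = numeric(), monomer = character())
    list(
      genome = tibble(id = chrom_name, description = "",
                      seq = paste0(chrom, collapse = ""), ambiguous = FALSE),
      repeats = repeats,
      truth = list(
        locus_start = if (n_copies > 0L) as.integer(locus_start) else NA_integer_,
        locus_end = if (n_copies > 0L) as.integer(locus_end) else NA_integer_,
        monomer = monomer, n_copies = n_copies, seed = seed
      )
    )
  })
}

#' Generate a gene-family screening fixture with known truth
#'
#' Emits gene models, a homology hit table and a domain table in which every
#' true member passes all screen criteria and each decoy violates exactly one
#' (E-value, identity, coverage, or missing domain). The first
#' `tandem_cluster_spec$n` true members are placed as a tandem cluster
#' spanning `tandem_cluster_spec$span_bp` on the named chromosome.
#'
#' @param n_genes Total genes.
#' @param n_true_members True family members (must be >= the cluster size and
#'   <= `n_genes`).
#' @param tandem_cluster_spec List with `chrom`, `n` (genes in the cluster)
#'   and `span_bp` (end of last minus start of first member).
#' @param query_domain Pfam accession required of members (default PF08392,
#'   the FAE1/KCS condensation domain).
#' @param seed Integer seed.
#' @return List with `genes`, `hits`, `query_lengths`, `domains`,
#'   `query_domain` and `truth` (tibble `gene_id`, `role`, `is_member` plus a
#'   `cluster` list).
#' @export
make_family_fixture <- function(n_genes = 50L, n_true_members = 12L,
                                tandem_cluster_spec = list(chrom = "chr4",
                                                           n = 10L,
                                                           span_bp = 270000L),
                                query_domain = "PF08392", seed = 1L) {
  if (n_true_members > n_genes) abort("n_true_members must be <= n_genes")
  nc <- tandem_cluster_spec$n
  span <- tandem_cluster_spec$span_bp
  if (nc > n_true_members) abort("cluster size exceeds n_true_members")
  gene_width <- 2000L
  if (nc > 1L && span < nc * gene_width) {
    abort("span too small for requested gene count at minimum gene width")
  }
  with_seed(seed, {
    ids <- sprintf("gene_%03d", seq_len(n_genes))
    # cluster genes: evenly spaced so that last end - first start = span
    cl_start0 <- 1000000L
    gap <- if (nc > 1L) (span - gene_width) / (nc - 1L) else 0
    cl_starts <- as.integer(round(cl_start0 + (seq_len(nc) - 1L) * gap))
    cluster <- tibble(
      gene_id = ids[seq_len(nc)], chrom = tandem_cluster_spec$chrom,
      start = cl_starts, end = cl_starts + gene_width,
      strand = "+", family_label = NA_character_
    )
    n_rest <- n_genes - nc
    rest <- tibble(
      gene_id = ids[nc + seq_len(n_rest)],
      chrom = paste0("chr", 1L + (seq_len(n_rest) - 1L) %% 3L),
      start = 100000L + 200000L * ((seq_len(n_rest) - 1L) %/% 3L),
      strand = "+", family_label = NA_character_
    ) |> mutate(end = .data$start + gene_width, .after = "start")
    genes <- bind_rows(cluster, rest)
    member_ids <- ids[seq_len(n_true_members)]
    decoy_ids <- setdiff(ids, member_ids)
    violations <- rep(c("decoy_evalue", "decoy_identity", "decoy_coverage",
                        "decoy_domain"), length.out = length(decoy_ids))
    qlen <- 400L
    mk_hit <- function(gene, evalue, identity, aln_len) {
      tibble(query_id = gene, subject_id = "AT_query_1",
             pct_identity = identity, aln_length = aln_len,
             mismatch = as.integer(round(aln_len * (100 - identity) / 100)),
             gapopen = 0L, qstart = 1L, qend = aln_len,
             sstart = 1L, send = aln_len,
             evalue = evalue, bitscore = round(aln_len * 1.8))
    }
    hits <- bind_rows(
      purrr::map(member_ids, function(g) mk_hit(g, 1e-8, 75, 320L)),
      purrr::map2(decoy_ids, violations, function(g, v) {
        switch(v,
               decoy_evalue = mk_hit(g, 1e-3, 75, 320L),
               decoy_identity = mk_hit(g, 1e-8, 30, 320L),
               decoy_coverage = mk_hit(g, 1e-8, 75, 120L),
               decoy_domain = mk_hit(g, 1e-8, 75, 320L))
      })
    )
    with_domain <- c(member_ids, decoy_ids[violations != "decoy_domain"])
    domains <- tibble(gene_id = with_domain, pfam_acc = query_domain,
                      domain_evalue = 1e-10)
    truth <- tibble(
      gene_id = c(member_ids, decoy_ids),
      role = c(rep("member", length(member_ids)), violations)
    ) |> mutate(is_member = .data$role == "member")
    list(
      genes = genes, hits = hits,
      query_lengths = setNames(rep(qlen, n_genes), ids),
      domains = domains, query_domain = query_domain,
      truth = truth,
      cluster = list(chrom = tandem_cluster_spec$chrom,
                     gene_ids = cluster$gene_id, span_bp = span)
    )
  })
}

#' Generate a count matrix with planted stage-specific up-regulation
#'
#' Baseline counts are drawn from an over-dispersed negative-binomial model
#' with lognormal per-gene means; the selected genes have their expected
#' counts multiplied by `fold` in the later stage of `stage_pair`.
#'
#' @param n_genes Number of genes.
#' @param stages Character vector of stage labels, in order.
#' @param n_reps Replicates per stage (default 3).
#' @param upregulated List with `n` (number of planted genes) or `genes`
#'   (ids), `fold` (> 0) and `stage_pair` (length-2: earlier, later stage).
#' @param size Negative-binomial size (inverse dispersion) of replicate
#'   counts; the default 100 corresponds to a 10% biological coefficient of
#'   variation, typical of well-controlled replicated RNA-seq.
#' @param seed Integer seed.
#' @return List with `counts` (tibble `gene_id` + one column per sample),
#'   `gene_lengths` (tibble), `sample_stages` (named vector),
#'   `library_sizes` (named vector of mapped-read totals; the fixture
#'   emulates the counted subset of a full transcriptome, so totals are fixed
#'   at one million reads per sample rather than at the fixture column sums)
#'   and `truth` (list `genes`, `fold`, `stage_pair`).
#' @export
make_expression_fixture <- function(n_genes = 1000L,
                                    stages = c("70DAF", "85DAF", "100DAF"),
                                    n_reps = 3L,
                                    upregulated = list(n = 3L, fold = 4.7,
                                                       stage_pair = c("85DAF", "100DAF")),
                                    size = 100, seed = 1L) {
  fold <- upregulated$fold
  if (fold <= 0) abort("fold must be > 0")
  sp <- upregulated$stage_pair
  if (!all(sp %in% stages)) {
    abort(paste0("unknown stage in stage_pair: ", setdiff(sp, stages)[[1L]]))
  }
  with_seed(seed, {
    ids <- sprintf("g%04d", seq_len(n_genes))
    up <- if (!is.null(upregulated$genes)) upregulated$genes
          else ids[seq_len(upregulated$n)]
    lengths <- sample(500:3000, n_genes, replace = TRUE)
    base_mu <- exp(stats::rnorm(n_genes, mean = 4, sd = 1))
    # planted genes are well-expressed, like the seed-development marker genes
    # whose fold changes this fixture emulates; fold recovery is only
    # well-posed away from the counting-noise floor
    base_mu[ids %in% up] <- exp(5.5)
    samples <- as.vector(outer(stages, seq_len(n_reps),
                               function(s, r) paste0(s, "_r", r)))
    sample_stages <- setNames(rep(stages, times = n_reps), samples)
    counts <- matrix(0L, n_genes, length(samples),
                     dimnames = list(ids, samples))
    for (s in samples) {
      mu <- base_mu
      if (sample_stages[[s]] == sp[[2L]]) mu[ids %in% up] <- mu[ids %in% up] * fold
      counts[, s] <- rnbinom(n_genes, mu = mu, size = size)
    }
    list(
      counts = matrix_to_tibble(counts),
      gene_lengths = tibble(gene_id = ids, length = lengths),
      sample_stages = sample_stages,
      library_sizes = setNames(rep(1e6, length(samples)), samples),
      truth = list(genes = up, fold = fold, stage_pair = sp, seed = seed)
    )
  })
}
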