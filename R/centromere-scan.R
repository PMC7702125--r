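revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Best identity between two tandem-repeat monomers
#'
#' Tandem-repeat consensus monomers are circular (the reported phase is
#' arbitrary) and strand-less. Identity is therefore computed as the best
#' local alignment of one monomer -- and of its reverse complement -- against
#' the other monomer doubled (which contains every rotation), divided by the
#' shorter monomer length.
#'
#' @param m1,m2 Monomer strings.
#' @return Identity fraction in `[0, 1]`.
#' @export
monomer_identity <- function(m1, m2) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  doubled <- Biostrings::DNAString(paste0(m1, m1))
  shorter <- min(nchar(m1), nchar(m2))
  best <- 0
  for (probe in c(m2, revcomp(m2))) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(probe), doubled, type = "local",
      substitutionMatrix = mat, gapOpening = 2, gapExtension = 0.5
    )
    best <- max(best, Biostrings::nmatch(aln) / shorter)
  }
  min(best, 1)
}

#' Cluster tandem-repeat monomers into satellite families
#'
#' Filters repeat records to a period band, then performs single-linkage
#' clustering in which two monomers join when [monomer_identity()] (rotation-
#' and strand-invariant) is at least `min_identity`. Records are canonically
#' sorted before the greedy pass so clustering is independent of input order.
#'
#' @param repeats Tibble from [read_trf_dat()] (columns `chrom`, `start`,
#'   `end`, `period`, `copy_number`, `monomer`).
#' @param min_identity Identity threshold for joining (default 0.80).
#' @param period_range Length-2 vector: monomer periods retained (default
#'   `c(50, 500)` bp, the band containing typical plant centromeric
#'   satellites).
#' @return Tibble of clusters ordered by `total_bases` descending, with
#'   columns `cluster_id`, `representative_monomer`, `monomer_length`,
#'   `n_members`, `total_copies`, `total_bases` and a `members` list-column
#'   of the member records.
#' @export
cluster_monomers <- function(repeats, min_identity = 0.80,
                             period_range = c(50, 500)) {
  kept <- repeats |>
    filter(.data$period >= period_range[[1L]],
           .data$period <= period_range[[2L]]) |>
    arrange(desc(.data$end - .data$start + 1L), .data$chrom, .data$start)
  if (nrow(kept) == 0L) abort("no tandem repeats within period_range")
  n <- nrow(kept)
  parent <- seq_len(n)
  find <- function(i) { while (parent[[i]] != i) i <- parent[[i]]; i }
  if (n > 1L) {
    for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      if (find(i) == find(j)) next
      if (monomer_identity(kept$monomer[[i]], kept$monomer[[j]]) >= min_identity) {
        parent[find(j)] <- find(i)
      }
    }
  }
  comp <- vapply(seq_len(n), find, 0L)
  kept$`..comp` <- comp
  clusters <- kept |>
    group_by(.data$`..comp`) |>
    summarise(
      total_copies = sum(.data$copy_number),
      total_bases = sum(.data$end - .data$start + 1L),
      representative_monomer = .data$monomer[[which.max(.data$copy_number)]],
      n_members = dplyr::n(),
      members = list(dplyr::pick("chrom", "start", "end", "period",
                                 "copy_number", "monomer"))
    ) |>
    ungroup() |>
    arrange(desc(.data$total_bases)) |>
    mutate(cluster_id = paste0("cluster_", row_number()),
           monomer_length = nchar(.data$representative_monomer)) |>
    select("cluster_id", "representative_monomer", "monomer_length",
           "n_members", "total_copies", "total_bases", "members")
  clusters
}

#' Pick the base (centromeric candidate) satellite cluster
#'
#' The cluster covering the most genomic bases; ties broken by the longer
#' representative monomer.
#'
#' @param clusters Tibble from [cluster_monomers()].
#' @return One-row tibble.
#' @export
base_repeat <- function(clusters) {
  if (nrow(clusters) == 0L) abort("no clusters")
  clusters |>
    arrange(desc(.data$total_bases), desc(.data$monomer_length)) |>
    slice(1L)
}

as_dna_set <- function(genome) {
  if (inherits(genome, "DNAStringSet")) return(genome)
  if (is.data.frame(genome)) return(Biostrings::DNAStringSet(setNames(genome$seq, genome$id)))
  if (is.character(genome) && !is.null(names(genome))) {
    return(Biostrings::DNAStringSet(genome))
  }
  abort("genome must be a DNAStringSet, a read_fasta() tibble, or a named character vector")
}

#' Map a satellite monomer across a genome
#'
#' Scans both strands of every chromosome for full-length copies of the
#' monomer, keeping hits with identity at least `min_identity`. The internal
#' scanner ([Biostrings::matchPattern()] with mismatches) reports only
#' full-length matches, so the aligned fraction of the monomer is always 1
#' and `min_coverage` applies when externally produced tabular hits are
#' supplied instead via `hits` (e.g. BLASTN output, mirroring an
#' identity/overlap filter).
#'
#' @param genome A `DNAStringSet`, [read_fasta()] tibble, or named character
#'   vector of chromosome sequences.
#' @param monomer Monomer string (length >= 20).
#' @param min_identity Minimum identity fraction (default 0.80).
#' @param min_coverage Minimum aligned fraction of the monomer (default 0.90).
#' @param hits Optional externally supplied hit table with columns `chrom`,
#'   `start`, `end`, `strand`, `identity`, `coverage`; when given it is
#'   filtered by the two thresholds and returned instead of scanning.
#' @return Tibble with columns `chrom`, `start`, `end`, `strand`, `identity`.
#' @export
map_monomer <- function(genome, monomer, min_identity = 0.80,
                        min_coverage = 0.90, hits = NULL) {
  if (!is.null(hits)) {
    return(hits |>
             filter(.data$identity >= min_identity,
                    .data$coverage >= min_coverage) |>
             select("chrom", "start", "end", "strand", "identity"))
  }
  if (nchar(monomer) < 20L) abort("monomer shorter than minimum seed length (20 bp)")
  set <- as_dna_set(genome)
  len <- nchar(monomer)
  max_mm <- floor((1 - min_identity) * len)
  out <- list()
  for (ch in names(set)) {
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") monomer else revcomp(monomer)
      m <- Biostrings::matchPattern(pat, set[[ch]], max.mismatch = max_mm,
                                    with.indels = FALSE)
      if (length(m) == 0L) next
      mm <- vapply(as.character(m), function(s) {
        sum(strsplit(s, "")[[1L]] != strsplit(pat, "")[[1L]])
      }, 0L, USE.NAMES = FALSE)
      out[[length(out) + 1L]] <- tibble(
        chrom = ch,
        start = BiocGenerics::start(m),
        end = BiocGenerics::end(m),
        strand = strand,
        identity = 1 - mm / len
      )
    }
  }
  if (length(out) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), identity = numeric()))
  }
  # a copy matched on both strands (same start) is kept once, best identity
  bind_rows(out) |>
    group_by(.data$chrom, .data$start) |>
    arrange(desc(.data$identity), .by_group = TRUE) |>
    slice(1L) |>
    ungroup() |>
    arrange(.data$chrom, .data$start)
}

window_densities <- function(hits_ch, chrom_len, window) {
  n_win <- ceiling(chrom_len / window)
  dens <- numeric(n_win)
  if (nrow(hits_ch) > 0L) {
    for (k in seq_len(nrow(hits_ch))) {
      s <- hits_ch$start[[k]]; e <- hits_ch$end[[k]]
      w1 <- (s - 1L) %/% window; w2 <- (e - 1L) %/% window
      for (w in w1:w2) {
        ws <- w * window + 1L; we <- min((w + 1L) * window, chrom_len)
        dens[[w + 1L]] <- dens[[w + 1L]] + max(0L, min(e, we) - max(s, ws) + 1L)
      }
    }
  }
  dens
}

#' Call per-chromosome centromeres from satellite hit density
#'
#' Sums satellite base pairs in non-overlapping windows per chromosome. The
#' maximal window, merged with flanking contiguous windows holding at least
#' half its density, becomes the centromere call; a chromosome whose maximal
#' window carries less than `min_fraction` satellite sequence gets
#' `status = "no_call"` (some chromosomes genuinely lack a density peak).
#'
#' @param hits Tibble from [map_monomer()].
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @param window Window size in bp (default 300000, i.e. 300 kb).
#' @param min_fraction Minimum satellite fraction of the maximal window for a
#'   call (default 0.05).
#' @param monomer Representative monomer of the base repeat; used to report
#'   `monomer_length` and `monomer_gc`.
#' @return Tibble with one row per chromosome in `chrom_lengths`: `chrom`,
#'   `start`, `end`, `peak_density` (satellite bp in the maximal window),
#'   `monomer_length`, `monomer_gc` and `status`.
#' @export
call_centromeres <- function(hits, chrom_lengths, window = 300000L,
                             min_fraction = 0.05, monomer = NULL) {
  if (window <= 0) abort("window must be > 0")
  unknown <- setdiff(unique(hits$chrom), names(chrom_lengths))
  if (length(unknown) > 0L) {
    abort(paste0("chromosome absent from chrom_lengths: ", unknown[[1L]]))
  }
  mono_len <- if (is.null(monomer)) NA_integer_ else nchar(monomer)
  mono_gc <- if (is.null(monomer)) NA_real_ else gc_content(monomer)
  rows <- purrr::imap(chrom_lengths, function(chrom_len, ch) {
    dens <- window_densities(hits[hits$chrom == ch, , drop = FALSE],
                             chrom_len, window)
    peak <- max(dens)
    if (peak / window < min_fraction) {
      return(tibble(chrom = ch, start = NA_integer_, end = NA_integer_,
                    peak_density = peak, monomer_length = mono_len,
                    monomer_gc = mono_gc, status = "no_call"))
    }
    wmax <- which.max(dens)
    lo <- wmax
    while (lo > 1L && dens[[lo - 1L]] >= peak / 2) lo <- lo - 1L
    hi <- wmax
    while (hi < length(dens) && dens[[hi + 1L]] >= peak / 2) hi <- hi + 1L
    tibble(chrom = ch,
           start = (lo - 1L) * window + 1L,
           end = as.integer(min(hi * window, chrom_len)),
           peak_density = peak, monomer_length = mono_len,
           monomer_gc = mono_gc, status = "called")
  })
  bind_rows(rows)
}

#' End-to-end centromere scan
#'
#' Runs the full satellite pipeline: cluster tandem-repeat monomers, pick the
#' base repeat, map it across the genome, and call per-chromosome
#' centromeres.
#'
#' @inheritParams cluster_monomers
#' @inheritParams map_monomer
#' @inheritParams call_centromeres
#' @return List with `clusters`, `base_repeat` (one-row tibble), `hits` and
#'   `calls`.
#' @export
scan_centromeres <- function(genome, repeats, min_identity = 0.80,
                             period_range = c(50, 500), min_coverage = 0.90,
                             window = 300000L, min_fraction = 0.05) {
  set <- as_dna_set(genome)
  clusters <- cluster_monomers(repeats, min_identity = min_identity,
                               period_range = period_range)
  base <- base_repeat(clusters)
  hits <- map_monomer(set, base$representative_monomer[[1L]],
                      min_identity = min_identity, min_coverage = min_coverage)
  calls <- call_centromeres(hits, setNames(Biostrings::width(set), names(set)),
                            window = window, min_fraction = min_fraction,
                            monomer = base$representative_monomer[[1L]])
  list(clusters = clusters, base_repeat = base, hits = hits, calls = calls)
}
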