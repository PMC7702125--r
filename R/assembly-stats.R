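#' Nxx length statistic of an assembly
#'
#' The smallest length L such that sequences of length >= L together cover at
#' least x% of the total assembly (descending-cumulative definition, with an
#' inclusive threshold). N50 is `nxx(lengths, 50)`.
#'
#' @param lengths Positive sequence lengths in bp.
#' @param x Percentage in (0, 100).
#' @return Length in bp.
#' @export
nxx <- function(lengths, x = 50) {
  if (length(lengths) == 0L) abort("empty length set")
  if (any(lengths <= 0)) abort("lengths must be > 0")
  if (x <= 0 || x >= 100) abort("x must be in (0, 100)")
  s <- sort(lengths, decreasing = TRUE)
  target <- sum(s) * x / 100
  s[[which(cumsum(s) >= target)[[1L]]]]
}

#' Round half away from zero to a fixed number of decimals
#'
#' Unlike [base::round()] (banker's rounding), `.5` always rounds up in
#' magnitude -- the convention of printed percentage tables.
#'
#' @param x Numeric.
#' @param decimals Number of decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, decimals = 0L) {
  f <- 10^decimals
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Completeness percentage from found/total counts
#'
#' `100 * found / total`, rounded half-up to `decimals` places -- the
#' arithmetic behind CEGMA/BUSCO completeness, anchoring and annotation
#' rates.
#'
#' @param found Count found (0 <= found <= total).
#' @param total Total count (>= 1).
#' @param decimals Decimal places (default 2).
#' @return Percentage.
#' @export
completeness_percent <- function(found, total, decimals = 2L) {
  if (total < 1) abort("total must be >= 1")
  if (found < 0 || found > total) abort("found must be in [0, total]")
  round_half_up(100 * found / total, decimals)
}

#' GC content of a nucleotide sequence
#'
#' `100 * (G + C) / (A + C + G + T)`; characters outside A/C/G/T are excluded
#' from the denominator.
#'
#' @param seq Nucleotide string.
#' @return GC percentage.
#' @export
gc_content <- function(seq) {
  if (!nzchar(seq)) abort("empty sequence")
  v <- strsplit(toupper(seq), "")[[1L]]
  acgt <- v[v %in% c("A", "C", "G", "T")]
  if (length(acgt) == 0L) abort("no unambiguous A/C/G/T characters")
  100 * sum(acgt %in% c("G", "C")) / length(acgt)
}

#' Assembly summary statistics for a set of sequences
#'
#' @param lengths Positive sequence lengths in bp, or a [read_fasta()] tibble
#'   (lengths are then taken from the sequences and GC content is computed).
#' @return One-row tibble with `n_seqs`, `total_bp`, `max_bp`, `n50`, `n90`
#'   and (when sequences are available) `gc_pct`.
#' @export
assembly_stats <- function(lengths) {
  gc <- NA_real_
  if (is.data.frame(lengths)) {
    seqs <- lengths$seq
    gc <- gc_content(paste(seqs, collapse = ""))
    lengths <- nchar(seqs)
  }
  tibble(
    n_seqs = length(lengths),
    total_bp = sum(lengths),
    max_bp = max(lengths),
    n50 = nxx(lengths, 50),
    n90 = nxx(lengths, 90),
    gc_pct = gc
  )
}
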