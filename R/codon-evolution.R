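#' Fourfold-degenerate codon prefixes of the standard genetic code
#'
#' The eight two-base codon prefixes for which all four third-position
#' nucleotides encode the same amino acid: Ala (GC), Arg (CG), Gly (GG),
#' Leu (CT), Pro (CC), Ser (TC), Thr (AC) and Val (GT).
#' @export
fourfold_prefixes <- c("GC", "CG", "GG", "CT", "CC", "TC", "AC", "GT")

split_codons <- function(seq) {
  n <- nchar(seq)
  substring(seq, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

check_codon_alignment <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b)) abort("aligned sequences differ in length")
  if (nchar(seq_a) %% 3L != 0L) abort("alignment length not divisible by 3")
  if (nchar(seq_a) == 0L) abort("empty alignment")
  invisible(TRUE)
}

#' Identify fourfold-degenerate third-codon-position columns
#'
#' A third-position column of a codon alignment is fourfold degenerate (4D)
#' iff (i) both codons are gap-free and contain only A/C/G/T, (ii) the two
#' codons agree at positions 1 and 2, and (iii) the shared two-base prefix
#' belongs to a fourfold-degenerate synonymous family of the standard genetic
#' code ([fourfold_prefixes]).
#'
#' @param seq_a,seq_b Aligned coding sequences (equal length, multiple of 3).
#' @return Integer vector of 1-based alignment positions of the qualifying
#'   third-codon-position columns.
#' @export
classify_fourfold_sites <- function(seq_a, seq_b) {
  check_codon_alignment(seq_a, seq_b)
  ca <- split_codons(toupper(seq_a))
  cb <- split_codons(toupper(seq_b))
  ok <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  pa <- substr(ca, 1L, 2L)
  pb <- substr(cb, 1L, 2L)
  keep <- ok & pa == pb & pa %in% fourfold_prefixes
  which(keep) * 3L
}

PURINES <- c("A", "G")

#' Count transitions and transversions at fourfold-degenerate sites
#'
#' Per 4D column: A-G and C-T differences are transitions; purine-pyrimidine
#' differences are transversions; identical columns count as neither.
#'
#' @inheritParams classify_fourfold_sites
#' @param sites Integer positions from [classify_fourfold_sites()].
#' @return Named list with `n_transversion` and `n_transition`.
#' @export
count_substitutions_4d <- function(seq_a, seq_b, sites) {
  if (length(sites) == 0L) {
    return(list(n_transversion = 0L, n_transition = 0L))
  }
  a <- substring(toupper(seq_a), sites, sites)
  b <- substring(toupper(seq_b), sites, sites)
  differ <- a != b
  transition <- differ & ((a %in% PURINES) == (b %in% PURINES))
  list(
    n_transversion = sum(differ & !transition),
    n_transition = sum(transition)
  )
}

#' Raw 4DTv: transversions per fourfold-degenerate site
#'
#' @param n_transversion Number of transversion differences at 4D sites.
#' @param n_4d Number of 4D sites.
#' @return `n_transversion / n_4d`, or `NA_real_` when `n_4d` is 0 (the pair
#'   is then excluded from distributions rather than raising an error).
#' @export
raw_4dtv <- function(n_transversion, n_4d) {
  ifelse(n_4d >= 1L, n_transversion / n_4d, NA_real_)
}

#' HKY-consistent distance correction of the raw 4DTv
#'
#' Applies the transversion-distance component shared by the HKY85/TN93
#' model family: with purine frequency \eqn{\pi_R} and pyrimidine frequency
#' \eqn{\pi_Y}, a raw transversion fraction Q is corrected to
#' \deqn{-2 \pi_R \pi_Y \log(1 - Q / (2 \pi_R \pi_Y)),}
#' the expected number of transversions per site. At equal base frequencies
#' this reduces to \eqn{-\frac{1}{2}\log(1 - 2Q)}.
#'
#' @param raw_q Raw 4DTv value(s) in `[0, 1]`.
#' @param base_freqs Length-4 frequency vector (A, C, G, T) pooled over both
#'   sequences at the 4D sites.
#' @return Corrected value(s); `NA_real_` where the correction is saturated
#'   (`raw_q >= 2 * piR * piY`).
#' @export
corrected_4dtv <- function(raw_q, base_freqs = rep(0.25, 4)) {
  if (any(raw_q < 0 | raw_q > 1, na.rm = TRUE)) abort("raw_q must be in [0, 1]")
  piR <- base_freqs[[1L]] + base_freqs[[3L]]
  piY <- base_freqs[[2L]] + base_freqs[[4L]]
  cap <- 2 * piR * piY
  ifelse(!is.na(raw_q) & raw_q < cap, -cap * log(1 - raw_q / cap), NA_real_)
}

#' Full 4DTv computation for one aligned pair
#'
#' @inheritParams classify_fourfold_sites
#' @param pair_id Identifier carried into the result.
#' @return One-row tibble with `pair_id`, `n_4d`, `n_transversion`,
#'   `n_transition`, `raw_4dtv`, `corrected_4dtv`, the pooled 4D-site base
#'   frequencies `pi_a` .. `pi_t`, and a `status` of `"ok"`, `"no_4d_sites"`
#'   or `"saturated"`.
#' @export
pair_4dtv <- function(seq_a, seq_b, pair_id = NA_character_) {
  sites <- classify_fourfold_sites(seq_a, seq_b)
  n_4d <- length(sites)
  if (n_4d == 0L) {
    return(tibble(pair_id = pair_id, n_4d = 0L, n_transversion = 0L,
                  n_transition = 0L, raw_4dtv = NA_real_,
                  corrected_4dtv = NA_real_, pi_a = NA_real_, pi_c = NA_real_,
                  pi_g = NA_real_, pi_t = NA_real_, status = "no_4d_sites"))
  }
  subs <- count_substitutions_4d(seq_a, seq_b, sites)
  pooled <- c(substring(toupper(seq_a), sites, sites),
              substring(toupper(seq_b), sites, sites))
  freqs <- vapply(c("A", "C", "G", "T"), function(b) mean(pooled == b), 0)
  raw <- raw_4dtv(subs$n_transversion, n_4d)
  corr <- corrected_4dtv(raw, freqs)
  tibble(
    pair_id = pair_id, n_4d = n_4d,
    n_transversion = subs$n_transversion, n_transition = subs$n_transition,
    raw_4dtv = raw, corrected_4dtv = corr,
    pi_a = freqs[[1L]], pi_c = freqs[[2L]], pi_g = freqs[[3L]], pi_t = freqs[[4L]],
    status = if (is.na(corr)) "saturated" else "ok"
  )
}

#' Paranome 4DTv distribution and its modal peak
#'
#' Computes per-pair raw and corrected 4DTv for a set of aligned paralog
#' pairs, bins the chosen statistic into fixed-width bins starting at 0, and
#' reports the modal bin midpoint as the distribution peak -- the signature of
#' a whole-genome duplication. Pairs with fewer than `min_4d_sites` 4D sites
#' or with a saturated correction are excluded and counted.
#'
#' @param pairs Data frame with columns `pair_id`, `seq_a`, `seq_b` (aligned,
#'   equal-length, codon-framed sequences).
#' @param min_4d_sites Minimum number of 4D sites for a pair to enter the
#'   distribution (default 10).
#' @param bin_width Histogram bin width (default 0.02).
#' @param value Which statistic to bin: `"corrected"` (default) or `"raw"`.
#' @return An object of class `paranome_4dtv`; see [tidy.paranome_4dtv()],
#'   [glance.paranome_4dtv()] and [autoplot.paranome_4dtv()].
#' @export
paranome_4dtv <- function(pairs, min_4d_sites = 10L, bin_width = 0.02,
                          value = c("corrected", "raw")) {
  value <- match.arg(value)
  if (nrow(pairs) == 0L) abort("no pairs supplied")
  results <- purrr::pmap(
    list(pairs$seq_a, pairs$seq_b, as.character(pairs$pair_id)),
    function(a, b, id) pair_4dtv(a, b, id)
  ) |> bind_rows()
  results$status[results$status != "no_4d_sites" &
                   results$n_4d < min_4d_sites] <- "too_few_sites"
  # saturation only affects the corrected statistic; raw values stay usable
  usable <- if (value == "raw") c("ok", "saturated") else "ok"
  used <- results[results$status %in% usable, , drop = FALSE]
  if (nrow(used) == 0L) abort("no usable pairs after exclusions")
  v <- if (value == "corrected") used$corrected_4dtv else used$raw_4dtv
  bin <- floor(v / bin_width)
  counts <- table(bin)
  hist <- tibble(
    bin_mid = (as.integer(names(counts)) + 0.5) * bin_width,
    count = as.integer(counts)
  ) |> arrange(.data$bin_mid)
  modal <- which(hist$count == max(hist$count))
  structure(
    list(
      pairs = results,
      histogram = hist,
      peak = hist$bin_mid[[modal[[1L]]]],
      peak_tied = length(modal) > 1L,
      value = value,
      bin_width = bin_width,
      min_4d_sites = min_4d_sites,
      n_excluded = sum(!results$status %in% usable)
    ),
    class = "paranome_4dtv"
  )
}

#' @export
print.paranome_4dtv <- function(x, ...) {
  cat("Paranome 4DTv distribution (", x$value, " values)\n", sep = "")
  cat("  pairs used:", sum(x$pairs$status == "ok"),
      " excluded:", x$n_excluded, "\n")
  cat("  peak:", format(x$peak), "(bin width", x$bin_width,
      if (x$peak_tied) ", tied)" else ")", "\n")
  invisible(x)
}

#' Per-pair 4DTv results of a paranome scan
#' @param x A `paranome_4dtv` object.
#' @param ... Unused.
#' @return Tibble with one row per input pair.
#' @export
tidy.paranome_4dtv <- function(x, ...) x$pairs

#' One-row summary of a paranome 4DTv distribution
#' @param x A `paranome_4dtv` object.
#' @param ... Unused.
#' @return One-row tibble with counts, the peak and the tie flag.
#' @export
glance.paranome_4dtv <- function(x, ...) {
  tibble(
    n_pairs = nrow(x$pairs),
    n_used = sum(x$pairs$status == "ok"),
    n_too_few_sites = sum(x$pairs$status == "too_few_sites"),
    n_saturated = sum(x$pairs$status == "saturated"),
    n_no_4d = sum(x$pairs$status == "no_4d_sites"),
    peak = x$peak,
    peak_tied = x$peak_tied,
    bin_width = x$bin_width
  )
}

#' Histogram of a paranome 4DTv distribution
#' @param object A `paranome_4dtv` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.paranome_4dtv <- function(object, ...) {
  ggplot(object$histogram, aes(x = .data$bin_mid, y = .data$count)) +
    geom_col(width = object$bin_width, fill = "steelblue") +
    geom_vline(xintercept = object$peak, linetype = "dashed", colour = "red") +
    labs(x = paste0(object$value, " 4DTv"), y = "paralog pairs",
         title = "Paranome 4DTv distribution",
         subtitle = paste("peak =", format(object$peak))) +
    theme_minimal()
}
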