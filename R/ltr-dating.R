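#' Uncorrected pairwise distance between two aligned LTRs
#'
#' Mismatch fraction over comparable columns. Columns containing a gap or any
#' character outside A/C/G/T in either sequence are excluded from both the
#' numerator and the denominator.
#'
#' @param ltr5,ltr3 Aligned sequences of equal length.
#' @return Mismatch fraction in `[0, 1]`.
#' @export
p_distance <- function(ltr5, ltr3) {
  if (nchar(ltr5) != nchar(ltr3)) abort("aligned LTRs differ in length")
  a <- strsplit(toupper(ltr5), "")[[1L]]
  b <- strsplit(toupper(ltr3), "")[[1L]]
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  if (!any(ok)) abort("no comparable columns (all gapped or ambiguous)")
  sum(a[ok] != b[ok]) / sum(ok)
}

#' Jukes-Cantor distance from an observed mismatch fraction
#'
#' \eqn{K = -\frac{3}{4} \log(1 - \frac{4}{3} p)}, correcting the observed
#' proportion of differing sites for multiple substitutions.
#'
#' @param p Mismatch fraction(s).
#' @return Substitutions per site; `NA_real_` where `p >= 0.75` (saturated).
#' @export
jc_distance <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p must be in [0, 1]")
  ifelse(!is.na(p) & p < 0.75, -0.75 * log(1 - 4 * p / 3), NA_real_)
}

#' LTR insertion time from inter-LTR divergence
#'
#' The two LTRs of a retrotransposon are identical at insertion; each then
#' accumulates substitutions independently, so with divergence `K`
#' (substitutions/site) and substitution rate `r` (substitutions/site/year)
#' the insertion age is \eqn{T = K / (2 r)}.
#'
#' @param K Jukes-Cantor distance(s) between the two LTRs.
#' @param rate Substitution rate per site per year; the default is the
#'   general plant nuclear rate 1.3e-8.
#' @return Age(s) in years.
#' @export
insertion_time <- function(K, rate = 1.3e-8) {
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    abort("rate must be a single positive number")
  }
  if (any(K < 0, na.rm = TRUE)) abort("K must be >= 0")
  K / (2 * rate)
}

#' Globally align an unaligned LTR pair
#'
#' Needleman-Wunsch global alignment with affine gaps (match 1, mismatch -1,
#' gap open 2, gap extend 0.5) via [pwalign::pairwiseAlignment()] /
#' [Biostrings::pairwiseAlignment()].
#'
#' @param ltr5,ltr3 Unaligned nucleotide strings.
#' @return Named list with aligned `ltr5` and `ltr3` strings of equal length.
#' @export
align_ltr_pair <- function(ltr5, ltr3) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(ltr5), Biostrings::DNAString(ltr3),
    type = "global", substitutionMatrix = mat,
    gapOpening = 2, gapExtension = 0.5
  )
  list(
    ltr5 = as.character(Biostrings::alignedPattern(aln)),
    ltr3 = as.character(Biostrings::alignedSubject(aln))
  )
}

#' Date a cohort of LTR retrotransposons
#'
#' Computes, for each element, the uncorrected distance between its two LTRs,
#' the Jukes-Cantor correction, and the insertion age `T = K / (2 r)`.
#'
#' @param pairs Data frame with columns `element_id`, `ltr5`, `ltr3`. When
#'   `aligned = FALSE` the pairs are first aligned with [align_ltr_pair()].
#' @param rate Substitution rate per site per year (default 1.3e-8).
#' @param aligned Are the input pairs already aligned (equal length)?
#' @return Tibble with columns `element_id`, `p`, `K`, `t_years`, `t_mya` and
#'   `status` (`"ok"` or `"saturated"`).
#' @export
ltr_ages <- function(pairs, rate = 1.3e-8, aligned = TRUE) {
  stopifnot(all(c("element_id", "ltr5", "ltr3") %in% names(pairs)))
  rows <- purrr::pmap(
    list(pairs$element_id, pairs$ltr5, pairs$ltr3),
    function(id, a, b) {
      if (!aligned) {
        al <- align_ltr_pair(a, b)
        a <- al$ltr5; b <- al$ltr3
      }
      p <- p_distance(a, b)
      K <- jc_distance(p)
      tibble(element_id = id, p = p, K = K,
             t_years = if (is.na(K)) NA_real_ else insertion_time(K, rate),
             status = if (is.na(K)) "saturated" else "ok")
    }
  )
  bind_rows(rows) |> mutate(t_mya = .data$t_years / 1e6, .before = "status")
}

#' Insertion-age profile of an LTR cohort
#'
#' Bins insertion ages (in Mya) into fixed-width bins starting at 0 and
#' reports the modal bin -- the "burst" age of retrotransposon activity.
#' Saturated elements are excluded and counted separately.
#'
#' @param ages Tibble from [ltr_ages()] (columns `t_mya`, `status`), or a
#'   pairs data frame accepted by [ltr_ages()].
#' @param bin_mya Bin width in Mya (default 0.25).
#' @param rate Substitution rate, used only when raw pairs are supplied.
#' @return An object of class `ltr_age_profile` with `tidy()`, `glance()` and
#'   `autoplot()` methods.
#' @export
age_profile <- function(ages, bin_mya = 0.25, rate = 1.3e-8) {
  if (!"t_mya" %in% names(ages)) ages <- ltr_ages(ages, rate = rate)
  usable <- ages[ages$status == "ok", , drop = FALSE]
  if (nrow(usable) == 0L) abort("no datable elements after exclusions")
  bin <- floor(usable$t_mya / bin_mya)
  counts <- table(bin)
  hist <- tibble(
    bin_mid = (as.integer(names(counts)) + 0.5) * bin_mya,
    count = as.integer(counts)
  ) |> arrange(.data$bin_mid)
  modal <- which(hist$count == max(hist$count))
  structure(
    list(
      ages = ages,
      histogram = hist,
      burst_peak_mya = hist$bin_mid[[modal[[1L]]]],
      peak_tied = length(modal) > 1L,
      bin_mya = bin_mya,
      n_saturated = sum(ages$status == "saturated")
    ),
    class = "ltr_age_profile"
  )
}

#' @export
print.ltr_age_profile <- function(x, ...) {
  cat("LTR insertion-age profile\n")
  cat("  elements dated:", sum(x$ages$status == "ok"),
      " saturated:", x$n_saturated, "\n")
  cat("  burst peak:", format(x$burst_peak_mya), "Mya (bin", x$bin_mya, "Mya)\n")
  invisible(x)
}

#' Per-element ages of an LTR age profile
#' @param x An `ltr_age_profile` object.
#' @param ... Unused.
#' @return Tibble with one row per element.
#' @export
tidy.ltr_age_profile <- function(x, ...) x$ages

#' One-row summary of an LTR age profile
#' @param x An `ltr_age_profile` object.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
glance.ltr_age_profile <- function(x, ...) {
  ok <- x$ages$status == "ok"
  tibble(
    n_elements = nrow(x$ages),
    n_dated = sum(ok),
    n_saturated = x$n_saturated,
    mean_age_mya = mean(x$ages$t_mya[ok]),
    burst_peak_mya = x$burst_peak_mya,
    peak_tied = x$peak_tied,
    bin_mya = x$bin_mya
  )
}

#' Histogram of LTR insertion ages
#' @param object An `ltr_age_profile` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ltr_age_profile <- function(object, ...) {
  ggplot(object$histogram, aes(x = .data$bin_mid, y = .data$count)) +
    geom_col(width = object$bin_mya, fill = "darkgreen") +
    geom_vline(xintercept = object$burst_peak_mya, linetype = "dashed",
               colour = "red") +
    labs(x = "insertion age (Mya)", y = "elements",
         title = "LTR retrotransposon insertion ages",
         subtitle = paste("burst peak =", format(object$burst_peak_mya), "Mya")) +
    theme_minimal()
}
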