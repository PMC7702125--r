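#' HKY85 rate matrix, normalised to one expected substitution per site
#'
#' Builds the HKY85 instantaneous rate matrix with transition/transversion
#' rate ratio `kappa` and stationary base frequencies `freqs`, scaled so the
#' mean substitution rate at stationarity is 1 (branch lengths are then
#' expected substitutions per site).
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param freqs Numeric length-4 vector of stationary frequencies in order
#'   A, C, G, T; must be positive and sum to 1.
#' @return A 4x4 matrix with dimnames `c("A","C","G","T")`.
#' @export
hky_rate_matrix <- function(kappa = 2, freqs = rep(0.25, 4)) {
  check_hky(kappa, freqs)
  bases <- c("A", "C", "G", "T")
  Q <- matrix(0, 4, 4, dimnames = list(bases, bases))
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    Q[i, j] <- if (is_transition(bases[i], bases[j])) kappa * freqs[j] else freqs[j]
  }
  diag(Q) <- -rowSums(Q)
  scale <- -sum(freqs * diag(Q))
  Q / scale
}

check_hky <- function(kappa, freqs) {
  if (!is.numeric(kappa) || length(kappa) != 1L || kappa <= 0) {
    abort("kappa must be a single positive number")
  }
  if (length(freqs) != 4L || any(freqs <= 0) || abs(sum(freqs) - 1) > 1e-8) {
    abort("freqs must be four positive values summing to 1 (order A, C, G, T)")
  }
  invisible(TRUE)
}

is_transition <- function(a, b) {
  (a %in% c("A", "G") && b %in% c("A", "G")) ||
    (a %in% c("C", "T") && b %in% c("C", "T"))
}

#' HKY85 transition-probability matrix P(t) = exp(Qt)
#'
#' Computed by spectral decomposition of the reversible rate matrix
#' (symmetrised with the stationary distribution), which is exact and stable.
#'
#' @inheritParams hky_rate_matrix
#' @param t Branch length in expected substitutions per site (>= 0).
#' @return A 4x4 stochastic matrix over A, C, G, T.
#' @export
hky_pmatrix <- function(t, kappa = 2, freqs = rep(0.25, 4)) {
  if (t < 0) abort("branch length must be >= 0")
  Q <- hky_rate_matrix(kappa, freqs)
  d <- sqrt(freqs)
  S <- diag(d) %*% Q %*% diag(1 / d)
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  P <- diag(1 / d) %*% e$vectors %*% diag(exp(e$values * t)) %*%
    t(e$vectors) %*% diag(d)
  P[P < 0] <- 0
  dimnames(P) <- dimnames(Q)
  P / rowSums(P)
}

#' Expected transversion probability between two sequences at divergence d
#'
#' The probability that a site, stationary at the root and diverged a total
#' of `d` expected substitutions per site under HKY85, shows a
#' purine-pyrimidine difference. This is the quantity the raw 4DTv statistic
#' estimates at fourfold-degenerate sites.
#'
#' @inheritParams hky_rate_matrix
#' @param d Total pairwise divergence in expected substitutions per site.
#' @return A single probability.
#' @export
hky_transversion_prob <- function(d, kappa = 2, freqs = rep(0.25, 4)) {
  P <- hky_pmatrix(d, kappa, freqs)
  bases <- c("A", "C", "G", "T")
  tv <- outer(bases, bases, Vectorize(function(a, b) a != b && !is_transition(a, b)))
  sum(freqs * rowSums(P * tv))
}

#' Fraction of substitutions that are transversions under normalised HKY85
#'
#' At stationarity with the rate matrix scaled to one substitution per site,
#' this is the instantaneous transversion flux; multiplying a total divergence
#' by it gives the expected transversion distance.
#'
#' @inheritParams hky_rate_matrix
#' @return A single fraction in (0, 1).
#' @export
hky_transversion_fraction <- function(kappa = 2, freqs = rep(0.25, 4)) {
  Q <- hky_rate_matrix(kappa, freqs)
  bases <- c("A", "C", "G", "T")
  tv <- outer(bases, bases, Vectorize(function(a, b) a != b && !is_transition(a, b)))
  sum(freqs * rowSums(Q * tv))
}
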