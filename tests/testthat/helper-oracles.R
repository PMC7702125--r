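# Independent brute-force oracles used across tests. These deliberately share
# no code with the implementation: the genetic code comes from Biostrings'
# GENETIC_CODE table and matrix exponentials from Matrix::expm.

# Per-codon-column 4D classifier and substitution counter.
oracle_4d_counts <- function(seq_a, seq_b) {
  gc_table <- Biostrings::GENETIC_CODE
  n_codons <- nchar(seq_a) %/% 3L
  n4d <- 0L; tv <- 0L; ts <- 0L
  for (k in seq_len(n_codons)) {
    ca <- substr(seq_a, 3L * k - 2L, 3L * k)
    cb <- substr(seq_b, 3L * k - 2L, 3L * k)
    if (!grepl("^[ACGT]{3}$", ca) || !grepl("^[ACGT]{3}$", cb)) next
    if (substr(ca, 1L, 2L) != substr(cb, 1L, 2L)) next
    aas <- gc_table[paste0(substr(ca, 1L, 2L), c("A", "C", "G", "T"))]
    if (length(unique(aas)) != 1L) next
    n4d <- n4d + 1L
    b1 <- substr(ca, 3L, 3L); b2 <- substr(cb, 3L, 3L)
    if (b1 != b2) {
      same_class <- (b1 %in% c("A", "G")) == (b2 %in% c("A", "G"))
      if (same_class) ts <- ts + 1L else tv <- tv + 1L
    }
  }
  list(n_4d = n4d, n_transversion = tv, n_transition = ts)
}

# Exact transversion probability at total divergence d under HKY85, via a
# hand-built rate matrix and Matrix::expm (independent of hky_pmatrix's
# spectral route).
oracle_hky_tv_prob <- function(d, kappa = 2, freqs = rep(0.25, 4)) {
  bases <- c("A", "C", "G", "T")
  transition <- function(a, b) {
    (a %in% c("A", "G") && b %in% c("A", "G")) ||
      (a %in% c("C", "T") && b %in% c("C", "T"))
  }
  Q <- matrix(0, 4, 4, dimnames = list(bases, bases))
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    Q[i, j] <- if (transition(bases[i], bases[j])) kappa * freqs[j] else freqs[j]
  }
  diag(Q) <- -rowSums(Q)
  Q <- Q / -sum(freqs * diag(Q))
  P <- as.matrix(Matrix::expm(Q * d))
  tv <- outer(bases, bases,
              Vectorize(function(a, b) a != b && !transition(a, b)))
  sum(freqs * rowSums(P * tv))
}

random_dna <- function(n) paste0(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# Random codon-frame alignment pair with substitutions and occasional
# ambiguity characters, for property tests.
random_codon_pair <- function(n_codons, sub_rate = 0.2, ambig_rate = 0.02) {
  a <- sample(c("A", "C", "G", "T"), 3L * n_codons, TRUE)
  b <- a
  flip <- runif(length(b)) < sub_rate
  b[flip] <- vapply(b[flip], function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1L), "")
  amb <- runif(length(b)) < ambig_rate
  b[amb] <- "N"
  list(seq_a = paste0(a, collapse = ""), seq_b = paste0(b, collapse = ""))
}
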