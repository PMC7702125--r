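counts_to_matrix <- function(counts) {
  if (is.matrix(counts)) return(counts)
  stopifnot(is.data.frame(counts))
  m <- as.matrix(counts[, -1L, drop = FALSE])
  rownames(m) <- counts[[1L]]
  storage.mode(m) <- "double"
  m
}

matrix_to_tibble <- function(m, id_col = "gene_id") {
  as_tibble(m, rownames = id_col)
}

lengths_vector <- function(gene_lengths, genes) {
  if (is.data.frame(gene_lengths)) {
    gene_lengths <- setNames(gene_lengths[[2L]], gene_lengths[[1L]])
  }
  missing <- setdiff(genes, names(gene_lengths))
  if (length(missing) > 0L) {
    abort(paste0("gene length missing for: ", missing[[1L]]))
  }
  gene_lengths[genes]
}

#' RPKM normalisation of a read-count matrix
#'
#' Reads per kilobase of transcript per million mapped reads:
#' `counts * 1e9 / (library_size * gene_length)`.
#'
#' @param counts Genes-by-samples count table: a tibble whose first column is
#'   the gene id, or a numeric matrix with gene rownames.
#' @param gene_lengths Named vector (or two-column data frame) of gene
#'   lengths in bp.
#' @param library_sizes Named vector of mapped-read totals per sample;
#'   defaults to the column sums of `counts`.
#' @return Tibble of the same shape as `counts` (gene id column plus one
#'   numeric column per sample).
#' @export
rpkm <- function(counts, gene_lengths, library_sizes = NULL) {
  m <- counts_to_matrix(counts)
  if (any(m < 0)) abort("counts must be >= 0")
  len <- lengths_vector(gene_lengths, rownames(m))
  if (any(len <= 0)) abort("gene lengths must be > 0")
  if (is.null(library_sizes)) library_sizes <- colSums(m)
  if (is.data.frame(library_sizes)) {
    library_sizes <- setNames(library_sizes[[2L]], library_sizes[[1L]])
  }
  if (!is.null(names(library_sizes))) library_sizes <- library_sizes[colnames(m)]
  if (any(is.na(library_sizes)) || any(library_sizes <= 0)) {
    abort("library sizes must be positive for every sample")
  }
  r <- sweep(sweep(m, 2L, as.numeric(library_sizes), "/"), 1L,
             as.numeric(len), "/") * 1e9
  matrix_to_tibble(r)
}

#' Thresholded log-transform of expression values
#'
#' Returns `log10(x + 1)`, except that values with `x <= 1` are set to 0 --
#' low-expression flooring applied before heat-map display.
#'
#' @param x RPKM value(s), >= 0.
#' @return Transformed value(s).
#' @export
log_expression <- function(x) {
  if (any(x < 0, na.rm = TRUE)) abort("expression values must be >= 0")
  ifelse(x <= 1, 0, log10(x + 1))
}

#' Per-gene fold change between two stages
#'
#' Replicates are averaged on the RPKM scale within each stage; the fold
#' change is `(mean_b + pseudocount) / (mean_a + pseudocount)` and genes are
#' ranked by descending fold.
#'
#' @param rpkm_tbl RPKM tibble from [rpkm()] (gene id column plus samples).
#' @param sample_stages Named character vector mapping sample column names to
#'   stage labels.
#' @param stage_a,stage_b The earlier and later stage labels to compare.
#' @param pseudocount Added to both means (default 1 RPKM).
#' @return Tibble with columns `gene_id`, `mean_a`, `mean_b`, `fold`, `rank`,
#'   sorted by descending fold.
#' @export
stage_fold_change <- function(rpkm_tbl, sample_stages, stage_a, stage_b,
                              pseudocount = 1) {
  m <- counts_to_matrix(rpkm_tbl)
  for (st in c(stage_a, stage_b)) {
    if (!st %in% sample_stages) abort(paste0("stage not present: ", st))
  }
  cols_a <- names(sample_stages)[sample_stages == stage_a]
  cols_b <- names(sample_stages)[sample_stages == stage_b]
  missing <- setdiff(c(cols_a, cols_b), colnames(m))
  if (length(missing) > 0L) abort(paste0("sample column missing: ", missing[[1L]]))
  mean_a <- rowMeans(m[, cols_a, drop = FALSE])
  mean_b <- rowMeans(m[, cols_b, drop = FALSE])
  tibble(
    gene_id = rownames(m),
    mean_a = unname(mean_a),
    mean_b = unname(mean_b),
    fold = unname((mean_b + pseudocount) / (mean_a + pseudocount))
  ) |>
    arrange(desc(.data$fold)) |>
    mutate(rank = row_number())
}

#' Row (per-gene) z-scores of an expression table
#'
#' Standardises each gene across samples: `(x - row mean) / row sd`. Rows
#' with zero variance are set to all zeros and flagged.
#'
#' @param log_tbl Expression tibble (gene id column plus >= 2 sample
#'   columns), typically already log-transformed.
#' @return Tibble of the same shape plus a logical `constant` column.
#' @export
row_zscore <- function(log_tbl) {
  m <- counts_to_matrix(log_tbl)
  if (ncol(m) < 2L) abort("row z-scores need at least 2 samples")
  mu <- rowMeans(m)
  sdv <- apply(m, 1L, sd)
  constant <- sdv == 0
  z <- (m - mu) / ifelse(constant, 1, sdv)
  z[constant, ] <- 0
  matrix_to_tibble(z) |> mutate(constant = unname(constant))
}

#' Relative expression by the 2^-ddCt method
#'
#' For each gene and sample, `dCt = mean(ct_target) - mean(ct_reference)`
#' over replicates; `ddCt = dCt - dCt(calibrator sample)`; relative
#' expression is `2^-ddCt` (1 for the calibrator itself).
#'
#' @param qpcr Tibble with columns `gene`, `sample`, `ct_target`,
#'   `ct_reference`, one row per replicate.
#' @param calibrator_sample Sample label used as the calibrator.
#' @return Tibble with columns `gene`, `sample`, `delta_ct`, `ddct`,
#'   `rel_expr`.
#' @export
ddct <- function(qpcr, calibrator_sample) {
  stopifnot(all(c("gene", "sample", "ct_target", "ct_reference") %in% names(qpcr)))
  if (any(is.na(qpcr$ct_reference))) abort("missing reference Ct value")
  if (!calibrator_sample %in% qpcr$sample) {
    abort(paste0("calibrator sample not present: ", calibrator_sample))
  }
  per <- qpcr |>
    group_by(.data$gene, .data$sample) |>
    summarise(delta_ct = mean(.data$ct_target) - mean(.data$ct_reference),
              .groups = "drop")
  cal <- per |>
    filter(.data$sample == calibrator_sample) |>
    select("gene", cal_delta_ct = "delta_ct")
  missing <- setdiff(unique(per$gene), cal$gene)
  if (length(missing) > 0L) {
    abort(paste0("gene without calibrator measurement: ", missing[[1L]]))
  }
  per |>
    left_join(cal, by = "gene") |>
    mutate(ddct = .data$delta_ct - .data$cal_delta_ct,
           rel_expr = 2^(-.data$ddct)) |>
    select("gene", "sample", "delta_ct", "ddct", "rel_expr")
}
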