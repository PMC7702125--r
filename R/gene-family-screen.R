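#' Two-criterion homology filter for gene-family candidates
#'
#' A gene passes when at least one of its hits simultaneously satisfies
#' `evalue <= max_evalue`, `pct_identity >= min_identity` and
#' `coverage >= min_coverage`. Defaults are the standard screen thresholds
#' (1e-5, 50, 50); boundary values pass.
#'
#' @param hits Tibble from [read_blast_tab()] (columns `query_id`, `evalue`,
#'   `pct_identity`, `coverage`).
#' @param max_evalue Maximum E-value (inclusive; default 1e-5).
#' @param min_identity Minimum percent identity (inclusive; default 50).
#' @param min_coverage Minimum percent query coverage (inclusive; default 50).
#' @return Character vector of passing query ids (sorted, unique).
#' @export
filter_homology <- function(hits, max_evalue = 1e-5, min_identity = 50,
                            min_coverage = 50) {
  if (nrow(hits) == 0L) return(character())
  if (any(is.na(hits$coverage))) abort("coverage must be populated on every hit")
  pass <- hits$evalue <= max_evalue &
    hits$pct_identity >= min_identity &
    hits$coverage >= min_coverage
  sort(unique(hits$query_id[pass]))
}

#' Require candidates to carry the query's Pfam domains
#'
#' A candidate is retained iff its annotated domain set is a superset of the
#' query domains (`mode = "superset"`, the default) or exactly equals it
#' (`mode = "exact"`).
#'
#' @param candidates Character vector of gene ids passing [filter_homology()].
#' @param domains Tibble from [read_domtbl()].
#' @param query_domains Character vector of Pfam accessions (non-empty).
#' @param mode `"superset"` or `"exact"`.
#' @return Character vector of retained gene ids (sorted).
#' @export
require_shared_domains <- function(candidates, domains, query_domains,
                                   mode = c("superset", "exact")) {
  mode <- match.arg(mode)
  if (length(query_domains) == 0L) abort("query_domains must be non-empty")
  keep <- vapply(candidates, function(g) {
    have <- unique(domains$pfam_acc[domains$gene_id == g])
    if (mode == "superset") all(query_domains %in% have)
    else setequal(have, query_domains)
  }, logical(1))
  sort(unname(candidates[keep]))
}

#' Pfam accessions diagnostic of the seven LEA protein groups
#' @export
lea_domain_map <- c(
  PF03760 = "LEA1", PF03168 = "LEA2", PF03242 = "LEA3", PF02987 = "LEA4",
  PF00477 = "LEA5", PF00257 = "dehydrin", PF04927 = "SMP"
)

#' Classify genes into LEA subfamilies by diagnostic Pfam domains
#'
#' Assigns a gene to every LEA group whose diagnostic domain it carries with
#' a domain E-value strictly below `max_evalue` (default 0.01). Genes
#' supported by more than one group are flagged `ambiguous`. Domain rows with
#' accessions outside the LEA map are ignored with a warning.
#'
#' @param domains Tibble from [read_domtbl()].
#' @param max_evalue Strict upper bound on the domain E-value (default 0.01).
#' @return Tibble with columns `gene_id`, `family`, `pfam_acc`,
#'   `domain_evalue`, `ambiguous`, one row per assignment.
#' @export
classify_lea <- function(domains, max_evalue = 0.01) {
  unknown <- setdiff(unique(domains$pfam_acc), names(lea_domain_map))
  if (length(unknown) > 0L) {
    warn(paste0("ignoring non-LEA Pfam accession(s): ",
                paste(unknown, collapse = ", ")))
  }
  hits <- domains |>
    filter(.data$pfam_acc %in% names(lea_domain_map),
           .data$domain_evalue < max_evalue) |>
    mutate(family = unname(lea_domain_map[.data$pfam_acc])) |>
    distinct(.data$gene_id, .data$family, .keep_all = TRUE)
  if (nrow(hits) == 0L) {
    return(tibble(gene_id = character(), family = character(),
                  pfam_acc = character(), domain_evalue = numeric(),
                  ambiguous = logical()))
  }
  hits |>
    group_by(.data$gene_id) |>
    mutate(ambiguous = dplyr::n_distinct(.data$family) > 1L) |>
    ungroup() |>
    select("gene_id", "family", "pfam_acc", "domain_evalue", "ambiguous") |>
    arrange(.data$gene_id, .data$family)
}

#' Detect tandem gene arrays within a family
#'
#' Within each chromosome, family members sorted by start position are
#' chained when consecutive members are within `max_gap_bp` (start-to-start)
#' and separated by at most `max_intervening` non-member genes. Maximal
#' chains of two or more genes are reported with their genomic span.
#'
#' @param members Tibble of family-member gene models (columns `gene_id`,
#'   `chrom`, `start`, `end`).
#' @param all_genes Tibble of all gene models on the same assembly, used to
#'   count intervening non-member genes.
#' @param max_gap_bp Maximum start-to-start distance between consecutive
#'   members of a chain (default 100000).
#' @param max_intervening Maximum number of non-member genes between
#'   consecutive members (default 5).
#' @return Tibble with one row per array: `array_id`, `chrom`, `n_genes`,
#'   `span_bp` (end of last minus start of first), `start`, `end` and a
#'   `gene_ids` list-column.
#' @export
detect_tandem_arrays <- function(members, all_genes, max_gap_bp = 100000L,
                                 max_intervening = 5L) {
  empty <- tibble(array_id = character(), chrom = character(),
                  n_genes = integer(), span_bp = integer(),
                  start = integer(), end = integer(), gene_ids = list())
  if (nrow(members) == 0L) return(empty)
  unknown <- setdiff(unique(members$chrom), unique(all_genes$chrom))
  if (length(unknown) > 0L) {
    abort(paste0("member gene on chromosome unknown to all_genes: ", unknown[[1L]]))
  }
  arrays <- list()
  for (ch in unique(members$chrom)) {
    mem <- members |> filter(.data$chrom == ch) |> arrange(.data$start)
    others <- all_genes |>
      filter(.data$chrom == ch, !.data$gene_id %in% mem$gene_id)
    if (nrow(mem) < 2L) next
    chain_id <- integer(nrow(mem))
    chain_id[[1L]] <- 1L
    for (k in 2:nrow(mem)) {
      gap <- mem$start[[k]] - mem$start[[k - 1L]]
      n_between <- sum(others$start > mem$start[[k - 1L]] &
                         others$start < mem$start[[k]])
      chain_id[[k]] <- if (gap <= max_gap_bp && n_between <= max_intervening) {
        chain_id[[k - 1L]]
      } else {
        chain_id[[k - 1L]] + 1L
      }
    }
    for (cid in unique(chain_id)) {
      rows <- mem[chain_id == cid, , drop = FALSE]
      if (nrow(rows) < 2L) next
      arrays[[length(arrays) + 1L]] <- tibble(
        chrom = ch,
        n_genes = nrow(rows),
        span_bp = rows$end[[nrow(rows)]] - rows$start[[1L]],
        start = rows$start[[1L]],
        end = rows$end[[nrow(rows)]],
        gene_ids = list(rows$gene_id)
      )
    }
  }
  if (length(arrays) == 0L) return(empty)
  bind_rows(arrays) |>
    arrange(.data$chrom, .data$start) |>
    mutate(array_id = paste0("array_", row_number()), .before = 1L)
}

#' Full gene-family screen
#'
#' Chains [filter_homology()] and [require_shared_domains()], then looks for
#' tandem arrays among the called members.
#'
#' @inheritParams filter_homology
#' @inheritParams require_shared_domains
#' @param genes Tibble of gene models from [read_gff3_genes()].
#' @inheritParams detect_tandem_arrays
#' @return List with `members` (character vector) and `arrays` (tibble).
#' @export
screen_family <- function(hits, domains, query_domains, genes,
                          max_evalue = 1e-5, min_identity = 50,
                          min_coverage = 50, max_gap_bp = 100000L,
                          max_intervening = 5L) {
  candidates <- filter_homology(hits, max_evalue, min_identity, min_coverage)
  members <- require_shared_domains(candidates, domains, query_domains)
  member_models <- genes |> filter(.data$gene_id %in% members)
  arrays <- detect_tandem_arrays(member_models, genes,
                                 max_gap_bp = max_gap_bp,
                                 max_intervening = max_intervening)
  list(members = members, arrays = arrays)
}
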