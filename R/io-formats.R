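#' Read a FASTA file into a tibble of sequence records
#'
#' Wraps [Biostrings::readBStringSet()] and normalises the result into the
#' tabular record form used throughout the package. Sequences are upper-cased
#' on read; records whose sequence contains characters outside `A`, `C`, `G`,
#' `T` (gaps, IUPAC ambiguity codes, or protein residues) are kept but marked
#' in the `ambiguous` column so that downstream site classification can skip
#' the affected columns.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `description`, `seq` and `ambiguous`
#'   (logical), one row per record, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) abort(paste0("no records in FASTA file: ", path))
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  if (any(id == "")) abort("FASTA record with empty id")
  dup <- id[duplicated(id)]
  if (length(dup) > 0L) {
    abort(paste0("duplicate FASTA id: ", dup[[1L]]))
  }
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  seq <- toupper(as.character(set))
  if (any(!nzchar(seq))) abort("empty sequence in FASTA file")
  tibble(
    id = unname(id),
    description = unname(description),
    seq = unname(seq),
    ambiguous = grepl("[^ACGT]", seq)
  )
}

#' Write sequence records to a FASTA file
#'
#' Inverse of [read_fasta()] on its own output (byte-stable round trip up to
#' line wrapping).
#'
#' @param records Tibble or data frame with columns `id`, `seq` and optionally
#'   `description`.
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  stopifnot(all(c("id", "seq") %in% names(records)))
  desc <- if ("description" %in% names(records)) records$description
          else rep("", nrow(records))
  header <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  lines <- purrr::map2(header, records$seq, function(h, s) {
    starts <- seq(1L, nchar(s), by = width)
    c(paste0(">", h), substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  })
  writeLines(unlist(lines), path)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Retains only rows of feature type `gene`; coordinates stay 1-based
#' inclusive, the GFF3 convention, which is also this package's internal
#' convention. The `ID` attribute becomes `gene_id`; an optional `family`
#' attribute becomes `family_label`.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end`, `strand`
#'   and `family_label`, in file order.
#' @export
read_gff3_genes <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  keep <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  out <- list()
  for (i in keep) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 9L) abort(paste0("GFF3 line ", i, ": fewer than 9 columns"))
    if (f[[3L]] != "gene") next
    start <- suppressWarnings(as.integer(f[[4L]]))
    end <- suppressWarnings(as.integer(f[[5L]]))
    if (is.na(start) || is.na(end)) {
      abort(paste0("GFF3 line ", i, ": non-numeric coordinates"))
    }
    if (start > end) abort(paste0("GFF3 line ", i, ": start > end"))
    if (start < 1L) abort(paste0("GFF3 line ", i, ": start < 1"))
    if (!f[[7L]] %in% c("+", "-")) {
      abort(paste0("GFF3 line ", i, ": strand must be + or -"))
    }
    attrs <- strsplit(f[[9L]], ";", fixed = TRUE)[[1L]]
    kv <- strsplit(attrs, "=", fixed = TRUE)
    keys <- vapply(kv, `[[`, "", 1L)
    vals <- vapply(kv, function(x) if (length(x) > 1L) x[[2L]] else NA_character_, "")
    if (!"ID" %in% keys) abort(paste0("GFF3 line ", i, ": gene without ID attribute"))
    out[[length(out) + 1L]] <- tibble(
      gene_id = vals[[match("ID", keys)]],
      chrom = f[[1L]],
      start = start,
      end = end,
      strand = f[[7L]],
      family_label = if ("family" %in% keys) vals[[match("family", keys)]] else NA_character_
    )
  }
  if (length(out) == 0L) {
    return(tibble(gene_id = character(), chrom = character(),
                  start = integer(), end = integer(),
                  strand = character(), family_label = character()))
  }
  bind_rows(out)
}

blast6_cols <- c("query_id", "subject_id", "pct_identity", "aln_length",
                 "mismatch", "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore")

#' Read a tabular BLAST (outfmt 6) hit table
#'
#' Reads the standard 12-column tab-separated dialect and joins query lengths
#' to derive per-hit query coverage, `100 * aln_length / query_length` --
#' the quantity the downstream homology filter thresholds.
#'
#' @param path Path to the hit table.
#' @param query_lengths Named numeric vector (or two-column data frame with
#'   columns `id` and `length`) mapping every query id to its length in
#'   residues/bp.
#' @return A tibble with the 12 standard columns plus `query_length` and
#'   `coverage`. An empty file yields an empty tibble.
#' @export
read_blast_tab <- function(path, query_lengths) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (is.data.frame(query_lengths)) {
    query_lengths <- setNames(query_lengths$length, query_lengths$id)
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  if (length(lines) == 0L) {
    return(tibble(!!!setNames(rep(list(character()), 12L), blast6_cols)) |>
             mutate(across(c("pct_identity", "evalue", "bitscore"), as.numeric),
                    across(c("aln_length", "mismatch", "gapopen", "qstart",
                             "qend", "sstart", "send"), as.integer),
                    query_length = numeric(), coverage = numeric()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 12L)
  if (length(bad) > 0L) {
    abort(paste0("BLAST table line ", bad[[1L]], ": fewer than 12 columns"))
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:12))
  num_cols <- 3:12
  numeric_part <- suppressWarnings(apply(m[, num_cols, drop = FALSE], 2, as.numeric))
  numeric_part <- matrix(numeric_part, ncol = length(num_cols))
  bad_row <- which(apply(is.na(numeric_part), 1, any))
  if (length(bad_row) > 0L) {
    abort(paste0("BLAST table line ", bad_row[[1L]], ": non-numeric column"))
  }
  hits <- tibble(
    query_id = m[, 1L], subject_id = m[, 2L],
    pct_identity = numeric_part[, 1L],
    aln_length = as.integer(numeric_part[, 2L]),
    mismatch = as.integer(numeric_part[, 3L]),
    gapopen = as.integer(numeric_part[, 4L]),
    qstart = as.integer(numeric_part[, 5L]),
    qend = as.integer(numeric_part[, 6L]),
    sstart = as.integer(numeric_part[, 7L]),
    send = as.integer(numeric_part[, 8L]),
    evalue = numeric_part[, 9L],
    bitscore = numeric_part[, 10L]
  )
  missing <- setdiff(unique(hits$query_id), names(query_lengths))
  if (length(missing) > 0L) {
    abort(paste0("query id absent from query_lengths: ", missing[[1L]]))
  }
  hits |>
    mutate(query_length = unname(query_lengths[.data$query_id]),
           coverage = 100 * .data$aln_length / .data$query_length)
}

#' Collapse multiple HSPs to one best hit per query-subject pair
#'
#' Keeps, within each query-subject pair, the hit with the lowest E-value,
#' ties broken by the highest bit-score.
#'
#' @param hits Tibble as returned by [read_blast_tab()].
#' @return Tibble with one row per query-subject pair.
#' @export
best_hits <- function(hits) {
  hits |>
    group_by(.data$query_id, .data$subject_id) |>
    arrange(.data$evalue, desc(.data$bitscore), .by_group = TRUE) |>
    slice(1L) |>
    ungroup()
}

#' Write a hit table in tabular BLAST (outfmt 6) form
#'
#' Inverse of [read_blast_tab()] on the 12 standard columns.
#'
#' @param hits Tibble with the 12 standard columns (extra columns such as
#'   `coverage` are dropped).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_blast_tab <- function(hits, path) {
  df <- as.data.frame(hits)[, blast6_cols, drop = FALSE]
  df$evalue <- formatC(df$evalue, format = "g", digits = 6)
  df$pct_identity <- formatC(df$pct_identity, format = "g", digits = 6)
  df$bitscore <- formatC(df$bitscore, format = "g", digits = 6)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write gene models as a GFF3 file
#'
#' Inverse of [read_gff3_genes()].
#'
#' @param genes Tibble with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` and optionally `family_label`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3_genes <- function(genes, path) {
  fam <- if ("family_label" %in% names(genes)) genes$family_label else NA_character_
  attrs <- ifelse(is.na(fam),
                  paste0("ID=", genes$gene_id),
                  paste0("ID=", genes$gene_id, ";family=", fam))
  lines <- c("##gff-version 3",
             paste(genes$chrom, "evoscan", "gene", genes$start, genes$end,
                   ".", genes$strand, ".", attrs, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a Tandem Repeats Finder .dat table
#'
#' Parses the `.dat` dialect: `Sequence: <name>` headers introduce a
#' chromosome, and each subsequent data row carries
#' `start end period copy_number ... consensus`. The consensus monomer is
#' taken as the field whose length equals the stated period (field 14 in the
#' full 15-column TRF output).
#'
#' @param path Path to a `.dat` file.
#' @return A tibble with columns `chrom`, `start`, `end`, `period`,
#'   `copy_number` and `monomer` (1-based inclusive coordinates).
#' @export
read_trf_dat <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  chrom <- NA_character_
  out <- list()
  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]])
    if (!nzchar(line)) next
    if (grepl("^Sequence:", line)) {
      chrom <- trimws(sub("^Sequence:", "", line))
      chrom <- sub("\\s.*$", "", chrom)
      next
    }
    if (grepl("^(Parameters:|Tandem Repeats|Gary Benson|Program written|Please cite|Version|Boston)", line)) next
    f <- strsplit(line, "\\s+")[[1L]]
    first <- suppressWarnings(as.numeric(f[[1L]]))
    if (is.na(first)) next  # free-text banner lines in real TRF output
    if (is.na(chrom)) abort(paste0(".dat line ", i, ": data row before any Sequence header"))
    if (length(f) < 5L) abort(paste0(".dat line ", i, ": too few fields"))
    start <- as.integer(f[[1L]]); end <- as.integer(f[[2L]])
    period <- as.integer(f[[3L]]); copies <- as.numeric(f[[4L]])
    if (any(is.na(c(start, end, period, copies)))) {
      abort(paste0(".dat line ", i, ": non-numeric field"))
    }
    cand <- f[-(1:4)]
    nt <- grepl("^[ACGTNacgtn]+$", cand)
    monomer <- cand[nt & nchar(cand) == period]
    if (length(monomer) == 0L) {
      abort(paste0(".dat line ", i, ": no consensus field of length ", period))
    }
    out[[length(out) + 1L]] <- tibble(
      chrom = chrom, start = start, end = end,
      period = period, copy_number = copies,
      monomer = toupper(monomer[[1L]])
    )
  }
  if (length(out) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  period = integer(), copy_number = numeric(),
                  monomer = character()))
  }
  res <- bind_rows(out)
  bad <- which(res$end - res$start + 1L < res$period)
  if (length(bad) > 0L) {
    abort(paste0("tandem repeat shorter than its period at row ", bad[[1L]]))
  }
  res
}

#' Write tandem-repeat records as a Tandem Repeats Finder .dat table
#'
#' Emits the dialect accepted by [read_trf_dat()]: one `Sequence:` header per
#' chromosome followed by its data rows.
#'
#' @param repeats Tibble with columns `chrom`, `start`, `end`, `period`,
#'   `copy_number`, `monomer`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trf_dat <- function(repeats, path) {
  lines <- character()
  for (ch in unique(repeats$chrom)) {
    lines <- c(lines, paste("Sequence:", ch))
    rows <- repeats[repeats$chrom == ch, , drop = FALSE]
    gc_counts <- vapply(rows$monomer, function(m) {
      v <- strsplit(m, "")[[1L]]
      c(sum(v == "A"), sum(v == "C"), sum(v == "G"), sum(v == "T"))
    }, numeric(4))
    pct <- round(100 * t(gc_counts) / nchar(rows$monomer))
    lines <- c(lines, sprintf(
      "%d %d %d %.1f %d %d %d %d %d %d %d %d %.2f %s %s",
      rows$start, rows$end, rows$period, rows$copy_number,
      rows$period, 95L, 0L, 2L * rows$period,
      pct[, 1L], pct[, 2L], pct[, 3L], pct[, 4L], 1.9,
      rows$monomer, rows$monomer
    ))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an HMMER domain table (domtblout)
#'
#' Parses the whitespace-delimited per-domain table written by
#' `hmmsearch --domtblout`: the target (gene) name from column 1, the query
#' (Pfam) accession from column 5, and the domain independent E-value from
#' column 13. Comment lines starting with `#` are skipped; Pfam accession
#' versions (`PF03760.15`) are stripped to the bare accession.
#'
#' @param path Path to a domtblout file.
#' @return A tibble with columns `gene_id`, `pfam_acc` and `domain_evalue`,
#'   one row per domain hit, in file order.
#' @export
read_domtbl <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  out <- list()
  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]])
    if (!nzchar(line) || grepl("^#", line)) next
    f <- strsplit(line, "\\s+")[[1L]]
    if (length(f) < 13L) abort(paste0("domtblout line ", i, ": fewer than 13 columns"))
    ev <- suppressWarnings(as.numeric(f[[13L]]))
    if (is.na(ev)) abort(paste0("domtblout line ", i, ": non-numeric i-Evalue"))
    if (ev < 0) abort(paste0("domtblout line ", i, ": negative E-value"))
    acc <- sub("\\.\\d+$", "", f[[5L]])
    out[[length(out) + 1L]] <- tibble(
      gene_id = f[[1L]], pfam_acc = acc, domain_evalue = ev
    )
  }
  if (length(out) == 0L) {
    return(tibble(gene_id = character(), pfam_acc = character(),
                  domain_evalue = numeric()))
  }
  bind_rows(out)
}

#' Write a domain table in the dialect accepted by read_domtbl
#' @param domains Tibble with columns `gene_id`, `pfam_acc`, `domain_evalue`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_domtbl <- function(domains, path) {
  header <- "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc"
  rows <- sprintf(
    "%-20s -          400 %-20s %-11s 120 %9.2g  100.0   0.1   1   1 %9.2g %9.2g  100.0   0.1     1   120     1   400     1   400 0.95",
    domains$gene_id, paste0(domains$pfam_acc, "_dom"), domains$pfam_acc,
    domains$domain_evalue, domains$domain_evalue, domains$domain_evalue
  )
  writeLines(c(header, rows), path)
  invisible(path)
}
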