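# Readers and writers for the tabular formats the pipeline touches.
# Matrices, sample metadata and annotation are tab-separated; the
# target-interaction and gene->pathway tables use the comma-separated
# dialect of their upstream resources.

#' Read sample metadata
#'
#' Reads a tab-separated table with columns `sample_id`, `zt_hours`
#' (hours after lights-on, allowed range `[0, 36)`), `replicate`
#' (positive integer) and optionally `group`.
#'
#' @param path path to a TSV file.
#' @return a data.frame with the columns above, class `sample_meta`.
#' @export
read_sample_meta <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_sample_meta(df)
}

#' Validate (or construct) sample metadata
#'
#' @param df a data.frame with at least `sample_id` and `zt_hours`.
#' @return the validated data.frame.
#' @export
validate_sample_meta <- function(df) {
  need <- c("sample_id", "zt_hours")
  miss <- setdiff(need, names(df))
  if (length(miss))
    format_error("sample metadata is missing column(s): %s",
                 paste(miss, collapse = ", "))
  df$sample_id <- trimws(as.character(df$sample_id))
  if (anyDuplicated(df$sample_id))
    format_error("duplicate sample id(s): %s",
                 paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  if (!all(is.finite(df$zt_hours)))
    format_error("zt_hours must be finite")
  if (any(df$zt_hours < 0 | df$zt_hours >= 36))
    format_error("zt_hours must lie in [0, 36)")
  if (is.null(df$replicate)) df$replicate <- 1L
  if (any(df$replicate < 1 | df$replicate != round(df$replicate)))
    format_error("replicate must be a positive integer")
  if (is.null(df$group)) df$group <- ""
  class(df) <- c("sample_meta", "data.frame")
  df
}

#' Read an expression matrix
#'
#' Reads a tab-separated features x samples matrix of non-negative
#' normalized expression (relative units). The first column holds
#' feature ids; the header row holds sample ids. Columns are reordered
#' to follow the metadata order. Any unit of non-negative normalized
#' expression is accepted; the unit is the caller's to record.
#'
#' @param path path to a TSV file.
#' @param metadata sample metadata (see [read_sample_meta()]). Every
#'   sample in the file header must be present in `metadata`.
#' @return a numeric matrix with feature ids as rownames and sample ids
#'   as colnames.
#' @export
read_expression <- function(path, metadata) {
  metadata <- validate_sample_meta(as.data.frame(metadata))
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2)
    format_error("expression file needs a feature-id column plus >= 1 sample column")
  ids <- trimws(as.character(df[[1]]))
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  validate_expression(m, metadata)
}

#' Validate an expression matrix against its metadata
#'
#' Checks the matrix invariants (unique feature and sample ids, no
#' missing cells, all values >= 0, every sample known to the metadata)
#' and reorders columns to the metadata order.
#'
#' @param m numeric matrix, features in rows, samples in columns.
#' @param metadata sample metadata.
#' @return the validated, column-reordered matrix.
#' @export
validate_expression <- function(m, metadata) {
  metadata <- validate_sample_meta(as.data.frame(metadata))
  if (is.null(rownames(m)) || is.null(colnames(m)))
    format_error("expression matrix needs feature rownames and sample colnames")
  if (anyDuplicated(rownames(m)))
    format_error("duplicate feature id(s): %s",
                 paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  if (anyDuplicated(colnames(m)))
    format_error("duplicate sample id(s) in matrix header")
  bad <- which(!is.finite(m) | m < 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    format_error("invalid expression value at feature '%s', sample '%s' (%s)",
                 rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]],
                 format(m[bad[1, , drop = FALSE]]))
  unknown <- setdiff(colnames(m), metadata$sample_id)
  if (length(unknown))
    format_error("sample(s) in matrix absent from metadata: %s",
                 paste(unknown, collapse = ", "))
  keep <- metadata$sample_id[metadata$sample_id %in% colnames(m)]
  m[, keep, drop = FALSE]
}

#' Write an expression matrix
#'
#' Writes a features x samples matrix as tab-separated text with the
#' feature ids in the first column. Values are written at
#' `digits` significant digits, so write-then-read is the identity for
#' values already at that precision.
#'
#' @param m numeric matrix with dimnames.
#' @param path output path.
#' @param digits significant digits to keep (default 6).
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path, digits = 6) {
  df <- data.frame(feature_id = rownames(m),
                   signif(m, digits),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a mature-arm / precursor / locus annotation table
#'
#' Tab-separated columns `mature_id`, `arm` (`5p` or `3p`),
#' `precursor_id`, `locus_id`. Identifiers are whitespace-stripped and
#' case-sensitive. Duplicate (mature, precursor, locus) triples are an
#' error; the arm label must be consistent per mature id.
#'
#' @param path path to a TSV file.
#' @return a validated data.frame.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_annotation(df)
}

#' @rdname read_annotation
#' @param df a data.frame with the annotation columns.
#' @export
validate_annotation <- function(df) {
  need <- c("mature_id", "arm", "precursor_id", "locus_id")
  miss <- setdiff(need, names(df))
  if (length(miss))
    format_error("annotation is missing column(s): %s", paste(miss, collapse = ", "))
  for (col in need) df[[col]] <- trimws(as.character(df[[col]]))
  if (!all(df$arm %in% c("5p", "3p")))
    format_error("arm must be '5p' or '3p'")
  key <- paste(df$mature_id, df$precursor_id, df$locus_id, sep = "\r")
  if (anyDuplicated(key))
    format_error("duplicate (mature_id, precursor_id, locus_id) triple(s)")
  arms <- tapply(df$arm, df$mature_id, function(a) length(unique(a)))
  if (any(arms > 1))
    format_error("inconsistent arm label for mature id(s): %s",
                 paste(names(arms)[arms > 1], collapse = ", "))
  df[need]
}

# normalize a header name: lowercase, non-alphanumerics to "_"
.norm_name <- function(x) gsub("_+", "_", gsub("[^a-z0-9]+", "_", tolower(x)))

#' Read a miRNA target-interaction table
#'
#' Reads a comma-separated table in the dialect of curated
#' target-interaction catalogues: columns for the miRNA id, the target
#' gene symbol and the support type (header matching is tolerant of the
#' upstream capitalisation, e.g. `miRNA`, `Target Gene`,
#' `Support Type`, `Species (miRNA)`). Duplicate interactions are
#' collapsed; rows whose support type is not in `evidence_filter`
#' (when supplied) are dropped — the conventional strong-evidence
#' filter is `c("Functional MTI")`.
#'
#' @param path path to a CSV file.
#' @param evidence_filter optional character vector of support-type
#'   labels to keep; `NULL` keeps everything, an empty vector keeps
#'   nothing.
#' @return a data.frame with columns `mirna_id`, `target_gene`,
#'   `support_type`, `species`.
#' @export
read_targets <- function(path, evidence_filter = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  nm <- .norm_name(names(df))
  pick <- function(cands) {
    i <- which(nm %in% cands)
    if (length(i)) i[1] else NA_integer_
  }
  i_mir <- pick(c("mirna_id", "mirna"))
  i_gene <- pick(c("target_gene", "target_gene_symbol"))
  i_sup <- pick(c("support_type"))
  i_sp <- pick(c("species", "species_mirna"))
  if (is.na(i_mir) || is.na(i_gene) || is.na(i_sup))
    format_error("target table must have miRNA, target gene and support type columns")
  out <- data.frame(
    mirna_id = trimws(df[[i_mir]]),
    target_gene = trimws(df[[i_gene]]),
    support_type = trimws(df[[i_sup]]),
    species = if (!is.na(i_sp)) trimws(df[[i_sp]]) else "",
    stringsAsFactors = FALSE)
  if (any(out$target_gene == ""))
    format_error("empty target gene symbol at row %d",
                 which(out$target_gene == "")[1])
  if (!is.null(evidence_filter))
    out <- out[out$support_type %in% evidence_filter, , drop = FALSE]
  out <- unique(out)
  rownames(out) <- NULL
  out
}

#' Read a gene-to-pathway table
#'
#' Comma-separated columns `gene_symbol`, `pathway_accession`,
#' `pathway_name` (accessions like `P00059` with names like
#' "p53 pathway"). (gene, accession) pairs are deduplicated; empty
#' accessions are an error.
#'
#' @param path path to a CSV file.
#' @return a data.frame with the three columns.
#' @export
read_pathways <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  nm <- .norm_name(names(df))
  need <- c("gene_symbol", "pathway_accession", "pathway_name")
  if (!all(need %in% nm))
    format_error("pathway table must have columns gene_symbol, pathway_accession, pathway_name")
  out <- data.frame(gene_symbol = trimws(df[[which(nm == "gene_symbol")[1]]]),
                    pathway_accession = trimws(df[[which(nm == "pathway_accession")[1]]]),
                    pathway_name = trimws(df[[which(nm == "pathway_name")[1]]]),
                    stringsAsFactors = FALSE)
  if (any(out$pathway_accession == ""))
    format_error("empty pathway accession at row %d",
                 which(out$pathway_accession == "")[1])
  out <- out[!duplicated(out[c("gene_symbol", "pathway_accession")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a data.frame as tab-separated text
#'
#' @param df a data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a full dataset and return a structured report
#'
#' Cross-checks the mature and precursor matrices, annotation and
#' metadata, reporting per-table dimensions and any mature ids missing
#' from the annotation.
#'
#' @param mature,pre expression matrices.
#' @param annotation annotation table.
#' @param meta sample metadata.
#' @return a list with elements `n_mature`, `n_pre`, `n_samples`,
#'   `n_annotation_rows`, `unannotated_mature` and `ok`.
#' @export
validate_dataset <- function(mature, pre, annotation, meta) {
  meta <- validate_sample_meta(as.data.frame(meta))
  mature <- validate_expression(mature, meta)
  pre <- validate_expression(pre, meta)
  annotation <- validate_annotation(annotation)
  unann <- setdiff(rownames(mature), annotation$mature_id)
  list(n_mature = nrow(mature), n_pre = nrow(pre),
       n_samples = ncol(mature),
       n_annotation_rows = nrow(annotation),
       unannotated_mature = unann,
       ok = length(unann) == 0)
}
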