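# File I/O: expression matrices, sample metadata, qRT-PCR tables, rank tables.
# TSV is the canonical dialect; CSV is accepted via `format`. Decimal commas
# are accepted on input (benchmark tables in the literature print "15,5") but
# output always uses ".".

.pr_read_raw <- function(path, format = c("auto", "tsv", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) pr_stop(sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  }
  sep <- if (format == "csv") "," else "\t"
  df <- tryCatch(
    read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
               colClasses = "character", fill = FALSE,
               blank.lines.skip = TRUE, comment.char = ""),
    error = function(e) pr_stop(sprintf("malformed table '%s': %s",
                                        path, conditionMessage(e)))
  )
  df
}

# decimal-comma tolerant numeric parser; returns NA where not numeric
.pr_as_num <- function(x) {
  suppressWarnings(as.numeric(sub(",", ".", x, fixed = TRUE)))
}

#' Read an expression matrix from a delimited file
#'
#' The file must have one header row and one identifier column (the first).
#' A column named `length` (genes-in-rows orientation only) is reserved for
#' gene lengths in bases. Internally the matrix is always held genes x
#' samples; files with samples in rows are transposed on read.
#'
#' @param path path to a TSV (default) or CSV file.
#' @param orientation `"genes_in_rows"` (default) or `"samples_in_rows"`.
#' @param format `"auto"` (by extension), `"tsv"` or `"csv"`.
#' @param unit_tag unit tag to stamp on the result (default `"raw_count"`).
#' @return an [expression_matrix()].
#' @seealso [write_expression_matrix()]
#' @export
read_expression_matrix <- function(path,
                                   orientation = c("genes_in_rows",
                                                   "samples_in_rows"),
                                   format = c("auto", "tsv", "csv"),
                                   unit_tag = "raw_count") {
  orientation <- match.arg(orientation)
  df <- .pr_read_raw(path, format)
  if (ncol(df) < 2L || nrow(df) < 1L) pr_stop(sprintf("empty matrix in '%s'", path))
  ids <- df[[1L]]
  if (anyDuplicated(ids)) {
    pr_stop(sprintf("duplicate identifiers in '%s': %s", path,
                    paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  body <- df[, -1L, drop = FALSE]
  gene_lengths <- NULL
  if (orientation == "genes_in_rows" && "length" %in% names(body)) {
    gl <- .pr_as_num(body[["length"]])
    if (anyNA(gl) || any(gl <= 0)) pr_stop(sprintf("invalid gene length in '%s'", path))
    gene_lengths <- gl
    body <- body[, setdiff(names(body), "length"), drop = FALSE]
  }
  num <- vapply(body, .pr_as_num, numeric(nrow(body)))
  if (!is.matrix(num)) num <- matrix(num, nrow = nrow(body), dimnames = list(NULL, names(body)))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad)) {
    pr_stop(sprintf("non-numeric entry '%s' at row '%s', column '%s' of '%s'",
                    body[bad[1, 1], bad[1, 2]], ids[bad[1, 1]],
                    colnames(num)[bad[1, 2]], path))
  }
  neg <- which(num < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    rn <- ids[neg[1, 1]]; cn <- colnames(num)[neg[1, 2]]
    gene <- if (orientation == "genes_in_rows") rn else cn
    smp  <- if (orientation == "genes_in_rows") cn else rn
    pr_stop(sprintf("negative value %s for gene '%s', sample '%s' in '%s'",
                    format(num[neg[1, 1], neg[1, 2]]), gene, smp, path))
  }
  rownames(num) <- ids
  if (orientation == "samples_in_rows") num <- t(num)
  expression_matrix(num, gene_lengths = gene_lengths, unit_tag = unit_tag)
}

#' Write an expression matrix to a delimited file
#'
#' Genes in rows, identifier column `gene_id` first, then (if present) the
#' reserved `length` column, then one column per sample. Decimal separator is
#' always `"."`.
#'
#' @param m an [expression_matrix()].
#' @param path output path.
#' @param format `"tsv"` (default) or `"csv"`.
#' @export
write_expression_matrix <- function(m, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  v <- m$values
  df <- data.frame(gene_id = rownames(v), check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(m$gene_lengths)) df$length <- unname(m$gene_lengths)
  df <- cbind(df, as.data.frame(v, check.names = FALSE))
  write.table(df, path, sep = if (format == "csv") "," else "\t",
              quote = FALSE, row.names = FALSE, dec = ".")
  invisible(path)
}

#' Read a sample metadata table
#'
#' Requires at least two columns: sample identifier and exposure-group label
#' (columns named `sample_id` and `group_label` are used when present,
#' otherwise the first two columns). Any further columns are kept as
#' covariates. A group census is attached as attribute `"census"`; groups
#' with fewer than 2 samples trigger a classed warning
#' (`"piperank_small_group"`), since cross-validation degrades there —
#' designs with a 3-sample group do occur in published weak-signal studies.
#'
#' @param path path to a TSV/CSV metadata file.
#' @param format `"auto"`, `"tsv"` or `"csv"`.
#' @return data.frame with columns `sample_id`, `group_label` (+ covariates),
#'   attribute `census` = named integer vector of group sizes.
#' @export
read_metadata <- function(path, format = c("auto", "tsv", "csv")) {
  df <- .pr_read_raw(path, match.arg(format))
  if (ncol(df) < 2L) pr_stop(sprintf("metadata '%s' needs >= 2 columns", path))
  nm <- names(df)
  sid_col <- if ("sample_id" %in% nm) "sample_id" else nm[1L]
  grp_col <- if ("group_label" %in% nm) "group_label" else setdiff(nm, sid_col)[1L]
  out <- data.frame(sample_id = df[[sid_col]], group_label = df[[grp_col]],
                    stringsAsFactors = FALSE)
  extra <- setdiff(nm, c(sid_col, grp_col))
  for (cn in extra) out[[cn]] <- df[[cn]]
  validate_metadata(out)
}

#' @rdname read_metadata
#' @param meta a metadata data.frame with `sample_id` and `group_label`.
#' @export
validate_metadata <- function(meta) {
  if (!all(c("sample_id", "group_label") %in% names(meta))) {
    pr_stop("metadata must have sample_id and group_label columns")
  }
  if (anyDuplicated(meta$sample_id)) {
    pr_stop(sprintf("duplicate sample_id in metadata: %s",
                    paste(unique(meta$sample_id[duplicated(meta$sample_id)]),
                          collapse = ", ")))
  }
  census <- table(meta$group_label)
  small <- names(census)[census < 2L]
  if (length(small)) {
    pr_warn(sprintf("group(s) with fewer than 2 samples: %s",
                    paste(small, collapse = ", ")),
            class = "piperank_small_group")
  }
  attr(meta, "census") <- setNames(as.integer(census), names(census))
  meta
}

#' Check that every sample of a matrix is covered by metadata
#'
#' @param m an [expression_matrix()].
#' @param meta metadata data.frame (see [read_metadata()]).
#' @return invisibly, the samples shared (in matrix column order). Samples in
#'   the matrix but absent from metadata raise a data error listing the
#'   orphans.
#' @export
check_sample_coverage <- function(m, meta) {
  orphans <- setdiff(colnames(m$values), meta$sample_id)
  if (length(orphans)) {
    pr_stop(sprintf("samples present in matrix but absent from metadata: %s",
                    paste(orphans, collapse = ", ")), class = "data")
  }
  invisible(intersect(colnames(m$values), meta$sample_id))
}

#' Read a qRT-PCR table
#'
#' Genes in rows (panel genes), control replicates in columns. Values are
#' log-scale relative expression; the package treats them as "larger = more
#' expressed" and makes no assumption about the exact delta-Ct convention.
#' Negative values are allowed (log scale).
#'
#' @param path path to a TSV/CSV table, first column = gene id.
#' @param format `"auto"`, `"tsv"` or `"csv"`.
#' @return numeric matrix, panel genes x replicate samples.
#' @export
read_qpcr <- function(path, format = c("auto", "tsv", "csv")) {
  df <- .pr_read_raw(path, match.arg(format))
  if (ncol(df) < 2L || nrow(df) < 1L) pr_stop(sprintf("empty qPCR table '%s'", path))
  ids <- df[[1L]]
  if (anyDuplicated(ids)) pr_stop(sprintf("duplicate qPCR gene ids in '%s'", path))
  num <- vapply(df[, -1L, drop = FALSE], .pr_as_num, numeric(nrow(df)))
  if (!is.matrix(num)) num <- matrix(num, nrow = nrow(df), dimnames = list(NULL, names(df)[-1L]))
  if (anyNA(num)) pr_stop(sprintf("non-numeric entry in qPCR table '%s'", path))
  rownames(num) <- ids
  num
}

# Rank tables -----------------------------------------------------------

.pa_cols  <- c("Precision", "Accuracy", "Sum", "Rank")
.clf_cols <- c("Rank F1", "Rank NMI", "Sum", "Rank DGE", "Rank")
.stage_cols <- c("Trimming", "Mapping", "Counting", "Normalization")

#' Write a finalized rank table
#'
#' Layout follows the published benchmark tables: pipeline stage columns
#' first, then the mode-specific rank columns — precision/accuracy mode:
#' `Precision, Accuracy, Sum, Rank`; classifier mode:
#' `Rank F1, Rank NMI, Sum, Rank DGE, Rank`. Rows are ordered by final rank,
#' then pipeline label; fractional mid-ranks are written with a period
#' decimal (`15.5`).
#'
#' @param table a `pa_ranking` or `clf_ranking` object (see
#'   [rank_precision_accuracy()], [rank_classifier_ensemble()]), or a
#'   data.frame already in the output schema.
#' @param path output TSV path.
#' @export
write_rank_table <- function(table, path) {
  df <- as.data.frame(table)
  mode <- ranking_mode(df)
  cols <- if (mode == "pa") .pa_cols else .clf_cols
  if (!"Rank" %in% names(df) || anyNA(df$Rank)) {
    pr_stop("rank table not finalized: missing final Rank")
  }
  keep <- c(intersect(.stage_cols, names(df)),
            if (!any(.stage_cols %in% names(df))) "Pipeline", cols)
  keep <- intersect(keep, names(df))
  df <- df[order(df$Rank, .rank_label(df)), keep, drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, dec = ".")
  invisible(path)
}

#' @rdname write_rank_table
#' @export
read_rank_table <- function(path) {
  df <- .pr_read_raw(path, "tsv")
  mode <- ranking_mode(df)
  cols <- if (mode == "pa") .pa_cols else .clf_cols
  for (cn in cols) {
    x <- .pr_as_num(df[[cn]])
    if (anyNA(x)) pr_stop(sprintf("non-numeric '%s' column in rank table '%s'", cn, path))
    df[[cn]] <- x
  }
  attr(df, "mode") <- mode
  df
}

#' @noRd
ranking_mode <- function(df) {
  if (all(.clf_cols %in% names(df))) return("clf")
  if (all(.pa_cols %in% names(df))) return("pa")
  pr_stop("table has neither the precision/accuracy nor the classifier rank columns")
}

# canonical label for a rank-table row, used for deterministic ordering
.rank_label <- function(df) {
  if ("Pipeline" %in% names(df)) return(df$Pipeline)
  if (all(.stage_cols %in% names(df))) {
    return(do.call(paste, c(df[.stage_cols], sep = "+")))
  }
  do.call(paste, c(df[1L], sep = "+"))
}

#' Extract pipeline label / final rank pairs from a rank table
#'
#' @param df a data.frame read by [read_rank_table()] or a ranking object.
#' @return named numeric vector of final ranks, names = pipeline labels.
#' @export
final_ranks <- function(df) {
  df <- as.data.frame(df)
  setNames(as.numeric(df$Rank), .rank_label(df))
}

# Run reports -----------------------------------------------------------

#' Write a versioned JSON run report
#'
#' @param x named list of report fields (seed, config, per-pipeline metrics,
#'   ...); a `schema_version` and package version are added.
#' @param path output path.
#' @export
write_run_report <- function(x, path) {
  x <- c(list(schema_version = 1L,
              piperank_version = as.character(utils::packageVersion("piperank"))),
         x)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
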