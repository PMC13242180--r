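#' Gene-by-sample expression matrix
#'
#' The basic container moved between pipeline stages: a non-negative numeric
#' matrix with genes in rows and samples in columns, optionally carrying
#' per-gene transcript lengths (bases) and per-sample library sizes, plus a
#' unit tag recording which quantification scale the values are on.
#' Normalization functions update the tag; downstream code can therefore
#' refuse, say, TPM input where raw counts are required.
#'
#' @param values numeric matrix, genes x samples, with unique row and column
#'   names; all entries finite and >= 0.
#' @param gene_lengths optional positive numeric vector, one entry per gene
#'   (recycled names checked against rownames).
#' @param library_sizes optional positive numeric vector, one per sample.
#'   When absent, functions that need library sizes use column sums.
#' @param unit_tag one of `"raw_count"`, `"TPM"`, `"FPKM"`, `"coverage"`,
#'   `"TMM_scaled"`, `"RLE_scaled"`, `"UQ_scaled"`.
#' @return An object of class `"expression_matrix"`.
#' @examples
#' m <- expression_matrix(
#'   matrix(rpois(12, 50), 3, 4,
#'          dimnames = list(paste0("g", 1:3), paste0("s", 1:4))),
#'   gene_lengths = c(1000, 2000, 1500)
#' )
#' dim(m)
#' @export
expression_matrix <- function(values, gene_lengths = NULL,
                              library_sizes = NULL, unit_tag = "raw_count") {
  if (!is.matrix(values) || !is.numeric(values)) {
    pr_stop("`values` must be a numeric matrix")
  }
  m <- structure(
    list(values = values, gene_lengths = gene_lengths,
         library_sizes = library_sizes, unit_tag = unit_tag),
    class = "expression_matrix"
  )
  validate_expression_matrix(m)
}

#' @rdname expression_matrix
#' @param m an `expression_matrix`.
#' @export
validate_expression_matrix <- function(m) {
  v <- m$values
  if (nrow(v) == 0L || ncol(v) == 0L) pr_stop("empty expression matrix")
  gid <- rownames(v); sid <- colnames(v)
  if (is.null(gid) || is.null(sid)) {
    pr_stop("expression matrix must have gene rownames and sample colnames")
  }
  if (anyDuplicated(gid)) {
    pr_stop(sprintf("duplicate gene identifiers: %s",
                    paste(unique(gid[duplicated(gid)]), collapse = ", ")))
  }
  if (anyDuplicated(sid)) {
    pr_stop(sprintf("duplicate sample identifiers: %s",
                    paste(unique(sid[duplicated(sid)]), collapse = ", ")))
  }
  bad <- which(!is.finite(v) | v < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    pr_stop(sprintf(
      "invalid expression value %s for gene '%s', sample '%s' (finite, >= 0 required)",
      format(v[bad[1, 1], bad[1, 2]]), gid[bad[1, 1]], sid[bad[1, 2]]))
  }
  if (!is.null(m$gene_lengths)) {
    gl <- m$gene_lengths
    if (length(gl) != nrow(v)) pr_stop("gene_lengths must have one entry per gene")
    if (any(!is.finite(gl) | gl <= 0)) pr_stop("gene_lengths must all be positive")
    if (!is.null(names(gl)) && !identical(names(gl), gid)) {
      pr_stop("gene_lengths names disagree with gene identifiers")
    }
    names(m$gene_lengths) <- gid
  }
  if (!is.null(m$library_sizes)) {
    ls <- m$library_sizes
    if (length(ls) != ncol(v)) pr_stop("library_sizes must have one entry per sample")
    if (any(!is.finite(ls) | ls <= 0)) pr_stop("library_sizes must all be positive")
    names(m$library_sizes) <- sid
  }
  tags <- c("raw_count", "TPM", "FPKM", "coverage",
            "TMM_scaled", "RLE_scaled", "UQ_scaled")
  if (!is.character(m$unit_tag) || length(m$unit_tag) != 1L ||
      !(m$unit_tag %in% tags)) {
    pr_stop(sprintf("unit_tag must be one of: %s", paste(tags, collapse = ", ")))
  }
  m
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples [%s]%s\n",
              nrow(x$values), ncol(x$values), x$unit_tag,
              if (is.null(x$gene_lengths)) "" else ", with gene lengths"))
  print(x$values[seq_len(min(5L, nrow(x$values))),
                 seq_len(min(5L, ncol(x$values))), drop = FALSE])
  if (nrow(x$values) > 5L || ncol(x$values) > 5L) cat("...\n")
  invisible(x)
}

#' @export
as.matrix.expression_matrix <- function(x, ...) x$values

#' Effective library sizes
#'
#' Stored library sizes when present, column sums otherwise.
#' @param m an `expression_matrix`.
#' @return named numeric vector, one entry per sample.
#' @export
library_sizes <- function(m) {
  if (!is.null(m$library_sizes)) return(m$library_sizes)
  colSums(m$values)
}

#' Resolve an evaluation-panel gene list against a matrix
#'
#' Matching is exact after case folding; unresolved genes are reported, never
#' silently dropped.
#'
#' @param genes character vector of panel gene identifiers.
#' @param m an `expression_matrix`.
#' @param error if `TRUE` (default) unresolved genes raise a data error;
#'   otherwise they are returned in `$unmatched`.
#' @return list with `matched` (named character: panel id -> matrix rowname)
#'   and `unmatched` (character).
#' @export
match_panel_genes <- function(genes, m, error = TRUE) {
  idx <- match(tolower(genes), tolower(rownames(m$values)))
  unmatched <- genes[is.na(idx)]
  if (length(unmatched) && error) {
    pr_stop(sprintf("panel genes not found in matrix: %s",
                    paste(unmatched, collapse = ", ")), class = "data")
  }
  matched <- rownames(m$values)[idx[!is.na(idx)]]
  names(matched) <- genes[!is.na(idx)]
  list(matched = matched, unmatched = unmatched)
}

#' Evaluation panel for the precision/accuracy ranking
#'
#' A small set of genes (panel size `P`) measured by the gold-standard method
#' on `n` control replicates. Variance across replicates must be estimable,
#' hence `n >= 3`; `P >= 2` so a median over genes is meaningful.
#'
#' @param gene_ids character vector of panel gene identifiers.
#' @param n number of control replicates the panel was measured on.
#' @return object of class `"evaluation_panel"` with fields `P`, `n`,
#'   `gene_ids`.
#' @export
evaluation_panel <- function(gene_ids, n) {
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(gene_ids)) pr_stop("panel gene ids must be unique")
  if (length(gene_ids) < 2L) pr_stop("panel size P must be >= 2")
  n <- as.integer(n)
  if (is.na(n) || n < 3L) pr_stop("replicate count n must be >= 3")
  structure(list(P = length(gene_ids), n = n, gene_ids = gene_ids),
            class = "evaluation_panel")
}

#' @export
print.evaluation_panel <- function(x, ...) {
  cat(sprintf("evaluation_panel: P = %d genes, n = %d replicates\n", x$P, x$n))
  invisible(x)
}
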