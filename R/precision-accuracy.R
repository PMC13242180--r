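# qRT-PCR-anchored ranking: precision (replicate stability of the expression
# matrix) and accuracy (consistency with the gold-standard panel), combined
# by an equal-weight rank sum. Lower precision statistic = more stable;
# higher accuracy statistic = closer to qRT-PCR.

#' Precision statistic: replicate stability on an evaluation panel
#'
#' Per panel gene, the coefficient of variation (sd / mean, on the normalized
#' scale, not log) of expression across the control replicates; the
#' statistic aggregates the per-gene CVs (median by default, robust at panel
#' sizes around 20). Lower is better. Panel genes with all-zero expression
#' across the controls have an undefined CV and are excluded with a classed
#' warning; if more than half the panel drops out the statistic is refused.
#'
#' @param m an [expression_matrix()] (normalized expression).
#' @param panel an [evaluation_panel()] or character vector of panel genes.
#' @param controls character vector of control replicate sample ids
#'   (>= 3 required).
#' @param aggregate `"median"` (default) or `"mean"`.
#' @return non-negative scalar.
#' @export
precision_stat <- function(m, panel, controls, aggregate = c("median", "mean")) {
  aggregate <- match.arg(aggregate)
  genes <- if (inherits(panel, "evaluation_panel")) panel$gene_ids else as.character(panel)
  missing <- setdiff(controls, colnames(m$values))
  if (length(missing)) {
    pr_stop(sprintf("control sample(s) not in matrix: %s",
                    paste(missing, collapse = ", ")), class = "data")
  }
  if (length(controls) < 3L) pr_stop("need >= 3 control replicates")
  rows <- match_panel_genes(genes, m)$matched
  x <- m$values[rows, controls, drop = FALSE]
  mu <- rowMeans(x)
  zero <- mu == 0
  if (any(zero)) {
    pr_warn(sprintf("panel gene(s) with all-zero expression excluded: %s",
                    paste(names(rows)[zero], collapse = ", ")),
            class = "piperank_panel_dropout")
    if (sum(zero) > length(rows) / 2) {
      pr_stop("more than half the evaluation panel has zero expression",
              class = "data")
    }
    x <- x[!zero, , drop = FALSE]; mu <- mu[!zero]
  }
  cv <- apply(x, 1L, sd) / mu
  if (aggregate == "median") median(cv) else mean(cv)
}

#' Accuracy statistic: consistency with a qRT-PCR gold standard
#'
#' Per gene shared between the matrix and the qRT-PCR table (exact match
#' after case folding), the correlation across shared samples between
#' `log2(expression + 1)` and the qRT-PCR value; the statistic aggregates
#' the per-gene correlations (median by default). Spearman is the default
#' correlation because weak signals break linearity; Pearson is available.
#' Genes with zero variance on either side have an undefined correlation and
#' are excluded with a classed warning.
#'
#' @param m an [expression_matrix()].
#' @param q numeric matrix of qRT-PCR values, panel genes x samples (see
#'   [read_qpcr()]): log-scale, larger = more expressed.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param aggregate `"median"` (default) or `"mean"`.
#' @return scalar in \[-1, 1\].
#' @export
accuracy_stat <- function(m, q, method = c("spearman", "pearson"),
                          aggregate = c("median", "mean")) {
  method <- match.arg(method); aggregate <- match.arg(aggregate)
  gmatch <- match(tolower(rownames(q)), tolower(rownames(m$values)))
  shared_g <- which(!is.na(gmatch))
  if (length(shared_g) < 2L) {
    pr_stop("need >= 2 genes shared between matrix and qPCR table", class = "data")
  }
  shared_s <- intersect(colnames(q), colnames(m$values))
  if (length(shared_s) < 3L) {
    pr_stop("need >= 3 samples shared between matrix and qPCR table", class = "data")
  }
  rs <- vapply(shared_g, function(i) {
    e <- log2(m$values[gmatch[i], shared_s] + 1)
    p <- q[i, shared_s]
    if (sd(e) == 0 || sd(p) == 0) return(NA_real_)
    cor(e, p, method = method)
  }, numeric(1))
  if (anyNA(rs)) {
    pr_warn(sprintf("gene(s) with zero variance excluded from accuracy: %s",
                    paste(rownames(q)[shared_g][is.na(rs)], collapse = ", ")),
            class = "piperank_panel_dropout")
    rs <- rs[!is.na(rs)]
    if (!length(rs)) pr_stop("no gene with defined correlation", class = "data")
  }
  if (aggregate == "median") median(rs) else mean(rs)
}

#' Combine precision/accuracy component ranks into a final ranking
#'
#' The aggregation stage on its own: given per-pipeline precision and
#' accuracy ranks (mid-ranks allowed), the rank sum is their plain sum —
#' equal weighting is literal addition of ranks — and the final rank orders
#' pipelines by ascending rank sum, remaining ties broken lexicographically
#' by label (flagged in `tie_broken_by_label`).
#'
#' @param labels character vector of pipeline labels.
#' @param precision_rank,accuracy_rank numeric component ranks.
#' @return data.frame with `Pipeline`, `Precision`, `Accuracy`, `Sum`,
#'   `Rank`, `tie_broken_by_label`.
#' @export
aggregate_precision_accuracy <- function(labels, precision_rank, accuracy_rank) {
  n <- length(labels)
  if (n < 2L) pr_stop("need >= 2 pipelines to rank")
  stopifnot(length(precision_rank) == n, length(accuracy_rank) == n)
  rank_sum <- precision_rank + accuracy_rank
  o <- order(rank_sum, labels, method = "radix")
  df <- data.frame(Pipeline = labels[o],
                   Precision = precision_rank[o],
                   Accuracy = accuracy_rank[o],
                   Sum = rank_sum[o],
                   Rank = seq_len(n),
                   stringsAsFactors = FALSE)
  df$tie_broken_by_label <- duplicated(df$Sum) | duplicated(df$Sum, fromLast = TRUE)
  df
}

#' Precision/accuracy ranking of a pipeline ensemble
#'
#' Precision statistics are ranked ascending (lower variability = rank 1),
#' accuracy statistics descending (higher gold-standard agreement = rank 1),
#' with mid-ranks for ties — the source of fractional ranks such as 15.5.
#' Rank sum and final rank follow [aggregate_precision_accuracy()].
#'
#' @param stats data.frame with columns `label`, `precision`, `accuracy`
#'   (one row per pipeline), or `NULL` if `ensemble` etc. are given.
#' @param ensemble named list of [expression_matrix()] objects (names =
#'   pipeline labels); used with `qpcr`, `panel`, `controls` to compute the
#'   statistics via [precision_stat()] and [accuracy_stat()].
#' @param qpcr,panel,controls see [accuracy_stat()] and [precision_stat()].
#' @param ... further arguments passed to the two statistic functions
#'   (`method`, `aggregate`).
#' @return object of class `"pa_ranking"`: the aggregation data.frame plus
#'   the raw statistics as columns `precision_stat`, `accuracy_stat`.
#' @export
rank_precision_accuracy <- function(stats = NULL, ensemble = NULL, qpcr = NULL,
                                    panel = NULL, controls = NULL, ...) {
  if (is.null(stats)) {
    if (is.null(ensemble) || is.null(qpcr)) {
      pr_stop("either `stats` or (`ensemble` + `qpcr`) must be given")
    }
    if (is.null(panel)) panel <- rownames(qpcr)
    if (is.null(controls)) controls <- colnames(qpcr)
    stats <- data.frame(
      label = names(ensemble),
      precision = vapply(ensemble, precision_stat, numeric(1),
                         panel = panel, controls = controls),
      accuracy = vapply(ensemble, accuracy_stat, numeric(1), q = qpcr, ...),
      stringsAsFactors = FALSE
    )
  }
  if (nrow(stats) < 2L) pr_stop("need >= 2 pipelines to rank")
  pr_rank <- midrank(stats$precision, "ascending")
  ac_rank <- midrank(stats$accuracy, "descending")
  df <- aggregate_precision_accuracy(stats$label, pr_rank, ac_rank)
  i <- match(df$Pipeline, stats$label)
  df$precision_stat <- stats$precision[i]
  df$accuracy_stat <- stats$accuracy[i]
  structure(list(table = df), class = c("pa_ranking", "pipeline_ranking"))
}

# shared methods for ranking objects -------------------------------------

#' @export
as.data.frame.pipeline_ranking <- function(x, ...) x$table

#' @export
print.pa_ranking <- function(x, ...) {
  cat("Precision/accuracy pipeline ranking\n")
  print(x$table[, c("Pipeline", "Precision", "Accuracy", "Sum", "Rank")],
        row.names = FALSE)
  invisible(x)
}

#' @export
summary.pipeline_ranking <- function(object, ...) {
  df <- object$table
  cat(sprintf("%d pipelines; best: %s (rank sum %.6g)\n",
              nrow(df), df$Pipeline[1L], df$Sum[1L]))
  if (any(df$tie_broken_by_label)) {
    cat(sprintf("rank-sum ties broken lexicographically for: %s\n",
                paste(df$Pipeline[df$tie_broken_by_label], collapse = ", ")))
  }
  invisible(df)
}
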