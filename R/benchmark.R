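# Top-level driver: run both ranking strategies over a pipeline ensemble
# and quantify their concordance.

#' Benchmark a pipeline ensemble by the dual ranking strategy
#'
#' Runs the classifier-based ranking (always) and, when a qRT-PCR gold
#' standard is supplied, the precision/accuracy ranking, then aligns the
#' final ranks and computes their Spearman concordance. qRT-PCR-free
#' operation is first-class: gold-standard panels are frequently unavailable
#' (cost, non-overlapping gene sets), and the classifier ranking needs only
#' the expression matrices and group labels.
#'
#' @param ensemble named list of [expression_matrix()] objects over a shared
#'   sample set; names are the pipeline labels.
#' @param metadata metadata data.frame (see [read_metadata()]).
#' @param qpcr optional qRT-PCR matrix (see [read_qpcr()]).
#' @param panel optional [evaluation_panel()] or gene vector; defaults to
#'   the qPCR table's genes.
#' @param controls optional control sample ids for the precision statistic;
#'   defaults to the qPCR table's samples.
#' @param clf_config a [classifier_config()].
#' @param dge_threshold effect-size threshold for the DGE tie-break.
#' @param ... passed on to [rank_precision_accuracy()] (`method`,
#'   `aggregate`).
#' @return object of class `"pipeline_benchmark"`: list with `classifier`
#'   (a `clf_ranking`), `precision_accuracy` (a `pa_ranking` or `NULL`),
#'   `metrics` (per-pipeline data.frame), `rank_matrix`, `concordance`
#'   (Spearman between the two final rankings, or `NA` without qPCR).
#' @examples
#' base <- generate_base(synthetic_config(n_genes = 300, seed = 7))
#' lad <- emulate_ensemble(base, levels = c(0, 1), seed = 7)
#' cfg <- classifier_config(classifiers = "RF", repeats = 2, seed = 7,
#'                          top_k_features = 50)
#' bm <- benchmark_pipelines(lad$ensemble, base$metadata, clf_config = cfg)
#' bm
#' @export
benchmark_pipelines <- function(ensemble, metadata, qpcr = NULL, panel = NULL,
                                controls = NULL,
                                clf_config = classifier_config(),
                                dge_threshold = 0.8, ...) {
  if (is.null(names(ensemble)) || any(names(ensemble) == "")) {
    pr_stop("`ensemble` must be a fully named list of expression matrices")
  }
  if (length(ensemble) < 2L) pr_stop("need >= 2 pipelines to benchmark")

  # paired design: every pipeline is evaluated under the same seeded fold
  # assignments, so metric differences reflect the matrices, not fold luck
  results <- lapply(ensemble, function(m) {
    r <- cross_validated_metrics(m, metadata, clf_config)
    r$dge <- dge_count(m, metadata, threshold_d = dge_threshold)
    r
  })
  names(results) <- names(ensemble)
  clf <- rank_classifier_ensemble(results)

  pa <- NULL
  if (!is.null(qpcr)) {
    pa <- rank_precision_accuracy(ensemble = ensemble, qpcr = qpcr,
                                  panel = panel, controls = controls, ...)
  }

  metrics <- data.frame(
    label = names(ensemble),
    f1 = vapply(results, function(r) r$pooled_f1, numeric(1)),
    nmi = vapply(results, function(r) r$pooled_nmi, numeric(1)),
    dge_count = vapply(results, function(r) as.integer(r$dge), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )

  tables <- list(classifier = clf)
  if (!is.null(pa)) tables$precision_accuracy <- pa
  rank_matrix <- build_rank_matrix(tables)
  concordance <- if (is.null(pa)) NA_real_ else
    rank_concordance(final_ranks(clf), final_ranks(pa))

  structure(list(classifier = clf, precision_accuracy = pa,
                 metrics = metrics, rank_matrix = rank_matrix,
                 concordance = concordance),
            class = "pipeline_benchmark")
}

#' @export
print.pipeline_benchmark <- function(x, ...) {
  cat("Dual pipeline benchmark\n")
  cat("=======================\n")
  print(x$classifier)
  if (!is.null(x$precision_accuracy)) {
    cat("\n")
    print(x$precision_accuracy)
    cat(sprintf("\nSpearman concordance between strategies: %.3f\n",
                x$concordance))
  } else {
    cat("\n(no qRT-PCR gold standard: precision/accuracy ranking skipped)\n")
  }
  invisible(x)
}

#' @export
summary.pipeline_benchmark <- function(object, ...) {
  cat(sprintf("pipelines: %d\n", nrow(object$metrics)))
  cat(sprintf("classifier winner: %s\n", object$classifier$table$Pipeline[1L]))
  if (!is.null(object$precision_accuracy)) {
    cat(sprintf("precision/accuracy winner: %s\n",
                object$precision_accuracy$table$Pipeline[1L]))
    cat(sprintf("concordance (Spearman): %.3f\n", object$concordance))
  }
  invisible(object$metrics)
}

#' @export
plot.pipeline_benchmark <- function(x, file = NULL, ...) {
  if (is.null(file)) file <- tempfile(fileext = ".png")
  plot_rank_heatmap(x$rank_matrix, file)
  invisible(file)
}
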