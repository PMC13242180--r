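# Classifier-based ranking: repeated stratified cross-validation of RF and
# SVM classifiers on each pipeline's matrix, scored by NMI and macro-F1,
# aggregated by rank sums with a differential-expression effect-size
# tie-break.

#' Configuration for cross-validated classifier evaluation
#'
#' @param classifiers subset of `"RF"`, `"SVM_linear"`, `"SVM_gaussian"`.
#' @param folds number of stratified CV folds (>= 2); silently reduced to
#'   the smallest group size when a group is smaller than `folds`, so
#'   imbalanced designs (e.g. 3 vs 6) degrade gracefully.
#' @param repeats number of CV repetitions (>= 1), each with a fresh seeded
#'   fold assignment.
#' @param seed integer seed; the whole evaluation is reproducible from it.
#' @param feature_transform `"log2p1"` (default: log2(x + 1)) or `"none"`.
#' @param top_k_features keep only the `k` highest-variance features (after
#'   transform), or `NULL` for all. Variance filtering is label-free, so it
#'   cannot leak group information into the ranking.
#' @param num_trees random-forest tree count (default 500).
#' @param pooling `"mean_metric"` (default: mean of the per-classifier
#'   metric, then one rank per metric) or `"rank_sum"` (per-classifier ranks
#'   summed) — how per-classifier results merge into the single F1/NMI rank
#'   columns.
#' @return object of class `"classifier_config"`.
#' @export
classifier_config <- function(classifiers = c("RF", "SVM_linear", "SVM_gaussian"),
                              folds = 5L, repeats = 20L, seed = 1L,
                              feature_transform = c("log2p1", "none"),
                              top_k_features = 500L, num_trees = 500L,
                              pooling = c("mean_metric", "rank_sum")) {
  classifiers <- match.arg(classifiers, several.ok = TRUE)
  if (folds < 2L) pr_stop("folds must be >= 2")
  if (repeats < 1L) pr_stop("repeats must be >= 1")
  structure(list(classifiers = classifiers, folds = as.integer(folds),
                 repeats = as.integer(repeats), seed = as.integer(seed),
                 feature_transform = match.arg(feature_transform),
                 top_k_features = if (is.null(top_k_features)) NULL else as.integer(top_k_features),
                 num_trees = as.integer(num_trees),
                 pooling = match.arg(pooling)),
            class = "classifier_config")
}

# Metrics ----------------------------------------------------------------

#' Normalized mutual information between two labelings
#'
#' `I(T;P) / sqrt(H(T) * H(P))` from the contingency table, natural logs.
#' Degenerate conventions: if both partitions are single-cluster (hence
#' identical as partitions) the value is 1; if exactly one partition is
#' single-cluster (zero entropy) while the other is not, the value is 0.
#'
#' @param labels_true,labels_pred equal-length label vectors.
#' @return scalar in \[0, 1\].
#' @export
nmi <- function(labels_true, labels_pred) {
  if (length(labels_true) != length(labels_pred)) {
    pr_stop("label vectors must have equal length")
  }
  if (length(labels_true) == 0L) pr_stop("label vectors must be non-empty")
  nmi_from_table(table(labels_true, labels_pred))
}

#' @rdname nmi
#' @param tab contingency table (matrix of non-negative counts).
#' @export
nmi_from_table <- function(tab) {
  tab <- as.matrix(tab)
  N <- sum(tab)
  if (N == 0) pr_stop("empty contingency table")
  pi <- rowSums(tab) / N
  pj <- colSums(tab) / N
  Ht <- -sum(ifelse(pi > 0, pi * log(pi), 0))
  Hp <- -sum(ifelse(pj > 0, pj * log(pj), 0))
  if (Ht == 0 && Hp == 0) return(1)
  if (Ht == 0 || Hp == 0) return(0)
  p <- tab / N
  e <- outer(pi, pj)
  mi <- sum(ifelse(p > 0, p * log(p / e), 0))
  val <- mi / sqrt(Ht * Hp)
  min(max(val, 0), 1)
}

#' Macro-averaged F1 score
#'
#' F1 per true class (harmonic mean of precision and recall, 0 when both are
#' undefined), averaged with equal class weight — robust to group imbalance.
#'
#' @inheritParams nmi
#' @return scalar in \[0, 1\].
#' @export
macro_f1 <- function(labels_true, labels_pred) {
  if (length(labels_true) != length(labels_pred)) {
    pr_stop("label vectors must have equal length")
  }
  classes <- unique(as.character(labels_true))
  f1 <- vapply(classes, function(cl) {
    tp <- sum(labels_true == cl & labels_pred == cl)
    fp <- sum(labels_true != cl & labels_pred == cl)
    fn <- sum(labels_true == cl & labels_pred != cl)
    if (2 * tp + fp + fn == 0) return(0)
    2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1)
}

# Cross-validation -------------------------------------------------------

# stratified fold assignment: within each class, shuffle and deal round-robin
.stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

.fit_predict <- function(clf, xtr, ytr, xte, num_trees) {
  if (clf == "RF") {
    fit <- ranger::ranger(x = xtr, y = factor(ytr), num.trees = num_trees,
                          seed = sample.int(.Machine$integer.max, 1L),
                          num.threads = 1L)
    return(as.character(stats::predict(fit, data = xte,
                                       num.threads = 1L)$predictions))
  }
  # SVMs: standardize using training-fold statistics only
  ctr <- colMeans(xtr)
  scl <- apply(xtr, 2L, sd); scl[scl == 0] <- 1
  xtr <- sweep(sweep(xtr, 2L, ctr), 2L, scl, "/")
  xte <- sweep(sweep(xte, 2L, ctr), 2L, scl, "/")
  kern <- if (clf == "SVM_linear") "linear" else "radial"
  fit <- e1071::svm(x = xtr, y = factor(ytr), kernel = kern, scale = FALSE)
  as.character(stats::predict(fit, xte))
}

#' Repeated cross-validated classification metrics for one pipeline
#'
#' The expression matrix is transposed to samples x genes, transformed and
#' variance-filtered per the config, then for each repeat a stratified fold
#' assignment is drawn (seeded) and each configured classifier is trained on
#' the in-fold samples and evaluated on the held-out fold. Out-of-fold
#' predictions are pooled within a repeat, scored by macro-F1 and NMI
#' against the true group labels, and averaged over repeats; the pooled
#' metric is the mean over classifiers. Fully reproducible given
#' `cfg$seed`.
#'
#' @param m an [expression_matrix()].
#' @param meta metadata data.frame (see [read_metadata()]); >= 2 groups and
#'   >= 2 samples per group required.
#' @param cfg a [classifier_config()].
#' @return object of class `"classification_result"`: list with
#'   `per_classifier` (data.frame classifier / f1 / nmi), `pooled_f1`,
#'   `pooled_nmi`, `folds_used`.
#' @export
cross_validated_metrics <- function(m, meta, cfg = classifier_config()) {
  check_sample_coverage(m, meta)
  samples <- colnames(m$values)
  labels <- meta$group_label[match(samples, meta$sample_id)]
  census <- table(labels)
  if (length(census) < 2L) pr_stop("need >= 2 groups for classification", class = "data")
  if (any(census < 2L)) {
    pr_stop(sprintf("group(s) with < 2 samples cannot be cross-validated: %s",
                    paste(names(census)[census < 2L], collapse = ", ")),
            class = "data")
  }
  k <- min(cfg$folds, min(census))
  x <- t(m$values)                                 # samples x genes
  if (cfg$feature_transform == "log2p1") x <- log2(x + 1)
  if (!is.null(cfg$top_k_features) && ncol(x) > cfg$top_k_features) {
    v <- apply(x, 2L, var)
    x <- x[, order(v, decreasing = TRUE)[seq_len(cfg$top_k_features)], drop = FALSE]
  }

  runner <- function() {
    per_rep <- array(NA_real_,
                     dim = c(cfg$repeats, length(cfg$classifiers), 2L),
                     dimnames = list(NULL, cfg$classifiers, c("f1", "nmi")))
    for (r in seq_len(cfg$repeats)) {
      fold <- .stratified_folds(labels, k)
      # every training split must contain every class; redraw once if not
      ok <- all(vapply(seq_len(k), function(f)
        length(unique(labels[fold != f])) == length(census), logical(1)))
      if (!ok) {
        fold <- .stratified_folds(labels, k)
        ok <- all(vapply(seq_len(k), function(f)
          length(unique(labels[fold != f])) == length(census), logical(1)))
        if (!ok) pr_stop("could not draw folds with all classes in training",
                         class = "data")
      }
      for (clf in cfg$classifiers) {
        pred <- character(length(labels))
        for (f in seq_len(k)) {
          te <- fold == f
          pred[te] <- .fit_predict(clf, x[!te, , drop = FALSE], labels[!te],
                                   x[te, , drop = FALSE], cfg$num_trees)
        }
        per_rep[r, clf, "f1"] <- macro_f1(labels, pred)
        per_rep[r, clf, "nmi"] <- nmi(labels, pred)
      }
    }
    per_rep
  }
  per_rep <- .with_seed(cfg$seed, runner())

  per_classifier <- data.frame(
    classifier = cfg$classifiers,
    f1 = colMeans(per_rep[, , "f1", drop = FALSE])[, 1L],
    nmi = colMeans(per_rep[, , "nmi", drop = FALSE])[, 1L],
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(per_classifier = per_classifier,
                 pooled_f1 = mean(per_classifier$f1),
                 pooled_nmi = mean(per_classifier$nmi),
                 folds_used = k),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("classification_result (%d-fold CV): pooled F1 = %.3f, NMI = %.3f\n",
              x$folds_used, x$pooled_f1, x$pooled_nmi))
  print(x$per_classifier, row.names = FALSE)
  invisible(x)
}

# run expr under a local, seeded RNG without disturbing the caller's stream
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Differential-expression effect sizes -----------------------------------

#' Per-gene maximal pairwise effect size (Cohen's d)
#'
#' On `log2(x + 1)` values, for every pair of groups the standardized mean
#' difference (Cohen's d with pooled SD) is computed per gene; the returned
#' statistic is the maximal absolute d over group pairs. A zero pooled SD
#' with equal means gives d = 0; with unequal means, d = Inf (a perfectly
#' consistent shift).
#'
#' @inheritParams cross_validated_metrics
#' @return named numeric vector, one max |d| per gene.
#' @export
dge_effect_sizes <- function(m, meta) {
  check_sample_coverage(m, meta)
  samples <- colnames(m$values)
  labels <- meta$group_label[match(samples, meta$sample_id)]
  groups <- unique(labels)
  if (length(groups) < 2L) pr_stop("need >= 2 groups", class = "data")
  x <- log2(m$values + 1)
  gm <- vapply(groups, function(g) rowMeans(x[, labels == g, drop = FALSE]),
               numeric(nrow(x)))
  gv <- vapply(groups, function(g) {
    xs <- x[, labels == g, drop = FALSE]
    rowSums((xs - rowMeans(xs))^2) / (ncol(xs) - 1L)
  }, numeric(nrow(x)))
  n <- vapply(groups, function(g) sum(labels == g), numeric(1))
  maxd <- rep(0, nrow(x))
  for (i in seq_len(length(groups) - 1L)) for (j in (i + 1L):length(groups)) {
    sp <- sqrt(((n[i] - 1) * gv[, i] + (n[j] - 1) * gv[, j]) / (n[i] + n[j] - 2))
    diff <- abs(gm[, i] - gm[, j])
    d <- ifelse(sp > 0, diff / sp, ifelse(diff > 0, Inf, 0))
    maxd <- pmax(maxd, d)
  }
  setNames(maxd, rownames(x))
}

#' Count of differentially expressed genes by effect size
#'
#' Number of genes whose maximal pairwise |Cohen's d| reaches
#' `threshold_d`. No p-value correction is applied: in weak-signal regimes
#' corrected DE counts are often near zero, which would make the tie-break
#' uninformative.
#'
#' @inheritParams dge_effect_sizes
#' @param threshold_d effect-size threshold (default 0.8, a conventional
#'   "large" effect).
#' @return non-negative integer with attribute `"sum_effect"` (the summed
#'   finite effect sizes, logged so the aggregate-effect reading of the
#'   tie-break stays available).
#' @export
dge_count <- function(m, meta, threshold_d = 0.8) {
  if (!is.numeric(threshold_d) || threshold_d <= 0) {
    pr_stop("threshold_d must be positive")
  }
  d <- dge_effect_sizes(m, meta)
  structure(sum(d >= threshold_d),
            sum_effect = sum(d[is.finite(d)]))
}

# Aggregation ------------------------------------------------------------

#' Combine classifier component ranks into a final ranking
#'
#' The aggregation and tie-break stages on their own, so that published
#' component ranks can be fed through unchanged. Rank sum = F1 rank + NMI
#' rank; pipelines are ordered by ascending rank sum; within groups of equal
#' rank sum only, the DGE rank (ascending) orders them; remaining exact ties
#' are broken lexicographically by label and flagged. The DGE rank never
#' reorders pipelines with distinct rank sums.
#'
#' @param labels character pipeline labels.
#' @param rank_f1,rank_nmi,rank_dge numeric component ranks (mid-ranks
#'   allowed).
#' @return data.frame with `Pipeline`, `Rank F1`, `Rank NMI`, `Sum`,
#'   `Rank DGE`, `Rank`, `tie_broken_by_label`.
#' @export
aggregate_classifier_ranks <- function(labels, rank_f1, rank_nmi, rank_dge) {
  n <- length(labels)
  if (n < 2L) pr_stop("need >= 2 pipelines to rank")
  stopifnot(length(rank_f1) == n, length(rank_nmi) == n, length(rank_dge) == n)
  rank_sum <- rank_f1 + rank_nmi
  o <- order(rank_sum, rank_dge, labels, method = "radix")
  df <- data.frame(Pipeline = labels[o], check.names = FALSE,
                   stringsAsFactors = FALSE)
  df[["Rank F1"]] <- rank_f1[o]
  df[["Rank NMI"]] <- rank_nmi[o]
  df[["Sum"]] <- rank_sum[o]
  df[["Rank DGE"]] <- rank_dge[o]
  df[["Rank"]] <- seq_len(n)
  key <- paste(df$Sum, df[["Rank DGE"]])
  df$tie_broken_by_label <- duplicated(key) | duplicated(key, fromLast = TRUE)
  df
}

#' Classifier-based ranking of a pipeline ensemble
#'
#' Pooled F1 and NMI are ranked descending with mid-ranks for metric ties
#' (rank 1 = highest metric); DGE counts are ranked descending likewise.
#' Aggregation and tie-breaking follow [aggregate_classifier_ranks()].
#'
#' @param results named list (names = pipeline labels) where each element
#'   has `pooled_f1`, `pooled_nmi` (a `"classification_result"`) and a
#'   `dge` count, or a data.frame with columns `label`, `f1`, `nmi`, `dge`.
#' @return object of class `"clf_ranking"` holding the aggregation table
#'   plus the raw metrics.
#' @seealso [benchmark_pipelines()] for the full pipeline-ensemble driver.
#' @export
rank_classifier_ensemble <- function(results) {
  if (is.data.frame(results)) {
    stats <- results
  } else {
    stats <- data.frame(
      label = names(results),
      f1 = vapply(results, function(r) r$pooled_f1, numeric(1)),
      nmi = vapply(results, function(r) r$pooled_nmi, numeric(1)),
      dge = vapply(results, function(r) as.numeric(r$dge), numeric(1)),
      stringsAsFactors = FALSE
    )
  }
  if (nrow(stats) < 2L) pr_stop("need >= 2 pipelines to rank")
  rf1 <- midrank(stats$f1, "descending")
  rnmi <- midrank(stats$nmi, "descending")
  rdge <- midrank(stats$dge, "descending")
  df <- aggregate_classifier_ranks(stats$label, rf1, rnmi, rdge)
  i <- match(df$Pipeline, stats$label)
  df$f1 <- stats$f1[i]; df$nmi <- stats$nmi[i]; df$dge_count <- stats$dge[i]
  structure(list(table = df), class = c("clf_ranking", "pipeline_ranking"))
}

#' @export
print.clf_ranking <- function(x, ...) {
  cat("Classifier-based pipeline ranking\n")
  print(x$table[, c("Pipeline", "Rank F1", "Rank NMI", "Sum", "Rank DGE", "Rank")],
        row.names = FALSE)
  invisible(x)
}
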