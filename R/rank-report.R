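# Rank utilities, concordance between ranking strategies, and the aligned
# rank-matrix heatmap used to compare strategies across a pipeline ensemble.

#' Mid-rank a vector
#'
#' Rank 1 is best in the given direction; tied values share the mean of the
#' positions they occupy (the source of fractional ranks like 15.5).
#'
#' @param values finite numeric vector.
#' @param direction `"ascending"` (small = rank 1) or `"descending"`.
#' @return numeric rank vector.
#' @examples
#' midrank(c(5, 5, 7), "ascending")      # 1.5 1.5 3
#' midrank(c(0.9, 0.8, 0.8), "descending")  # 1 2.5 2.5
#' @export
midrank <- function(values, direction = c("ascending", "descending")) {
  direction <- match.arg(direction)
  if (length(values) == 0L) pr_stop("cannot rank an empty vector")
  if (any(!is.finite(values))) pr_stop("values must be finite")
  if (direction == "descending") values <- -values
  rank(values, ties.method = "average")
}

#' Concordance between two rankings
#'
#' Tie-corrected Spearman correlation between two rank vectors over the same
#' pipelines (matched by name when named).
#'
#' @param a,b numeric rank vectors; when named, `b` is reordered to `a`'s
#'   names and the pipeline sets must coincide.
#' @return scalar in \[-1, 1\].
#' @export
rank_concordance <- function(a, b) {
  if (!is.null(names(a)) || !is.null(names(b))) {
    if (is.null(names(a)) || is.null(names(b)) ||
        !setequal(names(a), names(b))) {
      pr_stop("rankings cover different pipeline sets", class = "data")
    }
    b <- b[names(a)]
  } else if (length(a) != length(b)) {
    pr_stop("rankings cover different pipeline sets", class = "data")
  }
  cor(a, b, method = "spearman")
}

#' Align ranking strategies into a rank matrix, with optional heatmap
#'
#' @param tables named list of rankings: `pa_ranking` / `clf_ranking`
#'   objects, rank-table data.frames (see [read_rank_table()]), or named
#'   rank vectors. All must cover the same pipeline set.
#' @param file optional path: the matrix is written as TSV (pipelines in
#'   rows, strategies in columns).
#' @param heatmap optional path (`.png` or `.pdf`): a single-hue heatmap is
#'   written with low (good) ranks at the dark end. Plot output is a side
#'   effect; analytics always come from the returned matrix / TSV.
#' @return numeric matrix, pipelines x strategies, invisibly when `file` is
#'   given.
#' @export
build_rank_matrix <- function(tables, file = NULL, heatmap = NULL) {
  if (is.null(names(tables)) || any(names(tables) == "")) {
    pr_stop("`tables` must be a fully named list of ranking strategies")
  }
  vecs <- lapply(tables, function(t) {
    if (is.numeric(t) && !is.null(names(t))) t else final_ranks(t)
  })
  ref <- sort(names(vecs[[1L]]))
  for (nm in names(vecs)) {
    if (!setequal(names(vecs[[nm]]), ref)) {
      only <- c(setdiff(names(vecs[[nm]]), ref), setdiff(ref, names(vecs[[nm]])))
      pr_stop(sprintf("pipeline(s) present in one table only: %s",
                      paste(unique(only), collapse = ", ")), class = "data")
    }
  }
  mat <- vapply(vecs, function(v) v[ref], numeric(length(ref)))
  if (!is.matrix(mat)) mat <- matrix(mat, nrow = length(ref),
                                     dimnames = list(ref, names(vecs)))
  rownames(mat) <- ref
  if (!is.null(file)) {
    df <- data.frame(Pipeline = rownames(mat), mat, check.names = FALSE)
    write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(heatmap)) plot_rank_heatmap(mat, heatmap)
  if (is.null(file)) mat else invisible(mat)
}

#' @rdname build_rank_matrix
#' @param mat a rank matrix as returned by `build_rank_matrix`.
#' @export
plot_rank_heatmap <- function(mat, heatmap) {
  pal <- grDevices::colorRampPalette(c("#08306B", "#C6DBEF"))(100)
  ph <- pheatmap::pheatmap(
    mat, color = pal, cluster_cols = FALSE,
    cluster_rows = nrow(mat) > 2,
    show_rownames = nrow(mat) <= 40,
    main = "Pipeline ranks by strategy (dark = high-performing)",
    silent = TRUE
  )
  if (grepl("\\.pdf$", heatmap)) {
    grDevices::pdf(heatmap, width = 6, height = max(4, nrow(mat) * 0.15))
  } else {
    grDevices::png(heatmap, width = 900,
                   height = max(500, nrow(mat) * 16), res = 120)
  }
  grid::grid.newpage()
  grid::grid.draw(ph$gtable)
  grDevices::dev.off()
  invisible(heatmap)
}

#' Pairwise concordance matrix of ranking strategies
#'
#' @inheritParams build_rank_matrix
#' @return symmetric matrix of Spearman concordances with unit diagonal.
#' @export
concordance_matrix <- function(tables) {
  mat <- build_rank_matrix(tables)
  k <- ncol(mat)
  out <- diag(1, k)
  dimnames(out) <- list(colnames(mat), colnames(mat))
  if (k > 1L) {
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      out[i, j] <- out[j, i] <- rank_concordance(mat[, i], mat[, j])
    }
  }
  out
}
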