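# The normalization stage of the pipeline space, implemented from formulas:
# within-sample methods (TPM, FPKM, per-base coverage) and between-sample
# scaling-factor methods (TMM, RLE/median-of-ratios, upper quartile).

.require_counts <- function(m, op) {
  if (m$unit_tag != "raw_count") {
    pr_stop(sprintf("%s requires raw counts, got unit_tag '%s'", op, m$unit_tag),
            class = "data")
  }
}

.require_lengths <- function(m, op) {
  if (is.null(m$gene_lengths)) {
    pr_stop(sprintf("%s requires gene lengths", op), class = "data")
  }
}

#' Transcripts per million
#'
#' Per sample: `rate_g = count_g / length_g`; `TPM_g = 1e6 * rate_g /
#' sum(rate)`. Every TPM column sums to 1e6, so TPM is invariant to
#' sequencing depth within a sample.
#'
#' @param m an [expression_matrix()] with raw counts and gene lengths.
#' @return an `expression_matrix` with `unit_tag = "TPM"`.
#' @export
norm_tpm <- function(m) {
  .require_counts(m, "TPM"); .require_lengths(m, "TPM")
  rate <- m$values / m$gene_lengths
  tot <- colSums(rate)
  if (any(tot == 0)) {
    pr_stop(sprintf("TPM undefined for all-zero sample(s): %s",
                    paste(colnames(m$values)[tot == 0], collapse = ", ")),
            class = "data")
  }
  out <- sweep(rate, 2L, tot, "/") * 1e6
  expression_matrix(out, gene_lengths = m$gene_lengths,
                    library_sizes = m$library_sizes, unit_tag = "TPM")
}

#' Fragments per kilobase per million
#'
#' `FPKM_g = count_g * 1e9 / (length_g * library_size)`; library sizes
#' default to column sums.
#'
#' @inheritParams norm_tpm
#' @export
norm_fpkm <- function(m) {
  .require_counts(m, "FPKM"); .require_lengths(m, "FPKM")
  ls <- library_sizes(m)
  if (any(ls == 0)) {
    pr_stop(sprintf("zero library size for sample(s): %s",
                    paste(colnames(m$values)[ls == 0], collapse = ", ")),
            class = "data")
  }
  out <- sweep(m$values / m$gene_lengths, 2L, ls, "/") * 1e9
  expression_matrix(out, gene_lengths = m$gene_lengths,
                    library_sizes = m$library_sizes, unit_tag = "FPKM")
}

#' Per-base read coverage
#'
#' `coverage_g = count_g * read_length / length_g`: the average number of
#' reads covering each base of the transcript, the per-transcript coverage
#' statistic reported by assembly-based quantifiers.
#'
#' @inheritParams norm_tpm
#' @param read_length positive integer, default 100.
#' @export
norm_coverage <- function(m, read_length = 100) {
  .require_counts(m, "coverage"); .require_lengths(m, "coverage")
  if (!is.numeric(read_length) || length(read_length) != 1L || read_length <= 0) {
    pr_stop("read_length must be a positive number")
  }
  out <- m$values * read_length / m$gene_lengths
  expression_matrix(out, gene_lengths = m$gene_lengths,
                    library_sizes = m$library_sizes, unit_tag = "coverage")
}

# Scaling factors --------------------------------------------------------

#' Between-sample scaling factors
#'
#' Container for TMM / RLE / UQ factors; factors are rescaled so their
#' geometric mean is 1, making them pure composition corrections on top of
#' library size.
#'
#' @param sample_ids character vector.
#' @param factors positive finite numeric vector, same length.
#' @param method `"TMM"`, `"RLE"` or `"UQ"`.
#' @return object of class `"scaling_factors"`.
#' @export
scaling_factors <- function(sample_ids, factors, method) {
  if (length(sample_ids) != length(factors)) pr_stop("one factor per sample required")
  if (any(!is.finite(factors) | factors <= 0)) {
    pr_stop("scaling factors must be finite and > 0", class = "data")
  }
  method <- match.arg(method, c("TMM", "RLE", "UQ"))
  factors <- factors / exp(mean(log(factors)))   # geometric mean 1
  structure(list(sample_ids = as.character(sample_ids),
                 factors = setNames(factors, sample_ids), method = method),
            class = "scaling_factors")
}

#' @export
print.scaling_factors <- function(x, ...) {
  cat(sprintf("scaling_factors (%s):\n", x$method))
  print(signif(x$factors, 5))
  invisible(x)
}

#' Trimmed mean of M-values (TMM) scaling factors
#'
#' For each sample against a reference sample, per-gene log2 expression
#' ratios M and average log2 abundances A are computed over genes nonzero in
#' both (after dividing by library size). The most extreme 30 percent of M
#' values and 5 percent of A values are trimmed on each side, and the factor
#' is 2 to the precision-weighted mean of the remaining M values, with
#' inverse binomial-variance weights. Factors are rescaled to geometric
#' mean 1.
#'
#' @param m an [expression_matrix()] of raw counts, >= 2 samples, each with
#'   at least one nonzero count.
#' @param reference sample id to use as reference, or `NULL` (default) to
#'   pick the sample whose upper-quartile count fraction is closest to the
#'   mean.
#' @param trim_m,trim_a two-sided trim fractions for M and A (defaults 0.30
#'   and 0.05).
#' @return a [scaling_factors()] of method `"TMM"`.
#' @export
tmm_factors <- function(m, reference = NULL, trim_m = 0.30, trim_a = 0.05) {
  .require_counts(m, "TMM")
  v <- m$values
  if (ncol(v) < 2L) pr_stop("TMM needs >= 2 samples")
  ls <- library_sizes(m)
  if (any(colSums(v) == 0)) {
    pr_stop(sprintf("all-zero sample(s): %s",
                    paste(colnames(v)[colSums(v) == 0], collapse = ", ")),
            class = "data")
  }
  if (is.null(reference)) {
    uq <- apply(v, 2L, function(y) quantile(y, 0.75)) / ls
    reference <- colnames(v)[which.min(abs(uq - mean(uq)))]
  } else if (!reference %in% colnames(v)) {
    pr_stop(sprintf("reference sample '%s' not in matrix", reference), class = "data")
  }
  yr <- v[, reference]; nr <- ls[[reference]]
  f <- vapply(colnames(v), function(s) {
    if (s == reference) return(1)
    ys <- v[, s]; ns <- ls[[s]]
    keep <- ys > 0 & yr > 0
    if (!any(keep)) {
      pr_stop(sprintf("sample '%s' shares no nonzero genes with reference '%s'",
                      s, reference), class = "data")
    }
    .tmm_one(ys[keep], yr[keep], ns, nr, trim_m, trim_a)
  }, numeric(1))
  scaling_factors(colnames(v), f, "TMM")
}

# one-sample TMM against a reference; inputs already restricted to genes
# nonzero in both
.tmm_one <- function(ys, yr, ns, nr, trim_m, trim_a) {
  M <- log2((ys / ns) / (yr / nr))
  A <- 0.5 * log2((ys / ns) * (yr / nr))
  w <- 1 / ((ns - ys) / (ns * ys) + (nr - yr) / (nr * yr))
  if (max(abs(M)) < 1e-6) return(1)      # identical composition
  n <- length(M)
  loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
  loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
  rM <- rank(M, ties.method = "first"); rA <- rank(A, ties.method = "first")
  keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(keep)) return(1)
  2^(sum(w[keep] * M[keep]) / sum(w[keep]))
}

#' Relative log expression (median-of-ratios) scaling factors
#'
#' Reference profile = per-gene geometric mean over samples, using only genes
#' nonzero in every sample; each sample's raw size factor is the median over
#' those genes of count / reference. Factors are divided by library size
#' (composition-only, so a pure depth difference gives factor 1 after the
#' geometric-mean rescale) to match the [apply_factors()] convention, which
#' applies the depth adjustment itself.
#'
#' @inheritParams tmm_factors
#' @return a [scaling_factors()] of method `"RLE"`.
#' @export
rle_factors <- function(m) {
  .require_counts(m, "RLE")
  v <- m$values
  allpos <- rowSums(v == 0) == 0L
  if (!any(allpos)) {
    pr_stop("RLE undefined: no gene with nonzero counts in all samples",
            class = "data")
  }
  sub <- v[allpos, , drop = FALSE]
  ref <- exp(rowMeans(log(sub)))
  f <- apply(sub / ref, 2L, median) / library_sizes(m)
  scaling_factors(colnames(v), f, "RLE")
}

#' Upper-quartile scaling factors
#'
#' Per sample, the 75th percentile of nonzero counts divided by library
#' size, rescaled to geometric mean 1.
#'
#' @inheritParams tmm_factors
#' @return a [scaling_factors()] of method `"UQ"`.
#' @export
uq_factors <- function(m) {
  .require_counts(m, "UQ")
  v <- m$values
  ls <- library_sizes(m)
  f <- vapply(seq_len(ncol(v)), function(j) {
    y <- v[, j][v[, j] > 0]
    if (!length(y)) {
      pr_stop(sprintf("all-zero sample '%s'", colnames(v)[j]), class = "data")
    }
    quantile(y, 0.75) / ls[[j]]
  }, numeric(1))
  scaling_factors(colnames(v), f, "UQ")
}

#' Apply between-sample scaling factors
#'
#' Column `s` is divided by `factor_s * library_size_s / mean(library_size)`,
#' i.e. factors correct composition on top of an ordinary depth adjustment.
#'
#' @param m an [expression_matrix()].
#' @param f a [scaling_factors()] covering every sample of `m`.
#' @return an `expression_matrix` with unit tag `"TMM_scaled"`,
#'   `"RLE_scaled"` or `"UQ_scaled"` according to `f$method`.
#' @export
apply_factors <- function(m, f) {
  missing <- setdiff(colnames(m$values), f$sample_ids)
  if (length(missing)) {
    pr_stop(sprintf("no scaling factor for sample(s): %s",
                    paste(missing, collapse = ", ")), class = "data")
  }
  ls <- library_sizes(m)
  eff <- f$factors[colnames(m$values)] * ls / mean(ls)
  out <- sweep(m$values, 2L, eff, "/")
  expression_matrix(out, gene_lengths = m$gene_lengths,
                    library_sizes = m$library_sizes,
                    unit_tag = paste0(f$method, "_scaled"))
}

#' Normalize a count matrix by a named method
#'
#' Dispatcher over the six bundled normalization methods, matching the
#' normalization stage ids of [default_stage_inventory()] (case-insensitive).
#'
#' @param m an [expression_matrix()] of raw counts.
#' @param method one of `"tpm"`, `"fpkm"`, `"coverage"`, `"tmm"`, `"rle"`,
#'   `"uq"`.
#' @param read_length passed to [norm_coverage()].
#' @return a normalized `expression_matrix`.
#' @export
normalize_matrix <- function(m, method, read_length = 100) {
  method <- tolower(method)
  switch(method,
    tpm      = norm_tpm(m),
    fpkm     = norm_fpkm(m),
    coverage = norm_coverage(m, read_length = read_length),
    tmm      = apply_factors(m, tmm_factors(m)),
    rle      = apply_factors(m, rle_factors(m)),
    uq       = apply_factors(m, uq_factors(m)),
    pr_stop(sprintf("unknown normalization method '%s'", method))
  )
}
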