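test_that("precision statistic is the median CV across control replicates", {
  # gene A: mean 1, sd 0.1; gene B: mean 1, sd 0.3 -> CVs 0.1 and 0.3
  v <- rbind(gA = c(0.9, 1.0, 1.1), gB = c(0.7, 1.0, 1.3))
  colnames(v) <- paste0("c", 1:3)
  m <- em(v, unit = "TPM")
  expect_equal(precision_stat(m, c("gA", "gB"), paste0("c", 1:3)), 0.2)
  expect_equal(precision_stat(m, c("gA", "gB"), paste0("c", 1:3),
                              aggregate = "mean"), 0.2)

  const <- em(matrix(5, 3, 4), unit = "TPM")
  expect_equal(precision_stat(const, rownames(const$values),
                              colnames(const$values)), 0)

  # CV is scale invariant
  m10 <- em(10 * v, unit = "TPM")
  expect_equal(precision_stat(m10, c("gA", "gB"), paste0("c", 1:3)), 0.2)
})

test_that("all-zero panel genes are excluded with a warning, en masse an error", {
  v <- rbind(gA = c(1, 2, 3), gB = c(0, 0, 0), gC = c(2, 2, 2))
  colnames(v) <- paste0("c", 1:3)
  m <- em(v)
  expect_warning(precision_stat(m, c("gA", "gB", "gC"), paste0("c", 1:3)),
                 class = "piperank_panel_dropout")
  v2 <- rbind(gA = c(1, 2, 3), gB = c(0, 0, 0), gC = c(0, 0, 0))
  colnames(v2) <- paste0("c", 1:3)
  expect_error(
    suppressWarnings(precision_stat(em(v2), c("gA", "gB", "gC"), paste0("c", 1:3))),
    class = "piperank_data_error")
  # unresolved panel genes are an error, not silently dropped
  expect_error(precision_stat(m, c("gA", "gX"), paste0("c", 1:3)),
               "gX", class = "piperank_data_error")
})

test_that("accuracy statistic hits 1 / -1 at perfect agreement / inversion", {
  set.seed(21)
  q <- matrix(runif(15, 0, 10), 3, 5,
              dimnames = list(c("gA", "gB", "gC"), paste0("c", 1:5)))
  perfect <- em(from_log2(q))
  expect_equal(accuracy_stat(perfect, q), 1)
  inverted <- em(from_log2(10 - q))
  expect_equal(accuracy_stat(inverted, q), -1)
  # case-folded gene matching
  qq <- q; rownames(qq) <- toupper(rownames(qq))
  expect_equal(accuracy_stat(perfect, qq), 1)
})

test_that("accuracy aggregates per-gene correlations by their median", {
  set.seed(22)
  e <- matrix(rlnorm(8 * 5, 4, 1), 5, 8,
              dimnames = list(paste0("g", 1:5), paste0("c", 1:8)))
  q <- log2(e + 1) + matrix(rnorm(40, 0, 1.5), 5, 8)
  m <- em(e)
  for (meth in c("spearman", "pearson")) {
    oracle <- median(vapply(1:5, function(i)
      cor(log2(e[i, ] + 1), q[i, ], method = meth), numeric(1)))
    expect_equal(accuracy_stat(m, q, method = meth), oracle)
  }
  # zero-variance gene dropped with warning
  e2 <- e; e2[2, ] <- 3
  expect_warning(accuracy_stat(em(e2), q), class = "piperank_panel_dropout")
})

test_that("rank sums add component ranks and final rank orders by the sum", {
  agg <- aggregate_precision_accuracy(c("pipeA", "pipeB"), c(15.5, 23), c(25, 19))
  expect_equal(agg$Sum, c(40.5, 42))
  expect_equal(agg$Rank, 1:2)
  expect_equal(agg$Pipeline, c("pipeA", "pipeB"))
  expect_error(aggregate_precision_accuracy("solo", 1, 1),
               class = "piperank_validation_error")
})

test_that("mid-ranks conserve total rank mass and break stat ties fairly", {
  set.seed(23)
  for (i in 1:10) {
    n <- sample(4:12, 1)
    stats <- data.frame(
      label = sprintf("p%02d", 1:n),
      precision = sample(round(runif(n, 0, 1), 1), n, replace = FALSE),
      accuracy = round(runif(n, -1, 1), 1))
    r <- as.data.frame(rank_precision_accuracy(stats))
    expect_equal(sum(r$Precision), n * (n + 1) / 2)
    expect_equal(sum(r$Accuracy), n * (n + 1) / 2)
    expect_identical(sort(r$Rank), 1:n)          # permutation of 1..N
    expect_true(all(diff(r$Sum) >= 0))           # final rank monotone in sum
  }
  # two pipelines tied on precision among N = 4 share mid-rank 1.5
  stats <- data.frame(label = c("a", "b", "c", "d"),
                      precision = c(0.1, 0.1, 0.5, 0.9),
                      accuracy = c(0.9, 0.8, 0.7, 0.6))
  r <- as.data.frame(rank_precision_accuracy(stats))
  expect_equal(sort(r$Precision[r$Pipeline %in% c("a", "b")]), c(1.5, 1.5))
})

test_that("a pipeline identical to the gold standard attains accuracy rank 1", {
  set.seed(24)
  q <- matrix(runif(4 * 6, 1, 9), 4, 6,
              dimnames = list(paste0("g", 1:4), paste0("c", 1:6)))
  ens <- list(
    perfect = em(from_log2(q)),
    noisy   = em(from_log2(pmax(q + matrix(rnorm(24, 0, 2), 4, 6), 0))),
    inverse = em(from_log2(10 - q))
  )
  r <- as.data.frame(rank_precision_accuracy(ensemble = ens, qpcr = q))
  expect_equal(r$Accuracy[r$Pipeline == "perfect"], 1)
})
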