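test_that("TPM matches hand-derived values and its defining invariants", {
  m1 <- em(matrix(c(10, 10), 2, 1), lengths = c(1000, 2000))
  expect_equal(unname(norm_tpm(m1)$values[, 1]),
               c(666666.67, 333333.33), tolerance = 1e-8)
  expect_identical(norm_tpm(m1)$unit_tag, "TPM")

  single <- em(matrix(7, 1, 2), lengths = 500)
  expect_equal(unname(norm_tpm(single)$values), matrix(1e6, 1, 2), ignore_attr = TRUE)

  set.seed(5)
  m <- em(rand_counts(50, 6, seed = 5), lengths = round(runif(50, 300, 5000)))
  tp <- norm_tpm(m)
  expect_equal(unname(colSums(tp$values)), rep(1e6, 6), tolerance = 1e-6)

  # depth invariance: doubling a sample's counts leaves its TPM unchanged
  v2 <- m$values; v2[, 3] <- v2[, 3] * 2
  tp2 <- norm_tpm(em(v2, lengths = m$gene_lengths))
  expect_equal(tp2$values[, 3], tp$values[, 3])

  bad <- em(cbind(s1 = c(1, 2), s2 = c(0, 0)), lengths = c(100, 100))
  err <- expect_error(norm_tpm(bad), class = "piperank_data_error")
  expect_match(conditionMessage(err), "s2")
})

test_that("FPKM follows its formula and relates to TPM by column rescaling", {
  m <- em(matrix(c(100, 1e6 - 100), 2, 1), lengths = c(1000, 1000))
  expect_equal(norm_fpkm(m)$values[1, 1], 100)
  m0 <- em(matrix(c(0, 50), 2, 1), lengths = c(1000, 500))
  expect_equal(norm_fpkm(m0)$values[1, 1], 0)

  set.seed(6)
  mm <- em(rand_counts(40, 4, seed = 6), lengths = round(runif(40, 300, 5000)))
  fp <- norm_fpkm(mm)$values
  rescaled <- sweep(fp, 2, colSums(fp), "/") * 1e6
  expect_equal(rescaled, norm_tpm(mm)$values, tolerance = 1e-10)
})

test_that("coverage is count * read_length / length", {
  m <- em(matrix(50, 1, 1), lengths = 1000)
  expect_equal(norm_coverage(m, read_length = 100)$values[1, 1], 5)
  expect_equal(norm_coverage(m, read_length = 1000)$values[1, 1], 50)
  expect_equal(norm_coverage(em(matrix(0, 1, 1), lengths = 10))$values[1, 1], 0)
  expect_error(norm_coverage(m, read_length = -1),
               class = "piperank_validation_error")
})

test_that("TMM factors are 1 for identical or depth-only-different columns", {
  v <- rand_counts(30, 3, seed = 7)
  same <- em(cbind(s1 = v[, 1], s2 = v[, 1], s3 = v[, 1]))
  expect_equal(unname(tmm_factors(same)$factors), rep(1, 3))
  depth <- em(cbind(s1 = v[, 1], s2 = 2 * v[, 1]))
  expect_equal(unname(tmm_factors(depth)$factors), rep(1, 2))
})

test_that("TMM matches the brute-force trimmed-weighted-mean oracle to 1e-8", {
  for (seed in 1:5) {
    set.seed(seed)
    counts <- matrix(rpois(18, 400) + round(runif(18, 0, 7)), 6, 3,
                     dimnames = list(sprintf("g%d", 1:6), sprintf("s%d", 1:3)))
    f_pkg <- tmm_factors(em(counts), reference = "s1")$factors
    f_orc <- tmm_oracle_all(counts, "s1")
    expect_equal(unname(f_pkg), unname(f_orc), tolerance = 1e-8)
  }
})

test_that("TMM and RLE agree with edgeR on tie-free random counts", {
  skip_if_not_installed("edgeR")
  set.seed(11)
  counts <- matrix(rpois(200 * 4, 300) + rpois(800, 17), 200, 4,
                   dimnames = list(sprintf("g%d", 1:200), sprintf("s%d", 1:4)))
  counts[1:30, 2] <- counts[1:30, 2] * 4   # composition bias
  f_tmm <- tmm_factors(em(counts), reference = "s1")$factors
  e_tmm <- edgeR::calcNormFactors(counts, method = "TMM", refColumn = 1)
  expect_equal(unname(f_tmm), unname(e_tmm), tolerance = 1e-10)
  f_rle <- rle_factors(em(counts))$factors
  e_rle <- edgeR::calcNormFactors(counts, method = "RLE")
  expect_equal(unname(f_rle), unname(e_rle), tolerance = 1e-10)
})

test_that("RLE excludes zero-containing genes and matches a hand computation", {
  counts <- cbind(s1 = c(10, 20, 40, 0, 100),
                  s2 = c(20, 10, 80, 5, 100),
                  s3 = c(10, 40, 40, 7, 100))
  rownames(counts) <- sprintf("g%d", 1:5)
  f <- rle_factors(em(counts))$factors
  # by hand: gene 4 (a zero in s1) is excluded from the reference
  sub <- counts[-4, ]
  ref <- exp(rowMeans(log(sub)))
  raw <- apply(sub / ref, 2, median) / colSums(counts)
  expect_equal(unname(f), unname(raw / exp(mean(log(raw)))), tolerance = 1e-12)

  same <- em(cbind(s1 = counts[, 1], s2 = counts[, 1]))
  expect_equal(unname(rle_factors(same)$factors), rep(1, 2))
  depth <- em(cbind(s1 = counts[, 3], s2 = 3 * counts[, 3]))
  expect_equal(unname(rle_factors(depth)$factors), rep(1, 2))

  allz <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_error(rle_factors(em(allz)), "no gene",
               class = "piperank_data_error")
})

test_that("UQ factors correct composition, not depth", {
  v <- rand_counts(100, 2, seed = 9)
  depth <- em(cbind(s1 = v[, 1], s2 = 5 * v[, 1]))
  expect_equal(unname(uq_factors(depth)$factors), rep(1, 2), tolerance = 1e-12)
})

test_that("apply_factors composes correctly with the factor methods", {
  v <- rand_counts(20, 2, seed = 10)
  m <- em(v)
  unit <- scaling_factors(colnames(v), c(1, 1), "TMM")
  expect_equal(apply_factors(m, unit)$values,
               sweep(v, 2, colSums(v) / mean(colSums(v)), "/"))
  expect_identical(apply_factors(m, unit)$unit_tag, "TMM_scaled")

  eq <- em(v, libsizes = c(1, 1))
  f12 <- scaling_factors(colnames(v), c(1, 2), "RLE")
  applied <- apply_factors(eq, f12)$values
  # geometric-mean rescale maps (1,2) to (1/sqrt(2), sqrt(2))
  expect_equal(applied[, 2] / applied[, 1], (v[, 2] / v[, 1]) / 2)

  same <- em(cbind(s1 = v[, 1], s2 = v[, 1]))
  expect_equal(apply_factors(same, tmm_factors(same))$values,
               sweep(same$values, 2, 1, "/"))

  other <- scaling_factors(c("x1", "x2"), c(1, 1), "TMM")
  expect_error(apply_factors(m, other), class = "piperank_data_error")
})

test_that("all normalizations commute with gene-order permutation", {
  set.seed(12)
  m <- em(rand_counts(30, 4, seed = 12), lengths = round(runif(30, 300, 3000)))
  perm <- sample(30)
  pm <- expression_matrix(m$values[perm, ], gene_lengths = m$gene_lengths[perm])
  for (meth in c("tpm", "fpkm", "coverage", "tmm", "rle", "uq")) {
    a <- normalize_matrix(m, meth)$values[perm, ]
    b <- normalize_matrix(pm, meth)$values
    expect_equal(a, b, tolerance = 1e-12, label = meth)
  }
})

test_that("scaling factors always have geometric mean 1", {
  set.seed(13)
  m <- em(rand_counts(60, 5, seed = 13))
  for (f in list(tmm_factors(m), rle_factors(m), uq_factors(m))) {
    expect_equal(exp(mean(log(f$factors))), 1, tolerance = 1e-9)
  }
})

test_that("normalizing already-normalized matrices is refused", {
  m <- em(rand_counts(5, 3), lengths = rep(1000, 5))
  tp <- norm_tpm(m)
  expect_error(norm_tpm(tp), class = "piperank_data_error")
  expect_error(tmm_factors(tp), class = "piperank_data_error")
})
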