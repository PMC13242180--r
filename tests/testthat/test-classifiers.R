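test_that("NMI matches the entropy identity and its degenerate conventions", {
  expect_equal(nmi(c(1, 1, 2, 2, 3), c(1, 1, 2, 2, 3)), 1)
  expect_equal(nmi(rep("a", 4), rep("b", 4)), 1)     # both single-cluster
  expect_equal(nmi(c(1, 1, 2, 2), rep(1, 4)), 0)     # degenerate prediction
  expect_equal(nmi(rep(1, 4), c(1, 1, 2, 2)), 0)
  expect_equal(nmi_from_table(matrix(c(50, 50, 50, 50), 2, 2)), 0)  # independent
  expect_equal(nmi_from_table(matrix(c(8, 2, 2, 8), 2, 2)),
               nmi_oracle(matrix(c(8, 2, 2, 8), 2, 2)), tolerance = 1e-12)
  expect_error(nmi(1:3, 1:4), class = "piperank_validation_error")
  # labels vs table routes agree
  set.seed(31)
  t1 <- sample(1:3, 60, replace = TRUE); p1 <- sample(1:2, 60, replace = TRUE)
  expect_equal(nmi(t1, p1), nmi_oracle(table(t1, p1)), tolerance = 1e-12)
})

test_that("macro-F1 weights classes equally", {
  truth <- c(rep("a", 8), rep("b", 2))
  pred <- c(rep("a", 8), rep("a", 2))      # class b never predicted
  # F1(a) = 16/18, F1(b) = 0 -> macro = 4/9
  expect_equal(macro_f1(truth, pred), (16 / 18) / 2)
  expect_equal(macro_f1(truth, truth), 1)
})

test_that("perfectly separable groups reach F1 = NMI = 1", {
  meta <- meta_df(list(A = 10, B = 10))
  v <- matrix(0, 30, 20, dimnames = list(sprintf("g%d", 1:30), meta$sample_id))
  v[1:15, meta$group_label == "B"] <- 1000   # disjoint, widely separated
  v <- v + 1  # avoid all-zero rows without adding noise
  r <- cross_validated_metrics(em(v), meta,
        classifier_config(folds = 5, repeats = 3, seed = 1, top_k_features = NULL))
  expect_equal(r$pooled_f1, 1)
  expect_equal(r$pooled_nmi, 1)
})

test_that("labels independent of features give near-zero NMI", {
  set.seed(32)
  v <- matrix(rpois(30 * 20, 50), 30, 20,
              dimnames = list(sprintf("g%d", 1:30), sprintf("s%d", 1:20)))
  meta <- validate_metadata(data.frame(
    sample_id = colnames(v),
    group_label = sample(rep(c("A", "B"), each = 10))))
  r <- cross_validated_metrics(em(v), meta,
        classifier_config(classifiers = "RF", folds = 5, repeats = 50,
                          seed = 2, top_k_features = NULL))
  expect_lt(r$pooled_nmi, 0.15)
})

test_that("cross-validated metrics are bit-identical across reruns", {
  set.seed(33)
  base <- generate_base(synthetic_config(n_genes = 120, de_fraction = 0.2,
                                         effect_size_log2 = 1.5, seed = 9))
  cfg <- classifier_config(repeats = 2, top_k_features = 40, seed = 7)
  r1 <- cross_validated_metrics(base$matrix, base$metadata, cfg)
  r2 <- cross_validated_metrics(base$matrix, base$metadata, cfg)
  expect_identical(r1$per_classifier, r2$per_classifier)
  # and the evaluation does not disturb the caller's RNG stream
  set.seed(40); before <- rnorm(1)
  set.seed(40); invisible(cross_validated_metrics(base$matrix, base$metadata, cfg))
  expect_identical(rnorm(1), before)
})

test_that("imbalanced small designs reduce the fold count gracefully", {
  meta <- meta_df(list(Saline = 3, MK801 = 6))
  set.seed(34)
  v <- matrix(rpois(40 * 9, 60), 40, 9,
              dimnames = list(sprintf("g%d", 1:40), meta$sample_id))
  r <- cross_validated_metrics(em(v), meta,
        classifier_config(classifiers = "RF", folds = 5, repeats = 2, seed = 1))
  expect_equal(r$folds_used, 3L)
  # singleton groups cannot be cross-validated at all
  bad <- validate_metadata(data.frame(sample_id = colnames(v),
                                      group_label = c("X", rep("Y", 8)))) |>
    suppressWarnings()
  expect_error(cross_validated_metrics(em(v), bad,
                                       classifier_config(seed = 1)),
               class = "piperank_data_error")
})

test_that("DGE counts follow the constructed effect sizes exactly", {
  meta <- meta_df(list(A = 4, B = 4))
  pat <- c(-1.5, -0.5, 0.5, 1.5)   # sd = sqrt(5/3) either group
  s <- sd(pat)
  y <- matrix(rep(5 + pat, each = 100), 100, 8, byrow = FALSE,
              dimnames = list(sprintf("g%d", 1:100), meta$sample_id))
  y[, 5:8] <- 5 + matrix(rep(pat, each = 100), 100, 4)
  y[1:10, 5:8] <- y[1:10, 5:8] + 2 * s   # d = 2 for ten genes, 0 elsewhere
  m <- em(from_log2(y))
  expect_equal(as.integer(dge_count(m, meta, threshold_d = 0.8)), 10L)
  expect_equal(as.integer(dge_count(m, meta, threshold_d = 2.5)), 0L)

  # identical distributions in both groups
  flat <- em(from_log2(matrix(rep(5 + pat, each = 20), 20, 8)[, c(1:4, 1:4)]))
  colnames(flat$values) <- meta$sample_id
  expect_equal(as.integer(dge_count(flat, meta)), 0L)

  # every gene shifted by 10 pooled SDs
  yy <- y; yy[, 5:8] <- 5 + matrix(rep(pat, each = 100), 100, 4) + 10 * s
  expect_equal(as.integer(dge_count(em(from_log2(yy)), meta)), 100L)

  # zero pooled SD: equal means -> 0; unequal means -> counted
  z <- matrix(3, 4, 8, dimnames = list(paste0("g", 1:4), meta$sample_id))
  expect_equal(as.integer(dge_count(em(z), meta)), 0L)
  z[1, 5:8] <- 9
  expect_equal(as.integer(dge_count(em(z), meta)), 1L)
})

test_that("classifier aggregation reproduces published rank-table rows", {
  # single-winner case: ranks (7,1) sum to 8 and take final rank 1
  t2 <- published_rank_table("rat_clf")
  lab <- do.call(paste, c(t2[c("Trimming", "Mapping", "Counting",
                               "Normalization")], sep = "+"))
  agg <- aggregate_classifier_ranks(lab, t2[["Rank F1"]], t2[["Rank NMI"]],
                                    t2[["Rank DGE"]])
  expect_equal(agg$Sum[agg$Pipeline == "Trimmomatic+TopHat2+StringTie+Coverage"], 8)
  expect_equal(agg$Rank[agg$Pipeline == "Trimmomatic+TopHat2+StringTie+Coverage"], 1L)
  t3 <- published_rank_table("zebrafish_clf")
  lab3 <- do.call(paste, c(t3[c("Trimming", "Mapping", "Counting",
                                "Normalization")], sep = "+"))
  agg3 <- aggregate_classifier_ranks(lab3, t3[["Rank F1"]], t3[["Rank NMI"]],
                                     t3[["Rank DGE"]])
  expect_equal(agg3$Sum[agg3$Rank == 1], 2)
  expect_equal(agg3$Pipeline[1], "Bbduk+HiSat2+StringTie+FPKM")
})

test_that("final ranking is invariant to the input order of pipelines", {
  set.seed(35)
  stats <- data.frame(label = sprintf("p%02d", 1:12),
                      f1 = round(runif(12), 2), nmi = round(runif(12), 2),
                      dge = sample(50, 12))
  a <- as.data.frame(rank_classifier_ensemble(stats))
  for (i in 1:5) {
    b <- as.data.frame(rank_classifier_ensemble(stats[sample(12), ]))
    expect_identical(b, a)
  }
})

test_that("the DGE stage reorders only within equal rank sums", {
  stats <- data.frame(label = c("a", "b", "c", "d"),
                      f1 =  c(0.9, 0.8, 0.8, 0.5),
                      nmi = c(0.9, 0.7, 0.7, 0.5),
                      dge = c(1, 5, 9, 100))
  r <- as.data.frame(rank_classifier_ensemble(stats))
  # b and c tie on rank sum; c wins by larger DGE count despite d's huge count
  expect_equal(r$Pipeline, c("a", "c", "b", "d"))
  # with the tie group's DGE equalized, only the label tie-break remains
  stats$dge <- 7
  r2 <- as.data.frame(rank_classifier_ensemble(stats))
  expect_equal(r2$Pipeline, c("a", "b", "c", "d"))
  expect_true(all(r2$tie_broken_by_label[r2$Pipeline %in% c("b", "c")]))
})

test_that("clean matrices stochastically dominate noise-corrupted copies", {
  wins <- 0L
  for (s in 1:50) {
    base <- generate_base(synthetic_config(n_genes = 150, de_fraction = 0.2,
                                           effect_size_log2 = 1.0,
                                           nb_dispersion = 0.2,
                                           groups = c(A = 6L, B = 6L), seed = s))
    lad <- emulate_ensemble(base, levels = c(0, 2), seed = s)
    cfg <- classifier_config(classifiers = "RF", repeats = 2,
                             top_k_features = 50, seed = s)
    r <- lapply(lad$ensemble, function(m) {
      x <- cross_validated_metrics(m, base$metadata, cfg)
      x$dge <- dge_count(m, base$metadata)
      x
    })
    tab <- as.data.frame(rank_classifier_ensemble(r))
    sums <- setNames(tab$Sum, tab$Pipeline)
    if (sums[["level_0"]] <= sums[["level_2"]]) wins <- wins + 1L
  }
  expect_gte(wins / 50, 0.9)
})
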