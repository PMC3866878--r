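test_that("the learning/validation split stratifies and is seed-reproducible", {
  y <- c(rep(1, 165), rep(0, 116))
  sp <- stratified_split(y, 186 / 281, seed = 1)
  expect_identical(length(sp$learning), 186L)
  expect_identical(length(sp$validation), 95L)
  expect_length(intersect(sp$learning, sp$validation), 0)
  # class-1 proportion within one sample of overall in each part
  for (part in sp) {
    expected <- length(part) * 165 / 281
    expect_lte(abs(sum(y[part]) - expected), 1)
  }

  y2 <- rep(c(0, 1), 50)
  sp2 <- stratified_split(y2, 0.5, seed = 3)
  expect_equal(sum(y2[sp2$learning]), 25)
  expect_equal(sum(1 - y2[sp2$learning]), 25)

  for (s in 1:10) {
    a <- stratified_split(y, 0.66, seed = s)
    b <- stratified_split(y, 0.66, seed = s)
    expect_identical(a, b)
  }
  expect_false(identical(stratified_split(y, 0.66, seed = 1),
                         stratified_split(y, 0.66, seed = 2)))
  expect_error(stratified_split(c(0, 1, 1, 1), 0.5), "too small")
})

test_that("stratified folds partition the samples with balanced classes", {
  y <- rep(c(0, 1), 10)
  f <- stratified_kfold(y, k = 10, seed = 2)
  expect_identical(sort(unique(f)), 1:10)
  for (fold in 1:10) {   # one of each class per fold
    expect_equal(sum(y[f == fold]), 1)
    expect_equal(sum(1 - y[f == fold]), 1)
  }

  set.seed(5)
  y2 <- random_labels(93, 5, p = 0.6)
  f2 <- stratified_kfold(y2, k = 10, seed = 7)
  sizes <- tabulate(f2, 10)
  expect_lte(diff(range(sizes)), 1)                 # balanced partition
  expect_identical(sum(sizes), 93L)                 # covers all samples
  for (fold in 1:10) {
    expected1 <- sum(y2) * sizes[fold] / 93
    expect_lte(abs(sum(y2[f2 == fold]) - expected1), 1)
  }
  expect_error(stratified_kfold(c(rep(0, 30), 1, 1), k = 10), "fewer than k")
})

test_that("the candidate grid reproduces the 16 covariate combinations", {
  specs <- enumerate_model_specs(n_pairs = 1)
  expect_identical(nrow(specs), 16L)
  expect_identical(specs$model_id[1], "1.1")
  expect_false(any(unlist(specs[1, c("age", "gleason_score", "tumor_pct",
                                     "erg_fusion")])))
  s13 <- specs$spec[[which(specs$model_id == "1.3")]]
  expect_identical(s13$clinical, "gleason_score")
  s19 <- specs$spec[[which(specs$model_id == "1.9")]]
  expect_setequal(s19$clinical, c("gleason_score", "tumor_pct"))
  s116 <- specs$spec[[which(specs$model_id == "1.16")]]
  expect_length(s116$clinical, 4)
  # every subset appears exactly once
  sig <- apply(as.matrix(specs[, c("age", "gleason_score", "tumor_pct",
                                   "erg_fusion")]), 1, paste, collapse = "")
  expect_identical(anyDuplicated(sig), 0L)
})

test_that("gene ranking reproduces per-gene Welch t-tests", {
  x <- random_expr(8, 20, 21)
  y <- random_labels(20, 21)
  rk <- ttest_rank_genes(x, y)
  for (g in rownames(x)) {
    ref <- t.test(x[g, y == 1], x[g, y == 0], var.equal = FALSE)
    row <- rk[rk$gene_id == g, ]
    expect_equal(row$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(row$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(row$p_value, ref$p.value, tolerance = 1e-10)
  }
  expect_true(all(diff(rk$p_value) >= 0))
})

test_that("a strongly shifted gene is ranked first among null genes", {
  set.seed(33)
  n <- 100
  y <- rep(c(0, 1), each = 50)
  x <- random_expr(500, n, 33)
  x["g250", y == 1] <- x["g250", y == 1] + 3 * sd(x["g250", ])
  rk <- ttest_rank_genes(x, y)
  expect_identical(rk$gene_id[1], "g250")
})

test_that("degenerate zero-variance genes rank last", {
  x <- random_expr(4, 12, 8)
  x["g002", ] <- 5  # flat gene
  y <- random_labels(12, 8)
  rk <- ttest_rank_genes(x, y)
  expect_identical(rk$gene_id[4], "g002")
  expect_true(is.na(rk$p_value[4]))
})

test_that("null p-values are approximately uniform", {
  set.seed(55)
  x <- random_expr(400, 60, 55)
  y <- rep(c(0, 1), 30)
  p <- ttest_rank_genes(x, y)$p_value
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.001)
  expect_gt(mean(p < 0.05), 0.01)  # sanity: the test has its nominal size
  expect_lt(mean(p < 0.05), 0.12)
})

test_that("cross-validation returns a complete, summarised record", {
  sim <- simulate_tsp_dataset(n_samples = 80, n_genes = 30,
                              planted_pairs = data.frame(q0 = 0.9, q1 = 0.1),
                              seed = 12)
  spec <- model_spec("gleason_score", n_pairs = 1, id = "1.3")
  cv <- run_cv(sim$expression, sim$clinical, sim$labels, spec,
               n_iter = 3, k = 5, seed = 9)
  expect_s3_class(cv, "tsp_cv")
  expect_identical(nrow(cv$iterations), 3L)
  expect_identical(nrow(cv$folds), 15L)
  expect_true(all(is.finite(cv$iterations$auc_pooled)))
  expect_gte(cv$mean_auc, cv$ci95[["lower"]] - 1e-12)
  expect_lte(cv$mean_auc, cv$ci95[["upper"]] + 1e-12)
  td <- tidy(cv)
  expect_identical(names(td), c("iteration", "auc_pooled", "auc_per_fold"))
  gl <- glance(cv)
  expect_identical(gl$model_id, "1.3")
  expect_identical(gl$n_iter, 3L)
  # determinism from the master seed
  cv2 <- run_cv(sim$expression, sim$clinical, sim$labels, spec,
                n_iter = 3, k = 5, seed = 9)
  expect_identical(cv$iterations, cv2$iterations)
})

test_that("in-fold selection uses training data only and is auditable", {
  sim <- simulate_tsp_dataset(n_samples = 60, n_genes = 20,
                              planted_pairs = data.frame(q0 = 0.9, q1 = 0.1),
                              seed = 14)
  spec <- model_spec(character(0), n_pairs = 1, id = "1.1")
  cv <- run_cv(sim$expression, clinical = NULL, labels = sim$labels,
               spec = spec, n_iter = 2, k = 4, seed = 3)
  x <- as_expr_matrix(sim$expression)
  for (i in seq_len(nrow(cv$folds))) {
    rec <- cv$folds[i, ]
    train <- rec$train[[1]]
    test <- rec$test[[1]]
    expect_length(intersect(train, test), 0)
    # recompute the selection from the logged training indices
    redo <- select_pairs(score_pairs(x[, train], sim$labels[train]), k = 1)
    logged <- rec$features[[1]]
    expect_identical(redo$gene_u, logged$gene_u)
    expect_identical(redo$gene_v, logged$gene_v)
    expect_equal(redo$delta, logged$delta)
  }
})

test_that("clinical-only specs skip selection; empty models are rejected", {
  sim <- simulate_tsp_dataset(n_samples = 60, n_genes = 10,
                              planted_pairs = NULL, seed = 18)
  spec <- model_spec("gleason_score", n_pairs = 0)
  cv <- run_cv(sim$expression, sim$clinical, sim$labels, spec,
               n_iter = 2, k = 4, seed = 5)
  expect_true(all(vapply(cv$folds$features, is.null, logical(1))))
  expect_error(model_spec(character(0), n_pairs = 0), "empty model")
})

test_that("the t-test selector enters raw expression at the gene budget", {
  sim <- simulate_tsp_dataset(n_samples = 60, n_genes = 15,
                              planted_pairs = NULL, seed = 19)
  spec <- model_spec(character(0), n_pairs = 1, id = "1.1")
  cv <- run_cv(sim$expression, NULL, sim$labels, spec,
               n_iter = 2, k = 4, selector = "ttest", seed = 6)
  expect_identical(cv$gene_budget, 2L)
  expect_true(all(lengths(cv$folds$features) == 2L))
  expect_true(all(grepl("^expr_", names(cv$folds$coef[[1]])[-1])))
})

test_that("permuted labels give chance-level cross-validated AUC", {
  sim <- simulate_tsp_dataset(n_samples = 150, n_genes = 40,
                              planted_pairs = data.frame(q0 = 0.9, q1 = 0.1),
                              seed = 27)
  set.seed(101)
  yperm <- sample(sim$labels)
  spec <- model_spec(character(0), n_pairs = 1, id = "1.1")
  cv <- run_cv(sim$expression, NULL, yperm, spec, n_iter = 4, k = 5, seed = 11)
  expect_lt(abs(cv$mean_auc - 0.5), 0.12)
})

test_that("the best model is chosen by mean AUC and validated without leakage", {
  sim <- simulate_tsp_dataset(n_samples = 140, n_genes = 30,
                              planted_pairs = data.frame(q0 = 0.9, q1 = 0.1),
                              seed = 40)
  sp <- stratified_split(sim$labels, 0.65, seed = 2)
  x <- as_expr_matrix(sim$expression)
  specs <- enumerate_model_specs(n_pairs = 1)[c(1, 3), ]  # models 1.1, 1.3
  grid <- run_cv_grid(x[, sp$learning], sim$clinical[sp$learning, ],
                      sim$labels[sp$learning], specs,
                      n_iter = 2, k = 4, seed = 77)
  final <- finalize_model(grid, sim$expression, sim$clinical, sim$labels,
                          sp$learning, sp$validation)
  expect_s3_class(final, "tsp_final")
  expect_identical(final$spec$id, grid$model_id[which.max(grid$mean_auc)])
  expect_length(intersect(final$learning, final$validation), 0)
  expect_true(final$validation_auc >= 0 && final$validation_auc <= 1)
  expect_identical(nrow(final$panel), 1L)
  expect_true(all(c("gene_u", "gene_v", "times_selected") %in%
                    names(final$selection_frequencies)))
  # argmax contract on a synthetic grid
  fake <- grid
  fake$mean_auc <- c(0.84, 0.76)
  fake$cv[[1]]$mean_auc <- 0.84
  fake$cv[[2]]$mean_auc <- 0.76
  f2 <- finalize_model(fake, sim$expression, sim$clinical, sim$labels,
                       sp$learning, sp$validation)
  expect_identical(f2$spec$id, fake$model_id[1])
  # a single-class validation set is rejected
  expect_error(
    finalize_model(grid, sim$expression, sim$clinical, sim$labels,
                   which(sim$labels == 0)[1:20], which(sim$labels == 1)[1:10]),
    "single class")
  expect_error(
    finalize_model(grid, sim$expression, sim$clinical, sim$labels,
                   1:10, 5:20), "overlap")
})

test_that("mean CV AUC responds monotonically to the planted effect size", {
  deltas <- c(0, 0.4, 0.8)
  aucs <- vapply(seq_along(deltas), function(i) {
    d <- deltas[i]
    sim <- simulate_tsp_dataset(
      n_samples = 160, n_genes = 30,
      planted_pairs = data.frame(q0 = 0.5 + d / 2, q1 = 0.5 - d / 2),
      seed = 60 + i)
    spec <- model_spec(character(0), n_pairs = 1, id = "1.1")
    run_cv(sim$expression, NULL, sim$labels, spec,
           n_iter = 3, k = 5, seed = 60 + i)$mean_auc
  }, numeric(1))
  expect_true(all(diff(aucs) > -0.05))  # non-decreasing up to MC noise
  expect_gt(aucs[3], aucs[1] + 0.15)
})
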