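#' Stratified learning/validation split
#'
#' One-time stratified division of the samples: each part's class-1 count is
#' within one sample of exact proportionality, and the split is reproducible
#' from the seed.
#'
#' @param labels 0/1 outcome vector.
#' @param learning_fraction Fraction of samples in the learning part
#'   (strictly between 0 and 1).
#' @param seed Integer seed.
#' @return A list with sorted integer index vectors `learning` and
#'   `validation`.
#' @export
stratified_split <- function(labels, learning_fraction, seed = NULL) {
  labels <- check_labels(labels)
  if (!is.numeric(learning_fraction) || learning_fraction <= 0 ||
      learning_fraction >= 1) {
    stop("learning_fraction must be strictly between 0 and 1", call. = FALSE)
  }
  n <- length(labels)
  n1 <- sum(labels == 1L)
  n0 <- n - n1
  n_learn <- round(learning_fraction * n)
  l1 <- round(learning_fraction * n1)
  l0 <- n_learn - l1
  if (l1 < 1L || l1 > n1 - 1L || l0 < 1L || l0 > n0 - 1L) {
    stop("a class is too small to stratify at this fraction", call. = FALSE)
  }
  with_seed(seed, {
    pick1 <- sample(which(labels == 1L), l1)
    pick0 <- sample(which(labels == 0L), l0)
    learning <- sort(c(pick1, pick0))
    list(learning = learning,
         validation = setdiff(seq_len(n), learning))
  })
}

#' Stratified k-fold assignment
#'
#' Partitions samples into `k` disjoint folds so that every fold's class-1
#' count is within one of exact proportionality and total fold sizes differ
#' by at most one.
#'
#' @param labels 0/1 outcome vector.
#' @param k Number of folds (default 10); each class must have at least `k`
#'   members.
#' @param seed Integer seed.
#' @return An integer vector of fold ids (1..k), one per sample.
#' @export
stratified_kfold <- function(labels, k = 10L, seed = NULL) {
  labels <- check_labels(labels)
  k <- as.integer(k)
  if (is.na(k) || k < 2L) stop("k must be at least 2", call. = FALSE)
  for (cls in c(0L, 1L)) {
    if (sum(labels == cls) < k) {
      stop("class ", cls, " has fewer than k = ", k, " samples", call. = FALSE)
    }
  }
  with_seed(seed, {
    fold <- integer(length(labels))
    ord1 <- sample(which(labels == 1L))
    fold[ord1] <- rep_len(seq_len(k), length(ord1))
    # Deal class 0 starting with the folds that got fewer class-1 samples,
    # keeping total fold sizes within one of each other.
    sizes <- tabulate(fold[ord1], k)
    ord0 <- sample(which(labels == 0L))
    fold[ord0] <- rep_len(order(sizes), length(ord0))
    fold
  })
}

# Row-wise Welch two-sample t statistics (unpooled variances).
welch_rows <- function(x, labels) {
  i0 <- labels == 0L
  i1 <- labels == 1L
  n0 <- sum(i0); n1 <- sum(i1)
  m0 <- rowMeans(x[, i0, drop = FALSE])
  m1 <- rowMeans(x[, i1, drop = FALSE])
  v0 <- rowSums((x[, i0, drop = FALSE] - m0)^2) / (n0 - 1)
  v1 <- rowSums((x[, i1, drop = FALSE] - m1)^2) / (n1 - 1)
  a0 <- v0 / n0
  a1 <- v1 / n1
  se <- sqrt(a0 + a1)
  stat <- (m1 - m0) / se
  df <- (a0 + a1)^2 / (a0^2 / (n0 - 1) + a1^2 / (n1 - 1))
  p <- 2 * pt(-abs(stat), df)
  list(statistic = stat, df = df, p_value = p)
}

#' Rank genes by per-gene Welch t-tests
#'
#' The one-gene-at-a-time baseline selector: a two-sided Welch
#' (unequal-variance) t-test per gene, ranked by ascending p-value with the
#' gene's row index breaking exact ties. Genes with zero variance in both
#' classes have an undefined statistic and are ranked last.
#'
#' @param expression Expression data (see [as_expr_matrix()]).
#' @param labels 0/1 outcome vector; each class needs >= 2 samples.
#' @return A tibble with `gene_id`, `statistic`, `df`, `p_value`, `rank`,
#'   sorted by rank.
#' @export
ttest_rank_genes <- function(expression, labels) {
  x <- as_expr_matrix(expression)
  labels <- check_labels(labels, ncol(x))
  if (sum(labels == 0L) < 2L || sum(labels == 1L) < 2L) {
    stop("each class needs at least 2 samples for a t-test", call. = FALSE)
  }
  w <- welch_rows(x, labels)
  ord <- order(w$p_value, seq_len(nrow(x)), na.last = TRUE)
  tibble::tibble(
    gene_id = rownames(x)[ord],
    statistic = unname(w$statistic[ord]),
    df = unname(w$df[ord]),
    p_value = unname(w$p_value[ord]),
    rank = seq_along(ord)
  )
}

# Table-1 layout: which clinical covariates each numbered model includes.
MODEL_GRID <- list(
  "1.1" = character(0),
  "1.2" = "age",
  "1.3" = "gleason_score",
  "1.4" = "tumor_pct",
  "1.5" = "erg_fusion",
  "1.6" = c("age", "gleason_score"),
  "1.7" = c("age", "tumor_pct"),
  "1.8" = c("age", "erg_fusion"),
  "1.9" = c("gleason_score", "tumor_pct"),
  "1.10" = c("gleason_score", "erg_fusion"),
  "1.11" = c("tumor_pct", "erg_fusion"),
  "1.12" = c("age", "gleason_score", "tumor_pct"),
  "1.13" = c("age", "gleason_score", "erg_fusion"),
  "1.14" = c("age", "tumor_pct", "erg_fusion"),
  "1.15" = c("gleason_score", "tumor_pct", "erg_fusion"),
  "1.16" = c("age", "gleason_score", "tumor_pct", "erg_fusion")
)

#' Enumerate the 16 candidate model specifications
#'
#' All 2^4 subsets of the clinical covariates (age, Gleason score, tumor
#' percentage, ERG fusion), each combined with `n_pairs` TSP pairs, numbered
#' 1.1 (pairs only) through 1.16 (all four clinical covariates plus pairs).
#'
#' @param n_pairs Pairs per model (default 1).
#' @param encoding Pair encoding passed to [model_spec()].
#' @return A tibble with `model_id`, one logical column per covariate,
#'   `n_pairs`, and a `spec` list-column of [model_spec()] objects.
#' @export
enumerate_model_specs <- function(n_pairs = 1L, encoding = "indicator") {
  ids <- names(MODEL_GRID)
  specs <- purrr::map2(MODEL_GRID, ids, function(cov, id) {
    model_spec(clinical = cov, n_pairs = n_pairs, encoding = encoding, id = id)
  })
  tibble::tibble(
    model_id = ids,
    age = purrr::map_lgl(MODEL_GRID, ~ "age" %in% .x),
    gleason_score = purrr::map_lgl(MODEL_GRID, ~ "gleason_score" %in% .x),
    tumor_pct = purrr::map_lgl(MODEL_GRID, ~ "tumor_pct" %in% .x),
    erg_fusion = purrr::map_lgl(MODEL_GRID, ~ "erg_fusion" %in% .x),
    n_pairs = as.integer(n_pairs),
    spec = unname(specs)
  )
}

# Feature selection on training-fold data only; returns what build_design
# needs downstream.
select_features <- function(x_train, labels_train, spec, selector, gene_budget) {
  if (selector == "tsp") {
    if (spec$n_pairs == 0L) return(NULL)
    scores <- score_pairs(x_train, labels_train)
    select_pairs(scores, k = spec$n_pairs, disjoint = TRUE)
  } else {
    if (gene_budget == 0L) return(NULL)
    ranking <- ttest_rank_genes(x_train, labels_train)
    ranking$gene_id[seq_len(gene_budget)]
  }
}

# Design for the given samples and selected features (pairs or gene list).
design_for <- function(x, clinical, labels, spec, features, selector) {
  if (selector == "tsp") {
    return(build_design(x, clinical, panel = features, spec = spec))
  }
  # t-test baseline: clinical subset + raw expression of the selected genes.
  out <- if (length(spec$clinical)) {
    base_spec <- model_spec(clinical = spec$clinical, n_pairs = 0L,
                            id = spec$id)
    build_design(x, clinical, panel = NULL, spec = base_spec)
  } else {
    tibble::tibble(sample_id = colnames(x))
  }
  if (!is.null(features)) {
    raw <- t(x[features, , drop = FALSE])
    colnames(raw) <- paste0("expr_", features)
    out <- dplyr::bind_cols(out, tibble::as_tibble(raw))
  }
  out
}

#' Repeated stratified k-fold cross-validation of one model specification
#'
#' The evaluation protocol: for each of `n_iter` iterations the learning
#' samples are split into `k` stratified folds; within each fold's training
#' part the features are selected anew (TSP pairs, or top t-test genes for
#' the one-gene-at-a-time baseline), the logistic model is fitted, and
#' probabilities are predicted for the held-out fold. Each iteration yields
#' one AUC from the pooled out-of-fold probabilities (default) and also the
#' mean of the 10 per-fold AUCs; the `n_iter` AUCs are summarised by their
#' mean and a percentile interval.
#'
#' Feature selection never sees held-out samples; every fold's training
#' indices and selected features are logged so the selection can be audited
#' by recomputation.
#'
#' @param expression,clinical Learning-set data (see [build_design()]).
#' @param labels 0/1 outcome vector for the learning samples.
#' @param spec A [model_spec()].
#' @param n_iter Number of CV repetitions (the study protocol uses 100).
#' @param k Folds per repetition (default 10).
#' @param selector `"tsp"` (pair selection) or `"ttest"` (one-gene-at-a-time
#'   baseline with `gene_budget` genes entered as raw expression).
#' @param gene_budget Genes used by the t-test selector; defaults to
#'   `2 * n_pairs` so both selectors spend the same gene budget.
#' @param seed Master seed; per-iteration sub-seeds are spawned from it.
#' @param auc_mode Which per-iteration AUC the summary uses: `"pooled"`
#'   (default) or `"per_fold"`.
#' @param ci_level Coverage of the percentile interval.
#' @return A `tsp_cv` object; see [tidy.tsp_cv()] and [glance.tsp_cv()].
#' @export
run_cv <- function(expression, clinical = NULL, labels, spec,
                   n_iter = 100L, k = 10L,
                   selector = c("tsp", "ttest"),
                   gene_budget = NULL, seed = NULL,
                   auc_mode = c("pooled", "per_fold"),
                   ci_level = 0.95) {
  selector <- match.arg(selector)
  auc_mode <- match.arg(auc_mode)
  stopifnot(inherits(spec, "tsp_model_spec"))
  x <- as_expr_matrix(expression)
  labels <- check_labels(labels, ncol(x))
  n_iter <- as.integer(n_iter)
  gene_budget <- as.integer(gene_budget %||% (2L * spec$n_pairs))

  iter_seeds <- with_seed(seed, draw_subseeds(n_iter))

  fold_log <- vector("list", n_iter)
  iter_auc_pooled <- numeric(n_iter)
  iter_auc_fold <- numeric(n_iter)

  for (it in seq_len(n_iter)) {
    folds <- stratified_kfold(labels, k, seed = iter_seeds[it])
    oof <- rep(NA_real_, length(labels))
    recs <- vector("list", k)
    for (f in seq_len(k)) {
      test_idx <- which(folds == f)
      train_idx <- which(folds != f)
      feats <- select_features(x[, train_idx, drop = FALSE],
                               labels[train_idx], spec, selector, gene_budget)
      des_all <- design_for(x, clinical, labels, spec, feats, selector)
      ri <- match(colnames(x), des_all$sample_id)
      fit <- fit_logit(des_all[ri[train_idx], , drop = FALSE],
                       labels[train_idx])
      prob <- predict(fit, des_all[ri[test_idx], , drop = FALSE])
      oof[test_idx] <- prob
      auc_f <- tryCatch(roc_auc(prob, labels[test_idx])$auc,
                        error = function(e) NA_real_)
      recs[[f]] <- tibble::tibble(
        iteration = it, fold = f,
        train = list(train_idx), test = list(test_idx),
        features = list(feats),
        coef = list(coef(fit)),
        converged = fit$converged, ridge_used = fit$ridge_used,
        auc_fold = auc_f
      )
    }
    fold_log[[it]] <- dplyr::bind_rows(recs)
    iter_auc_pooled[it] <- roc_auc(oof, labels)$auc
    iter_auc_fold[it] <- mean(fold_log[[it]]$auc_fold, na.rm = TRUE)
  }

  auc <- if (auc_mode == "pooled") iter_auc_pooled else iter_auc_fold
  ci <- if (n_iter >= 2L) percentile_ci(auc, ci_level) else
    tibble::tibble(lower = NA_real_, upper = NA_real_, level = ci_level)

  structure(list(
    spec = spec, selector = selector, gene_budget = gene_budget,
    n_iter = n_iter, k = k, seed = seed, iter_seeds = iter_seeds,
    auc_mode = auc_mode,
    iterations = tibble::tibble(iteration = seq_len(n_iter),
                                auc_pooled = iter_auc_pooled,
                                auc_per_fold = iter_auc_fold),
    folds = dplyr::bind_rows(fold_log),
    mean_auc = mean(auc),
    ci95 = c(lower = ci$lower, upper = ci$upper),
    ci_level = ci_level,
    n_samples = ncol(x)
  ), class = "tsp_cv")
}

#' @export
print.tsp_cv <- function(x, ...) {
  cat("<tsp_cv> model", x$spec$id %||% "", "|", x$selector, "selector |",
      x$n_iter, "x", x$k, "-fold\n")
  cat(sprintf("  mean AUC %.3f  [%.3f, %.3f] (%s, %d%% percentile)\n",
              x$mean_auc, x$ci95[["lower"]], x$ci95[["upper"]],
              x$auc_mode, round(100 * x$ci_level)))
  invisible(x)
}

#' Tidy per-iteration cross-validation AUCs
#'
#' @param x A `tsp_cv` object.
#' @param ... Unused.
#' @return A tibble with one row per CV repetition: `iteration`,
#'   `auc_pooled`, `auc_per_fold`.
#' @export
tidy.tsp_cv <- function(x, ...) x$iterations

#' One-row summary of a cross-validation run
#'
#' @param x A `tsp_cv` object.
#' @param ... Unused.
#' @export
glance.tsp_cv <- function(x, ...) {
  tibble::tibble(
    model_id = x$spec$id %||% NA_character_,
    selector = x$selector,
    n_pairs = x$spec$n_pairs,
    mean_auc = x$mean_auc,
    ci_lo = x$ci95[["lower"]],
    ci_hi = x$ci95[["upper"]],
    n_iter = x$n_iter,
    k = x$k
  )
}

#' Cross-validate a grid of model specifications
#'
#' Runs [run_cv()] for each spec (by default the 16-model grid of
#' [enumerate_model_specs()]) on the same learning data, spawning one
#' sub-seed per model from the master seed.
#'
#' @inheritParams run_cv
#' @param specs A tibble with `model_id` and `spec` columns, as produced by
#'   [enumerate_model_specs()].
#' @return A tibble: one row per model with its summary columns and the full
#'   `tsp_cv` object in a `cv` list-column.
#' @export
run_cv_grid <- function(expression, clinical = NULL, labels,
                        specs = enumerate_model_specs(),
                        n_iter = 100L, k = 10L, selector = "tsp",
                        gene_budget = NULL, seed = NULL, ...) {
  model_seeds <- with_seed(seed, draw_subseeds(nrow(specs)))
  cvs <- purrr::map(seq_len(nrow(specs)), function(i) {
    run_cv(expression, clinical, labels, specs$spec[[i]],
           n_iter = n_iter, k = k, selector = selector,
           gene_budget = gene_budget, seed = model_seeds[i], ...)
  })
  dplyr::bind_cols(
    dplyr::bind_rows(purrr::map(cvs, glance)),
    tibble::tibble(cv = cvs)
  )
}

#' Pick the best model and build the final validated classifier
#'
#' Selects the specification with the largest mean cross-validated AUC
#' (ties broken toward fewer covariates), re-runs feature selection and
#' refits the coefficients on the full learning set, and reports the AUC on
#' the held-out validation samples — which were never touched during
#' selection or fitting.
#'
#' @param grid Result of [run_cv_grid()] on the learning samples.
#' @param expression,clinical,labels The full data set.
#' @param learning,validation Disjoint index vectors into the samples, e.g.
#'   from [stratified_split()].
#' @return A `tsp_final` object with the chosen spec, the panel and fit from
#'   the full learning set, per-fold pair-selection frequencies, and
#'   `validation_auc`.
#' @export
finalize_model <- function(grid, expression, clinical = NULL, labels,
                           learning, validation) {
  stopifnot(is.data.frame(grid), "cv" %in% names(grid))
  if (length(intersect(learning, validation)) > 0L) {
    stop("learning and validation indices overlap", call. = FALSE)
  }
  x <- as_expr_matrix(expression)
  labels <- check_labels(labels, ncol(x))
  if (length(unique(labels[validation])) < 2L) {
    stop("validation set contains a single class", call. = FALSE)
  }

  n_cov <- vapply(grid$cv, function(cv) {
    length(cv$spec$clinical) + cv$spec$n_pairs
  }, numeric(1))
  best <- order(-grid$mean_auc, n_cov)[1L]
  cv <- grid$cv[[best]]
  spec <- cv$spec
  selector <- cv$selector

  x_learn <- x[, learning, drop = FALSE]
  feats <- select_features(x_learn, labels[learning], spec, selector,
                           cv$gene_budget)
  des_all <- design_for(x, clinical, labels, spec, feats, selector)
  ri <- match(colnames(x), des_all$sample_id)
  fit <- fit_logit(des_all[ri[learning], , drop = FALSE], labels[learning])
  prob_val <- predict(fit, des_all[ri[validation], , drop = FALSE])
  val_auc <- roc_auc(prob_val, labels[validation])

  # How often each pair (or gene) was picked across the CV folds.
  freq <- if (selector == "tsp" && spec$n_pairs > 0L) {
    dplyr::count(
      dplyr::bind_rows(cv$folds$features),
      .data$gene_u, .data$gene_v, name = "times_selected",
      sort = TRUE
    )
  } else if (selector == "ttest" && cv$gene_budget > 0L) {
    tibble::tibble(gene_id = unlist(cv$folds$features)) |>
      dplyr::count(.data$gene_id, name = "times_selected", sort = TRUE)
  }

  structure(list(
    spec = spec, selector = selector, cv = cv,
    panel = feats, fit = fit,
    selection_frequencies = freq,
    learning = learning, validation = validation,
    validation_auc = val_auc$auc,
    validation_probs = prob_val
  ), class = "tsp_final")
}

#' @export
print.tsp_final <- function(x, ...) {
  cat("<tsp_final> best model", x$spec$id %||% "", "(",
      if (length(x$spec$clinical)) paste(x$spec$clinical, collapse = " + ")
      else "no clinical", "+", x$spec$n_pairs, "pair(s) )\n")
  cat(sprintf("  learning mean CV AUC %.3f | validation AUC %.3f\n",
              x$cv$mean_auc, x$validation_auc))
  invisible(x)
}
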