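#' Default class-conditional clinical distributions
#'
#' Plausible cohort-level defaults for an elderly watchful-waiting prostate
#' cancer population: lethal cases (class 1) are somewhat older, carry higher
#' Gleason grades, larger tumor volume fractions and a higher ERG-fusion
#' rate. Each entry holds the class-0 and class-1 parameters and can be
#' overridden wholesale or per covariate.
#'
#' @return A named list with entries `age` (normal mean/sd per class),
#'   `gleason_score` (category probabilities over grades 6-9 per class),
#'   `tumor_pct` (Beta shape parameters per class, scaled to 0-100) and
#'   `erg_fusion` (Bernoulli rate per class).
#' @export
default_clinical_effects <- function() {
  list(
    age = list(mean = c(70, 74), sd = c(8, 7)),
    gleason_score = list(levels = 6:9,
                         prob0 = c(0.45, 0.40, 0.10, 0.05),
                         prob1 = c(0.10, 0.35, 0.35, 0.20)),
    tumor_pct = list(shape1 = c(2, 4), shape2 = c(4, 3)),
    erg_fusion = list(rate = c(0.30, 0.50))
  )
}

#' Simulate an expression study with planted reversal gene pairs
#'
#' Generates a genes-by-samples expression matrix, a clinical table and a
#' binary outcome with known ground truth, shaped like a two-class
#' prognostic cohort (defaults: 281 samples with a 165/281 event fraction
#' and 6,100 genes — the shape of the published prostate cohort the method
#' was evaluated on).
#'
#' Labels are drawn first (Bernoulli with `class1_fraction`). Null genes are
#' Gaussian with gene-specific baseline and spread, exchangeable across
#' classes. Each planted pair `(u, v)` is built from a cyclic-shift uniform
#' copula: `U ~ Unif(0,1)`, `V = (U + 1 - q_c) mod 1` for a sample of class
#' `c`, and both genes map through the same increasing quantile transform.
#' This makes the ordering indicator `x_u < x_v` exactly Bernoulli(`q_c`)
#' within class `c` while each gene's marginal distribution is *identical*
#' in both classes — a pure reversal signal with no per-gene mean shift, so
#' one-gene tests have no power against it.
#'
#' @param n_samples Number of samples.
#' @param n_genes Number of genes (>= twice the number of planted pairs).
#' @param class1_fraction Probability a sample is class 1 (the event class).
#' @param planted_pairs Data frame with columns `q0`, `q1` (one row per
#'   planted pair; ordering probabilities in each class), or `NULL` for a
#'   pure-null matrix. Default: three strong reversal pairs (0.9, 0.1).
#' @param clinical_effects Class-conditional clinical parameters
#'   ([default_clinical_effects()]).
#' @param baseline_range,sd_range Ranges of the per-gene Gaussian baseline
#'   and SD (log-intensity scale).
#' @param seed Integer seed; identical parameters and seed give
#'   bit-identical output.
#' @return A list with `expression` (tibble: `gene_id` + one column per
#'   sample), `clinical` (tibble: `sample_id`, age, gleason_score,
#'   tumor_pct, erg_fusion, label), `labels` (integer vector) and `truth`
#'   (planted pair table with `gene_u`, `gene_v`, `q0`, `q1`, `delta_true`).
#' @export
simulate_tsp_dataset <- function(n_samples = 281L,
                                 n_genes = 6100L,
                                 class1_fraction = 165 / 281,
                                 planted_pairs = data.frame(q0 = rep(0.9, 3),
                                                            q1 = rep(0.1, 3)),
                                 clinical_effects = default_clinical_effects(),
                                 baseline_range = c(4, 12),
                                 sd_range = c(0.6, 1.4),
                                 seed = NULL) {
  n_samples <- as.integer(n_samples)
  n_genes <- as.integer(n_genes)
  if (n_samples < 4L) stop("need at least 4 samples", call. = FALSE)
  if (class1_fraction <= 0 || class1_fraction >= 1) {
    stop("class1_fraction must be strictly between 0 and 1", call. = FALSE)
  }
  n_pairs <- if (is.null(planted_pairs)) 0L else nrow(planted_pairs)
  if (n_pairs > 0L) {
    stopifnot(all(c("q0", "q1") %in% names(planted_pairs)))
    q <- c(planted_pairs$q0, planted_pairs$q1)
    if (any(!is.finite(q)) || any(q < 0 | q > 1)) {
      stop("planted q0/q1 must lie in [0, 1]", call. = FALSE)
    }
  }
  if (n_genes < max(2L, 2L * n_pairs)) {
    stop("n_genes must be at least 2 x the number of planted pairs",
         call. = FALSE)
  }

  with_seed(seed, {
    labels <- rbinom(n_samples, 1L, class1_fraction)
    if (length(unique(labels)) < 2L) {
      stop("degenerate draw: a class is empty; use more samples or a less ",
           "extreme class1_fraction", call. = FALSE)
    }

    gene_ids <- sprintf("g%05d", seq_len(n_genes))
    sample_ids <- sprintf("s%04d", seq_len(n_samples))
    baseline <- runif(n_genes, baseline_range[1], baseline_range[2])
    gsd <- runif(n_genes, sd_range[1], sd_range[2])

    x <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples)
    x <- x * gsd + baseline  # recycles by row index: per-gene scale/shift
    dimnames(x) <- list(gene_ids, sample_ids)

    truth <- NULL
    if (n_pairs > 0L) {
      planted_idx <- sample.int(n_genes, 2L * n_pairs)
      for (p in seq_len(n_pairs)) {
        iu <- planted_idx[2L * p - 1L]
        iv <- planted_idx[2L * p]
        q0 <- planted_pairs$q0[p]
        q1 <- planted_pairs$q1[p]
        # shift 1 - q_c; q = 1 needs an infinitesimal shift (shift 0 would
        # tie the genes and the strict indicator counts ties as 0)
        s0 <- if (q0 == 1) 1e-12 else 1 - q0
        s1 <- if (q1 == 1) 1e-12 else 1 - q1
        u <- runif(n_samples)
        v <- (u + ifelse(labels == 1L, s1, s0)) %% 1
        v <- pmin(pmax(v, 1e-12), 1 - 1e-12)
        a <- baseline[iu]
        b <- gsd[iu]
        x[iu, ] <- a + b * qnorm(u)
        x[iv, ] <- a + b * qnorm(v)
      }
      truth <- tibble::tibble(
        gene_u = gene_ids[planted_idx[seq(1L, 2L * n_pairs, by = 2L)]],
        gene_v = gene_ids[planted_idx[seq(2L, 2L * n_pairs, by = 2L)]],
        q0 = planted_pairs$q0, q1 = planted_pairs$q1,
        delta_true = abs(planted_pairs$q0 - planted_pairs$q1)
      )
    }

    ce <- clinical_effects
    cls <- labels + 1L  # 1 -> class-0 params, 2 -> class-1 params
    age <- rnorm(n_samples, ce$age$mean[cls], ce$age$sd[cls])
    age <- pmax(age, 40)
    gs_prob <- rbind(ce$gleason_score$prob0, ce$gleason_score$prob1)
    gleason <- vapply(cls, function(ci) {
      sample(ce$gleason_score$levels, 1L, prob = gs_prob[ci, ])
    }, integer(1))
    tumor <- 100 * rbeta(n_samples, ce$tumor_pct$shape1[cls],
                         ce$tumor_pct$shape2[cls])
    erg <- rbinom(n_samples, 1L, ce$erg_fusion$rate[cls])

    clinical <- tibble::tibble(
      sample_id = sample_ids,
      age = age,
      gleason_score = gleason,
      tumor_pct = tumor,
      erg_fusion = erg,
      label = labels
    )

    list(expression = expr_as_tibble(x),
         clinical = clinical,
         labels = labels,
         truth = truth)
  })
}

#' Simulate binary outcomes from a logistic model
#'
#' Forward simulation of the logit model: for each design row,
#' `eta = b0 + sum_i b_i x_i` and `y ~ Bernoulli(plogis(eta))`.
#'
#' @param design Design tibble (a `sample_id` column is carried through).
#' @param beta0 Intercept.
#' @param betas Coefficients, either named after the design columns or
#'   positional in column order; length must match.
#' @param seed Integer seed.
#' @return A tibble with `sample_id` (if present), `eta`, `prob`, `label`.
#' @export
simulate_labels <- function(design, beta0, betas, seed = NULL) {
  stopifnot(is.data.frame(design))
  ids <- if ("sample_id" %in% names(design)) design$sample_id else NULL
  xdf <- design[, setdiff(names(design), "sample_id"), drop = FALSE]
  if (length(betas) != ncol(xdf)) {
    stop("betas length (", length(betas), ") does not match design columns (",
         ncol(xdf), ")", call. = FALSE)
  }
  if (!is.null(names(betas))) {
    if (!setequal(names(betas), names(xdf))) {
      stop("beta names do not match design columns", call. = FALSE)
    }
    betas <- betas[names(xdf)]
  }
  eta <- beta0 + drop(as.matrix(xdf) %*% unname(betas))
  prob <- plogis(eta)
  lab <- with_seed(seed, rbinom(length(eta), 1L, prob))
  out <- tibble::tibble(eta = eta, prob = prob, label = lab)
  if (!is.null(ids)) out <- dplyr::bind_cols(tibble::tibble(sample_id = ids), out)
  out
}
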