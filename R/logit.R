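CLINICAL_COVARIATES <- c("age", "gleason_score", "tumor_pct", "erg_fusion")

#' Specify a candidate model: clinical covariates plus TSP pairs
#'
#' @param clinical Character vector, a subset of
#'   `c("age", "gleason_score", "tumor_pct", "erg_fusion")` (may be empty).
#' @param n_pairs Number of top-scoring pairs entering the model (0 allowed
#'   for clinical-only baselines, but the model must contain at least one
#'   covariate overall).
#' @param encoding How a pair enters the design: `"indicator"` (default; one
#'   0/1 ordering covariate per pair, preserving rank invariance) or `"raw"`
#'   (the two genes' expression values, two columns per pair).
#' @param id Optional model label (e.g. `"1.3"`).
#' @return An object of class `tsp_model_spec`.
#' @export
model_spec <- function(clinical = character(0), n_pairs = 1L,
                       encoding = c("indicator", "raw"), id = NULL) {
  encoding <- match.arg(encoding)
  clinical <- as.character(clinical)
  bad <- setdiff(clinical, CLINICAL_COVARIATES)
  if (length(bad)) {
    stop("unknown clinical covariates: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  n_pairs <- as.integer(n_pairs)
  if (is.na(n_pairs) || n_pairs < 0L) stop("n_pairs must be >= 0", call. = FALSE)
  if (length(clinical) == 0L && n_pairs == 0L) {
    stop("empty model: include at least one clinical covariate or one pair",
         call. = FALSE)
  }
  structure(list(clinical = clinical, n_pairs = n_pairs,
                 encoding = encoding, id = id),
            class = "tsp_model_spec")
}

#' @export
print.tsp_model_spec <- function(x, ...) {
  cat("<tsp_model_spec", if (!is.null(x$id)) paste0(" ", x$id), ">\n", sep = "")
  cat("  clinical: ",
      if (length(x$clinical)) paste(x$clinical, collapse = ", ") else "(none)",
      "\n", sep = "")
  cat("  pairs:    ", x$n_pairs, " (", x$encoding, " encoding)\n", sep = "")
  invisible(x)
}

#' Build the design matrix for a model specification
#'
#' Columns are the spec's clinical covariates (in the fixed order age,
#' gleason_score, tumor_pct, erg_fusion) followed by the pair features of the
#' first `n_pairs` panel pairs: one `tsp<i>` indicator column per pair, or
#' two `expr_<gene>` columns per pair under raw encoding. Samples with a
#' missing value in any modeled clinical covariate are dropped with a
#' message.
#'
#' @param expression Expression data (needed when `n_pairs > 0`).
#' @param clinical Clinical tibble with `sample_id` plus covariate columns,
#'   aligned to the expression samples; may be `NULL` when the spec uses no
#'   clinical covariates.
#' @param panel Pair table from [select_pairs()]; may be `NULL` when
#'   `n_pairs = 0`.
#' @param spec A [model_spec()].
#' @return A tibble with `sample_id` plus one column per design covariate.
#' @export
build_design <- function(expression, clinical = NULL, panel = NULL, spec) {
  stopifnot(inherits(spec, "tsp_model_spec"))
  x <- as_expr_matrix(expression)
  samples <- colnames(x)

  out <- tibble::tibble(sample_id = samples)

  if (length(spec$clinical)) {
    if (is.null(clinical)) {
      stop("spec uses clinical covariates but no clinical table was given",
           call. = FALSE)
    }
    stopifnot(is.data.frame(clinical), "sample_id" %in% names(clinical))
    idx <- match(samples, clinical$sample_id)
    if (any(is.na(idx))) {
      stop("clinical table is missing samples: ",
           paste(utils::head(samples[is.na(idx)], 5L), collapse = ", "),
           call. = FALSE)
    }
    missing_cols <- setdiff(spec$clinical, names(clinical))
    if (length(missing_cols)) {
      stop("clinical table lacks columns: ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    covs <- intersect(CLINICAL_COVARIATES, spec$clinical)
    out <- dplyr::bind_cols(out, clinical[idx, covs, drop = FALSE])
  }

  if (spec$n_pairs > 0L) {
    if (is.null(panel) || nrow(panel) < spec$n_pairs) {
      stop("spec requests ", spec$n_pairs, " pairs but the panel has ",
           if (is.null(panel)) 0L else nrow(panel), call. = FALSE)
    }
    panel <- panel[seq_len(spec$n_pairs), , drop = FALSE]
    if (spec$encoding == "indicator") {
      feats <- predict_pairs(x, panel)
      out <- dplyr::bind_cols(out, feats[, -1L, drop = FALSE])
    } else {
      genes <- unique(c(rbind(panel$gene_u, panel$gene_v)))
      raw <- t(x[vapply(genes, resolve_gene, integer(1), x = x), , drop = FALSE])
      colnames(raw) <- paste0("expr_", genes)
      out <- dplyr::bind_cols(out, tibble::as_tibble(raw))
    }
  }

  drop <- !stats::complete.cases(out)
  if (any(drop)) {
    message("dropping ", sum(drop), " sample(s) with missing modeled covariates")
    out <- out[!drop, , drop = FALSE]
  }
  out
}

#' Fit the logistic model by maximum likelihood
#'
#' Maximises the binomial log-likelihood of the logit model
#' `log(p/(1-p)) = b0 + sum_i b_i x_i` by iteratively reweighted least
#' squares with step-halving (so the likelihood never decreases across
#' iterations). If the coefficients diverge — the usual symptom of separable
#' data, frequent with indicator covariates on small folds — the model is
#' refitted with a small ridge penalty on the slopes (never the intercept)
#' and flagged.
#'
#' @param design Design tibble from [build_design()] (a `sample_id` column,
#'   if present, is used as the row identifier).
#' @param labels 0/1 outcome vector aligned with the design rows.
#' @param max_iter Maximum IRLS iterations.
#' @param tol Convergence tolerance on the maximum absolute component of the
#'   likelihood gradient.
#' @param ridge_lambda Ridge penalty used by the separation fallback.
#' @return An object of class `tsp_logit` with coefficients, standard
#'   errors, the log-likelihood trace and convergence metadata.
#' @export
fit_logit <- function(design, labels, max_iter = 100L, tol = 1e-8,
                      ridge_lambda = 1e-4) {
  stopifnot(is.data.frame(design))
  ids <- if ("sample_id" %in% names(design)) design$sample_id else NULL
  xdf <- design[, setdiff(names(design), "sample_id"), drop = FALSE]
  if (anyNA(xdf)) stop("design matrix contains missing values", call. = FALSE)
  y <- check_labels(labels, nrow(xdf), require_both = FALSE)

  X <- cbind(`(Intercept)` = 1, as.matrix(xdf))
  storage.mode(X) <- "double"

  # Constant (zero-variance) covariate columns cannot be estimated.
  const <- c(FALSE, apply(X[, -1L, drop = FALSE], 2L, function(z) {
    diff(range(z)) == 0
  }))
  dropped <- colnames(X)[const]
  if (length(dropped)) {
    warning("dropping constant design column(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
    X <- X[, !const, drop = FALSE]
  }

  if (nrow(X) <= ncol(X)) {
    warning("fewer samples than coefficients + 1; fitting with ridge penalty",
            call. = FALSE)
    fit <- irls_fit(X, y, max_iter, tol, ridge_lambda)
    fit$ridge_used <- TRUE
  } else {
    fit <- irls_fit(X, y, max_iter, tol, lambda = 0)
    if (fit$diverged) {
      fit <- irls_fit(X, y, max_iter, tol, lambda = ridge_lambda)
      fit$ridge_used <- TRUE
    } else {
      fit$ridge_used <- FALSE
    }
  }

  structure(list(
    coefficients = fit$beta,
    std_error = fit$se,
    vcov = fit$vcov,
    converged = fit$converged,
    n_iter = fit$iter,
    log_likelihood = fit$ll,
    ll_trace = fit$trace,
    ridge_used = fit$ridge_used,
    ridge_lambda = if (fit$ridge_used) ridge_lambda else 0,
    dropped = dropped,
    terms = colnames(X)[-1L],
    nobs = nrow(X),
    sample_id = ids
  ), class = "tsp_logit")
}

# Core IRLS loop with step-halving on the (penalised) log-likelihood.
irls_fit <- function(X, y, max_iter, tol, lambda) {
  p <- ncol(X)
  pen <- rep(lambda, p)
  pen[1L] <- 0  # never penalise the intercept
  beta <- rep(0, p)

  loglik <- function(b) {
    eta <- drop(X %*% b)
    sum(y * eta - log1p(exp(eta)))  # equivalent stable form of Eq-style sum
  }
  pll <- function(b) loglik(b) - sum(pen * b^2) / 2

  ll_cur <- pll(beta)
  trace <- loglik(beta)
  converged <- FALSE
  diverged <- FALSE
  iter <- 0L

  for (it in seq_len(max_iter)) {
    iter <- it
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    grad <- drop(crossprod(X, y - mu)) - pen * beta
    if (max(abs(grad)) < tol) {
      converged <- TRUE
      break
    }
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X, X * w) + diag(pen, p)
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) {
      diverged <- TRUE
      break
    }
    # Step-halving: guarantee the objective is non-decreasing.
    s <- 1
    repeat {
      cand <- beta + s * step
      ll_new <- pll(cand)
      if (is.finite(ll_new) && ll_new >= ll_cur - 1e-12) break
      s <- s / 2
      if (s < 1e-10) break
    }
    beta <- beta + s * step
    ll_cur <- pll(beta)
    trace <- c(trace, loglik(beta))
    if (lambda == 0 && max(abs(beta[-1L])) > 15) {
      diverged <- TRUE
      break
    }
  }

  mu <- plogis(drop(X %*% beta))
  w <- pmax(mu * (1 - mu), 1e-10)
  H <- crossprod(X, X * w) + diag(pen, p)
  V <- tryCatch(solve(H), error = function(e) matrix(NA_real_, p, p))
  se <- sqrt(pmax(diag(V), 0))
  names(beta) <- names(se) <- colnames(X)
  dimnames(V) <- list(colnames(X), colnames(X))

  list(beta = beta, se = se, vcov = V, converged = converged,
       diverged = diverged, iter = iter, ll = loglik(beta), trace = trace)
}

#' @export
print.tsp_logit <- function(x, ...) {
  cat("<tsp_logit> n =", x$nobs, "| logLik =", format(x$log_likelihood, digits = 6),
      if (x$ridge_used) "| ridge fallback engaged", "\n")
  print(round(x$coefficients, 4))
  if (!x$converged) cat("  (did not converge in", x$n_iter, "iterations)\n")
  invisible(x)
}

#' @export
coef.tsp_logit <- function(object, ...) object$coefficients

#' @export
logLik.tsp_logit <- function(object, ...) {
  structure(object$log_likelihood, df = length(object$coefficients),
            nobs = object$nobs, class = "logLik")
}

#' Predicted probabilities from a fitted logistic model
#'
#' @param object A `tsp_logit` fit.
#' @param design A design tibble whose covariate columns match the model's
#'   terms by name (order-independent; extra or missing columns error).
#' @param type `"response"` for probabilities, `"link"` for the linear
#'   predictor.
#' @param ... Unused.
#' @return A numeric vector, one value per design row.
#' @export
predict.tsp_logit <- function(object, design,
                              type = c("response", "link"), ...) {
  type <- match.arg(type)
  stopifnot(is.data.frame(design))
  xdf <- design[, setdiff(names(design), "sample_id"), drop = FALSE]
  need <- object$terms
  if (!setequal(names(xdf), need)) {
    stop("design columns {", paste(sort(names(xdf)), collapse = ", "),
         "} do not match model terms {", paste(sort(need), collapse = ", "),
         "}", call. = FALSE)
  }
  X <- cbind(1, as.matrix(xdf[, need, drop = FALSE]))
  eta <- drop(X %*% object$coefficients)
  if (type == "link") eta else plogis(eta)
}

#' Binomial log-likelihood of a fitted model on given data
#'
#' Evaluates `sum_j y_j log p_j + (1 - y_j) log(1 - p_j)` at the model's
#' coefficients; never positive.
#'
#' @inheritParams predict.tsp_logit
#' @param labels 0/1 outcome vector aligned with the design rows.
#' @return A single non-positive number.
#' @export
log_likelihood <- function(object, design, labels) {
  eta <- predict(object, design, type = "link")
  y <- check_labels(labels, length(eta), require_both = FALSE)
  sum(y * eta - log1p(exp(eta)))
}

#' @rdname fit_logit
#' @param x A `tsp_logit` object.
#' @param ... Unused.
#' @export
tidy.tsp_logit <- function(x, ...) {
  est <- x$coefficients
  se <- x$std_error
  stat <- est / se
  tibble::tibble(
    term = names(est),
    estimate = unname(est),
    std.error = unname(se),
    statistic = unname(stat),
    p.value = 2 * pnorm(-abs(unname(stat)))
  )
}

#' @rdname fit_logit
#' @export
glance.tsp_logit <- function(x, ...) {
  tibble::tibble(
    logLik = x$log_likelihood,
    deviance = -2 * x$log_likelihood,
    AIC = -2 * x$log_likelihood + 2 * length(x$coefficients),
    nobs = x$nobs,
    n_iter = x$n_iter,
    converged = x$converged,
    ridge_used = x$ridge_used
  )
}
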