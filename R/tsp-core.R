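#' Within-sample ordering indicator
#'
#' The elementary relative-expression event: `1` when `x_u < x_v` and `0`
#' otherwise. Ties count as `0` — the ordering "u below v" is only credited
#' when it holds strictly.
#'
#' @param x_u,x_v Numeric vectors of equal length (expression of the two
#'   genes across samples).
#' @return An integer vector of 0/1 values.
#' @examples
#' indicator_lt(c(1, 2, 5), c(2, 2, 0))  # 1 0 0
#' @export
indicator_lt <- function(x_u, x_v) {
  if (!is.numeric(x_u) || !is.numeric(x_v)) {
    stop("indicator_lt() expects numeric inputs", call. = FALSE)
  }
  if (length(x_u) != length(x_v)) {
    stop("x_u and x_v must have equal length", call. = FALSE)
  }
  if (any(!is.finite(x_u)) || any(!is.finite(x_v))) {
    stop("indicator_lt() requires finite values", call. = FALSE)
  }
  as.integer(x_u < x_v)
}

#' Pair score from class-conditional ordering probabilities
#'
#' `tsp_score(p0, p1)` is the absolute difference `|p0 - p1|` between the
#' probabilities of observing the ordering `x_u < x_v` in each class — the
#' quantity maximised by the top-scoring pair method.
#'
#' @param p0,p1 Ordering probabilities in `[0, 1]` (vectorised).
#' @return `|p0 - p1|`.
#' @export
tsp_score <- function(p0, p1) {
  if (any(!is.finite(p0)) || any(!is.finite(p1)) ||
      any(p0 < 0 | p0 > 1) || any(p1 < 0 | p1 > 1)) {
    stop("p0 and p1 must be probabilities in [0, 1]", call. = FALSE)
  }
  abs(p0 - p1)
}

#' Class-conditional ordering probabilities for one gene pair
#'
#' Estimates `p0 = P(x_u < x_v | class 0)` and `p1 = P(x_u < x_v | class 1)`
#' by counting the strict ordering event within each class.
#'
#' @param expression Expression data (see [as_expr_matrix()]).
#' @param labels 0/1 phenotype vector aligned with the sample columns.
#' @param u,v Gene identifiers (or row indices) of the pair; must differ.
#' @return A one-row tibble with `gene_u`, `gene_v`, `p0`, `p1`, `delta`.
#' @export
pair_probs <- function(expression, labels, u, v) {
  x <- as_expr_matrix(expression)
  labels <- check_labels(labels, ncol(x))
  iu <- resolve_gene(x, u)
  iv <- resolve_gene(x, v)
  if (iu == iv) stop("u and v must be two different genes", call. = FALSE)
  ind <- indicator_lt(x[iu, ], x[iv, ])
  p0 <- mean(ind[labels == 0L])
  p1 <- mean(ind[labels == 1L])
  tibble::tibble(gene_u = rownames(x)[iu], gene_v = rownames(x)[iv],
                 p0 = p0, p1 = p1, delta = tsp_score(p0, p1))
}

resolve_gene <- function(x, g) {
  if (is.character(g)) {
    i <- match(g, rownames(x))
    if (is.na(i)) stop("unknown gene identifier: ", g, call. = FALSE)
  } else {
    i <- as.integer(g)
    if (is.na(i) || i < 1L || i > nrow(x)) {
      stop("gene index out of range: ", g, call. = FALSE)
    }
  }
  i
}

#' Score every gene pair by the rank-based reversal statistic
#'
#' Computes, for all `M(M-1)/2` unordered gene pairs, the class-conditional
#' ordering probabilities and their difference `delta`, plus a secondary
#' rank-gap score used to break ties among equal deltas. Each pair is stored
#' once, oriented so that `p0 >= p1` (so the ordering `x_u < x_v` is the one
#' more frequent in class 0), and the result is sorted by
#' (`delta` desc, `tiebreak` desc, gene indices).
#'
#' The tiebreak is the absolute between-class difference of the mean
#' within-sample rank gap of the two genes, the usual secondary statistic of
#' k-TSP selection.
#'
#' @param expression Expression data (see [as_expr_matrix()]).
#' @param labels 0/1 phenotype vector aligned with the sample columns.
#' @param prefilter Optional gene pre-filter applied before pair enumeration:
#'   `"none"` (default; all genes), `"variance"` (top `prefilter_n` genes by
#'   overall variance) or `"ttest"` (top `prefilter_n` by Welch t statistic).
#' @param prefilter_n Number of genes kept when `prefilter != "none"`.
#' @return A tibble with columns `gene_u`, `gene_v`, `p0`, `p1`, `delta`,
#'   `tiebreak`, `rank`.
#' @export
score_pairs <- function(expression, labels,
                        prefilter = c("none", "variance", "ttest"),
                        prefilter_n = 1000L) {
  prefilter <- match.arg(prefilter)
  x <- as_expr_matrix(expression)
  labels <- check_labels(labels, ncol(x))

  if (prefilter != "none" && nrow(x) > prefilter_n) {
    keep <- switch(prefilter,
      variance = order(apply(x, 1L, var), decreasing = TRUE)[seq_len(prefilter_n)],
      ttest = {
        tt <- welch_rows(x, labels)
        order(tt$p_value, -abs(tt$statistic), na.last = TRUE)[seq_len(prefilter_n)]
      }
    )
    x <- x[sort(keep), , drop = FALSE]
  }
  if (nrow(x) < 2L) stop("need at least 2 genes to form pairs", call. = FALSE)

  n0 <- sum(labels == 0L)
  n1 <- sum(labels == 1L)
  cts <- cpp_pair_counts(x, labels)

  # Both ordered directions; with continuous (tie-free) data these carry the
  # same delta and orientation just fixes p0 >= p1.
  p0_f <- cts$c0_lt / n0; p1_f <- cts$c1_lt / n1
  p0_r <- cts$c0_gt / n0; p1_r <- cts$c1_gt / n1
  d_f <- abs(p0_f - p1_f)
  d_r <- abs(p0_r - p1_r)
  ok_f <- p0_f >= p1_f
  ok_r <- p0_r >= p1_r
  # Prefer the p0 >= p1 orientation; among admissible ones take the larger
  # delta; fall back to the larger delta when neither direction satisfies it.
  use_r <- ifelse(ok_f & ok_r, d_r > d_f,
           ifelse(ok_r & !ok_f, TRUE,
           ifelse(ok_f & !ok_r, FALSE, d_r > d_f)))

  iu <- ifelse(use_r, cts$v, cts$u)
  iv <- ifelse(use_r, cts$u, cts$v)
  p0 <- ifelse(use_r, p0_r, p0_f)
  p1 <- ifelse(use_r, p1_r, p1_f)
  delta <- ifelse(use_r, d_r, d_f)

  # Secondary rank-gap score from per-class mean within-sample ranks.
  rk <- apply(x, 2L, rank)
  m0 <- rowMeans(rk[, labels == 0L, drop = FALSE])
  m1 <- rowMeans(rk[, labels == 1L, drop = FALSE])
  tiebreak <- abs((m0[iu] - m0[iv]) - (m1[iu] - m1[iv]))

  ord <- order(-delta, -tiebreak, pmin(iu, iv), pmax(iu, iv))
  out <- tibble::tibble(
    gene_u = rownames(x)[iu][ord],
    gene_v = rownames(x)[iv][ord],
    p0 = p0[ord], p1 = p1[ord], delta = delta[ord],
    tiebreak = unname(tiebreak[ord]),
    rank = seq_along(ord)
  )
  attr(out, "n0") <- n0
  attr(out, "n1") <- n1
  out
}

#' Select the top-scoring pairs as a classifier panel
#'
#' Takes the first `k` pairs of a sorted pair-score table. With
#' `disjoint = TRUE` (default) a pair sharing a gene with an
#' already-selected pair is skipped, so the panel genes are non-overlapping.
#'
#' @param scores A pair-score tibble as produced by [score_pairs()].
#' @param k Number of pairs to select (>= 1).
#' @param disjoint Require gene-disjoint pairs (greedy skip)?
#' @return A tibble of `k` rows (a "TSP panel") with a `disjoint` attribute.
#' @export
select_pairs <- function(scores, k = 1L, disjoint = TRUE) {
  stopifnot(is.data.frame(scores))
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be a positive integer", call. = FALSE)
  if (disjoint) {
    used <- character(0)
    pick <- integer(0)
    for (i in seq_len(nrow(scores))) {
      g <- c(scores$gene_u[i], scores$gene_v[i])
      if (!any(g %in% used)) {
        pick <- c(pick, i)
        used <- c(used, g)
        if (length(pick) == k) break
      }
    }
  } else {
    pick <- seq_len(min(k, nrow(scores)))
  }
  if (length(pick) < k) {
    stop("requested ", k, " pairs but only ", length(pick),
         " eligible pairs are available", call. = FALSE)
  }
  out <- scores[pick, , drop = FALSE]
  attr(out, "disjoint") <- disjoint
  out
}

#' Classify samples with a single top-scoring pair
#'
#' For a pair oriented so the ordering `x_u < x_v` is the one more frequent
#' in class 0 (`p0 >= p1`), a sample is predicted class 0 when it shows that
#' ordering and class 1 otherwise.
#'
#' @param expression Expression data containing the pair's genes.
#' @param pair A one-row pair table (a row of [score_pairs()] output).
#' @return A tibble with `sample_id` and `predicted` (0/1 integer).
#' @export
tsp_predict <- function(expression, pair) {
  stopifnot(is.data.frame(pair), nrow(pair) == 1L)
  x <- as_expr_matrix(expression)
  iu <- resolve_gene(x, pair$gene_u)
  iv <- resolve_gene(x, pair$gene_v)
  ind <- indicator_lt(x[iu, ], x[iv, ])
  tibble::tibble(sample_id = colnames(x),
                 predicted = ifelse(ind == 1L, 0L, 1L))
}

#' Pair indicator features for a panel of gene pairs
#'
#' One 0/1 column per pair: the within-sample ordering event
#' `x_u < x_v` for that pair's genes.
#'
#' @param expression Expression data containing the panel's genes.
#' @param panel A pair table ([select_pairs()] output).
#' @return A tibble with `sample_id` plus one `tsp<i>` column per pair.
#' @export
predict_pairs <- function(expression, panel) {
  stopifnot(is.data.frame(panel), nrow(panel) >= 1L)
  x <- as_expr_matrix(expression)
  cols <- lapply(seq_len(nrow(panel)), function(i) {
    iu <- resolve_gene(x, panel$gene_u[i])
    iv <- resolve_gene(x, panel$gene_v[i])
    indicator_lt(x[iu, ], x[iv, ])
  })
  names(cols) <- paste0("tsp", seq_len(nrow(panel)))
  tibble::as_tibble(c(list(sample_id = colnames(x)), cols))
}
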