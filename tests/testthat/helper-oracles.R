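# Independent brute-force oracles: plain double loops, no shared code with
# the package internals.

# Recount ordering indicators per class for every unordered pair, applying
# the documented orientation contract (prefer p0 >= p1; among admissible
# orientations take the larger delta).
oracle_pair_scores <- function(x, labels) {
  m <- nrow(x)
  out <- list()
  r <- 0L
  for (a in seq_len(m - 1)) {
    for (b in seq(a + 1, m)) {
      p0_f <- mean(x[a, labels == 0] < x[b, labels == 0])
      p1_f <- mean(x[a, labels == 1] < x[b, labels == 1])
      p0_r <- mean(x[b, labels == 0] < x[a, labels == 0])
      p1_r <- mean(x[b, labels == 1] < x[a, labels == 1])
      d_f <- abs(p0_f - p1_f); d_r <- abs(p0_r - p1_r)
      ok_f <- p0_f >= p1_f; ok_r <- p0_r >= p1_r
      rev <- if (ok_f && ok_r) d_r > d_f else if (ok_r && !ok_f) TRUE
             else if (ok_f && !ok_r) FALSE else d_r > d_f
      r <- r + 1L
      out[[r]] <- data.frame(
        gene_u = rownames(x)[if (rev) b else a],
        gene_v = rownames(x)[if (rev) a else b],
        p0 = if (rev) p0_r else p0_f,
        p1 = if (rev) p1_r else p1_f,
        delta = if (rev) d_r else d_f
      )
    }
  }
  do.call(rbind, out)
}

# Exhaustive O(n_pos * n_neg) AUC with ties counted one half.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Direct term-by-term binomial log-likelihood.
oracle_loglik <- function(beta, X, y) {
  eta <- as.vector(cbind(1, X) %*% beta)
  p <- 1 / (1 + exp(-eta))
  sum(y * log(p) + (1 - y) * log(1 - p))
}

# Sort-and-interpolate percentile (type-7 definition written out by hand).
oracle_quantile <- function(v, prob) {
  v <- sort(v)
  n <- length(v)
  h <- (n - 1) * prob + 1
  lo <- floor(h); hi <- ceiling(h)
  v[lo] + (h - lo) * (v[hi] - v[lo])
}

random_expr <- function(m, n, seed) {
  set.seed(seed)
  x <- matrix(rnorm(m * n, mean = 8, sd = 2), m, n)
  dimnames(x) <- list(sprintf("g%03d", seq_len(m)), sprintf("s%03d", seq_len(n)))
  x
}

random_labels <- function(n, seed, p = 0.5) {
  set.seed(seed)
  repeat {
    y <- rbinom(n, 1, p)
    if (length(unique(y)) == 2) return(y)
  }
}
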