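`%||%` <- function(x, y) if (is.null(x)) y else x

# Evaluate code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Independent sub-seeds spawned from the current RNG stream; kept < 2^31.
draw_subseeds <- function(n) {
  sample.int(.Machine$integer.max - 1L, n)
}

#' Coerce a tabular expression object to a genes-by-samples matrix
#'
#' Accepts either a numeric matrix with gene identifiers as row names and
#' sample identifiers as column names, or a data frame whose first column
#' holds gene identifiers and whose remaining columns are one numeric column
#' per sample (the layout written by [write_expression()]).
#'
#' @param expression Expression data as described above.
#' @return A numeric matrix (genes x samples) with dimnames.
#' @export
as_expr_matrix <- function(expression) {
  if (is.matrix(expression)) {
    x <- expression
    if (is.null(rownames(x)) || is.null(colnames(x))) {
      stop("expression matrix must carry gene row names and sample column names",
           call. = FALSE)
    }
  } else if (is.data.frame(expression)) {
    if (ncol(expression) < 2L) {
      stop("expression table needs a gene identifier column plus sample columns",
           call. = FALSE)
    }
    ids <- as.character(expression[[1L]])
    x <- as.matrix(expression[, -1L, drop = FALSE])
    storage.mode(x) <- "double"
    rownames(x) <- ids
  } else {
    stop("expression must be a matrix or a data frame", call. = FALSE)
  }
  if (nrow(x) < 2L || ncol(x) < 2L) {
    stop("expression data must have at least 2 genes and 2 samples", call. = FALSE)
  }
  if (anyDuplicated(rownames(x))) {
    dup <- unique(rownames(x)[duplicated(rownames(x))])
    stop("duplicated gene identifiers: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(colnames(x))) {
    dup <- unique(colnames(x)[duplicated(colnames(x))])
    stop("duplicated sample identifiers: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(x))) {
    stop("expression values must all be finite (no NA/NaN/Inf)", call. = FALSE)
  }
  x
}

# Validate a binary phenotype vector against a sample count.
check_labels <- function(labels, n = NULL, require_both = TRUE) {
  if (is.logical(labels)) labels <- as.integer(labels)
  if (!is.numeric(labels) || any(is.na(labels)) || !all(labels %in% c(0, 1))) {
    stop("labels must be a vector of 0/1 values with no missing entries",
         call. = FALSE)
  }
  labels <- as.integer(labels)
  if (!is.null(n) && length(labels) != n) {
    stop("labels length (", length(labels), ") does not match sample count (",
         n, ")", call. = FALSE)
  }
  if (require_both) {
    if (sum(labels == 0L) < 1L) stop("no class-0 samples in labels", call. = FALSE)
    if (sum(labels == 1L) < 1L) stop("no class-1 samples in labels", call. = FALSE)
  }
  labels
}

# Convert a genes-by-samples matrix back to the tabular layout.
expr_as_tibble <- function(x) {
  tibble::as_tibble(cbind(
    tibble::tibble(gene_id = rownames(x)),
    tibble::as_tibble(x)
  ))
}
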