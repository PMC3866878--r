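#' Read a tab-delimited expression table
#'
#' Expected layout: header row of sample identifiers, first column the gene
#' identifier, one row per gene, tab-delimited. Duplicated gene identifiers,
#' non-numeric cells and ragged rows are rejected with the offending
#' location.
#'
#' @param path File path.
#' @return A tibble (`gene_id` + one numeric column per sample).
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_guess()))
  probs <- readr::problems(tbl)
  if (nrow(probs) > 0L) {
    stop("malformed expression file ", path, " (first issue at line ",
         probs$row[1] + 1L, ": ", probs$expected[1], ")", call. = FALSE)
  }
  if (ncol(tbl) < 3L) {
    stop("expression file needs a gene column and at least 2 samples",
         call. = FALSE)
  }
  names(tbl)[1] <- "gene_id"
  tbl$gene_id <- as.character(tbl$gene_id)
  bad <- !vapply(tbl[-1L], is.numeric, logical(1))
  if (any(bad)) {
    stop("non-numeric expression column(s): ",
         paste(names(tbl)[-1L][bad], collapse = ", "), call. = FALSE)
  }
  as_expr_matrix(tbl)  # full validation (duplicates, finiteness)
  tbl
}

#' Write a tab-delimited expression table
#'
#' @param expression Expression data (tibble or matrix).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expression, path) {
  x <- as_expr_matrix(expression)
  readr::write_tsv(expr_as_tibble(x), path)
  invisible(path)
}

#' Read a clinical table with outcome labels
#'
#' CSV schema: `sample_id, age, gleason_score, tumor_pct, erg_fusion, label`.
#' Ranges are validated (age > 0, tumor_pct in \[0, 100\], erg_fusion and
#' label in \{0, 1\}) and a single-class label column is rejected before any
#' modeling can happen. When `sample_ids` is supplied the table is aligned
#' to that order and unmatched identifiers are an error.
#'
#' @param path File path.
#' @param sample_ids Optional character vector giving the required sample
#'   order (e.g. the expression column order).
#' @return A list with `clinical` (tibble without the label column) and
#'   `labels` (integer 0/1 vector).
#' @export
read_clinical <- function(path, sample_ids = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", "age", "gleason_score", "tumor_pct", "erg_fusion",
            "label")
  missing_cols <- setdiff(need, names(tbl))
  if (length(missing_cols)) {
    stop("clinical file lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  tbl$sample_id <- as.character(tbl$sample_id)
  if (anyDuplicated(tbl$sample_id)) {
    stop("duplicated sample_id in clinical file", call. = FALSE)
  }
  ok_age <- is.na(tbl$age) | tbl$age > 0
  if (!all(ok_age)) stop("age must be positive", call. = FALSE)
  ok_t <- is.na(tbl$tumor_pct) | (tbl$tumor_pct >= 0 & tbl$tumor_pct <= 100)
  if (!all(ok_t)) {
    stop("tumor_pct out of [0, 100] for sample(s): ",
         paste(tbl$sample_id[!ok_t], collapse = ", "), call. = FALSE)
  }
  ok_e <- is.na(tbl$erg_fusion) | tbl$erg_fusion %in% c(0, 1)
  if (!all(ok_e)) stop("erg_fusion must be 0 or 1", call. = FALSE)

  if (!is.null(sample_ids)) {
    unmatched <- setdiff(sample_ids, tbl$sample_id)
    if (length(unmatched)) {
      stop("clinical file is missing sample id(s): ",
           paste(unmatched, collapse = ", "), call. = FALSE)
    }
    tbl <- tbl[match(sample_ids, tbl$sample_id), , drop = FALSE]
  }
  labels <- check_labels(tbl$label)  # rejects single-class outcomes
  list(clinical = tbl[, setdiff(names(tbl), "label"), drop = FALSE],
       labels = labels)
}

#' Write a clinical table (with labels) to CSV
#'
#' @param clinical Clinical tibble including a `label` column (as produced
#'   by [simulate_tsp_dataset()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clinical, path) {
  readr::write_csv(clinical, path)
  invisible(path)
}

#' Write / read a pair-score table
#'
#' Tab-delimited with columns `gene_u, gene_v, p0, p1, delta, tiebreak,
#' rank`, in score order.
#'
#' @param scores Pair-score tibble from [score_pairs()].
#' @param path File path.
#' @return `path` invisibly (write); the tibble (read).
#' @export
write_pair_scores <- function(scores, path) {
  readr::write_tsv(scores, path)
  invisible(path)
}

#' @rdname write_pair_scores
#' @export
read_pair_scores <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write a machine-readable run manifest
#'
#' Records the configuration, seed and package version of a run as JSON so
#' any output can be regenerated from the manifest alone.
#'
#' @param config Named list of run parameters.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(config, path) {
  config$package_version <- as.character(utils::packageVersion("tsplogit"))
  config$r_version <- paste(R.version$major, R.version$minor, sep = ".")
  jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
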