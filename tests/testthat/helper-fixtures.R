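# The six-sample counting example: class 0 pairs (1,2),(3,4),(5,1) and
# class 1 pairs (2,1),(4,3),(1,5), giving p0 = 2/3, p1 = 1/3.
counting_example <- function() {
  x <- rbind(
    gA = c(1, 3, 5, 2, 4, 1),
    gB = c(2, 4, 1, 1, 3, 5)
  )
  colnames(x) <- paste0("s", 1:6)
  list(x = x, labels = c(0, 0, 0, 1, 1, 1))
}

# Minimal clinical table matched to a sample id vector.
toy_clinical <- function(sample_ids, labels, seed = 1) {
  set.seed(seed)
  n <- length(sample_ids)
  tibble::tibble(
    sample_id = sample_ids,
    age = round(rnorm(n, 72, 6), 1),
    gleason_score = sample(6:9, n, replace = TRUE),
    tumor_pct = round(runif(n, 5, 95), 1),
    erg_fusion = rbinom(n, 1, 0.4),
    label = as.integer(labels)
  )
}
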