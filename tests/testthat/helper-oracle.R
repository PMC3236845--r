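# Independent brute-force oracle for the best-offset search: enumerate every
# achievable {score >= t} / {score < t} partition (thresholds at each
# distinct score plus +Inf) and minimize the weighted two-cell entropy,
# computed from scratch with table().
bf_best_entropy <- function(scores, labels) {
  n <- length(scores)
  best <- Inf
  for (t in c(sort(unique(scores)), Inf)) {
    up <- scores >= t
    e <- 0
    for (cell in list(which(up), which(!up))) {
      if (length(cell) > 0L) {
        p <- as.numeric(table(labels[cell])) / length(cell)
        e <- e + (length(cell) / n) * (-sum(p * log2(p)))
      }
    }
    best <- min(best, e)
  }
  best
}

# Hand-rolled binary entropy in bits.
hbin <- function(p) {
  term <- function(z) if (z > 0) -z * log2(z) else 0
  term(p) + term(1 - p)
}

# Row subsetting that bypasses construction-time validation, as the
# evaluation harness does internally.
.subset_rows_for_test <- function(d, idx) splitrank:::.subset_rows(d, idx)

# Write a small dataset CSV + schema JSON pair into a temp dir and return
# the two paths.
write_toy_csv <- function(df, roles, dir = NULL) {
  if (is.null(dir)) {
    dir <- tempfile("toy")
    dir.create(dir)
  }
  csv <- file.path(dir, "toy.csv")
  utils::write.csv(df, csv, row.names = FALSE, quote = FALSE)
  schema <- file.path(dir, "toy.json")
  write_schema(attribute_schema(roles), schema)
  list(csv = csv, schema = schema)
}
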