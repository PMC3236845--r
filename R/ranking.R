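# Ranking reports and their TSV/JSON serialization.

#' Build a ranking report from entropy estimates
#'
#' @param estimates List of `entropy_estimate` objects (see
#'   [attribute_conditional_entropy()]).
#' @param seed Base seed of the ranking run, recorded in the metadata.
#' @return A `ranking_report` data frame with columns `rank`, `attribute`,
#'   `q`, `entropy_bits`, sorted ascending by entropy (ties broken by
#'   attribute name). The per-attribute estimates and the run metadata
#'   (`n_projections`, `seed`, `kernel`) are carried as attributes.
#' @export
ranking_report <- function(estimates, seed = NULL) {
  stopifnot(length(estimates) > 0L)
  df <- data.frame(
    attribute = vapply(estimates, function(e) e$attribute, character(1L)),
    q = vapply(estimates, function(e) e$q, integer(1L)),
    entropy_bits = vapply(estimates, function(e) e$entropy, numeric(1L)),
    stringsAsFactors = FALSE
  )
  o <- order(df$entropy_bits, df$attribute)
  df <- df[o, , drop = FALSE]
  df <- cbind(rank = seq_len(nrow(df)), df)
  rownames(df) <- NULL
  structure(df,
            class = c("ranking_report", "data.frame"),
            estimates = estimates[o],
            meta = list(
              n_projections = estimates[[1L]]$n_projections,
              seed = seed,
              kernel = format(estimates[[1L]]$kernel)
            ))
}

#' Write or read a ranking report
#'
#' The report is written as a TSV with columns `rank`, `attribute`, `q`,
#' `entropy_bits` (entropies printed with 17 significant digits so the
#' round-trip is lossless) plus a JSON sidecar `<path>.json` recording the
#' number of projections, the seed and the kernel.
#'
#' @param report A [ranking_report()]; must be non-empty.
#' @param path Output TSV path.
#' @return `write_ranking()` returns `path` invisibly; `read_ranking()`
#'   returns the reconstructed `ranking_report`.
#' @export
write_ranking <- function(report, path) {
  if (!inherits(report, "ranking_report") || nrow(report) == 0L) {
    stop("cannot write an empty ranking report", call. = FALSE)
  }
  lines <- c(
    "rank\tattribute\tq\tentropy_bits",
    sprintf("%d\t%s\t%d\t%.17g",
            report$rank, report$attribute, report$q, report$entropy_bits)
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  meta <- attr(report, "meta") %||% list()
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_ranking
#' @export
read_ranking <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  meta <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) meta <- jsonlite::fromJSON(sidecar)
  structure(df, class = c("ranking_report", "data.frame"), meta = meta)
}

#' @export
print.ranking_report <- function(x, ...) {
  meta <- attr(x, "meta")
  cat("<ranking_report>")
  if (!is.null(meta)) {
    cat(sprintf(" N=%s seed=%s kernel=%s",
                meta$n_projections %||% "?",
                meta$seed %||% "none", meta$kernel %||% "?"))
  }
  cat("\n")
  print.data.frame(x)
  invisible(x)
}
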