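# Dataset container and schema-driven CSV I/O.

.encode_codes <- function(x, levels = NULL, what = "value") {
  x <- as.character(x)
  if (is.null(levels)) levels <- unique(x)  # first-appearance order
  codes <- match(x, levels)
  if (anyNA(codes)) {
    bad <- unique(x[is.na(codes)])
    stop(sprintf("%s '%s' not in the declared level set", what, bad[1L]),
         call. = FALSE)
  }
  list(codes = as.integer(codes), levels = as.character(levels))
}

#' Construct a supervised dataset
#'
#' The container holds a continuous feature matrix, integer class codes in
#' `1..k`, and a table of candidate categorical partition attributes stored
#' as dense integer level codes `1..q` (level names are kept for reporting;
#' codes are assigned in first-appearance order unless levels are declared).
#'
#' @param features Numeric matrix (or data frame), one sample per row.
#' @param labels Class labels; coerced to character and encoded as integer
#'   codes against `label_levels`.
#' @param categorical Optional data frame of categorical attribute values,
#'   one column per candidate attribute.
#' @param label_levels,cat_levels Optional declared level orders: a character
#'   vector for labels, a named list of character vectors for categorical
#'   attributes. Observed values must belong to the declared sets.
#' @param label_name Name used for the label column when the dataset is
#'   written back to CSV.
#' @param sample_ids Optional opaque identifiers, one per row.
#' @return An object of class `supervised_dataset` with elements `features`,
#'   `labels` (integer codes), `label_levels`, `categorical` (integer code
#'   data frame), `cat_levels`, `label_name`, `sample_ids`.
#' @export
supervised_dataset <- function(features, labels, categorical = NULL,
                               label_levels = NULL, cat_levels = NULL,
                               label_name = "y", sample_ids = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (anyNA(features)) {
    stop("missing values in continuous features are not supported", call. = FALSE)
  }
  if (is.null(colnames(features))) {
    colnames(features) <- paste0("V", seq_len(ncol(features)))
  }
  n <- nrow(features)
  if (length(labels) != n) stop("labels and features disagree on row count", call. = FALSE)
  if (anyNA(labels)) stop("missing class labels are not allowed", call. = FALSE)
  lab <- .encode_codes(labels, label_levels, what = "label")
  if (length(lab$levels) < 2L) {
    stop("label column has fewer than 2 classes", call. = FALSE)
  }

  if (is.null(categorical)) {
    categorical <- data.frame(matrix(nrow = n, ncol = 0L))
  }
  categorical <- as.data.frame(categorical, stringsAsFactors = FALSE)
  if (nrow(categorical) != n && ncol(categorical) > 0L) {
    stop("categorical table and features disagree on row count", call. = FALSE)
  }
  levs <- list()
  codes <- categorical
  for (nm in names(categorical)) {
    if (anyNA(categorical[[nm]])) {
      stop(sprintf("missing values in categorical attribute '%s'", nm), call. = FALSE)
    }
    enc <- .encode_codes(categorical[[nm]], cat_levels[[nm]],
                         what = sprintf("attribute '%s' level", nm))
    codes[[nm]] <- enc$codes
    levs[[nm]] <- enc$levels
  }
  if (!is.null(sample_ids) && length(sample_ids) != n) {
    stop("sample_ids and features disagree on row count", call. = FALSE)
  }

  structure(
    list(features = features, labels = lab$codes, label_levels = lab$levels,
         categorical = codes, cat_levels = levs,
         label_name = label_name, sample_ids = sample_ids),
    class = "supervised_dataset"
  )
}

#' @export
print.supervised_dataset <- function(x, ...) {
  cat(sprintf(
    "<supervised_dataset> %d samples, %d continuous features, %d classes, %d categorical attribute(s)\n",
    nrow(x$features), ncol(x$features), length(x$label_levels),
    ncol(x$categorical)))
  if (ncol(x$categorical) > 0L) {
    q <- vapply(x$cat_levels, length, integer(1L))
    cat("  attributes:", paste(sprintf("%s (q=%d)", names(q), q), collapse = ", "), "\n")
  }
  invisible(x)
}

n_samples <- function(dataset) nrow(dataset$features)
n_classes <- function(dataset) length(dataset$label_levels)

#' Declare column roles for a tabular dataset
#'
#' @param columns Named character vector mapping every CSV column to a role
#'   in `continuous`, `categorical`, `label`, `ignore`. Exactly one column
#'   must have the `label` role.
#' @param max_levels Cardinality cap used by [filter_candidates()]; attributes
#'   with more observed levels are dropped from ranking (default 10).
#' @param levels Optional named list declaring the level order of categorical
#'   attributes.
#' @param label_levels Optional declared label level order.
#' @return An object of class `attribute_schema`.
#' @export
attribute_schema <- function(columns, max_levels = 10L, levels = NULL,
                             label_levels = NULL) {
  columns <- unlist(columns)
  if (is.null(names(columns)) || any(!nzchar(names(columns)))) {
    stop("every column role must be named", call. = FALSE)
  }
  ok <- columns %in% c("continuous", "categorical", "label", "ignore")
  if (!all(ok)) {
    stop(sprintf("unknown column role '%s'", columns[!ok][1L]), call. = FALSE)
  }
  if (sum(columns == "label") != 1L) {
    stop("schema must declare exactly one label column", call. = FALSE)
  }
  if (!is.numeric(max_levels) || max_levels < 2) {
    stop("max_levels must be at least 2", call. = FALSE)
  }
  structure(list(columns = columns, max_levels = as.integer(max_levels),
                 levels = levels, label_levels = label_levels),
            class = "attribute_schema")
}

#' Read or write an attribute schema as JSON
#'
#' The JSON layout is `{"columns": {name: role, ...}, "max_levels": int}`
#' with optional `"levels"` and `"label_levels"` entries declaring level
#' orders.
#'
#' @param path Path of the JSON file.
#' @return `read_schema()` returns an [attribute_schema()]; `write_schema()`
#'   returns `path` invisibly.
#' @export
read_schema <- function(path) {
  js <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  levels <- js$levels
  if (!is.null(levels)) levels <- lapply(levels, as.character)
  attribute_schema(columns = unlist(js$columns),
                   max_levels = js$max_levels %||% 10L,
                   levels = levels,
                   label_levels = js$label_levels)
}

#' @rdname read_schema
#' @param schema An [attribute_schema()].
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "attribute_schema"))
  out <- list(columns = as.list(schema$columns), max_levels = schema$max_levels)
  if (!is.null(schema$levels)) out$levels <- schema$levels
  if (!is.null(schema$label_levels)) out$label_levels <- schema$label_levels
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a CSV file into a supervised dataset
#'
#' The CSV must have a header row and the schema must assign a role to every
#' column. Continuous columns must parse as numbers with no missing entries;
#' the label column must contain at least two distinct values. Row order is
#' preserved.
#'
#' @param csv_path Path of the CSV file.
#' @param schema An [attribute_schema()] (or path of a schema JSON file).
#' @return A [supervised_dataset()].
#' @export
read_dataset <- function(csv_path, schema) {
  if (is.character(schema)) schema <- read_schema(schema)
  stopifnot(inherits(schema, "attribute_schema"))
  df <- utils::read.csv(csv_path, check.names = FALSE, stringsAsFactors = FALSE)
  roles <- schema$columns
  missing_role <- setdiff(names(df), names(roles))
  if (length(missing_role) > 0L) {
    stop(sprintf("column '%s' has no role in the schema", missing_role[1L]),
         call. = FALSE)
  }
  label_col <- names(roles)[roles == "label"]
  if (!label_col %in% names(df)) {
    stop(sprintf("label column '%s' is missing from the file", label_col),
         call. = FALSE)
  }
  cont_cols <- intersect(names(df), names(roles)[roles == "continuous"])
  cat_cols <- intersect(names(df), names(roles)[roles == "categorical"])
  for (nm in cont_cols) {
    if (!is.numeric(df[[nm]])) {
      stop(sprintf("non-numeric value in continuous column '%s'", nm),
           call. = FALSE)
    }
  }
  if (length(unique(df[[label_col]])) < 2L) {
    stop("label column has fewer than 2 classes", call. = FALSE)
  }
  supervised_dataset(
    features = df[cont_cols], labels = df[[label_col]],
    categorical = df[cat_cols],
    label_levels = schema$label_levels, cat_levels = schema$levels,
    label_name = label_col
  )
}

#' Write a supervised dataset back to CSV
#'
#' Categorical codes and labels are written as their level names so that
#' re-reading the file with a schema that declares the same level orders
#' (written by `schema_path`, or [dataset_schema()]) reproduces the dataset
#' exactly.
#'
#' @param dataset A [supervised_dataset()].
#' @param csv_path Output CSV path.
#' @param schema_path Optional path; when given, a schema JSON with explicit
#'   level declarations is written alongside.
#' @return `csv_path`, invisibly.
#' @export
write_dataset <- function(dataset, csv_path, schema_path = NULL) {
  stopifnot(inherits(dataset, "supervised_dataset"))
  df <- as.data.frame(dataset$features, check.names = FALSE)
  for (nm in names(dataset$categorical)) {
    df[[nm]] <- dataset$cat_levels[[nm]][dataset$categorical[[nm]]]
  }
  df[[dataset$label_name]] <- dataset$label_levels[dataset$labels]
  utils::write.csv(df, csv_path, row.names = FALSE, quote = FALSE)
  if (!is.null(schema_path)) write_schema(dataset_schema(dataset), schema_path)
  invisible(csv_path)
}

#' Schema describing an existing dataset
#'
#' @param dataset A [supervised_dataset()].
#' @param max_levels Cardinality cap recorded in the schema.
#' @return An [attribute_schema()] with explicit level declarations.
#' @export
dataset_schema <- function(dataset, max_levels = 10L) {
  roles <- c(
    stats::setNames(rep("continuous", ncol(dataset$features)),
                    colnames(dataset$features)),
    stats::setNames(rep("categorical", ncol(dataset$categorical)),
                    names(dataset$categorical))
  )
  roles[dataset$label_name] <- "label"
  attribute_schema(roles, max_levels = max_levels,
                   levels = dataset$cat_levels,
                   label_levels = dataset$label_levels)
}

.subset_rows <- function(dataset, idx) {
  structure(
    list(features = dataset$features[idx, , drop = FALSE],
         labels = dataset$labels[idx],
         label_levels = dataset$label_levels,
         categorical = dataset$categorical[idx, , drop = FALSE],
         cat_levels = dataset$cat_levels,
         label_name = dataset$label_name,
         sample_ids = dataset$sample_ids[idx]),
    class = "supervised_dataset"
  )
}
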