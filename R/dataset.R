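#' Declare the kind of a single feature
#'
#' A feature schema records how a column is to be interpreted:
#' `"continuous"` features take arbitrary real values, `"categorical"`
#' and `"ordinal"` features are integer-coded with an explicit set of
#' valid level codes, and `"uninformative"` features are continuous
#' noise columns carrying no outcome signal.
#'
#' @param name Feature name (unique within a dataset).
#' @param kind One of `"continuous"`, `"categorical"`, `"ordinal"`,
#'   `"uninformative"`.
#' @param levels Ordered numeric vector of valid codes for coded
#'   (categorical/ordinal) features; must be empty for continuous and
#'   uninformative features.
#' @return An object of class `mb_feature_schema`.
#' @export
feature_schema <- function(name, kind, levels = numeric(0)) {
  kind <- match.arg(kind, c("continuous", "categorical", "ordinal", "uninformative"))
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop_invalid("feature name must be a non-empty string")
  }
  coded <- kind %in% c("categorical", "ordinal")
  levels <- as.numeric(levels)
  if (coded && length(levels) < 2L) {
    stop_invalid("feature '%s': %s features need >= 2 levels", name, kind)
  }
  if (!coded && length(levels) > 0L) {
    stop_invalid("feature '%s': %s features must not declare levels", name, kind)
  }
  structure(list(name = name, kind = kind, levels = sort(levels)),
            class = "mb_feature_schema")
}

is_coded <- function(fs) fs$kind %in% c("categorical", "ordinal")

#' Construct a dataset container
#'
#' Bundles an `N x d` numeric value matrix with its per-feature schema
#' and (optionally) a binary outcome vector. Missing cells are
#' represented internally by `NA`.
#'
#' @param values Numeric matrix, one row per sample, one column per
#'   feature.
#' @param schema List of [feature_schema()] objects, one per column. If
#'   omitted, all columns are declared continuous.
#' @param labels Optional length-`N` vector with entries in `{0, 1}`.
#' @param seed Integer recorded for provenance (`NA` if the data did not
#'   come from a seeded generator).
#' @return An object of class `mb_dataset` with elements `values`,
#'   `schema`, `labels`, `seed`.
#' @export
mb_dataset <- function(values, schema = NULL, labels = NULL, seed = NA_integer_) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values)
  d <- ncol(values)
  if (n < 1L || d < 1L) stop_invalid("dataset must have >= 1 row and >= 1 column")
  rownames(values) <- NULL
  if (is.null(schema)) {
    nm <- colnames(values)
    if (is.null(nm)) nm <- character(d)
    blank <- !nzchar(nm)
    nm[blank] <- sprintf("f%02d", which(blank))
    schema <- lapply(nm, feature_schema, kind = "continuous")
  }
  if (length(schema) != d) stop_invalid("schema length (%d) != number of columns (%d)",
                                        length(schema), d)
  nms <- vapply(schema, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop_invalid("feature names must be unique")
  colnames(values) <- nms
  for (j in seq_len(d)) {
    fs <- schema[[j]]
    if (is_coded(fs)) {
      obs <- values[, j][!is.na(values[, j])]
      bad <- setdiff(unique(obs), fs$levels)
      if (length(bad)) {
        stop_invalid("column '%s' contains code %s outside its declared levels",
                     fs$name, format(bad[1]))
      }
    }
  }
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != n) stop_invalid("labels length != number of rows")
    if (!all(labels %in% c(0L, 1L))) stop_invalid("labels must be 0/1")
  }
  structure(list(values = values, schema = schema, labels = labels,
                 seed = as.integer(seed)),
            class = "mb_dataset")
}

#' @export
print.mb_dataset <- function(x, ...) {
  kinds <- table(vapply(x$schema, `[[`, character(1), "kind"))
  cat(sprintf("<mb_dataset> %d samples x %d features (%s)%s; %d missing cells\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s %s", kinds, names(kinds)), collapse = ", "),
              if (is.null(x$labels)) "" else "; binary outcome",
              sum(is.na(x$values))))
  invisible(x)
}

n_samples <- function(ds) nrow(ds$values)
n_features <- function(ds) ncol(ds$values)

subset_rows <- function(ds, idx) {
  mb_dataset(ds$values[idx, , drop = FALSE], ds$schema,
             if (is.null(ds$labels)) NULL else ds$labels[idx], ds$seed)
}

as_values <- function(x) {
  if (inherits(x, "mb_dataset")) x$values else {
    x <- as.matrix(x); storage.mode(x) <- "double"; x
  }
}

# full-precision number formatting: %.17g round-trips doubles exactly
fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- ""
  out
}

#' Write a dataset to CSV with a JSON schema sidecar
#'
#' The CSV has one header row of feature names (labels, if present, go
#' in a final column named `outcome`); missing cells are written as
#' empty fields. Doubles are written with 17 significant digits so that
#' a write/read round trip is bit-identical. The sidecar lists feature
#' kinds and levels.
#'
#' @param ds An [mb_dataset()].
#' @param path Output CSV path.
#' @param schema_path Output path for the JSON schema sidecar; defaults
#'   to `path` with a `.schema.json` extension.
#' @return Invisibly, the two paths written.
#' @export
write_dataset_csv <- function(ds, path, schema_path = NULL) {
  if (is.null(schema_path)) schema_path <- schema_path_for(path)
  m <- apply(ds$values, 2, fmt_num)
  if (!is.matrix(m)) m <- matrix(m, nrow = nrow(ds$values))
  colnames(m) <- colnames(ds$values)
  if (!is.null(ds$labels)) m <- cbind(m, outcome = as.character(ds$labels))
  write.table(m, path, sep = ",", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  sch <- lapply(ds$schema, function(fs) {
    list(name = fs$name, kind = fs$kind, levels = fs$levels)
  })
  jsonlite::write_json(list(features = sch, seed = ds$seed),
                       schema_path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(path, schema_path))
}

schema_path_for <- function(path) sub("\\.csv$", "", path) |> paste0(".schema.json")

read_schema_json <- function(schema_path) {
  raw <- jsonlite::read_json(schema_path)
  schema <- lapply(raw$features, function(f) {
    feature_schema(f$name, f$kind, unlist(f$levels))
  })
  list(schema = schema,
       seed = if (is.null(raw$seed)) NA_integer_ else raw$seed)
}

#' Read a dataset from CSV plus its schema sidecar
#'
#' Empty fields become missing cells. Coded columns are validated
#' against their declared levels; a violation reports the offending row
#' and column.
#'
#' @param path CSV path written by [write_dataset_csv()] (or matching
#'   its layout: header row, optional final `outcome` column).
#' @param schema_path JSON schema sidecar path.
#' @return An [mb_dataset()], possibly containing missing cells.
#' @export
read_dataset_csv <- function(path, schema_path = NULL) {
  if (is.null(schema_path)) schema_path <- schema_path_for(path)
  sch <- read_schema_json(schema_path)
  df <- read.csv(path, check.names = FALSE, na.strings = "",
                 colClasses = "numeric")
  labels <- NULL
  if ("outcome" %in% names(df)) {
    labels <- df[["outcome"]]
    df[["outcome"]] <- NULL
  }
  want <- vapply(sch$schema, `[[`, character(1), "name")
  if (!identical(names(df), want)) {
    stop_invalid("CSV header does not match schema sidecar (saw: %s)",
                 paste(names(df), collapse = ", "))
  }
  vals <- as.matrix(df)
  for (j in seq_along(sch$schema)) {
    fs <- sch$schema[[j]]
    if (is_coded(fs)) {
      bad <- which(!is.na(vals[, j]) & !(vals[, j] %in% fs$levels))
      if (length(bad)) {
        stop_invalid("invalid level code %s at row %d, column '%s'",
                     format(vals[bad[1], j]), bad[1], fs$name)
      }
    }
  }
  mb_dataset(vals, sch$schema, labels, sch$seed)
}
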