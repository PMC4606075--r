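#' Read and write feature datasets as CSV
#'
#' The CSV form of a [feature_dataset()]: one header row, numeric feature
#' columns, and a named label column carrying class names (never indices).
#' Writing then reading reproduces the dataset exactly; the class-name order
#' is first appearance in the file.
#'
#' @param path File path.
#' @param label Name of the label column.
#' @return `read_dataset_csv` returns a [feature_dataset()];
#'   `write_dataset_csv` returns `path` invisibly.
#' @export
read_dataset_csv <- function(path, label = "class") {
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  hdr <- names(raw)
  if (anyDuplicated(hdr))
    stop(sprintf("duplicate header name(s): %s",
                 paste(unique(hdr[duplicated(hdr)]), collapse = ", ")),
         call. = FALSE)
  if (!(label %in% hdr))
    stop(sprintf("label column '%s' not found in header", label),
         call. = FALSE)
  feat <- setdiff(hdr, label)
  if (!length(feat))
    stop("file has no feature columns (p = 0)", call. = FALSE)
  x <- matrix(NA_real_, nrow(raw), length(feat),
              dimnames = list(NULL, feat))
  for (j in seq_along(feat)) {
    v <- suppressWarnings(as.numeric(raw[[feat[j]]]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1L]
      stop(sprintf("non-numeric feature cell at row %d, column '%s': '%s'",
                   i, feat[j], raw[[feat[j]]][i]), call. = FALSE)
    }
    x[, j] <- v
  }
  # Numeric-looking labels stay class names, not feature values.
  feature_dataset(x, as.character(raw[[label]]))
}

#' @rdname read_dataset_csv
#' @param dataset A [feature_dataset()].
#' @export
write_dataset_csv <- function(dataset, path, label = "class") {
  stopifnot(inherits(dataset, "feature_dataset"))
  if (label %in% dataset$feature_names)
    stop(sprintf("label column name '%s' collides with a feature name",
                 label), call. = FALSE)
  df <- as.data.frame(dataset$x, check.names = FALSE)
  df[[label]] <- dataset$class_names[dataset$y]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read and write feature datasets as ARFF
#'
#' Dense attribute-relation format files with numeric feature attributes and
#' one nominal class attribute (by default the last nominal attribute). The
#' nominal class declaration supplies the class-name set. Missing feature
#' cells (`?`) map to 0 under the default absent-means-not-present policy.
#' Sparse-format ARFF and string attributes are rejected.
#'
#' @param path File path.
#' @param class_attribute Name of the class attribute; `NULL` (default)
#'   takes the last nominal attribute.
#' @return `read_arff` returns a [feature_dataset()]; `write_arff` returns
#'   `path` invisibly.
#' @export
read_arff <- function(path, class_attribute = NULL) {
  lines <- readLines(path, warn = FALSE)
  in_data <- FALSE
  decl <- list()  # nominal attribute name -> declared level order
  for (ln in lines) {
    t <- trimws(ln)
    if (in_data && nzchar(t) && !startsWith(t, "%")) {
      if (startsWith(t, "{"))
        stop("sparse-format ARFF is not supported", call. = FALSE)
      break
    }
    if (grepl("^@data", t, ignore.case = TRUE)) in_data <- TRUE
    if (grepl("^@attribute\\s", t, ignore.case = TRUE)) {
      rest <- trimws(sub("^@attribute\\s+", "", t, ignore.case = TRUE))
      if (startsWith(rest, "'") || startsWith(rest, "\"")) {
        quote_chr <- substr(rest, 1L, 1L)
        end <- regexpr(quote_chr, substring(rest, 2L), fixed = TRUE)
        nm <- substr(rest, 2L, end)
        type <- trimws(substring(rest, end + 2L))
      } else {
        nm <- sub("\\s.*$", "", rest)
        type <- trimws(sub("^\\S+\\s*", "", rest))
      }
      if (grepl("^string\\b", type, ignore.case = TRUE))
        stop("string attributes are not supported", call. = FALSE)
      if (startsWith(type, "{")) {
        lev <- strsplit(sub("\\}.*$", "", sub("^\\{", "", type)), ",")[[1L]]
        decl[[nm]] <- gsub("^['\"]|['\"]$", "", trimws(lev))
      }
    }
  }
  df <- foreign::read.arff(path)
  if (is.null(class_attribute)) {
    if (!length(decl))
      stop("no nominal attribute found to use as the class", call. = FALSE)
    class_attribute <- names(decl)[length(decl)]
  }
  if (!(class_attribute %in% names(df)))
    stop(sprintf("class attribute '%s' not found", class_attribute),
         call. = FALSE)
  if (is.null(decl[[class_attribute]]))
    stop(sprintf("class attribute '%s' is not nominal", class_attribute),
         call. = FALSE)
  # impose the declared level set and order; foreign keeps only observed ones
  cls <- factor(as.character(df[[class_attribute]]),
                levels = decl[[class_attribute]])
  feat <- setdiff(names(df), class_attribute)
  if (!length(feat))
    stop("ARFF file has no feature attributes", call. = FALSE)
  bad <- feat[!vapply(df[feat], is.numeric, logical(1))]
  if (length(bad))
    stop(sprintf("non-numeric feature attribute(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  x <- as.matrix(df[feat])
  x[is.na(x)] <- 0  # '?' in a feature cell: absent means not present
  if (anyNA(cls))
    stop("missing value in the class attribute", call. = FALSE)
  # levels() carries the declared class set even if some level is unused
  feature_dataset(x, as.character(cls), class_names = levels(cls))
}

#' @rdname read_arff
#' @param dataset A [feature_dataset()].
#' @param relation Relation name written to the `@relation` header.
#' @export
write_arff <- function(dataset, path, relation = "dataset",
                       class_attribute = "class") {
  stopifnot(inherits(dataset, "feature_dataset"))
  df <- as.data.frame(dataset$x, check.names = FALSE)
  df[[class_attribute]] <- factor(dataset$class_names[dataset$y],
                                  levels = dataset$class_names)
  foreign::write.arff(df, path, relation = relation)
  invisible(path)
}

#' Construct a transaction set of herb itemsets
#'
#' One itemset per prescription; items within a transaction are unique (a
#' herb counts once regardless of dosage). The vocabulary is the union of
#' all transactions.
#'
#' @param transactions List of character vectors (one itemset per
#'   prescription).
#' @return An object of class `transaction_set` with elements
#'   `transactions` and `vocabulary`.
#' @export
transaction_set <- function(transactions) {
  transactions <- lapply(transactions, function(tr) {
    tr <- as.character(tr)
    if (anyDuplicated(tr)) {
      warning("duplicate item(s) within a transaction collapsed",
              call. = FALSE)
      tr <- unique(tr)
    }
    tr
  })
  structure(
    list(transactions = transactions,
         vocabulary = sort(unique(unlist(transactions, use.names = FALSE)))),
    class = "transaction_set")
}

#' @export
print.transaction_set <- function(x, ...) {
  cat(sprintf("<transaction_set> %d transaction(s), %d distinct item(s)\n",
              length(x$transactions), length(x$vocabulary)))
  invisible(x)
}

#' @export
length.transaction_set <- function(x) length(x$transactions)

#' Read and write transaction files
#'
#' One prescription per line, items separated by `sep`. Duplicate items
#' within a line are collapsed with a warning; empty lines are skipped with
#' a warning. A write/read round trip preserves the itemsets.
#'
#' @param path File path.
#' @param sep Item delimiter, default comma.
#' @return `read_transactions` returns a [transaction_set()];
#'   `write_transactions` returns `path` invisibly.
#' @export
read_transactions <- function(path, sep = ",") {
  lines <- readLines(path, warn = FALSE)
  empty <- !nzchar(trimws(lines))
  if (any(empty))
    warning(sprintf("skipped %d empty line(s)", sum(empty)), call. = FALSE)
  lines <- lines[!empty]
  transaction_set(lapply(strsplit(lines, sep, fixed = TRUE),
                         function(v) trimws(v)[nzchar(trimws(v))]))
}

#' @rdname read_transactions
#' @param ts A [transaction_set()].
#' @export
write_transactions <- function(ts, path, sep = ",") {
  stopifnot(inherits(ts, "transaction_set"))
  writeLines(vapply(ts$transactions, paste, character(1), collapse = sep),
             path)
  invisible(path)
}
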