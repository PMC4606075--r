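#' Construct a clinical case record
#'
#' A case record holds one clinical visit: the recorded symptom/examination
#' values, the syndrome diagnosis, and the prescription (herb, dosage) list.
#'
#' @param case_id Identifier of the case.
#' @param specialist_id Identifier of the specialist (doctor) owning the case.
#' @param template_id Identifier of the inquiry template the case was entered
#'   under; together with `specialist_id` it scopes dataset retrieval.
#' @param symptoms Named list or named vector mapping item names to values
#'   (binary 0/1 or a categorical level as a character string). Names must be
#'   unique.
#' @param syndrome Class name (syndrome label) of this record, or `NA` if
#'   undiagnosed.
#' @param visit_index Positive integer; 1 for the first visit.
#' @param prescription Herbs prescribed at this visit: either a character
#'   vector of herb names or a named numeric vector of dosages in grams
#'   (names = herbs). Herb names must be unique.
#' @return An object of class `case_record`.
#' @examples
#' case_record("c1", "zhang", "fatty_liver",
#'   symptoms = list(Nausea = 1, Thirsty = 0, `State of tongue` = "red"),
#'   syndrome = "phlegm_stasis",
#'   prescription = c(salvia = 15, hawthorn = 10))
#' @export
case_record <- function(case_id, specialist_id, template_id, symptoms,
                        syndrome = NA_character_, visit_index = 1L,
                        prescription = character()) {
  visit_index <- stopifnot_scalar_count(visit_index, "visit_index")
  symptoms <- as.list(symptoms)
  if (length(symptoms) && (is.null(names(symptoms)) || anyNA(names(symptoms)) ||
                           any(names(symptoms) == "")))
    stop("all symptom values must be named", call. = FALSE)
  if (anyDuplicated(names(symptoms)))
    stop("symptom item names must be unique within a record", call. = FALSE)
  herbs <- if (is.null(names(prescription))) as.character(prescription)
           else names(prescription)
  if (anyDuplicated(herbs))
    stop("herb names within one prescription must be unique", call. = FALSE)
  dosage <- if (is.numeric(prescription)) as.numeric(prescription)
            else rep(NA_real_, length(herbs))
  structure(
    list(case_id = as.character(case_id),
         specialist_id = as.character(specialist_id),
         template_id = as.character(template_id),
         visit_index = visit_index,
         symptoms = symptoms,
         syndrome = as.character(syndrome),
         prescription = stats::setNames(dosage, herbs)),
    class = "case_record")
}

#' @export
print.case_record <- function(x, ...) {
  cat(sprintf("<case_record %s> specialist=%s template=%s visit=%d\n",
              x$case_id, x$specialist_id, x$template_id, x$visit_index))
  cat(sprintf("  syndrome: %s; %d symptom item(s); %d herb(s)\n",
              x$syndrome, length(x$symptoms), length(x$prescription)))
  invisible(x)
}

#' Construct a feature dataset
#'
#' The analyzable form of a set of clinical cases: an n x p numeric feature
#' matrix, integer class labels in 1..k, and the feature/class names. This is
#' the "target dataset" consumed by the classifiers and the evaluation
#' harness.
#'
#' @param x Numeric matrix (n x p) of feature values.
#' @param y Integer vector of class indices in `1..k` (length n), or a
#'   factor/character vector of class names (converted in first-appearance
#'   order when `class_names` is not given).
#' @param feature_names Character vector of p unique column names; defaults
#'   to `colnames(x)`.
#' @param class_names Character vector of the k class names; classes are
#'   1-based and files always carry names, never indices.
#' @return An object of class `feature_dataset` with elements `x`, `y`,
#'   `feature_names`, `class_names`.
#' @export
feature_dataset <- function(x, y, feature_names = colnames(x),
                            class_names = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(feature_names))
    feature_names <- paste0("V", seq_len(ncol(x)))
  feature_names <- as.character(feature_names)
  if (length(feature_names) != ncol(x))
    stop("length(feature_names) must equal ncol(x)", call. = FALSE)
  if (anyDuplicated(feature_names))
    stop("feature names must be unique", call. = FALSE)
  if (is.character(y) || is.factor(y)) {
    y <- as.character(y)
    if (is.null(class_names)) class_names <- unique(y)
    if (!all(y %in% class_names))
      stop("labels found in 'y' that are absent from 'class_names'",
           call. = FALSE)
    y <- match(y, class_names)
  } else {
    y <- as.integer(y)
    if (is.null(class_names)) {
      if (!length(y)) stop("cannot infer class names from empty 'y'",
                           call. = FALSE)
      class_names <- paste0("class", seq_len(max(y)))
    }
  }
  if (length(y) != nrow(x))
    stop("length(y) must equal nrow(x)", call. = FALSE)
  if (anyNA(y) || any(y < 1L) || any(y > length(class_names)))
    stop("class indices in 'y' must lie in 1..k", call. = FALSE)
  colnames(x) <- feature_names
  structure(
    list(x = x, y = y,
         feature_names = feature_names,
         class_names = as.character(class_names)),
    class = "feature_dataset")
}

#' @export
print.feature_dataset <- function(x, ...) {
  counts <- tabulate(x$y, nbins = length(x$class_names))
  cat(sprintf("<feature_dataset> n=%d, p=%d, k=%d\n",
              nrow(x$x), ncol(x$x), length(x$class_names)))
  cat("  classes:", paste(sprintf("%s (%d)", x$class_names, counts),
                          collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.feature_dataset <- function(x) dim(x$x)

#' Declare feature encodings for clinical items
#'
#' Symptom tables mix binary items (present/absent) with categorical items
#' such as the state of the tongue. `item_binary()` declares a 0/1 item;
#' `item_categorical()` declares an item with a fixed level set that is
#' expanded into one indicator column per level, named `item=level`.
#'
#' @param levels Character vector of the allowed category levels.
#' @return An item declaration used by [encode_features()] and
#'   [retrieve_dataset()].
#' @export
item_binary <- function() structure(list(type = "binary"), class = "item_spec")

#' @rdname item_binary
#' @export
item_categorical <- function(levels) {
  levels <- as.character(levels)
  if (!length(levels) || anyDuplicated(levels))
    stop("'levels' must be a nonempty set of unique level names",
         call. = FALSE)
  structure(list(type = "categorical", levels = levels), class = "item_spec")
}

# Normalise an items argument: a plain character vector means all-binary.
as_item_specs <- function(items) {
  if (is.character(items)) {
    if (!length(items)) stop("'items' must be nonempty", call. = FALSE)
    return(stats::setNames(replicate(length(items), item_binary(),
                                     simplify = FALSE), items))
  }
  if (!is.list(items) || is.null(names(items)) || !length(items))
    stop("'items' must be a character vector or a named list of item specs",
         call. = FALSE)
  lapply(items, function(s) {
    if (!inherits(s, "item_spec"))
      stop("each item must be declared with item_binary() or item_categorical()",
           call. = FALSE)
    s
  })
}

# Column names produced by a set of item declarations, in declaration order.
encoded_column_names <- function(specs) {
  unlist(lapply(names(specs), function(nm) {
    s <- specs[[nm]]
    if (s$type == "binary") nm else paste0(nm, "=", s$levels)
  }), use.names = FALSE)
}

#' Encode clinical items as numeric feature columns
#'
#' Binary items become one 0/1 column; a categorical item with L levels
#' becomes L indicator columns (`item=level`), at most one of which is 1.
#' An absent value encodes as all zeros across the item's columns — the
#' default "symptom not recorded means not present" policy.
#'
#' @param records List of [case_record()] objects.
#' @param items Either a character vector of item names (all treated as
#'   binary) or a named list of [item_binary()]/[item_categorical()]
#'   declarations.
#' @return Numeric matrix with one row per record, columns in declaration
#'   order.
#' @export
encode_features <- function(records, items) {
  specs <- as_item_specs(items)
  cols <- encoded_column_names(specs)
  out <- matrix(0, nrow = length(records), ncol = length(cols),
                dimnames = list(NULL, cols))
  for (r in seq_along(records)) {
    sym <- records[[r]]$symptoms
    at <- 0L
    for (nm in names(specs)) {
      s <- specs[[nm]]
      v <- sym[[nm]]
      if (s$type == "binary") {
        at <- at + 1L
        if (!is.null(v) && !is.na(v)) {
          vn <- suppressWarnings(as.numeric(v))
          if (is.na(vn) || !(vn %in% c(0, 1)))
            stop(sprintf("record %d: binary item '%s' has non-0/1 value '%s'",
                         r, nm, as.character(v)), call. = FALSE)
          out[r, at] <- vn
        }
      } else {
        if (!is.null(v) && !is.na(v)) {
          idx <- match(as.character(v), s$levels)
          if (is.na(idx))
            stop(sprintf("record %d: unseen level '%s' for categorical item '%s'",
                         r, as.character(v), nm), call. = FALSE)
          out[r, at + idx] <- 1
        }
        at <- at + length(s$levels)
      }
    }
  }
  out
}

#' Retrieve an analyzable dataset from stored clinical cases
#'
#' Filters the case collection down to one specialist and template, encodes
#' the requested items as feature columns, and attaches the class labels.
#' Class names are taken in first-appearance order over the selected records.
#'
#' @param cases List of [case_record()] objects.
#' @param specialist_id,template_id Filters; `NULL` means "any".
#' @param items Item names (character) or named item declarations; see
#'   [encode_features()].
#' @param label_item Which record field carries the class label; the default
#'   `"syndrome"` uses the syndrome diagnosis. Any symptom item name may be
#'   given instead.
#' @param missing Policy for a requested item absent from a record:
#'   `"zero"` (default; absent means not present) or `"drop"` (drop the
#'   record).
#' @param first_visit_only If `TRUE`, keep only records with
#'   `visit_index == 1`, so repeated visits of one patient do not become
#'   separate analysis rows.
#' @return A [feature_dataset()].
#' @export
retrieve_dataset <- function(cases, specialist_id = NULL, template_id = NULL,
                             items, label_item = "syndrome",
                             missing = c("zero", "drop"),
                             first_visit_only = FALSE) {
  missing <- match.arg(missing)
  specs <- as_item_specs(items)
  keep <- vapply(cases, function(cr) {
    (is.null(specialist_id) || cr$specialist_id == specialist_id) &&
      (is.null(template_id) || cr$template_id == template_id) &&
      (!first_visit_only || cr$visit_index == 1L)
  }, logical(1))
  sel <- cases[keep]
  if (!length(sel))
    stop("no records match the requested specialist/template filters",
         call. = FALSE)
  labels <- vapply(sel, function(cr) {
    v <- if (identical(label_item, "syndrome")) cr$syndrome
         else cr$symptoms[[label_item]]
    if (is.null(v)) NA_character_ else as.character(v)
  }, character(1))
  if (anyNA(labels))
    stop(sprintf("label item '%s' is missing in %d selected record(s)",
                 label_item, sum(is.na(labels))), call. = FALSE)
  if (missing == "drop") {
    complete <- vapply(sel, function(cr) {
      all(vapply(names(specs), function(nm) {
        v <- cr$symptoms[[nm]]
        !is.null(v) && !is.na(v)
      }, logical(1)))
    }, logical(1))
    if (!all(complete))
      warning(sprintf("dropping %d record(s) with missing requested items",
                      sum(!complete)), call. = FALSE)
    sel <- sel[complete]
    labels <- labels[complete]
    if (!length(sel))
      stop("all matching records were dropped by the missing-item policy",
           call. = FALSE)
  }
  x <- encode_features(sel, specs)
  feature_dataset(x, labels)
}
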