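#' Herb occurrence-frequency ranking
#'
#' Counts, for every item, the number of transactions containing it (once
#' per transaction regardless of dosage), sorted by count descending with
#' lexicographic tie-break, truncated to `top_n`. The normalized frequency
#' is count / number of transactions.
#'
#' @param ts A [transaction_set()].
#' @param top_n Keep the first `top_n` entries (default all).
#' @param normalize `"transactions"` (default; count over the number of
#'   transactions) or `"max"` (count over the largest count).
#' @return A data frame of class `frequency_ranking` with columns `item`,
#'   `count`, `normalized`.
#' @export
occurrence_frequency <- function(ts, top_n = Inf,
                                 normalize = c("transactions", "max")) {
  stopifnot(inherits(ts, "transaction_set"))
  normalize <- match.arg(normalize)
  if (!is.numeric(top_n) || length(top_n) != 1L || is.na(top_n) || top_n <= 0)
    stop("'top_n' must be a positive number", call. = FALSE)
  items <- unlist(ts$transactions, use.names = FALSE)
  if (!length(items)) {
    out <- data.frame(item = character(), count = integer(),
                      normalized = numeric())
    class(out) <- c("frequency_ranking", "data.frame")
    return(out)
  }
  tab <- table(items)
  ord <- order(-as.integer(tab), names(tab), method = "radix")
  counts <- as.integer(tab)[ord]
  denom <- if (normalize == "transactions") length(ts$transactions)
           else max(counts)
  out <- data.frame(item = names(tab)[ord], count = counts,
                    normalized = counts / denom)
  out <- utils::head(out, n = if (is.finite(top_n)) top_n else nrow(out))
  rownames(out) <- NULL
  class(out) <- c("frequency_ranking", "data.frame")
  out
}

#' Remove items from every transaction
#'
#' Deletes the excluded items (e.g. the basic core formula already
#' established for the disease) from each transaction so the remaining
#' herbs can be ranked on their own. Transactions that become empty are
#' kept, so supports stay comparable before and after removal.
#'
#' @param ts A [transaction_set()].
#' @param excluded Character vector of items to delete.
#' @return A [transaction_set()].
#' @export
remove_items <- function(ts, excluded) {
  stopifnot(inherits(ts, "transaction_set"))
  excluded <- as.character(excluded)
  missing <- setdiff(excluded, ts$vocabulary)
  if (length(missing))
    message(sprintf("item(s) not in the vocabulary (no-op): %s",
                    paste(missing, collapse = ", ")))
  out <- lapply(ts$transactions, function(tr) setdiff(tr, excluded))
  structure(list(transactions = out,
                 vocabulary = setdiff(ts$vocabulary, excluded)),
            class = "transaction_set")
}

#' Apriori frequent itemset mining
#'
#' Level-wise search for all itemsets whose support (number of containing
#' transactions) reaches `min_support`: size-L candidates are generated by
#' joining frequent (L-1)-itemsets that share a prefix and pruned unless
#' every (L-1)-subset is frequent, then counted exactly against the
#' transactions.
#'
#' @param ts A [transaction_set()].
#' @param min_support Minimum support as a transaction count; default
#'   `max(2, ceiling(0.05 * n))`.
#' @return A data frame of class `frequent_itemsets` with columns `items`
#'   (list of character vectors, each sorted), `size`, and `support`,
#'   ordered by size then support descending.
#' @export
apriori <- function(ts, min_support = NULL) {
  stopifnot(inherits(ts, "transaction_set"))
  n <- length(ts$transactions)
  if (is.null(min_support)) min_support <- max(2, ceiling(0.05 * n))
  min_support <- stopifnot_scalar_count(min_support, "min_support")

  empty <- data.frame(size = integer(), support = integer())
  empty$items <- list()
  class(empty) <- c("frequent_itemsets", "data.frame")
  if (min_support > n || n == 0L) return(empty[, c("items", "size", "support")])

  # transactions as sorted integer vectors over the vocabulary
  vocab <- ts$vocabulary
  tr <- lapply(ts$transactions, function(t) sort(match(t, vocab)))

  count_support <- function(cands) {
    vapply(cands, function(s) {
      sum(vapply(tr, function(t) all(s %in% t), logical(1)))
    }, integer(1))
  }

  sup1 <- tabulate(unlist(tr, use.names = FALSE), nbins = length(vocab))
  frequent <- lapply(which(sup1 >= min_support), identity)
  supports <- sup1[sup1 >= min_support]
  all_items <- frequent
  all_supports <- supports
  all_sizes <- rep(1L, length(frequent))

  level <- frequent
  lsize <- 1L
  while (length(level) > 1L) {
    keyset <- vapply(level, paste, character(1), collapse = ",")
    # join step: two frequent L-sets sharing their first L-1 items
    prefix <- vapply(level, function(s)
      paste(s[-length(s)], collapse = ","), character(1))
    last <- vapply(level, function(s) s[length(s)], integer(1))
    cands <- list()
    for (grp in split(seq_along(level), prefix)) {
      if (length(grp) < 2L) next
      grp <- grp[order(last[grp])]
      for (a in seq_along(grp)[-length(grp)]) {
        for (b in seq.int(a + 1L, length(grp))) {
          cand <- c(level[[grp[a]]], last[grp[b]])
          # prune: every L-subset of the candidate must be frequent
          ok <- all(vapply(seq_along(cand), function(d)
            paste(cand[-d], collapse = ",") %in% keyset, logical(1)))
          if (ok) cands[[length(cands) + 1L]] <- cand
        }
      }
    }
    if (!length(cands)) break
    sup <- count_support(cands)
    keep <- sup >= min_support
    if (!any(keep)) break
    level <- cands[keep]
    lsize <- lsize + 1L
    all_items <- c(all_items, level)
    all_supports <- c(all_supports, sup[keep])
    all_sizes <- c(all_sizes, rep(lsize, sum(keep)))
  }

  items <- lapply(all_items, function(s) vocab[s])
  ord <- order(all_sizes, -all_supports,
               vapply(items, paste, character(1), collapse = ","),
               method = "radix")
  out <- data.frame(size = all_sizes[ord], support = all_supports[ord])
  out$items <- items[ord]
  out <- out[, c("items", "size", "support")]
  rownames(out) <- NULL
  class(out) <- c("frequent_itemsets", "data.frame")
  out
}

#' @export
print.frequent_itemsets <- function(x, ...) {
  if (!nrow(x)) { cat("<frequent_itemsets> none\n"); return(invisible(x)) }
  df <- data.frame(itemset = vapply(x$items, paste, character(1),
                                    collapse = ", "),
                   size = x$size, support = x$support)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Most frequent itemset of each size
#'
#' Reduces a frequent-itemset table to one row per itemset size: the
#' support-maximal itemset (ties broken by lexicographic item order), the
#' layout of a "most frequent n-itemsets" summary table. Supports are
#' non-increasing in the size by anti-monotonicity.
#'
#' @param frequent A `frequent_itemsets` data frame from [apriori()].
#' @return Data frame with columns `size`, `support`, `itemset` (comma
#'   separated item names).
#' @export
most_frequent_by_size <- function(frequent) {
  if (!nrow(frequent)) stop("'frequent' is empty", call. = FALSE)
  out <- do.call(rbind, lapply(split(seq_len(nrow(frequent)),
                                     frequent$size), function(rows) {
    sup <- frequent$support[rows]
    best <- rows[sup == max(sup)]
    keys <- vapply(frequent$items[best], paste, character(1),
                   collapse = ", ")
    pick <- best[order(keys, method = "radix")[1L]]
    data.frame(size = frequent$size[pick],
               support = frequent$support[pick],
               itemset = paste(frequent$items[[pick]], collapse = ", "))
  }))
  rownames(out) <- NULL
  out[order(out$size), ]
}

#' Suggest a core-formula cutoff from a frequency ranking
#'
#' Experts read the core formula off the frequency ranking at the point
#' where occurrence "goes down obviously". This formalises that as the
#' position of the largest relative drop: the index `m` maximising
#' `count[m] / count[m + 1]` (smallest `m` on ties). The ratio is
#' returned so a human can accept or override the suggestion; a ratio
#' near 1 signals no confident cutoff.
#'
#' @param ranking A `frequency_ranking` from [occurrence_frequency()] (or
#'   any data frame with a `count` column), at least 2 entries.
#' @return List with `index` (items 1..index are above the drop) and
#'   `drop_ratio`.
#' @export
suggest_core_cutoff <- function(ranking) {
  counts <- as.numeric(ranking$count)
  if (length(counts) < 2L)
    stop("at least 2 ranking entries are required", call. = FALSE)
  lower <- counts[-1L]
  if (any(lower == 0)) {
    warning("zero count(s) in the ranking interior; ratios use an epsilon floor",
            call. = FALSE)
    lower <- pmax(lower, 1e-9)
  }
  ratios <- counts[-length(counts)] / lower
  idx <- which.max(ratios)  # first maximum: smallest index on ties
  list(index = idx, drop_ratio = ratios[idx])
}

#' Rank features by information gain about the class
#'
#' For each (binary or discretised) feature X, the gain
#' `H(Y) - H(Y | X)` in bits, with entropies over the empirical joint
#' frequencies; sorted descending with name tie-break. Used for key-symptom
#' discovery: symptoms carrying most information about the syndrome.
#'
#' @param dataset A [feature_dataset()] whose columns take finitely many
#'   values (0/1 indicators or small integer codes).
#' @return Data frame with columns `feature`, `gain` (bits).
#' @export
info_gain_rank <- function(dataset) {
  stopifnot(inherits(dataset, "feature_dataset"))
  y <- dataset$y
  n <- length(y)
  ent <- function(counts) {
    p <- counts[counts > 0] / sum(counts)
    -sum(p * log2(p))
  }
  h_y <- ent(tabulate(y))
  gains <- vapply(seq_len(ncol(dataset$x)), function(j) {
    v <- dataset$x[, j]
    u <- unique(v)
    if (length(u) > 32L || any(v != round(v)))
      stop(sprintf(
        "feature '%s' looks continuous; discretise it first (see encode_features)",
        dataset$feature_names[j]), call. = FALSE)
    h_cond <- 0
    for (val in u) {
      rows <- v == val
      h_cond <- h_cond + sum(rows) / n * ent(tabulate(y[rows]))
    }
    h_y - h_cond
  }, numeric(1))
  out <- data.frame(feature = dataset$feature_names, gain = gains)
  out <- out[order(-out$gain, out$feature, method = "radix"), ]
  rownames(out) <- NULL
  out
}

#' Recommend a core formula from observed symptoms
#'
#' The end of the mining pipeline: classify the symptom vector with a
#' fitted [maplsc()] model, then look the predicted syndrome up in a map
#' from syndrome to its mined core formula. The coupled probabilities are
#' returned for transparency.
#'
#' @param model A fitted [maplsc()] model.
#' @param core_map Named list: syndrome name -> character vector of herbs
#'   (nonempty, no duplicates). Every class of the model must be present.
#' @param x A length-p symptom feature vector.
#' @return List with `syndrome`, `herbs`, `probabilities`.
#' @export
recommend_formula <- function(model, core_map, x) {
  stopifnot(inherits(model, "maplsc"))
  if (!is.list(core_map) || is.null(names(core_map)))
    stop("'core_map' must be a named list of herb vectors", call. = FALSE)
  for (nm in names(core_map)) {
    h <- core_map[[nm]]
    if (!length(h) || anyDuplicated(h))
      stop(sprintf("core formula for '%s' must be nonempty without duplicates",
                   nm), call. = FALSE)
  }
  p <- predict(model, x, type = "prob")[1L, ]
  syndrome <- model$class_names[which.max(p)]
  if (!(syndrome %in% names(core_map)))
    stop(sprintf("predicted syndrome '%s' has no core-formula entry",
                 syndrome), call. = FALSE)
  list(syndrome = syndrome,
       herbs = as.character(core_map[[syndrome]]),
       probabilities = p)
}
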