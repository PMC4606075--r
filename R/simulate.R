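#' Specification for synthetic clinical case tables
#'
#' Describes a small, imbalanced, multiclass symptom table of the kind
#' collected in specialist clinics: n visits, p binary symptom items, k
#' syndrome classes with a dominant majority class, and class-conditional
#' signal — each class has its own disjoint set of symptoms that are
#' present at a higher rate than the background. Defaults mirror a
#' fatty-liver study scale: 63 records, 32 symptom items, 3 syndromes
#' with priors (0.72, 0.16, 0.12).
#'
#' @param n Sample count.
#' @param p Symptom (feature) count.
#' @param k Class count.
#' @param class_priors Probability of each class, summing to 1.
#' @param signal_features_per_class Number of symptoms characteristic of
#'   each class (disjoint across classes; `k * signal_features_per_class
#'   <= p`).
#' @param present_prob_signal Presence rate of a class's own signal
#'   symptoms.
#' @param present_prob_background Presence rate of all other symptoms.
#' @param seed Integer seed.
#' @return An object of class `case_gen_spec`.
#' @export
case_gen_spec <- function(n = 63L, p = 32L, k = 3L,
                          class_priors = c(0.72, 0.16, 0.12),
                          signal_features_per_class = 5L,
                          present_prob_signal = 0.8,
                          present_prob_background = 0.1,
                          seed = 1L) {
  n <- stopifnot_scalar_count(n, "n")
  p <- stopifnot_scalar_count(p, "p")
  k <- stopifnot_scalar_count(k, "k")
  spc <- stopifnot_scalar_count(signal_features_per_class,
                                "signal_features_per_class")
  if (length(class_priors) != k)
    stop("'class_priors' must have length k", call. = FALSE)
  if (abs(sum(class_priors) - 1) > 1e-12)
    stop("'class_priors' must sum to 1", call. = FALSE)
  if (any(class_priors < 0))
    stop("'class_priors' must be non-negative", call. = FALSE)
  for (pr in c(present_prob_signal, present_prob_background))
    if (!is.numeric(pr) || pr < 0 || pr > 1)
      stop("presence probabilities must lie in [0, 1]", call. = FALSE)
  if (k * spc > p)
    stop("k * signal_features_per_class must not exceed p", call. = FALSE)
  structure(
    list(n = n, p = p, k = k, class_priors = as.numeric(class_priors),
         signal_features_per_class = spc,
         present_prob_signal = present_prob_signal,
         present_prob_background = present_prob_background,
         seed = as.integer(seed)),
    class = "case_gen_spec")
}

#' Generate a synthetic clinical case table
#'
#' Draws class labels from the prior and then each symptom independently:
#' symptom j of a class-c sample is Bernoulli(`present_prob_signal`) when
#' j belongs to class c's signal set (features
#' `(c-1)*m + 1 .. c*m` with `m = signal_features_per_class`), else
#' Bernoulli(`present_prob_background`). The same seed always reproduces
#' the identical dataset.
#'
#' @param spec A [case_gen_spec()].
#' @return A [feature_dataset()] with feature names `symptom01, ...` and
#'   class names `syndrome1, ...`. The planted signal features of each
#'   class are recorded in `attr(, "signal_features")`.
#' @export
gen_cases <- function(spec = case_gen_spec()) {
  stopifnot(inherits(spec, "case_gen_spec"))
  with_seed(spec$seed, {
    y <- sample.int(spec$k, spec$n, replace = TRUE, prob = spec$class_priors)
    m <- spec$signal_features_per_class
    signal <- lapply(seq_len(spec$k), function(c) (c - 1L) * m + seq_len(m))
    prob <- matrix(spec$present_prob_background, spec$n, spec$p)
    for (c in seq_len(spec$k))
      prob[y == c, signal[[c]]] <- spec$present_prob_signal
    x <- matrix(as.numeric(stats::runif(spec$n * spec$p) < prob),
                spec$n, spec$p)
    colnames(x) <- sprintf("symptom%02d", seq_len(spec$p))
    ds <- feature_dataset(x, y,
                          class_names = paste0("syndrome", seq_len(spec$k)))
    attr(ds, "signal_features") <- signal
    ds
  })
}

#' Specification for synthetic prescription transactions
#'
#' Describes prescriptions carrying a planted structure: a basic core
#' formula included (whole) with high probability, a per-syndrome addon
#' set included with moderate probability, and Poisson-many noise herbs
#' drawn uniformly from the rest of the vocabulary. The defaults emulate
#' the mining setting of a core-formula study: an 8-herb core at
#' inclusion rate 0.9 and a 2-herb syndrome addon, with the addon and
#' noise rates placed so the core's frequency visibly drops off at rank 8.
#'
#' @param n_transactions Number of prescriptions.
#' @param vocabulary Character vector of all herb names; default
#'   `herb01..herb30`.
#' @param core_formula Items of the basic core formula (default the first
#'   8 herbs).
#' @param p_core Probability a prescription includes the whole core.
#' @param addon_map Named list: syndrome -> addon item set, disjoint from
#'   the core; default one syndrome with herbs 9-10.
#' @param p_addon Probability a prescription includes its syndrome's
#'   addons.
#' @param noise_items_per_rx Mean (Poisson) number of noise herbs per
#'   prescription, drawn from the vocabulary outside core and addons.
#' @param seed Integer seed.
#' @return An object of class `rx_gen_spec`.
#' @export
rx_gen_spec <- function(n_transactions = 500L,
                        vocabulary = sprintf("herb%02d", 1:30),
                        core_formula = sprintf("herb%02d", 1:8),
                        p_core = 0.9,
                        addon_map = list(
                          syndrome1 = sprintf("herb%02d", 9:10)),
                        p_addon = 0.45,
                        noise_items_per_rx = 6,
                        seed = 1L) {
  n_transactions <- stopifnot_scalar_count(n_transactions, "n_transactions")
  vocabulary <- as.character(vocabulary)
  core_formula <- as.character(core_formula)
  addons <- unique(unlist(addon_map, use.names = FALSE))
  if (length(intersect(core_formula, addons)))
    stop("core formula and addon sets must be disjoint", call. = FALSE)
  if (!all(c(core_formula, addons) %in% vocabulary))
    stop("vocabulary must contain every core and addon item", call. = FALSE)
  for (pr in c(p_core, p_addon))
    if (!is.numeric(pr) || pr < 0 || pr > 1)
      stop("inclusion probabilities must lie in [0, 1]", call. = FALSE)
  if (noise_items_per_rx < 0)
    stop("'noise_items_per_rx' must be non-negative", call. = FALSE)
  structure(
    list(n_transactions = n_transactions, vocabulary = vocabulary,
         core_formula = core_formula, p_core = p_core,
         addon_map = addon_map, p_addon = p_addon,
         noise_items_per_rx = noise_items_per_rx,
         seed = as.integer(seed)),
    class = "rx_gen_spec")
}

#' Generate synthetic prescription transactions
#'
#' Each transaction is the union of the core formula (with probability
#' `p_core`, included whole), the addon set of its syndrome (probability
#' `p_addon`), and `Poisson(noise_items_per_rx)` noise herbs sampled
#' without replacement from the remaining vocabulary.
#'
#' @param spec An [rx_gen_spec()].
#' @param labels Optional character vector (length `n_transactions`) of
#'   syndrome names matching `names(spec$addon_map)`; if `NULL`, every
#'   transaction belongs to the first syndrome in the map.
#' @return A [transaction_set()].
#' @export
gen_prescriptions <- function(spec = rx_gen_spec(), labels = NULL) {
  stopifnot(inherits(spec, "rx_gen_spec"))
  n <- spec$n_transactions
  if (is.null(labels)) {
    labels <- rep(names(spec$addon_map)[1L], n)
  } else {
    labels <- as.character(labels)
    if (length(labels) != n)
      stop("'labels' must have length n_transactions", call. = FALSE)
    if (!all(labels %in% names(spec$addon_map)))
      stop("every label needs an entry in addon_map", call. = FALSE)
  }
  addons <- unique(unlist(spec$addon_map, use.names = FALSE))
  noise_pool <- setdiff(spec$vocabulary, c(spec$core_formula, addons))
  with_seed(spec$seed, {
    trs <- vector("list", n)
    for (r in seq_len(n)) {
      items <- character()
      if (stats::runif(1) < spec$p_core)
        items <- c(items, spec$core_formula)
      if (stats::runif(1) < spec$p_addon)
        items <- c(items, spec$addon_map[[labels[r]]])
      n_noise <- min(stats::rpois(1, spec$noise_items_per_rx),
                     length(noise_pool))
      if (n_noise > 0)
        items <- c(items, sample(noise_pool, n_noise))
      trs[[r]] <- items
    }
    transaction_set(trs)
  })
}
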