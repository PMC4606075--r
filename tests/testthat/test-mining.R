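test_that("occurrence frequency counts once per transaction with deterministic ordering", {
  ts <- transaction_set(list(c("a", "b"), "a", c("a", "c")))
  rk <- occurrence_frequency(ts)
  expect_equal(rk$item, c("a", "b", "c"))  # ties b/c broken by name
  expect_equal(rk$count, c(3L, 1L, 1L))
  expect_equal(rk$normalized, c(1, 1 / 3, 1 / 3))
  expect_equal(occurrence_frequency(ts, top_n = 1)$item, "a")
  expect_equal(nrow(occurrence_frequency(transaction_set(list()))), 0L)
  expect_error(occurrence_frequency(ts, top_n = 0), "positive")
  # alternative normalization: count over the maximum count
  expect_equal(occurrence_frequency(ts, normalize = "max")$normalized,
               c(1, 1 / 3, 1 / 3))
})

test_that("remove_items deletes items, keeps emptied transactions, and shrinks the vocabulary", {
  ts <- transaction_set(list(c("a", "b"), "a"))
  out <- remove_items(ts, "a")
  expect_equal(length(out), 2L)
  expect_equal(out$transactions[[1]], "b")
  expect_equal(out$transactions[[2]], character(0))
  expect_equal(out$vocabulary, "b")
  expect_message(noop <- remove_items(ts, "zzz"), "no-op")
  expect_equal(noop$transactions, ts$transactions)
  expect_equal(remove_items(ts, character())$transactions, ts$transactions)
})

test_that("apriori reproduces the hand-enumerated toy result", {
  ts <- transaction_set(list(c("a", "b", "c"), c("a", "b"),
                             c("a", "c"), c("a", "b", "c")))
  freq <- apriori(ts, min_support = 2)
  got <- apriori_as_map(freq)
  expect_mapequal(as.list(got),
                  list(a = 4L, b = 3L, c = 3L, `a,b` = 3L, `a,c` = 3L,
                       `b,c` = 2L, `a,b,c` = 2L))
  expect_equal(nrow(apriori(ts, min_support = 5)), 0L)
  expect_error(apriori(ts, min_support = 0), "positive")
})

test_that("apriori equals brute-force enumeration on random transaction sets", {
  set.seed(99)
  for (rep in 1:40) {
    ts <- random_transactions(n = sample(5:30, 1), v = sample(3:10, 1))
    ms <- sample(2:5, 1)
    got <- apriori_as_map(apriori(ts, min_support = ms))
    want <- brute_force_frequent(ts$transactions, ms)
    if (length(want) == 0L) {
      expect_length(got, 0L)
    } else {
      expect_mapequal(as.list(got), as.list(want))
    }
  }
})

test_that("support is anti-monotone in itemset size", {
  set.seed(17)
  ts <- random_transactions(n = 30, v = 6)
  freq <- apriori(ts, min_support = 2)
  key <- apriori_as_map(freq)
  for (i in which(freq$size > 1)) {
    items <- freq$items[[i]]
    for (d in seq_along(items)) {
      sub <- paste(sort(items[-d]), collapse = ",")
      expect_gte(key[[sub]], freq$support[i])
    }
  }
})

test_that("most_frequent_by_size picks the support-maximal witness per size", {
  ts <- transaction_set(list(c("a", "b", "c"), c("a", "b"),
                             c("a", "c"), c("a", "b", "c")))
  tab <- most_frequent_by_size(apriori(ts, min_support = 2))
  expect_equal(tab$size, 1:3)
  expect_equal(tab$support, c(4L, 3L, 2L))
  expect_equal(tab$itemset, c("a", "a, b", "a, b, c"))  # lexicographic tie
  expect_true(all(diff(tab$support) <= 0))
  single <- most_frequent_by_size(apriori(
    transaction_set(list(c("x", "y"))), min_support = 1))
  expect_equal(single$support, c(1L, 1L))
})

test_that("the cutoff heuristic finds the largest relative drop", {
  rk <- data.frame(count = c(10, 9, 8, 2, 1))
  cut <- suggest_core_cutoff(rk)
  expect_equal(cut$index, 3L)
  expect_equal(cut$drop_ratio, 4)
  # geometric counts: all ratios tie, smallest index wins
  geo <- suggest_core_cutoff(data.frame(count = c(8, 4, 2, 1)))
  expect_equal(geo$index, 1L)
  flat <- suggest_core_cutoff(data.frame(count = c(5, 5, 5)))
  expect_equal(flat$drop_ratio, 1)
  expect_warning(zero <- suggest_core_cutoff(data.frame(count = c(4, 0, 0))),
                 "zero")
  expect_equal(zero$index, 1L)
  expect_error(suggest_core_cutoff(data.frame(count = 3)), "at least 2")
})

test_that("information gain ranks label-matching features at 1 bit and constants at 0", {
  y <- rep(1:2, each = 10)
  x <- cbind(match_label = rep(0:1, each = 10),
             constant = 1,
             indep = rep(c(0, 1), 10))
  ds <- feature_dataset(x, y, class_names = c("a", "b"))
  rk <- info_gain_rank(ds)
  expect_equal(rk$gain[rk$feature == "match_label"], 1)
  expect_equal(rk$gain[rk$feature == "constant"], 0)
  expect_equal(rk$gain[rk$feature == "indep"], 0)
  expect_equal(rk$feature[1], "match_label")
  cont <- feature_dataset(matrix(rnorm(20), 10, 2), rep(1:2, 5),
                          class_names = c("a", "b"))
  expect_error(info_gain_rank(cont), "discretise")
})

test_that("formula recommendation composes classification and the core map", {
  d <- make_two_class(seed = 21)
  fit <- maplsc(d$x, d$y, ncomp = 2)
  core_map <- list(A = c("h1", "h2"), B = "h3")
  a_point <- colMeans(d$x[d$y == "A", ])
  rec <- recommend_formula(fit, core_map, a_point)
  expect_equal(rec$syndrome, "A")
  expect_equal(rec$herbs, c("h1", "h2"))
  expect_gt(rec$probabilities["A"], 0.5)
  b_point <- colMeans(d$x[d$y == "B", ])
  expect_error(recommend_formula(fit, list(A = c("h1", "h2")), b_point),
               "'B' has no core-formula entry")
  expect_error(recommend_formula(fit, list(A = c("h1", "h1"), B = "h3"),
                                 a_point), "duplicates")
  expect_identical(rec, recommend_formula(fit, core_map, a_point))
})

test_that("the full mining pipeline recovers a planted core formula and addon pair", {
  spec <- rx_gen_spec(seed = 33)
  ts <- gen_prescriptions(spec)
  rk <- occurrence_frequency(ts)
  cut <- suggest_core_cutoff(rk)
  expect_equal(cut$index, 8L)
  expect_setequal(rk$item[seq_len(cut$index)], spec$core_formula)
  pruned <- remove_items(ts, rk$item[seq_len(cut$index)])
  tab <- most_frequent_by_size(apriori(pruned))
  top_pair <- strsplit(tab$itemset[tab$size == 2], ", ", fixed = TRUE)[[1]]
  expect_setequal(top_pair, spec$addon_map[[1]])
})
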