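test_that("case records validate their invariants", {
  expect_error(case_record("c", "s", "t", symptoms = list(a = 1),
                           visit_index = 0), "visit_index")
  expect_error(case_record("c", "s", "t", symptoms = list(a = 1, a = 0)),
               "unique")
  expect_error(case_record("c", "s", "t", symptoms = list(a = 1),
                           prescription = c("x", "x")), "unique")
  cr <- case_record("c", "s", "t", symptoms = list(a = 1),
                    prescription = c(salvia = 12))
  expect_equal(names(cr$prescription), "salvia")
  expect_equal(unname(cr$prescription), 12)
})

test_that("retrieve_dataset filters by specialist/template and orders classes by first appearance", {
  cases <- make_case_records()
  ds <- retrieve_dataset(cases, specialist_id = "zhang", template_id = "fl",
                         items = c("Nausea", "Thirsty"))
  expect_s3_class(ds, "feature_dataset")
  expect_equal(dim(ds), c(3L, 2L))
  # labels appear in order (B, A, B) -> class_names (B, A), y = (1, 2, 1)
  expect_equal(ds$class_names, c("B", "A"))
  expect_equal(ds$y, c(1L, 2L, 1L))
  expect_equal(ds$x[, "Nausea"], c(1, 0, 1))
})

test_that("retrieve_dataset errors on empty matches and missing labels", {
  cases <- make_case_records()
  expect_error(retrieve_dataset(cases, specialist_id = "nobody",
                                items = "Nausea"), "no records match")
  undiagnosed <- c(cases, list(case_record("c5", "zhang", "fl",
                                           symptoms = list(Nausea = 1))))
  expect_error(retrieve_dataset(undiagnosed, specialist_id = "zhang",
                                items = "Nausea"), "missing")
})

test_that("the drop policy removes exactly the records lacking a requested item", {
  cases <- make_case_records()
  cases[[2]]$symptoms$Nausea <- NULL
  expect_warning(
    ds <- retrieve_dataset(cases, specialist_id = "zhang",
                           items = c("Nausea", "Thirsty"),
                           missing = "drop"),
    "dropping 1")
  expect_equal(nrow(ds$x), 2L)
  # default policy instead encodes the absent value as 0
  ds0 <- retrieve_dataset(cases, specialist_id = "zhang",
                          items = c("Nausea", "Thirsty"))
  expect_equal(nrow(ds0$x), 3L)
  expect_equal(unname(ds0$x[2, "Nausea"]), 0)
})

test_that("retrieval output is monotone non-increasing in the filters", {
  cases <- make_case_records()
  n_all <- nrow(retrieve_dataset(cases, items = "Nausea")$x)
  n_spec <- nrow(retrieve_dataset(cases, specialist_id = "zhang",
                                  items = "Nausea")$x)
  n_both <- nrow(retrieve_dataset(cases, specialist_id = "zhang",
                                  template_id = "fl", first_visit_only = TRUE,
                                  items = "Nausea")$x)
  expect_true(n_all >= n_spec && n_spec >= n_both)
})

test_that("categorical items expand to indicator columns with row sums at most 1", {
  cases <- make_case_records()
  specs <- list(Nausea = item_binary(),
                Tongue = item_categorical(c("red", "pale", "purple")))
  x <- encode_features(cases, specs)
  expect_equal(colnames(x),
               c("Nausea", "Tongue=red", "Tongue=pale", "Tongue=purple"))
  tongue <- x[, startsWith(colnames(x), "Tongue=")]
  expect_true(all(rowSums(tongue) <= 1))
  expect_equal(unname(x[1, "Tongue=red"]), 1)
  # absent value -> all-zero indicators
  cases[[1]]$symptoms$Tongue <- NULL
  x2 <- encode_features(cases, specs)
  expect_equal(unname(x2[1, 2:4]), c(0, 0, 0))
  # deterministic: same input, identical encoding
  expect_identical(encode_features(cases, specs), x2)
})

test_that("unseen categorical levels are rejected by name", {
  cases <- make_case_records()
  specs <- list(Tongue = item_categorical(c("red", "pale")))
  cases[[1]]$symptoms$Tongue <- "green"
  expect_error(encode_features(cases, specs), "green.*Tongue")
})

test_that("feature_dataset enforces its invariants", {
  x <- matrix(1:6, 3, 2)
  expect_error(feature_dataset(x, c(1L, 2L)), "length")
  expect_error(feature_dataset(x, c(1L, 2L, 5L),
                               class_names = c("a", "b")), "1..k")
  expect_error(feature_dataset(x, c(1L, 1L, 2L),
                               feature_names = c("f", "f"),
                               class_names = c("a", "b")), "unique")
})
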