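test_that("the ensemble holds one calibrated classifier per unordered class pair", {
  d <- make_gaussian3()
  fit <- maplsc(d$x, d$y, ncomp = 2)
  expect_equal(length(fit$pairs), 3L)  # k(k-1)/2, k = 3
  got <- lapply(fit$pairs, function(pr) c(pr$i, pr$j))
  expect_setequal(lapply(got, paste, collapse = ","),
                  list("1,2", "1,3", "2,3"))
  # each pair was trained only on its two classes
  for (pr in fit$pairs)
    expect_setequal(c(pr$classifier$positive, pr$classifier$negative),
                    fit$class_names[c(pr$i, pr$j)])
  d4 <- list(x = rbind(d$x, d$x[1:8, ] + 10),
             y = c(d$y, rep("s4", 8)))
  expect_equal(length(maplsc(d4$x, d4$y, ncomp = 2)$pairs), 6L)
  expect_error(maplsc(d$x, rep("only", nrow(d$x))), "two classes")
})

test_that("pairwise posteriors complete to r_ij + r_ji = 1 inside (0,1)", {
  d <- make_gaussian3(seed = 3)
  fit <- maplsc(d$x, d$y, ncomp = 2)
  r <- pairwise_posteriors(fit, d$x[1, ])
  off <- !diag(3)
  expect_equal(r[off] + t(r)[off], rep(1, 6))
  expect_true(all(r[off] > 0 & r[off] < 1))
  expect_true(all(is.na(diag(r))))
})

test_that("coupling evaluates the closed form and always sums to one", {
  r2 <- matrix(c(NA, 0.2, 0.8, NA), 2, 2)
  expect_equal(unname(couple(r2)), c(0.8, 0.2))
  r3 <- matrix(0.5, 3, 3); diag(r3) <- NA
  expect_equal(unname(couple(r3)), rep(1 / 3, 3))
  # all pairwise duels won by the smaller index: p = (2/3, 1/3, 0)
  r <- matrix(NA, 3, 3)
  r[1, 2] <- r[1, 3] <- r[2, 3] <- 1
  r[2, 1] <- r[3, 1] <- r[3, 2] <- 0
  expect_equal(unname(couple(r)), c(2 / 3, 1 / 3, 0))
  expect_error(couple(matrix(1)), "k >= 2")
  bad <- matrix(c(NA, 0.5, 0.9, NA), 2, 2)
  expect_error(couple(bad), "r\\[i,j\\]")
})

test_that("prediction is the argmax of coupled probabilities with deterministic ties", {
  d <- make_gaussian3(seed = 5, shift = 6)
  fit <- maplsc(d$x, d$y, ncomp = 2)
  p <- predict(fit, d$x, type = "prob")
  expect_equal(unname(rowSums(p)), rep(1, nrow(p)), tolerance = 1e-9)
  cls <- predict(fit, d$x)
  expect_equal(as.character(cls),
               fit$class_names[apply(p, 1, which.max)])
  # training accuracy on well-separated Gaussians reaches 1
  expect_equal(mean(as.character(cls) == d$y), 1)
})

test_that("with k = 2 coupling reduces to thresholding the single pair", {
  d <- make_two_class(seed = 2)
  fit <- maplsc(d$x, d$y, ncomp = 2)
  p <- predict(fit, d$x, type = "prob")
  pair <- fit$pairs[[1]]
  f <- aplsc_score(pair$classifier, d$x)
  r12 <- sigmoid_posterior(pair$a, pair$b, f)
  expect_equal(unname(p[, 1]), unname(r12))
  expect_equal(as.character(predict(fit, d$x)),
               ifelse(r12 > 0.5, fit$class_names[1], fit$class_names[2]))
  # hard pairwise vote agrees with the coupled decision for k = 2
  votes <- ifelse(f > 0, fit$class_names[1], fit$class_names[2])
  agree <- votes == as.character(predict(fit, d$x))
  expect_true(all(agree[abs(r12 - 0.5) > 1e-8]))
})

test_that("relabelling classes permutes the coupled probabilities identically", {
  d <- make_gaussian3(seed = 11)
  fit <- maplsc(d$x, d$y, ncomp = 2)
  p <- predict(fit, d$x, type = "prob")
  for (rep in 1:3) {
    perm <- sample(3)
    nm <- c("s1", "s2", "s3")
    relabeled <- nm[perm][match(d$y, nm)]  # old class i is renamed nm[perm][i]
    fit2 <- maplsc(d$x, relabeled, ncomp = 2)
    p2 <- predict(fit2, d$x, type = "prob")
    expect_equal(unname(p2[, nm[perm]]), unname(p[, nm]), tolerance = 1e-6)
  }
})

test_that("a saved model reloads with identical predictions", {
  d <- make_gaussian3(seed = 7)
  fit <- maplsc(d$x, d$y, ncomp = 2)
  path <- withr::local_tempfile(fileext = ".json")
  maplsc_save(fit, path)
  back <- maplsc_load(path)
  expect_identical(back$class_names, fit$class_names)
  expect_equal(predict(back, d$x, type = "prob"),
               predict(fit, d$x, type = "prob"))
})

test_that("the formula interface matches the matrix interface", {
  d <- make_gaussian3(seed = 13)
  df <- data.frame(d$x, syndrome = d$y)
  fit_f <- maplsc(syndrome ~ ., data = df, ncomp = 2)
  fit_m <- maplsc(d$x, d$y, ncomp = 2)
  expect_equal(unname(predict(fit_f, df, type = "prob")),
               unname(predict(fit_m, d$x, type = "prob")))
})
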