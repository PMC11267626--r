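test_that("the registry pairs every method with its sensible settings only", {
  reg <- harmonizationRegistry()
  expect_equal(nrow(reg), 17)
  expect_equal(sum(reg$setting == "sum_to_sum"), 4)
  expect_equal(sum(reg$setting == "items_to_sum"), 7)
  expect_equal(sum(reg$setting == "items_to_items"), 6)
  expect_false(any(duplicated(paste(reg$method, reg$setting))))
  d <- tinyDataset(150, 2)
  expect_error(trainMapper("rf_regression", "sum_to_sum", d),
               "more than one predictor")
  expect_error(trainMapper("svm_classification", "sum_to_sum", d),
               "more than one predictor")
  expect_error(trainMapper("irt", "items_to_items", d), "items_to_sum")
  expect_error(trainMapper("linear_equating", "items_to_sum", d),
               "sum scores")
  expect_error(buildFeatures(d, "sum_to_sum", method = "rf_regression"))
})

test_that("feature construction follows the mapping setting", {
  d <- tinyDataset(100, 5)
  f1 <- buildFeatures(d, "sum_to_sum")
  expect_equal(dim(f1$X), c(100, 1))
  expect_equal(f1$X[[1]], sourceSums(d))
  f2 <- buildFeatures(d, "items_to_sum")
  expect_equal(dim(f2$X), c(100, 5))
  expect_length(f2$y, 100)
  f3 <- buildFeatures(d, "items_to_items")
  expect_equal(ncol(f3$Y), 11)
  m <- trainMapper("linear_regression", "items_to_items", d)
  expect_length(m@fit$items, 11)              # one sub-model per target item
})

test_that("a noiseless linear relation is recovered exactly", {
  set.seed(17)
  src <- matrix(sample(0:2, 300 * 5, replace = TRUE), 300, 5)
  tgt <- cbind(src, matrix(0L, 300, 6))       # target sum == source sum
  d <- responseDataset(src, tgt)
  m <- trainMapper("linear_regression", "items_to_sum", d)
  cf <- coef(m@fit$lm)
  expect_equal(unname(cf), c(0, 1, 1, 1, 1, 1), tolerance = 1e-8)
  expect_equal(rmse(targetSums(d), predict(m, d)), 0, tolerance = 1e-8)
})

test_that("a constant target is predicted as that constant", {
  set.seed(18)
  src <- matrix(sample(0:2, 200 * 5, replace = TRUE), 200, 5)
  tgt <- matrix(rep(c(1L, 0L), c(3, 8)), 200, 11, byrow = TRUE)  # sum 3 always
  d <- responseDataset(src, tgt)
  for (method in c("linear_regression", "rf_regression", "svm_regression",
                   "ordinal_regression", "rf_classification",
                   "svm_classification")) {
    m <- suppressWarnings(trainMapper(method, "items_to_sum", d, seed = 1))
    expect_equal(predict(m, d), rep(3, 200),
                 tolerance = if (method == "svm_regression") 0.11 else 1e-6)
  }
  # linear equating maps everything to the constant target mean
  m <- trainMapper("linear_equating", "sum_to_sum", d)
  expect_equal(predict(m, d), rep(3, 200), tolerance = 1e-10)
})

test_that("cumulative-logit training recovers known ordinal-model parameters", {
  # average recovery error over replications of n = 5000 draws from a known
  # cumulative-logit model (slopes 1.1 / 0.7, cutpoints 1.0 / 2.5)
  errs <- vapply(1:3, function(s) {
    set.seed(s)
    n <- 5000
    x1 <- sample(0:2, n, replace = TRUE)
    x2 <- sample(0:2, n, replace = TRUE)
    lat <- 1.1 * x1 + 0.7 * x2 + rlogis(n)
    y <- as.integer(cut(lat, c(-Inf, 1.0, 2.5, Inf))) - 1L
    d <- responseDataset(cbind(x1, x2), matrix(y, ncol = 1))
    fit <- trainMapper("ordinal_regression", "items_to_items", d)@fit$items[[1]]
    max(abs(c(coef(fit) - c(1.1, 0.7), fit$zeta - c(1.0, 2.5))))
  }, numeric(1))
  expect_lt(mean(errs), 0.1)
  # hard predictions are integer category labels; soft ones are expectations
  set.seed(1)
  x1 <- sample(0:2, 800, replace = TRUE); x2 <- sample(0:2, 800, replace = TRUE)
  y <- as.integer(cut(1.1 * x1 + 0.7 * x2 + rlogis(800),
                      c(-Inf, 1.0, 2.5, Inf))) - 1L
  d <- responseDataset(cbind(x1, x2), matrix(y, ncol = 1))
  m <- trainMapper("ordinal_regression", "items_to_items", d)
  expect_true(all(predict(m, d) == floor(predict(m, d))))
  msoft <- trainMapper("ordinal_regression", "items_to_items", d,
                       softOrdinal = TRUE)
  expect_false(all(predict(msoft, d) == floor(predict(msoft, d))))
})

test_that("predictions are row-wise independent, deterministic and clamped", {
  d <- tinyDataset(250, 7)
  test <- d[201:250]
  perm <- sample(50)
  for (method in c("linear_regression", "rf_regression",
                   "svm_classification", "ordinal_regression")) {
    m <- trainMapper(method, "items_to_sum", d[1:200], seed = 3)
    p <- predict(m, test)
    expect_equal(predict(m, test[perm]), p[perm], tolerance = 1e-12)
    expect_true(all(p >= 0 & p <= 22))
    m2 <- trainMapper(method, "items_to_sum", d[1:200], seed = 3)
    expect_equal(predict(m2, test), p, tolerance = 1e-12)
  }
  # classification output is integer-valued
  mc <- trainMapper("rf_classification", "items_to_sum", d[1:200], seed = 3)
  expect_true(all(predict(mc, test) == round(predict(mc, test))))
  expect_identical(mc@outputType, "integer")
})

test_that("items_to_items classifiers sum their per-item predictions", {
  # target items copy source item 1, so a person with x1 = 2 must sum to 22
  set.seed(29)
  src <- matrix(sample(0:2, 250 * 5, replace = TRUE), 250, 5)
  tgt <- matrix(src[, 1], 250, 11)
  d <- responseDataset(src, tgt)
  m <- trainMapper("svm_classification", "items_to_items", d, seed = 1)
  pred <- predict(m, d)
  expect_true(all(pred[src[, 1] == 2] == 22))
  expect_true(all(pred[src[, 1] == 0] == 0))
})
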