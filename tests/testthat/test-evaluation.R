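test_that("rmse follows its definition and scaling property", {
  expect_equal(rmse(c(2, 4, 4), c(2, 4, 4)), 0)
  expect_equal(rmse(c(2, 4, 4), c(1, 4, 6)), sqrt(5 / 3), tolerance = 1e-12)
  set.seed(2)
  obs <- rnorm(50); res <- rnorm(50)
  for (c0 in c(0.5, 2, -3))
    expect_equal(rmse(obs, obs + c0 * res), abs(c0) * rmse(obs, obs + res),
                 tolerance = 1e-12)
  expect_error(rmse(1:3, 1:4), "lengths differ")
  expect_error(rmse(numeric(0), numeric(0)), "empty")
})

test_that("k-fold splits partition evenly, reproducibly, into 80/20 train/test", {
  f <- kfoldSplit(10, 5, seed = 1)
  expect_equal(sort(unique(f)), 1:5)
  expect_equal(as.numeric(table(f)), rep(2, 5))
  expect_identical(kfoldSplit(10, 5, seed = 1), f)
  f2 <- kfoldSplit(1551, 5, seed = 9)
  expect_true(all(abs(table(f2) - 1551 / 5) < 1))
  expect_true(all(1551 - table(f2) >= 1240))   # every training set ~80%
  expect_error(kfoldSplit(3, 5), "k <= n")
})

test_that("Guttman's lambda-2 matches closed forms and dominates alpha", {
  # orthogonal items: numerator vanishes
  X0 <- cbind(c(1, -1, 1, -1), c(1, 1, -1, -1))
  expect_equal(guttmanLambda2(X0), 0)
  # two items with variances 1 and covariance .5: lambda2 = 2c/(v+c) = 2/3
  X2 <- MASS::mvrnorm(200, c(0, 0), matrix(c(1, 0.5, 0.5, 1), 2),
                      empirical = TRUE)
  expect_equal(guttmanLambda2(X2), 2 / 3, tolerance = 1e-10)
  expect_equal(cronbachAlpha(X2), 2 / 3, tolerance = 1e-10)  # parallel items
  expect_error(guttmanLambda2(matrix(1, 4, 1)), "2 items")
  expect_error(guttmanLambda2(matrix(1, 4, 3)), "variance")
  # lambda-2 never falls below alpha (known Guttman inequality)
  set.seed(12)
  for (r in 1:100) {
    m <- sample(2:8, 1)
    X <- matrix(sample(0:2, 60 * m, replace = TRUE), 60, m) +
      matrix(rnorm(60), 60, m) * runif(1, 0, 1)
    expect_gte(guttmanLambda2(X), cronbachAlpha(X) - 1e-12)
  }
})

test_that("the more reliable scale is chosen as criterion, with a logged tie-break", {
  d <- tinyDataset(1200, 3)
  dec <- chooseDirection(d)
  expect_identical(dec$criterion, "target")
  expect_identical(dec$predictor, "source")
  expect_gt(dec$lambda2_target, dec$lambda2_source)
  # swapping the scales swaps the decision
  swapped <- responseDataset(targetResponses(d), sourceResponses(d))
  dec2 <- chooseDirection(swapped)
  expect_identical(dec2$criterion, "source")
  # exact tie: identical matrices, longer (target) scale wins and is flagged
  X <- sourceResponses(d)
  tie <- chooseDirection(responseDataset(X, X))
  expect_identical(tie$criterion, "target")
  expect_match(tie$note, "tie")
})

test_that("the comparison report is complete, fold-shared and correctly summarized", {
  d <- tinyDataset(300, 8)
  rep1 <- suppressWarnings(runComparison(d, k = 5, seed = 4))
  folds <- cvFolds(rep1)
  expect_equal(nrow(folds), 17 * 5)
  expect_false(any(is.na(folds$rmse)))
  expect_true(all(table(folds$fold) == 17))
  sm <- cvSummary(rep1)
  expect_equal(nrow(sm), 17)
  one <- folds[folds$method == "kernel_equating", ]
  expect_equal(sm$median_rmse[sm$method == "kernel_equating"],
               median(one$rmse))
  expect_equal(sm$sd_rmse[sm$method == "kernel_equating"], sd(one$rmse))
  # scatter pairs retained for one fold, sized like that fold's test set
  sc <- cvScatter(rep1)
  expect_equal(unique(sc$fold), 1)
  expect_equal(nrow(sc[sc$method == "irt", ]), sum(rep1@foldAssignment == 1))
  # report files
  outdir <- file.path(tempdir(), "cvrep")
  writeCVReport(rep1, outdir)
  expect_true(all(file.exists(file.path(outdir,
    c("table1.csv", "folds.csv", "scatter_fold1.csv", "direction.json")))))
  t1 <- read.csv(file.path(outdir, "table1.csv"))
  expect_identical(names(t1), c("method", "setting", "median_rmse",
                                "mean_rmse", "sd_rmse"))
})

test_that("a perfect oracle mapper reaches zero RMSE in every fold", {
  d <- tinyDataset(300, 5)
  reg <- data.frame(method = "oracle", setting = "items_to_sum")
  rep1 <- runComparison(d, k = 5, seed = 2, registry = reg)
  expect_equal(cvFolds(rep1)$rmse, rep(0, 5))
})

test_that("no test-fold row influences any trained model", {
  d <- tinyDataset(300, 6)
  folds <- kfoldSplit(300, 5, seed = 1)
  test <- folds == 1
  # mutate the test rows only
  src <- sourceResponses(d); tgt <- targetResponses(d)
  src[test, ] <- (src[test, ] + 1L) %% 3L
  tgt[test, ] <- (tgt[test, ] + 2L) %% 3L
  dMut <- responseDataset(src, tgt, personIds = personIds(d))
  newdata <- d[test]
  for (combo in list(c("linear_regression", "items_to_sum"),
                     c("rf_regression", "items_to_sum"),
                     c("kernel_equating", "sum_to_sum"),
                     c("irt", "items_to_sum"))) {
    m1 <- trainMapper(combo[1], combo[2], d[!test], seed = 7)
    m2 <- trainMapper(combo[1], combo[2], dMut[!test], seed = 7)
    expect_equal(predict(m1, newdata), predict(m2, newdata),
                 tolerance = 1e-12, info = combo[1])
  }
})

test_that("mapper failures are recorded per combination without aborting the run", {
  d <- tinyDataset(150, 9)
  # a constant source sum breaks linear equating (degenerate distribution)
  dBad <- responseDataset(matrix(1L, nPersons(d), 5),
                          targetResponses(d))
  reg <- data.frame(method = c("linear_equating", "linear_regression"),
                    setting = "sum_to_sum")
  rep1 <- suppressWarnings(runComparison(dBad, k = 3, seed = 1,
                                         registry = reg,
                                         applyDirection = FALSE))
  folds <- cvFolds(rep1)
  eqRows <- folds[folds$method == "linear_equating", ]
  expect_true(all(is.na(eqRows$rmse)))
  expect_true(all(grepl("degenerate", eqRows$error)))
  lmRows <- folds[folds$method == "linear_regression", ]
  expect_false(any(is.na(lmRows$rmse)))
})
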