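#' Registry of valid method-by-setting combinations
#'
#' The comparison grid: 4 sum-to-sum combinations (linear equating, kernel
#' equating, linear regression, ordinal regression), 7 items-to-sum (IRT
#' plus the six ML methods) and 6 items-to-items (the six ML methods) -- 17
#' in total.  Sum-to-sum is only sensible for the two equating methods and
#' the two regressions (a single predictor carries too little structure for
#' forests and SVMs); the IRT crosswalk is intrinsically items-to-sum.
#'
#' @return data.frame with columns \code{method} and \code{setting}.
#' @examples
#' nrow(harmonizationRegistry())  # 17
#' @export
harmonizationRegistry <- function() {
  rbind(
    data.frame(method = c("linear_equating", "kernel_equating",
                          "linear_regression", "ordinal_regression"),
               setting = "sum_to_sum"),
    data.frame(method = c("irt", "linear_regression", "ordinal_regression",
                          "rf_regression", "rf_classification",
                          "svm_regression", "svm_classification"),
               setting = "items_to_sum"),
    data.frame(method = c("linear_regression", "ordinal_regression",
                          "rf_regression", "rf_classification",
                          "svm_regression", "svm_classification"),
               setting = "items_to_items")
  )
}

.validCombination <- function(method, setting) {
  reg <- harmonizationRegistry()
  method == "oracle" ||
    any(reg$method == method & reg$setting == setting)
}

.assertCombination <- function(method, setting) {
  if (!.validCombination(method, setting)) {
    reason <- if (method %in% c("rf_regression", "rf_classification",
                                "svm_regression", "svm_classification") &&
                  setting == "sum_to_sum")
      "sum_to_sum needs more than one predictor to be sensible for forests and SVMs"
    else if (method == "irt")
      "the IRT crosswalk is defined for the items_to_sum setting only"
    else if (method %in% c("linear_equating", "kernel_equating"))
      "equating operates on sum scores only (sum_to_sum)"
    else "combination not in the registry"
    stop(sprintf("invalid method/setting combination '%s' x '%s': %s",
                 method, setting, reason), call. = FALSE)
  }
  invisible(TRUE)
}

#' Build predictor and target representations for a mapping setting
#'
#' \code{sum_to_sum}: one predictor (source sum), target sum as outcome.
#' \code{items_to_sum}: the source items as predictors, target sum as
#' outcome.  \code{items_to_items}: source items as predictors, each target
#' item a separate outcome (one sub-model per item at training time).
#'
#' @param dataset a \linkS4class{ResponseDataset}.
#' @param setting mapping setting tag.
#' @param method optional method tag; when given the combination is
#'   validated against the registry.
#' @return list with \code{X} (data.frame of predictors), \code{y} (target
#'   sum) and, for items_to_items, \code{Y} (matrix of item targets).
#' @export
buildFeatures <- function(dataset, setting = c("sum_to_sum", "items_to_sum",
                                               "items_to_items"),
                          method = NULL) {
  setting <- match.arg(setting)
  if (!is.null(method)) .assertCombination(method, setting)
  src <- sourceResponses(dataset)
  out <- switch(setting,
    sum_to_sum = list(X = data.frame(src_sum = sourceSums(dataset)),
                      y = targetSums(dataset)),
    items_to_sum = list(X = as.data.frame(src), y = targetSums(dataset)),
    items_to_items = list(X = as.data.frame(src), y = targetSums(dataset),
                          Y = targetResponses(dataset)))
  names(out$X) <- paste0("x", seq_along(out$X))
  out
}

## maximum category score per item (3-category scales: 2)
.itemMax <- function(dataset) max(2, max(targetResponses(dataset)))

## ---- per-method fitting helpers -------------------------------------------

## degenerate training targets (a single observed value) get a constant
## model, so every mapper honours the "constant in, constant out" contract
.constantFit <- function(value) structure(list(value = value),
                                          class = "harmonexConstant")

.fitOrdinal <- function(X, y, levels) {
  if (length(unique(y)) == 1L) return(.constantFit(y[1]))
  yf <- factor(y, levels = levels)
  df <- cbind(X, .y = yf)
  fml <- stats::as.formula(paste(".y ~", paste(names(X), collapse = " + ")))
  fit <- tryCatch(
    suppressWarnings(MASS::polr(fml, data = df, method = "logistic")),
    error = function(e) {
      df$.y <- droplevels(df$.y)
      suppressWarnings(MASS::polr(fml, data = df, method = "logistic"))
    })
  fit
}

.predictOrdinal <- function(fit, X, soft = FALSE) {
  if (inherits(fit, "harmonexConstant")) return(rep(fit$value, nrow(X)))
  if (soft) {
    pr <- stats::predict(fit, newdata = X, type = "probs")
    if (is.null(dim(pr))) pr <- matrix(pr, nrow = 1)
    lev <- as.numeric(colnames(pr))
    as.numeric(pr %*% lev)
  } else {
    as.numeric(as.character(stats::predict(fit, newdata = X, type = "class")))
  }
}

.fitRFClass <- function(X, y, seed) {
  if (length(unique(y)) == 1L) return(.constantFit(y[1]))
  set.seed(seed)
  randomForest::randomForest(x = X, y = droplevels(factor(y)), ntree = 500)
}

## score-based aggregation for ordered labels: the class at which the
## cumulative forest vote share reaches 0.5 (a weighted median on the
## score scale, respecting the ordering)
.predictRFClass <- function(fit, X) {
  if (inherits(fit, "harmonexConstant")) return(rep(fit$value, nrow(X)))
  pr <- stats::predict(fit, newdata = X, type = "prob")
  lev <- as.numeric(colnames(pr))
  ord <- order(lev)
  pr <- pr[, ord, drop = FALSE]; lev <- lev[ord]
  idx <- apply(pr, 1, function(p) which(cumsum(p) >= 0.5)[1])
  lev[idx]
}

.fitSVM <- function(X, y, type, seed) {
  if (length(unique(y)) == 1L) return(.constantFit(as.numeric(y[1])))
  set.seed(seed)
  sc <- vapply(X, stats::sd, numeric(1)) > 0
  if (type == "C-classification") y <- droplevels(factor(y))
  e1071::svm(x = X, y = y, type = type, kernel = "linear", cost = 1,
             epsilon = 0.1, scale = sc)
}

.predictSVM <- function(fit, X, classification = FALSE) {
  if (inherits(fit, "harmonexConstant")) return(rep(fit$value, nrow(X)))
  p <- stats::predict(fit, newdata = X)
  if (classification) as.numeric(as.character(p)) else as.numeric(p)
}

#' Train a harmonization mapper
#'
#' One interface over all 17 method-by-setting combinations: equating
#' (sum-to-sum), the IRT crosswalk (items-to-sum) and the ML methods
#' (linear regression via \code{lm}; cumulative-logit ordinal regression;
#' eps-regression / C-classification linear-kernel SVMs with cost 1,
#' epsilon 0.1; 500-tree random forests, classification forests aggregated
#' by a score-based weighted median over ordered labels).  Classification
#' label spaces are the full score ranges (0..max sum, or 0..2 per item);
#' labels unseen in training are dropped at fit time where the fitter
#' requires it, predictions are mapped back to integer scores.
#'
#' Training is deterministic given \code{seed} (tree and SVM fits are
#' seeded).  The method \code{"oracle"} (any setting) memorizes nothing and
#' predicts the observed target sums of whatever data it is given -- a
#' pipeline-soundness check, not a real mapper.
#'
#' @param method method tag, see \code{\link{harmonizationRegistry}}.
#' @param setting mapping setting tag.
#' @param train a \linkS4class{ResponseDataset} (training persons only).
#' @param seed integer seed for stochastic fitters.
#' @param softOrdinal predict the expected category instead of the modal
#'   category from ordinal regressions (default FALSE: hard prediction,
#'   integer output).
#' @param roundItems round per-item regression predictions before summing in
#'   the items_to_items setting (default FALSE).
#' @param ... method-specific options passed on (e.g. \code{bandwidthGrid},
#'   \code{bivariate} for kernel equating; \code{nQuad}, \code{tol} for the
#'   GPCM fit).
#' @return A \linkS4class{HarmonizationModel}.
#' @examples
#' d <- makeSyntheticDataset(n = 300, seed = 3)
#' m <- trainMapper("linear_regression", "items_to_sum", d, seed = 1)
#' head(predict(m, d))
#' @export
trainMapper <- function(method, setting, train, seed = 1,
                        softOrdinal = FALSE, roundItems = FALSE, ...) {
  .assertCombination(method, setting)
  stopifnot(is(train, "ResponseDataset"))
  seed <- as.integer(seed)
  maxT <- ncol(targetResponses(train)) * .itemMax(train)
  feats <- if (method == "oracle") NULL else buildFeatures(train, setting)
  fit <- switch(method,
    oracle = list(),
    linear_equating = {
      src <- scoreDistribution(sourceSums(train),
                               c(0, ncol(sourceResponses(train)) * 2))
      tgt <- scoreDistribution(targetSums(train), c(0, maxT))
      list(eq = linearEquate(src, tgt))
    },
    kernel_equating = {
      list(eq = kernelEquate(sourceSums(train), targetSums(train),
                             sourceRange = c(0, ncol(sourceResponses(train)) * 2),
                             targetRange = c(0, maxT), ...))
    },
    irt = {
      gf <- fitGPCM(cbind(sourceResponses(train), targetResponses(train)), ...)
      list(gpcm = gf, nSource = ncol(sourceResponses(train)))
    },
    linear_regression = {
      if (setting == "items_to_items") {
        mods <- apply(feats$Y, 2, function(yy)
          stats::lm(yy ~ ., data = feats$X), simplify = FALSE)
        list(items = mods)
      } else list(lm = stats::lm(feats$y ~ ., data = feats$X))
    },
    ordinal_regression = {
      if (setting == "items_to_items") {
        mods <- apply(feats$Y, 2, function(yy)
          .fitOrdinal(feats$X, yy, levels = 0:.itemMax(train)),
          simplify = FALSE)
        list(items = mods)
      } else list(ord = .fitOrdinal(feats$X, feats$y, levels = 0:maxT))
    },
    rf_regression = {
      set.seed(seed)
      if (setting == "items_to_items") {
        ## item targets take 3 values; regression on them is deliberate
        mods <- apply(feats$Y, 2, function(yy)
          suppressWarnings(randomForest::randomForest(x = feats$X,
                                                      y = as.numeric(yy),
                                                      ntree = 500)),
          simplify = FALSE)
        list(items = mods)
      } else list(rf = randomForest::randomForest(x = feats$X,
                                                  y = feats$y, ntree = 500))
    },
    rf_classification = {
      if (setting == "items_to_items") {
        mods <- apply(feats$Y, 2, function(yy)
          .fitRFClass(feats$X, yy, seed), simplify = FALSE)
        list(items = mods)
      } else list(rf = .fitRFClass(feats$X, feats$y, seed))
    },
    svm_regression = {
      if (setting == "items_to_items") {
        mods <- apply(feats$Y, 2, function(yy)
          .fitSVM(feats$X, as.numeric(yy), "eps-regression", seed),
          simplify = FALSE)
        list(items = mods)
      } else list(svm = .fitSVM(feats$X, feats$y, "eps-regression", seed))
    },
    svm_classification = {
      if (setting == "items_to_items") {
        mods <- apply(feats$Y, 2, function(yy)
          .fitSVM(feats$X, yy, "C-classification", seed), simplify = FALSE)
        list(items = mods)
      } else list(svm = .fitSVM(feats$X, feats$y, "C-classification", seed))
    },
    stop(sprintf("unknown method '%s'", method), call. = FALSE))
  outputType <- if (method %in% c("rf_classification", "svm_classification") ||
                    (method == "ordinal_regression" && !softOrdinal))
    "integer" else "real"
  fit$maxTarget <- maxT
  fit$softOrdinal <- softOrdinal
  fit$roundItems <- roundItems
  new("HarmonizationModel", method = method, setting = setting, fit = fit,
      outputType = outputType, seed = seed)
}

#' Predict harmonized target sums from a fitted mapper
#'
#' Applies the trained model to new source-scale data: items_to_items
#' mappers predict each target item and sum the predictions; regression
#' outputs are real-valued and clamped to the target sum range;
#' classification outputs are integers.  Predictions are row-wise
#' independent.
#'
#' @param object a \linkS4class{HarmonizationModel}.
#' @param newdata a \linkS4class{ResponseDataset}; only its source-scale
#'   responses are used (except by the \code{"oracle"} soundness check,
#'   which returns the observed target sums).
#' @param ... unused.
#' @return numeric vector of predicted target sum scores.
#' @export
setMethod("predict", "HarmonizationModel", function(object, newdata, ...) {
  stopifnot(is(newdata, "ResponseDataset"))
  fit <- object@fit
  maxT <- fit$maxTarget
  feats <- buildFeatures(newdata, object@setting)
  pred <- switch(object@method,
    oracle = targetSums(newdata),
    linear_equating = ,
    kernel_equating = applyEquating(fit$eq, feats$X[[1]], clamp = TRUE),
    irt = {
      bank <- itemBank(fit$gpcm)
      srcBank <- bank[seq_len(fit$nSource)]
      tgtBank <- bank[(fit$nSource + 1):nItems(bank)]
      th <- eapTheta(sourceResponses(newdata), srcBank)$eap
      expectedSumScore(th, tgtBank)
    },
    linear_regression = {
      if (object@setting == "items_to_items") {
        preds <- vapply(fit$items, function(mdl)
          as.numeric(stats::predict(mdl, newdata = feats$X)),
          numeric(nPersons(newdata)))
        if (fit$roundItems) preds <- round(preds)
        rowSums(preds)
      } else as.numeric(stats::predict(fit$lm, newdata = feats$X))
    },
    ordinal_regression = {
      if (object@setting == "items_to_items") {
        preds <- vapply(fit$items, function(mdl)
          .predictOrdinal(mdl, feats$X, soft = fit$softOrdinal),
          numeric(nPersons(newdata)))
        rowSums(preds)
      } else .predictOrdinal(fit$ord, feats$X, soft = fit$softOrdinal)
    },
    rf_regression = {
      if (object@setting == "items_to_items") {
        preds <- vapply(fit$items, function(mdl)
          as.numeric(stats::predict(mdl, newdata = feats$X)),
          numeric(nPersons(newdata)))
        if (fit$roundItems) preds <- round(preds)
        rowSums(preds)
      } else as.numeric(stats::predict(fit$rf, newdata = feats$X))
    },
    rf_classification = {
      if (object@setting == "items_to_items") {
        preds <- vapply(fit$items, function(mdl) .predictRFClass(mdl, feats$X),
                        numeric(nPersons(newdata)))
        rowSums(preds)
      } else .predictRFClass(fit$rf, feats$X)
    },
    svm_regression = {
      if (object@setting == "items_to_items") {
        preds <- vapply(fit$items, function(mdl) .predictSVM(mdl, feats$X),
                        numeric(nPersons(newdata)))
        if (fit$roundItems) preds <- round(preds)
        rowSums(preds)
      } else .predictSVM(fit$svm, feats$X)
    },
    svm_classification = {
      if (object@setting == "items_to_items") {
        preds <- vapply(fit$items, function(mdl)
          .predictSVM(mdl, feats$X, classification = TRUE),
          numeric(nPersons(newdata)))
        rowSums(preds)
      } else .predictSVM(fit$svm, feats$X, classification = TRUE)
    })
  pmin(pmax(as.numeric(pred), 0), maxT)
})

setMethod("show", "HarmonizationModel", function(object) {
  cat(sprintf("HarmonizationModel: %s x %s (%s output), seed %d\n",
              object@method, object@setting, object@outputType, object@seed))
})
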