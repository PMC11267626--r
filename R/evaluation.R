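#' Root mean squared error
#'
#' \eqn{\sqrt{\mathrm{mean}((obs - pred)^2)}}: the per-person differences
#' between observed and harmonized scores are squared, averaged and rooted.
#'
#' @param observed,predicted numeric vectors of equal, nonzero length.
#' @return nonnegative scalar.
#' @examples
#' rmse(c(2, 4, 4), c(1, 4, 6))  # sqrt(5/3)
#' @export
rmse <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("observed and predicted lengths differ", call. = FALSE)
  if (length(observed) == 0) stop("empty input", call. = FALSE)
  if (anyNA(observed) || anyNA(predicted))
    stop("NA values in input", call. = FALSE)
  sqrt(mean((observed - predicted)^2))
}

#' Random k-fold assignment
#'
#' Partitions \code{n} persons into \code{k} folds whose sizes differ by at
#' most one; reproducible by seed.  In the cross-validation loop each fold
#' serves once as the test set (so each training set holds about
#' \eqn{(k-1)/k} of the sample; 80\% for k = 5).
#'
#' @param n number of persons.
#' @param k number of folds (2 <= k <= n).
#' @param seed integer seed.
#' @return integer vector of fold ids in \code{1..k}, one per person.
#' @export
kfoldSplit <- function(n, k = 5, seed = 1) {
  if (k < 2 || k > n) stop("need 2 <= k <= n", call. = FALSE)
  set.seed(as.integer(seed))
  sample(rep(seq_len(k), length.out = n))
}

#' Guttman's lambda-2 reliability
#'
#' \deqn{\lambda_2 = \frac{\sigma_X^2 - \sum_j \sigma_j^2 +
#'   \sqrt{\tfrac{m}{m-1}\sum_{j \ne l}\sigma_{jl}^2}}{\sigma_X^2},}
#' with \eqn{\sigma_X^2} the total-score variance and \eqn{\sigma_{jl}} the
#' item covariances.  Never below Cronbach's alpha on the same matrix.
#'
#' @param responses numeric matrix (persons x items), m >= 2 items.
#' @param varConvention \code{"unbiased"} (n-1, default) or \code{"ml"} (n)
#'   covariance denominator.
#' @return scalar in \eqn{(-\infty, 1]}.
#' @examples
#' guttmanLambda2(MASS::mvrnorm(500, c(0, 0),
#'                matrix(c(1, .5, .5, 1), 2), empirical = TRUE))  # 2/3
#' @export
guttmanLambda2 <- function(responses, varConvention = c("unbiased", "ml")) {
  varConvention <- match.arg(varConvention)
  X <- as.matrix(responses)
  m <- ncol(X)
  if (m < 2) stop("need at least 2 items", call. = FALSE)
  C <- stats::cov(X)
  if (varConvention == "ml") C <- C * (nrow(X) - 1) / nrow(X)
  vX <- sum(C)
  if (vX <= 0) stop("zero total-score variance: reliability undefined",
                    call. = FALSE)
  off2 <- sum(C^2) - sum(diag(C)^2)
  (vX - sum(diag(C)) + sqrt(m / (m - 1) * off2)) / vX
}

#' Cronbach's alpha
#'
#' \eqn{\alpha = \frac{m}{m-1}\left(1 - \sum_j \sigma_j^2 / \sigma_X^2\right)}.
#' Provided as the classical lower benchmark for \code{\link{guttmanLambda2}}.
#'
#' @inheritParams guttmanLambda2
#' @return scalar.
#' @export
cronbachAlpha <- function(responses, varConvention = c("unbiased", "ml")) {
  varConvention <- match.arg(varConvention)
  X <- as.matrix(responses)
  m <- ncol(X)
  if (m < 2) stop("need at least 2 items", call. = FALSE)
  C <- stats::cov(X)
  if (varConvention == "ml") C <- C * (nrow(X) - 1) / nrow(X)
  vX <- sum(C)
  if (vX <= 0) stop("zero total-score variance", call. = FALSE)
  m / (m - 1) * (1 - sum(diag(C)) / vX)
}

#' Choose the harmonization direction by scale reliability
#'
#' The more reliable scale keeps its metric and becomes the criterion
#' (prediction target); the other becomes the predictor.  On a tie the
#' longer scale is taken as the criterion (and the decision is flagged).
#'
#' @param dataset a \linkS4class{ResponseDataset}.
#' @param varConvention passed to \code{\link{guttmanLambda2}}.
#' @return list with \code{predictor} and \code{criterion} ("source" /
#'   "target"), \code{lambda2_source}, \code{lambda2_target} and a
#'   human-readable \code{note}.
#' @export
chooseDirection <- function(dataset, varConvention = "unbiased") {
  l2s <- guttmanLambda2(sourceResponses(dataset), varConvention)
  l2t <- guttmanLambda2(targetResponses(dataset), varConvention)
  if (l2s == l2t) {
    longer <- if (ncol(targetResponses(dataset)) >=
                  ncol(sourceResponses(dataset))) "target" else "source"
    crit <- longer
    note <- sprintf("tie on lambda-2 (%.4f): longer scale (%s) chosen as criterion",
                    l2s, longer)
  } else {
    crit <- if (l2t > l2s) "target" else "source"
    note <- sprintf("criterion = %s scale (lambda-2 %.4f vs %.4f)",
                    crit, max(l2s, l2t), min(l2s, l2t))
  }
  list(predictor = if (crit == "target") "source" else "target",
       criterion = crit, lambda2_source = l2s, lambda2_target = l2t,
       note = note)
}

## swap the roles of the two scales
.swapDataset <- function(dataset) {
  tr <- trueTraits(dataset)
  if (nrow(tr) && ncol(tr) > 1) tr <- tr[, rev(seq_len(ncol(tr))), drop = FALSE]
  responseDataset(targetResponses(dataset), sourceResponses(dataset),
                  personIds = personIds(dataset), traits = tr)
}

#' Cross-validated comparison of all harmonization methods
#'
#' The full evaluation: Guttman's lambda-2 decides (or confirms) the
#' harmonization direction, a single k-fold split (shared across all
#' combinations, so split noise does not enter the comparison) drives the
#' cross-validation, and every registry combination is trained on k-1 folds
#' and evaluated by RMSE on the held-out fold, predicting from
#' source-scale data alone.  Mapper failures are recorded per combination
#' without aborting the rest.  Observed-vs-predicted pairs are retained for
#' one fold for scatter diagnostics.
#'
#' @param dataset a \linkS4class{ResponseDataset}.
#' @param k number of folds (default 5).
#' @param seed pipeline seed: governs the fold split and all stochastic
#'   fitters.
#' @param registry data.frame of method/setting combinations to evaluate
#'   (default \code{\link{harmonizationRegistry}}); may include the
#'   \code{"oracle"} soundness check.
#' @param scatterFold fold whose observed/predicted pairs are retained.
#' @param sharedFolds share one fold split across combinations (default);
#'   \code{FALSE} re-splits per combination with seed offset by its row
#'   index.
#' @param applyDirection when the reliability decision prefers the source
#'   scale as criterion, swap the scales before evaluating (default TRUE;
#'   the decision is logged either way).
#' @param varConvention variance convention for reliabilities and equating
#'   moments.
#' @param ... passed to \code{\link{trainMapper}}.
#' @return A \linkS4class{CVReport}.
#' @export
runComparison <- function(dataset, k = 5, seed = 1,
                          registry = harmonizationRegistry(),
                          scatterFold = 1, sharedFolds = TRUE,
                          applyDirection = TRUE,
                          varConvention = "unbiased", ...) {
  stopifnot(is(dataset, "ResponseDataset"))
  dir <- tryCatch(chooseDirection(dataset, varConvention),
                  error = function(e)
                    list(predictor = "source", criterion = "target",
                         lambda2_source = NA_real_, lambda2_target = NA_real_,
                         note = paste("reliability undefined:",
                                      conditionMessage(e))))
  if (applyDirection && dir$criterion == "source") {
    dataset <- .swapDataset(dataset)
    dir$note <- paste(dir$note, "(scales swapped for evaluation)")
  }
  n <- nPersons(dataset)
  foldsShared <- kfoldSplit(n, k, seed)
  foldRows <- list(); scatRows <- list()
  for (ci in seq_len(nrow(registry))) {
    method <- registry$method[ci]; setting <- registry$setting[ci]
    folds <- if (sharedFolds) foldsShared else kfoldSplit(n, k, seed + ci)
    for (f in seq_len(k)) {
      test <- dataset[folds == f]
      train <- dataset[folds != f]
      res <- tryCatch({
        mdl <- trainMapper(method, setting, train, seed = seed, ...)
        pred <- predict(mdl, test)
        list(rmse = rmse(targetSums(test), pred), pred = pred, err = NA_character_)
      }, error = function(e) list(rmse = NA_real_, pred = NULL,
                                  err = conditionMessage(e)))
      foldRows[[length(foldRows) + 1L]] <-
        data.frame(method = method, setting = setting, fold = f,
                   rmse = res$rmse, n_test = nPersons(test),
                   error = res$err, stringsAsFactors = FALSE)
      if (f == scatterFold && !is.null(res$pred))
        scatRows[[length(scatRows) + 1L]] <-
          data.frame(method = method, setting = setting, fold = f,
                     observed = targetSums(test), predicted = res$pred,
                     stringsAsFactors = FALSE)
    }
  }
  folds <- do.call(rbind, foldRows)
  scatter <- if (length(scatRows)) do.call(rbind, scatRows) else
    data.frame(method = character(), setting = character(),
               fold = integer(), observed = numeric(), predicted = numeric())
  agg <- function(fun) stats::aggregate(rmse ~ method + setting, data = folds,
                                        FUN = fun, na.action = stats::na.pass)
  sm <- agg(function(x) stats::median(x))
  sm$mean_rmse <- agg(function(x) mean(x))$rmse
  sm$sd_rmse <- agg(function(x) stats::sd(x))$rmse
  names(sm)[names(sm) == "rmse"] <- "median_rmse"
  ## keep registry order
  sm <- sm[match(paste(registry$method, registry$setting),
                 paste(sm$method, sm$setting)), ]
  rownames(sm) <- NULL
  new("CVReport", folds = folds, summary = sm, scatter = scatter,
      reliability = dir, foldAssignment = foldsShared,
      seed = as.integer(seed))
}

#' Accessors for \linkS4class{CVReport}
#' @param x a \linkS4class{CVReport}.
#' @param ... unused.
#' @name CVReport-accessors
NULL

#' @rdname CVReport-accessors
#' @export
setMethod("cvSummary", "CVReport", function(x, ...) x@summary)

#' @rdname CVReport-accessors
#' @export
setMethod("cvFolds", "CVReport", function(x, ...) x@folds)

#' @rdname CVReport-accessors
#' @export
setMethod("cvScatter", "CVReport", function(x, ...) x@scatter)

setMethod("show", "CVReport", function(object) {
  cat(sprintf("CVReport: %d method x setting combinations, %d folds, seed %d\n",
              nrow(object@summary), max(object@folds$fold), object@seed))
  cat(" ", object@reliability$note, "\n")
  sm <- object@summary
  sm$median_rmse <- round(sm$median_rmse, 3)
  sm$mean_rmse <- round(sm$mean_rmse, 3)
  sm$sd_rmse <- round(sm$sd_rmse, 3)
  print(sm[order(sm$median_rmse), ], row.names = FALSE)
})

#' Write a CV report as plot-ready CSV files
#'
#' Writes \code{table1.csv} (per-combination median/mean/SD RMSE),
#' \code{folds.csv} (per-fold RMSE) and \code{scatter_fold<j>.csv}
#' (observed vs predicted for the retained fold), plus
#' \code{direction.json} logging the reliability-based direction decision.
#'
#' @param report a \linkS4class{CVReport}.
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
writeCVReport <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(cvSummary(report), file.path(dir, "table1.csv"),
                   row.names = FALSE)
  utils::write.csv(cvFolds(report), file.path(dir, "folds.csv"),
                   row.names = FALSE)
  sc <- cvScatter(report)
  if (nrow(sc))
    utils::write.csv(sc, file.path(dir, sprintf("scatter_fold%d.csv",
                                                sc$fold[1])),
                     row.names = FALSE)
  jsonlite::write_json(report@reliability, file.path(dir, "direction.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Prediction-bias diagnostic by observed-score band
#'
#' Mean prediction error (predicted minus observed) among persons with low
#' observed target scores and among persons with high observed scores, from
#' a report's retained scatter pairs.  With right-skewed general-population
#' data, harmonization typically overestimates at the floor and
#' underestimates high scores.
#'
#' @param report a \linkS4class{CVReport}.
#' @param method,setting combination to diagnose.
#' @param lowScore observed score defining the floor band (default 0).
#' @param highScore lower bound of the high band (default 10).
#' @return list with \code{meanErrorLow} and \code{meanErrorHigh}
#'   (NA when a band is empty).
#' @export
biasDiagnostic <- function(report, method, setting, lowScore = 0,
                           highScore = 10) {
  sc <- cvScatter(report)
  sc <- sc[sc$method == method & sc$setting == setting, ]
  if (!nrow(sc)) stop("no scatter pairs for this combination", call. = FALSE)
  err <- sc$predicted - sc$observed
  list(meanErrorLow = if (any(sc$observed <= lowScore))
         mean(err[sc$observed <= lowScore]) else NA_real_,
       meanErrorHigh = if (any(sc$observed >= highScore))
         mean(err[sc$observed >= highScore]) else NA_real_)
}
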