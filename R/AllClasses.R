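#' @import methods
NULL

#' Polytomous item bank
#'
#' Holds one Generalized Partial Credit Model parameter set per item: a
#' positive discrimination \code{a} and a vector of adjacent-category
#' thresholds \code{b} (K-1 thresholds for a K-category item).  A threshold
#' is the latent-trait value at which two adjacent response categories are
#' equally probable.  Category scores default to \code{0..K-1}; non-standard
#' scores arise only when an empty category has been collapsed into its
#' neighbour (see \code{\link{fitGPCM}}).
#'
#' @slot itemIds character vector of item identifiers.
#' @slot a numeric vector of discriminations, one per item, all > 0.
#' @slot b list of numeric threshold vectors, one per item.
#' @slot scores list of numeric category-score vectors, one per item;
#'   element \code{i} has length \code{length(b[[i]]) + 1}.
#' @export
setClass("ItemBank",
  representation(itemIds = "character", a = "numeric", b = "list",
                 scores = "list"),
  validity = function(object) {
    m <- length(object@itemIds)
    if (length(object@a) != m || length(object@b) != m ||
        length(object@scores) != m)
      return("itemIds, a, b and scores must have one entry per item")
    if (any(!is.finite(object@a)) || any(object@a <= 0))
      return("all discriminations must be finite and > 0")
    for (i in seq_len(m)) {
      bi <- object@b[[i]]; si <- object@scores[[i]]
      if (any(!is.finite(bi))) return("thresholds must be finite")
      if (length(si) != length(bi) + 1L)
        return(sprintf("item '%s': scores must have length(b) + 1 entries",
                       object@itemIds[i]))
      if (any(diff(si) <= 0))
        return("category scores must be strictly increasing")
    }
    TRUE
  })

#' Paired two-scale response data (single-group design)
#'
#' The same persons answered both instruments, so the two response matrices
#' share row order.  Responses are complete-case integers in \code{0..K-1}
#' (here K = 3).  Simulated datasets may carry the generating latent traits.
#'
#' @slot personIds character vector, one id per row.
#' @slot source integer matrix, n x (number of source items).
#' @slot target integer matrix, n x (number of target items).
#' @slot traits numeric matrix of generating latent traits (0 columns when
#'   unknown); column 1 drives the source scale, the last column the target.
#' @export
setClass("ResponseDataset",
  representation(personIds = "character", source = "matrix",
                 target = "matrix", traits = "matrix"),
  validity = function(object) {
    n <- length(object@personIds)
    if (nrow(object@source) != n || nrow(object@target) != n)
      return("source and target must have one row per person id")
    for (nm in c("source", "target")) {
      x <- slot(object, nm)
      if (anyNA(x)) return(sprintf("%s responses contain NA (complete cases required)", nm))
      if (any(x != round(x)) || any(x < 0))
        return(sprintf("%s responses must be nonnegative integers", nm))
    }
    if (nrow(object@traits) != 0 && nrow(object@traits) != n)
      return("traits must be empty or have one row per person")
    TRUE
  })

#' Discrete sum-score distribution
#'
#' Relative frequencies over the full contiguous score range of a scale;
#' scores never observed are kept with probability zero.  Moments are those
#' of the raw scores the distribution was built from (variance convention
#' selectable at construction).
#'
#' @slot support integer vector, contiguous.
#' @slot probs numeric vector of relative frequencies (sums to 1).
#' @slot counts numeric vector of observed counts per support point.
#' @slot mean,sd numeric scalar moments of the raw scores.
#' @slot n integer number of observations.
#' @export
setClass("ScoreDistribution",
  representation(support = "integer", probs = "numeric", counts = "numeric",
                 mean = "numeric", sd = "numeric", n = "integer"),
  validity = function(object) {
    if (length(object@support) != length(object@probs))
      return("support and probs lengths differ")
    if (any(diff(object@support) != 1L))
      return("support must be contiguous integers")
    if (any(object@probs < 0)) return("probabilities must be nonnegative")
    if (abs(sum(object@probs) - 1) > 1e-8)
      return("probabilities must sum to 1")
    TRUE
  })

#' Monotone score-concordance function
#'
#' An equating transformation e(x) from the source-score scale to the
#' target-score scale, with its provenance (method, moments used, kernel
#' bandwidths, continuization constants) in \code{metadata}.
#'
#' @slot method one of "mean", "linear", "equipercentile", "kernel".
#' @slot sourceRange,targetRange numeric length-2 score ranges.
#' @slot fun vectorized function evaluating e(x) for real x.
#' @slot metadata list of method-specific constants.
#' @export
setClass("EquatingFunction",
  representation(method = "character", sourceRange = "numeric",
                 targetRange = "numeric", fun = "function",
                 metadata = "list"),
  validity = function(object) {
    if (!object@method %in% c("mean", "linear", "equipercentile", "kernel"))
      return("unknown equating method tag")
    if (length(object@sourceRange) != 2 || length(object@targetRange) != 2)
      return("ranges must have length 2")
    TRUE
  })

#' Fitted Generalized Partial Credit Model
#'
#' Result of marginal maximum likelihood EM estimation with a standard
#' normal latent-trait prior (the identification constraint).
#'
#' @slot itemBank fitted \linkS4class{ItemBank}.
#' @slot nodes,weights numeric quadrature grid used by EM and EAP scoring.
#' @slot logLik numeric marginal log-likelihood trace, one value per EM cycle.
#' @slot converged logical.
#' @slot nIter integer number of EM cycles run.
#' @export
setClass("GPCMFit",
  representation(itemBank = "ItemBank", nodes = "numeric",
                 weights = "numeric", logLik = "numeric",
                 converged = "logical", nIter = "integer"))

#' Fitted harmonization model
#'
#' A trained mapper tagged by method and mapping setting, with a uniform
#' predict contract: \code{predict(model, newdata)} returns one harmonized
#' target sum score per person in \code{newdata}.
#'
#' @slot method method tag (see \code{\link{harmonizationRegistry}}).
#' @slot setting one of "sum_to_sum", "items_to_sum", "items_to_items".
#' @slot fit method-specific fitted state.
#' @slot outputType "real" or "integer".
#' @slot seed integer seed the training used.
#' @export
setClass("HarmonizationModel",
  representation(method = "character", setting = "character", fit = "list",
                 outputType = "character", seed = "integer"))

#' Cross-validated method-comparison report
#'
#' Per-fold RMSE for every (method, setting) combination in the registry,
#' with median/mean/SD summaries over folds, observed-vs-predicted scatter
#' pairs for one retained fold, the reliability-based direction decision and
#' the fold assignment used.
#'
#' @slot folds data.frame: method, setting, fold, rmse, n_test, error.
#' @slot summary data.frame: method, setting, median_rmse, mean_rmse, sd_rmse.
#' @slot scatter data.frame: method, setting, fold, observed, predicted.
#' @slot reliability list: lambda2_source, lambda2_target, criterion, note.
#' @slot foldAssignment integer vector mapping person to fold.
#' @slot seed integer pipeline seed.
#' @export
setClass("CVReport",
  representation(folds = "data.frame", summary = "data.frame",
                 scatter = "data.frame", reliability = "list",
                 foldAssignment = "integer", seed = "integer"))
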