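#' Construct a paired response dataset
#'
#' @param source integer matrix of source-scale responses (n x m_s).
#' @param target integer matrix of target-scale responses (n x m_t).
#' @param personIds optional character ids; defaults to \code{p1..pn}.
#' @param traits optional numeric matrix of generating latent traits.
#' @return A \linkS4class{ResponseDataset}.
#' @export
responseDataset <- function(source, target, personIds = NULL, traits = NULL) {
  source <- as.matrix(source); target <- as.matrix(target)
  storage.mode(source) <- "integer"; storage.mode(target) <- "integer"
  n <- nrow(source)
  if (is.null(personIds)) personIds <- paste0("p", seq_len(n))
  if (is.null(traits)) traits <- matrix(numeric(0), nrow = 0, ncol = 0)
  new("ResponseDataset", personIds = as.character(personIds),
      source = source, target = target, traits = as.matrix(traits))
}

#' Accessors for \linkS4class{ResponseDataset}
#' @param x a \linkS4class{ResponseDataset}.
#' @param ... unused.
#' @name ResponseDataset-accessors
NULL

#' @rdname ResponseDataset-accessors
#' @export
setMethod("personIds", "ResponseDataset", function(x, ...) x@personIds)

#' @rdname ResponseDataset-accessors
#' @export
setMethod("sourceResponses", "ResponseDataset", function(x, ...) x@source)

#' @rdname ResponseDataset-accessors
#' @export
setMethod("targetResponses", "ResponseDataset", function(x, ...) x@target)

#' @rdname ResponseDataset-accessors
#' @export
setMethod("sourceSums", "ResponseDataset", function(x, ...) {
  as.numeric(rowSums(x@source))
})

#' @rdname ResponseDataset-accessors
#' @export
setMethod("targetSums", "ResponseDataset", function(x, ...) {
  as.numeric(rowSums(x@target))
})

#' @rdname ResponseDataset-accessors
#' @export
setMethod("trueTraits", "ResponseDataset", function(x, ...) x@traits)

#' @rdname ResponseDataset-accessors
#' @export
setMethod("nPersons", "ResponseDataset", function(x, ...) length(x@personIds))

#' Subset persons of a response dataset
#' @param x a \linkS4class{ResponseDataset}; \code{i} row (person) indices.
#' @param i,j,drop see \code{[}; \code{j} and \code{drop} are ignored.
#' @param ... unused.
#' @export
setMethod("[", "ResponseDataset", function(x, i, j, ..., drop = TRUE) {
  tr <- if (nrow(x@traits)) x@traits[i, , drop = FALSE] else x@traits
  new("ResponseDataset", personIds = x@personIds[i],
      source = x@source[i, , drop = FALSE],
      target = x@target[i, , drop = FALSE], traits = tr)
})

setMethod("show", "ResponseDataset", function(object) {
  cat(sprintf("ResponseDataset: %d persons, %d source + %d target items\n",
              nPersons(object), ncol(object@source), ncol(object@target)))
  cat(sprintf("  source sums: mean %.2f (range %d..%d); target sums: mean %.2f (range %d..%d)\n",
              mean(sourceSums(object)), min(object@source %*% rep(1, ncol(object@source))),
              max(rowSums(object@source)), mean(targetSums(object)),
              min(rowSums(object@target)), max(rowSums(object@target))))
  if (nrow(object@traits))
    cat(sprintf("  simulation truth: %d latent trait column(s)\n",
                ncol(object@traits)))
})

#' Simulate polytomous responses from a GPCM item bank
#'
#' Draws one response per person and item from \code{\link{gpcmProbs}} at
#' that person's trait value.  Reproducible: the RNG is seeded with
#' \code{seed} before the draw.
#'
#' @param traits numeric vector of latent-trait values, one per person.
#' @param bank an \linkS4class{ItemBank}.
#' @param seed integer RNG seed.
#' @return integer matrix, persons x items, with \code{itemIds(bank)} as
#'   column names.
#' @export
simulateResponses <- function(traits, bank, seed) {
  stopifnot(is(bank, "ItemBank"))
  if (!is.numeric(traits) || any(!is.finite(traits)))
    stop("traits must be finite numeric values", call. = FALSE)
  set.seed(as.integer(seed))
  n <- length(traits); m <- nItems(bank)
  X <- matrix(0L, n, m, dimnames = list(NULL, itemIds(bank)))
  for (i in seq_len(m)) {
    P <- gpcmProbs(traits, bank@a[i], bank@b[[i]], bank@scores[[i]])
    cum <- t(apply(P, 1L, cumsum))
    u <- stats::runif(n)
    X[, i] <- as.integer(rowSums(u > cum[, -ncol(cum), drop = FALSE]))
  }
  X
}

#' Generate a paper-scale paired two-scale sample
#'
#' Simulates the kind of general-population sample the pipeline is built
#' for: n persons (default 1551) answering a 5-item and an 11-item
#' 3-category scale, with right-skewed sum-score distributions, scale
#' reliabilities near 0.80 (source) and 0.82 (target) and -- in the
#' \code{"correlated_traits"} scenario -- a between-scale sum-score
#' correlation near 0.43.
#'
#' Scenarios: \code{"unidimensional"} draws a single standard-normal trait
#' driving both scales (the assumption the IRT crosswalk makes);
#' \code{"correlated_traits"} draws two standard-normal traits with
#' correlation \code{rho} (fixture default 0.57), source items loading on
#' trait 1 and target items on trait 2, emulating partial construct overlap.
#'
#' Seed-derivation rule: the trait draw uses \code{seed}, the source
#' response draw \code{seed + 1}, the target response draw \code{seed + 2}.
#' Output is byte-identical for identical \code{(n, scenario, seed)}.
#'
#' @param n number of persons (>= 100).
#' @param scenario \code{"correlated_traits"} (default, emulates partial
#'   overlap) or \code{"unidimensional"}.
#' @param seed integer pipeline seed.
#' @param banks item banks and trait correlation as returned by
#'   \code{\link{defaultItemBanks}}.
#' @param rho trait correlation for the correlated-traits scenario;
#'   default taken from the fixture.
#' @return A \linkS4class{ResponseDataset} carrying the generating traits.
#' @examples
#' d <- makeSyntheticDataset(n = 200, seed = 7)
#' cor(sourceSums(d), targetSums(d))
#' @export
makeSyntheticDataset <- function(n = 1551,
                                 scenario = c("correlated_traits",
                                              "unidimensional"),
                                 seed = 1, banks = defaultItemBanks(),
                                 rho = NULL) {
  if (n < 100) stop("n must be at least 100", call. = FALSE)
  scenario <- match.arg(scenario)
  seed <- as.integer(seed)
  if (is.null(rho)) rho <- banks$traitCorrelation
  if (abs(rho) > 1) stop("trait correlation must lie in [-1, 1]", call. = FALSE)
  set.seed(seed)
  if (scenario == "unidimensional") {
    th <- stats::rnorm(n)
    traits <- cbind(theta = th)
    thSrc <- th; thTgt <- th
  } else {
    th1 <- stats::rnorm(n)
    th2 <- rho * th1 + sqrt(1 - rho^2) * stats::rnorm(n)
    traits <- cbind(theta_source = th1, theta_target = th2)
    thSrc <- th1; thTgt <- th2
  }
  src <- simulateResponses(thSrc, banks$source, seed = seed + 1L)
  tgt <- simulateResponses(thTgt, banks$target, seed = seed + 2L)
  responseDataset(src, tgt, traits = traits)
}

#' Write / read a response dataset as CSV
#'
#' One row per person with columns \code{person_id}, \code{src_*},
#' \code{tgt_*} and, when requested and available, the generating trait
#' columns (\code{theta_*}).
#'
#' @param x a \linkS4class{ResponseDataset}.
#' @param path file path.
#' @param includeTraits write simulation-truth trait columns if present.
#' @return \code{writeResponseDataset} returns \code{path} invisibly;
#'   \code{readResponseDataset} returns a \linkS4class{ResponseDataset}.
#' @export
writeResponseDataset <- function(x, path, includeTraits = FALSE) {
  df <- data.frame(person_id = personIds(x), check.names = FALSE)
  src <- sourceResponses(x); tgt <- targetResponses(x)
  colnames(src) <- paste0("src_", seq_len(ncol(src)))
  colnames(tgt) <- paste0("tgt_", seq_len(ncol(tgt)))
  df <- cbind(df, src, tgt)
  if (includeTraits && nrow(x@traits)) {
    tr <- x@traits
    if (is.null(colnames(tr))) colnames(tr) <- paste0("theta_", seq_len(ncol(tr)))
    df <- cbind(df, tr)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeResponseDataset
#' @export
readResponseDataset <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  srcCols <- grep("^src_", names(df)); tgtCols <- grep("^tgt_", names(df))
  thCols <- grep("^theta", names(df))
  traits <- if (length(thCols)) as.matrix(df[, thCols, drop = FALSE]) else NULL
  responseDataset(df[, srcCols, drop = FALSE], df[, tgtCols, drop = FALSE],
                  personIds = df$person_id, traits = traits)
}
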