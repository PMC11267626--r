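#' GPCM category response probabilities
#'
#' Category probabilities of the Generalized Partial Credit Model,
#' \deqn{P(X = k \mid \theta) \propto \exp\sum_{v \le k} a\,(\theta - b_v),}
#' with the empty sum equal to 0 for the lowest category.  A threshold
#' \eqn{b_k} is the trait value at which categories \eqn{k-1} and \eqn{k}
#' are exactly equally probable.  With non-consecutive category scores
#' \eqn{s_k} (collapsed categories) each step is weighted by its score
#' increment: \eqn{\sum_{v\le k} a\,(s_v - s_{v-1})(\theta - b_v)}.
#'
#' @param theta numeric vector of latent-trait values.
#' @param a positive discrimination.
#' @param b numeric vector of K-1 thresholds.
#' @param scores category scores, default \code{0:(K-1)}.
#' @return matrix \code{length(theta)} x K of probabilities; rows sum to 1.
#' @examples
#' gpcmProbs(0, a = 1, b = c(0, 1))      # (0.4223, 0.4223, 0.1554)
#' gpcmProbs(-0.5, a = 1.2, b = c(-0.5, 0.8))[, 1:2]  # equal pair
#' @export
gpcmProbs <- function(theta, a, b, scores = NULL) {
  if (any(!is.finite(theta)))
    stop("theta must be finite", call. = FALSE)
  if (!is.finite(a) || a <= 0)
    stop("discrimination 'a' must be finite and > 0", call. = FALSE)
  if (any(!is.finite(b)))
    stop("thresholds 'b' must be finite", call. = FALSE)
  K <- length(b) + 1L
  if (is.null(scores)) scores <- 0:(K - 1L)
  d <- diff(scores)                       # score increments per step
  # eta_k = a * (s_k * theta - C_k), C_k = sum_{v<=k} d_v b_v, relative to s_0
  C <- c(0, cumsum(d * b))
  S <- scores - scores[1L]
  eta <- a * (outer(theta, S) - rep(C, each = length(theta)))
  eta <- eta - apply(eta, 1L, max)
  ex <- exp(eta)
  ex / rowSums(ex)
}

#' Expected item score under the GPCM
#'
#' \eqn{E(X \mid \theta) = \sum_k s_k P(k \mid \theta)}; non-decreasing in
#' theta for any valid item.
#'
#' @inheritParams gpcmProbs
#' @return numeric vector, one value per theta.
#' @export
expectedItemScore <- function(theta, a, b, scores = NULL) {
  K <- length(b) + 1L
  if (is.null(scores)) scores <- 0:(K - 1L)
  drop(gpcmProbs(theta, a, b, scores) %*% scores)
}

#' Expected sum score over an item bank
#'
#' The model-implied total score \eqn{\sum_i E(X_i \mid \theta)} on the
#' bank's scale; strictly increasing in theta and bounded by
#' \code{[0, maxSumScore(bank)]}.  This is the second half of the IRT
#' crosswalk: a trait estimate from one instrument is converted into the
#' expected total on the other.
#'
#' @param theta numeric vector of trait values.
#' @param bank an \linkS4class{ItemBank} (e.g. the target-scale items of a
#'   joint \code{\link{fitGPCM}}).
#' @return numeric vector, one expected sum per theta.
#' @examples
#' expectedSumScore(0, ItemBank("i", 1, list(c(0, 1))))  # 0.7331
#' @export
expectedSumScore <- function(theta, bank) {
  stopifnot(is(bank, "ItemBank"))
  out <- numeric(length(theta))
  for (i in seq_len(nItems(bank)))
    out <- out + expectedItemScore(theta, bank@a[i], bank@b[[i]],
                                   bank@scores[[i]])
  out
}
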