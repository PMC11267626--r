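#' Quadrature grid for EM and EAP scoring
#'
#' 61 equally spaced nodes on [-6, 6] with standard-normal density weights
#' (normalized to sum 1).  A dense fixed grid keeps both estimation and
#' scoring deterministic.
#'
#' @param nQuad number of nodes.
#' @param range trait range covered.
#' @return list with numeric \code{nodes} and \code{weights}.
#' @export
quadratureGrid <- function(nQuad = 61, range = c(-6, 6)) {
  nodes <- seq(range[1], range[2], length.out = nQuad)
  w <- stats::dnorm(nodes)
  list(nodes = nodes, weights = w / sum(w))
}

## per-item category-probability matrix over the quadrature nodes
.itemProbs <- function(nodes, a, b, scores) gpcmProbs(nodes, a, b, scores)

## derivative structures for the M-step Newton update of one item.
## eta_k = a (S_k theta - C_k); params p = (a, b_1..b_{K-1}).
.itemDerivMats <- function(nodes, a, b, scores) {
  d <- diff(scores); K <- length(scores)
  C <- c(0, cumsum(d * b)); S <- scores - scores[1]
  Q <- length(nodes)
  G <- vector("list", K)  # npar = K matrices, each Q x K
  G[[1]] <- outer(nodes, S) - rep(C, each = Q)        # d eta_k / d a
  for (v in seq_len(K - 1))                            # d eta_k / d b_v
    G[[v + 1]] <- matrix(rep(-a * d[v] * (seq_len(K) - 1 >= v), each = Q), Q, K)
  G
}

## One (or a few) Newton updates with step-halving for one item, maximizing
## the expected complete-data log-likelihood sum_qk R_qk log P_qk.
.mStepItem <- function(nodes, R, a, b, scores, nSteps = 3) {
  K <- length(scores)
  obj <- function(a, b) {
    P <- .itemProbs(nodes, a, b, scores)
    sum(R * log(pmax(P, 1e-300)))
  }
  cur <- obj(a, b)
  for (step in seq_len(nSteps)) {
    P <- .itemProbs(nodes, a, b, scores)
    N <- rowSums(R)
    D <- R - N * P
    G <- .itemDerivMats(nodes, a, b, scores)
    npar <- K
    grad <- vapply(G, function(g) sum(D * g), numeric(1))
    bar <- vapply(G, function(g) rowSums(P * g), numeric(length(nodes)))
    H <- matrix(0, npar, npar)
    for (i in seq_len(npar)) for (j in i:npar) {
      Eij <- rowSums(P * G[[i]] * G[[j]])
      H[i, j] <- H[j, i] <- -sum(N * (Eij - bar[, i] * bar[, j]))
    }
    d <- diff(scores)
    for (v in seq_len(K - 1)) {  # cross second-derivative of eta in (a, b_v)
      t1 <- sum(D * G[[v + 1]]) / a
      H[1, v + 1] <- H[1, v + 1] + t1
      H[v + 1, 1] <- H[v + 1, 1] + t1
    }
    delta <- tryCatch(solve(H, -grad), error = function(e) grad * 1e-3)
    t <- 1
    improved <- FALSE
    for (half in 1:20) {
      aNew <- a + t * delta[1]; bNew <- b + t * delta[-1]
      if (aNew > 1e-3) {
        val <- obj(aNew, bNew)
        if (is.finite(val) && val >= cur - 1e-10) {
          a <- aNew; b <- bNew; cur <- val; improved <- val > cur - 1e-10
          improved <- TRUE
          break
        }
      }
      t <- t / 2
    }
    if (!improved) break
  }
  list(a = a, b = b)
}

#' Fit the Generalized Partial Credit Model by marginal maximum likelihood
#'
#' Joint unidimensional GPCM fit to all items of a response matrix by an EM
#' algorithm: the E-step integrates the latent trait over a fixed 61-node
#' quadrature grid with a standard-normal prior (the identification
#' constraint; estimates are not rescaled), the M-step runs per-item Newton
#' updates with step-halving on the expected complete-data log-likelihood.
#' The marginal log-likelihood trace is non-decreasing; convergence is
#' declared when the largest absolute parameter change drops below
#' \code{tol}.
#'
#' Starting values: all discriminations 1; thresholds at the
#' quantile-implied points \eqn{\Phi^{-1}(P(X \le k-1))}.
#'
#' Every item must show at least 2 observed categories.  Items with empty
#' categories abort with a message naming the item unless
#' \code{emptyCategories = "collapse"}, which merges each empty category
#' into its lower (for the lowest, upper) neighbour for fitting while
#' keeping the original category scores, so expected sum scores stay on the
#' original scale.
#'
#' @param responses integer matrix (persons x items), categories coded
#'   \code{0..K-1}, complete cases.
#' @param nQuad,thetaRange quadrature grid settings.
#' @param tol convergence tolerance on the maximum absolute parameter
#'   change.
#' @param maxIter EM cycle cap.
#' @param emptyCategories \code{"error"} (default) or \code{"collapse"}.
#' @return A \linkS4class{GPCMFit}.
#' @examples
#' d <- makeSyntheticDataset(n = 300, scenario = "unidimensional", seed = 1)
#' fit <- fitGPCM(cbind(sourceResponses(d), targetResponses(d)))
#' fit
#' @export
fitGPCM <- function(responses, nQuad = 61, thetaRange = c(-6, 6),
                    tol = 1e-4, maxIter = 500,
                    emptyCategories = c("error", "collapse")) {
  emptyCategories <- match.arg(emptyCategories)
  responses <- as.matrix(responses)
  if (anyNA(responses)) stop("responses contain NA", call. = FALSE)
  n <- nrow(responses); m <- ncol(responses)
  ids <- colnames(responses)
  if (is.null(ids)) ids <- paste0("item_", seq_len(m))
  Kmax <- max(responses) + 1L

  ## category bookkeeping per item (handles empty categories)
  recoded <- matrix(0L, n, m)
  scoresList <- vector("list", m)
  for (i in seq_len(m)) {
    obs <- sort(unique(responses[, i]))
    full <- 0:max(Kmax - 1L, max(obs))
    if (length(obs) < 2)
      stop(sprintf("item '%s' has a single observed category", ids[i]),
           call. = FALSE)
    if (length(obs) < length(full)) {
      if (emptyCategories == "error")
        stop(sprintf("item '%s' has empty categories (%s); use emptyCategories = 'collapse'",
                     ids[i], paste(setdiff(full, obs), collapse = ",")),
             call. = FALSE)
    }
    scoresList[[i]] <- as.numeric(obs)
    recoded[, i] <- match(responses[, i], obs) - 1L
  }

  grid <- quadratureGrid(nQuad, thetaRange)
  nodes <- grid$nodes; w <- grid$weights
  Q <- length(nodes)

  ## starting values
  a <- rep(1, m)
  b <- vector("list", m)
  for (i in seq_len(m)) {
    K <- length(scoresList[[i]])
    cp <- cumsum(tabulate(recoded[, i] + 1L, nbins = K))[- K] / n
    b[[i]] <- pmin(pmax(stats::qnorm(cp), -2.5), 2.5)
  }

  llTrace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < maxIter) {
    iter <- iter + 1L
    ## E-step
    P <- lapply(seq_len(m), function(i)
      .itemProbs(nodes, a[i], b[[i]], scoresList[[i]]))
    L <- matrix(1, Q, n)
    for (i in seq_len(m)) L <- L * P[[i]][, recoded[, i] + 1L]
    Lw <- L * w
    colsum <- colSums(Lw)
    llTrace <- c(llTrace, sum(log(colsum)))
    post <- Lw / rep(colsum, each = Q)
    ## M-step
    maxChange <- 0
    for (i in seq_len(m)) {
      K <- length(scoresList[[i]])
      Ind <- outer(recoded[, i], 0:(K - 1L), "==") + 0
      R <- post %*% Ind
      upd <- .mStepItem(nodes, R, a[i], b[[i]], scoresList[[i]])
      maxChange <- max(maxChange, abs(upd$a - a[i]), abs(upd$b - b[[i]]))
      a[i] <- upd$a; b[[i]] <- upd$b
    }
    if (maxChange < tol) { converged <- TRUE; break }
  }
  bank <- ItemBank(ids, a, b, scores = scoresList)
  new("GPCMFit", itemBank = bank, nodes = nodes, weights = w,
      logLik = llTrace, converged = converged, nIter = iter)
}

#' @rdname GPCMFit-accessors
#' @export
setMethod("itemBank", "GPCMFit", function(x, ...) x@itemBank)

#' Accessors for \linkS4class{GPCMFit}
#' @param x a \linkS4class{GPCMFit}.
#' @param ... unused.
#' @name GPCMFit-accessors
NULL

setMethod("show", "GPCMFit", function(object) {
  cat(sprintf("GPCMFit: %d items, %d EM cycles (%s), logLik %.3f\n",
              nItems(object@itemBank), object@nIter,
              if (object@converged) "converged" else "NOT converged",
              utils::tail(object@logLik, 1)))
})

#' Expected a posteriori (EAP) trait estimates
#'
#' Posterior mean and SD of the latent trait for each response pattern,
#' under a standard-normal prior, computed on the same fixed quadrature
#' grid the EM uses:
#' \deqn{\hat\theta = \sum_q \theta_q w_q L(x|\theta_q) / \sum_q w_q L(x|\theta_q).}
#' A pattern with zero items returns the prior (EAP 0, SD 1).
#'
#' @param responses integer matrix (persons x items) on the bank's items.
#' @param bank an \linkS4class{ItemBank} (e.g. the source-scale part of a
#'   joint fit).
#' @param nQuad,thetaRange quadrature settings (keep defaults to match the
#'   EM grid).
#' @return data.frame with columns \code{eap} and \code{posteriorSD}.
#' @export
eapTheta <- function(responses, bank, nQuad = 61, thetaRange = c(-6, 6)) {
  stopifnot(is(bank, "ItemBank"))
  responses <- as.matrix(responses)
  n <- nrow(responses); m <- ncol(responses)
  if (m != nItems(bank))
    stop("responses and item bank disagree on the number of items",
         call. = FALSE)
  if (m == 0L)
    return(data.frame(eap = rep(0, n), posteriorSD = rep(1, n)))
  grid <- quadratureGrid(nQuad, thetaRange)
  nodes <- grid$nodes; w <- grid$weights
  L <- matrix(1, length(nodes), n)
  for (i in seq_len(m)) {
    sc <- bank@scores[[i]]
    xi <- match(responses[, i], sc)
    if (anyNA(xi))
      stop(sprintf("item '%s': unknown category code", bank@itemIds[i]),
           call. = FALSE)
    P <- .itemProbs(nodes, bank@a[i], bank@b[[i]], sc)
    L <- L * P[, xi]
  }
  Lw <- L * w
  norm <- colSums(Lw)
  eap <- colSums(Lw * nodes) / norm
  m2 <- colSums(Lw * nodes^2) / norm
  data.frame(eap = eap, posteriorSD = sqrt(pmax(m2 - eap^2, 0)))
}

#' IRT crosswalk: harmonize source responses to expected target sums
#'
#' The full IRT chain: fit the unidimensional GPCM jointly to all source and
#' target items of the training data, estimate each test person's latent
#' trait by EAP from the source items alone, then convert the trait estimate
#' into the expected target-scale sum score conditional on the target items'
#' parameters.  Output is real-valued (not rounded).
#'
#' @param train a \linkS4class{ResponseDataset} (training fold).
#' @param testSource integer matrix of source-scale responses for the
#'   persons to be harmonized.
#' @param fit optional pre-computed joint \linkS4class{GPCMFit} on
#'   \code{train}'s 16-item data (refit when NULL).
#' @param ... passed to \code{\link{fitGPCM}}.
#' @return numeric predicted target sum scores, in
#'   \code{[0, maxSumScore(targetBank)]}.
#' @export
irtHarmonize <- function(train, testSource, fit = NULL, ...) {
  stopifnot(is(train, "ResponseDataset"))
  mS <- ncol(sourceResponses(train))
  if (is.null(fit))
    fit <- fitGPCM(cbind(sourceResponses(train), targetResponses(train)), ...)
  bank <- itemBank(fit)
  srcBank <- bank[seq_len(mS)]
  tgtBank <- bank[(mS + 1):nItems(bank)]
  th <- eapTheta(as.matrix(testSource), srcBank)$eap
  expectedSumScore(th, tgtBank)
}
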