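#' Empirical distribution of integer sum scores
#'
#' Relative frequencies over the full contiguous score range of the scale;
#' scores never observed are kept with probability zero so that every
#' distribution on a scale shares one support.
#'
#' @param scores integer-valued observed sum scores (non-empty).
#' @param range numeric length-2 score range of the scale; defaults to
#'   \code{c(0, max(scores))}.
#' @param varConvention \code{"unbiased"} (n-1 denominator, default) or
#'   \code{"ml"} (n) for the cached standard deviation.
#' @return A \linkS4class{ScoreDistribution}.
#' @examples
#' scoreDistribution(c(0, 0, 1, 2), range = c(0, 2))  # probs .5 .25 .25
#' @export
scoreDistribution <- function(scores, range = NULL,
                              varConvention = c("unbiased", "ml")) {
  varConvention <- match.arg(varConvention)
  if (length(scores) == 0) stop("no scores supplied", call. = FALSE)
  if (anyNA(scores) || any(scores != round(scores)))
    stop("scores must be integers without NA", call. = FALSE)
  if (is.null(range)) range <- c(0, max(scores))
  if (any(scores < range[1]) || any(scores > range[2]))
    stop("scores outside the scale range", call. = FALSE)
  support <- as.integer(range[1]):as.integer(range[2])
  counts <- as.numeric(table(factor(scores, levels = support)))
  n <- length(scores)
  s <- stats::sd(scores)
  if (varConvention == "ml") s <- s * sqrt((n - 1) / n)
  if (n == 1) s <- 0
  new("ScoreDistribution", support = support, probs = counts / n,
      counts = counts, mean = mean(scores), sd = s, n = as.integer(n))
}

setMethod("show", "ScoreDistribution", function(object) {
  cat(sprintf("ScoreDistribution: support %d..%d, n = %d, mean %.3f, sd %.3f\n",
              min(object@support), max(object@support), object@n,
              object@mean, object@sd))
})

## pmf moments (used by kernel continuization, which must preserve the pmf's
## own mean and variance regardless of the sample-variance convention)
.pmfMoments <- function(dist) {
  mu <- sum(dist@probs * dist@support)
  list(mean = mu, var = sum(dist@probs * (dist@support - mu)^2))
}

#' Polynomial log-linear presmoothing of a score distribution
#'
#' Replaces the empirical relative frequencies by those fitted from a
#' Poisson log-linear model with raw polynomial terms up to \code{degree},
#' which preserves the first \code{degree} moments.  \code{degree = 0}
#' returns the distribution unchanged (assumption-free default).
#'
#' @param dist a \linkS4class{ScoreDistribution}.
#' @param degree nonnegative integer polynomial degree.
#' @return A \linkS4class{ScoreDistribution} with smoothed probabilities.
#' @export
presmoothScoreDistribution <- function(dist, degree = 0) {
  if (degree == 0) return(dist)
  x <- dist@support
  X <- stats::poly(x, degree = degree, raw = TRUE)
  fit <- stats::glm(dist@counts ~ X, family = stats::poisson())
  p <- as.numeric(stats::fitted(fit))
  new("ScoreDistribution", support = dist@support, probs = p / sum(p),
      counts = dist@counts, mean = dist@mean, sd = dist@sd, n = dist@n)
}

.equatingFunction <- function(method, fun, src, tgt, metadata = list()) {
  new("EquatingFunction", method = method, fun = fun,
      sourceRange = as.numeric(range(src@support)),
      targetRange = as.numeric(range(tgt@support)), metadata = metadata)
}

#' Mean equating
#'
#' Shifts source scores so the transformed mean equals the target mean:
#' \eqn{e(x) = x - \mu_{src} + \mu_{tgt}}.
#'
#' @param src,tgt \linkS4class{ScoreDistribution}s of the source and target
#'   sum scores.
#' @return An \linkS4class{EquatingFunction}.
#' @export
meanEquate <- function(src, tgt) {
  shift <- tgt@mean - src@mean
  .equatingFunction("mean", function(x) x + shift, src, tgt,
                    metadata = list(mu_src = src@mean, mu_tgt = tgt@mean))
}

#' Linear equating
#'
#' Matches both mean and standard deviation of the target:
#' \eqn{e(x) = (\sigma_{tgt}/\sigma_{src})(x - \mu_{src}) + \mu_{tgt}}.
#'
#' @inheritParams meanEquate
#' @return An \linkS4class{EquatingFunction}.
#' @export
linearEquate <- function(src, tgt) {
  if (src@sd <= 0)
    stop("degenerate source distribution: zero standard deviation",
         call. = FALSE)
  slope <- tgt@sd / src@sd
  muS <- src@mean; muT <- tgt@mean
  .equatingFunction("linear", function(x) slope * (x - muS) + muT, src, tgt,
                    metadata = list(mu_src = muS, sd_src = src@sd,
                                    mu_tgt = muT, sd_tgt = tgt@sd,
                                    slope = slope))
}

## Continuized percentile rank of integer-score pmf: each score spread
## uniformly over (x - .5, x + .5), i.e. PR(x)/100 = F(x-1) + .5 f(x) at
## integers, linearly interpolated between half-integers.
.prFun <- function(dist) {
  knots <- c(dist@support[1] - 0.5, dist@support + 0.5)
  Fk <- c(0, cumsum(dist@probs))
  function(x) {
    p <- stats::approx(knots, Fk, xout = x, rule = 2)$y
    pmin(pmax(p, 0), 1)
  }
}

## Inverse of the continuized percentile rank: smallest y* with F(y*) >= p,
## then y* - .5 + (p - F(y*-1))/f(y*).  When p lands exactly on the CDF value
## that opens a run of zero-frequency scores, return the midpoint of the run.
.prInverse <- function(dist) {
  sup <- dist@support; f <- dist@probs; Fc <- cumsum(f)
  function(p) {
    vapply(p, function(pp) {
      if (pp <= 0) return(sup[1] - 0.5)
      if (pp >= 1) pp <- 1
      j <- which(Fc >= pp - 1e-12)[1]
      Fprev <- if (j == 1) 0 else Fc[j - 1]
      e <- if (f[j] > 0) sup[j] - 0.5 + (pp - Fprev) / f[j] else sup[j] - 0.5
      # tie rule: p exactly at a cumulative value followed by zero-frequency run
      if (abs(pp - Fc[j]) < 1e-12 && j < length(sup) && f[j + 1] == 0) {
        r <- 0L
        while (j + r + 1L <= length(sup) && f[j + r + 1L] == 0) r <- r + 1L
        e <- sup[j] + 0.5 + r / 2
      }
      e
    }, numeric(1))
  }
}

#' Equipercentile equating
#'
#' Transforms source scores so their continuized percentile ranks match the
#' target's: \eqn{e(x) = G^{-1}(PR_{src}(x)/100)}, with the standard
#' uniform-kernel (0.5-offset) continuization on both sides.  Beyond the
#' source support the function continues linearly with its boundary slope.
#'
#' @inheritParams meanEquate
#' @param presmoothDegree optional polynomial log-linear presmoothing degree
#'   applied to both distributions (0 = empirical frequencies).
#' @return An \linkS4class{EquatingFunction}.
#' @examples
#' s <- scoreDistribution(c(0, 0, 1, 1, 2), range = c(0, 2))
#' t <- scoreDistribution(0:4, range = c(0, 4))
#' applyEquating(equipercentileEquate(s, t), 0:2, clamp = FALSE)
#' @export
equipercentileEquate <- function(src, tgt, presmoothDegree = 0) {
  srcS <- presmoothScoreDistribution(src, presmoothDegree)
  tgtS <- presmoothScoreDistribution(tgt, presmoothDegree)
  pr <- .prFun(srcS); inv <- .prInverse(tgtS)
  lo <- min(srcS@support); hi <- max(srcS@support)
  core <- function(x) inv(pr(x))
  fun <- function(x) {
    out <- numeric(length(x))
    inside <- x >= lo & x <= hi
    out[inside] <- core(x[inside])
    if (any(!inside)) {  # linear continuation with boundary slope
      sLo <- core(lo + 1) - core(lo)
      sHi <- core(hi) - core(hi - 1)
      below <- x < lo; above <- x > hi
      out[below] <- core(lo) + sLo * (x[below] - lo)
      out[above] <- core(hi) + sHi * (x[above] - hi)
    }
    out
  }
  .equatingFunction("equipercentile", fun, src, tgt,
                    metadata = list(presmooth_degree = presmoothDegree))
}

## Gaussian-kernel continuized CDF and density of a discrete pmf.
## a_h = sqrt(sigma^2/(sigma^2 + h^2)) preserves the pmf mean and variance.
.kernelCDF <- function(dist, h) {
  m <- .pmfMoments(dist)
  if (m$var <= 0) stop("degenerate distribution: zero variance", call. = FALSE)
  a <- sqrt(m$var / (m$var + h^2))
  sup <- dist@support; p <- dist@probs; mu <- m$mean
  list(a = a, h = h,
       cdf = function(x) {
         z <- outer(x, a * sup + (1 - a) * mu, "-") / (a * h)
         as.numeric(stats::pnorm(z) %*% p)
       },
       pdf = function(x) {
         z <- outer(x, a * sup + (1 - a) * mu, "-") / (a * h)
         as.numeric(stats::dnorm(z) %*% p) / (a * h)
       })
}

## Standard continuization penalty: squared distance between the continuized
## density and the relative frequencies at the support points.
.kernelPenalty <- function(dist, h) {
  k <- .kernelCDF(dist, h)
  sum((dist@probs - k$pdf(dist@support))^2)
}

.selectBandwidth <- function(dist, grid) {
  pen <- vapply(grid, function(h) .kernelPenalty(dist, h), numeric(1))
  grid[which.min(pen)]
}

#' Gaussian-kernel equating for the single-group design
#'
#' Continuizes both sum-score distributions with a Gaussian kernel using the
#' mean- and variance-preserving rescaling
#' \eqn{F_h(x) = \sum_j r_j \Phi\{(x - a_h x_j - (1-a_h)\mu)/(a_h h)\}},
#' \eqn{a_h = \sqrt{\sigma^2/(\sigma^2+h^2)}}, then equates through the
#' continuous CDFs: \eqn{e(x) = G_{h'}^{-1}(F_h(x))}, which is strictly
#' increasing.  Bandwidths are chosen per marginal by minimizing the
#' standard penalty (squared distance between continuized density and
#' relative frequencies at the support points) over a fixed grid, unless
#' given explicitly.
#'
#' The paired scores come from the same persons; by default the two
#' empirical marginals are used.  With \code{bivariate = TRUE} the joint
#' score table is first presmoothed by a Poisson log-linear model (powers up
#' to \code{bivariateDegree} per margin plus a linear-by-linear association
#' term, so the dependence informs the smoothed marginals), and the
#' marginals of that fit are equated.
#'
#' @param x,y paired integer sum scores of the same persons (length >= 50).
#' @param sourceRange,targetRange score ranges; default
#'   \code{c(0, max(...))}.
#' @param bandwidth optional numeric length-2 (source, target) bandwidths;
#'   \code{NULL} selects by penalty minimization.
#' @param bandwidthGrid search grid for the bandwidth; default 61 log-spaced
#'   points on [0.05, 3].
#' @param presmoothDegree univariate log-linear presmoothing degree
#'   (0 = empirical), ignored when \code{bivariate = TRUE}.
#' @param bivariate use bivariate log-linear presmoothing of the joint table.
#' @param bivariateDegree integer length-2 polynomial degrees per margin for
#'   the bivariate presmoothing.
#' @param varConvention variance convention for the cached moments.
#' @return An \linkS4class{EquatingFunction} with chosen bandwidths and
#'   continuization constants in \code{metadata}.
#' @export
kernelEquate <- function(x, y, sourceRange = NULL, targetRange = NULL,
                         bandwidth = NULL,
                         bandwidthGrid = exp(seq(log(0.05), log(3),
                                                 length.out = 61)),
                         presmoothDegree = 0, bivariate = FALSE,
                         bivariateDegree = c(3, 3),
                         varConvention = "unbiased") {
  if (length(x) != length(y))
    stop("x and y must be paired scores of the same persons", call. = FALSE)
  if (length(x) < 50)
    stop("kernel equating needs at least 50 paired scores", call. = FALSE)
  src <- scoreDistribution(x, sourceRange, varConvention)
  tgt <- scoreDistribution(y, targetRange, varConvention)
  if (bivariate) {
    sm <- .bivariatePresmooth(x, y, src, tgt, bivariateDegree)
    srcS <- sm$src; tgtS <- sm$tgt
  } else {
    srcS <- presmoothScoreDistribution(src, presmoothDegree)
    tgtS <- presmoothScoreDistribution(tgt, presmoothDegree)
  }
  if (is.null(bandwidth)) {
    hx <- .selectBandwidth(srcS, bandwidthGrid)
    hy <- .selectBandwidth(tgtS, bandwidthGrid)
  } else {
    bandwidth <- rep(bandwidth, length.out = 2)
    hx <- bandwidth[1]; hy <- bandwidth[2]
  }
  Fh <- .kernelCDF(srcS, hx); Gh <- .kernelCDF(tgtS, hy)
  mT <- .pmfMoments(tgtS)
  lo0 <- min(tgtS@support) - 6 * (hy + 1); hi0 <- max(tgtS@support) + 6 * (hy + 1)
  Ginv <- function(p) {
    vapply(p, function(pp) {
      lo <- lo0; hi <- hi0
      while (Gh$cdf(lo) > pp) lo <- lo - 5
      while (Gh$cdf(hi) < pp) hi <- hi + 5
      stats::uniroot(function(u) Gh$cdf(u) - pp, c(lo, hi),
                     tol = 1e-10)$root
    }, numeric(1))
  }
  fun <- function(xx) Ginv(Fh$cdf(xx))
  .equatingFunction("kernel", fun, src, tgt,
                    metadata = list(bandwidth_source = hx,
                                    bandwidth_target = hy,
                                    a_source = Fh$a, a_target = Gh$a,
                                    bivariate = bivariate,
                                    presmooth_degree = presmoothDegree))
}

## Bivariate log-linear presmoothing of the joint (x, y) score table:
## log mu = polynomial in x + polynomial in y + x:y association term.
.bivariatePresmooth <- function(x, y, src, tgt, degree) {
  grid <- expand.grid(sx = src@support, sy = tgt@support)
  cnt <- table(factor(x, levels = src@support),
               factor(y, levels = tgt@support))
  grid$count <- as.numeric(cnt)
  Xs <- stats::poly(grid$sx, degree = degree[1], raw = TRUE)
  Ys <- stats::poly(grid$sy, degree = degree[2], raw = TRUE)
  fit <- stats::glm(grid$count ~ Xs + Ys + I(grid$sx * grid$sy),
                    family = stats::poisson())
  mu <- stats::fitted(fit)
  joint <- matrix(mu / sum(mu), nrow = length(src@support))
  mk <- function(dist, p) new("ScoreDistribution", support = dist@support,
                              probs = p / sum(p), counts = dist@counts,
                              mean = dist@mean, sd = dist@sd, n = dist@n)
  list(src = mk(src, rowSums(joint)), tgt = mk(tgt, colSums(joint)))
}

#' Apply an equating function to scores
#'
#' Evaluates e(x) and (by default) clamps the result to the target range.
#' Scores beyond the source range are extrapolated by the function's linear
#' continuation and flagged with a warning.
#'
#' @param fn an \linkS4class{EquatingFunction}.
#' @param scores numeric scores on the source scale.
#' @param clamp clamp output to the target range (default TRUE).
#' @return numeric harmonized scores (real-valued; rounding, if wanted, is a
#'   separate post-step).
#' @export
applyEquating <- function(fn, scores, clamp = TRUE) {
  stopifnot(is(fn, "EquatingFunction"))
  outside <- scores < fn@sourceRange[1] | scores > fn@sourceRange[2]
  if (any(outside))
    warning(sprintf("%d score(s) outside the source range [%g, %g]; extrapolated",
                    sum(outside), fn@sourceRange[1], fn@sourceRange[2]),
            call. = FALSE)
  out <- fn@fun(scores)
  if (clamp) out <- pmin(pmax(out, fn@targetRange[1]), fn@targetRange[2])
  out
}

setMethod("show", "EquatingFunction", function(object) {
  cat(sprintf("EquatingFunction (%s): [%g, %g] -> [%g, %g]\n", object@method,
              object@sourceRange[1], object@sourceRange[2],
              object@targetRange[1], object@targetRange[2]))
  if (object@method == "kernel")
    cat(sprintf("  bandwidths: source %.4g, target %.4g\n",
                object@metadata$bandwidth_source,
                object@metadata$bandwidth_target))
})

#' Tabulate a score crosswalk
#'
#' Evaluates the concordance at every integer source score, giving the
#' lookup table practitioners use to convert scores between instruments.
#'
#' @param fn an \linkS4class{EquatingFunction}.
#' @param clamp clamp to the target range.
#' @return data.frame with columns \code{source_score},
#'   \code{harmonized_target_score}, \code{method} and \code{bandwidth}
#'   (NA unless kernel equating).
#' @export
crosswalkTable <- function(fn, clamp = TRUE) {
  xs <- fn@sourceRange[1]:fn@sourceRange[2]
  data.frame(source_score = xs,
             harmonized_target_score = applyEquating(fn, xs, clamp = clamp),
             method = fn@method,
             bandwidth = if (fn@method == "kernel")
               fn@metadata$bandwidth_source else NA_real_)
}

#' Write a crosswalk table to CSV
#' @param fn an \linkS4class{EquatingFunction}.
#' @param path output CSV path.
#' @param clamp clamp to the target range.
#' @return \code{path}, invisibly.
#' @export
writeCrosswalk <- function(fn, path, clamp = TRUE) {
  utils::write.csv(crosswalkTable(fn, clamp = clamp), path, row.names = FALSE)
  invisible(path)
}
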