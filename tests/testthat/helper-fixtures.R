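# shared fixtures: small score samples with exact relative frequencies,
# and an independent percentile-rank inversion oracle for toy distributions

# scores realizing given counts on a contiguous support starting at `from`
scoresFromCounts <- function(counts, from = 0) {
  rep(seq(from, length.out = length(counts)), counts)
}

# independent equipercentile oracle: percentile rank with 0.5-offset
# continuization, inverted on the target distribution (direct transcription
# of the textbook formula, written separately from the package code)
oracleEquipercentile <- function(srcProbs, tgtProbs, x,
                                 srcFrom = 0, tgtFrom = 0) {
  Fs <- cumsum(srcProbs); Ft <- cumsum(tgtProbs)
  xi <- x - srcFrom + 1
  p <- (if (xi > 1) Fs[xi - 1] else 0) + 0.5 * srcProbs[xi]
  ystar <- which(Ft >= p - 1e-12)[1]
  Fprev <- if (ystar > 1) Ft[ystar - 1] else 0
  (ystar - 1 + tgtFrom) - 0.5 + (p - Fprev) / tgtProbs[ystar]
}

# dense-grid posterior-mean oracle for EAP scoring
oracleEAP <- function(pattern, bank, gridN = 2001, lim = 8) {
  th <- seq(-lim, lim, length.out = gridN)
  L <- stats::dnorm(th)
  a <- discrim(bank); b <- thresholds(bank)
  for (i in seq_along(pattern))
    L <- L * gpcmProbs(th, a[[i]], b[[i]])[, pattern[i] + 1]
  sum(th * L) / sum(L)
}

# small deterministic paired dataset builders
tinyDataset <- function(n = 200, seed = 42, scenario = "correlated_traits") {
  makeSyntheticDataset(n = n, scenario = scenario, seed = seed)
}
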