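test_that("score distributions count correctly over the full scale range", {
  d <- scoreDistribution(c(0, 0, 1, 2), range = c(0, 2))
  expect_equal(d@probs, c(0.5, 0.25, 0.25))
  expect_error(scoreDistribution(numeric(0)), "no scores")
  expect_error(scoreDistribution(c(0, 3), range = c(0, 2)), "outside")
  ds <- scoreDistribution(targetSums(tinyDataset(1551, 1)), c(0, 22))
  expect_equal(sum(ds@probs), 1, tolerance = 1e-12)
  expect_length(ds@support, 23)
})

test_that("mean equating shifts by the mean difference with unit slope", {
  s <- scoreDistribution(scoresFromCounts(c(1, 2, 1)), c(0, 10))
  expect_equal(applyEquating(meanEquate(s, s), c(0, 5, 10)), c(0, 5, 10))
  s2 <- scoreDistribution(c(1, 2, 3), c(0, 10))      # mean 2
  t2 <- scoreDistribution(c(4, 5, 6), c(0, 10))      # mean 5
  e <- meanEquate(s2, t2)
  expect_equal(applyEquating(e, 3, clamp = FALSE), 6)
  xs <- 0:9
  expect_equal(diff(applyEquating(e, xs, clamp = FALSE)), rep(1, 9))
})

test_that("linear equating matches its closed form and the moment/symmetry invariants", {
  s <- scoreDistribution(c(1, 3, 5), c(0, 10))       # mean 3, sd 2
  t <- scoreDistribution(c(2, 6, 10), c(0, 22))      # mean 6, sd 4
  e <- linearEquate(s, t)
  expect_equal(applyEquating(e, 5, clamp = FALSE), 10, tolerance = 1e-10)
  # transformed source scores reproduce the target moments exactly
  z <- applyEquating(e, c(1, 3, 5), clamp = FALSE)
  expect_equal(mean(z), 6, tolerance = 1e-10)
  expect_equal(sd(z), 4, tolerance = 1e-10)
  # src -> tgt composed with tgt -> src is the identity
  back <- linearEquate(t, s)
  xs <- seq(0, 10, by = 0.5)
  expect_equal(applyEquating(back, applyEquating(e, xs, clamp = FALSE),
                             clamp = FALSE), xs, tolerance = 1e-10)
  # identical distributions give the identity; equal sds reduce to mean equating
  expect_equal(applyEquating(linearEquate(s, s), xs, clamp = FALSE), xs,
               tolerance = 1e-12)
  t3 <- scoreDistribution(c(3, 5, 7), c(0, 10))      # sd 2 like src, mean 5
  expect_equal(applyEquating(linearEquate(s, t3), xs, clamp = FALSE),
               applyEquating(meanEquate(s, t3), xs, clamp = FALSE),
               tolerance = 1e-12)
  expect_error(linearEquate(scoreDistribution(rep(2, 5), c(0, 4)), t),
               "degenerate")
})

test_that("equipercentile equating matches the hand-computed and brute-force oracles", {
  # the worked toy: src (.5,.3,.2) on 0..2, tgt uniform on 0..4, PR(1)=65
  s <- scoreDistribution(scoresFromCounts(c(5, 3, 2)), c(0, 2))
  t <- scoreDistribution(0:4, c(0, 4))
  e <- equipercentileEquate(s, t)
  expect_equal(applyEquating(e, 1, clamp = FALSE), 2.75, tolerance = 1e-10)
  # self-equating is the identity on positive-frequency support points
  expect_equal(applyEquating(equipercentileEquate(s, s), 0:2, clamp = FALSE),
               as.numeric(0:2), tolerance = 1e-10)
  # random toy distributions against the independent oracle
  set.seed(8)
  for (r in 1:25) {
    ns <- sample(3:5, 1); nt <- sample(3:5, 1)
    cs <- sample(1:9, ns, replace = TRUE); ct <- sample(1:9, nt, replace = TRUE)
    sd1 <- scoreDistribution(scoresFromCounts(cs), c(0, ns - 1))
    td1 <- scoreDistribution(scoresFromCounts(ct), c(0, nt - 1))
    ef <- equipercentileEquate(sd1, td1)
    got <- applyEquating(ef, 0:(ns - 1), clamp = FALSE)
    want <- vapply(0:(ns - 1), function(x)
      oracleEquipercentile(sd1@probs, td1@probs, x), numeric(1))
    expect_equal(got, want, tolerance = 1e-10)
    expect_true(all(diff(got) >= -1e-12))   # monotone over the support
  }
})

test_that("the zero-frequency tie rule lands in the middle of the gap", {
  # PR_src(1) = 0.5 exactly; target cdf is flat at 0.5 across scores 1 and 2
  s <- scoreDistribution(scoresFromCounts(c(1, 3, 1)), c(0, 2))
  t <- scoreDistribution(scoresFromCounts(c(1, 0, 0, 1)), c(0, 3))
  expect_equal(applyEquating(equipercentileEquate(s, t), 1, clamp = FALSE),
               1.5, tolerance = 1e-10)
})

test_that("kernel equating is the identity on itself and centres symmetric pmfs", {
  d <- tinyDataset(500, 2)
  ke <- kernelEquate(sourceSums(d), sourceSums(d), c(0, 10), c(0, 10))
  xs <- 0:10
  expect_lt(max(abs(applyEquating(ke, xs) - xs)), 1e-6)
  expect_true(ke@metadata$bandwidth_source >= 0.05 &&
              ke@metadata$bandwidth_source <= 3)
  # symmetric source around 2 equated to symmetric target around 4:
  # F_h(centre) = 0.5 for any h, so e(2) = 4
  xsym <- scoresFromCounts(c(10, 30, 10)) + 1          # symmetric around 2
  ysym <- scoresFromCounts(c(10, 30, 10)) + 3          # symmetric around 4
  for (h in c(0.2, 0.7, 2)) {
    k2 <- kernelEquate(xsym, ysym, c(0, 6), c(0, 8), bandwidth = h)
    expect_equal(applyEquating(k2, 2, clamp = FALSE), 4, tolerance = 1e-7)
    cw <- crosswalkTable(k2, clamp = FALSE)
    # strictly increasing where the continuized CDF is numerically resolvable
    expect_true(all(diff(cw$harmonized_target_score) > -1e-6))
    expect_true(all(diff(cw$harmonized_target_score[2:5]) > 0))
  }
})

test_that("small-bandwidth kernel equating agrees with equipercentile on the toy pmf", {
  toy <- rep(scoresFromCounts(c(5, 3, 2)), 10)
  ke <- kernelEquate(toy, toy, c(0, 2), c(0, 2), bandwidth = 0.001)
  sd1 <- scoreDistribution(toy, c(0, 2))
  ep <- equipercentileEquate(sd1, sd1)
  expect_lt(max(abs(applyEquating(ke, 0:2, clamp = FALSE) -
                    applyEquating(ep, 0:2, clamp = FALSE))), 0.01)
})

test_that("presmoothing options preserve normalization and the fitted moments", {
  d <- tinyDataset(400, 6)
  ds <- scoreDistribution(targetSums(d), c(0, 22))
  sm <- presmoothScoreDistribution(ds, degree = 2)
  expect_equal(sum(sm@probs), 1, tolerance = 1e-10)
  # Poisson log-linear fit with raw polynomial terms preserves mean and variance
  expect_equal(sum(sm@probs * sm@support), mean(targetSums(d)),
               tolerance = 1e-6)
  expect_equal(sum(sm@probs * sm@support^2), mean(targetSums(d)^2),
               tolerance = 1e-4)
  # bivariate presmoothing still yields a monotone equating function
  kb <- kernelEquate(sourceSums(d), targetSums(d), c(0, 10), c(0, 22),
                     bivariate = TRUE)
  cw <- crosswalkTable(kb, clamp = FALSE)
  expect_true(all(diff(cw$harmonized_target_score) > 0))
  expect_true(kb@metadata$bivariate)
})

test_that("applying an equating function clamps, extrapolates and flags", {
  s <- scoreDistribution(c(1, 3, 5), c(0, 10))
  t <- scoreDistribution(c(2, 6, 10), c(0, 22))
  e <- linearEquate(s, t)                      # e(10) = 20? slope 2: e(10)=20
  expect_equal(suppressWarnings(applyEquating(e, 12, clamp = FALSE)), 24,
               tolerance = 1e-10)
  expect_warning(out <- applyEquating(e, 12), "outside the source range")
  expect_equal(out, 22)                        # clamped to the target range
  shift <- meanEquate(scoreDistribution(c(0, 1, 2), c(0, 10)),
                      scoreDistribution(c(3, 4, 5), c(0, 22)))
  expect_equal(applyEquating(shift, c(0, 1, 2)), c(3, 4, 5))
  # crosswalk export round-trip
  path <- tempfile(fileext = ".csv")
  writeCrosswalk(e, path)
  cw <- read.csv(path)
  expect_identical(names(cw), c("source_score", "harmonized_target_score",
                                "method", "bandwidth"))
  expect_equal(nrow(cw), 11)
})
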