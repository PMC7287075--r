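# VAC machinery: spike-count binning, GP smoothing, Welch partial
# eta-squared, and the JR-vs-SD comparison.

test_that("binned counts conserve the in-window spikes", {
  tr <- quickSession(1, seed = 71)[1:30, ]
  set.seed(72)
  spk <- sort(runif(2000, 0, max(tr$tEnd)))
  w <- epochWindow("stimulus_onset", -250, 0)
  cnt <- binCounts(spk, tr, w)
  expect_equal(ncol(cnt), 25)
  want <- vapply(seq_len(nrow(tr)), function(i)
    sum(spk >= tr$stimOn[i] - 0.25 & spk < tr$stimOn[i]), numeric(1))
  expect_equal(rowSums(cnt), want)
  # no spikes -> all zero; one spike -> exactly one nonzero bin
  expect_true(all(binCounts(numeric(0), tr, w) == 0))
  one <- binCounts(tr$stimOn[3] - 0.112, tr, w)
  expect_equal(sum(one), 1)
  expect_equal(sum(one != 0), 1)
})

test_that("GP smoothing leaves constant data flat and recovers planted level means", {
  set.seed(73)
  covar <- data.frame(trial = 1:80, jr = rep(3:12, 8), sd = rep(1:4, 20))
  flat <- matrix(4L, 80, 10)
  attr(flat, "binCentersMs") <- seq(5, 95, by = 10)
  smf <- gprSmooth(flat, covar)
  expect_lt(diff(range(smf$rate)) / mean(smf$rate), 0.01)
  # noiseless additive JR effect: per-level means within 5%
  lam <- 3 + (covar$jr - 3) * 0.8
  cnt <- matrix(rep(round(lam), 10), 80, 10)
  attr(cnt, "binCentersMs") <- seq(5, 95, by = 10)
  sm <- gprSmooth(cnt, covar)
  est <- tapply(rowMeans(sm$rate), covar$jr, mean)
  want <- tapply(round(lam) * 100, covar$jr, mean)   # 10-ms bins -> sp/s
  expect_equal(as.numeric(est), as.numeric(want),
               tolerance = 0.05 * mean(want))
  # posterior SD collapses for noiseless data relative to noisy data
  noisy <- matrix(rpois(800, rep(lam, 10)), 80, 10)
  attr(noisy, "binCentersMs") <- seq(5, 95, by = 10)
  smn <- gprSmooth(noisy, covar)
  expect_lt(mean(sm$sd), 0.3 * mean(smn$sd))
  expect_error(gprSmooth(cnt, transform(covar, sd = 1)), "2 levels")
})

test_that("partial eta-squared follows the F/df formula", {
  expect_equal(partialEta2FromF(1, 1, 10), 1 / 11)
  expect_equal(partialEta2FromF(0, 5, 50), 0)
  set.seed(74)
  x <- rnorm(60); g <- rep(1:3, 20)
  w <- welchPartialEta2(x, g)
  expect_equal(w$etaP2, w$F * w$df1 / (w$F * w$df1 + w$df2))
  expect_gte(w$etaP2, 0); expect_lte(w$etaP2, 1)
})

test_that("Welch F agrees with the hand-coded oracle to 1e-10", {
  set.seed(75)
  for (i in 1:1000) {
    k <- sample(2:5, 1)
    g <- rep(seq_len(k), times = sample(3:12, k, replace = TRUE))
    x <- rnorm(length(g), mean = g * runif(1), sd = runif(1, 0.5, 2))
    got <- welchPartialEta2(x, g)
    want <- welchOracle(x, g)
    expect_equal(got$F, want$F, tolerance = 1e-10)
    expect_equal(got$df1, want$df1, tolerance = 1e-10)
    expect_equal(got$df2, want$df2, tolerance = 1e-10)
  }
})

test_that("two-group Welch F equals the squared Welch t", {
  set.seed(76)
  x <- c(rnorm(20, 0, 1), rnorm(15, 1, 3))
  g <- rep(1:2, c(20, 15))
  expect_equal(welchPartialEta2(x, g)$F,
               unname(t.test(x[g == 1], x[g == 2])$statistic)^2)
})

test_that("eta-squared is invariant to affine rescaling of all rates", {
  set.seed(77)
  v <- rnorm(60, 10); b <- rnorm(60, 2); g <- rep(1:4, 15)
  a1 <- welchPartialEta2(v, g, baseline = b)
  a2 <- welchPartialEta2(5 * v + 3, g, baseline = 5 * b + 3)
  expect_equal(a1$etaP2, a2$etaP2, tolerance = 1e-12)
})

test_that("degenerate groupings produce named errors", {
  expect_error(welchPartialEta2(rnorm(10), rep(1, 10)), "2 group levels")
  expect_error(welchPartialEta2(c(rnorm(9), 1), c(rep(1, 9), 2)),
               "fewer than 2")
  expect_error(welchPartialEta2(c(rnorm(9), 1, 1), c(rep(1, 9), 2, 2)),
               "zero variance")
})

test_that("identical group means give near-zero VAC", {
  set.seed(78)
  w <- welchPartialEta2(rnorm(300), rep(1:3, 100))
  expect_lt(w$etaP2, 0.05)
})

test_that("planted JR-dominant tuning yields VAC(JR) > VAC(SD) in all epochs", {
  tr <- quickSession(5, seed = 81)
  jw <- seq(-0.5, 0.5, length.out = 11)
  vacs <- lapply(1:6, function(u) {
    p <- neuronParams(clusterId = ((u - 1) %% 3) + 1, jrWeights = jw,
                      baselineHz = 4, amplitudeHz = 40)
    spk <- simulateUnit(p, tr, seed = 90 + u)
    computeVac(spk, tr)
  })
  for (ep in c("visual", "presaccadic", "postsaccadic")) {
    jr <- vapply(vacs, function(v)
      v$etaP2[v$epoch == ep & v$variable == "jr"], numeric(1))
    sd_ <- vapply(vacs, function(v)
      v$etaP2[v$epoch == ep & v$variable == "sd"], numeric(1))
    expect_gt(mean(jr), mean(sd_))
  }
  # the JR-vs-SD scatter summary sees the same dominance
  vj <- vapply(vacs, function(v)
    mean(v$etaP2[v$variable == "jr"]), numeric(1))
  vs <- vapply(vacs, function(v)
    mean(v$etaP2[v$variable == "sd"]), numeric(1))
  sc <- vacScatter(vj, vs)
  expect_gt(sc$nJrGreater, sc$nSdGreater)
})

test_that("VAC scatter statistics behave on trivial and null inputs", {
  expect_equal(vacScatter(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3))$rs, 1)
  set.seed(82)
  sc <- vacScatter(runif(300), runif(300))
  expect_lt(abs(sc$rs), 0.15)
})
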