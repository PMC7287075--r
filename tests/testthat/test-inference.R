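# Resampling machinery and unit-level hypothesis tests.

test_that("bootstrap distributions are deterministic, degenerate when apt, calibrated", {
  const <- bootstrapDistribution(rep(3, 20), mean, n = 200, seed = 1)
  expect_equal(const$ci, c(3, 3))
  single <- bootstrapDistribution(5, mean, n = 50, seed = 2)
  expect_true(all(single$dist == 5))
  set.seed(10); x <- rnorm(30)
  expect_identical(bootstrapDistribution(x, mean, n = 100, seed = 4)$dist,
                   bootstrapDistribution(x, mean, n = 100, seed = 4)$dist)
  # CI coverage of the true mean ~ 95%
  set.seed(11)
  cover <- mean(vapply(1:300, function(i) {
    x <- rnorm(40, 2)
    ci <- bootstrapDistribution(x, mean, n = 300)$ci
    ci[1] <= 2 && 2 <= ci[2]
  }, logical(1)))
  expect_gt(cover, 0.88); expect_lt(cover, 0.99)
})

test_that("shuffle test p-values are exact at the floor and uniform under the null", {
  stat <- function(lab, resp) abs(cor(lab, resp))
  res <- shuffleTest(rep(1:4, 10), rep(1:4, 10), stat, nPerm = 99, seed = 5)
  expect_equal(res$p, 1 / 100)
  expect_length(res$null, 99)
  expect_error(shuffleTest(rep(1, 10), rnorm(10), stat), "2 label levels")
  # null calibration: rejection at alpha = 0.05 close to 0.05
  set.seed(6)
  rej <- mean(vapply(1:200, function(i) {
    lab <- rep(1:2, 15)
    shuffleTest(lab, rnorm(30), stat, nPerm = 99)$p <= 0.05
  }, logical(1)))
  expect_gt(rej, 0.01); expect_lt(rej, 0.10)
})

test_that("label multiset is preserved within each permutation", {
  lab <- c(1, 1, 1, 2, 3, 3)
  seen <- shuffleTest(lab, rnorm(6),
                      function(l, r) { expect_equal(sort(l), sort(lab)); 0 },
                      nPerm = 20, seed = 7)
  expect_s3_class(seen, "ShuffleResult")
})

test_that("best/worst test finds no identity coding in unstructured responses", {
  set.seed(8)
  ud <- lapply(1:40, function(u)
    list(z = rnorm(70), stim = rep(1:7, 10)))
  res <- bestWorstIdentityTest(ud, nShuffle = 10, seed = 9)
  expect_lt(abs(res$test$meanObs - res$test$meanShuf), 0.15)
  expect_gt(res$test$p, 0.01)
})

test_that("transient rank tuning is detected during learning and not after", {
  tr <- quickSession(10, seed = 91)
  ch <- choiceTrials(tr)
  w <- epochWindow("stimulus_onset", 40, 150)
  units <- lapply(1:14, function(u) {
    p <- neuronParams(clusterId = ((u - 1) %% 2) + 1, rankGainMax = 0.8,
                      baselineHz = 4, amplitudeHz = 45)
    spk <- simulateUnit(p, tr, seed = 92 + u)
    z <- zscoreRates(epochSpikeRate(spk, ch, w))$z
    list(z = z, stim = ch$stimRF, trial = ch$choiceTrial)
  })
  early <- lapply(units, function(u)
    list(z = u$z[u$trial <= 250], stim = u$stim[u$trial <= 250]))
  late <- lapply(units, function(u)
    list(z = u$z[u$trial > 250], stim = u$stim[u$trial > 250]))
  resE <- bestWorstIdentityTest(early, nShuffle = 20, seed = 93)
  resL <- bestWorstIdentityTest(late, nShuffle = 20, seed = 94)
  expect_lt(resE$test$p, 0.01)
  expect_gt(resE$test$meanObs, resE$test$meanShuf)
  expect_gt(resL$test$p, 0.05)
})

test_that("outcome tests calibrate to alpha on exchangeable counts", {
  set.seed(12)
  outcomes <- rep(c(TRUE, FALSE), 30)
  units <- lapply(1:400, function(u) matrix(rpois(60, 5), 60, 1))
  res <- outcomeEffectTests(units, outcomes, epochNames = "visual")
  expect_gt(res$summary$fracSignificant, 0.01)
  expect_lt(res$summary$fracSignificant, 0.09)
  # planted 3-SD shift: near-certain rejection
  shift <- lapply(1:50, function(u)
    matrix(c(rnorm(30, 10), rnorm(30, 10 + 3 * 1)), 60, 1))
  resS <- outcomeEffectTests(shift, c(rep(TRUE, 30), rep(FALSE, 30)),
                             epochNames = "visual")
  expect_gt(resS$summary$fracSignificant, 0.9)
  expect_error(outcomeEffectTests(units[1:2], rep(TRUE, 60)),
               "both outcomes")
})

test_that("Kruskal-Wallis panel attributes effects to the right factor", {
  tr <- quickSession(3, seed = 95)
  w <- epochWindow("stimulus_onset", 40, 150)
  counts <- lapply(1:10, function(u) {
    p <- neuronParams(clusterId = 1, baselineHz = 3, amplitudeHz = 40)
    spk <- simulateUnit(p, tr, seed = 96 + u)
    epochSpikeRate(spk, tr, w) * 0.11   # counts in the 110 ms window
  })
  fac <- data.frame(
    targetLoc = ifelse(tr$phase == 1L,
                       ifelse(is.na(tr$stimRF), "out", "in"), NA),
    saccadeDir = ifelse(tr$phase == 2L, tr$chosenLoc, NA),
    outcome = ifelse(tr$phase == 2L, tr$rewarded, NA))
  res <- kruskalEffectPanel(counts, fac)
  s <- res$summary
  expect_equal(s$fracSignificant[s$factor == "targetLoc"], 1)
  # spatial gain only: location dominates outcome
  expect_gt(s$fracSignificant[s$factor == "targetLoc"],
            s$fracSignificant[s$factor == "outcome"])
  # single-level factor skipped
  one <- kruskalEffectPanel(counts[[1]],
                            data.frame(all = rep(1, nrow(tr)),
                                       dir = tr$chosenLoc))
  expect_false("all" %in% one$table$factor)
  # all-null factors reject at ~alpha
  set.seed(13)
  nullRes <- kruskalEffectPanel(
    lapply(1:300, function(u) rpois(40, 6)),
    data.frame(f = rep(1:2, 20)))
  expect_lt(nullRes$summary$fracSignificant, 0.09)
})

test_that("prior-reward firing effects are null for outcome-blind units and recover planted gains", {
  set.seed(14)
  n <- 1600
  rew <- runif(n) < 0.7
  toward <- runif(n) < 0.5
  base <- rnorm(n, 20, 3)
  r0 <- priorRewardNeuralTest(base, rew, toward)
  expect_lt(max(abs(r0$meanDiff)), 0.8)
  expect_gt(min(r0$p), 0.01)
  g <- 4
  hist <- base + g * c(FALSE, rew[-n])
  r1 <- priorRewardNeuralTest(hist, rew, toward)
  expect_equal(r1$meanDiff, rep(g, 2), tolerance = 1.2)
  # first trial has no predecessor
  expect_equal(sum(r1$nAfterReward + r1$nAfterNoReward), n - 1)
})
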