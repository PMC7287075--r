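# Population analyses: profile clustering, preferred-condition sorting,
# OLE decoding and its bootstrap.

makeProfiles <- function(nPerFamily, families = 1:2, noise = 0.05,
                         seed = 1) {
  set.seed(seed)
  tg <- seq(-0.25, 1, by = 0.01)
  tm <- serialTI:::responseTemplates()
  do.call(rbind, lapply(families, function(f) {
    base <- tm[[f]](tg, tg - 0.23)
    t(replicate(nPerFamily, base + rnorm(length(tg), 0, noise)))
  }))
}

test_that("identical profiles collapse to one cluster", {
  prof <- matrix(rep(sin(seq(0, 6, length.out = 80)), 5), 5, byrow = TRUE)
  cl <- clusterProfiles(prof)
  expect_equal(cl$nClusters, 1)
})

test_that("two well-separated families are recovered exactly", {
  prof <- makeProfiles(20, families = c(1, 4))
  truth <- rep(1:2, each = 20)
  cl <- clusterProfiles(prof)
  expect_equal(cl$nClusters, 2)
  expect_equal(adjustedRand(cl$labels, truth), 1)
})

test_that("clustering is invariant to per-unit affine rescaling", {
  prof <- makeProfiles(10, families = c(2, 3), seed = 2)
  scaled <- prof * runif(nrow(prof), 0.5, 5) + rnorm(nrow(prof))
  a <- clusterProfiles(prof); b <- clusterProfiles(scaled)
  expect_equal(adjustedRand(a$labels, b$labels), 1)
})

test_that("constant profiles are excluded with a notice", {
  prof <- makeProfiles(5, families = 1, seed = 3)
  prof <- rbind(prof, rep(2, ncol(prof)))
  expect_message(cl <- clusterProfiles(prof), "excluded")
  expect_equal(cl$excluded, 6L)
  expect_length(cl$labels, 5)
  expect_error(clusterProfiles(prof, cutoffR = 1.2), "cutoffR")
})

test_that("preferred-condition sort recovers planted argmax levels stably", {
  set.seed(5)
  planted <- c(3, 1, 4, 1, 2)
  z <- t(sapply(planted, function(k) {
    v <- rep(0, 5); v[k] <- 2; v
  }))
  ps <- preferredConditionSort(z)
  expect_equal(unname(ps$preferred), planted)
  expect_equal(ps$order, order(planted, seq_along(planted)))
  expect_equal(preferredConditionSort(z[1, , drop = FALSE])$order, 1L)
  expect_error(preferredConditionSort(rbind(c(1, NA))), "every level")
})

test_that("OLE attains zero training error on noiseless linear targets", {
  set.seed(6)
  X <- matrix(rnorm(200 * 6), 200, 6)
  w <- rnorm(6)
  y <- drop(X %*% w) + 2
  m <- oleFit(X, y)
  expect_lt(max(abs(olePredict(m, X) - y)), 1e-8)
  # constant target: intercept-only
  mc <- oleFit(X, rep(4, 200))
  expect_equal(mc@weights, rep(0, 6))
  expect_equal(olePredict(mc, X), rep(4, 200))
  # rank-deficient design: minimum-norm with warning
  Xd <- cbind(X[, 1], X[, 1], X[, 2])
  expect_warning(md <- oleFit(Xd, X[, 1] + X[, 2]), "rank-deficient")
  expect_true(all(is.finite(md@weights)))
  expect_lt(max(abs(olePredict(md, Xd) - (X[, 1] + X[, 2]))), 1e-8)
})

test_that("OLE predictions absorb constant shifts of a unit's rates", {
  set.seed(7)
  X <- matrix(rnorm(150 * 4), 150, 4)
  y <- drop(X %*% c(1, -2, 0.5, 1)) + rnorm(150, 0, 0.1)
  Xs <- X; Xs[, 2] <- Xs[, 2] + 7
  expect_equal(olePredict(oleFit(X, y), X), olePredict(oleFit(Xs, y), Xs),
               tolerance = 1e-8)
})

test_that("population decoding beats the trivial predictor on held-out trials", {
  tr <- quickSession(6, seed = 61)
  ch <- choiceTrials(tr)
  pars <- samplePopulationParams(10, seed = 62, jrScale = 0.4, sdScale = 0.05)
  pop <- simulatePopulation(pars, tr, seed = 63)
  w <- epochWindow("stimulus_onset", 40, endEvent = "saccade_onset")
  X <- sapply(seq_len(nUnits(pop)), function(u)
    zscoreRates(epochSpikeRate(spikeTimes(pop, u), ch, w))$z)
  train <- seq_len(nrow(ch)) %% 2 == 0
  m <- oleFit(X[train, ], ch$jr[train])
  mseHeld <- mean((olePredict(m, X[!train, ]) - ch$jr[!train])^2)
  expect_lt(mseHeld, var(ch$jr[!train]))
})

test_that("bootstrap CIs are degenerate without noise and shrink with n", {
  X <- matrix(rep(c(1, 2, 3), each = 30), ncol = 1)
  y <- drop(X) * 2
  dec <- oleDecodeBootstrap(X, y, nBoot = 50, seed = 1)
  expect_lt(max(dec$hi - dec$lo), 1e-8)
  expect_equal(dec$estimate, c(2, 4, 6))
  # width ~ 1/sqrt(trials)
  set.seed(2)
  mk <- function(n) {
    yy <- rep(1:3, length.out = n)
    XX <- cbind(yy + rnorm(n), rnorm(n))
    d <- oleDecodeBootstrap(XX, yy, nBoot = 200, seed = 3)
    mean(d$hi - d$lo)
  }
  ratio <- mk(60) / mk(960)
  expect_gt(ratio, 2)
  expect_lt(ratio, 8)
})
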