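# Behavioral generator: choice-accuracy model, learning curve shape,
# spatial win-stay/lose-shift bias, latencies.

test_that("choice accuracy starts at chance and grows with trial and distance", {
  p <- agentParams()
  expect_equal(choiceAccuracy(6, TRUE, 1, p), 0.5, tolerance = 0.02)
  off <- agentParams(bSdMax = 0, bTerm = 0)
  expect_equal(choiceAccuracy(1:6, FALSE, 500, off), rep(0.5, 6))
  expect_gt(choiceAccuracy(6, FALSE, 250, p), choiceAccuracy(1, FALSE, 250, p))
  # monotone in t and in SD
  grid <- choiceAccuracy(rep(1:6, each = 4), FALSE,
                         rep(c(1, 50, 250, 800), 6), p)
  m <- matrix(grid, nrow = 4)
  expect_true(all(diff(t(m)) >= 0))   # over t within each SD
  expect_true(all(apply(m, 1, diff) >= 0))  # over SD at each t
  expect_error(choiceAccuracy(1, FALSE, 0, p), "t must be")
})

test_that("naive agent performs at chance over an all-pairs block", {
  accs <- vapply(1:20, function(s) {
    tr <- quickSession(1, naiveAgentParams(), seed = 100 + s)
    mean(choiceTrials(tr)$correct)
  }, numeric(1))
  se <- sqrt(0.25 / (20 * 42))
  expect_lt(abs(mean(accs) - 0.5), 3 * se)
})

test_that("default agent learns: chance early, above 0.70 after trial 300", {
  accs <- sapply(1:8, function(s) {
    ch <- choiceTrials(quickSession(20, seed = 300 + s))
    ma <- movingAccuracy(ch$correct)
    c(first = ma$accuracy[13], late = mean(ch$correct[ch$choiceTrial > 300]))
  })
  expect_lt(abs(mean(accs["first", ]) - 0.5), 0.08)
  expect_gt(mean(accs["late", ]), 0.70)
  # accuracy ordering by SD is monotone late in learning (mean over seeds)
  bySd <- rowMeans(sapply(1:8, function(s) {
    ch <- choiceTrials(quickSession(20, seed = 300 + s))
    late <- ch[ch$choiceTrial > 400, ]
    tapply(late$correct, late$sd, mean)
  }))
  expect_true(all(diff(bySd) > -0.02))
  expect_gt(bySd[6], bySd[1])
})

test_that("extreme stay parameters force location repetition", {
  p <- agentParams(pWinstay = 1, pLoseshiftStay = 1)
  ch <- choiceTrials(quickSession(2, p, seed = 7))
  expect_true(all(ch$chosenLoc[-1] == ch$chosenLoc[-nrow(ch)]))
})

test_that("default spatial bias is recovered by direct counting", {
  sess <- lapply(1:30, function(s) quickSession(20, seed = 1000 + s))
  ws <- winstayLoseshift(sess)
  expect_equal(unname(ws$summary["afterReward", "mean"]), 0.56,
               tolerance = 0.025)
  expect_equal(unname(ws$summary["afterNoReward", "mean"]), 0.48,
               tolerance = 0.025)
  expect_lt(ws$summary["afterReward", "p"], 0.001)
})

test_that("equal stay parameters leave no lag-1 location autocorrelation", {
  p <- agentParams(pWinstay = 0.5, pLoseshiftStay = 0.5)
  locs <- unlist(lapply(1:3, function(s)
    choiceTrials(quickSession(20, p, seed = 50 + s))$chosenLoc))
  n <- length(locs)
  expect_lt(abs(cor(locs[-1], locs[-n])), 3 / sqrt(n))
})

test_that("item-level choices carry no reward-history mechanism", {
  # stationary agent (no learning drift): conditional probabilities equal
  flat <- agentParams(bSdMax = 0, bTerm = 0)
  sess <- lapply(1:25, function(s) quickSession(10, flat, seed = 2000 + s))
  ih <- itemRewardHistory(sess)
  expect_lt(abs(ih$choiceTest$diff), 0.025)
  expect_gt(ih$choiceTest$p, 0.01)
  # default agent: only the small learning-trend artifact remains, with
  # rewarded choices slightly *less* likely to be repeated, never more
  sessL <- lapply(1:25, function(s) quickSession(10, seed = 2100 + s))
  ihL <- itemRewardHistory(sessL)
  expect_lt(ihL$choiceTest$diff, 0.02)
  expect_gt(ihL$choiceTest$diff, -0.08)
})

test_that("latencies are truncated to the response deadline with the set SD shift", {
  ch <- do.call(rbind, lapply(1:10, function(s)
    choiceTrials(quickSession(20, seed = 600 + s))))
  expect_true(all(ch$latencyMs > 0 & ch$latencyMs <= 1500))
  expect_equal(mean(ch$latencyMs[ch$sd == 1]) - mean(ch$latencyMs[ch$sd == 6]),
               1.4 * 5, tolerance = 2)
  # rewarded coincides with correct on choice trials
  expect_identical(ch$rewarded, ch$correct)
})
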