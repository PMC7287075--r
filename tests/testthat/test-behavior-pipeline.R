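# Behavioral analyses: moving accuracy, accuracy-at-trial estimates,
# SD-performance correlation, RT by SD, win-stay, item reward history.

test_that("moving accuracy matches a brute-force windowed mean", {
  expect_true(all(movingAccuracy(rep(TRUE, 60))$accuracy == 1))
  alt <- rep(c(TRUE, FALSE), 30)
  ma <- movingAccuracy(alt)$accuracy[13:48]    # full central windows
  expect_true(all(abs(abs(ma - 0.5) - 0.02) < 1e-9))  # 13/25 or 12/25
  set.seed(21)
  x <- runif(200) < 0.7
  got <- movingAccuracy(x)$accuracy
  want <- vapply(1:200, function(i)
    mean(x[max(1, i - 12):min(200, i + 12)]), numeric(1))
  expect_equal(got, want)
  expect_error(movingAccuracy(c(TRUE, FALSE)), "fewer trials")
  expect_message(movingAccuracy(x, groupBy = c(rep(1, 190), rep(2, 10))),
                 "omitted")
})

test_that("accuracy-at-trial is calibrated on stationary data and ordered by learning", {
  tr <- quickSession(10, naiveAgentParams(), seed = 23)
  # window method: per-pair binomial noise at ~10 trials/pair
  estW <- accuracyAtTrial(tr, 250, method = "window")
  expect_equal(nrow(estW), 21)
  expect_lt(mean(abs(estW$accuracy - 0.5)), 0.15)
  # GP smoothing pools across pairs and trials: much tighter
  estG <- accuracyAtTrial(tr, 250, method = "gpr")
  expect_equal(nrow(estG), 21)
  expect_lt(max(abs(estG$accuracy - 0.5)), 0.15)
  # default (learning) agent: estimate at 500 >= at 250 for every SD,
  # averaged over seeds, and the two methods agree on smooth curves
  diffs <- rowMeans(sapply(1:5, function(s) {
    tr <- quickSession(15, seed = 400 + s)
    a250 <- accuracyAtTrial(tr, 250, method = "gpr")
    a500 <- accuracyAtTrial(tr, 500, method = "gpr")
    tapply(a500$accuracy - a250$accuracy, a250$sd, mean)
  }))
  expect_true(all(diffs > -0.03))
  tr <- quickSession(15, seed = 25)
  aw <- accuracyAtTrial(tr, 400, method = "window")
  ag <- accuracyAtTrial(tr, 400, method = "gpr")
  expect_lt(mean(abs(aw$accuracy - ag$accuracy)), 0.1)
  expect_error(accuracyAtTrial(tr, 10000), "beyond")
})

test_that("SD-performance correlation behaves on exact, degenerate and simulated data", {
  expect_equal(sdPerformanceCorrelation(1:6 / 10, 1:6)$r, 1)
  expect_error(sdPerformanceCorrelation(rep(0.7, 6), 1:6), "constant")
  obs <- do.call(rbind, lapply(1:20, function(s) {
    ch <- choiceTrials(quickSession(10, seed = 500 + s))
    late <- ch[ch$choiceTrial > 150, ]
    data.frame(sd = 1:6,
               acc = as.numeric(tapply(late$correct, late$sd, mean)))
  }))
  r <- sdPerformanceCorrelation(obs$acc, obs$sd)
  expect_gt(r$r, 0.3)
  expect_lt(r$p, 0.001)
  expect_equal(r$r2, r$r^2)
})

test_that("RT-by-SD recovers planted mean offsets and the generator's ~7 ms range", {
  set.seed(26)
  sd_ <- rep(1:6, each = 500)
  lat <- rnorm(3000, 240 - 2 * sd_, 5)
  r <- rtBySd(lat, sd_)
  expect_equal(r$rangeMs, 10, tolerance = 1)
  expect_lt(r$p, 1e-10)
  # identical distributions: tiny range, p not extreme
  r0 <- rtBySd(rnorm(1200, 230, 30), rep(1:6, 200))
  expect_lt(r0$rangeMs, 8)
  # generator closed loop (scaled down from the full-data version)
  ch <- do.call(rbind, lapply(1:25, function(s)
    choiceTrials(quickSession(20, seed = 700 + s))))
  rg <- rtBySd(ch$latencyMs, ch$sd)
  expect_equal(rg$rangeMs, 7, tolerance = 2.5)
  expect_lt(rg$p, 1e-4)
})

test_that("win-stay proportions match direct pattern counts", {
  alt <- data.frame(phase = 2L, chosenLoc = rep(c(1L, -1L), 30),
                    rewarded = rep(c(TRUE, FALSE), 30))
  ws <- winstayLoseshift(alt)
  expect_equal(unname(unlist(ws$perSession)), c(0, 0))
  coin <- lapply(1:10, function(s)
    choiceTrials(quickSession(10, naiveAgentParams(), seed = 800 + s)))
  wc <- winstayLoseshift(coin)
  expect_equal(unname(wc$summary[, "mean"]), c(0.5, 0.5), tolerance = 0.04)
})

test_that("item reward history recovers planted stickiness and flags empty tables", {
  # planted conditional choice probabilities by construction
  set.seed(27)
  mk <- function() {
    n <- 600
    pair <- t(replicate(n, sample(1:7, 2)))
    tr <- data.frame(phase = rep(2L, n),
                     stimRF = pmin(pair[, 1], pair[, 2]),
                     stimOpp = pmax(pair[, 1], pair[, 2]),
                     chosenRank = NA_integer_, rewarded = NA,
                     latencyMs = 250)
    last <- rep(NA, 7)
    for (i in 1:n) {
      it <- c(tr$stimRF[i], tr$stimOpp[i])
      # choose item 4 with prob .6 after its rewarded choice, .4 after
      # unrewarded, .5 otherwise; others uniform
      p <- 0.5
      if (4 %in% it && !is.na(last[4])) p <- if (last[4]) 0.6 else 0.4
      pick <- if (4 %in% it) {
        if (runif(1) < p) 4 else setdiff(it, 4)
      } else sample(it, 1)
      tr$chosenRank[i] <- pick
      tr$rewarded[i] <- runif(1) < 0.5
      last[pick] <- tr$rewarded[i]
    }
    tr
  }
  sess <- replicate(8, mk(), simplify = FALSE)
  ih <- itemRewardHistory(sess, items = 4)
  expect_lt(abs(ih$choiceTest$diff - 0.2), 0.06)
  expect_lt(ih$choiceTest$p, 0.01)
  # all-A-choices session: non-terminal items never chosen -> no cells
  degenerate <- data.frame(phase = 2L, stimRF = 1L, stimOpp = 5L,
                           chosenRank = 1L, rewarded = TRUE, latencyMs = 250)
  degenerate <- degenerate[rep(1, 50), ]
  expect_error(itemRewardHistory(degenerate), "no item-history cells")
})
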