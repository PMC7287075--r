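# Shared fixtures: all built in code at test time.

# small simulated session (5 single blocks + nPairBlocks all-pairs blocks)
quickSession <- function(nPairBlocks = 2, agent = agentParams(), seed = 42,
                         nItems = 7) {
  sch <- buildSessionSchedule(stimulusList(nItems), nPairBlocks, seed = seed)
  simulateSession(sch, agent, seed = seed + 1L)
}

choiceTrials <- function(trials) trials[trials$phase == 2L, , drop = FALSE]

# adjusted Rand index between two labelings (closed form on the
# contingency table), used as the clustering-recovery score
adjustedRand <- function(a, b) {
  tab <- table(a, b)
  sumij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  exp_ <- ai * bj / n2
  (sumij - exp_) / ((ai + bj) / 2 - exp_)
}

# independent Welch one-way F oracle, straight from the formula
welchOracle <- function(values, groups) {
  g <- split(values, groups)
  ni <- lengths(g)
  mi <- vapply(g, mean, numeric(1))
  vi <- vapply(g, var, numeric(1))
  wi <- ni / vi
  k <- length(g)
  mw <- sum(wi * mi) / sum(wi)
  A <- sum(wi * (mi - mw)^2) / (k - 1)
  lam <- sum((1 - wi / sum(wi))^2 / (ni - 1)) / (k^2 - 1)
  list(F = A / (1 + 2 * lam * (k - 2)),
       df1 = k - 1, df2 = 1 / (3 * lam))
}

# one-row trial record with fixed timing, for rate-function tests
fakeTrial <- function(phase = 2L, stimRF = 2L, stimOpp = 5L, jr = 7L,
                      sd = 3L, choiceTrial = 300L, latency = 0.23,
                      rewarded = TRUE) {
  data.frame(phase = phase, stimRF = stimRF, stimOpp = stimOpp, jr = jr,
             sd = sd, choiceTrial = choiceTrial, tStart = 0, stimOn = 1,
             saccOn = 1 + latency, feedback = 1 + latency + 0.5,
             rewarded = rewarded, tEnd = 3)
}
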