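## Generative model of choice behavior: logistic symbolic-distance learning
## with a terminal-item bonus, a lag-1 spatial win-stay/lose-shift bias, and
## truncated-normal saccade latencies with a weak inverse SD dependence.

#' @rdname agentParams
#' @export
setClass("AgentParams",
  representation(b0 = "numeric", bSdMax = "numeric", tauLearn = "numeric",
                 bTerm = "numeric", pWinstay = "numeric",
                 pLoseshiftStay = "numeric", rtMu = "numeric",
                 rtSigma = "numeric", rtSdSlope = "numeric",
                 rtMuSingle = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@pWinstay < 0 || object@pWinstay > 1 ||
        object@pLoseshiftStay < 0 || object@pLoseshiftStay > 1)
      msg <- c(msg, "stay probabilities must lie in [0, 1]")
    if (object@rtSigma <= 0) msg <- c(msg, "rtSigma must be > 0")
    if (object@tauLearn <= 0) msg <- c(msg, "tauLearn must be > 0")
    if (length(msg)) msg else TRUE
  })

#' Behavioral agent parameters
#'
#' Parameters of the generative choice model. Accuracy follows a logistic
#' model whose symbolic-distance slope ramps up with a learning time constant
#' of `tauLearn` trials, so that performance rises from chance (0.5) to a
#' plateau around 0.75 within roughly 250-300 choice trials. A terminal-item
#' bonus raises accuracy for pairs containing the first or last list item.
#' After each choice a lag-1 spatial bias is applied: the previously chosen
#' location is repeated with probability `pWinstay` after a rewarded trial
#' (default 0.56) and `pLoseshiftStay` after an unrewarded one (default 0.48).
#' Saccade latencies are truncated normal with mean `rtMu - rtSdSlope * SD`
#' ms and SD `rtSigma` ms; the default slope of 1.4 ms per rank of symbolic
#' distance gives a ~7 ms range of mean latency across SD 1..6.
#'
#' @param b0 baseline log-odds of a correct choice (default 0 = chance).
#' @param bSdMax asymptotic symbolic-distance slope in log-odds per rank.
#' @param tauLearn learning time constant, in choice trials.
#' @param bTerm terminal-item bonus, log-odds.
#' @param pWinstay probability of repeating a rewarded location.
#' @param pLoseshiftStay probability of repeating an unrewarded location.
#' @param rtMu,rtSigma choice-latency mean and SD, ms.
#' @param rtSdSlope decrease in mean latency per unit symbolic distance, ms.
#' @param rtMuSingle mean latency for single-target trials, ms.
#' @return An `AgentParams` object.
#' @export
agentParams <- function(b0 = 0, bSdMax = 0.45, tauLearn = 100, bTerm = 0.45,
                        pWinstay = 0.56, pLoseshiftStay = 0.48,
                        rtMu = 232, rtSigma = 31, rtSdSlope = 1.4,
                        rtMuSingle = 150) {
  new("AgentParams", b0 = b0, bSdMax = bSdMax, tauLearn = tauLearn,
      bTerm = bTerm, pWinstay = pWinstay, pLoseshiftStay = pLoseshiftStay,
      rtMu = rtMu, rtSigma = rtSigma, rtSdSlope = rtSdSlope,
      rtMuSingle = rtMuSingle)
}

#' A "naive" agent with all learning and bias effects switched off
#' @return An `AgentParams` whose choices are uniform between the two
#'   presented stimuli, with no spatial bias and no latency-SD dependence.
#' @rdname agentParams
#' @export
naiveAgentParams <- function() {
  agentParams(b0 = 0, bSdMax = 0, bTerm = 0, pWinstay = 0.5,
              pLoseshiftStay = 0.5, rtSdSlope = 0)
}

setMethod("show", "AgentParams", function(object) {
  cat(sprintf(
    "AgentParams: bSdMax=%.2f tauLearn=%.0f bTerm=%.2f winstay=%.2f/%.2f rt=%0.f+/-%.0f ms\n",
    object@bSdMax, object@tauLearn, object@bTerm, object@pWinstay,
    object@pLoseshiftStay, object@rtMu, object@rtSigma))
})

#' Probability of a correct choice
#'
#' `P(correct) = logistic(b0 + L(t) * (bSdMax * SD + bTerm * terminal))` with
#' the learning factor `L(t) = 1 - exp(-t / tauLearn)`, where `t` is the
#' choice-trial index. Both the symbolic-distance slope and the terminal-item
#' bonus are learned, so performance starts at chance (`logistic(b0)`) on the
#' first trial. Monotone nondecreasing in both `t` and symbolic distance.
#'
#' @param sd symbolic distance of the pair (vectorized).
#' @param terminal logical, pair contains the first or last list item.
#' @param t choice-trial index, `>= 1` (vectorized).
#' @param params an [agentParams()].
#' @return probability vector.
#' @export
choiceAccuracy <- function(sd, terminal, t, params = agentParams()) {
  if (any(t < 1)) stop("trial index t must be >= 1")
  learn <- 1 - exp(-t / params@tauLearn)
  plogis(params@b0 +
         learn * (params@bSdMax * sd + params@bTerm * as.numeric(terminal)))
}

## one truncated-normal latency draw per trial, support (0, deadline]
rtruncnorm <- function(n, mean, sd, lo = 0, hi = 1500) {
  u <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  qnorm(u, mean, sd)
}

#' Simulate a behavioral session
#'
#' Runs the agent through a [buildSessionSchedule()] trial by trial. On each
#' choice trial the chosen item is drawn from [choiceAccuracy()]; a lag-1
#' spatial override then shifts the trial's natural location-repeat
#' probability by a tracked stickiness increment so that the session-average
#' repeat rate equals `pWinstay` after rewarded trials and `pLoseshiftStay`
#' after unrewarded ones, while choices remain item-driven.
#' Correct means choosing the lower-ranked item; all correctly completed
#' trials are rewarded. Single-stimulus (phase 1) trials are always rewarded.
#' Event times accumulate on a session clock with the trial-timing intervals
#' of [sampleTrialTiming()] and a fixed 0.5 s intertrial interval.
#'
#' @param schedule a `SessionSchedule`.
#' @param params an [agentParams()].
#' @param seed optional integer seed; the simulation is deterministic given
#'   the seed.
#' @return data.frame of trial records: schedule columns plus `chosenLoc`
#'   (+1 = receptive-field location, -1 = opposite), `chosenRank`, `correct`,
#'   `rewarded`, `latencyMs`, `terminal`, and event times in session seconds
#'   (`tStart`, `stimOn`, `saccOn`, `feedback`, `rewardT`, `tEnd`).
#' @export
simulateSession <- function(schedule, params = agentParams(), seed = NULL) {
  stopifnot(is(schedule, "SessionSchedule"))
  tr <- scheduleTrials(schedule)
  n <- nrow(tr)
  nList <- nItems(schedule@list)
  withSeed(seed, {
    timing <- sampleTrialTiming(n)
    tr$terminal <- ifelse(tr$phase == 2L,
      pmin(tr$stimRF, tr$stimOpp) == 1L | pmax(tr$stimRF, tr$stimOpp) == nList,
      NA)
    chosenLoc <- integer(n); chosenRank <- integer(n)
    correct <- logical(n); rewarded <- logical(n)
    latency <- numeric(n)
    prevLoc <- NA_integer_; prevRew <- NA
    r0bar <- c(0.5, 0.5)   # tracked natural repeat prob, per prev-outcome
    repSum <- c(0, 0); repN <- c(0L, 0L)  # realized repeats, per condition
    for (i in seq_len(n)) {
      if (tr$phase[i] == 1L) {
        # single stimulus: saccade to it, always rewarded
        chosenLoc[i] <- if (is.na(tr$stimRF[i])) -1L else 1L
        chosenRank[i] <- if (is.na(tr$stimRF[i])) tr$stimOpp[i] else tr$stimRF[i]
        correct[i] <- TRUE; rewarded[i] <- TRUE
        latency[i] <- rtruncnorm(1, params@rtMuSingle, params@rtSigma)
      } else {
        lo <- pmin(tr$stimRF[i], tr$stimOpp[i])
        hi <- pmax(tr$stimRF[i], tr$stimOpp[i])
        p <- choiceAccuracy(tr$sd[i], tr$terminal[i],
                            tr$choiceTrial[i], params)
        pickLow <- runif(1) < p
        rank <- if (pickLow) lo else hi
        loc <- if (rank == tr$stimRF[i]) 1L else -1L
        # lag-1 spatial override: shifts this trial's natural repeat
        # probability r0 (known before the draw: p or 1-p depending on
        # where the lower-ranked item sits) by a stickiness increment
        # delta = pStay - <r0>, where <r0> is the running per-condition
        # mean, so the session-average repeat rate converges to pStay
        # while choices remain item-driven. Counterbalanced blocks make
        # <r0> sit slightly below 0.5 after rewards, which the tracking
        # absorbs.
        if (!is.na(prevLoc)) {
          cond <- if (isTRUE(prevRew)) 1L else 2L
          pStay <- if (cond == 1L) params@pWinstay
                   else params@pLoseshiftStay
          lowAtPrev <- (prevLoc == 1L && tr$stimRF[i] == lo) ||
                       (prevLoc == -1L && tr$stimOpp[i] == lo)
          r0 <- if (lowAtPrev) p else 1 - p
          # feedback on the realized rate absorbs the saturation loss on
          # trials where r0 is already close to 1
          fb <- if (repN[cond] > 0)
            pStay - repSum[cond] / repN[cond] else 0
          delta <- pStay - r0bar[cond] + 2 * fb
          if (pStay >= 1) {
            loc <- prevLoc
          } else if (pStay <= 0) {
            loc <- -prevLoc
          } else if (delta > 0 && loc != prevLoc) {
            if (runif(1) < min(1, delta / (1 - r0))) loc <- prevLoc
          } else if (delta < 0 && loc == prevLoc) {
            if (runif(1) < min(1, -delta / r0)) loc <- -prevLoc
          }
          # exponentially weighted tracker follows the learning-induced
          # drift of r0 with little lag
          r0bar[cond] <- 0.95 * r0bar[cond] + 0.05 * r0
          repSum[cond] <- repSum[cond] + (loc == prevLoc)
          repN[cond] <- repN[cond] + 1L
        }
        rank <- if (loc == 1L) tr$stimRF[i] else tr$stimOpp[i]
        chosenLoc[i] <- loc; chosenRank[i] <- rank
        correct[i] <- rank == lo
        rewarded[i] <- correct[i]
        latency[i] <- rtruncnorm(
          1, params@rtMu - params@rtSdSlope * tr$sd[i], params@rtSigma)
        prevLoc <- loc; prevRew <- rewarded[i]
      }
    }
    tr$chosenLoc <- chosenLoc
    tr$chosenRank <- chosenRank
    tr$correct <- correct
    tr$rewarded <- rewarded
    tr$latencyMs <- latency
    # session clock
    iti <- 0.5
    trialSpan <- timing$fixDelay + latency / 1000 + timing$holdInterval +
      timing$rewardInterval + 0.5   # 0.5 s tail after reward/feedback
    tStart <- cumsum(c(0, head(trialSpan + iti, -1)))
    tr$tStart <- tStart
    tr$stimOn <- tStart + timing$fixDelay
    tr$saccOn <- tr$stimOn + latency / 1000
    tr$feedback <- tr$saccOn + timing$holdInterval
    tr$rewardT <- ifelse(rewarded, tr$feedback + timing$rewardInterval, NA)
    tr$tEnd <- tStart + trialSpan
    tr
  })
}
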