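## Behavioral analyses: moving-window learning curves, per-pair accuracy at
## fixed trial points (windowed or GP-smoothed), symbolic-distance/accuracy
## correlation, reaction time by symbolic distance, spatial win-stay /
## lose-shift, and item-level reward-history effects.

#' Moving-window accuracy curves
#'
#' Centered moving proportion correct with a 25-trial default window,
#' truncated at the edges. With `groupBy`, one curve per group (e.g.
#' symbolic distance), computed over that group's own trial sequence; groups
#' with fewer trials than the window are omitted with a notice.
#'
#' @param correct logical vector of per-trial outcomes, in trial order.
#' @param window window length in trials.
#' @param groupBy optional per-trial grouping values.
#' @return data.frame with `trial` (index within the input, or within group),
#'   `group` (or `NA`), `accuracy`.
#' @export
movingAccuracy <- function(correct, window = 25, groupBy = NULL) {
  movingMean <- function(x) {
    n <- length(x)
    half <- (window - 1) %/% 2
    cs <- cumsum(c(0, x))
    i <- seq_len(n)
    lo <- pmax(1, i - half); hi <- pmin(n, i + window - 1 - half)
    (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }
  if (is.null(groupBy)) {
    if (length(correct) < window) stop("fewer trials than the window")
    return(data.frame(trial = seq_along(correct), group = NA,
                      accuracy = movingMean(as.numeric(correct))))
  }
  out <- list()
  for (g in sort(unique(groupBy))) {
    idx <- which(groupBy == g)
    if (length(idx) < window) {
      message("group ", g, " has fewer trials than the window; omitted")
      next
    }
    out[[as.character(g)]] <- data.frame(
      trial = idx, group = g,
      accuracy = movingMean(as.numeric(correct[idx])))
  }
  do.call(rbind, out)
}

## exact GP regression of a scalar response on trial covariates
gpFitPredict <- function(Xtrain, y, Xpred, lengthScales, signalVar = NULL,
                         noiseVar = NULL) {
  sqd <- function(A, B, l) {
    out <- 0
    for (j in seq_len(ncol(A)))
      out <- out + outer(A[, j], B[, j], `-`)^2 / l[j]^2
    out
  }
  K <- exp(-0.5 * sqd(Xtrain, Xtrain, lengthScales))
  e <- eigen(K, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  yc <- y - mean(y)
  yt <- crossprod(e$vectors, yc)
  v <- var(y)
  if (is.null(signalVar) || is.null(noiseVar)) {
    nll <- function(p) {
      d <- exp(p[1]) * lam + exp(p[2])
      0.5 * (sum(log(d)) + sum(yt^2 / d))
    }
    op <- optim(log(c(v, v / 2)), nll, method = "Nelder-Mead",
                control = list(maxit = 200))
    signalVar <- exp(op$par[1]); noiseVar <- exp(op$par[2])
  }
  alpha <- e$vectors %*% (yt / (signalVar * lam + noiseVar))
  Ks <- exp(-0.5 * sqd(Xpred, Xtrain, lengthScales))
  as.numeric(signalVar * Ks %*% alpha) + mean(y)
}

#' Per-pair accuracy estimated at a fixed trial point
#'
#' Estimates each pair's accuracy at choice trial `t` (typically 250 or 500).
#' `method = "window"` uses the proportion correct among that pair's trials
#' within `halfSpan` choice trials of `t`; `method = "gpr"` smooths the
#' binary outcomes of all choice trials with a Gaussian-process prior over
#' (trial, SD, JR) — squared-exponential kernel, Gaussian noise — and reports
#' the posterior mean at `t` for each pair's (SD, JR).
#'
#' @param trials trial table from [simulateSession()] (choice trials used).
#' @param t choice-trial point of interest.
#' @param method `"window"` or `"gpr"`.
#' @param halfSpan half-width of the trial window (window method).
#' @param lengthScales kernel length-scales `c(trial, sd, jr)` (gpr method).
#' @return data.frame with one row per pair: `rankLow`, `rankHigh`, `sd`,
#'   `jr`, `accuracy`, clipped to \[0, 1\] for the GP method.
#' @export
accuracyAtTrial <- function(trials, t = 250, method = c("window", "gpr"),
                            halfSpan = 105, lengthScales = c(150, 1.5, 2)) {
  method <- match.arg(method)
  tr <- trials[trials$phase == 2L, , drop = FALSE]
  if (t > max(tr$choiceTrial)) stop("t lies beyond the session")
  tr$rankLow <- pmin(tr$stimRF, tr$stimOpp)
  tr$rankHigh <- pmax(tr$stimRF, tr$stimOpp)
  pairs <- unique(tr[, c("rankLow", "rankHigh", "sd", "jr")])
  pairs <- pairs[order(pairs$rankLow, pairs$rankHigh), ]
  if (method == "window") {
    acc <- mapply(function(lo, hi) {
      sel <- tr$rankLow == lo & tr$rankHigh == hi &
        abs(tr$choiceTrial - t) <= halfSpan
      mean(tr$correct[sel])
    }, pairs$rankLow, pairs$rankHigh)
  } else {
    X <- cbind(tr$choiceTrial, tr$sd, tr$jr)
    Xp <- cbind(t, pairs$sd, pairs$jr)
    acc <- gpFitPredict(X, as.numeric(tr$correct), Xp, lengthScales)
    acc <- pmin(1, pmax(0, acc))
  }
  pairs$accuracy <- acc
  rownames(pairs) <- NULL
  pairs
}

#' Correlation of performance with symbolic distance
#'
#' Pearson correlation (with two-sided p and r-squared) between accuracy
#' observations and their symbolic distance; the standard observation unit
#' is per-session, per-SD-level accuracy pooled across sessions.
#'
#' @param accuracy accuracy observations.
#' @param sd symbolic distance of each observation.
#' @return list with `r`, `p`, `r2`, `n`.
#' @export
sdPerformanceCorrelation <- function(accuracy, sd) {
  ok <- !is.na(accuracy) & !is.na(sd)
  if (sum(ok) < 3L) stop("need at least 3 observations")
  if (var(accuracy[ok]) == 0 || var(sd[ok]) == 0)
    stop("correlation undefined: a variable is constant")
  ct <- cor.test(accuracy[ok], sd[ok])
  list(r = unname(ct$estimate), p = ct$p.value,
       r2 = unname(ct$estimate)^2, n = sum(ok))
}

#' Reaction time by symbolic distance
#'
#' Per-SD mean latencies, a one-way ANOVA across SD levels, and the range
#' (max - min) of the level means — the quantity that is only a few ms even
#' when the ANOVA is overwhelmingly significant at large N.
#'
#' @param latencyMs per-trial saccade latencies, ms.
#' @param sd per-trial symbolic distance.
#' @return list with `means` (named per level), `F`, `p`, `rangeMs`, `n`.
#' @export
rtBySd <- function(latencyMs, sd) {
  ok <- !is.na(latencyMs) & !is.na(sd)
  g <- factor(sd[ok])
  if (nlevels(g) < 2L) stop("need at least 2 symbolic-distance levels")
  means <- tapply(latencyMs[ok], g, mean)
  a <- anova(lm(latencyMs[ok] ~ g))
  list(means = means, F = a$`F value`[1], p = a$`Pr(>F)`[1],
       rangeMs = max(means) - min(means), n = sum(ok))
}

## lag-1 location repeats conditioned on previous outcome, one session
sessionStayProportions <- function(trials) {
  tr <- trials[trials$phase == 2L, , drop = FALSE]
  if (nrow(tr) < 2L) stop("need at least 2 choice trials")
  rep1 <- tr$chosenLoc[-1] == tr$chosenLoc[-nrow(tr)]
  prevRew <- tr$rewarded[-nrow(tr)]
  c(afterReward = mean(rep1[prevRew]), afterNoReward = mean(rep1[!prevRew]))
}

#' Spatial win-stay / lose-shift analysis
#'
#' For each session, the proportion of choice trials on which the previous
#' trial's chosen location is repeated, conditioned on whether the previous
#' trial was rewarded. Across sessions, one-sample t-tests against the
#' chance value 0.5 and Cohen's d = (mean - 0.5) / sd.
#'
#' @param sessions a trial table or list of trial tables (one per session).
#' @return list with `perSession` (data.frame of the two proportions),
#'   `summary` (means, t-test p values, Cohen's d per condition).
#' @export
winstayLoseshift <- function(sessions) {
  if (is.data.frame(sessions)) sessions <- list(sessions)
  per <- t(vapply(sessions, sessionStayProportions, numeric(2)))
  per <- as.data.frame(per)
  summarise <- function(x) {
    x <- x[!is.na(x)]
    tt <- if (length(x) > 1 && sd(x) > 0) t.test(x, mu = 0.5)
      else list(p.value = NA_real_)
    c(mean = mean(x), p = tt$p.value,
      d = if (length(x) > 1 && sd(x) > 0) (mean(x) - 0.5) / sd(x)
        else NA_real_)
  }
  list(perSession = per,
       summary = rbind(afterReward = summarise(per$afterReward),
                       afterNoReward = summarise(per$afterNoReward)))
}

## per (session, item): choice probability and latency conditioned on the
## outcome of the most recent previous choice of that item
itemHistoryOneSession <- function(trials, items) {
  tr <- trials[trials$phase == 2L, , drop = FALSE]
  n <- nrow(tr)
  out <- list()
  for (it in items) {
    presented <- which(tr$stimRF == it | tr$stimOpp == it)
    chosePrev <- rep(NA, n)      # outcome of last previous choice of `it`
    lastOutcome <- NA
    for (i in seq_len(n)) {
      chosePrev[i] <- lastOutcome
      if (tr$chosenRank[i] == it) lastOutcome <- tr$rewarded[i]
    }
    sel <- presented[!is.na(chosePrev[presented])]
    if (!length(sel)) next
    prevRew <- chosePrev[sel] == TRUE
    chose <- tr$chosenRank[sel] == it
    pR <- if (any(prevRew)) mean(chose[prevRew]) else NA_real_
    pU <- if (any(!prevRew)) mean(chose[!prevRew]) else NA_real_
    lR <- if (any(prevRew)) mean(tr$latencyMs[sel][prevRew]) else NA_real_
    lU <- if (any(!prevRew)) mean(tr$latencyMs[sel][!prevRew]) else NA_real_
    out[[as.character(it)]] <- data.frame(
      item = it, pAfterReward = pR, pAfterNoReward = pU,
      rtAfterReward = lR, rtAfterNoReward = lU)
  }
  do.call(rbind, out)
}

#' Item-level reward-history analysis
#'
#' For each non-terminal list item, the probability of choosing that item on
#' trials where it is presented, conditioned on whether the most recent
#' previous choice of that item was rewarded; likewise for saccade latency.
#' Cells whose denominator is zero are dropped and counted. Paired t-tests
#' (paired by session and item) compare the two conditional probabilities and
#' the two conditional latencies.
#'
#' @param sessions a trial table or list of trial tables.
#' @param items item ranks to analyze (default 2..6, the non-terminal items
#'   of a 7-item list).
#' @return list with `table` (per session x item), `nDropped`, `choiceTest`
#'   and `latencyTest` (paired t-test results as lists with `diff`, `p`,
#'   `n`).
#' @export
itemRewardHistory <- function(sessions, items = 2:6) {
  if (is.data.frame(sessions)) sessions <- list(sessions)
  tabs <- lapply(seq_along(sessions), function(s) {
    d <- itemHistoryOneSession(sessions[[s]], items)
    if (!is.null(d) && nrow(d)) d$session <- s
    d
  })
  tab <- do.call(rbind, tabs)
  if (is.null(tab) || !nrow(tab))
    stop("no item-history cells could be computed ",
         "(all conditional denominators empty)")
  nTotal <- nrow(tab) * 2L
  pairTest <- function(a, b) {
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 2L) return(list(diff = NA_real_, p = NA_real_, n = sum(ok)))
    tt <- t.test(a[ok], b[ok], paired = TRUE)
    list(diff = mean(a[ok] - b[ok]), p = tt$p.value, n = sum(ok))
  }
  nDropped <- sum(is.na(tab$pAfterReward)) + sum(is.na(tab$pAfterNoReward))
  list(table = tab, nDropped = nDropped,
       choiceTest = pairTest(tab$pAfterReward, tab$pAfterNoReward),
       latencyTest = pairTest(tab$rtAfterReward, tab$rtAfterNoReward))
}
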