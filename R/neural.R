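## Spike-train processing: epoch rates, session z-scores, kernel-density rate
## estimates with MISE-optimized bandwidth, and condition-sorted PSTHs.

#' Define a peri-event counting window
#'
#' Fixed windows run `[startMs, endMs)` relative to `align`; variable-end
#' windows (e.g. stimulus onset to saccade) are obtained by giving `endEvent`
#' instead of `endMs`.
#'
#' @param align `"stimulus_onset"` or `"saccade_onset"`.
#' @param startMs window start, ms relative to the alignment event.
#' @param endMs window end, ms (ignored when `endEvent` is given).
#' @param endEvent optional event name ending the window.
#' @return list describing the window.
#' @export
epochWindow <- function(align = c("stimulus_onset", "saccade_onset"),
                        startMs = 0, endMs = NULL, endEvent = NULL) {
  align <- match.arg(align)
  if (is.null(endMs) && is.null(endEvent))
    stop("one of endMs or endEvent is required")
  if (!is.null(endMs) && is.null(endEvent) && startMs >= endMs)
    stop("window start must precede end")
  list(align = align, startMs = startMs, endMs = endMs, endEvent = endEvent)
}

eventTimes <- function(trials, event) {
  switch(event,
    stimulus_onset = trials$stimOn,
    saccade_onset = trials$saccOn,
    feedback = trials$feedback,
    stop("unknown alignment event: ", event))
}

windowBounds <- function(trials, window) {
  t0 <- eventTimes(trials, window$align) + window$startMs / 1000
  t1 <- if (is.null(window$endEvent))
    eventTimes(trials, window$align) + window$endMs / 1000
  else eventTimes(trials, window$endEvent)
  list(t0 = t0, t1 = t1)
}

#' Per-trial firing rate in an epoch
#'
#' Counts spikes in the window on each trial and divides by the window
#' duration (sp/s). Supports variable-end windows such as stimulus onset to
#' saccade onset. Trials whose alignment (or end) event is missing, or whose
#' window has nonpositive duration, get `NA`.
#'
#' @param spikes sorted spike-time vector (session seconds).
#' @param trials trial table with event-time columns.
#' @param window an [epochWindow()] or one row of [epochScheme()].
#' @return numeric vector of rates, one per trial.
#' @export
epochSpikeRate <- function(spikes, trials, window) {
  if (is.data.frame(window))
    window <- epochWindow(window$align[1], window$startMs[1], window$endMs[1])
  b <- windowBounds(trials, window)
  dur <- b$t1 - b$t0
  ok <- !is.na(b$t0) & !is.na(b$t1) & dur > 0
  cnt <- rep(NA_real_, nrow(trials))
  if (any(ok)) {
    n1 <- findInterval(b$t1[ok], spikes, left.open = TRUE)
    n0 <- findInterval(b$t0[ok], spikes, left.open = TRUE)
    cnt[ok] <- (n1 - n0) / dur[ok]
  }
  cnt
}

#' Session z-score of per-trial firing rates
#'
#' Standardizes per-trial rates with the session mean and the population-SD
#' (divide-by-N) convention: `z = (FR - mu) / sigma`. `NA` trials are ignored
#' for the moments and propagate as `NA`.
#'
#' @param rates per-trial rates.
#' @return list with `z` (same length as input), `mu`, `sigma`.
#' @export
zscoreRates <- function(rates) {
  ok <- !is.na(rates)
  if (sum(ok) < 2L) stop("z-score needs at least 2 trials")
  mu <- mean(rates[ok])
  sigma <- sqrt(mean((rates[ok] - mu)^2))
  if (sigma == 0) stop("degenerate unit: zero rate variance, z-score undefined")
  list(z = (rates - mu) / sigma, mu = mu, sigma = sigma)
}

#' Silverman's rule-of-thumb bandwidth
#'
#' `0.9 * min(sd, IQR/1.34) * n^(-1/5)`, used for eye-movement density
#' estimates and as the fallback when the spike-train bandwidth search does
#' not bracket an interior minimum.
#'
#' @param x numeric sample.
#' @return bandwidth on the scale of `x`.
#' @export
silvermanBandwidth <- function(x) {
  n <- length(x)
  if (n < 2L) stop("need at least 2 observations")
  s <- min(sd(x), diff(quantile(x, c(0.25, 0.75), names = FALSE)) / 1.34)
  if (s == 0) s <- sd(x)
  0.9 * s * n^(-1/5)
}

## Least-squares (MISE) cross-validation cost for a Gaussian-kernel intensity
## estimate, evaluated on binned spike times; minimized over a bandwidth grid.
ssBandwidth <- function(spk, lo, hi, dt, candidates) {
  pad <- 5 * max(candidates)
  breaks <- seq(lo - pad, hi + pad + dt, by = dt)
  y <- tabulate(findInterval(spk, breaks), nbins = length(breaks) - 1L)
  n <- sum(y)
  cost <- vapply(candidates, function(w) {
    half <- ceiling(5 * w / dt)
    kw <- dnorm((-half:half) * dt, sd = w)
    lam <- convolve(y, rev(kw), type = "open")[(half + 1):(half + length(y))]
    sum(lam^2) * dt - 2 * (sum(y * lam) - n * dnorm(0, sd = w))
  }, numeric(1))
  list(cost = cost, best = which.min(cost))
}

#' Kernel-density estimate of trial-averaged firing rate
#'
#' Gaussian-kernel rate estimate from event-aligned spike times pooled over
#' trials, `lambda(t) = (1/nTrials) * sum_i k_w(t - x_i)`, with the bandwidth
#' chosen by minimizing a least-squares (MISE) cross-validation cost over a
#' log-spaced bandwidth grid. If the cost has no interior minimum on the
#' grid, Silverman's rule is used instead. The estimate integrates to the
#' mean spike count per trial.
#'
#' @param spikes spike times relative to the alignment event, seconds.
#' @param nTrials number of trials pooled.
#' @param range time range `c(lo, hi)` of the output grid, seconds.
#' @param gridMs output grid step, ms.
#' @param bandwidthMs optional fixed bandwidth, ms (skips selection).
#' @return list of class `RateEstimate`: `time` (s), `rate` (sp/s),
#'   `bandwidthMs`, `nTrials`.
#' @export
kdeRate <- function(spikes, nTrials, range = c(-0.25, 1), gridMs = 1,
                    bandwidthMs = NULL) {
  lo <- range[1]; hi <- range[2]
  grid <- seq(lo, hi, by = gridMs / 1000)
  if (length(spikes) == 0L) {
    return(structure(list(time = grid, rate = numeric(length(grid)),
                          bandwidthMs = NA_real_, nTrials = nTrials),
                     class = "RateEstimate"))
  }
  if (is.null(bandwidthMs)) {
    if (length(spikes) == 1L) {
      w <- 0.01
    } else {
      cand <- exp(seq(log(0.002), log((hi - lo) / 4), length.out = 25))
      sel <- ssBandwidth(spikes, lo, hi, 0.001, cand)
      w <- if (sel$best == 1L || sel$best == length(cand))
        silvermanBandwidth(spikes) else cand[sel$best]
    }
  } else w <- bandwidthMs / 1000
  rate <- vapply(grid, function(t0) sum(dnorm(t0 - spikes, sd = w)),
                 numeric(1)) / nTrials
  structure(list(time = grid, rate = rate, bandwidthMs = w * 1000,
                 nTrials = nTrials), class = "RateEstimate")
}

#' @export
print.RateEstimate <- function(x, ...) {
  cat(sprintf(
    "RateEstimate: %d points on [%.3f, %.3f] s, bw %.1f ms, %d trials\n",
    length(x$time), min(x$time), max(x$time), x$bandwidthMs, x$nTrials))
  invisible(x)
}

#' Condition-sorted PSTHs and z-scored condition means
#'
#' Splits trials by a grouping variable, computes one [kdeRate()] estimate
#' per level, and the per-level mean session z-score of the epoch rate in a
#' named window. Grouping variables: `"jr"`, `"sd"`, `"rankRF"` (rank of the
#' in-field stimulus) and `"saccadeDir"` use choice trials;
#' `"targetLoc"` uses single-stimulus trials (in vs. out of field). Levels
#' with no trials are omitted with a notice.
#'
#' @param spikes sorted session spike times.
#' @param trials trial table.
#' @param groupBy grouping variable name.
#' @param align alignment event for the PSTHs.
#' @param range PSTH time range, seconds.
#' @param zWindow [epochWindow()] for the condition means (default the
#'   40-150 ms visual identity window).
#' @param bandwidthMs optional fixed PSTH bandwidth.
#' @return list with `estimates` (named list of `RateEstimate`), `zMeans`
#'   (named per-level mean z), `counts` (trials per level).
#' @export
psthByCondition <- function(spikes, trials,
                            groupBy = c("jr", "sd", "rankRF", "saccadeDir",
                                        "targetLoc"),
                            align = "stimulus_onset", range = c(-0.25, 1),
                            zWindow = epochWindow("stimulus_onset", 40, 150),
                            bandwidthMs = NULL) {
  groupBy <- match.arg(groupBy)
  use <- if (groupBy == "targetLoc") trials$phase == 1L else trials$phase == 2L
  tr <- trials[use, , drop = FALSE]
  if (nrow(tr) == 0L) stop("no trials for grouping variable ", groupBy)
  g <- switch(groupBy,
    jr = tr$jr, sd = tr$sd, rankRF = tr$stimRF, saccadeDir = tr$chosenLoc,
    targetLoc = ifelse(is.na(tr$stimRF), -1L, 1L))
  keep <- !is.na(g)
  tr <- tr[keep, , drop = FALSE]; g <- g[keep]
  ev <- eventTimes(tr, align)
  z <- zscoreRates(epochSpikeRate(spikes, tr, zWindow))$z
  lev <- sort(unique(g))
  ests <- list(); zm <- numeric(0); cnt <- integer(0)
  for (L in lev) {
    idx <- which(g == L)
    rel <- unlist(lapply(idx, function(i) {
      s <- spikes[spikes >= ev[i] + range[1] & spikes < ev[i] + range[2]]
      s - ev[i]
    }))
    key <- as.character(L)
    ests[[key]] <- kdeRate(rel, length(idx), range = range,
                           bandwidthMs = bandwidthMs)
    zm[key] <- mean(z[idx], na.rm = TRUE)
    cnt[key] <- length(idx)
  }
  list(estimates = ests, zMeans = zm, counts = cnt)
}
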