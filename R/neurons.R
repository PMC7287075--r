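## Generative model of spiking units: six temporal-profile families, a
## multiplicative receptive-field gain, joint-rank / symbolic-distance
## modulation, a transient rank code that waxes and wanes with learning, and
## (optional) post-feedback outcome modulation. Spikes are drawn from an
## inhomogeneous Poisson process by thinning.

## The six response-profile families. Each template maps times relative to
## stimulus onset (tStim) and saccade onset (tSacc), in seconds, to a
## dimensionless modulation with peak magnitude ~1.
responseTemplates <- function() {
  list(
    visualTransient = function(tStim, tSacc)
      exp(-((tStim - 0.07) / 0.025)^2 / 2),
    visualSustained = function(tStim, tSacc)
      plogis((tStim - 0.05) / 0.01) * exp(-pmax(tStim - 0.05, 0) / 0.8),
    presaccadicRamp = function(tStim, tSacc)
      plogis((tStim - 0.04) / 0.02) *
        ifelse(tSacc < 0, exp(tSacc / 0.12), exp(-tSacc / 0.03)),
    postsaccadic = function(tStim, tSacc)
      exp(-((tSacc - 0.15) / 0.07)^2 / 2),
    suppressed = function(tStim, tSacc)
      -plogis((tStim - 0.04) / 0.015) * exp(-pmax(tStim - 0.04, 0) / 0.5),
    delayTonic = function(tStim, tSacc)
      plogis((tSacc - 0.35) / 0.08))
}

#' @rdname neuronParams
#' @export
setClass("NeuronParams",
  representation(clusterId = "integer", baselineHz = "numeric",
                 amplitudeHz = "numeric", spatialGain = "numeric",
                 jrWeights = "numeric", sdWeights = "numeric",
                 rankGainMax = "numeric", rankCenter = "numeric",
                 rankWidth = "numeric", outcomeGain = "numeric",
                 modTau = "numeric", tShift = "numeric", tScale = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!object@clusterId %in% 1:6)
      msg <- c(msg, "clusterId must be in 1..6")
    if (length(object@jrWeights) != 11L)
      msg <- c(msg, "jrWeights must have 11 entries (joint ranks 3..13)")
    if (length(object@sdWeights) != 6L)
      msg <- c(msg, "sdWeights must have 6 entries (symbolic distances 1..6)")
    if (!is.finite(object@baselineHz)) msg <- c(msg, "baselineHz must be finite")
    if (object@modTau < 0) msg <- c(msg, "modTau must be >= 0")
    if (object@tScale <= 0) msg <- c(msg, "tScale must be > 0")
    if (length(msg)) msg else TRUE
  })

#' Spiking-unit parameters
#'
#' Parameters of one simulated unit. The firing rate is
#' `softplus(baseline + A * template(t) * gain * (1 + mod) + outcome)` where
#' `template` is one of six temporal-profile families (visual transient,
#' visual sustained, presaccadic ramp, postsaccadic, suppressed, delay/tonic),
#' `gain` is `spatialGain` (default 2, matching the observed ~2:1 in- vs.
#' out-of-field response ratio) for the stimulus inside the receptive field
#' and 1 otherwise, and `mod` collects joint-rank, symbolic-distance and rank
#' terms. On pair trials the rate is the mean of the two single-stimulus
#' rates (response averaging). The rank code is a signed linear code over
#' ranks, zero-mean across the list, applied to the in-field item and scaled
#' by a Gaussian learning schedule `rankGainMax *
#' exp(-((t - rankCenter)/rankWidth)^2)` over choice trials, so rank
#' selectivity is present transiently during learning and absent afterwards.
#'
#' @param clusterId temporal-profile family, 1..6.
#' @param baselineHz baseline rate before the softplus link.
#' @param amplitudeHz template response amplitude.
#' @param spatialGain in-receptive-field multiplier.
#' @param jrWeights modulation per joint-rank level 3..13 (length 11).
#' @param sdWeights modulation per symbolic-distance level 1..6 (length 6).
#' @param rankGainMax peak amplitude of the transient rank code.
#' @param rankCenter,rankWidth center and width (choice trials) of the rank
#'   learning schedule.
#' @param outcomeGain additive post-feedback modulation, Hz (default 0:
#'   outcome effects are negligible in the data this emulates).
#' @param modTau learning time constant (choice trials) with which the
#'   joint-rank/symbolic-distance modulation emerges,
#'   `1 - exp(-t / modTau)`; the modulation then remains stable, matching
#'   order-related tuning that develops during learning and persists. 0
#'   disables the ramp.
#' @param tShift,tScale per-unit temporal jitter of the template (s, ratio).
#' @return A `NeuronParams` object.
#' @export
neuronParams <- function(clusterId = 1L, baselineHz = 3,
                         amplitudeHz = 35, spatialGain = 2,
                         jrWeights = rep(0, 11), sdWeights = rep(0, 6),
                         rankGainMax = 0, rankCenter = 125, rankWidth = 75,
                         outcomeGain = 0, modTau = 100, tShift = 0,
                         tScale = 1) {
  if (clusterId == 5L && baselineHz < 10) baselineHz <- 20  # room to suppress
  new("NeuronParams", clusterId = as.integer(clusterId),
      baselineHz = baselineHz, amplitudeHz = amplitudeHz,
      spatialGain = spatialGain, jrWeights = jrWeights,
      sdWeights = sdWeights, rankGainMax = rankGainMax,
      rankCenter = rankCenter, rankWidth = rankWidth,
      outcomeGain = outcomeGain, modTau = modTau, tShift = tShift,
      tScale = tScale)
}

setMethod("show", "NeuronParams", function(object) {
  fam <- names(responseTemplates())[object@clusterId]
  cat(sprintf("NeuronParams: family %d (%s), baseline %.1f Hz, amp %.1f Hz\n",
              object@clusterId, fam, object@baselineHz, object@amplitudeHz))
})

## zero-mean signed linear code over ranks; lower rank -> positive
rankCode <- function(rank, nList = 7L) {
  ((nList + 1) / 2 - rank) / ((nList - 1) / 2)
}

## Gaussian learning schedule over choice trials
rankGainAt <- function(params, choiceTrial) {
  if (is.na(choiceTrial)) return(0)
  params@rankGainMax *
    exp(-((choiceTrial - params@rankCenter) / params@rankWidth)^2)
}

#' Instantaneous firing rate of a unit on one trial
#'
#' Evaluates the unit's rate (Hz) on a grid of times relative to stimulus
#' onset. Single-stimulus trials use only the presented stimulus's term;
#' pair trials average the two single-stimulus rates pointwise.
#'
#' @param params a [neuronParams()].
#' @param trial a single trial record (one row of [simulateSession()]).
#' @param tGrid times relative to stimulus onset, seconds.
#' @param nList list length (for the rank code).
#' @return numeric vector of rates in Hz, same length as `tGrid`.
#' @export
rateFunction <- function(params, trial, tGrid, nList = 7L) {
  tmpl <- responseTemplates()[[params@clusterId]]
  lat <- trial$saccOn - trial$stimOn
  tSacc <- tGrid - lat
  tv <- tmpl((tGrid - params@tShift) / params@tScale,
             (tSacc - params@tShift) / params@tScale)
  isPair <- trial$phase == 2L
  jrsd <- 0
  if (isPair) {
    ramp <- if (params@modTau > 0)
      1 - exp(-trial$choiceTrial / params@modTau) else 1
    jrsd <- ramp *
      (params@jrWeights[trial$jr - 2L] + params@sdWeights[trial$sd])
  }
  outc <- 0
  if (params@outcomeGain != 0 && !is.null(trial$feedback) &&
      !is.na(trial$feedback)) {
    x <- tGrid - (trial$feedback - trial$stimOn)
    sgn <- if (isTRUE(trial$rewarded)) 1 else -1
    outc <- params@outcomeGain * sgn * ifelse(x > 0, exp(-x / 0.25), 0)
  }
  oneStim <- function(rank, inRF) {
    gain <- if (inRF) params@spatialGain else 1
    mod <- jrsd
    if (inRF && isPair)
      mod <- mod + rankGainAt(params, trial$choiceTrial) * rankCode(rank, nList)
    softplus(params@baselineHz +
             params@amplitudeHz * tv * gain * (1 + mod) + outc)
  }
  parts <- list()
  if (!is.na(trial$stimRF)) parts <- c(parts, list(oneStim(trial$stimRF, TRUE)))
  if (!is.na(trial$stimOpp))
    parts <- c(parts, list(oneStim(trial$stimOpp, FALSE)))
  Reduce(`+`, parts) / length(parts)
}

#' Simulate a unit's spike train over a session
#'
#' Draws spikes from an inhomogeneous Poisson process by thinning the
#' [rateFunction()] over a peri-trial span (0.5 s before stimulus onset to
#' 0.6 s after feedback) on each trial. Spike times are on the session clock.
#'
#' @param params a [neuronParams()].
#' @param trials trial table from [simulateSession()].
#' @param seed optional integer seed; deterministic given the seed.
#' @param dtMs rate-grid resolution, ms.
#' @param nList list length.
#' @return sorted numeric vector of spike times (session seconds).
#' @export
simulateUnit <- function(params, trials, seed = NULL, dtMs = 1, nList = 7L) {
  if (nrow(trials) == 0L) stop("trials must be nonempty")
  withSeed(seed, {
    out <- vector("list", nrow(trials))
    for (i in seq_len(nrow(trials))) {
      tri <- trials[i, ]
      t0 <- -0.5
      t1 <- (tri$feedback - tri$stimOn) + 0.6
      grid <- seq(t0, t1, by = dtMs / 1000)
      rate <- rateFunction(params, tri, grid, nList)
      rMax <- max(rate)
      if (rMax <= 0) next
      span <- t1 - t0
      nHom <- rpois(1, rMax * span)
      if (nHom == 0L) next
      tt <- runif(nHom, t0, t1)
      ri <- rate[pmin(length(grid), floor((tt - t0) / (dtMs / 1000)) + 1L)]
      keep <- runif(nHom) < ri / rMax
      out[[i]] <- tri$stimOn + sort(tt[keep])
    }
    sort(unlist(out))
  })
}

#' @rdname simulatePopulation
#' @export
setClass("SpikeTrainSet",
  representation(spikes = "list", info = "data.frame", span = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@spikes) != nrow(object@info))
      msg <- c(msg, "one info row per unit required")
    for (s in object@spikes) {
      if (is.unsorted(s)) { msg <- c(msg, "spike times must be sorted"); break }
      if (length(s) && (s[1] < object@span[1] || s[length(s)] > object@span[2])) {
        msg <- c(msg, "spike times must lie within the session span"); break
      }
    }
    if (length(msg)) msg else TRUE
  })

#' Simulate a population of units on a common session
#'
#' Runs [simulateUnit()] for each parameter set against the same trial table,
#' giving a pseudo-population with trial-aligned activity.
#'
#' @param paramsList list of [neuronParams()].
#' @param trials trial table from [simulateSession()].
#' @param seed master seed; each unit gets an independent child stream.
#' @param ... passed to [simulateUnit()].
#' @return A `SpikeTrainSet` with per-unit spike-time vectors and metadata.
#' @export
simulatePopulation <- function(paramsList, trials, seed = NULL, ...) {
  seeds <- if (is.null(seed)) vector("list", length(paramsList))
    else as.list(childSeeds(seed, length(paramsList)))
  spikes <- lapply(seq_along(paramsList), function(i)
    simulateUnit(paramsList[[i]], trials, seed = seeds[[i]], ...))
  info <- data.frame(
    unit = seq_along(paramsList),
    clusterId = vapply(paramsList, function(p) p@clusterId, integer(1)))
  span <- c(min(trials$tStart) - 1, max(trials$tEnd) + 1)
  new("SpikeTrainSet", spikes = spikes, info = info, span = span)
}

#' @rdname simulatePopulation
#' @param x a `SpikeTrainSet`.
#' @param unit unit index.
#' @export
setGeneric("spikeTimes", function(x, unit) standardGeneric("spikeTimes"))

#' @rdname simulatePopulation
#' @export
setMethod("spikeTimes", "SpikeTrainSet", function(x, unit) x@spikes[[unit]])

#' @rdname simulatePopulation
#' @export
setGeneric("unitInfo", function(x) standardGeneric("unitInfo"))

#' @rdname simulatePopulation
#' @export
setMethod("unitInfo", "SpikeTrainSet", function(x) x@info)

#' @rdname simulatePopulation
#' @export
setGeneric("nUnits", function(x) standardGeneric("nUnits"))

#' @rdname simulatePopulation
#' @export
setMethod("nUnits", "SpikeTrainSet", function(x) length(x@spikes))

setMethod("show", "SpikeTrainSet", function(object) {
  cat("SpikeTrainSet:", length(object@spikes), "units,",
      sum(lengths(object@spikes)), "spikes, span",
      sprintf("%.1f-%.1f s\n", object@span[1], object@span[2]))
})

#' Draw a population of unit parameters
#'
#' Samples `nUnits` parameter sets spanning all six temporal-profile
#' families, with per-unit temporal jitter, lognormal amplitude variability,
#' and smooth random joint-rank / symbolic-distance weight profiles (linear
#' plus quadratic in the level, random amplitude). Defaults put somewhat more
#' modulation on joint rank than on symbolic distance, and give a transient
#' rank code to a fraction `rankFrac` of units.
#'
#' @param nUnits number of units.
#' @param seed integer seed.
#' @param clusterIds optional family assignment per unit; default cycles
#'   through all 6 families.
#' @param jrScale,sdScale SD of the random joint-rank and symbolic-distance
#'   weight amplitudes.
#' @param rankFrac fraction of units with a transient rank code.
#' @param rankGain peak rank-code amplitude for those units.
#' @param outcomeGain post-feedback modulation (default 0).
#' @return list of [neuronParams()].
#' @export
samplePopulationParams <- function(nUnits = 142L, seed = NULL,
                                   clusterIds = NULL, jrScale = 0.2,
                                   sdScale = 0.1, rankFrac = 0.5,
                                   rankGain = 0.3, outcomeGain = 0) {
  if (is.null(clusterIds))
    clusterIds <- rep_len(1:6, nUnits)
  withSeed(seed, {
    lapply(seq_len(nUnits), function(i) {
      jrx <- seq(-1, 1, length.out = 11)
      sdx <- seq(-1, 1, length.out = 6)
      jw <- rnorm(1, 0, jrScale) * jrx + rnorm(1, 0, jrScale) * (jrx^2 - 0.5)
      sw <- rnorm(1, 0, sdScale) * sdx + rnorm(1, 0, sdScale) * (sdx^2 - 0.5)
      neuronParams(
        clusterId = clusterIds[i],
        baselineHz = exp(rnorm(1, log(3), 0.25)),
        amplitudeHz = exp(rnorm(1, log(35), 0.2)),
        jrWeights = jw, sdWeights = sw,
        rankGainMax = if (runif(1) < rankFrac) rankGain else 0,
        outcomeGain = outcomeGain,
        tShift = rnorm(1, 0, 0.008),
        tScale = exp(rnorm(1, 0, 0.06)))
    })
  })
}

#' Generate 1 kHz eye-position traces
#'
#' Produces per-trial horizontal/vertical eye positions sampled at 1 kHz:
#' fixation at the display center with low-pass Gaussian jitter, then a
#' smooth sigmoidal saccade to the chosen target (at `eccentricityDeg` along
#' the horizontal diametric axis) beginning at the trial's saccade onset.
#'
#' @param trials trial table from [simulateSession()].
#' @param seed optional integer seed.
#' @param eccentricityDeg target eccentricity, degrees.
#' @param jitterSd fixation jitter SD, degrees.
#' @param sampleRate samples per second.
#' @param padS trace padding before stimulus onset and after the saccade, s.
#' @return list with one matrix per trial, columns `time` (s, relative to
#'   stimulus onset), `h`, `v` (degrees).
#' @export
generateEyeTrace <- function(trials, seed = NULL, eccentricityDeg = 8,
                             jitterSd = 0.05, sampleRate = 1000,
                             padS = 0.4) {
  withSeed(seed, {
    lapply(seq_len(nrow(trials)), function(i) {
      tri <- trials[i, ]
      lat <- tri$saccOn - tri$stimOn
      tt <- seq(-padS, lat + padS, by = 1 / sampleRate)
      m <- length(tt)
      smoothNoise <- function() {
        k <- dnorm(seq(-30, 30), sd = 10)
        x <- convolve(rnorm(m + 60), rev(k / sum(k)), type = "open")
        x <- x[31:(30 + m)]
        x / max(sd(x), 1e-12) * jitterSd
      }
      h <- smoothNoise(); v <- smoothNoise()
      if (!is.na(tri$chosenLoc)) {
        target <- tri$chosenLoc * eccentricityDeg
        # midpoint 23 ms after onset with 5 ms slope: the position excursion
        # (and hence threshold crossing) starts at the nominal saccade onset
        h <- h + target * plogis((tt - (lat + 0.023)) / 0.005)
      }
      cbind(time = tt, h = h, v = v)
    })
  })
}
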