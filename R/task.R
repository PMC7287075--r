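## Task structure: ordered stimulus lists, pair metrics, block schedules,
## trial timing, and named peri-event analysis epochs.

#' @rdname stimulusList
#' @export
setClass("StimulusList",
  representation(nItems = "integer", itemIds = "character"),
  validity = function(object) {
    msg <- character()
    if (object@nItems < 2L) msg <- c(msg, "nItems must be >= 2")
    if (length(object@itemIds) != object@nItems)
      msg <- c(msg, "itemIds must have one label per rank")
    if (anyDuplicated(object@itemIds)) msg <- c(msg, "itemIds must be unique")
    if (length(msg)) msg else TRUE
  })

#' Ordered stimulus list
#'
#' An implicitly ordered list of `nItems` stimuli. Rank 1 is the highest-value
#' item ("A"); on a choice trial the subject is rewarded for selecting the
#' lower-ranked (earlier-letter) of the two presented items.
#'
#' @param nItems number of list items (default 7, the standard list length).
#' @param itemIds labels in rank order; defaults to "A", "B", ...
#' @return A `StimulusList` object.
#' @examples
#' lst <- stimulusList(7)
#' nItems(lst)
#' @export
stimulusList <- function(nItems = 7L, itemIds = NULL) {
  nItems <- as.integer(nItems)
  if (is.na(nItems) || nItems < 2L)
    stop("invalid stimulus list: nItems must be an integer >= 2")
  if (is.null(itemIds)) {
    itemIds <- if (nItems <= 26L) LETTERS[seq_len(nItems)]
      else paste0("S", seq_len(nItems))
  }
  new("StimulusList", nItems = nItems, itemIds = as.character(itemIds))
}

#' @rdname stimulusList
#' @param x a `StimulusList`.
#' @export
setGeneric("nItems", function(x) standardGeneric("nItems"))

#' @rdname stimulusList
#' @export
setMethod("nItems", "StimulusList", function(x) x@nItems)

#' @rdname stimulusList
#' @export
setGeneric("itemIds", function(x) standardGeneric("itemIds"))

#' @rdname stimulusList
#' @export
setMethod("itemIds", "StimulusList", function(x) x@itemIds)

setMethod("show", "StimulusList", function(object) {
  cat("StimulusList of", object@nItems, "items:",
      paste(object@itemIds, collapse = " "), "\n")
})

#' Symbolic distance and joint rank of a stimulus pair
#'
#' Symbolic distance (SD) is the difference of the two item ranks; joint rank
#' (JR) is their sum. SD measures relative list position (adjacent pairs have
#' SD = 1), JR measures absolute list position; over the balanced pair set of
#' a list the two are numerically uncorrelated. Both are vectorized.
#'
#' @param rankLow,rankHigh integer ranks with `rankLow < rankHigh`.
#' @return integer vector of distances (or sums).
#' @examples
#' symbolicDistance(2, 3)  # pair BC -> 1
#' jointRank(1, 7)         # pair AG -> 8
#' @export
symbolicDistance <- function(rankLow, rankHigh) {
  checkPair(rankLow, rankHigh)
  as.integer(rankHigh - rankLow)
}

#' @rdname symbolicDistance
#' @export
jointRank <- function(rankLow, rankHigh) {
  checkPair(rankLow, rankHigh)
  as.integer(rankLow + rankHigh)
}

checkPair <- function(rankLow, rankHigh) {
  if (length(rankLow) != length(rankHigh))
    stop("rankLow and rankHigh must have equal length")
  if (any(rankLow < 1L) || any(rankHigh <= rankLow))
    stop("invalid pair: require 1 <= rankLow < rankHigh")
  invisible(TRUE)
}

#' Recover item ranks from joint rank and symbolic distance
#'
#' The two item ranks can be decomposed from the (JR, SD) encoding:
#' `rankHigh = (JR + SD) / 2` and `rankLow = (JR - SD) / 2`. The pair exists
#' only when JR and SD have equal parity and the recovered ranks fall inside
#' the list.
#'
#' @param jr joint rank (sum of ranks).
#' @param sd symbolic distance (difference of ranks), `>= 1`.
#' @param nItems list length used for the range check (default 7).
#' @return data.frame with columns `rankLow`, `rankHigh`.
#' @examples
#' decomposeRanks(8, 6)  # AG -> ranks 1 and 7
#' @export
decomposeRanks <- function(jr, sd, nItems = 7L) {
  jr <- as.integer(jr); sd <- as.integer(sd)
  if (any((jr + sd) %% 2L != 0L))
    stop("no such pair: joint rank and symbolic distance have unequal parity")
  hi <- (jr + sd) %/% 2L
  lo <- (jr - sd) %/% 2L
  if (any(lo < 1L) || any(hi > nItems) || any(sd < 1L))
    stop("no such pair: decomposed ranks fall outside 1..", nItems)
  data.frame(rankLow = lo, rankHigh = hi)
}

#' Enumerate all stimulus pairs of a list
#'
#' Every unordered pair of distinct ranks, each exactly once: `n(n-1)/2` pairs
#' (21 for a 7-item list), annotated with symbolic distance, joint rank, and
#' a terminal-item flag (pair contains the first or last list item).
#'
#' @param list a [stimulusList()].
#' @return data.frame with one row per pair: `rankLow`, `rankHigh`, `label`,
#'   `sd`, `jr`, `terminal`.
#' @examples
#' nrow(enumeratePairs(stimulusList(7)))  # 21
#' @export
enumeratePairs <- function(list = stimulusList(7L)) {
  if (!is(list, "StimulusList")) stop("invalid list: need a StimulusList")
  n <- nItems(list)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  lo <- as.integer(idx[, "row"]); hi <- as.integer(idx[, "col"])
  ord <- order(lo, hi)
  lo <- lo[ord]; hi <- hi[ord]
  data.frame(
    rankLow = lo, rankHigh = hi,
    label = paste0(itemIds(list)[lo], itemIds(list)[hi]),
    sd = symbolicDistance(lo, hi),
    jr = jointRank(lo, hi),
    terminal = lo == 1L | hi == n)
}

## truncated shifted-exponential rate giving mean 0.5 s on [0.4, 1.2];
## solved once and cached (the task states only range, skew and mean)
fixDelayRate <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      f <- function(r) 1 / r - 0.8 * exp(-0.8 * r) / (1 - exp(-0.8 * r)) - 0.1
      cache <<- uniroot(f, c(1, 100), tol = 1e-12)$root
    }
    cache
  }
})

#' Sample trial timing parameters
#'
#' Draws the stochastic intervals of the trial: a positively skewed fixation
#' delay on \[0.4, 1.2\] s with mean 0.5 s (truncated shifted exponential),
#' a uniform \[0.4, 0.6\] s post-saccade hold, and a uniform \[0.35, 0.65\] s
#' feedback-to-reward interval. The response deadline is fixed at 1.5 s.
#'
#' @param n number of trials.
#' @param seed optional integer seed.
#' @return data.frame with columns `fixDelay`, `holdInterval`,
#'   `rewardInterval`, `responseDeadline` (seconds).
#' @export
sampleTrialTiming <- function(n, seed = NULL) {
  withSeed(seed, {
    r <- fixDelayRate()
    u <- runif(n)
    fix <- 0.4 - log(1 - u * (1 - exp(-0.8 * r))) / r
    data.frame(
      fixDelay = fix,
      holdInterval = runif(n, 0.4, 0.6),
      rewardInterval = runif(n, 0.35, 0.65),
      responseDeadline = 1.5)
  })
}

#' @rdname buildSessionSchedule
#' @export
setClass("SessionSchedule",
  representation(trials = "data.frame", list = "StimulusList",
                 nPairBlocks = "integer"),
  validity = function(object) {
    need <- c("phase", "block", "stimRF", "stimOpp", "sd", "jr")
    if (!all(need %in% names(object@trials)))
      return("schedule trial table is missing required columns")
    TRUE
  })

#' Build a session schedule
#'
#' Phase 1 presents single stimuli: 5 blocks, each containing every list item
#' once inside and once outside the recorded cell's receptive field (14 trials
#' per block for a 7-item list; 70 in total), shuffled within block. Phase 2
#' presents all pairs: each block contains every pair twice, once per
#' positional arrangement (lower-ranked item in vs. out of the receptive
#' field), i.e. 42 trials per block for a 7-item list, shuffled within block;
#' up to 20 pair blocks (840 trials).
#'
#' @param list a [stimulusList()].
#' @param nPairBlocks number of phase-2 (all-pairs) blocks, 1..20.
#' @param seed optional integer seed controlling the within-block shuffles.
#' @return A `SessionSchedule`; its trial table has columns `phase` (1 or 2),
#'   `block`, `stimRF` / `stimOpp` (rank of the stimulus at the receptive-field
#'   and opposite location; one is `NA` on single-stimulus trials), `sd`, `jr`
#'   (NA in phase 1), and `choiceTrial` (index among phase-2 trials).
#' @examples
#' sch <- buildSessionSchedule(stimulusList(7), nPairBlocks = 20, seed = 1)
#' nrow(scheduleTrials(sch))  # 70 + 840
#' @export
buildSessionSchedule <- function(list = stimulusList(7L), nPairBlocks = 20L,
                                 seed = NULL) {
  nPairBlocks <- as.integer(nPairBlocks)
  if (nPairBlocks < 1L || nPairBlocks > 20L)
    stop("nPairBlocks must be between 1 and 20")
  n <- nItems(list)
  pairs <- enumeratePairs(list)
  withSeed(seed, {
    p1 <- do.call(rbind, lapply(seq_len(5L), function(b) {
      blk <- data.frame(
        phase = 1L, block = b,
        stimRF = c(seq_len(n), rep(NA_integer_, n)),
        stimOpp = c(rep(NA_integer_, n), seq_len(n)),
        sd = NA_integer_, jr = NA_integer_)
      blk[sample.int(nrow(blk)), ]
    }))
    p2 <- do.call(rbind, lapply(seq_len(nPairBlocks), function(b) {
      lowIn <- data.frame(phase = 2L, block = 5L + b,
                          stimRF = pairs$rankLow, stimOpp = pairs$rankHigh,
                          sd = pairs$sd, jr = pairs$jr)
      lowOut <- data.frame(phase = 2L, block = 5L + b,
                           stimRF = pairs$rankHigh, stimOpp = pairs$rankLow,
                           sd = pairs$sd, jr = pairs$jr)
      blk <- rbind(lowIn, lowOut)
      blk[sample.int(nrow(blk)), ]
    }))
    trials <- rbind(p1, p2)
    rownames(trials) <- NULL
    trials$trial <- seq_len(nrow(trials))
    trials$choiceTrial <- NA_integer_
    trials$choiceTrial[trials$phase == 2L] <- seq_len(sum(trials$phase == 2L))
    new("SessionSchedule", trials = trials, list = list,
        nPairBlocks = nPairBlocks)
  })
}

#' @rdname buildSessionSchedule
#' @param x a `SessionSchedule`.
#' @export
setGeneric("scheduleTrials", function(x) standardGeneric("scheduleTrials"))

#' @rdname buildSessionSchedule
#' @export
setMethod("scheduleTrials", "SessionSchedule", function(x) x@trials)

setMethod("show", "SessionSchedule", function(object) {
  tr <- object@trials
  cat("SessionSchedule:", sum(tr$phase == 1L), "single-stimulus +",
      sum(tr$phase == 2L), "choice trials (",
      object@nPairBlocks, "pair blocks,", nItems(object@list), "items)\n")
})

#' Named peri-event analysis epochs
#'
#' Returns the preset epoch windows used by the analyses, as half-open
#' intervals \[start, end) in ms relative to an alignment event
#' (`stimulus_onset` or `saccade_onset`):
#' \describe{
#'   \item{vac}{baseline -250..0 re stimulus; visual +5..+150 re stimulus;
#'     presaccadic -100..0 re saccade; postsaccadic 0..+500 re saccade.}
#'   \item{outcome}{background -200..0 re stimulus; visual +40..+150 re
#'     stimulus; presaccadic -150..0 re saccade.}
#'   \item{identity}{visual window +40..+150 re stimulus.}
#' }
#'
#' @param scheme one of `"vac"`, `"outcome"`, `"identity"`.
#' @return data.frame with columns `epoch`, `align`, `startMs`, `endMs`.
#' @export
epochScheme <- function(scheme = c("vac", "outcome", "identity")) {
  scheme <- match.arg(scheme)
  out <- switch(scheme,
    vac = data.frame(
      epoch = c("baseline", "visual", "presaccadic", "postsaccadic"),
      align = c("stimulus_onset", "stimulus_onset",
                "saccade_onset", "saccade_onset"),
      startMs = c(-250, 5, -100, 0),
      endMs = c(0, 150, 0, 500)),
    outcome = data.frame(
      epoch = c("background", "visual", "presaccadic"),
      align = c("stimulus_onset", "stimulus_onset", "saccade_onset"),
      startMs = c(-200, 40, -150),
      endMs = c(0, 150, 0)),
    identity = data.frame(
      epoch = "visual", align = "stimulus_onset",
      startMs = 40, endMs = 150))
  stopifnot(all(out$startMs < out$endMs))
  out
}
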