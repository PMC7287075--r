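## Resampling machinery and unit-level hypothesis tests: bootstrap
## distributions, label-shuffle (permutation) tests, the best/worst stimulus
## identity test, outcome (correct vs. incorrect) effects, Kruskal-Wallis
## explanatory-variable panels, and prior-reward effects on firing.

#' Bootstrap distribution of a statistic
#'
#' Draws `n` resamples of the observations with replacement, applies the
#' statistic, and returns the resampled distribution with a percentile 95%
#' confidence interval. Deterministic given the seed.
#'
#' @param x observation vector (length >= 2 unless `statistic` handles less).
#' @param statistic function of a numeric vector returning a scalar.
#' @param n number of bootstrap iterations (default 10,000).
#' @param seed optional integer seed.
#' @return list with `dist` (length `n`), `ci` (2.5/97.5 percentiles),
#'   `observed`.
#' @export
bootstrapDistribution <- function(x, statistic = mean, n = 10000,
                                  seed = NULL) {
  withSeed(seed, {
    d <- vapply(seq_len(n), function(i)
      statistic(x[sample.int(length(x), replace = TRUE)]), numeric(1))
    list(dist = d, ci = quantile(d, c(0.025, 0.975), names = FALSE),
         observed = statistic(x))
  })
}

#' Label-shuffle (random permutation) test
#'
#' Permutes the explanatory-variable labels among trials — each label occurs
#' as many times in every shuffle as in the original data — and compares the
#' observed statistic with the permutation null. The p value uses the
#' add-one convention `p = (1 + #(null >= observed)) / (1 + nPerm)`, so it is
#' never exactly zero.
#'
#' @param labels trial labels (>= 2 distinct levels).
#' @param responses per-trial responses.
#' @param statistic function `(labels, responses) -> scalar`; larger =
#'   stronger apparent tuning.
#' @param nPerm number of permutations.
#' @param seed optional integer seed.
#' @return list of class `ShuffleResult`: `observed`, `null` (length
#'   `nPerm`), `p`, `nPerm`.
#' @export
shuffleTest <- function(labels, responses, statistic, nPerm = 1000,
                        seed = NULL) {
  if (length(unique(labels)) < 2L)
    stop("shuffle test needs at least 2 label levels")
  withSeed(seed, {
    obs <- statistic(labels, responses)
    null <- vapply(seq_len(nPerm), function(i)
      statistic(sample(labels), responses), numeric(1))
    structure(list(observed = obs, null = null,
                   p = (1 + sum(null >= obs)) / (1 + nPerm), nPerm = nPerm),
              class = "ShuffleResult")
  })
}

#' @export
print.ShuffleResult <- function(x, ...) {
  cat(sprintf("ShuffleResult: observed %.4g, p = %.4g (%d permutations)\n",
              x$observed, x$p, x$nPerm))
  invisible(x)
}

## best/worst mean z for one unit, ties toward the lower stimulus rank
bestWorstMeans <- function(z, stim) {
  m <- tapply(z, stim, mean)
  m <- m[order(as.numeric(names(m)))]
  c(best = m[[which.max(m)]], worst = m[[which.min(m)]])
}

#' Best/worst stimulus identity test across units
#'
#' For each unit, the mean z-scored visual-epoch rate of its apparently best
#' (argmax across stimuli) and worst stimulus is compared with the same
#' quantities computed after shuffling the stimulus labels among trials —
#' the control for preferences that arise by chance from finite sampling.
#' Across units, a paired t-test compares the observed best-worst span with
#' the shuffled one. Applied to single-stimulus trials it probes inherent
#' visual selectivity; applied to the first 250 choice trials vs. later
#' choice trials it probes the transient rank code that appears during
#' learning and disappears at plateau.
#'
#' @param unitData list with one entry per unit, each a list/data.frame with
#'   `z` (per-trial z rates in the identity window) and `stim` (stimulus rank
#'   labels). Units missing a stimulus are excluded with a notice.
#' @param nShuffle label shuffles per unit (their best/worst means are
#'   averaged).
#' @param seed optional integer seed.
#' @return list with `perUnit` (data.frame of observed and shuffled best and
#'   worst means), `test` (paired t-test on best-worst spans), `nExcluded`.
#' @export
bestWorstIdentityTest <- function(unitData, nShuffle = 1, seed = NULL) {
  withSeed(seed, {
    rows <- list(); excl <- 0L
    for (u in seq_along(unitData)) {
      z <- unitData[[u]]$z; stim <- unitData[[u]]$stim
      ok <- !is.na(z)
      z <- z[ok]; stim <- stim[ok]
      if (length(unique(stim)) < 2L || !length(z)) { excl <- excl + 1L; next }
      obs <- bestWorstMeans(z, stim)
      sh <- rowMeans(vapply(seq_len(nShuffle), function(i)
        bestWorstMeans(z, sample(stim)), numeric(2)))
      rows[[length(rows) + 1L]] <- data.frame(
        unit = u, best = obs["best"], worst = obs["worst"],
        bestShuf = sh["best"], worstShuf = sh["worst"])
    }
    if (excl) message(excl, " unit(s) excluded (missing stimulus levels)")
    per <- do.call(rbind, rows)
    rownames(per) <- NULL
    spanObs <- per$best - per$worst
    spanShuf <- per$bestShuf - per$worstShuf
    tt <- t.test(spanObs, spanShuf, paired = TRUE)
    list(perUnit = per,
         test = list(meanObs = mean(spanObs), meanShuf = mean(spanShuf),
                     t = unname(tt$statistic), p = tt$p.value, n = nrow(per)),
         nExcluded = excl)
  })
}

## eta-squared from a Kruskal-Wallis H (rank-based effect size)
kruskalEta2 <- function(H, k, n) max(0, (H - k + 1) / (n - k))

#' Outcome (correct vs. incorrect) effects per unit and epoch
#'
#' For each unit and epoch, a Wilcoxon rank-sum test of spike counts on
#' correct vs. incorrect trials at alpha = 0.05, with a rank-based
#' eta-squared effect size. Units with only one outcome present are skipped.
#'
#' @param counts list (one per unit) of matrices trials x epochs, or a single
#'   matrix for one unit.
#' @param outcomes logical per-trial correctness (shared across units).
#' @param epochNames optional epoch names (defaults to matrix colnames).
#' @param alpha significance criterion.
#' @return list with `table` (unit x epoch rows: `p`, `eta2`, `significant`)
#'   and `summary` (per epoch: fraction significant and mean effect size).
#' @export
outcomeEffectTests <- function(counts, outcomes, epochNames = NULL,
                               alpha = 0.05) {
  if (is.matrix(counts)) counts <- list(counts)
  if (length(unique(outcomes[!is.na(outcomes)])) < 2L)
    stop("both outcomes must be present")
  rows <- list()
  for (u in seq_along(counts)) {
    m <- counts[[u]]
    eps <- epochNames
    if (is.null(eps)) eps <- colnames(m)
    if (is.null(eps)) eps <- paste0("epoch", seq_len(ncol(m)))
    for (j in seq_len(ncol(m))) {
      x <- m[outcomes %in% TRUE, j]; y <- m[outcomes %in% FALSE, j]
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      if (!length(x) || !length(y)) next
      p <- suppressWarnings(wilcox.test(x, y)$p.value)
      kw <- suppressWarnings(
        kruskal.test(c(x, y), factor(rep(1:2, c(length(x), length(y))))))
      eta <- kruskalEta2(unname(kw$statistic), 2L, length(x) + length(y))
      rows[[length(rows) + 1L]] <- data.frame(
        unit = u, epoch = eps[j], p = p, eta2 = eta,
        significant = p < alpha)
    }
  }
  tab <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(tab, tab$epoch), function(d)
    data.frame(epoch = d$epoch[1], fracSignificant = mean(d$significant),
               meanEta2 = mean(d$eta2))))
  rownames(summary) <- NULL
  list(table = tab, summary = summary)
}

#' Kruskal-Wallis explanatory-variable panel
#'
#' Independent Kruskal-Wallis tests of each unit's spike counts against each
#' explanatory factor (e.g. target location, saccade direction, outcome) at
#' alpha = 0.05, with rank-based generalized eta-squared effect sizes.
#' Factors with fewer than 2 levels are skipped.
#'
#' @param counts list of per-unit count vectors (or a single vector).
#' @param factors data.frame of per-trial factors (shared across units).
#' @param alpha significance criterion.
#' @return list with `table` (unit x factor rows) and `summary` (per factor:
#'   fraction of significant units, mean effect size among significant
#'   units).
#' @export
kruskalEffectPanel <- function(counts, factors, alpha = 0.05) {
  if (!is.list(counts) || is.data.frame(counts)) counts <- list(counts)
  rows <- list()
  for (u in seq_along(counts)) {
    x <- counts[[u]]
    for (f in names(factors)) {
      g <- factor(factors[[f]])
      ok <- !is.na(x) & !is.na(g)
      if (length(unique(g[ok])) < 2L) next
      kw <- suppressWarnings(kruskal.test(x[ok], droplevels(g[ok])))
      H <- unname(kw$statistic)
      k <- length(unique(g[ok]))
      rows[[length(rows) + 1L]] <- data.frame(
        unit = u, factor = f, H = H, p = kw$p.value,
        eta2 = kruskalEta2(H, k, sum(ok)),
        significant = kw$p.value < alpha)
    }
  }
  tab <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(tab, tab$factor), function(d)
    data.frame(factor = d$factor[1], fracSignificant = mean(d$significant),
               meanEta2Significant = if (any(d$significant))
                 mean(d$eta2[d$significant]) else NA_real_)))
  rownames(summary) <- NULL
  list(table = tab, summary = summary)
}

#' Effect of the previous trial's outcome on firing rate
#'
#' Compares the firing rate between stimulus onset and the choice saccade on
#' trials following a rewarded vs. an unrewarded trial, separately for
#' saccades toward and away from the receptive field. The first trial (no
#' predecessor) is excluded.
#'
#' @param rates per-trial stimulus-to-saccade rates (sp/s), in trial order.
#' @param rewarded per-trial reward outcomes, in trial order.
#' @param saccadeTowardRF logical per trial.
#' @return data.frame with one row per saccade direction: `direction`,
#'   `meanDiff` (after-reward minus after-no-reward, sp/s), `p` (Welch
#'   t-test), `nAfterReward`, `nAfterNoReward`.
#' @export
priorRewardNeuralTest <- function(rates, rewarded, saccadeTowardRF) {
  n <- length(rates)
  stopifnot(length(rewarded) == n, length(saccadeTowardRF) == n)
  prev <- c(NA, rewarded[-n])
  out <- list()
  for (dir in c(TRUE, FALSE)) {
    sel <- !is.na(prev) & saccadeTowardRF == dir & !is.na(rates)
    a <- rates[sel & prev %in% TRUE]; b <- rates[sel & prev %in% FALSE]
    if (length(a) < 2L || length(b) < 2L)
      stop("need at least 2 trials in each previous-outcome condition")
    tt <- t.test(a, b)
    out[[length(out) + 1L]] <- data.frame(
      direction = if (dir) "towardRF" else "awayRF",
      meanDiff = mean(a) - mean(b), p = tt$p.value,
      nAfterReward = length(a), nAfterNoReward = length(b))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
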