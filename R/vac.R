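## Variance-accounted-for (VAC) quantification: 10-ms spike counts are
## smoothed by Gaussian-process regression over (trial, time, joint rank,
## symbolic distance), averaged within named epochs, baseline-subtracted,
## and the variance accounted for by JR or SD is measured as partial
## eta-squared from Welch's unequal-variance one-way F test.

#' Bin spikes into fixed-width count bins within an epoch
#'
#' @param spikes sorted session spike times.
#' @param trials trial table.
#' @param window a fixed-end [epochWindow()] (or an [epochScheme()] row).
#' @param binMs bin width, ms (default 10).
#' @return integer matrix trials x bins; attribute `"binCentersMs"` gives the
#'   bin centers relative to the alignment event.
#' @export
binCounts <- function(spikes, trials, window, binMs = 10) {
  if (is.data.frame(window))
    window <- epochWindow(window$align[1], window$startMs[1], window$endMs[1])
  if (is.null(window$endMs)) stop("binCounts needs a fixed-end window")
  edges <- seq(window$startMs, window$endMs, by = binMs) / 1000
  ev <- eventTimes(trials, window$align)
  nb <- length(edges) - 1L
  out <- matrix(0L, nrow(trials), nb)
  for (i in seq_len(nrow(trials))) {
    if (is.na(ev[i])) { out[i, ] <- NA_integer_; next }
    cum <- findInterval(ev[i] + edges, spikes, left.open = TRUE)
    out[i, ] <- diff(cum)
  }
  attr(out, "binCentersMs") <- (head(edges, -1) + tail(edges, -1)) / 2 * 1000
  out
}

medianHeuristic <- function(x, fallback = 1) {
  d <- abs(outer(x, x, `-`))
  m <- median(d[upper.tri(d)])
  if (!is.finite(m) || m == 0) fallback else m
}

#' Gaussian-process smoothing of binned spike counts
#'
#' Smooths square-root-transformed counts with a Gaussian-process prior whose
#' covariance is a product of a squared-exponential kernel over trial
#' covariates (trial index, joint rank, symbolic distance, each with its own
#' length-scale) and a squared-exponential kernel over within-epoch time.
#' The variance-stabilizing square-root transform makes the observation model
#' Gaussian, so the posterior is exact; the product (Kronecker) structure of
#' the covariance keeps it cheap via separate eigendecompositions. Signal and
#' noise variances are fit by maximizing the marginal likelihood;
#' length-scales default to the median heuristic on trial index and fixed
#' values on the ordinal covariates. If the optimizer fails, fixed
#' variance-heuristic hyperparameters are used with a notice.
#'
#' The prior encodes the smoothing assumption that trials at similar times in
#' learning and with similar symbolic distance and joint rank should display
#' similar activity.
#'
#' @param counts matrix trials x bins from [binCounts()].
#' @param covariates data.frame with per-trial `trial`, `jr`, `sd`.
#' @param binCentersMs bin centers, ms (defaults to the `counts` attribute).
#' @param lengthScales named list overriding `trial`, `jr`, `sd` (covariate
#'   units) and `time` (ms) length-scales.
#' @return list with `rate` (posterior-mean rate, sp/s, trials x bins), `sd`
#'   (posterior SD on the same scale), `sqrtMean` (posterior mean on the
#'   sqrt-count scale) and `hyper`.
#' @export
gprSmooth <- function(counts, covariates, binCentersMs = NULL,
                      lengthScales = list()) {
  if (is.null(binCentersMs)) binCentersMs <- attr(counts, "binCentersMs")
  stopifnot(nrow(counts) == nrow(covariates), !is.null(binCentersMs))
  if (length(unique(covariates$jr)) < 2L ||
      length(unique(covariates$sd)) < 2L)
    stop("need at least 2 levels of each covariate")
  ls <- list(trial = medianHeuristic(covariates$trial, 50) / 2,
             jr = 2, sd = 1.5, time = 25)
  ls[names(lengthScales)] <- lengthScales
  binMs <- diff(binCentersMs[1:2])
  y <- sqrt(counts + 3 / 8)
  mu <- mean(y)
  yc <- y - mu
  sq <- function(x, l) outer(x, x, `-`)^2 / l^2
  K1 <- exp(-0.5 * (sq(covariates$trial, ls$trial) +
                    sq(covariates$jr, ls$jr) + sq(covariates$sd, ls$sd)))
  K2 <- exp(-0.5 * sq(binCentersMs, ls$time))
  e1 <- eigen(K1, symmetric = TRUE)
  e2 <- eigen(K2, symmetric = TRUE)
  lam <- pmax(outer(e1$values, e2$values), 0)
  yt <- crossprod(e1$vectors, yc %*% e2$vectors)
  v <- var(as.numeric(yc))
  scale <- 1000 / binMs
  if (v < 1e-12) {
    # constant counts: the posterior is the flat mean with no uncertainty
    flat <- matrix(mu, nrow(counts), ncol(counts))
    return(list(rate = flat^2 * scale, sd = 0 * flat, sqrtMean = flat,
                hyper = list(signalVar = 0, noiseVar = 0,
                             lengthScales = ls)))
  }
  nll <- function(p) {
    s2 <- exp(p[1]); n2 <- exp(p[2])
    d <- s2 * lam + n2
    0.5 * (sum(log(d)) + sum(yt^2 / d))
  }
  hyp <- tryCatch({
    op <- optim(log(c(v, v / 2)), nll, method = "Nelder-Mead",
                control = list(maxit = 300))
    exp(op$par)
  }, error = function(e) {
    message("marginal-likelihood fit failed; using variance heuristic")
    c(v, v / 2)
  })
  s2 <- hyp[1]; n2 <- hyp[2]
  d <- s2 * lam + n2
  M <- e1$vectors %*% (yt * (s2 * lam / d)) %*% t(e2$vectors) + mu
  Vp <- (e1$vectors^2) %*% (s2 * lam - (s2 * lam)^2 / d) %*% t(e2$vectors^2)
  Vp <- pmax(Vp, 0)
  rate <- pmax(M, 0)^2 * scale
  rateSd <- 2 * pmax(M, 0) * sqrt(Vp) * scale   # delta method
  list(rate = rate, sd = rateSd, sqrtMean = M,
       hyper = list(signalVar = s2, noiseVar = n2, lengthScales = ls))
}

#' Per-trial GP-smoothed epoch rates for one unit
#'
#' For each epoch of the scheme, bins the unit's spikes at `binMs`, smooths
#' the counts with [gprSmooth()] over (trial, time, JR, SD), and averages the
#' posterior-mean rate within the epoch, yielding one smoothed rate per
#' choice trial and epoch.
#'
#' @param spikes sorted session spike times.
#' @param trials trial table; only choice (phase-2) trials are used.
#' @param scheme an [epochScheme()] table (default the 4-epoch VAC scheme).
#' @param binMs count bin width, ms.
#' @param ... passed to [gprSmooth()].
#' @return list with `rates` (matrix choice-trials x epochs) and `trials`
#'   (the choice-trial table used).
#' @export
vacEpochRates <- function(spikes, trials, scheme = epochScheme("vac"),
                          binMs = 10, ...) {
  tr <- trials[trials$phase == 2L, , drop = FALSE]
  covar <- data.frame(trial = tr$choiceTrial, jr = tr$jr, sd = tr$sd)
  rates <- sapply(seq_len(nrow(scheme)), function(k) {
    cnt <- binCounts(spikes, tr, scheme[k, ], binMs = binMs)
    sm <- gprSmooth(cnt, covar, ...)
    rowMeans(sm$rate)
  })
  colnames(rates) <- scheme$epoch
  list(rates = rates, trials = tr)
}

#' Partial eta-squared from an F statistic
#'
#' `eta_p^2 = F * df1 / (F * df1 + df2)`.
#'
#' @param F F statistic.
#' @param df1,df2 numerator and denominator degrees of freedom.
#' @return partial eta-squared in \[0, 1\].
#' @export
partialEta2FromF <- function(F, df1, df2) F * df1 / (F * df1 + df2)

#' Welch-test partial eta-squared for one grouping variable
#'
#' Subtracts the per-trial baseline (if given), runs Welch's one-way F test
#' for unequal variances across the levels of the grouping variable, and
#' converts it to partial eta-squared:
#' `eta_p^2 = F * df1 / (F * df1 + df2)`.
#'
#' @param values per-trial epoch-averaged rates.
#' @param groups per-trial variable level (joint rank or symbolic distance).
#' @param baseline optional per-trial baseline rates to subtract.
#' @return list with `F`, `df1`, `df2`, `etaP2`.
#' @export
welchPartialEta2 <- function(values, groups, baseline = NULL) {
  if (!is.null(baseline)) values <- values - baseline
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 group levels")
  tab <- table(groups)
  if (any(tab < 2L))
    stop("level(s) with fewer than 2 observations: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  vz <- tapply(values, groups, var)
  if (any(vz == 0))
    stop("level(s) with zero variance: ",
         paste(names(vz)[vz == 0], collapse = ", "))
  wt <- oneway.test(values ~ groups, var.equal = FALSE)
  Fv <- unname(wt$statistic)
  df1 <- unname(wt$parameter[1]); df2 <- unname(wt$parameter[2])
  list(F = Fv, df1 = df1, df2 = df2, etaP2 = partialEta2FromF(Fv, df1, df2))
}

#' Full VAC table for one unit
#'
#' Computes [vacEpochRates()], subtracts the baseline epoch per trial, and
#' returns the Welch partial eta-squared for joint rank and symbolic distance
#' in every post-baseline epoch. Optionally excludes the extreme joint-rank
#' levels (3 and 13, the unique-pair levels) before testing.
#'
#' @param spikes sorted session spike times.
#' @param trials trial table.
#' @param scheme epoch scheme; the first epoch is treated as the baseline.
#' @param excludeExtremeJr drop trials with JR in `c(3, 13)`.
#' @param ... passed to [vacEpochRates()].
#' @return data.frame with columns `epoch`, `variable`, `F`, `df1`, `df2`,
#'   `etaP2`.
#' @export
computeVac <- function(spikes, trials, scheme = epochScheme("vac"),
                       excludeExtremeJr = FALSE, ...) {
  er <- vacEpochRates(spikes, trials, scheme = scheme, ...)
  rates <- er$rates; tr <- er$trials
  if (excludeExtremeJr) {
    keep <- !(tr$jr %in% c(3L, 13L))
    rates <- rates[keep, , drop = FALSE]; tr <- tr[keep, , drop = FALSE]
  }
  base <- rates[, 1]
  out <- list()
  for (ep in colnames(rates)[-1]) {
    for (vn in c("jr", "sd")) {
      w <- welchPartialEta2(rates[, ep], tr[[vn]], baseline = base)
      out[[paste(ep, vn)]] <- data.frame(
        epoch = ep, variable = vn, F = w$F, df1 = w$df1, df2 = w$df2,
        etaP2 = w$etaP2)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Joint-rank vs. symbolic-distance VAC comparison across units
#'
#' Pairs per-unit VAC values for the two variables in one epoch, reports
#' their Spearman rank correlation and the counts of units in which each
#' variable dominates.
#'
#' @param vacJr,vacSd per-unit partial eta-squared for joint rank and
#'   symbolic distance (equal length, paired by unit).
#' @return list with `rs` (Spearman correlation), `p`, `nJrGreater`,
#'   `nSdGreater`, and the paired `table`.
#' @export
vacScatter <- function(vacJr, vacSd) {
  stopifnot(length(vacJr) == length(vacSd))
  ct <- suppressWarnings(cor.test(vacJr, vacSd, method = "spearman"))
  list(rs = unname(ct$estimate), p = ct$p.value,
       nJrGreater = sum(vacJr > vacSd), nSdGreater = sum(vacSd > vacJr),
       table = data.frame(unit = seq_along(vacJr), jr = vacJr, sd = vacSd))
}
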