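## Population analyses: hierarchical clustering of temporal profiles on
## correlation distance, preferred-condition sorting, and optimal linear
## estimator (OLE) decoding of joint rank / symbolic distance with bootstrap
## confidence intervals.

#' Z-scored temporal response profiles of a population
#'
#' For each unit, KDE-smooths the mean firing rate vs. time across all trials
#' (all conditions), then z-standardizes the profile over time. These are the
#' inputs to [clusterProfiles()].
#'
#' @param pop a `SpikeTrainSet` from [simulatePopulation()] (or a list of
#'   spike-time vectors).
#' @param trials trial table shared by the units.
#' @param align alignment event.
#' @param range profile time range, seconds.
#' @param bandwidthMs PSTH bandwidth (fixed, for comparability across units).
#' @param gridMs profile grid step, ms.
#' @return matrix units x time of z-scored mean rates.
#' @export
unitTemporalProfiles <- function(pop, trials, align = "stimulus_onset",
                                 range = c(-0.25, 1), bandwidthMs = 20,
                                 gridMs = 5) {
  spk <- if (is(pop, "SpikeTrainSet")) pop@spikes else pop
  ev <- eventTimes(trials, align)
  prof <- t(vapply(spk, function(s) {
    rel <- unlist(lapply(ev, function(e) {
      x <- s[s >= e + range[1] & s < e + range[2]]
      x - e
    }))
    kdeRate(rel, nrow(trials), range = range, gridMs = gridMs,
            bandwidthMs = bandwidthMs)$rate
  }, numeric(length(seq(range[1], range[2], by = gridMs / 1000)))))
  t(apply(prof, 1, function(r) {
    s <- sqrt(mean((r - mean(r))^2))
    if (s == 0) rep(NA_real_, length(r)) else (r - mean(r)) / s
  }))
}

#' Cluster temporal profiles by correlation similarity
#'
#' Agglomerative hierarchical clustering of per-unit z-scored temporal
#' profiles using distance `1 - Pearson r` and average linkage, cut at
#' `r = cutoffR` (distance `1 - cutoffR`, default 0.3). Units with constant
#' (zero-variance) profiles, for which correlation is undefined, are excluded
#' with a notice. The dendrogram leaves are reordered so that adjacent units
#' are similar (weights given by the first principal component of the
#' profiles).
#'
#' @param profiles matrix units x time (e.g. from [unitTemporalProfiles()]).
#' @param cutoffR correlation cutoff for cluster membership, in (0, 1).
#' @param linkage linkage method for [stats::hclust()].
#' @return list with `labels` (cluster id per retained unit), `nClusters`,
#'   `hclust`, `order` (optimal leaf order, indices into retained units),
#'   `excluded` (indices of dropped units).
#' @export
clusterProfiles <- function(profiles, cutoffR = 0.7, linkage = "average") {
  if (cutoffR <= 0 || cutoffR >= 1) stop("cutoffR must be in (0, 1)")
  if (nrow(profiles) < 2L) stop("need at least 2 profiles")
  sds <- apply(profiles, 1, sd)
  excluded <- which(is.na(sds) | sds == 0 | apply(is.na(profiles), 1, any))
  keep <- setdiff(seq_len(nrow(profiles)), excluded)
  if (length(excluded))
    message(length(excluded), " constant profile(s) excluded from clustering")
  if (length(keep) < 2L) stop("fewer than 2 usable profiles")
  p <- profiles[keep, , drop = FALSE]
  d <- as.dist(1 - cor(t(p)))
  hc <- hclust(d, method = linkage)
  labels <- cutree(hc, h = 1 - cutoffR)
  wts <- prcomp(p, center = TRUE, scale. = FALSE)$x[, 1]
  dend <- reorder(as.dendrogram(hc), wts, agglo.FUN = mean)
  list(labels = labels, nClusters = length(unique(labels)), hclust = hc,
       order = order.dendrogram(dend), excluded = excluded, units = keep)
}

#' Sort units by preferred condition level
#'
#' Orders units by the level (of joint rank or symbolic distance) at which
#' their mean z-scored rate is maximal; ties are broken toward the lower
#' level, and units with the same preference keep their id order (stable).
#'
#' @param zByLevel matrix units x levels of mean z-scored rates (all levels
#'   estimated for every unit).
#' @return list with `order` (unit indices) and `preferred` (argmax level
#'   index per unit, in input order).
#' @export
preferredConditionSort <- function(zByLevel) {
  if (any(is.na(zByLevel))) stop("every unit needs every level estimated")
  pref <- apply(zByLevel, 1, which.max)   # which.max: first (lowest) on ties
  list(order = order(pref, seq_len(nrow(zByLevel))), preferred = pref)
}

#' @rdname oleFit
#' @export
setClass("OleModel",
  representation(weights = "numeric", intercept = "numeric",
                 trainIdx = "integer"),
  validity = function(object) {
    if (any(!is.finite(object@weights)) || !is.finite(object@intercept))
      "weights and intercept must be finite" else TRUE
  })

#' Optimal linear estimator of a scalar trial variable
#'
#' Fits the least-squares linear readout of a scalar variable (joint rank or
#' symbolic distance) from the population vector of z-scored rates:
#' `y ~ intercept + X w`, minimizing squared prediction error on the training
#' trials. A rank-deficient design yields the minimum-norm least-squares
#' solution, with a warning.
#'
#' @param X matrix trials x units of z-scored rates.
#' @param y target per trial (must vary).
#' @param trainIdx optional training-trial indices (default all).
#' @return An `OleModel`.
#' @export
oleFit <- function(X, y, trainIdx = seq_len(nrow(X))) {
  X <- as.matrix(X)
  if (var(y[trainIdx]) == 0) {
    return(new("OleModel", weights = rep(0, ncol(X)),
               intercept = mean(y[trainIdx]),
               trainIdx = as.integer(trainIdx)))
  }
  Xt <- X[trainIdx, , drop = FALSE]
  Xc <- sweep(Xt, 2, colMeans(Xt))
  yc <- y[trainIdx] - mean(y[trainIdx])
  sv <- svd(Xc)
  tol <- max(dim(Xc)) * .Machine$double.eps * sv$d[1]
  pos <- sv$d > tol
  if (sum(pos) < ncol(Xc))
    warning("rank-deficient design: returning minimum-norm solution")
  w <- sv$v[, pos, drop = FALSE] %*%
    ((crossprod(sv$u[, pos, drop = FALSE], yc)) / sv$d[pos])
  w <- as.numeric(w)
  b <- mean(y[trainIdx]) - sum(colMeans(Xt) * w)
  new("OleModel", weights = w, intercept = b, trainIdx = as.integer(trainIdx))
}

#' @rdname oleFit
#' @param model an `OleModel`.
#' @export
olePredict <- function(model, X) {
  as.numeric(as.matrix(X) %*% model@weights + model@intercept)
}

setMethod("show", "OleModel", function(object) {
  cat(sprintf("OleModel: %d units, intercept %.3f, %d training trials\n",
              length(object@weights), object@intercept,
              length(object@trainIdx)))
})

#' OLE decoding with bootstrap confidence intervals
#'
#' Decodes the target variable per level: trials are resampled with
#' replacement, the OLE is refit on each resample, and the mean prediction
#' per target level is recorded. The point estimate is from the full-data
#' fit; the 95% CI are the 2.5/97.5 bootstrap percentiles. Optionally the
#' analysis is run separately for early (choice trial <= `splitAt`) and late
#' trials, to compare decoding before and after learning has stabilized.
#'
#' @param X matrix trials x units of z-scored rates.
#' @param y target per trial (joint rank or symbolic distance).
#' @param nBoot bootstrap iterations (10,000 for final figures; smaller
#'   values give a fast mode).
#' @param seed integer seed.
#' @param splitAt optional choice-trial index separating early from late
#'   trials; requires `trialIndex`.
#' @param trialIndex per-trial choice index (needed with `splitAt`).
#' @return data.frame with one row per (segment, level): `segment`, `level`,
#'   `estimate`, `lo`, `hi`, plus attribute `"rmse"` giving per-segment
#'   root-mean-square decoding error.
#' @export
oleDecodeBootstrap <- function(X, y, nBoot = 1000, seed = NULL,
                               splitAt = NULL, trialIndex = NULL) {
  X <- as.matrix(X)
  segs <- list(all = seq_len(nrow(X)))
  if (!is.null(splitAt)) {
    if (is.null(trialIndex)) stop("splitAt requires trialIndex")
    segs <- list(early = which(trialIndex <= splitAt),
                 late = which(trialIndex > splitAt))
  }
  withSeed(seed, {
    out <- list(); rmse <- numeric(0)
    for (nm in names(segs)) {
      idx <- segs[[nm]]
      Xs <- X[idx, , drop = FALSE]; ys <- y[idx]
      lev <- sort(unique(ys))
      full <- oleFit(Xs, ys)
      pred <- olePredict(full, Xs)
      est <- vapply(lev, function(L) mean(pred[ys == L]), numeric(1))
      rmse[nm] <- sqrt(mean((pred - ys)^2))
      bootMat <- matrix(NA_real_, nBoot, length(lev))
      for (b in seq_len(nBoot)) {
        rs <- sample.int(length(ys), replace = TRUE)
        if (var(ys[rs]) == 0) { rs <- seq_along(ys) }
        m <- suppressWarnings(oleFit(Xs[rs, , drop = FALSE], ys[rs]))
        pb <- olePredict(m, Xs[rs, , drop = FALSE])
        bootMat[b, ] <- vapply(lev, function(L) {
          sel <- ys[rs] == L
          if (any(sel)) mean(pb[sel]) else NA_real_
        }, numeric(1))
      }
      ci <- apply(bootMat, 2, quantile, probs = c(0.025, 0.975), na.rm = TRUE)
      out[[nm]] <- data.frame(segment = nm, level = lev, estimate = est,
                              lo = ci[1, ], hi = ci[2, ])
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    attr(res, "rmse") <- rmse
    res
  })
}
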