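## Session-bundle container and on-disk persistence. A bundle is one session
## of one list: manifest + trial table + per-unit spike times + optional eye
## traces. Tables are plain delimited text with full-precision (%.17g)
## doubles so that read(write(x)) reproduces x bit-exactly; eye traces are
## flat binary float64 arrays with a small header.

SCHEMA_VERSION <- "1.0"

#' @rdname sessionBundle
#' @export
setClass("SessionBundle",
  representation(manifest = "list", trials = "data.frame", spikes = "list",
                 unitInfo = "data.frame", eye = "list"),
  validity = function(object) {
    msg <- character()
    tr <- object@trials
    if (!identical(tr$trial, seq_len(nrow(tr))))
      msg <- c(msg, "trial indices must be contiguous from 1")
    if (length(object@spikes) != nrow(object@unitInfo))
      msg <- c(msg, "unitInfo must have one row per unit")
    span <- c(min(tr$tStart) - 1, max(tr$tEnd) + 1)
    for (s in object@spikes) {
      if (is.unsorted(s)) { msg <- c(msg, "spike times must be sorted"); break }
      if (length(s) && (s[1] < span[1] || s[length(s)] > span[2])) {
        msg <- c(msg, "spike times outside session span"); break
      }
    }
    if (length(object@eye) && length(object@eye) != nrow(tr))
      msg <- c(msg, "eye traces must have one entry per trial")
    if (length(msg)) msg else TRUE
  })

#' Session bundle
#'
#' Container for one simulated (or recorded) session: manifest, trial table,
#' per-unit spike-time vectors, and optional 1 kHz eye traces.
#'
#' @param manifest named list of session metadata (subject, seeds, generator
#'   parameters); a schema version is added automatically.
#' @param trials trial table from [simulateSession()].
#' @param spikes list of sorted spike-time vectors.
#' @param unitInfo data.frame with one row per unit.
#' @param eye optional list of per-trial eye-trace matrices.
#' @return A `SessionBundle`.
#' @export
sessionBundle <- function(manifest = list(), trials, spikes = list(),
                          unitInfo = data.frame(unit = integer())[FALSE, ,
                                                                  drop = FALSE],
                          eye = list()) {
  manifest$schemaVersion <- SCHEMA_VERSION
  if (length(spikes) && nrow(unitInfo) == 0L)
    unitInfo <- data.frame(unit = seq_along(spikes))
  new("SessionBundle", manifest = manifest, trials = trials,
      spikes = spikes, unitInfo = unitInfo, eye = eye)
}

#' @rdname sessionBundle
#' @param x a `SessionBundle`.
#' @export
setGeneric("bundleTrials", function(x) standardGeneric("bundleTrials"))

#' @rdname sessionBundle
#' @export
setMethod("bundleTrials", "SessionBundle", function(x) x@trials)

#' @rdname sessionBundle
#' @export
setGeneric("bundleManifest", function(x) standardGeneric("bundleManifest"))

#' @rdname sessionBundle
#' @export
setMethod("bundleManifest", "SessionBundle", function(x) x@manifest)

setMethod("show", "SessionBundle", function(object) {
  cat("SessionBundle:", nrow(object@trials), "trials,",
      length(object@spikes), "units,",
      if (length(object@eye)) "with" else "no", "eye traces\n")
})

#' Simulate a complete session bundle
#'
#' Builds a schedule, runs the behavioral agent, simulates a unit population
#' on the resulting trials, and (optionally) generates eye traces, all from
#' one master seed with independent child streams.
#'
#' @param subject subject label stored in the manifest.
#' @param nItems list length.
#' @param nPairBlocks number of all-pairs blocks.
#' @param nUnits number of simulated units.
#' @param agent an [agentParams()].
#' @param unitParams optional list of [neuronParams()] (default
#'   [samplePopulationParams()] of size `nUnits`).
#' @param eye generate eye traces?
#' @param seed master integer seed.
#' @return A [sessionBundle()].
#' @export
simulateBundle <- function(subject = "sim", nItems = 7L, nPairBlocks = 20L,
                           nUnits = 0L, agent = agentParams(),
                           unitParams = NULL, eye = FALSE, seed = 1L) {
  seeds <- childSeeds(seed, 4L)
  lst <- stimulusList(nItems)
  sch <- buildSessionSchedule(lst, nPairBlocks, seed = seeds[1])
  trials <- simulateSession(sch, agent, seed = seeds[2])
  spikes <- list(); info <- data.frame(unit = integer(0))
  if (is.null(unitParams) && nUnits > 0L)
    unitParams <- samplePopulationParams(nUnits, seed = seeds[3])
  if (!is.null(unitParams)) {
    pop <- simulatePopulation(unitParams, trials, seed = seeds[3],
                              nList = nItems)
    spikes <- pop@spikes
    info <- unitInfo(pop)
  }
  eyeTr <- if (eye) generateEyeTrace(trials, seed = seeds[4]) else list()
  sessionBundle(
    manifest = list(subject = subject, seed = seed, nItems = nItems,
                    nPairBlocks = nPairBlocks,
                    agent = list(bSdMax = agent@bSdMax,
                                 tauLearn = agent@tauLearn,
                                 bTerm = agent@bTerm,
                                 pWinstay = agent@pWinstay,
                                 pLoseshiftStay = agent@pLoseshiftStay,
                                 rtMu = agent@rtMu, rtSigma = agent@rtSigma,
                                 rtSdSlope = agent@rtSdSlope)),
    trials = trials, spikes = spikes, unitInfo = info, eye = eyeTr)
}

## full-precision text formatting: %.17g round-trips IEEE doubles exactly
fmtNum <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

writeTsv <- function(df, path) {
  cols <- lapply(df, function(col) {
    if (is.double(col)) fmtNum(col)
    else { out <- as.character(col); out[is.na(col)] <- "NA"; out }
  })
  classes <- vapply(df, function(col) class(col)[1], character(1))
  header <- paste(names(df), classes, sep = ":")
  lines <- c(paste(header, collapse = "\t"),
             do.call(paste, c(cols, sep = "\t")))
  writeLines(lines, path)
}

readTsv <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(strsplit(lines[1], "\t")[[1]], ":")
  nms <- vapply(hdr, `[`, character(1), 1)
  cls <- vapply(hdr, `[`, character(1), 2)
  if (length(lines) == 1L) {
    cells <- rep(list(character(0)), length(nms))
  } else {
    body <- strsplit(lines[-1], "\t")
    cells <- lapply(seq_along(nms), function(j)
      vapply(body, `[`, character(1), j))
  }
  df <- as.data.frame(lapply(seq_along(nms), function(j) {
    x <- cells[[j]]
    switch(cls[j],
      numeric = as.numeric(ifelse(x == "NA", NA, x)),
      integer = as.integer(ifelse(x == "NA", NA, x)),
      logical = as.logical(ifelse(x == "NA", NA, x)),
      x)
  }), col.names = nms)
  names(df) <- nms
  df
}

#' Write / read a session bundle on disk
#'
#' `writeBundle()` lays the bundle out as a directory: `manifest.yaml`, the
#' trial table `trials.tsv` (typed header, full-precision doubles), per-unit
#' spike-time files `units/unit_###.txt`, a unit index, and per-trial eye
#' traces as binary float64 files with a dimension header. `readBundle()`
#' reconstructs the bundle, verifying the schema version, file integrity and
#' spike-time monotonicity; the round trip reproduces the bundle bit-exactly.
#'
#' @param bundle a [sessionBundle()].
#' @param path target directory (created; must not already have a manifest).
#' @return `writeBundle()` the path, invisibly; `readBundle()` a
#'   `SessionBundle`.
#' @export
writeBundle <- function(bundle, path) {
  stopifnot(is(bundle, "SessionBundle"))
  validObject(bundle)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(bundle@manifest, file.path(path, "manifest.yaml"),
                   precision = 17)
  writeTsv(bundle@trials, file.path(path, "trials.tsv"))
  writeTsv(bundle@unitInfo, file.path(path, "units.tsv"))
  if (length(bundle@spikes)) {
    dir.create(file.path(path, "units"), showWarnings = FALSE)
    for (u in seq_along(bundle@spikes))
      writeLines(fmtNum(bundle@spikes[[u]]),
                 file.path(path, "units", sprintf("unit_%03d.txt", u)))
  }
  if (length(bundle@eye)) {
    dir.create(file.path(path, "eye"), showWarnings = FALSE)
    for (i in seq_along(bundle@eye)) {
      m <- bundle@eye[[i]]
      con <- file(file.path(path, "eye", sprintf("trial_%05d.bin", i)), "wb")
      writeBin(as.numeric(c(nrow(m), ncol(m))), con, size = 8)
      writeBin(as.numeric(m), con, size = 8)
      close(con)
    }
  }
  invisible(path)
}

#' @rdname writeBundle
#' @export
readBundle <- function(path) {
  mf <- file.path(path, "manifest.yaml")
  if (!file.exists(mf)) stop("missing file: manifest.yaml")
  manifest <- yaml::read_yaml(mf)
  if (!identical(manifest$schemaVersion, SCHEMA_VERSION))
    stop("schema-version mismatch: bundle has ",
         manifest$schemaVersion %||% "<none>", ", expected ", SCHEMA_VERSION)
  trials <- readTsv(file.path(path, "trials.tsv"))
  unitInfoDf <- readTsv(file.path(path, "units.tsv"))
  spikes <- lapply(seq_len(nrow(unitInfoDf)), function(u) {
    f <- file.path(path, "units", sprintf("unit_%03d.txt", u))
    if (!file.exists(f)) stop("missing file: ", basename(f))
    s <- as.numeric(readLines(f))
    if (anyNA(s)) stop("corrupt spike file: ", basename(f))
    if (is.unsorted(s)) stop("non-monotone spike times in ", basename(f))
    s
  })
  eyeDir <- file.path(path, "eye")
  eye <- list()
  if (dir.exists(eyeDir)) {
    eye <- lapply(seq_len(nrow(trials)), function(i) {
      f <- file.path(eyeDir, sprintf("trial_%05d.bin", i))
      if (!file.exists(f)) stop("missing file: ", basename(f))
      con <- file(f, "rb")
      on.exit(close(con))
      dims <- readBin(con, "numeric", 2, size = 8)
      m <- matrix(readBin(con, "numeric", prod(dims), size = 8),
                  dims[1], dims[2])
      colnames(m) <- c("time", "h", "v")
      m
    })
  }
  b <- sessionBundle(manifest = manifest, trials = trials, spikes = spikes,
                     unitInfo = unitInfoDf, eye = eye)
  validObject(b)
  b
}

`%||%` <- function(a, b) if (is.null(a)) b else a
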