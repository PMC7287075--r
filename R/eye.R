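## Eye kinematics: Gaussian-derivative velocity filtering, radial speed, and
## threshold-based saccade latency detection.

#' Eye velocity by derivative-of-Gaussian filtering
#'
#' Convolves a uniformly sampled position trace with the first derivative of
#' a temporal Gaussian, `dG/dt = -k * t * exp(-t^2 / tau^2)` with `tau` = 8 ms
#' by default. (The negative exponent is the standard Gaussian-derivative
#' kernel; a positive exponent would diverge.) The kernel is symmetric about
#' zero, so the filter introduces no time shift between position input and
#' velocity output, and `k` is set so that the gain for a linear position
#' ramp is exactly 1.0 at the given sample rate. The first and last
#' half-kernel samples, where the convolution is incomplete, are returned as
#' `NA`.
#'
#' @param position numeric position series (degrees).
#' @param tauMs Gaussian width parameter, ms.
#' @param sampleRate samples per second (default 1 kHz).
#' @return velocity series in degrees/s, same length as `position`.
#' @export
gaussianDerivativeVelocity <- function(position, tauMs = 8,
                                       sampleRate = 1000) {
  if (tauMs <= 0) stop("tauMs must be > 0")
  tau <- tauMs / 1000
  half <- ceiling(4 * tau * sampleRate)
  tk <- (-half:half) / sampleRate
  g <- -tk * exp(-tk^2 / tau^2)
  k <- 1 / sum(tk^2 * exp(-tk^2 / tau^2))    # unit gain on ramps
  kern <- k * g
  n <- length(position)
  if (n < length(kern))
    stop("position series shorter than the filter kernel (",
         length(kern), " samples)")
  v <- as.numeric(stats::filter(position, kern, sides = 2))
  v
}

#' Radial eye speed
#'
#' Combines horizontal and vertical velocity into radial speed,
#' `r'(t) = sqrt(h'(t)^2 + v'(t)^2)`.
#'
#' @param hVel,vVel equal-length velocity series.
#' @return speed series.
#' @export
radialSpeed <- function(hVel, vVel) {
  if (length(hVel) != length(vVel))
    stop("hVel and vVel must have equal length")
  sqrt(hVel^2 + vVel^2)
}

#' Detect saccade latency from a radial speed trace
#'
#' Finds the first time after stimulus onset at which radial speed stays at
#' or above `threshold` for at least `sustainMs` consecutive samples, and
#' returns the latency of that crossing in ms. The default threshold is
#' 30 deg/s sustained for 5 ms.
#'
#' @param speed radial speed series (deg/s); `NA` entries are treated as
#'   below threshold.
#' @param times sample times, seconds (same clock as `onset`).
#' @param onset stimulus-onset time, seconds.
#' @param threshold speed threshold, deg/s.
#' @param sustainMs minimum supra-threshold duration, ms.
#' @param sampleRate samples per second.
#' @return latency in ms, or `NA` if no sustained crossing is found.
#' @export
detectSaccadeLatency <- function(speed, times, onset, threshold = 30,
                                 sustainMs = 5, sampleRate = 1000) {
  if (onset < min(times, na.rm = TRUE) || onset > max(times, na.rm = TRUE))
    stop("onset lies outside the sampled trace")
  need <- max(1L, round(sustainMs * sampleRate / 1000))
  above <- !is.na(speed) & speed >= threshold & times >= onset
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= need)
  if (!length(hit)) return(NA_real_)
  (times[starts[hit[1]]] - onset) * 1000
}
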