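# Gait segmentation: initial-contact detection from foot vertical
# acceleration, stride-time outlier rejection, and 101-point stride
# time normalization.

# Indices of local maxima; boundary samples count so a contact at the very
# start or end of a recording is still detectable.
find_local_maxima <- function(x) {
  n <- length(x)
  if (n < 2) return(integer(0))
  left <- c(-Inf, x[-n])
  right <- c(x[-1], -Inf)
  which(x > left & x >= right)
}

# Topographic prominence of peak i: height above the higher of the two key
# saddles (walk out each side until a strictly higher sample or the boundary).
# A peak sitting on a signal edge has no saddle on that side, so only the
# existing side constrains its prominence.
peak_prominence <- function(x, i) {
  h <- x[i]
  lmin <- Inf
  j <- i
  while (j > 1) {
    j <- j - 1
    if (x[j] > h) break
    lmin <- min(lmin, x[j])
  }
  rmin <- Inf
  j <- i
  n <- length(x)
  while (j < n) {
    j <- j + 1
    if (x[j] > h) break
    rmin <- min(rmin, x[j])
  }
  if (is.infinite(lmin)) lmin <- -Inf
  if (is.infinite(rmin)) rmin <- -Inf
  h - max(lmin, rmin)
}

#' Estimate the dominant stride time from foot vertical acceleration
#'
#' Median spacing of the dominant acceleration peaks (local maxima reaching
#' at least `height_frac` of the signal maximum). Useful as the
#' `expected_stride_s` prior of [detect_initial_contacts()] when the walking
#' speed is unknown.
#'
#' @param accel Numeric vector of vertical acceleration samples (g).
#' @param rate Sampling rate in Hz.
#' @param height_frac Fraction of the global maximum a peak must reach.
#' @return Estimated stride time in seconds.
#' @export
estimate_stride_time <- function(accel, rate, height_frac = 0.5) {
  cand <- find_local_maxima(accel)
  cand <- cand[accel[cand] >= height_frac * max(accel)]
  if (length(cand) < 2)
    stop("trial unsegmentable: no dominant peak spacing found")
  stats::median(diff(cand)) / rate
}

#' Detect initial contacts from foot vertical acceleration
#'
#' Initial contacts are taken as the greatest vertical acceleration peaks:
#' local maxima whose topographic prominence is at least
#' `prominence_factor` times a robust noise scale (the median absolute
#' deviation, scaled to be consistent with the SD for Gaussian noise), kept
#' greedily from the highest down subject to a minimum inter-peak distance of
#' `min_separation_frac * expected_stride_s`.
#'
#' @param accel Numeric vector of vertical acceleration samples (g).
#' @param rate Sampling rate in Hz.
#' @param expected_stride_s Rough expected stride time in seconds; only the
#'   minimum peak separation depends on it.
#' @param min_separation_frac Fraction of the expected stride used as the
#'   minimum separation between accepted peaks.
#' @param prominence_factor Multiple of the robust noise scale a peak's
#'   prominence must reach.
#' @param height_frac Optional: additionally require peaks to reach this
#'   fraction of the trial's maximum acceleration. The prominence rule alone
#'   is scale-free, so isolated noise maxima can pass it wherever stride-time
#'   jitter leaves room beyond the minimum separation; a height criterion
#'   anchored to the dominant impact transients implements the "greatest
#'   peaks" reading directly. `NULL` (default) disables it.
#' @return Increasing vector of contact times in seconds (0-based, first
#'   sample is time 0). Errors if fewer than two peaks survive, in which case
#'   the trial is unsegmentable.
#' @examples
#' cfg <- simulation_config(strides_per_trial = 8)
#' tr <- simulate_trial(cfg, "TD", "Dry", "Normal", seed = 3)
#' detect_initial_contacts(tr$accel_vertical, tr$imu_rate_hz, 1.1)
#' @export
detect_initial_contacts <- function(accel, rate, expected_stride_s,
                                    min_separation_frac = 0.5,
                                    prominence_factor = 2,
                                    height_frac = NULL) {
  if (rate <= 0 || expected_stride_s <= 0)
    stop("rate and expected_stride_s must be positive")
  cand <- find_local_maxima(accel)
  if (length(cand) > 0) {
    noise <- stats::mad(accel)
    prom <- vapply(cand, function(i) peak_prominence(accel, i), numeric(1))
    cand <- cand[prom >= prominence_factor * noise & prom > 0]
    if (!is.null(height_frac))
      cand <- cand[accel[cand] >= height_frac * max(accel)]
  }
  min_gap <- min_separation_frac * expected_stride_s * rate
  sel <- integer(0)
  for (i in cand[order(accel[cand], decreasing = TRUE)]) {
    if (all(abs(i - sel) >= min_gap)) sel <- c(sel, i)
  }
  if (length(sel) < 2)
    stop("trial unsegmentable: fewer than 2 acceleration peaks detected")
  (sort(sel) - 1) / rate
}

#' Flag stride-time outliers (3-SD rule)
#'
#' Single, non-iterative pass: a stride is an outlier iff its duration
#' deviates from the mean of all durations by more than three sample
#' standard deviations. With identical durations the SD is zero and nothing
#' is flagged.
#'
#' @param durations Numeric vector of stride durations (s), length >= 3.
#' @return Logical vector aligned to `durations`.
#' @examples
#' flag_stride_outliers(c(rep(1, 50), 2))  # only the 2 s stride
#' @export
flag_stride_outliers <- function(durations) {
  if (length(durations) < 3)
    stop("need at least 3 strides to apply the outlier rule")
  s <- stats::sd(durations)
  if (s == 0) return(rep(FALSE, length(durations)))
  abs(durations - mean(durations)) > 3 * s
}

#' Build a stride set from initial-contact times
#'
#' @param initial_contact_times_s Strictly increasing contact times (s).
#' @return Object of class `stride_set`: contact times, stride durations
#'   (successive differences), outlier flags from [flag_stride_outliers()],
#'   and the indices of retained (non-outlier) strides.
#' @export
build_stride_set <- function(initial_contact_times_s) {
  ics <- initial_contact_times_s
  if (length(ics) < 2 || any(diff(ics) <= 0))
    stop("initial contact times must be strictly increasing, length >= 2")
  dur <- diff(ics)
  # the 3-SD rule needs at least 3 strides to estimate a spread; shorter
  # stride sets are kept whole
  flags <- if (length(dur) >= 3) flag_stride_outliers(dur)
           else rep(FALSE, length(dur))
  structure(list(
    initial_contact_times_s = ics,
    stride_durations_s = dur,
    outlier_flags = flags,
    retained_stride_indices = which(!flags)),
    class = "stride_set")
}

#' @export
print.stride_set <- function(x, ...) {
  cat(sprintf(
    "<stride_set: %d strides, %d retained, mean stride %.3f s (SD %.3f)>\n",
    length(x$stride_durations_s), length(x$retained_stride_indices),
    mean(x$stride_durations_s), stats::sd(x$stride_durations_s)))
  invisible(x)
}

pairing_muscles <- function(pairing) {
  switch(pairing,
         "RF/ST" = c("RF", "ST"),
         "TA/MG" = c("TA", "MG"),
         stop("unknown pairing: ", pairing,
              " (expected \"RF/ST\" or \"TA/MG\")"))
}

# Default antagonist designation: RF for the thigh pair, TA for the shank.
pairing_antagonist <- function(pairing) pairing_muscles(pairing)[1]

#' Time-normalize a muscle pair's envelopes to 101 points per stride
#'
#' For every retained stride, linearly interpolates each muscle's envelope
#' onto a fixed grid of 101 equally spaced points from 0 to 100% of the
#' stride (both endpoints included), so strides of different durations are
#' comparable. Strides are `[IC_i, IC_{i+1})` windows; a stride extending
#' beyond the recorded envelope is dropped rather than padded.
#'
#' @param envelope_trial An `envelope_trial` (normalized or not).
#' @param stride_set A [build_stride_set()] result for the same trial.
#' @param pairing `"RF/ST"` or `"TA/MG"`.
#' @return Object of class `stride_matrix`: `muscle_1` and `muscle_2`
#'   matrices of shape (retained strides x 101), row order following stride
#'   time, plus `pairing`, `muscles`, and `stride_ids`.
#' @export
build_stride_matrix <- function(envelope_trial, stride_set, pairing) {
  stopifnot(inherits(envelope_trial, "envelope_trial"),
            inherits(stride_set, "stride_set"))
  muscles <- pairing_muscles(pairing)
  env <- envelope_trial$envelopes
  rate <- envelope_trial$emg_rate_hz
  t_env <- (seq_len(nrow(env)) - 1) / rate
  t_max <- t_env[length(t_env)]
  ics <- stride_set$initial_contact_times_s

  keep <- stride_set$retained_stride_indices
  # drop strides not fully covered by the recording (allow one sample slack
  # at the tail; the final contact may fall between samples)
  keep <- keep[ics[keep] >= 0 & ics[keep + 1] <= t_max + 1 / rate]
  if (length(keep) < 1)
    stop("no retained stride lies within the recorded envelope")

  grid <- seq(0, 1, length.out = 101)
  n_env <- nrow(env)
  interp_rows <- function(muscle) {
    y <- env[, muscle]
    out <- matrix(0, nrow = length(keep), ncol = 101)
    for (r in seq_along(keep)) {
      i <- keep[r]
      xout <- ics[i] + grid * (ics[i + 1] - ics[i])
      # envelopes live on a regular grid: interpolate by sample index
      # (clamped at the ends, matching approx(..., rule = 2))
      pos <- pmin(pmax(xout * rate, 0), n_env - 1)
      i0 <- pmin(floor(pos), n_env - 2)
      frac <- pos - i0
      out[r, ] <- y[i0 + 1] * (1 - frac) + y[i0 + 2] * frac
    }
    out
  }
  structure(list(
    pairing = pairing,
    muscles = muscles,
    muscle_1 = interp_rows(muscles[1]),
    muscle_2 = interp_rows(muscles[2]),
    stride_ids = keep),
    class = "stride_matrix")
}

#' Plot a stride matrix as mean +/- SD activation bands
#'
#' @param x A `stride_matrix`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.stride_matrix <- function(x, ...) {
  phase <- seq(0, 100, length.out = 101)
  m1 <- colMeans(x$muscle_1)
  m2 <- colMeans(x$muscle_2)
  s1 <- apply(x$muscle_1, 2, stats::sd)
  s2 <- apply(x$muscle_2, 2, stats::sd)
  ylim <- range(0, m1 + s1, m2 + s2)
  graphics::matplot(phase, cbind(m1, m2), type = "l", lty = 1, lwd = 2,
                    col = c("firebrick", "navy"), ylim = ylim,
                    xlab = "Gait cycle (%)", ylab = "Normalized activation",
                    main = paste("Muscle pair", x$pairing), ...)
  graphics::polygon(c(phase, rev(phase)), c(m1 + s1, rev(pmax(m1 - s1, 0))),
                    col = grDevices::adjustcolor("firebrick", 0.2),
                    border = NA)
  graphics::polygon(c(phase, rev(phase)), c(m2 + s2, rev(pmax(m2 - s2, 0))),
                    col = grDevices::adjustcolor("navy", 0.2), border = NA)
  graphics::legend("topright", legend = x$muscles, col =
                     c("firebrick", "navy"), lty = 1, lwd = 2, bty = "n")
  invisible(x)
}
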