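# Linear-envelope extraction and dynamic normalization.

# Direct-form IIR filter with zero initial state: FIR part as a one-sided
# convolution, recursive part via the C-level recursive filter. Equivalent to
# signal::filter(Arma(b, a), x) but much faster on long EMG records.
iir_filter <- function(b, a, x) {
  nb <- length(b)
  z <- stats::filter(c(numeric(nb - 1), x), b, sides = 1)
  z <- z[-seq_len(nb - 1)]
  as.numeric(stats::filter(z, -a[-1], method = "recursive"))
}

# Zero-phase (forward-backward) Butterworth low-pass. Reflective (odd)
# padding of 3 x filter order at each end; each pass is `order`-th order, so
# the dual pass is effectively 2 x order. No cutoff correction is applied for
# the second pass.
butter_lowpass_filtfilt <- function(x, rate, cutoff_hz, order = 2,
                                    pad = 3L * order) {
  bf <- signal::butter(order, cutoff_hz / (rate / 2), type = "low")
  n <- length(x)
  front <- 2 * x[1] - x[seq(pad + 1L, 2L)]
  back <- 2 * x[n] - x[seq(n - 1L, n - pad)]
  xp <- c(front, x, back)
  y <- iir_filter(bf$b, bf$a, xp)
  y <- rev(iir_filter(bf$b, bf$a, rev(y)))
  y[seq(pad + 1L, pad + n)]
}

#' Linear envelope of a raw EMG series
#'
#' Classic envelope pipeline: remove bias (subtract the series mean),
#' full-wave rectify, then apply a dual-pass (zero-phase forward-backward)
#' Butterworth low-pass, 2nd order per pass with a 6 Hz cutoff by default.
#' Any negative undershoot left by the filter is clipped to zero, since
#' co-contraction indices assume nonnegative activation.
#'
#' @param x Numeric vector, raw EMG samples.
#' @param rate Sampling rate in Hz; must exceed twice the cutoff.
#' @param cutoff_hz Low-pass cutoff in Hz (per pass, uncorrected).
#' @param order Butterworth order per pass.
#' @return Nonnegative numeric vector, same length as `x`.
#' @examples
#' x <- rnorm(4000)
#' env <- linear_envelope(x, rate = 2000)
#' @export
linear_envelope <- function(x, rate, cutoff_hz = 6, order = 2) {
  if (rate <= 2 * cutoff_hz)
    stop("sampling rate must exceed twice the cutoff frequency")
  pad <- 3L * order
  if (length(x) < 3L * pad)
    stop("series shorter than minimum filterable length (", 3L * pad,
         " samples)")
  x <- x - mean(x)
  env <- butter_lowpass_filtfilt(abs(x), rate, cutoff_hz, order, pad)
  pmax(env, 0)
}

#' Envelope-extract every EMG channel of a raw trial
#'
#' @param trial A `raw_trial`.
#' @param cutoff_hz,order Passed to [linear_envelope()].
#' @return An object of class `envelope_trial`: the trial metadata plus an
#'   `envelopes` matrix (same shape as the raw EMG) and a
#'   `normalization_factor` slot, `NA` until [dynamic_normalize()] runs.
#' @export
process_trial <- function(trial, cutoff_hz = 6, order = 2) {
  stopifnot(inherits(trial, "raw_trial"))
  env <- apply(trial$emg, 2, linear_envelope, rate = trial$emg_rate_hz,
               cutoff_hz = cutoff_hz, order = order)
  colnames(env) <- colnames(trial$emg)
  structure(list(
    trial_id = trial$trial_id,
    participant_id = trial$participant_id,
    limb = trial$limb,
    population = trial$population,
    environment = trial$environment,
    speed = trial$speed,
    envelopes = env,
    emg_rate_hz = trial$emg_rate_hz,
    normalization_factor = rep(NA_real_, ncol(env))),
    class = "envelope_trial")
}

#' Dynamic normalization of one limb's envelope trials
#'
#' Divides every muscle's envelope, in every trial of a limb, by that
#' muscle's envelope maximum in the limb's Dry Fast trial (the reference
#' dynamic task). The reference trial's own envelope maxima become exactly 1;
#' other trials may exceed 1 and are left unclipped. Normalization is per
#' muscle and per limb: the two limbs of a participant get independent
#' factors.
#'
#' @param trials List of `envelope_trial` objects belonging to a single limb
#'   of a single participant, containing exactly one Dry Fast trial.
#' @return The same list, envelopes rescaled and `normalization_factor` set
#'   to the per-muscle divisors used.
#' @export
dynamic_normalize <- function(trials) {
  stopifnot(length(trials) >= 1,
            all(vapply(trials, inherits, logical(1), "envelope_trial")))
  key <- unique(vapply(trials, function(tr)
    paste(tr$participant_id, tr$limb), character(1)))
  if (length(key) != 1)
    stop("dynamic_normalize expects trials from a single participant limb; ",
         "got: ", paste(key, collapse = "; "))
  is_ref <- vapply(trials, function(tr)
    tr$environment == "Dry" && tr$speed == "Fast", logical(1))
  if (sum(is_ref) != 1)
    stop("limb ", key, " must contain exactly one Dry Fast reference trial ",
         "(found ", sum(is_ref), ")")
  fac <- apply(trials[[which(is_ref)]]$envelopes, 2, max)
  if (any(fac <= 0))
    stop("zero reference maximum (dead channel) for muscle(s): ",
         paste(names(fac)[fac <= 0], collapse = ", "))
  lapply(trials, function(tr) {
    tr$envelopes <- sweep(tr$envelopes, 2, fac, "/")
    tr$normalization_factor <- fac
    tr
  })
}

#' Dynamic normalization across a whole cohort
#'
#' Groups envelope trials by participant and limb and applies
#' [dynamic_normalize()] within each group, preserving the input order.
#'
#' @param trials List of `envelope_trial` objects (any number of limbs).
#' @return List of normalized `envelope_trial` objects, same order.
#' @export
normalize_cohort <- function(trials) {
  keys <- vapply(trials, function(tr)
    paste(tr$participant_id, tr$limb, sep = "|"), character(1))
  out <- vector("list", length(trials))
  for (k in unique(keys)) {
    i <- which(keys == k)
    out[i] <- dynamic_normalize(trials[i])
  }
  out
}

#' @export
print.envelope_trial <- function(x, ...) {
  normed <- if (all(is.na(x$normalization_factor))) "raw" else "normalized"
  cat(sprintf("<envelope_trial %s: %s %s %s %s, %d samples, %s>\n",
              x$trial_id, x$population, x$limb, x$environment, x$speed,
              nrow(x$envelopes), normed))
  invisible(x)
}
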