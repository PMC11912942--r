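# End-to-end pipeline: raw trials -> normalized envelopes -> stride
# segmentation -> per-trial CCI table.

#' Run the full co-contraction pipeline on a cohort of raw trials
#'
#' For every trial: extract linear envelopes, normalize each limb's trials
#' to its Dry Fast reference, detect initial contacts from the foot
#' acceleration channel, drop stride-time outliers (3-SD rule), time
#' normalize each muscle pair to the 101-point grid, and compute the
#' requested co-contraction indices. Trials whose acceleration trace cannot
#' be segmented are skipped with a warning, mirroring how trials lost to
#' equipment malfunction are excluded in practice.
#'
#' @param trials List of `raw_trial` objects (e.g. [simulate_cohort()]).
#' @param pairings Subset of `c("RF/ST", "TA/MG")`.
#' @param methods Subset of `c("unnithan", "rudolph", "fw")`.
#' @param cutoff_hz,order Envelope filter settings, see [linear_envelope()].
#' @param expected_stride_s Stride time prior for peak separation in
#'   [detect_initial_contacts()]; the default `NULL` estimates it per trial
#'   from the dominant acceleration peak spacing
#'   ([estimate_stride_time()]), which adapts the minimum peak separation
#'   to each condition's walking speed.
#' @param height_frac Peak-height criterion forwarded to
#'   [detect_initial_contacts()]; the default 0.5 keeps only peaks reaching
#'   half the trial's maximum acceleration, i.e. the dominant impact
#'   transients.
#' @param zero_policy Passed to the CCI formulas.
#' @return A data.frame (the CCI table): one row per trial x pairing x
#'   method with columns `trial_id, participant_id, limb, population,
#'   environment, speed, pairing, method, n_strides, value`.
#' @examples
#' cfg <- simulation_config(n_participants_td = 1, n_participants_cp = 0,
#'                          limbs = "left", strides_per_trial = 6)
#' cci <- analyze_cohort(simulate_cohort(cfg), pairings = "RF/ST",
#'                       methods = "unnithan")
#' @export
analyze_cohort <- function(trials,
                           pairings = PAIRINGS,
                           methods = cci_method_ids,
                           cutoff_hz = 6, order = 2,
                           expected_stride_s = NULL,
                           height_frac = 0.5,
                           zero_policy = "zero") {
  pairings <- match.arg(pairings, PAIRINGS, several.ok = TRUE)
  methods <- match.arg(methods, cci_method_ids, several.ok = TRUE)

  env_trials <- lapply(trials, process_trial, cutoff_hz = cutoff_hz,
                       order = order)
  env_trials <- normalize_cohort(env_trials)

  rows <- list()
  for (tr in env_trials) {
    ics <- tryCatch({
      acc <- attr_accel(trials, tr$trial_id)
      rate <- imu_rate(trials, tr$trial_id)
      prior <- expected_stride_s %||% estimate_stride_time(acc, rate)
      detect_initial_contacts(acc, rate, prior, height_frac = height_frac)
    },
      error = function(e) {
        warning("skipping trial ", tr$trial_id, ": ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    if (is.null(ics)) next
    ss <- build_stride_set(ics)
    for (pr in pairings) {
      sm <- build_stride_matrix(tr, ss, pr)
      for (me in methods) {
        res <- cci_trial(sm, me, zero_policy = zero_policy)
        rows[[length(rows) + 1L]] <- data.frame(
          trial_id = tr$trial_id,
          participant_id = tr$participant_id,
          limb = tr$limb,
          population = tr$population,
          environment = tr$environment,
          speed = tr$speed,
          pairing = pr,
          method = me,
          n_strides = res$n_strides,
          value = res$trial_value,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) stop("no trial could be analyzed")
  do.call(rbind, rows)
}

# raw-trial lookups by id (keeps analyze_cohort readable)
attr_accel <- function(trials, id) {
  trials[[match_trial(trials, id)]]$accel_vertical
}
imu_rate <- function(trials, id) {
  trials[[match_trial(trials, id)]]$imu_rate_hz
}
match_trial <- function(trials, id) {
  i <- which(vapply(trials, function(x) identical(x$trial_id, id),
                    logical(1)))
  if (length(i) != 1) stop("trial id not found: ", id)
  i
}
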