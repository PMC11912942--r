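# Synthetic treadmill gait trials: gait-phase-structured EMG bursts,
# amplitude-modulated white noise, and a foot vertical-acceleration channel
# with one dominant peak per initial contact.

MUSCLES <- c("TA", "MG", "RF", "ST")
POPULATIONS <- c("TD", "CP")
ENVIRONMENTS <- c("Dry", "Wet")
SPEEDS <- c("Slow", "Normal", "Fast")
PAIRINGS <- c("RF/ST", "TA/MG")

#' Configuration for the synthetic gait-trial generator
#'
#' Bundles every tunable of the simulator: cohort size, stride timing,
#' per-muscle burst templates on the gait-phase axis, and the multiplicative
#' condition effects (environment, speed, population) whose recovery the
#' downstream pipeline is tested against. Defaults emulate a pediatric
#' treadmill study: 15 typically developing (TD) and 10 cerebral palsy (CP)
#' participants, both limbs instrumented, EMG at 2000 Hz and foot
#' accelerometry at 142 Hz, walking at 75/100/125% of self-selected speed.
#' Effect magnitudes (aquatic attenuation, CP tonic co-activation, speed
#' scaling) are plausible inventions: their directions, not their sizes, are
#' what the pipeline must preserve.
#'
#' @param n_participants_td,n_participants_cp Number of TD and CP
#'   participants.
#' @param limbs Character vector of instrumented limbs per participant.
#' @param strides_per_trial Strides simulated per trial; a trial spans
#'   `strides_per_trial + 1` initial contacts.
#' @param stride_time_mean_s Mean stride time in seconds at Normal speed.
#' @param stride_time_cv Coefficient of variation of lognormal stride times.
#' @param outlier_stride_prob Probability that a stride is an outlier.
#' @param outlier_stride_scale Multiplier applied to outlier stride durations.
#' @param emg_rate_hz,imu_rate_hz Sampling rates of the EMG and accelerometer
#'   streams (Hz).
#' @param burst_centers,burst_widths,burst_amplitudes Named lists (TA, MG,
#'   RF, ST) of Gaussian burst centres, widths (SD) and heights on the
#'   gait-phase axis (fractions of the cycle). Bursts wrap modulo 1 so
#'   late-swing activity is continuous across the 100%->0% boundary.
#' @param coactivation_baseline Tonic activation floor common to all muscles;
#'   a named vector `c(TD = , CP = )` or a single value used for both
#'   populations. Higher for CP encodes the elevated co-activation that the
#'   co-contraction indices should detect.
#' @param env_amplitude_factor Multiplier on all activation in Wet
#'   (aquatic) trials; values below 1 encode reduced activation in water.
#' @param speed_amplitude_factors Named vector (Slow, Normal, Fast) of
#'   activation multipliers; stride time scales inversely with the same
#'   factor so faster walking means shorter, stronger strides.
#' @param participant_offset_sd SD (log scale) of a lognormal per-participant
#'   multiplier on burst amplitudes, shared across that participant's trials;
#'   motivates a random intercept per participant in the statistical model.
#' @param noise_sd SD of additive measurement noise (EMG channels and, at the
#'   same scale, the accelerometer floor).
#' @param seed Integer seed controlling the whole cohort.
#'
#' @return An object of class `simulation_config` (a validated list).
#' @examples
#' cfg <- simulation_config(n_participants_td = 1, n_participants_cp = 1,
#'                          strides_per_trial = 5)
#' cfg$speed_amplitude_factors
#' @export
simulation_config <- function(n_participants_td = 15,
                              n_participants_cp = 10,
                              limbs = c("left", "right"),
                              strides_per_trial = 150,
                              stride_time_mean_s = 1.1,
                              stride_time_cv = 0.05,
                              outlier_stride_prob = 0.02,
                              outlier_stride_scale = 1.8,
                              emg_rate_hz = 2000,
                              imu_rate_hz = 142,
                              burst_centers = list(
                                TA = c(0.05, 0.80), MG = 0.30,
                                RF = c(0.075, 0.625), ST = 0.97),
                              burst_widths = list(
                                TA = c(0.04, 0.10), MG = 0.10,
                                RF = c(0.05, 0.05), ST = 0.06),
                              burst_amplitudes = list(
                                TA = c(1.0, 0.8), MG = 1.2,
                                RF = c(1.0, 0.7), ST = 1.0),
                              coactivation_baseline = c(TD = 0.05, CP = 0.15),
                              env_amplitude_factor = 0.6,
                              speed_amplitude_factors = c(
                                Slow = 0.75, Normal = 1.0, Fast = 1.25),
                              participant_offset_sd = 0.15,
                              noise_sd = 0.01,
                              seed = 1L) {
  cfg <- list(
    n_participants_td = as.integer(n_participants_td),
    n_participants_cp = as.integer(n_participants_cp),
    limbs = limbs,
    strides_per_trial = as.integer(strides_per_trial),
    stride_time_mean_s = stride_time_mean_s,
    stride_time_cv = stride_time_cv,
    outlier_stride_prob = outlier_stride_prob,
    outlier_stride_scale = outlier_stride_scale,
    emg_rate_hz = emg_rate_hz,
    imu_rate_hz = imu_rate_hz,
    burst_centers = burst_centers,
    burst_widths = burst_widths,
    burst_amplitudes = burst_amplitudes,
    coactivation_baseline = coactivation_baseline,
    env_amplitude_factor = env_amplitude_factor,
    speed_amplitude_factors = speed_amplitude_factors,
    participant_offset_sd = participant_offset_sd,
    noise_sd = noise_sd,
    seed = as.integer(seed))
  validate_simulation_config(cfg)
  class(cfg) <- "simulation_config"
  cfg
}

validate_simulation_config <- function(cfg) {
  stopifnot(
    cfg$n_participants_td >= 0, cfg$n_participants_cp >= 0,
    length(cfg$limbs) >= 1, all(cfg$limbs %in% c("left", "right")),
    cfg$stride_time_mean_s > 0, cfg$stride_time_cv >= 0,
    cfg$emg_rate_hz > 0, cfg$imu_rate_hz > 0,
    cfg$outlier_stride_scale > 0,
    cfg$participant_offset_sd >= 0, cfg$noise_sd >= 0)
  if (cfg$outlier_stride_prob < 0 || cfg$outlier_stride_prob > 1)
    stop("outlier_stride_prob must lie in [0, 1]")
  for (fld in c("burst_centers", "burst_widths", "burst_amplitudes")) {
    if (!setequal(names(cfg[[fld]]), MUSCLES))
      stop(fld, " must be a named list covering exactly the muscles ",
           paste(MUSCLES, collapse = ", "))
  }
  for (m in MUSCLES) {
    nb <- length(cfg$burst_centers[[m]])
    if (length(cfg$burst_widths[[m]]) != nb ||
        length(cfg$burst_amplitudes[[m]]) != nb)
      stop("burst centers/widths/amplitudes for ", m,
           " must have equal length")
    if (any(cfg$burst_widths[[m]] <= 0)) stop("burst widths must be > 0")
    if (any(cfg$burst_amplitudes[[m]] < 0))
      stop("burst amplitudes must be >= 0")
    if (any(cfg$burst_centers[[m]] < 0 | cfg$burst_centers[[m]] >= 1))
      stop("burst centers must lie in [0, 1)")
  }
  if (any(baseline_for(cfg$coactivation_baseline, POPULATIONS) < 0))
    stop("coactivation_baseline must be nonnegative")
  if (!setequal(names(cfg$speed_amplitude_factors), SPEEDS))
    stop("speed_amplitude_factors must be named Slow, Normal, Fast")
  if (any(cfg$speed_amplitude_factors <= 0) || cfg$env_amplitude_factor <= 0)
    stop("amplitude factors must be > 0")
  invisible(cfg)
}

# Per-population tonic baseline; a bare scalar applies to both populations.
baseline_for <- function(baseline, population) {
  if (is.null(names(baseline))) return(rep(baseline[1], length(population)))
  if (!all(population %in% names(baseline)))
    stop("coactivation_baseline is missing a level for: ",
         paste(setdiff(population, names(baseline)), collapse = ", "))
  unname(baseline[population])
}

#' Muscle activation profile over the gait cycle
#'
#' Builds the noise-free activation waveform for one muscle under one
#' condition: a tonic co-activation floor plus a sum of Gaussian bursts on
#' the gait-phase axis, wrapped modulo 1 so bursts spanning the terminal
#' swing / initial contact boundary stay continuous, then scaled by the
#' environment and speed amplitude factors. The returned closure is the
#' ground truth against which envelope extraction and stride normalization
#' are validated.
#'
#' @param muscle One of `"TA"`, `"MG"`, `"RF"`, `"ST"`.
#' @param config A [simulation_config()].
#' @param population,environment,speed Condition labels.
#' @param participant_offset Multiplier on burst amplitudes (participant
#'   random effect); the tonic baseline is not scaled by it.
#' @return A vectorized function mapping gait-phase fractions (any real;
#'   interpreted modulo 1) to nonnegative activation.
#' @examples
#' cfg <- simulation_config()
#' f <- make_activation_profile("MG", cfg)
#' f(c(0, 0.3, 0.9))
#' @export
make_activation_profile <- function(muscle, config,
                                    population = "TD",
                                    environment = "Dry",
                                    speed = "Normal",
                                    participant_offset = 1) {
  if (!(is.character(muscle) && length(muscle) == 1 && muscle %in% MUSCLES))
    stop("unknown muscle id: ", paste(muscle, collapse = ","),
         " (expected one of ", paste(MUSCLES, collapse = ", "), ")")
  population <- match.arg(population, POPULATIONS)
  environment <- match.arg(environment, ENVIRONMENTS)
  speed <- match.arg(speed, SPEEDS)
  centers <- config$burst_centers[[muscle]]
  widths <- config$burst_widths[[muscle]]
  amps <- config$burst_amplitudes[[muscle]] * participant_offset
  base <- baseline_for(config$coactivation_baseline, population)
  scale <- condition_amplitude(config, environment, speed)
  force(scale)
  function(phase) {
    act <- rep.int(base, length(phase))
    for (j in seq_along(centers)) {
      d <- (phase - centers[j]) %% 1
      d <- d - (d > 0.5)          # nearest periodic image, in [-0.5, 0.5]
      act <- act + amps[j] * exp(-0.5 * (d / widths[j])^2)
    }
    scale * act
  }
}

condition_amplitude <- function(config, environment, speed) {
  env <- if (environment == "Wet") config$env_amplitude_factor else 1
  env * unname(config$speed_amplitude_factors[speed])
}

#' Simulate one raw treadmill walking trial
#'
#' Draws stride durations from a lognormal distribution (mean stride time
#' scaled inversely by the condition's speed factor, coefficient of variation
#' `stride_time_cv`), lengthens occasional outlier strides, then synthesizes
#' raw EMG as the condition's activation profile amplitude-modulating
#' zero-mean unit-variance white noise plus additive sensor noise. Full-wave
#' rectification and low-pass filtering of such a signal recovers the
#' activation profile up to the constant `sqrt(2/pi)`. The foot vertical
#' acceleration channel carries one dominant half-sine peak (~50 ms wide,
#' centred on each initial contact) over a low-amplitude noise floor. The
#' trial starts at an initial contact and both streams share the same clock.
#'
#' @param config A [simulation_config()].
#' @param population,environment,speed Condition labels for the trial.
#' @param participant_id,limb,trial_id Metadata carried through the pipeline.
#' @param participant_offset Participant-level burst-amplitude multiplier.
#' @param seed Integer seed; the same seed and condition give a bit-identical
#'   trial. Defaults to the config seed.
#' @return An object of class `raw_trial`: metadata, `emg` (samples x 4
#'   matrix, columns TA/MG/RF/ST, at `emg_rate_hz`), `accel_vertical` (g, at
#'   `imu_rate_hz`) and `true_initial_contacts_s` (simulation ground truth).
#' @examples
#' cfg <- simulation_config(strides_per_trial = 5)
#' tr <- simulate_trial(cfg, "TD", "Dry", "Fast", seed = 7)
#' length(tr$true_initial_contacts_s)  # strides + 1
#' @export
simulate_trial <- function(config, population, environment, speed,
                           participant_id = "TD01", limb = "left",
                           trial_id = NULL, participant_offset = 1,
                           seed = config$seed) {
  validate_simulation_config(config)
  if (config$strides_per_trial <= 0)
    stop("strides_per_trial must be positive")
  population <- match.arg(population, POPULATIONS)
  environment <- match.arg(environment, ENVIRONMENTS)
  speed <- match.arg(speed, SPEEDS)
  set.seed(as.integer(seed))

  n_str <- config$strides_per_trial
  sf <- unname(config$speed_amplitude_factors[speed])
  m <- config$stride_time_mean_s / sf
  cv <- config$stride_time_cv
  if (cv > 0) {
    sig2 <- log(1 + cv^2)
    dur <- stats::rlnorm(n_str, meanlog = log(m) - sig2 / 2,
                         sdlog = sqrt(sig2))
  } else {
    dur <- rep(m, n_str)
  }
  is_outlier <- stats::runif(n_str) < config$outlier_stride_prob
  dur[is_outlier] <- dur[is_outlier] * config$outlier_stride_scale
  ics <- c(0, cumsum(dur))
  total <- ics[n_str + 1]

  # EMG: activation profile evaluated at each sample's within-stride phase,
  # modulating white noise, plus additive sensor noise.
  t_emg <- seq(0, by = 1 / config$emg_rate_hz,
               length.out = floor(total * config$emg_rate_hz) + 1)
  idx <- pmin(findInterval(t_emg, ics), n_str)
  phase <- (t_emg - ics[idx]) / dur[idx]
  emg <- matrix(0, nrow = length(t_emg), ncol = length(MUSCLES),
                dimnames = list(NULL, MUSCLES))
  for (mus in MUSCLES) {
    prof <- make_activation_profile(mus, config, population, environment,
                                    speed, participant_offset)
    emg[, mus] <- prof(phase) * stats::rnorm(length(t_emg)) +
      config$noise_sd * stats::rnorm(length(t_emg))
  }

  # Accelerometer: half-sine impact transient centred on each contact.
  t_acc <- seq(0, by = 1 / config$imu_rate_hz,
               length.out = floor(total * config$imu_rate_hz) + 1)
  accel <- config$noise_sd * stats::rnorm(length(t_acc))
  half_width <- 0.025  # impact transient spans ~50 ms
  for (ic in ics) {
    w <- which(abs(t_acc - ic) <= half_width)
    accel[w] <- accel[w] + 2.0 * cos(pi * (t_acc[w] - ic) / (2 * half_width))
  }

  structure(list(
    trial_id = trial_id %||% sprintf("%s_%s_%s_%s", participant_id, limb,
                                     environment, speed),
    participant_id = participant_id,
    limb = limb,
    population = population,
    environment = environment,
    speed = speed,
    emg = emg,
    emg_rate_hz = config$emg_rate_hz,
    accel_vertical = accel,
    imu_rate_hz = config$imu_rate_hz,
    true_initial_contacts_s = ics),
    class = "raw_trial")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a full walking cohort
#'
#' Generates the complete factorial design: every participant walks all
#' 2 environments x 3 speeds on every instrumented limb, so a cohort holds
#' `(n_td + n_cp) * length(limbs) * 6` trials. Each participant receives a
#' lognormal burst-amplitude offset (SD `participant_offset_sd` on the log
#' scale) shared across all of their trials, which is what makes a
#' random-intercept-per-participant model appropriate downstream.
#'
#' @param config A [simulation_config()].
#' @return A list of [simulate_trial()] objects with the config attached as
#'   attribute `"config"`. Regenerating with the same config is bit-identical.
#' @examples
#' cfg <- simulation_config(n_participants_td = 1, n_participants_cp = 1,
#'                          limbs = "left", strides_per_trial = 5)
#' length(simulate_cohort(cfg))  # 2 participants x 1 limb x 6 conditions
#' @export
simulate_cohort <- function(config) {
  validate_simulation_config(config)
  set.seed(config$seed)
  ids <- c(sprintf("TD%02d", seq_len(config$n_participants_td)),
           sprintf("CP%02d", seq_len(config$n_participants_cp)))
  pops <- rep(POPULATIONS, c(config$n_participants_td,
                             config$n_participants_cp))
  n_trials <- length(ids) * length(config$limbs) *
    length(ENVIRONMENTS) * length(SPEEDS)
  sd0 <- config$participant_offset_sd
  offsets <- stats::rlnorm(length(ids), meanlog = -sd0^2 / 2, sdlog = sd0)
  trial_seeds <- sample.int(2147483646L, n_trials)

  trials <- vector("list", n_trials)
  k <- 0L
  for (p in seq_along(ids)) {
    for (lb in config$limbs) {
      for (env in ENVIRONMENTS) {
        for (sp in SPEEDS) {
          k <- k + 1L
          trials[[k]] <- simulate_trial(
            config, pops[p], env, sp,
            participant_id = ids[p], limb = lb,
            participant_offset = offsets[p],
            seed = trial_seeds[k])
        }
      }
    }
  }
  attr(trials, "config") <- config
  trials
}

#' @export
print.raw_trial <- function(x, ...) {
  cat(sprintf(
    "<raw_trial %s: %s %s %s %s, %d EMG samples @ %g Hz, %d contacts>\n",
    x$trial_id, x$population, x$limb, x$environment, x$speed,
    nrow(x$emg), x$emg_rate_hz, length(x$true_initial_contacts_s)))
  invisible(x)
}
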