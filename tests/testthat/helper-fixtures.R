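# Shared fixtures: small configs and hand-built container objects.

tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_participants_td = 1, n_participants_cp = 1, limbs = "left",
         strides_per_trial = 6, stride_time_mean_s = 1.0, seed = 101),
    list(...))
  do.call(simulation_config, args)
}

# A config with every condition effect switched off: no environment or speed
# scaling and a common co-activation baseline, so trial CCI differs across
# conditions only through noise. Used for type-I-error simulations.
null_config <- function(n_td = 5, n_cp = 5, strides = 6, seed = 1) {
  simulation_config(
    n_participants_td = n_td, n_participants_cp = n_cp, limbs = "left",
    strides_per_trial = strides, stride_time_mean_s = 1.0,
    env_amplitude_factor = 1,
    speed_amplitude_factors = c(Slow = 1, Normal = 1, Fast = 1),
    coactivation_baseline = 0.10,
    seed = seed)
}

# Envelope trial with prescribed envelope columns (defaults constant).
make_env_trial <- function(participant = "TD01", limb = "left",
                           environment = "Dry", speed = "Fast",
                           n = 2000, rate = 2000,
                           values = c(TA = 0.5, MG = 0.5, RF = 0.5,
                                      ST = 0.5),
                           envelopes = NULL) {
  env <- envelopes %||%
    sapply(values, function(v) rep(v, n))
  structure(list(
    trial_id = paste(participant, limb, environment, speed, sep = "_"),
    participant_id = participant, limb = limb, population = "TD",
    environment = environment, speed = speed,
    envelopes = env, emg_rate_hz = rate,
    normalization_factor = rep(NA_real_, ncol(env))),
    class = "envelope_trial")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stride matrix with prescribed constant rows per muscle.
make_stride_matrix <- function(rows_1, rows_2, pairing = "RF/ST") {
  structure(list(
    pairing = pairing,
    muscles = switch(pairing, "RF/ST" = c("RF", "ST"),
                     "TA/MG" = c("TA", "MG")),
    muscle_1 = t(sapply(rows_1, rep, 101)),
    muscle_2 = t(sapply(rows_2, rep, 101)),
    stride_ids = seq_along(rows_1)),
    class = "stride_matrix")
}
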