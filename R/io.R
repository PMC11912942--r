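# Long-format CSV interchange for simulated cohorts.

.datatable.aware <- TRUE

#' Write a cohort of raw trials to long-format CSV
#'
#' Writes three files to `dir`: `signals.csv` (columns `trial_id,
#' participant_id, limb, population, environment, speed, stream, channel,
#' time_s, value`, with `stream` either `emg` or `accel`), `metadata.csv`
#' (one row per trial with sampling rates), and `true_initial_contacts.csv`
#' (ground-truth contact times, simulation only).
#'
#' @param trials List of `raw_trial` objects.
#' @param dir Output directory, created if missing.
#' @return Invisibly, the paths of the three files written.
#' @export
write_cohort_csv <- function(trials, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sig <- data.table::rbindlist(lapply(trials, function(tr) {
    meta <- list(trial_id = tr$trial_id, participant_id = tr$participant_id,
                 limb = tr$limb, population = tr$population,
                 environment = tr$environment, speed = tr$speed)
    emg_t <- (seq_len(nrow(tr$emg)) - 1) / tr$emg_rate_hz
    emg_long <- data.table::rbindlist(lapply(colnames(tr$emg), function(m)
      do.call(data.table::data.table,
              c(meta, list(stream = "emg", channel = m, time_s = emg_t,
                           value = tr$emg[, m])))))
    acc_t <- (seq_along(tr$accel_vertical) - 1) / tr$imu_rate_hz
    acc_long <- do.call(
      data.table::data.table,
      c(meta, list(stream = "accel", channel = "vertical", time_s = acc_t,
                   value = tr$accel_vertical)))
    rbind(emg_long, acc_long)
  }))
  meta <- data.table::rbindlist(lapply(trials, function(tr)
    data.table::data.table(
      trial_id = tr$trial_id, participant_id = tr$participant_id,
      limb = tr$limb, population = tr$population,
      environment = tr$environment, speed = tr$speed,
      emg_rate_hz = tr$emg_rate_hz, imu_rate_hz = tr$imu_rate_hz)))
  contacts <- data.table::rbindlist(lapply(trials, function(tr)
    data.table::data.table(trial_id = tr$trial_id,
                           contact_s = tr$true_initial_contacts_s)))
  paths <- file.path(dir, c("signals.csv", "metadata.csv",
                            "true_initial_contacts.csv"))
  data.table::fwrite(sig, paths[1])
  data.table::fwrite(meta, paths[2])
  data.table::fwrite(contacts, paths[3])
  invisible(paths)
}

#' Read a cohort written by [write_cohort_csv()]
#'
#' @param dir Directory containing `signals.csv`, `metadata.csv` and
#'   (optionally) `true_initial_contacts.csv`.
#' @return List of `raw_trial` objects in the order of `metadata.csv`.
#' @export
read_cohort_csv <- function(dir) {
  sig <- data.table::fread(file.path(dir, "signals.csv"))
  meta <- data.table::fread(file.path(dir, "metadata.csv"))
  gt_path <- file.path(dir, "true_initial_contacts.csv")
  gt <- if (file.exists(gt_path)) data.table::fread(gt_path) else NULL
  lapply(seq_len(nrow(meta)), function(i) {
    m <- meta[i, ]
    s <- sig[sig$trial_id == m$trial_id, ]
    emg_long <- s[s$stream == "emg", ]
    emg <- vapply(MUSCLES, function(mus)
      emg_long$value[emg_long$channel == mus],
      numeric(sum(emg_long$channel == MUSCLES[1])))
    acc <- s$value[s$stream == "accel"]
    ics <- if (!is.null(gt)) gt$contact_s[gt$trial_id == m$trial_id]
           else numeric(0)
    structure(list(
      trial_id = m$trial_id, participant_id = m$participant_id,
      limb = m$limb, population = m$population,
      environment = m$environment, speed = m$speed,
      emg = emg, emg_rate_hz = m$emg_rate_hz,
      accel_vertical = acc, imu_rate_hz = m$imu_rate_hz,
      true_initial_contacts_s = ics),
      class = "raw_trial")
  })
}
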