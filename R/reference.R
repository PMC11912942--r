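# Published condition summary used by the worked examples.

#' Reference condition summary of stride-normalized CCI
#'
#' Condition-level means and SDs of trial CCI reported by a published study
#' of children (typically developing and with cerebral palsy) walking on
#' conventional (Dry) and aquatic (Wet) treadmills at three speeds, for the
#' RF/ST and TA/MG muscle pairings under all three index definitions. These
#' printed cell values are the worked-example input for
#' [environment_contrast()] and [speed_contrast()]: the study's reported
#' percent-change statements are recoverable from them to within rounding.
#'
#' @return A `condition_summary` data.frame (72 cells) with columns
#'   `pairing, method, population, environment, speed, mean, sd, n`, where
#'   `n` is the number of limbs contributing to each cell.
#' @examples
#' ref <- reference_cci_summary()
#' environment_contrast(ref, "RF/ST", "rudolph", "CP")$percent_change
#' @export
reference_cci_summary <- function() {
  # means/SDs by (speed x environment): Slow Dry, Slow Wet, Normal Dry,
  # Normal Wet, Fast Dry, Fast Wet
  cells <- list(
    list("RF/ST", "unnithan", "CP",
         c(16.66, 9.81, 19.39, 10.43, 22.87, 14.37),
         c(6.26, 4.66, 6.62, 4.98, 7.52, 8.07)),
    list("RF/ST", "unnithan", "TD",
         c(11.84, 9.74, 14.89, 10.81, 19.79, 13.43),
         c(4.60, 6.61, 4.81, 7.31, 5.42, 8.90)),
    list("RF/ST", "rudolph", "CP",
         c(0.27, 0.15, 0.31, 0.16, 0.37, 0.22),
         c(0.11, 0.08, 0.11, 0.08, 0.14, 0.13)),
    list("RF/ST", "rudolph", "TD",
         c(0.19, 0.15, 0.24, 0.16, 0.32, 0.20),
         c(0.08, 0.10, 0.08, 0.11, 0.10, 0.14)),
    list("RF/ST", "fw", "CP",
         c(99.98, 104.08, 96.31, 102.63, 97.21, 98.77),
         c(14.55, 20.32, 18.28, 19.38, 16.97, 19.40)),
    list("RF/ST", "fw", "TD",
         c(94.42, 92.06, 95.89, 91.56, 95.81, 90.83),
         c(20.64, 28.98, 20.83, 30.16, 13.00, 28.81)),
    list("TA/MG", "unnithan", "CP",
         c(15.70, 11.32, 17.83, 12.82, 20.78, 16.44),
         c(5.86, 5.56, 6.31, 6.29, 6.73, 8.04)),
    list("TA/MG", "unnithan", "TD",
         c(6.22, 4.97, 7.54, 5.75, 9.90, 7.76),
         c(1.78, 1.76, 2.94, 1.88, 4.04, 3.72)),
    list("TA/MG", "rudolph", "CP",
         c(0.25, 0.17, 0.28, 0.20, 0.33, 0.25),
         c(0.11, 0.09, 0.12, 0.10, 0.13, 0.13)),
    list("TA/MG", "rudolph", "TD",
         c(0.08, 0.07, 0.10, 0.08, 0.14, 0.10),
         c(0.03, 0.03, 0.05, 0.03, 0.06, 0.05)),
    list("TA/MG", "fw", "CP",
         c(96.58, 92.21, 98.29, 92.20, 98.10, 91.53),
         c(14.68, 32.13, 14.06, 30.08, 12.33, 29.42)),
    list("TA/MG", "fw", "TD",
         c(79.59, 68.77, 82.58, 67.46, 82.40, 64.93),
         c(9.83, 13.02, 9.36, 10.97, 10.62, 13.76)))
  # contributing limbs after data loss: TA/MG 28 TD / 15 CP, RF/ST 26 / 14
  n_limbs <- c("RF/ST.TD" = 26L, "RF/ST.CP" = 14L,
               "TA/MG.TD" = 28L, "TA/MG.CP" = 15L)
  grid <- expand.grid(speed = SPEEDS, environment = ENVIRONMENTS,
                      stringsAsFactors = FALSE)
  # cell vectors above are ordered Slow Dry, Slow Wet, Normal Dry, ...
  ord <- order(match(grid$speed, SPEEDS), match(grid$environment,
                                                ENVIRONMENTS))
  rows <- lapply(cells, function(cl) {
    data.frame(pairing = cl[[1]], method = cl[[2]], population = cl[[3]],
               environment = grid$environment[ord],
               speed = grid$speed[ord],
               mean = cl[[4]], sd = cl[[5]],
               n = n_limbs[paste(cl[[1]], cl[[3]], sep = ".")],
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("condition_summary", "data.frame")
  out
}
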