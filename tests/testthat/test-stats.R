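fake_cci_table <- function(values, population = "TD", environment = "Dry",
                           speed = "Slow", pairing = "RF/ST",
                           method = "unnithan") {
  data.frame(trial_id = paste0("t", seq_along(values)),
             participant_id = "TD01", limb = "left",
             population = population, environment = environment,
             speed = speed, pairing = pairing, method = method,
             n_strides = 10L, value = values, stringsAsFactors = FALSE)
}

# A full 2x3 condition grid with prescribed cell means (one pairing/method).
grid_summary <- function(dry, wet, population = "TD") {
  data.frame(pairing = "RF/ST", method = "unnithan",
             population = population,
             environment = rep(c("Dry", "Wet"), each = 3),
             speed = rep(c("Slow", "Normal", "Fast"), 2),
             mean = c(dry, wet), sd = 1, n = 10L,
             stringsAsFactors = FALSE)
}

test_that("condition cells summarize to mean, sample SD and count", {
  tab <- rbind(fake_cci_table(c(7, 7, 7)),
               fake_cci_table(c(10, 20), environment = "Wet"))
  s <- summarize_conditions(tab)
  dry <- s[s$environment == "Dry", ]
  wet <- s[s$environment == "Wet", ]
  expect_equal(c(dry$mean, dry$sd, dry$n), c(7, 0, 3))
  expect_equal(wet$mean, 15)
  expect_equal(wet$sd, sqrt(50))  # 7.071: two-point sample SD
  expect_error(summarize_conditions(tab[0, ]), "empty")
  expect_error(summarize_conditions(data.frame(a = 1)), "columns")
})

test_that("environment contrasts average speeds within environment", {
  s <- grid_summary(dry = c(10, 20, 30), wet = c(5, 10, 15))
  ct <- environment_contrast(s, "RF/ST", "unnithan", "TD")
  expect_s3_class(ct, "cci_contrast")
  expect_equal(ct$baseline_mean, 20)
  expect_equal(ct$comparison_mean, 10)
  expect_equal(ct$percent_change, -50)

  same <- grid_summary(dry = c(10, 20, 30), wet = c(10, 20, 30))
  expect_equal(environment_contrast(same, "RF/ST", "unnithan",
                                    "TD")$percent_change, 0)
  # all six cells are required
  expect_error(environment_contrast(s[-1, ], "RF/ST", "unnithan", "TD"),
               "missing cell")
})

test_that("speed contrasts honor the averaging scope", {
  s <- rbind(grid_summary(dry = c(10, 15, 20), wet = c(6, 9, 12)),
             grid_summary(dry = c(20, 25, 40), wet = c(10, 15, 20),
                          population = "CP"))
  # fixed environment, averaged over populations:
  # Slow (10+20)/2 = 15 -> Fast (20+40)/2 = 30
  ct <- speed_contrast(s, "RF/ST", "unnithan", "Slow", "Fast",
                       environment = "Dry")
  expect_equal(ct$percent_change, 100)
  expect_setequal(ct$averaging_scope, "population")
  # averaged over both environment and population:
  # Slow (10+6+20+10)/4 = 11.5 -> Fast (20+12+40+20)/4 = 23
  ct2 <- speed_contrast(s, "RF/ST", "unnithan", "Slow", "Fast")
  expect_equal(ct2$percent_change, 100)
  expect_setequal(ct2$averaging_scope, c("environment", "population"))
  # equal means give a null contrast
  eq <- grid_summary(dry = rep(7, 3), wet = rep(7, 3))
  expect_equal(speed_contrast(eq, "RF/ST", "unnithan", "Slow", "Normal",
                              environment = "Dry",
                              population = "TD")$percent_change, 0)
})

test_that("percent changes recover the published contrast statements", {
  ref <- reference_cci_summary()
  expect_equal(nrow(ref), 72)
  expect_equal(
    environment_contrast(ref, "RF/ST", "unnithan", "CP")$percent_change,
    -41.3, tolerance = 0.1 / 41.3)
  expect_equal(
    speed_contrast(ref, "TA/MG", "unnithan", "Slow", "Fast")$percent_change,
    43.6, tolerance = 0.1 / 43.6)
})

test_that("the model ladder is nested, ML-fitted and order-invariant", {
  cfg <- simulation_config(n_participants_td = 4, n_participants_cp = 4,
                           limbs = "left", strides_per_trial = 5,
                           stride_time_mean_s = 1.0, seed = 21)
  cci <- analyze_cohort(simulate_cohort(cfg), pairings = "RF/ST",
                        methods = "unnithan")
  lad <- suppressMessages(fit_model_ladder(cci))
  expect_s3_class(lad, "cci_ladder")
  expect_equal(nrow(lad$table), 8)
  # log-likelihood never decreases along a nested ML ladder
  expect_true(all(diff(lad$table$logLik) > -1e-6))
  expect_true(is.na(lad$table$p_value[1]))
  expect_true(all(lad$table$p_value[-1] >= 0 & lad$table$p_value[-1] <= 1))
  expect_true(is.logical(lad$singular))

  # row order of the input table must not matter
  set.seed(1)
  shuffled <- cci[sample(nrow(cci)), ]
  lad2 <- suppressMessages(fit_model_ladder(shuffled))
  expect_equal(lad2$table$AIC, lad$table$AIC, tolerance = 1e-8)
  expect_equal(lad2$selected, lad$selected)

  # limb nesting option produces one extra variance component, still fits
  # (single-limb data make that component degenerate: warnings expected)
  lad3 <- suppressWarnings(suppressMessages(
    fit_model_ladder(cci, max_models = 2, nest_limb = TRUE)))
  expect_equal(nrow(lad3$table), 2)
})

test_that("a pure environment effect is picked up at the right rung", {
  cfg <- simulation_config(
    n_participants_td = 5, n_participants_cp = 5, limbs = "left",
    strides_per_trial = 5, stride_time_mean_s = 1.0,
    env_amplitude_factor = 0.6,
    speed_amplitude_factors = c(Slow = 1, Normal = 1, Fast = 1),
    coactivation_baseline = 0.10, seed = 55)
  cci <- analyze_cohort(simulate_cohort(cfg), pairings = "RF/ST",
                        methods = "unnithan")
  lad <- suppressMessages(fit_model_ladder(cci))
  expect_lt(lad$table$p_value[2], 0.001)   # Environment addition
  expect_gt(min(lad$table$p_value[4]), 0.05)  # no Speed effect injected
})

test_that("degenerate ladder inputs are rejected", {
  one <- fake_cci_table(c(1, 2, 3))
  expect_error(fit_model_ladder(one), "2 participants")
  two <- rbind(one, transform(one, participant_id = "TD02"))
  expect_error(fit_model_ladder(two), "unobserved factor level")
})
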