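# Condition summaries, percent-change contrasts, and the nested linear
# mixed-effects model ladder.

#' Condition-level summary of a CCI table
#'
#' Mean, sample SD and limb-trial count of the trial CCI values in every
#' observed (pairing, method, population, environment, speed) cell.
#'
#' @param cci_table Data.frame as returned by [analyze_cohort()] (columns
#'   `pairing, method, population, environment, speed, value` required).
#' @return Data.frame of class `condition_summary` with columns `pairing,
#'   method, population, environment, speed, mean, sd, n`.
#' @export
summarize_conditions <- function(cci_table) {
  needed <- c("pairing", "method", "population", "environment", "speed",
              "value")
  if (!all(needed %in% names(cci_table)))
    stop("cci_table must contain columns: ", paste(needed, collapse = ", "))
  if (nrow(cci_table) == 0) stop("empty CCI table")
  agg <- stats::aggregate(
    value ~ pairing + method + population + environment + speed,
    data = cci_table,
    FUN = function(v) c(mean = mean(v),
                        sd = if (length(v) > 1) stats::sd(v) else 0,
                        n = length(v)))
  out <- cbind(agg[, 1:5, drop = FALSE], as.data.frame(agg$value))
  names(out)[6:8] <- c("mean", "sd", "n")
  out$n <- as.integer(out$n)
  class(out) <- c("condition_summary", "data.frame")
  out
}

summary_cell <- function(summary, pairing, method, population, environment,
                         speed) {
  i <- summary$pairing == pairing & summary$method == method &
    summary$population == population & summary$environment == environment &
    summary$speed == speed
  if (sum(i) != 1)
    stop(sprintf("missing cell: %s %s %s %s %s",
                 pairing, method, population, environment, speed))
  summary$mean[i]
}

new_contrast <- function(contrast_id, factor, averaging_scope,
                         baseline_level, comparison_level,
                         baseline_mean, comparison_mean) {
  structure(list(
    contrast_id = contrast_id,
    factor = factor,
    averaging_scope = averaging_scope,
    baseline_level = baseline_level,
    comparison_level = comparison_level,
    baseline_mean = baseline_mean,
    comparison_mean = comparison_mean,
    percent_change = 100 * (comparison_mean - baseline_mean) / baseline_mean),
    class = "cci_contrast")
}

#' @export
print.cci_contrast <- function(x, ...) {
  cat(sprintf("<cci_contrast %s: %s %s -> %s, averaged over %s>\n",
              x$contrast_id, x$factor, x$baseline_level, x$comparison_level,
              paste(x$averaging_scope, collapse = " + ")))
  cat(sprintf("  baseline mean %.4g, comparison mean %.4g: %+.1f%%\n",
              x$baseline_mean, x$comparison_mean, x$percent_change))
  invisible(x)
}

#' Environment (Wet vs Dry) percent-change contrast
#'
#' For one pairing, method and population, averages the three speed-level
#' cell means within each environment and reports the percent change of the
#' comparison environment relative to baseline. Computed from cell means,
#' the convention under which the published percent sentences are
#' recoverable from printed condition tables.
#'
#' @param summary A [summarize_conditions()] result (or any data.frame with
#'   the same columns, e.g. [reference_cci_summary()]).
#' @param pairing,method,population Cell selectors.
#' @param baseline,comparison Environment levels contrasted.
#' @return A `cci_contrast` object; `percent_change` is signed (negative =
#'   reduction in the comparison environment).
#' @examples
#' ref <- reference_cci_summary()
#' environment_contrast(ref, "RF/ST", "unnithan", "CP")  # about -41.3%
#' @export
environment_contrast <- function(summary, pairing, method, population,
                                 baseline = "Dry", comparison = "Wet") {
  cell_means <- function(env) vapply(
    SPEEDS, function(sp) summary_cell(summary, pairing, method, population,
                                      env, sp), numeric(1))
  b <- mean(cell_means(baseline))
  cmp <- mean(cell_means(comparison))
  new_contrast(
    contrast_id = sprintf("%s_%s_%s_%s_vs_%s", pairing, method, population,
                          comparison, baseline),
    factor = "environment",
    averaging_scope = "speed",
    baseline_level = baseline, comparison_level = comparison,
    baseline_mean = b, comparison_mean = cmp)
}

#' Speed percent-change contrast
#'
#' Percent change in mean CCI between two speed levels for one pairing and
#' method. Cell means are averaged over populations, and over environments
#' when `environment` is `NULL` (similarly `population` may be fixed to a
#' single level). Averaging is over cell means, not pooled trials.
#'
#' @inheritParams environment_contrast
#' @param from,to Baseline and comparison speed levels.
#' @param environment `NULL` to average over Dry and Wet, or one level.
#' @param population `NULL` to average over TD and CP, or one level.
#' @return A `cci_contrast` object.
#' @examples
#' ref <- reference_cci_summary()
#' speed_contrast(ref, "RF/ST", "unnithan", "Slow", "Fast",
#'                environment = "Dry")  # about +49.7%
#' @export
speed_contrast <- function(summary, pairing, method, from = "Slow",
                           to = "Fast", environment = NULL,
                           population = NULL) {
  envs <- environment %||% ENVIRONMENTS
  pops <- population %||% POPULATIONS
  averaged <- c(if (is.null(environment)) "environment",
                if (is.null(population)) "population")
  cell_means <- function(sp) {
    g <- expand.grid(env = envs, pop = pops, stringsAsFactors = FALSE)
    mean(mapply(function(e, p)
      summary_cell(summary, pairing, method, p, e, sp), g$env, g$pop))
  }
  new_contrast(
    contrast_id = sprintf("%s_%s_%s_to_%s%s%s", pairing, method, from, to,
                          if (!is.null(environment)) paste0("_", environment)
                          else "",
                          if (!is.null(population)) paste0("_", population)
                          else ""),
    factor = "speed",
    averaging_scope = if (length(averaged)) averaged else "none",
    baseline_level = from, comparison_level = to,
    baseline_mean = cell_means(from), comparison_mean = cell_means(to))
}

ladder_terms <- c(
  "1",
  "environment",
  "population",
  "speed",
  "environment:population",
  "environment:speed",
  "population:speed",
  "environment:population:speed")

#' Fit the nested mixed-effects model ladder
#'
#' Fits, by maximum likelihood, the sequence of linear mixed-effects models
#' of increasing complexity for trial CCI: starting from an intercept-only
#' model with a random intercept per participant, then adding Environment,
#' Population, Speed, and their two- and three-way interactions one term at
#' a time. Each addition is assessed with a likelihood-ratio test against
#' the previous model; the selected model is the most complex one whose
#' addition is significant at `alpha`. ML (not REML) is used throughout so
#' information criteria and likelihood ratios are comparable across fixed
#' effects structures. Limbs enter as repeated observations within
#' participant by default; `nest_limb = TRUE` adds a limb-within-participant
#' random intercept instead.
#'
#' @param cci_table Data.frame with columns `participant_id, limb,
#'   population, environment, speed, value` (one pairing and method; if
#'   several are present, select with `pairing` / `method`).
#' @param pairing,method Optional filters applied to `cci_table`.
#' @param alpha Significance level for the sequential likelihood-ratio
#'   tests.
#' @param max_models Truncate the ladder after this many models (2 fits just
#'   the intercept and Environment models).
#' @param nest_limb Add a `(1 | participant:limb)` random intercept.
#' @return Object of class `cci_ladder`: `table` (formula, df, AIC, BIC,
#'   log-likelihood, LRT p-value per model), `fits` (the `lmerMod` objects),
#'   `selected` (index of the selected model), `singular` (logical per
#'   model), and `alpha`.
#' @export
fit_model_ladder <- function(cci_table, pairing = NULL, method = NULL,
                             alpha = 0.05, max_models = length(ladder_terms),
                             nest_limb = FALSE) {
  df <- as.data.frame(cci_table)
  if (!is.null(pairing)) df <- df[df$pairing == pairing, ]
  if (!is.null(method)) df <- df[df$method == method, ]
  needed <- c("participant_id", "population", "environment", "speed",
              "value")
  if (!all(needed %in% names(df)))
    stop("cci_table must contain columns: ", paste(needed, collapse = ", "))
  if (nrow(df) == 0) stop("no rows to fit after filtering")
  if (length(unique(df$participant_id)) < 2)
    stop("need at least 2 participants for a random-intercept model")
  df$population <- factor(df$population, POPULATIONS)
  df$environment <- factor(df$environment, ENVIRONMENTS)
  df$speed <- factor(df$speed, SPEEDS)
  n_models <- min(max_models, length(ladder_terms))
  used_terms <- ladder_terms[seq_len(n_models)]
  # unobserved levels of factors entering the fitted fixed effects are fatal
  for (v in intersect(used_terms, c("environment", "population", "speed"))) {
    if (any(table(df[[v]]) == 0))
      stop("unobserved factor level in ", v)
  }

  ranef_str <- if (nest_limb)
    "(1 | participant_id) + (1 | participant_id:limb)"
  else "(1 | participant_id)"

  fits <- vector("list", n_models)
  singular <- logical(n_models)
  forms <- character(n_models)
  for (k in seq_len(n_models)) {
    fixed <- paste(used_terms[seq_len(k)], collapse = " + ")
    forms[k] <- paste("value ~", fixed, "+", ranef_str)
    fits[[k]] <- lme4::lmer(stats::as.formula(forms[k]), data = df,
                            REML = FALSE)
    singular[k] <- lme4::isSingular(fits[[k]])
  }
  p <- rep(NA_real_, n_models)
  for (k in seq_len(n_models)[-1]) {
    p[k] <- stats::anova(fits[[k - 1]], fits[[k]])[2, "Pr(>Chisq)"]
  }
  sig <- which(!is.na(p) & p < alpha)
  selected <- if (length(sig)) max(sig) else 1L

  tab <- data.frame(
    model = forms,
    df = vapply(fits, function(f) attr(stats::logLik(f), "df"), numeric(1)),
    AIC = vapply(fits, stats::AIC, numeric(1)),
    BIC = vapply(fits, stats::BIC, numeric(1)),
    logLik = vapply(fits, function(f) as.numeric(stats::logLik(f)),
                    numeric(1)),
    p_value = p,
    stringsAsFactors = FALSE)

  structure(list(table = tab, fits = fits, selected = selected,
                 singular = singular, alpha = alpha),
            class = "cci_ladder")
}

#' @export
print.cci_ladder <- function(x, digits = 4, ...) {
  cat("Nested mixed-effects model ladder (ML fits, sequential LRTs)\n\n")
  tab <- x$table
  tab$AIC <- round(tab$AIC, 1)
  tab$BIC <- round(tab$BIC, 1)
  tab$logLik <- round(tab$logLik, 2)
  tab$p_value <- signif(tab$p_value, 3)
  tab$selected <- ifelse(seq_len(nrow(tab)) == x$selected, "<==", "")
  print(tab, row.names = FALSE, right = FALSE)
  if (any(x$singular))
    cat("\nNote: singular fit(s) at model(s) ",
        paste(which(x$singular), collapse = ", "), "\n", sep = "")
  cat(sprintf("\nSelected: model %d (most complex addition with LRT p < %g)\n",
              x$selected, x$alpha))
  invisible(x)
}

#' @export
summary.cci_ladder <- function(object, ...) {
  print(object)
  cat("\n--- Selected model fit ---\n")
  print(summary(object$fits[[object$selected]]))
  invisible(object)
}

#' Plot information criteria along the model ladder
#'
#' @param x A `cci_ladder`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.cci_ladder <- function(x, ...) {
  k <- seq_len(nrow(x$table))
  graphics::matplot(k, cbind(x$table$AIC, x$table$BIC), type = "b", pch = 19,
                    lty = 1, col = c("firebrick", "navy"),
                    xlab = "Model (increasing complexity)",
                    ylab = "Information criterion", ...)
  graphics::abline(v = x$selected, lty = 3)
  graphics::legend("topright", c("AIC", "BIC"), col = c("firebrick", "navy"),
                   lty = 1, pch = 19, bty = "n")
  invisible(x)
}
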