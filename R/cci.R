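# Co-contraction indices: common-area integral (Unnithan), smaller/larger
# weighted ratio (Rudolph), and antagonist fraction of total activation
# (Falconer & Winter). Per-stride values on the 101-point phase grid, then
# one trial value as the mean over retained strides.

check_pair <- function(emg_1, emg_2) {
  if (length(emg_1) != length(emg_2))
    stop("the two activation series must have equal length")
  if (length(emg_1) < 2)
    stop("activation series must have at least 2 samples")
  if (any(emg_1 < 0) || any(emg_2 < 0))
    stop("activation series must be nonnegative")
  invisible(TRUE)
}

#' Common-area co-contraction index
#'
#' The integral over the gait cycle of the pointwise minimum of the two
#' muscles' activation envelopes -- the area shared by the two waveforms,
#' capturing both intensity and duration of simultaneous activation. The
#' integral is trapezoidal on the percent phase axis (0-100), so a constant
#' common activation of `c` yields `100 * c`. Symmetric in its arguments:
#' the muscles carry no agonist/antagonist role here.
#'
#' @param emg_1,emg_2 Nonnegative activation envelopes on a common phase
#'   grid (typically the 101-point stride grid).
#' @return Nonnegative scalar, units of normalized activation x % stride.
#' @examples
#' cci_unnithan(rep(0.2, 101), rep(0.5, 101))  # 20
#' @export
cci_unnithan <- function(emg_1, emg_2) {
  check_pair(emg_1, emg_2)
  phase <- seq(0, 100, length.out = length(emg_1))
  pracma::trapz(phase, pmin(emg_1, emg_2))
}

#' Magnitude-and-timing co-contraction index
#'
#' At each phase point the smaller and larger of the two activations form
#' the ratio-weighted sum `(smaller / larger) * (smaller + larger)`; the
#' index is the mean over the phase grid. Low values indicate selective
#' activation, high values generalized co-activation. Points where both
#' muscles are silent contribute according to `zero_policy`.
#'
#' @inheritParams cci_unnithan
#' @param zero_policy What a sample with larger activation equal to 0
#'   contributes: `"zero"` (default; co-contraction requires activation) or
#'   `"drop"` (sample excluded from the mean).
#' @return Nonnegative scalar on the scale of the activations.
#' @examples
#' cci_rudolph(rep(0.1, 101), rep(0.3, 101))  # (0.1/0.3) * 0.4
#' @export
cci_rudolph <- function(emg_1, emg_2, zero_policy = c("zero", "drop")) {
  check_pair(emg_1, emg_2)
  zero_policy <- match.arg(zero_policy)
  s <- pmin(emg_1, emg_2)
  l <- pmax(emg_1, emg_2)
  active <- l > 0
  v <- numeric(length(l))
  v[active] <- (s[active] / l[active]) * (s[active] + l[active])
  if (zero_policy == "drop") {
    if (!any(active)) return(0)
    return(mean(v[active]))
  }
  mean(v)
}

#' Antagonist-fraction co-contraction index
#'
#' At each phase point, twice the antagonist activation as a percentage of
#' the summed pair activation: 0% when the antagonist is silent, 100% when
#' the pair is balanced, 200% when only the antagonist is active. The index
#' is the mean over the phase grid. The antagonist is a fixed designation
#' for the whole gait cycle (by convention RF in the RF/ST pair and TA in
#' the TA/MG pair).
#'
#' @param emg_ant,emg_ago Nonnegative antagonist and agonist envelopes on a
#'   common phase grid.
#' @param zero_policy Contribution of samples with zero total activation:
#'   `"zero"` (default) or `"drop"`.
#' @return Scalar in \[0, 200\] (percent).
#' @examples
#' cci_falconer_winter(rep(0.3, 101), rep(0.3, 101))  # 100
#' @export
cci_falconer_winter <- function(emg_ant, emg_ago,
                                zero_policy = c("zero", "drop")) {
  check_pair(emg_ant, emg_ago)
  zero_policy <- match.arg(zero_policy)
  tot <- emg_ant + emg_ago
  active <- tot > 0
  v <- numeric(length(tot))
  v[active] <- 2 * emg_ant[active] / tot[active] * 100
  if (zero_policy == "drop") {
    if (!any(active)) return(0)
    return(mean(v[active]))
  }
  mean(v)
}

cci_method_ids <- c("unnithan", "rudolph", "fw")

#' Per-stride and trial-level CCI for one stride matrix
#'
#' Applies the chosen index to every retained stride of a
#' [build_stride_matrix()] result and averages the per-stride values into a
#' single trial value.
#'
#' @param stride_matrix A `stride_matrix`.
#' @param method `"unnithan"`, `"rudolph"`, or `"fw"`.
#' @param antagonist Muscle id treated as the antagonist for `"fw"`;
#'   defaults to the pairing convention (RF for RF/ST, TA for TA/MG).
#' @param zero_policy Passed to the per-sample formulas.
#' @return List with `method`, `pairing`, `antagonist`, `per_stride`
#'   (numeric vector), `trial_value` (their mean) and `n_strides`.
#' @export
cci_trial <- function(stride_matrix, method = cci_method_ids,
                      antagonist = NULL, zero_policy = "zero") {
  stopifnot(inherits(stride_matrix, "stride_matrix"))
  method <- match.arg(method)
  n <- nrow(stride_matrix$muscle_1)
  if (n < 1) stop("empty stride matrix")
  antagonist <- antagonist %||% pairing_antagonist(stride_matrix$pairing)
  if (!antagonist %in% stride_matrix$muscles)
    stop("antagonist ", antagonist, " is not part of pairing ",
         stride_matrix$pairing)
  ant_first <- antagonist == stride_matrix$muscles[1]

  per_stride <- vapply(seq_len(n), function(r) {
    e1 <- stride_matrix$muscle_1[r, ]
    e2 <- stride_matrix$muscle_2[r, ]
    switch(method,
           unnithan = cci_unnithan(e1, e2),
           rudolph = cci_rudolph(e1, e2, zero_policy),
           fw = if (ant_first) cci_falconer_winter(e1, e2, zero_policy)
                else cci_falconer_winter(e2, e1, zero_policy))
  }, numeric(1))

  list(method = method,
       pairing = stride_matrix$pairing,
       antagonist = antagonist,
       per_stride = per_stride,
       trial_value = mean(per_stride),
       n_strides = n)
}
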