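#' Homogeneity (linear-extrapolation) error
#'
#' Quantifies how far a population's steady-state response deviates from
#' linear scaling in the input amplitude. Given steady-state rates at
#' drive amplitudes 0, 5 and 10 Hz, the 5 Hz perturbation is linearly
#' extrapolated to 10 Hz and compared against the simulated 10 Hz
#' response:
#' \deqn{\Delta F = |(F_{10} - F_0) - 2 (F_5 - F_0)|}
#' The error is zero exactly when a linear extrapolation predicts the
#' data. Vectorized over populations.
#'
#' @param f0,f5,f10 steady-state rates (Hz) at drive amplitudes 0, 5
#'   and 10 Hz (or any 1:2 amplitude ratio).
#' @return absolute prediction error (Hz).
#' @examples
#' homogeneity_error(3, 4, 6)   # |3 - 2| = 1
#' @export
homogeneity_error <- function(f0, f5, f10) {
  abs((f10 - f0) - 2 * (f5 - f0))
}

#' Homogeneity assay on the column
#'
#' Runs the background-only condition plus step drives at half and full
#' amplitude and returns the per-population homogeneity error, both
#' absolute and relative to the pre-stimulus steady state (in percent).
#'
#' @param column a [build_column()] network.
#' @param layer,specificity,sources_per_neuron see [drive_protocol()].
#' @param amplitude full drive amplitude (Hz); the half-amplitude run
#'   uses `amplitude / 2`.
#' @param f0 optional precomputed background steady-state rates (named,
#'   Hz) to share across assays; computed if missing.
#' @param settle,stim,dt,pre_window,post_window protocol parameters.
#' @param initial optional settled initial states (see [run_drive()]);
#'   when supplied, a short `settle` epoch suffices.
#' @return list with `error` (Hz), `rel_error_pct` (percent of `f0`),
#'   `f0`, `f_half`, `f_full`, and `warnings` from either run.
#' @export
homogeneity_assay <- function(column, layer, specificity = "balanced",
                              amplitude = 10, sources_per_neuron = 100,
                              f0 = NULL, settle = 100, stim = 100, dt = 0.1,
                              pre_window = 20, post_window = 20,
                              initial = NULL) {
  warnings <- character()
  run_amp <- function(a) {
    res <- step_perturbation(column, layer, specificity, amplitude = a,
                             sources_per_neuron = sources_per_neuron,
                             settle = settle, stim = stim, dt = dt,
                             pre_window = pre_window,
                             post_window = post_window, initial = initial)
    warnings <<- c(warnings, res$warnings)
    res
  }
  half <- run_amp(amplitude / 2)
  full <- run_amp(amplitude)
  if (is.null(f0)) f0 <- half$pre_rates
  err <- homogeneity_error(f0, half$post_rates, full$post_rates)
  list(error = err, rel_error_pct = 100 * err / f0, f0 = f0,
       f_half = half$post_rates, f_full = full$post_rates,
       warnings = unique(warnings))
}

#' Additivity (superposition) assay
#'
#' Drives two layers separately and jointly (three simulations with
#' identical per-layer inputs) and compares, per population, the sum of
#' the two single-layer perturbations with the joint perturbation. For
#' a linear system the two agree exactly.
#'
#' @param column a [build_column()] network.
#' @param layers a pair of distinct layer labels.
#' @param specificity,amplitude,sources_per_neuron drive parameters
#'   applied identically to both layers.
#' @param settle,stim,dt,pre_window,post_window protocol parameters.
#' @param initial optional settled initial states (see [run_drive()]).
#' @return list with `sum_of_singles` and `joint` (Hz, per population),
#'   the component perturbations, and accumulated `warnings`.
#' @export
additivity_test <- function(column, layers, specificity = "balanced",
                            amplitude = 10, sources_per_neuron = 100,
                            settle = 100, stim = 100, dt = 0.1,
                            pre_window = 20, post_window = 20,
                            initial = NULL) {
  if (length(layers) != 2 || layers[1] == layers[2])
    stop("additivity_test needs two distinct layers")
  run1 <- step_perturbation(column, layers[1], specificity, amplitude,
                            sources_per_neuron, settle, stim, dt,
                            pre_window, post_window, initial)
  run2 <- step_perturbation(column, layers[2], specificity, amplitude,
                            sources_per_neuron, settle, stim, dt,
                            pre_window, post_window, initial)
  joint <- step_perturbation(column, layers, specificity, amplitude,
                             sources_per_neuron, settle, stim, dt,
                             pre_window, post_window, initial)
  list(sum_of_singles = run1$delta + run2$delta, joint = joint$delta,
       single = list(run1$delta, run2$delta),
       warnings = unique(c(run1$warnings, run2$warnings, joint$warnings)))
}
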