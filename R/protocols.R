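#' Laminar drive protocol
#'
#' Describes an excitatory external drive into one or more layers of the
#' column. Target specificity selects which cell class receives the
#' drive: `"excitatory"` targets only the e population of each layer,
#' `"inhibitory"` only the i population, `"balanced"` both with
#' identical per-neuron input. In every condition the drive itself is an
#' excitatory projection (positive synaptic weight); only its targets
#' differ.
#'
#' @param layer one or more of `"L2/3"`/`"L23"`, `"L4"`, `"L5"`, `"L6"`.
#' @param specificity `"balanced"`, `"excitatory"` or `"inhibitory"`.
#' @param signal a [rate_signal()]; its onset is set to the settle time
#'   by [run_drive()].
#' @param sources_per_neuron in-degree of the drive connection (default
#'   100 independent presynaptic sources per target neuron).
#' @return A `drive_protocol`.
#' @export
drive_protocol <- function(layer, specificity = c("balanced", "excitatory",
                                                  "inhibitory"),
                           signal, sources_per_neuron = 100) {
  specificity <- match.arg(specificity)
  stopifnot(inherits(signal, "rate_signal"))
  targets <- unlist(lapply(layer, function(l) {
    ei <- layer_populations(l)
    switch(specificity, excitatory = ei[1], inhibitory = ei[2], balanced = ei)
  }))
  structure(list(layer = layer, specificity = specificity, signal = signal,
                 sources_per_neuron = sources_per_neuron, targets = targets),
            class = "drive_protocol")
}

#' Run a stimulus protocol on the column
#'
#' Applies the standard two-epoch protocol: the column settles under
#' background drive alone for `settle` ms (reaching a pre-stimulus
#' steady state), then the protocol's layer-specific stimulus turns on
#' (its onset is forced to `settle`) and the run continues for `stim`
#' ms. The drive is attached as an extra external population projecting
#' with the excitatory synaptic weight and the protocol's in-degree onto
#' the targeted population(s).
#'
#' @param column a [build_column()] network.
#' @param protocol a [drive_protocol()].
#' @param settle,stim epoch durations (ms).
#' @param dt time step (ms).
#' @param initial optional named list of `density_state`s (e.g. the
#'   `final_states` of a previous background-only run): with an already
#'   settled initial condition a short `settle` epoch suffices.
#' @return `rate_traces` with attributes `onset` (= `settle`) and
#'   `protocol`.
#' @export
run_drive <- function(column, protocol, settle = 100, stim = 100, dt = 0.1,
                      initial = NULL) {
  stopifnot(inherits(column, "cortical_column"),
            inherits(protocol, "drive_protocol"))
  meta <- attr(column, "column_meta")
  sig <- protocol$signal
  sig$onset <- settle
  specs <- unname(column$populations)
  conns <- column$connections
  if (any(vapply(protocol$targets, function(t)
    !(t %in% column$internal), TRUE)))
    stop("drive targets name populations absent from the column")
  specs <- c(specs, list(external_population("drive", sig)))
  for (tgt in protocol$targets)
    conns[[length(conns) + 1L]] <- connection(
      "drive", tgt, in_degree = protocol$sources_per_neuron,
      weight = meta$w_exc, delay = 0)
  net <- build_network(specs, conns)
  traces <- run_network(net, duration = settle + stim, dt = dt,
                        initial = initial)
  attr(traces, "onset") <- settle
  attr(traces, "protocol") <- protocol
  traces
}

#' Steady-state rate perturbation
#'
#' The output perturbation of a step stimulus is the post-stimulus
#' steady-state rate minus the pre-stimulus steady-state rate, per
#' population. Steady states are measured as mean rates over the final
#' `pre_window` ms before stimulus onset and the final `post_window` ms
#' of the run. If either window is visibly non-stationary (the two
#' window halves differ by more than 5% of the window mean and by more
#' than 0.01 Hz absolute), a warning string is recorded in the result.
#'
#' @param traces `rate_traces` from [run_drive()].
#' @param pre_window,post_window window lengths (ms, >= 10).
#' @param onset stimulus onset (ms); defaults to the `onset` attribute.
#' @return A `perturbation_result`: list with `delta` (Hz, post minus
#'   pre), `pre_rates`, `post_rates`, `warnings`.
#' @export
steady_state_perturbation <- function(traces, pre_window = 20,
                                      post_window = 20,
                                      onset = attr(traces, "onset")) {
  stopifnot(inherits(traces, "rate_traces"))
  if (is.null(onset)) stop("supply the stimulus onset time")
  if (pre_window < 10 || post_window < 10) stop("windows must be >= 10 ms")
  t_end <- max(traces$times)
  if (onset - pre_window < 0 || onset + post_window > t_end + 1e-9)
    stop("windows must lie inside the trace")
  warnings <- character()
  window_mean <- function(lo, hi, label) {
    sel <- traces$times > lo & traces$times <= hi
    m <- colMeans(traces$rates[sel, , drop = FALSE])
    half <- traces$times[sel] <= (lo + hi) / 2
    drift <- abs(colMeans(traces$rates[sel, , drop = FALSE][half, , drop = FALSE]) -
                 colMeans(traces$rates[sel, , drop = FALSE][!half, , drop = FALSE]))
    bad <- drift > pmax(0.05 * abs(m), 0.01)
    if (any(bad))
      warnings <<- c(warnings, sprintf(
        "non-stationary %s window for %s", label,
        paste(colnames(traces$rates)[bad], collapse = ", ")))
    m
  }
  pre <- window_mean(onset - pre_window, onset, "pre")
  post <- window_mean(t_end - post_window, t_end, "post")
  structure(list(delta = post - pre, pre_rates = pre, post_rates = post,
                 warnings = warnings),
            class = "perturbation_result")
}

#' @exportS3Method base::print
print.perturbation_result <- function(x, ...) {
  cat("<perturbation_result> delta F (Hz):\n")
  print(round(x$delta, 4))
  if (length(x$warnings)) cat("warnings:", x$warnings, sep = "\n  ")
  invisible(x)
}

#' Step-drive perturbation in one call
#'
#' Convenience wrapper: builds a step [drive_protocol()], runs it, and
#' extracts the steady-state perturbation.
#'
#' @param column a [build_column()] network.
#' @param layer,specificity,sources_per_neuron see [drive_protocol()].
#' @param amplitude step amplitude (Hz) in excess of background.
#' @param settle,stim,dt see [run_drive()].
#' @param pre_window,post_window see [steady_state_perturbation()].
#' @return A `perturbation_result`.
#' @export
step_perturbation <- function(column, layer, specificity = "balanced",
                              amplitude = 20, sources_per_neuron = 100,
                              settle = 100, stim = 100, dt = 0.1,
                              pre_window = 20, post_window = 20,
                              initial = NULL) {
  pr <- drive_protocol(layer, specificity,
                       rate_signal("step", baseline = 0,
                                   amplitude = amplitude),
                       sources_per_neuron)
  traces <- run_drive(column, pr, settle = settle, stim = stim, dt = dt,
                      initial = initial)
  steady_state_perturbation(traces, pre_window, post_window)
}
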