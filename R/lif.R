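#' Spiking-ensemble specification for the Monte-Carlo LIF oracle
#'
#' Describes a network of explicitly simulated leaky integrate-and-fire
#' neurons with instantaneous (shot-noise) synapses, used as the
#' brute-force validation oracle for the density solver. Each trial
#' draws a fresh connectivity realization (every target neuron samples
#' its mean in-degree of presynaptic partners) and fresh Gaussian
#' initial voltages; background and stimulus arrive as independent
#' Poisson event trains per neuron.
#'
#' @param pop_sizes named integer vector of neurons per population.
#' @param in_degree_mat target x source matrix of mean in-degrees.
#' @param weight_mat target x source matrix of synaptic jumps (mV).
#' @param delay_mat target x source matrix of mean delays (ms).
#' @param delay_sd_mat target x source matrix of per-synapse delay
#'   standard deviations (ms); each synapse draws its delay from a
#'   normal truncated below at one integration step.
#' @param tau_m membrane time constant (ms).
#' @param v_theta,v_reset threshold and reset (mV, relative to rest).
#' @param bg_rate named vector: effective background event rate per
#'   neuron (Hz, already multiplied by the background in-degree).
#' @param bg_weight background synaptic jump (mV).
#' @param t_ref refractory period (ms); the column model uses 0.
#' @param init_mean,init_sd Gaussian initial-voltage parameters (mV).
#' @param seed mandatory integer seed.
#' @return A `lif_ensemble_spec`.
#' @export
lif_ensemble_spec <- function(pop_sizes, in_degree_mat = NULL,
                              weight_mat = NULL, delay_mat = NULL,
                              delay_sd_mat = NULL,
                              tau_m = 10, v_theta = 15, v_reset = 0,
                              bg_rate = 0, bg_weight = 0, t_ref = 0,
                              init_mean = 0, init_sd = 5, seed) {
  if (missing(seed)) stop("a seed is mandatory for the spiking oracle")
  npop <- length(pop_sizes)
  if (is.null(names(pop_sizes))) names(pop_sizes) <- paste0("pop", seq_len(npop))
  zero <- matrix(0, npop, npop)
  if (is.null(in_degree_mat)) in_degree_mat <- zero
  if (is.null(weight_mat)) weight_mat <- zero
  if (is.null(delay_mat)) delay_mat <- zero
  if (is.null(delay_sd_mat)) delay_sd_mat <- zero
  if (any(pop_sizes < 1)) stop("every population needs at least one neuron")
  bg_rate <- rep_len(bg_rate, npop)
  structure(list(pop_sizes = pop_sizes, in_degree_mat = in_degree_mat,
                 weight_mat = weight_mat, delay_mat = delay_mat,
                 delay_sd_mat = delay_sd_mat,
                 tau_m = tau_m, v_theta = v_theta, v_reset = v_reset,
                 bg_rate = bg_rate, bg_weight = bg_weight, t_ref = t_ref,
                 init_mean = init_mean, init_sd = init_sd,
                 seed = as.integer(seed)),
            class = "lif_ensemble_spec")
}

#' Column-model spiking spec at reduced scale
#'
#' Converts a column configuration into a spiking-ensemble spec with
#' population sizes multiplied by `scale`. In-degrees always use the
#' full-scale population counts (the density model's coupling is
#' parameterized by in-degree, so scaling down the instantiated neurons
#' must preserve the per-neuron input statistics).
#'
#' @param config a `column_config`.
#' @param scale population-size scale factor (e.g. 0.1).
#' @param seed mandatory integer seed.
#' @param in_degree_method in-degree convention, as in [build_column()].
#' @return A `lif_ensemble_spec`.
#' @export
lif_column_spec <- function(config = default_column_config(), scale = 0.1,
                            seed,
                            in_degree_method = c("binomial", "product")) {
  validate_column_config(config)
  pops <- config$populations
  w_exc <- weight_from_charge(config$synapse$current_amplitude,
                              config$synapse$tau_s,
                              config$synapse$capacitance)
  w_inh <- -config$synapse$g_inh_ratio * w_exc
  bg <- rescale_background(config$background$rate, w_exc,
                           config$background$rescale)
  is_inh <- grepl("i$", pops)
  kin <- column_in_degrees(config, match.arg(in_degree_method))
  wmat <- matrix(ifelse(rep(is_inh, each = length(pops)), w_inh, w_exc),
                 nrow = length(pops), dimnames = dimnames(config$conn_prob))
  dmat <- matrix(ifelse(rep(is_inh, each = length(pops)),
                        config$delays$inhibitory, config$delays$excitatory),
                 nrow = length(pops), dimnames = dimnames(config$conn_prob))
  dsd <- matrix(ifelse(rep(is_inh, each = length(pops)),
                       config$delays$inhibitory_sd %||% 0,
                       config$delays$excitatory_sd %||% 0),
                nrow = length(pops), dimnames = dimnames(config$conn_prob))
  sizes <- pmax(1L, as.integer(round(config$population_sizes * scale)))
  names(sizes) <- pops
  lif_ensemble_spec(sizes, kin, wmat, dmat, dsd,
                    tau_m = config$neuron$tau_m,
                    v_theta = config$neuron$v_theta,
                    v_reset = config$neuron$v_reset,
                    bg_rate = config$background$in_degree * bg$rate,
                    bg_weight = bg$weight,
                    t_ref = config$neuron$t_ref, seed = seed)
}

#' Run the Monte-Carlo LIF ensemble
#'
#' Simulates `n_trials` independent trials (fresh connectivity and
#' initial voltages per trial, seeded as `spec$seed + trial`) and
#' returns per-population firing-rate traces binned at `bin_ms`,
#' averaged across trials, together with the per-trial traces for
#' standard-error estimation. Identical seeds give identical spike
#' trains.
#'
#' @param spec a [lif_ensemble_spec()].
#' @param stimulus optional [drive_protocol()]; its signal drives the
#'   targeted populations at `sources_per_neuron` times the signal rate
#'   per neuron, with the excitatory weight `stim_weight`.
#' @param duration simulated time (ms).
#' @param n_trials number of trials (>= 1).
#' @param dt integration step (ms).
#' @param bin_ms rate bin width (ms).
#' @param stim_weight stimulus synaptic jump (mV).
#' @param stim_onset stimulus onset override (ms).
#' @return list with `times` (bin centers, ms), `rates` (bins x
#'   populations, trial-averaged, Hz), `trial_rates` (array bins x
#'   populations x trials).
#' @export
simulate_ensemble <- function(spec, stimulus = NULL, duration, n_trials = 1,
                              dt = 0.1, bin_ms = 1, stim_weight = 0.1756,
                              stim_onset = NULL) {
  stopifnot(inherits(spec, "lif_ensemble_spec"))
  if (duration < dt) stop("duration must be >= dt")
  if (n_trials < 1) stop("n_trials must be >= 1")
  n_steps <- as.integer(round(duration / dt))
  bin_steps <- as.integer(round(bin_ms / dt))
  npop <- length(spec$pop_sizes)
  stim_rate <- matrix(0, n_steps, npop)
  if (!is.null(stimulus)) {
    stopifnot(inherits(stimulus, "drive_protocol"))
    sig <- stimulus$signal
    if (!is.null(stim_onset)) sig$onset <- stim_onset
    t_grid <- (seq_len(n_steps) - 1L) * dt
    per_neuron <- stimulus$sources_per_neuron * signal_rate(sig, t_grid)
    for (tgt in stimulus$targets) {
      j <- match(tgt, names(spec$pop_sizes))
      if (is.na(j)) stop(sprintf("stimulus target '%s' not in the ensemble", tgt))
      stim_rate[, j] <- stim_rate[, j] + per_neuron
    }
  }
  n_bins <- ceiling(n_steps / bin_steps)
  trial_rates <- array(0, dim = c(n_bins, npop, n_trials))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  for (tr in seq_len(n_trials)) {
    set.seed(spec$seed + tr)
    res <- lif_trial_cpp(as.integer(spec$pop_sizes), spec$in_degree_mat,
                         spec$weight_mat, spec$delay_mat, spec$delay_sd_mat,
                         spec$tau_m, spec$v_theta,
                         spec$v_reset, spec$bg_rate, spec$bg_weight,
                         stim_rate, stim_weight, dt, n_steps,
                         spec$init_mean, spec$init_sd,
                         bin_steps, as.integer(round(spec$t_ref / dt)))
    trial_rates[, , tr] <- res$rates
  }
  rates <- apply(trial_rates, c(1, 2), mean)
  colnames(rates) <- names(spec$pop_sizes)
  list(times = (seq_len(n_bins) - 0.5) * bin_ms, rates = rates,
       trial_rates = trial_rates)
}

#' Steady-state summary of an ensemble run
#'
#' Mean and standard error (across trials) of the per-population rate
#' over a trailing window.
#'
#' @param ens result of [simulate_ensemble()].
#' @param window trailing window (ms).
#' @return data.frame with `population`, `mean_hz`, `se_hz`.
#' @export
ensemble_steady_state <- function(ens, window = 50) {
  sel <- ens$times > max(ens$times) - window
  per_trial <- apply(ens$trial_rates[sel, , , drop = FALSE], c(2, 3), mean)
  n_tr <- dim(ens$trial_rates)[3]
  data.frame(population = colnames(ens$rates),
             mean_hz = rowMeans(per_trial),
             se_hz = apply(per_trial, 1, stats::sd) / sqrt(n_tr),
             row.names = NULL)
}
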