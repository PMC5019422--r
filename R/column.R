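#' The packaged cortical column configuration
#'
#' Loads the four-layer, two cell-type column constants (population
#' sizes, connection-probability matrix, neuron and synapse parameters,
#' background drive, delays) shipped with the package in
#' `extdata/potjans_diesmann_column.yaml`, transcribed from the Potjans
#' & Diesmann (2014) microcircuit with the L4e to L2/3e probability
#' doubled to 0.088 and the background rate/weight rescaling applied at
#' build time.
#'
#' @param path optional path to an alternative YAML file with the same
#'   schema.
#' @return A `column_config`: list with `populations`,
#'   `population_sizes` (named), `conn_prob` (8x8 matrix, target rows x
#'   source columns), `neuron`, `synapse`, `background`, `delays`.
#' @export
default_column_config <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "potjans_diesmann_column.yaml",
                        package = "dipdeR", mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  pops <- unlist(raw$populations)
  cp <- do.call(rbind, raw$conn_prob[pops])
  dimnames(cp) <- list(target = pops, source = pops)
  cfg <- structure(list(
    populations = pops,
    population_sizes = stats::setNames(unlist(raw$population_sizes), pops),
    conn_prob = cp,
    neuron = raw$neuron,
    synapse = raw$synapse,
    background = list(
      in_degree = stats::setNames(unlist(raw$background$in_degree), pops),
      rate = raw$background$rate,
      rescale = raw$background$rescale),
    delays = raw$delays), class = "column_config")
  validate_column_config(cfg, packaged = is.null(path))
  cfg
}

#' Validate a column configuration
#'
#' Checks ranges and shapes; names the offending field on failure.
#' `packaged = TRUE` additionally asserts the packaged constants (the
#' 0.088 L4e to L2/3e override and the inhibitory/excitatory weight
#' ratio of 4) so that transcription errors cannot pass silently; a
#' user-perturbed matrix (e.g. from [perturb_connectivity()]) skips
#' those equality checks.
#'
#' @param config a `column_config`.
#' @param packaged assert the packaged literal values too.
#' @return `config`, invisibly.
#' @export
validate_column_config <- function(config, packaged = FALSE) {
  fail <- function(field, msg)
    stop(sprintf("invalid column config: field '%s' %s", field, msg))
  cp <- config$conn_prob
  if (!is.matrix(cp) || any(dim(cp) != length(config$populations)))
    fail("conn_prob", "must be a square matrix over the populations")
  if (any(cp < 0) || any(cp > 1)) fail("conn_prob", "entries must lie in [0, 1]")
  if (any(config$population_sizes <= 0)) fail("population_sizes", "must be > 0")
  if (config$background$rescale <= 0) fail("background.rescale", "must be > 0")
  if (config$background$rate < 0) fail("background.rate", "must be >= 0")
  if (any(config$background$in_degree < 0)) fail("background.in_degree", "must be >= 0")
  if (config$neuron$tau_m <= 0) fail("neuron.tau_m", "must be > 0")
  if (config$neuron$v_theta <= 0) fail("neuron.v_theta", "must be > 0")
  if (config$synapse$capacitance <= 0) fail("synapse.capacitance", "must be > 0")
  if (config$synapse$tau_s <= 0) fail("synapse.tau_s", "must be > 0")
  if (config$synapse$g_inh_ratio <= 0) fail("synapse.g_inh_ratio", "must be > 0")
  if (packaged) {
    if (abs(cp["L23e", "L4e"] - 0.088) > 1e-12)
      fail("conn_prob[L23e, L4e]", "must equal the doubled value 0.088")
    if (config$synapse$g_inh_ratio != 4)
      fail("synapse.g_inh_ratio", "must equal 4")
  }
  invisible(config)
}

#' Charge-conserving synaptic weight conversion
#'
#' Converts an exponential postsynaptic-current synapse into the
#' equivalent instantaneous voltage jump by integrating the total
#' delivered charge: \eqn{\Delta v = Q / C_m = (w / C_m)
#' \int_0^\infty e^{-t/\tau_s} dt = w \tau_s / C_m}. With the packaged
#' constants (87.8 pA, 0.5 ms, 250 pF) this gives 0.1756 mV for an
#' excitatory synapse; inhibitory synapses are this value times minus
#' the inhibitory/excitatory ratio (4), i.e. -0.7024 mV.
#'
#' @param current_amplitude PSC amplitude (pA), positive (apply the sign
#'   afterwards for inhibition).
#' @param tau_s synaptic time constant (ms), positive.
#' @param capacitance membrane capacitance (pF), positive.
#' @return voltage jump in mV.
#' @examples
#' weight_from_charge(87.8, 0.5, 250)   # 0.1756
#' @export
weight_from_charge <- function(current_amplitude, tau_s, capacitance) {
  if (!is.finite(current_amplitude) || current_amplitude <= 0)
    stop("current_amplitude must be > 0")
  if (!is.finite(tau_s) || tau_s <= 0) stop("tau_s must be > 0")
  if (!is.finite(capacitance) || capacitance <= 0)
    stop("capacitance must be > 0")
  current_amplitude * tau_s / capacitance
}

#' In-degree of a probabilistic connection
#'
#' The expected number of inputs per target neuron is the pairwise
#' connection probability times the size of the presynaptic population;
#' it multiplies the presynaptic rate in the density model's coupling.
#'
#' @param conn_prob_entry pairwise connection probability in \[0, 1\].
#' @param n_source presynaptic population size (>= 0).
#' @return in-degree (dimensionless).
#' @export
in_degree <- function(conn_prob_entry, n_source) {
  if (any(!is.finite(conn_prob_entry)) ||
      any(conn_prob_entry < 0) || any(conn_prob_entry > 1))
    stop("connection probability must lie in [0, 1]")
  if (any(n_source < 0)) stop("n_source must be >= 0")
  conn_prob_entry * n_source
}

#' Exact binomial in-degree of a probabilistic connection
#'
#' The source microcircuit derives the total synapse count of a
#' projection from its pairwise connection probability through the
#' binomial identity \eqn{K_{tot} = \ln(1-p) / \ln(1 - 1/(N_{pre}
#' N_{post}))} (synapses are drawn with replacement, so the expected
#' count exceeds \eqn{p N_{pre} N_{post}} for strong projections); the
#' per-neuron in-degree is \eqn{K_{tot} / N_{post} \approx -N_{pre}
#' \ln(1-p)}. For small probabilities this coincides with
#' [in_degree()]; for the strongest projections (e.g. recurrent
#' inhibition at p = 0.373) it is ~25% larger, which materially changes
#' the column's operating point.
#'
#' @param conn_prob_entry pairwise connection probability in \[0, 1).
#' @param n_source,n_target pre- and postsynaptic population sizes.
#' @return in-degree (dimensionless).
#' @export
in_degree_binomial <- function(conn_prob_entry, n_source, n_target) {
  if (any(conn_prob_entry < 0) || any(conn_prob_entry >= 1))
    stop("connection probability must lie in [0, 1)")
  ifelse(conn_prob_entry == 0, 0,
         log(1 - conn_prob_entry) /
           (n_target * log(1 - 1 / (as.numeric(n_source) * n_target))))
}

#' In-degree matrix of a column configuration
#'
#' @param config a `column_config`.
#' @param method `"binomial"` for the exact synapse-count formula
#'   ([in_degree_binomial()], the default used to build the column) or
#'   `"product"` for plain probability times source size
#'   ([in_degree()]).
#' @return target x source matrix of in-degrees.
#' @export
column_in_degrees <- function(config, method = c("binomial", "product")) {
  method <- match.arg(method)
  n <- length(config$populations)
  n_src <- matrix(config$population_sizes, n, n, byrow = TRUE)
  n_tgt <- matrix(config$population_sizes, n, n)
  k <- if (method == "binomial")
    in_degree_binomial(config$conn_prob, n_src, n_tgt)
  else in_degree(config$conn_prob, n_src)
  dimnames(k) <- dimnames(config$conn_prob)
  k
}

#' Background rescaling: trade rate for weight at fixed mean drive
#'
#' Divides the background rate by `factor` and multiplies the synaptic
#' weight by the same factor. The mean background input (rate x weight)
#' is exactly preserved while the shot-noise variance increases by
#' `factor`.
#'
#' @param rate background rate (Hz).
#' @param weight synaptic weight (mV).
#' @param factor rescale factor (> 0); the column model uses 8.54.
#' @return list with rescaled `rate` and `weight`.
#' @export
rescale_background <- function(rate, weight, factor) {
  if (!is.finite(factor) || factor <= 0) stop("factor must be > 0")
  list(rate = rate / factor, weight = weight * factor)
}

#' Build the cortical column network
#'
#' Constructs the 8-population recurrent network from a column
#' configuration: one internal (density-simulated) population per
#' layer/cell type with Gaussian initial voltages (mean 0, sd 5 mV),
#' recurrent connections with in-degree = connection probability x
#' presynaptic size, weights from the charge-conserving conversion
#' (+0.1756 mV excitatory, -0.7024 mV inhibitory), source-type mean
#' delays, and a shared external background population with the
#' rate/weight rescaling applied.
#'
#' @param config a [default_column_config()]-style `column_config`.
#' @param n_bins,v_min voltage grid resolution and lower wall shared by
#'   all populations. The default wall sits 21 inhibitory jumps below
#'   reset: strongly inhibited populations (L6e) carry mass far below
#'   reset, and a shallow wall visibly biases their rates.
#' @param in_degree_method `"binomial"` (exact synapse-count formula,
#'   default) or `"product"`; see [column_in_degrees()].
#' @return A `dipde_network` with attribute `column_meta` (config,
#'   excitatory/inhibitory/background weights, in-degree matrix).
#' @export
build_column <- function(config = default_column_config(), n_bins = 300,
                         v_min = -15,
                         in_degree_method = c("binomial", "product")) {
  validate_column_config(config)
  in_degree_method <- match.arg(in_degree_method)
  pops <- config$populations
  w_exc <- weight_from_charge(config$synapse$current_amplitude,
                              config$synapse$tau_s,
                              config$synapse$capacitance)
  w_inh <- -config$synapse$g_inh_ratio * w_exc
  bg <- rescale_background(config$background$rate, w_exc,
                           config$background$rescale)
  kin_mat <- column_in_degrees(config, in_degree_method)

  is_inh <- grepl("i$", pops)
  specs <- lapply(pops, function(nm)
    internal_population(nm, tau_m = config$neuron$tau_m, v_min = v_min,
                        v_theta = config$neuron$v_theta, n_bins = n_bins,
                        init_mean = 0, init_sd = 5))
  specs <- c(specs, list(external_population(
    "background", rate_signal("constant", baseline = bg$rate))))

  conns <- list()
  for (tgt in pops) {
    for (src in pops) {
      kin <- kin_mat[tgt, src]
      if (kin <= 0) next
      inh <- is_inh[match(src, pops)]
      conns[[length(conns) + 1L]] <- connection(
        src, tgt, in_degree = kin,
        weight = if (inh) w_inh else w_exc,
        delay = if (inh) config$delays$inhibitory else config$delays$excitatory,
        delay_sd = if (inh) config$delays$inhibitory_sd %||% 0
                   else config$delays$excitatory_sd %||% 0)
    }
    conns[[length(conns) + 1L]] <- connection(
      "background", tgt, in_degree = config$background$in_degree[[tgt]],
      weight = bg$weight, delay = 0)
  }

  net <- build_network(specs, conns)
  attr(net, "column_meta") <- list(config = config, w_exc = w_exc,
                                   w_inh = w_inh, w_bg = bg$weight,
                                   bg_rate = bg$rate, in_degrees = kin_mat,
                                   in_degree_method = in_degree_method)
  class(net) <- c("cortical_column", class(net))
  net
}

#' Map a layer label to its populations
#' @keywords internal
layer_populations <- function(layer) {
  layer <- sub("^L2/3$", "L23", layer)
  valid <- c("L23", "L4", "L5", "L6")
  if (!(layer %in% valid))
    stop(sprintf("unknown layer '%s' (use %s)", layer,
                 paste(valid, collapse = ", ")))
  paste0(layer, c("e", "i"))
}
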