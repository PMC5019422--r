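#' Declare an internal (density-simulated) population
#'
#' @param name unique population label, e.g. `"L5e"`.
#' @param tau_m membrane time constant (ms).
#' @param v_min,v_theta,n_bins voltage grid parameters, see
#'   [build_grid()].
#' @param init_mean,init_sd parameters of the Gaussian initial voltage
#'   density (mV).
#' @return A `population_spec`.
#' @export
internal_population <- function(name, tau_m = 10, v_min = -5, v_theta = 15,
                                n_bins = 200, init_mean = 0, init_sd = 5) {
  if (!is.finite(tau_m) || tau_m <= 0) stop("tau_m must be > 0")
  structure(list(name = name, kind = "internal", tau_m = tau_m,
                 v_min = v_min, v_theta = v_theta, n_bins = n_bins,
                 init_mean = init_mean, init_sd = init_sd),
            class = "population_spec")
}

#' Declare an external (prescribed-rate) population
#'
#' @param name unique population label.
#' @param signal a [rate_signal()] giving its firing rate over time.
#' @return A `population_spec`.
#' @export
external_population <- function(name, signal) {
  stopifnot(inherits(signal, "rate_signal"))
  structure(list(name = name, kind = "external", signal = signal),
            class = "population_spec")
}

#' Declare a rate connection
#'
#' The effective input rate delivered to the target's synaptic operator
#' is `in_degree` times the (delayed) source firing rate: the in-degree
#' models a convergent connection with that many independent presynaptic
#' sources per target neuron.
#'
#' @param source,target population names.
#' @param in_degree mean number of inputs per target neuron (>= 0).
#' @param weight synaptic voltage jump (mV); non-zero when
#'   `in_degree > 0`.
#' @param delay mean transmission delay (ms, >= 0); rounded to the
#'   nearest multiple of the simulation `dt` at run time.
#' @param delay_sd standard deviation (ms) of the per-synapse delay
#'   distribution. With `delay_sd = 0` the connection uses the single
#'   mean delay; with `delay_sd > 0` the rate coupling is convolved with
#'   a discretized Gaussian delay kernel truncated below at one time
#'   step (matching per-synapse delays drawn from a truncated normal,
#'   which damps artificial ringing that a single shared delay can
#'   sustain in a recurrent loop).
#' @return A `connection_spec`.
#' @export
connection <- function(source, target, in_degree, weight, delay = 0,
                       delay_sd = 0) {
  if (!is.finite(in_degree) || in_degree < 0) stop("in_degree must be >= 0")
  if (in_degree > 0 && (!is.finite(weight) || weight == 0))
    stop("weight must be non-zero when in_degree > 0")
  if (!is.finite(delay) || delay < 0) stop("delay must be >= 0")
  if (!is.finite(delay_sd) || delay_sd < 0) stop("delay_sd must be >= 0")
  structure(list(source = source, target = target, in_degree = in_degree,
                 weight = weight, delay = delay, delay_sd = delay_sd),
            class = "connection_spec")
}

#' Discretized truncated-Gaussian delay kernel
#'
#' Tap weights on the delay grid `d = dt, 2 dt, ...` proportional to a
#' normal density with the given mean and sd, truncated below at `dt`
#' and above at `mean + 4 sd`, normalized to sum to 1. With `sd = 0`
#' the kernel is a single tap at the rounded mean delay.
#'
#' @param delay,delay_sd mean and sd of the delay distribution (ms).
#' @param dt time step (ms).
#' @return data.frame with `steps` (integer delays) and `weight`.
#' @export
delay_kernel <- function(delay, delay_sd, dt) {
  if (delay_sd <= 0) {
    return(data.frame(steps = as.integer(round(delay / dt)), weight = 1))
  }
  lo <- 1L
  hi <- max(lo, as.integer(ceiling((delay + 4 * delay_sd) / dt)))
  steps <- lo:hi
  w <- stats::dnorm(steps * dt, mean = delay, sd = delay_sd)
  w <- w / sum(w)
  keep <- w > 1e-6
  w <- w[keep] / sum(w[keep])
  data.frame(steps = steps[keep], weight = w)
}

#' Assemble a population-density network
#'
#' Compiles the leak operator, the Gaussian initial state, and one
#' synaptic operator per distinct incoming weight for every internal
#' population, and indexes the connections for the run-time coupling
#' loop (recurrent coupling assigns the presynaptic population's output
#' rate, delayed and multiplied by the in-degree, to the postsynaptic
#' operator's input rate).
#'
#' @param populations list of [internal_population()] /
#'   [external_population()] specs; names must be unique.
#' @param connections list of [connection()] specs between declared
#'   populations; external populations cannot be targets.
#' @return A `dipde_network`.
#' @seealso [run_network()], [build_column()]
#' @export
build_network <- function(populations, connections = list()) {
  populations <- unname(populations)
  names <- vapply(populations, function(p) p$name, "")
  if (anyDuplicated(names)) stop("population names must be unique")
  kinds <- vapply(populations, function(p) p$kind, "")
  internal <- names[kinds == "internal"]
  external <- names[kinds == "external"]
  for (cn in connections) {
    if (!(cn$source %in% names))
      stop(sprintf("connection source '%s' names no declared population", cn$source))
    if (!(cn$target %in% names))
      stop(sprintf("connection target '%s' names no declared population", cn$target))
    if (cn$target %in% external)
      stop(sprintf("external population '%s' cannot be a connection target", cn$target))
  }
  pops <- stats::setNames(populations, names)

  # compile per-internal-population solver objects
  compiled <- list()
  for (nm in internal) {
    sp <- pops[[nm]]
    grid <- build_grid(sp$v_min, sp$v_theta, sp$n_bins)
    wts <- unique(vapply(
      Filter(function(cn) cn$target == nm && cn$in_degree > 0, connections),
      function(cn) cn$weight, 0))
    compiled[[nm]] <- list(
      grid = grid,
      leak = leak_operator(grid, sp$tau_m),
      ops = lapply(wts, function(w) synaptic_operator(grid, w)),
      weights = wts,
      init = gaussian_init(grid, sp$init_mean, sp$init_sd))
  }

  # connection table with integer indices for the C++ core (0-based)
  live <- Filter(function(cn) cn$in_degree > 0, connections)
  conn_table <- list(
    target = vapply(live, function(cn) match(cn$target, internal) - 1L, 0L),
    op = vapply(live, function(cn) {
      match(cn$weight, compiled[[cn$target]]$weights) - 1L
    }, 0L),
    source_type = vapply(live, function(cn)
      if (pops[[cn$source]]$kind == "internal") 0L else 1L, 0L),
    source = vapply(live, function(cn) {
      if (pops[[cn$source]]$kind == "internal") match(cn$source, internal) - 1L
      else match(cn$source, external) - 1L
    }, 0L),
    in_degree = vapply(live, function(cn) cn$in_degree, 0),
    delay = vapply(live, function(cn) cn$delay, 0),
    delay_sd = vapply(live, function(cn) cn$delay_sd %||% 0, 0))

  structure(list(populations = pops, connections = connections,
                 internal = internal, external = external,
                 compiled = compiled, conn_table = conn_table),
            class = "dipde_network")
}

#' @exportS3Method base::print
print.dipde_network <- function(x, ...) {
  cat(sprintf("<dipde_network> %d internal + %d external populations, %d connections\n",
              length(x$internal), length(x$external), length(x$connections)))
  invisible(x)
}

#' Run a population-density network simulation
#'
#' Advances all internal populations synchronously with time step `dt`:
#' at each step, delayed source rates are read first for every
#' connection (Jacobi update, order-independent), then each population
#' is advanced by the combined leak + synaptic operator update. Delay
#' buffers are pre-filled with each source's initial rate (the
#' prescribed rate at t = 0 for external populations, 0 for internal
#' ones). The simulation is fully deterministic.
#'
#' @param network a [build_network()] object.
#' @param duration total simulated time (ms).
#' @param dt time step (ms); the column analyses use 0.1 ms.
#' @param initial optional named list of `density_state` overrides for
#'   internal populations (default: each population's compiled Gaussian
#'   initial state), or the `rate_traces` of a previous run, in which
#'   case its final states are used and the internal delay buffers are
#'   pre-filled with its final rates (so a settled network resumes
#'   without a spurious onset transient).
#' @param initial_rates optional named vector (Hz) used to pre-fill the
#'   internal delay buffers; defaults to 0 (or to the final rates of an
#'   `initial` traces object).
#' @param courant Euler sub-step stability bound (max total outflow rate
#'   times sub-step).
#' @return A `rate_traces` object: list with `times` (ms, time at the
#'   end of each step), `rates` (matrix, one column per internal
#'   population, Hz), `dt`, and `final_states`.
#' @export
run_network <- function(network, duration, dt = 0.1, initial = NULL,
                        initial_rates = NULL, courant = 0.4) {
  stopifnot(inherits(network, "dipde_network"))
  if (inherits(initial, "rate_traces")) {
    if (is.null(initial_rates))
      initial_rates <- initial$rates[nrow(initial$rates), ]
    initial <- initial$final_states
  }
  if (!is.finite(duration) || duration < dt) stop("duration must be >= dt")
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0")
  n_steps <- as.integer(round(duration / dt))

  pops_cpp <- lapply(network$internal, function(nm) {
    cp <- network$compiled[[nm]]
    p0 <- if (!is.null(initial) && !is.null(initial[[nm]]))
      initial[[nm]]$mass else cp$init$mass
    if (length(p0) != cp$grid$n_bins) stop("initial state has wrong length")
    list(L = cp$leak$matrix,
         S = lapply(cp$ops, function(o) o$matrix),
         F = lapply(cp$ops, function(o) o$firing),
         p0 = p0)
  })

  n_ext <- length(network$external)
  ext_rates <- matrix(0, nrow = n_steps, ncol = max(1L, n_ext))
  if (n_ext > 0) {
    t_grid <- (seq_len(n_steps) - 1L) * dt   # rate during step k ~ rate at t_k
    for (j in seq_len(n_ext))
      ext_rates[, j] <- signal_rate(network$populations[[network$external[j]]]$signal,
                                    t_grid)
  }

  # expand each connection into its delay-kernel taps (a single tap when
  # delay_sd = 0); tap weights partition the in-degree
  ct <- network$conn_table
  taps <- lapply(seq_along(ct$target), function(i) {
    kern <- delay_kernel(ct$delay[i], ct$delay_sd[i], dt)
    data.frame(target = ct$target[i], op = ct$op[i],
               source_type = ct$source_type[i], source = ct$source[i],
               in_degree = ct$in_degree[i] * kern$weight,
               delay = kern$steps)
  })
  taps <- do.call(rbind, taps)
  init_rates <- numeric(length(network$internal))
  names(init_rates) <- network$internal
  if (!is.null(initial_rates)) {
    common <- intersect(names(initial_rates), network$internal)
    init_rates[common] <- initial_rates[common]
  }
  res <- dipde_run_cpp(pops_cpp, taps$target, taps$op, taps$source_type,
                       taps$source, taps$in_degree,
                       as.integer(taps$delay), ext_rates,
                       unname(init_rates), dt, n_steps, courant)
  rates <- res$rates
  colnames(rates) <- network$internal
  finals <- lapply(seq_along(network$internal), function(i)
    structure(list(mass = res$final[[i]], time = n_steps * dt),
              class = "density_state"))
  names(finals) <- network$internal
  structure(list(times = seq_len(n_steps) * dt, rates = rates, dt = dt,
                 final_states = finals),
            class = "rate_traces")
}

#' @exportS3Method base::print
print.rate_traces <- function(x, ...) {
  cat(sprintf("<rate_traces> %d steps of %g ms, populations: %s\n",
              length(x$times), x$dt, paste(colnames(x$rates), collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.rate_traces <- function(x, ...) {
  data.frame(time = x$times, x$rates, check.names = FALSE)
}

#' Write rate traces to CSV
#'
#' One `time` column (ms) plus one column per population (Hz), with an
#' optional machine-readable comment header.
#'
#' @param traces a `rate_traces` object.
#' @param path output file.
#' @param header optional named character vector written as leading
#'   `# key: value` comment lines.
#' @export
write_traces <- function(traces, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header))
    writeLines(sprintf("# %s: %s", names(header), header), con)
  utils::write.csv(as.data.frame(traces), con, row.names = FALSE)
  invisible(path)
}

#' Mean steady-state rates at the end of a run
#'
#' @param traces a `rate_traces` object.
#' @param window averaging window (ms) ending at the final sample.
#' @return named vector of mean rates (Hz).
#' @export
final_rates <- function(traces, window = 20) {
  sel <- traces$times > max(traces$times) - window
  colMeans(traces$rates[sel, , drop = FALSE])
}
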