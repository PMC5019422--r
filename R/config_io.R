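#' Build a network from a YAML/JSON configuration file
#'
#' The file has two sections. `populations` is a list of entries with a
#' `name` and a `kind`: internal entries take `tau_m`, `v_min`,
#' `v_theta`, `n_bins`, `init_mean`, `init_sd` (defaults as in
#' [internal_population()]); external entries take a `signal` block
#' with `kind` (`constant` / `step` / `sinusoid`), `baseline`,
#' `amplitude`, `onset`, `frequency`. `connections` is a list of
#' entries with `source`, `target`, `in_degree`, `weight`, `delay`,
#' `delay_sd`. All units are mV, ms and Hz.
#'
#' @param path YAML (or JSON, which YAML parses) configuration file.
#' @return A [build_network()] object.
#' @export
read_network_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$populations)) stop("config needs a 'populations' section")
  pops <- lapply(raw$populations, function(p) {
    if (is.null(p$name)) stop("every population needs a name")
    kind <- p$kind %||% "internal"
    if (kind == "internal") {
      internal_population(p$name,
                          tau_m = p$tau_m %||% 10,
                          v_min = p$v_min %||% -5,
                          v_theta = p$v_theta %||% 15,
                          n_bins = p$n_bins %||% 200,
                          init_mean = p$init_mean %||% 0,
                          init_sd = p$init_sd %||% 5)
    } else if (kind == "external") {
      sig <- p$signal
      if (is.null(sig)) stop(sprintf("external population '%s' needs a signal",
                                     p$name))
      external_population(p$name, rate_signal(
        kind = sig$kind %||% "constant",
        baseline = sig$baseline %||% 0,
        amplitude = sig$amplitude %||% 0,
        onset = sig$onset %||% 0,
        frequency = sig$frequency))
    } else stop(sprintf("unknown population kind '%s'", kind))
  })
  conns <- lapply(raw$connections, function(cn)
    connection(cn$source, cn$target,
               in_degree = cn$in_degree %||% 0,
               weight = cn$weight %||% 0,
               delay = cn$delay %||% 0,
               delay_sd = cn$delay_sd %||% 0))
  build_network(pops, conns)
}
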