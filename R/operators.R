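#' @keywords internal
flux_operator <- function(matrix, kind, firing, weight = NA_real_) {
  structure(list(matrix = matrix, kind = kind, firing = firing,
                 weight = weight, rate_scalable = kind == "synaptic"),
            class = "flux_operator")
}

#' @exportS3Method base::print
print.flux_operator <- function(x, ...) {
  cat(sprintf("<flux_operator> kind = %s, %d bins%s\n", x$kind,
              nrow(x$matrix),
              if (is.na(x$weight)) "" else sprintf(", weight = %g mV", x$weight)))
  invisible(x)
}

#' Leak flux operator
#'
#' Finite-volume discretization of the passive leak drift
#' \eqn{dv/dt = -v/\tau_m}. Mass crosses an interior edge at voltage
#' \eqn{v_e} toward the reset potential at rate
#' \eqn{|v_e| / (\tau_m \Delta v_{donor})}, the donor bin being the one
#' on the far side of the edge from 0. No leak flux crosses the
#' threshold or the lower wall (the drift points inward at both). The
#' bin containing 0 mV is the unique fixed point: under leak alone, all
#' mass collapses into it.
#'
#' @param grid a [build_grid()] object.
#' @param tau_m membrane time constant (ms), positive.
#' @return A `flux_operator` whose `matrix` (units 1/ms) has zero column
#'   sums (probability conservation) and non-negative off-diagonals.
#' @export
leak_operator <- function(grid, tau_m) {
  stopifnot(inherits(grid, "voltage_grid"))
  if (!is.finite(tau_m) || tau_m <= 0) stop("tau_m must be > 0")
  n <- grid$n_bins
  M <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    e <- grid$edges[i + 1L]  # edge between bin i (below) and i + 1 (above)
    if (e > 0) {             # mass above the edge drifts down
      r <- e / (tau_m * grid$widths[i + 1L])
      M[i, i + 1L] <- M[i, i + 1L] + r
      M[i + 1L, i + 1L] <- M[i + 1L, i + 1L] - r
    } else if (e < 0) {      # mass below the edge drifts up
      r <- -e / (tau_m * grid$widths[i])
      M[i + 1L, i] <- M[i + 1L, i] + r
      M[i, i] <- M[i, i] - r
    }
  }
  flux_operator(M, "leak", firing = numeric(n))
}

#' Shot-noise synaptic flux operator
#'
#' Unit-rate displacement operator for a synapse that instantaneously
#' jumps the membrane voltage by `weight` mV. Scaled by the presynaptic
#' rate \eqn{\lambda_{in}}, it moves each bin's probability mass by
#' `weight`; a jump landing between two bins is split between them by
#' linear interpolation so that total mass is conserved and the mean
#' displacement equals `weight` exactly. For excitatory weights, mass
#' displaced beyond threshold is re-injected in the reset bin and
#' recorded in the operator's `firing` vector (this flux, times the
#' presynaptic rate, is the population firing rate). For inhibitory
#' weights, mass that would cross the lower wall accumulates in the
#' lowest bin.
#'
#' @param grid a [build_grid()] object (uniform).
#' @param weight synaptic voltage jump (mV), non-zero, smaller in
#'   magnitude than the domain span.
#' @return A `flux_operator` with `kind = "synaptic"`; entry `firing[j]`
#'   is the fraction of bin `j`'s unit-rate outflow that crosses
#'   threshold.
#' @export
synaptic_operator <- function(grid, weight) {
  stopifnot(inherits(grid, "voltage_grid"))
  if (!is.finite(weight) || weight == 0) stop("synaptic weight must be non-zero")
  span <- grid$v_theta - grid$v_min
  if (abs(weight) >= span)
    stop("synaptic weight magnitude must be smaller than the voltage domain span")
  n <- grid$n_bins
  h <- grid$widths[1]
  if (max(abs(grid$widths - h)) > 1e-12 * h)
    stop("synaptic_operator requires a uniform grid")
  s <- weight / h
  if (abs(s - round(s)) < 1e-9) s <- round(s)  # snap near-integer shifts
  k <- floor(s)
  frac <- s - k
  reset <- grid$reset_index
  M <- matrix(0, n, n)
  fire <- numeric(n)
  for (j in seq_len(n)) {
    dests <- c(j + k, j + k + 1L)
    wts <- c(1 - frac, frac)
    for (m in 1:2) {
      wt <- wts[m]
      if (wt <= 0) next
      d <- dests[m]
      if (d > n) {              # crossed threshold: re-inject at reset
        M[reset, j] <- M[reset, j] + wt
        fire[j] <- fire[j] + wt
      } else if (d < 1L) {      # hit the lower wall: pile up in bin 1
        M[1L, j] <- M[1L, j] + wt
      } else {
        M[d, j] <- M[d, j] + wt
      }
    }
    M[j, j] <- M[j, j] - 1
    # enforce an exactly zero column sum against rounding in frac splits
    M[j, j] <- M[j, j] - sum(M[, j])
  }
  flux_operator(M, "synaptic", firing = fire, weight = weight)
}
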