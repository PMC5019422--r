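#' Discretize the membrane-voltage domain
#'
#' Builds a uniform finite-volume grid on the voltage interval
#' \eqn{[v_{min}, v_\theta]}. Each subdomain (bin) is half-open,
#' \eqn{[e_i, e_{i+1})}: a voltage falling exactly on an interior edge
#' belongs to the upper bin. The reset potential is fixed at 0 mV
#' (voltages are expressed relative to rest) and must lie inside the
#' domain; the bin containing it receives the probability mass
#' re-injected after threshold crossings.
#'
#' @param v_min lower edge of the voltage domain (mV), must be negative.
#'   The continuous theory lives on \eqn{(-\infty, v_\theta]}; choose
#'   `v_min` several inhibitory jumps below 0 so that the hard wall at
#'   `v_min` carries negligible mass.
#' @param v_theta spike threshold (mV), must be positive.
#' @param n_bins number of equal-width subdomains (at least 10).
#' @return An object of class `voltage_grid`: a list with `v_min`,
#'   `v_theta`, `edges` (length `n_bins + 1`), `widths`, `n_bins`,
#'   `reset_index` (1-based bin containing 0 mV).
#' @examples
#' g <- build_grid(-5, 15, 200)
#' g$widths[1]      # 0.1 mV
#' g$reset_index    # bin containing the reset potential
#' @seealso [gaussian_init()], [leak_operator()], [synaptic_operator()]
#' @export
build_grid <- function(v_min, v_theta, n_bins) {
  stopifnot(length(v_min) == 1L, length(v_theta) == 1L, length(n_bins) == 1L,
            is.finite(v_min), is.finite(v_theta))
  if (!(v_min < 0 && 0 < v_theta))
    stop("voltage domain must satisfy v_min < 0 < v_theta (reset = 0 mV)")
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 10L)
    stop("n_bins must be an integer >= 10")
  edges <- seq(v_min, v_theta, length.out = n_bins + 1L)
  widths <- diff(edges)
  reset_index <- findInterval(0, edges)
  structure(
    list(v_min = v_min, v_theta = v_theta, edges = edges, widths = widths,
         n_bins = n_bins, reset_index = reset_index),
    class = "voltage_grid")
}

#' @exportS3Method base::print
print.voltage_grid <- function(x, ...) {
  cat(sprintf("<voltage_grid> [%g, %g] mV, %d bins of %g mV, reset bin %d\n",
              x$v_min, x$v_theta, x$n_bins, x$widths[1], x$reset_index))
  invisible(x)
}

#' Gaussian initial voltage density
#'
#' Initializes the membrane-voltage probability density to a normal
#' distribution, integrated exactly over each subdomain and renormalized
#' so that the total probability mass is 1 (mass falling outside the
#' grid is folded back in by the renormalization). The column model
#' initializes every population with mean at the reset potential and a
#' standard deviation of 5 mV.
#'
#' @param grid a [build_grid()] object.
#' @param mean mean membrane voltage (mV).
#' @param sd standard deviation (mV), must be positive.
#' @return An object of class `density_state`: a list with `mass`
#'   (probability mass per bin, sums to 1) and `time` (ms).
#' @examples
#' g <- build_grid(-5, 15, 200)
#' s <- gaussian_init(g, 0, 5)
#' sum(s$mass)
#' @export
gaussian_init <- function(grid, mean = 0, sd = 5) {
  stopifnot(inherits(grid, "voltage_grid"))
  if (!is.finite(sd) || sd <= 0) stop("sd must be > 0")
  if (sd < min(grid$widths) * 1e-3) {
    # delta limit: all mass in the bin containing `mean` (half-open
    # convention: a mean exactly on an edge belongs to the upper bin)
    idx <- min(max(findInterval(mean, grid$edges), 1L), grid$n_bins)
    mass <- numeric(grid$n_bins)
    mass[idx] <- 1
  } else {
    cdf <- stats::pnorm(grid$edges, mean = mean, sd = sd)
    mass <- diff(cdf)
    tot <- sum(mass)
    if (tot <= 0) stop("initial Gaussian has no mass inside the grid")
    mass <- mass / tot
  }
  density_state(mass, time = 0)
}

#' Construct a density state from a mass vector
#'
#' @param mass non-negative probability mass per bin; must sum to 1
#'   within 1e-10 after the caller's own normalization.
#' @param time simulation time (ms).
#' @return A `density_state` object.
#' @export
density_state <- function(mass, time = 0) {
  mass <- as.numeric(mass)
  if (any(mass < -1e-12)) stop("probability mass must be non-negative")
  if (abs(sum(mass) - 1) > 1e-8)
    stop("probability mass must sum to 1")
  structure(list(mass = mass, time = time), class = "density_state")
}

#' @exportS3Method base::print
print.density_state <- function(x, ...) {
  cat(sprintf("<density_state> %d bins, total mass %.12f, t = %g ms\n",
              length(x$mass), sum(x$mass), x$time))
  invisible(x)
}

#' Tabulate a density state
#'
#' @param x a `density_state`.
#' @param grid the grid the state lives on.
#' @param ... unused.
#' @return data.frame with the left edge of each bin (mV) and its mass.
#' @export
as.data.frame.density_state <- function(x, grid = NULL, ...) {
  if (is.null(grid)) stop("supply the voltage_grid the state lives on")
  data.frame(v_left = grid$edges[-(grid$n_bins + 1L)], mass = x$mass)
}
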