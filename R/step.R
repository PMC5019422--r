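#' Advance a voltage density by one time step
#'
#' Applies the combined leak and synaptic flux operators to the
#' probability-mass vector over one step of length `dt`, returning the
#' updated state and the instantaneous population firing rate. The
#' formal update is \eqn{p(t + \Delta t) = \exp(\Delta t (L + \sum_s
#' \lambda_s S_s)) p(t)}; the default integrator is Heun (explicit
#' trapezoid) sub-stepping with the sub-step chosen so that the maximum
#' total outflow rate times the sub-step stays below `courant` (0.4).
#' The update matrix \eqn{I + hA + (hA)^2/2} has non-negative entries
#' whenever the sub-step times the maximum outflow is at most 1, so the
#' scheme conserves mass exactly and preserves non-negativity.
#' `method = "expm"` uses the exact matrix exponential
#' ([Matrix::expm()]) as a reference path.
#'
#' The firing rate is the probability mass carried across threshold by
#' the synaptic operators during the step (their `firing` flux into the
#' reset bin), divided by `dt`.
#'
#' @param state a `density_state`.
#' @param leak a leak `flux_operator` on the same grid.
#' @param synaptic_inputs list of inputs, each a list with elements
#'   `operator` (a synaptic `flux_operator`) and `rate` (presynaptic
#'   event rate, Hz, non-negative). An effective rate for a convergent
#'   connection is in-degree times per-source rate.
#' @param dt time step (ms).
#' @param method `"heun"` (sub-stepped, default) or `"expm"`.
#' @param courant sub-step stability bound for the sub-stepped path.
#' @return list with `state` (advanced `density_state`) and `rate`, the
#'   population firing rate over the step (Hz).
#' @examples
#' g <- build_grid(-5, 15, 200)
#' st <- gaussian_init(g, 0, 5)
#' L <- leak_operator(g, 10)
#' S <- synaptic_operator(g, 0.5)
#' out <- step_density(st, L, list(list(operator = S, rate = 800)), dt = 0.1)
#' out$rate
#' @export
step_density <- function(state, leak, synaptic_inputs = list(), dt,
                         method = c("heun", "expm"), courant = 0.4) {
  method <- match.arg(method)
  stopifnot(inherits(state, "density_state"), inherits(leak, "flux_operator"))
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0")
  n <- length(state$mass)
  A <- leak$matrix
  fire <- numeric(n)
  for (inp in synaptic_inputs) {
    op <- inp$operator
    rate <- inp$rate
    stopifnot(inherits(op, "flux_operator"))
    if (!is.finite(rate) || rate < 0) stop("presynaptic rates must be >= 0")
    lam <- rate / 1000                     # Hz -> events per ms
    if (lam == 0) next
    A <- A + lam * op$matrix
    fire <- fire + lam * op$firing
  }
  p <- state$mass
  if (method == "heun") {
    maxout <- max(0, -diag(A))
    n_sub <- max(1L, as.integer(ceiling(dt * maxout / courant)))
    h <- dt / n_sub
    spike <- 0
    for (i in seq_len(n_sub)) {
      f1 <- as.vector(A %*% p)
      y1 <- p + h * f1
      f2 <- as.vector(A %*% y1)
      spike <- spike + h * sum(fire * (p + y1)) / 2
      p <- p + h / 2 * (f1 + f2)
    }
  } else {
    p_new <- as.numeric(as.matrix(Matrix::expm(Matrix::Matrix(dt * A)) %*% p))
    spike <- dt * sum(fire * (p + p_new) / 2)  # trapezoidal firing flux
    p <- p_new
  }
  if (min(p) < -1e-12)
    stop("numerical scheme failure: negative probability mass")
  state$mass <- p
  state$time <- state$time + dt
  list(state = state, rate = 1000 * spike / dt)
}
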