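#' Prescribed firing-rate signal for an external population
#'
#' External populations deliver Poisson-like shot-noise input at a
#' prescribed, deterministic rate. Three shapes are supported:
#' * `constant`: `baseline` at all times;
#' * `step`: `baseline`, jumping to `baseline + amplitude` at `onset`;
#' * `sinusoid`: `baseline` before `onset`, then a raised cosine
#'   `baseline + amplitude * (1 - cos(2 pi f (t - onset))) / 2`, which
#'   starts continuously at `baseline`, never goes negative, and has
#'   peak excess exactly `amplitude`.
#'
#' @param kind `"constant"`, `"step"` or `"sinusoid"`.
#' @param baseline baseline rate (Hz, non-negative).
#' @param amplitude step height or sinusoid peak excess (Hz).
#' @param onset stimulus onset (ms).
#' @param frequency drive frequency (Hz), sinusoid only.
#' @return A `rate_signal` object.
#' @seealso [signal_rate()]
#' @export
rate_signal <- function(kind = c("constant", "step", "sinusoid"),
                        baseline = 0, amplitude = 0, onset = 0,
                        frequency = NULL) {
  kind <- match.arg(kind)
  if (!is.finite(baseline) || baseline < 0) stop("baseline rate must be >= 0")
  if (kind != "constant") {
    if (!is.finite(amplitude)) stop("amplitude must be finite")
    if (baseline + amplitude < 0)
      stop("rate signal would go negative: baseline + amplitude < 0")
    if (kind == "sinusoid" && amplitude < 0)
      stop("sinusoid amplitude must be >= 0")
  }
  if (kind == "sinusoid") {
    if (is.null(frequency) || !is.finite(frequency) || frequency <= 0)
      stop("sinusoid requires a positive frequency (Hz)")
  }
  structure(list(kind = kind, baseline = baseline, amplitude = amplitude,
                 onset = onset, frequency = frequency),
            class = "rate_signal")
}

#' Evaluate a rate signal
#'
#' @param signal a [rate_signal()].
#' @param t time(s) in ms.
#' @return rate(s) in Hz, vectorized over `t`.
#' @export
signal_rate <- function(signal, t) {
  stopifnot(inherits(signal, "rate_signal"))
  switch(signal$kind,
    constant = rep(signal$baseline, length(t)),
    step = ifelse(t >= signal$onset,
                  signal$baseline + signal$amplitude, signal$baseline),
    sinusoid = ifelse(t >= signal$onset,
      signal$baseline + signal$amplitude *
        (1 - cos(2 * pi * signal$frequency * (t - signal$onset) / 1000)) / 2,
      signal$baseline))
}

#' @exportS3Method base::print
print.rate_signal <- function(x, ...) {
  cat(sprintf("<rate_signal> %s, baseline %g Hz", x$kind, x$baseline))
  if (x$kind != "constant")
    cat(sprintf(", amplitude %g Hz, onset %g ms", x$amplitude, x$onset))
  if (x$kind == "sinusoid") cat(sprintf(", %g Hz drive", x$frequency))
  cat("\n")
  invisible(x)
}
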