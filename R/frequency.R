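#' Least-squares sinusoid fit at a fixed frequency
#'
#' Fits `a + b cos(2 pi f t) + c sin(2 pi f t)` to a uniformly sampled
#' series and returns the fundamental amplitude `sqrt(b^2 + c^2)`. More
#' robust than peak picking on short, noisy windows.
#'
#' @param x series values.
#' @param times_ms sample times (ms).
#' @param f_hz frequency (Hz).
#' @return list with `amplitude`, `offset`, `b`, `c`, `phase` (radians).
#' @export
fit_sinusoid <- function(x, times_ms, f_hz) {
  w <- 2 * pi * f_hz * times_ms / 1000
  X <- cbind(1, cos(w), sin(w))
  cf <- stats::lm.fit(X, x)$coefficients
  list(amplitude = sqrt(cf[2]^2 + cf[3]^2), offset = cf[1],
       b = unname(cf[2]), c = unname(cf[3]),
       phase = atan2(-cf[3], cf[2]))
}

#' Total harmonic distortion of a rate trace
#'
#' Compares the spectral power at harmonics of the driving frequency to
#' the power at the fundamental. The analysis window is trimmed from
#' its end to the largest whole number of drive periods (at least 3
#' required), harmonic amplitudes \eqn{A_i} are extracted by quadrature
#' at each harmonic up to the Nyquist frequency, and powers are
#' \eqn{V_i = A_i^2 / 2}. Two summaries are returned:
#' * `thd`: \eqn{\sum_{i \ge 2} V_i^2 / V_1}, the power-spectral form
#'   with squared harmonic powers over the fundamental power;
#' * `thd_amplitude`: \eqn{\sqrt{\sum_{i \ge 2} A_i^2} / A_1}, the
#'   conventional amplitude-ratio form.
#' Both are zero for a pure sinusoid. If the fundamental amplitude is
#' below `floor_hz` (responses that weak are not meaningfully resolved)
#' the result is flagged and the ratios are `NA`.
#'
#' @param x rate series (Hz).
#' @param f_drive driving frequency (Hz).
#' @param dt sample interval (ms).
#' @param window optional index range (integer vector) selecting the
#'   analysis window; it should exclude the onset transient. Default:
#'   the whole series.
#' @param max_harmonics cap on the number of harmonics (default: all up
#'   to Nyquist).
#' @param floor_hz minimum resolvable fundamental amplitude (Hz).
#' @return list with `thd`, `thd_amplitude`, `fundamental_amplitude`,
#'   `harmonic_amplitudes`, `flagged`.
#' @export
total_harmonic_distortion <- function(x, f_drive, dt, window = NULL,
                                      max_harmonics = Inf,
                                      floor_hz = 0.05) {
  if (!is.null(window)) x <- x[window]
  period_steps <- 1000 / (f_drive * dt)
  n_per <- floor(length(x) / period_steps)
  if (n_per < 3)
    stop("analysis window must cover at least 3 drive periods")
  n_use <- round(n_per * period_steps)
  x <- x[seq(length(x) - n_use + 1L, length(x))]
  t_ms <- (seq_along(x) - 1L) * dt
  x <- x - mean(x)
  nyquist <- 1000 / (2 * dt)
  n_harm <- min(floor(nyquist / f_drive), max_harmonics)
  amps <- vapply(seq_len(n_harm), function(i) {
    w <- 2 * pi * i * f_drive * t_ms / 1000
    2 * sqrt(mean(x * cos(w))^2 + mean(x * sin(w))^2)
  }, 0)
  a1 <- amps[1]
  if (a1 < floor_hz)
    return(list(thd = NA_real_, thd_amplitude = NA_real_,
                fundamental_amplitude = a1, harmonic_amplitudes = amps,
                flagged = TRUE))
  v <- amps^2 / 2
  list(thd = sum(v[-1]^2) / v[1],
       thd_amplitude = sqrt(sum(amps[-1]^2)) / a1,
       fundamental_amplitude = a1, harmonic_amplitudes = amps,
       flagged = FALSE)
}

#' -3 dB cutoff of a gain curve
#'
#' Finds the frequency at which the response first falls 3 dB below its
#' maximum, above the maximum, by log-log linear interpolation between
#' the bracketing sample frequencies. The reference is the maximum in
#' the sweep (not a zero-frequency gain, which is not sampled), which
#' also handles bandpass curves.
#'
#' `reference` selects the curve on which the \eqn{1/\sqrt{2}} ("3 dB
#' down") drop is read:
#' * `"power"` (default): the normalized power response, i.e. the
#'   squared modulation amplitude — the quantity a spectral estimate of
#'   the response reports, and the convention used when the gain curve
#'   is compared against power spectral densities of matched spiking
#'   simulations. The amplitude ratio at this cutoff is
#'   \eqn{2^{-1/4} \approx 0.841}.
#' * `"amplitude"`: the textbook half-power point, amplitude ratio
#'   \eqn{1/\sqrt{2}}.
#' The two coincide in reported frequency only for response shapes
#' measured on the matching scale; for the column's non-first-order
#' transfers they differ, and the methods vignette discusses the
#' choice.
#'
#' @param frequencies sweep frequencies (Hz), increasing.
#' @param gains non-negative amplitude gains at those frequencies.
#' @param reference `"power"` or `"amplitude"` (see above).
#' @return cutoff frequency (Hz), or `NA` with attribute
#'   `status = "out-of-band"` when the curve never crosses -3 dB within
#'   the band.
#' @export
cutoff_frequency <- function(frequencies, gains,
                             reference = c("power", "amplitude")) {
  reference <- match.arg(reference)
  stopifnot(length(frequencies) == length(gains), !is.unsorted(frequencies))
  if (any(gains < 0)) stop("gains must be >= 0")
  thr <- max(gains) *
    if (reference == "power") 2^(-1 / 4) else 1 / sqrt(2)
  i_pk <- which.max(gains)
  below <- which(gains < thr & seq_along(gains) > i_pk)
  if (!length(below))
    return(structure(NA_real_, status = "out-of-band"))
  i <- below[1]
  lf <- log(frequencies[(i - 1):i])
  lg <- log(gains[(i - 1):i])
  exp(lf[1] + (log(thr) - lg[1]) * diff(lf) / diff(lg))
}

#' Amplitude response and linear-filter characterization
#'
#' Sweeps sinusoidal drive across `frequencies`, extracts the output's
#' fundamental amplitude by least-squares fit on the post-transient
#' window, and forms the gain curve `A_out / A_in` (with `A_in` the
#' fundamental amplitude of the raised-cosine input, i.e. half its peak
#' excess). The -3 dB cutoff is interpolated from the gain curve, and
#' per-frequency THD is reported alongside.
#'
#' For estimator validation, `column` may instead be a function
#' `function(f_hz, amplitude_hz)` returning a list with `times` (ms)
#' and `response` (the output series with any onset transient already
#' excluded); this lets closed-form systems be swept through the same
#' estimator.
#'
#' @param column a [build_column()] network, or a generator function as
#'   above.
#' @param in_layer driven layer label.
#' @param out_population output population name, e.g. `"L5e"`.
#' @param frequencies sweep frequencies (Hz), at least 5, spanning the
#'   expected cutoff.
#' @param amplitude peak excess of the raised-cosine drive (Hz).
#' @param specificity drive target specificity.
#' @param sources_per_neuron drive in-degree.
#' @param settle settle epoch (ms).
#' @param transient post-onset transient discarded before fitting (ms).
#' @param n_periods whole drive periods retained for the fit.
#' @param dt time step (ms).
#' @param cutoff_reference `"power"` (default) or `"amplitude"`; see
#'   [cutoff_frequency()].
#' @return A `filter_characterization`: list with `frequencies`, `gain`
#'   (amplitude ratio), `power_gain` (its square), `cutoff_hz`, `thd`,
#'   `amplitude_out`, `amplitude_in`.
#' @export
amplitude_response <- function(column, in_layer = "L4",
                               out_population = "L5e", frequencies,
                               amplitude = 20, specificity = "balanced",
                               sources_per_neuron = 100, settle = 100,
                               transient = 100, n_periods = 3, dt = 0.1,
                               cutoff_reference = c("power", "amplitude")) {
  cutoff_reference <- match.arg(cutoff_reference)
  if (length(frequencies) < 5)
    stop("sweep at least 5 frequencies spanning the expected cutoff")
  frequencies <- sort(frequencies)
  a_in <- amplitude / 2
  gains <- numeric(length(frequencies))
  thd <- numeric(length(frequencies))
  a_out <- numeric(length(frequencies))
  for (i in seq_along(frequencies)) {
    f <- frequencies[i]
    period <- 1000 / f
    if (is.function(column)) {
      sim <- column(f, amplitude)
      t_ms <- sim$times
      y <- sim$response
    } else {
      stim <- transient + ceiling(n_periods * period)
      pr <- drive_protocol(in_layer, specificity,
                           rate_signal("sinusoid", baseline = 0,
                                       amplitude = amplitude,
                                       frequency = f),
                           sources_per_neuron)
      traces <- run_drive(column, pr, settle = settle, stim = stim, dt = dt)
      keep <- traces$times > settle + transient
      t_ms <- traces$times[keep]
      y <- traces$rates[keep, out_population]
    }
    n_use <- round(floor(length(y) * dt / period) * period / dt)
    sel <- seq(length(y) - n_use + 1L, length(y))
    fit <- fit_sinusoid(y[sel], t_ms[sel], f)
    a_out[i] <- fit$amplitude
    gains[i] <- fit$amplitude / a_in
    thd[i] <- tryCatch(
      total_harmonic_distortion(y[sel], f, dt)$thd,
      error = function(e) NA_real_)
  }
  structure(list(frequencies = frequencies, gain = gains,
                 power_gain = gains^2,
                 cutoff_hz = cutoff_frequency(frequencies, gains,
                                              cutoff_reference),
                 cutoff_reference = cutoff_reference,
                 thd = thd, amplitude_out = a_out, amplitude_in = a_in),
            class = "filter_characterization")
}

#' @exportS3Method base::print
print.filter_characterization <- function(x, ...) {
  cat("<filter_characterization>\n")
  print(data.frame(frequency_hz = x$frequencies, gain = signif(x$gain, 4)))
  co <- x$cutoff_hz
  if (is.na(co)) cat("cutoff: out of band\n")
  else cat(sprintf("-3 dB cutoff (%s response): %.2f Hz\n",
                   x$cutoff_reference, co))
  invisible(x)
}
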