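test_that("a zero-amplitude drive reproduces the background-only run", {
  col <- get_column()
  pr <- drive_protocol("L4", "balanced",
                       rate_signal("step", baseline = 0, amplitude = 0))
  tr <- run_drive(col, pr, settle = 20, stim = 30, dt = 0.1,
                  initial = get_bg_traces())
  base <- run_network(col, 50, 0.1, initial = get_bg_traces())
  expect_equal(tr$rates, base$rates, tolerance = 1e-12)
})

test_that("specificity only changes which populations receive the drive", {
  mk <- function(sp) drive_protocol("L4", sp,
                                    rate_signal("step", amplitude = 5))
  expect_equal(mk("balanced")$targets, c("L4e", "L4i"))
  expect_equal(mk("excitatory")$targets, "L4e")
  expect_equal(setdiff(mk("balanced")$targets, mk("excitatory")$targets),
               "L4i")
})

test_that("steady_state_perturbation computes post minus pre and flags drift", {
  mk_traces <- function(rates) {
    structure(list(times = seq_len(nrow(rates)) * 0.1, rates = rates,
                   dt = 0.1), class = "rate_traces")
  }
  flat <- mk_traces(matrix(3, 2000, 2,
                           dimnames = list(NULL, c("a", "b"))))
  res <- steady_state_perturbation(flat, onset = 100)
  expect_equal(unname(res$delta), c(0, 0))
  expect_length(res$warnings, 0)

  stepped <- mk_traces(cbind(a = c(rep(2, 1000), rep(5, 1000)),
                             b = rep(1, 2000)))
  res <- steady_state_perturbation(stepped, onset = 100)
  expect_equal(unname(res$delta), c(3, 0))

  drifting <- mk_traces(cbind(a = seq(0, 10, length.out = 2000)))
  res <- steady_state_perturbation(drifting, onset = 100)
  expect_match(res$warnings, "non-stationary", all = TRUE)
  expect_gt(length(res$warnings), 0)

  expect_error(steady_state_perturbation(flat, onset = 5), "inside")
  expect_error(steady_state_perturbation(flat, pre_window = 5, onset = 100),
               ">= 10 ms")
})

test_that("homogeneity error is the stated linear-extrapolation residual", {
  expect_equal(homogeneity_error(3, 4, 6), 1)
  expect_equal(homogeneity_error(0, 1, 2), 0)
  expect_equal(homogeneity_error(c(0, 3), c(1, 4), c(2, 6)), c(0, 1))
  expect_equal(homogeneity_error(5, 5 - 2, 5 - 4), 0)   # linear decrease
})

test_that("additivity is exact for a linear system and near-exact in the
          balanced column regime", {
  expect_error(additivity_test(get_column(), c("L4", "L4")), "distinct")
  # weak drive on a single background-driven population: responses in the
  # shallow-gain regime superpose to solver tolerance
  bg <- external_population("bg", rate_signal("constant", baseline = 1100))
  mk <- function(a1, a2) {
    build_network(
      list(internal_population("p", n_bins = 100),
           bg,
           external_population("d1", rate_signal("step", baseline = 0,
                                                 amplitude = a1, onset = 100)),
           external_population("d2", rate_signal("step", baseline = 0,
                                                 amplitude = a2, onset = 100))),
      list(connection("bg", "p", 1, 1.4996),
           connection("d1", "p", 1, 0.1756),
           connection("d2", "p", 1, 0.1756)))
  }
  delta <- function(a1, a2) {
    tr <- run_network(mk(a1, a2), 200, 0.1)
    attr(tr, "onset") <- 100
    steady_state_perturbation(tr, onset = 100)$delta
  }
  d1 <- delta(30, 0); d2 <- delta(0, 30); dj <- delta(30, 30)
  expect_lt(abs((d1 + d2) - dj), 0.02 * abs(dj))
})

test_that("pure sinusoids carry no harmonic distortion", {
  dt <- 0.1
  t <- seq(0, 499.9, by = dt)
  x <- 5 + 2 * sin(2 * pi * 20 * t / 1000)   # 10 exact periods per 500 ms
  res <- total_harmonic_distortion(x, 20, dt)
  expect_lt(res$thd, 1e-12)
  expect_lt(res$thd_amplitude, 1e-6)
  expect_equal(res$fundamental_amplitude, 2, tolerance = 1e-6)
  expect_false(res$flagged)
})

test_that("THD matches the closed-form spectrum of a two-harmonic signal", {
  dt <- 0.1
  t <- seq(0, 999.9, by = dt)
  x <- cos(2 * pi * 10 * t / 1000) + 0.1 * cos(2 * pi * 20 * t / 1000)
  res <- total_harmonic_distortion(x, 10, dt)
  # oracle: V1 = 1^2/2, V2 = 0.1^2/2; sum_i>=2 Vi^2 / V1 = 5e-5
  expect_equal(res$thd, (0.005^2) / 0.5, tolerance = 1e-6)
  expect_equal(res$thd_amplitude, 0.1, tolerance = 1e-6)
})

test_that("rectification creates measurable harmonics", {
  dt <- 0.1
  t <- seq(0, 999.9, by = dt)
  x <- pmax(sin(2 * pi * 10 * t / 1000), 0)
  res <- total_harmonic_distortion(x, 10, dt)
  expect_gt(res$thd, 1e-4)
  expect_gt(res$thd_amplitude, 0.1)
})

test_that("sub-floor fundamentals are flagged rather than reported", {
  dt <- 0.1
  t <- seq(0, 999.9, by = dt)
  x <- 0.01 * sin(2 * pi * 10 * t / 1000)
  res <- total_harmonic_distortion(x, 10, dt)
  expect_true(res$flagged)
  expect_true(is.na(res$thd))
  expect_error(total_harmonic_distortion(x[1:100], 10, dt), "3 drive periods")
})

test_that("the sinusoid fit recovers amplitude and offset", {
  t <- seq(0, 400, by = 0.1)
  x <- 7 + 1.3 * cos(2 * pi * 12 * t / 1000 + 0.7)
  fit <- fit_sinusoid(x, t, 12)
  expect_equal(unname(fit$amplitude), 1.3, tolerance = 1e-9)
  expect_equal(unname(fit$offset), 7, tolerance = 1e-9)
})

test_that("the estimator recovers a closed-form RC filter cutoff within 5%", {
  tau_s <- 0.01                       # 10 ms RC time constant
  fc_true <- 1 / (2 * pi * tau_s)     # 15.92 Hz
  rc_system <- function(f_hz, amplitude_hz) {
    gain <- 1 / sqrt(1 + (2 * pi * f_hz * tau_s)^2)
    phase <- -atan(2 * pi * f_hz * tau_s)
    t <- seq(0, max(400, 4000 / f_hz), by = 0.1)
    a_in <- amplitude_hz / 2
    list(times = t,
         response = 5 + a_in * gain * cos(2 * pi * f_hz * t / 1000 + phase))
  }
  fc <- amplitude_response(rc_system,
                           frequencies = c(2, 5, 10, 15, 20, 30, 45, 60),
                           amplitude = 10, cutoff_reference = "amplitude")
  expect_lt(abs(fc$cutoff_hz - fc_true) / fc_true, 0.05)
  # gains match |H| itself
  expect_equal(fc$gain, 1 / sqrt(1 + (fc$frequencies / fc_true)^2),
               tolerance = 1e-3)
})

test_that("normalized balanced gain curves are amplitude-invariant", {
  col <- get_column()
  freqs <- c(4, 8, 12, 20, 30)
  g <- sapply(c(10, 20), function(a)
    amplitude_response(col, "L4", "L5e", frequencies = freqs,
                       amplitude = a)$gain)
  norm <- sweep(g, 2, g[1, ], "/")
  expect_lt(max(abs(norm[, 1] - norm[, 2]) / norm[, 1]), 0.05)
})

test_that("cutoff interpolation handles bandpass and out-of-band curves", {
  f <- c(2, 5, 10, 20, 40, 80)
  bp <- c(0.2, 0.6, 1.0, 0.9, 0.5, 0.2)
  co <- cutoff_frequency(f, bp, reference = "amplitude")
  expect_gt(co, 20); expect_lt(co, 40)
  rising <- c(0.1, 0.2, 0.3, 0.5, 0.8, 1.0)
  out <- cutoff_frequency(f, rising)
  expect_true(is.na(out))
  expect_equal(attr(out, "status"), "out-of-band")
  # power reference crosses earlier than amplitude reference on a
  # monotone falling curve
  lp <- 1 / sqrt(1 + (f / 15)^2)
  expect_lt(cutoff_frequency(f, lp, "power"),
            cutoff_frequency(f, lp, "amplitude"))
})
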