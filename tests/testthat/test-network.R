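test_that("rate signals have the documented shapes and stay non-negative", {
  s <- rate_signal("step", baseline = 2, amplitude = 20, onset = 100)
  expect_equal(signal_rate(s, c(0, 99.9, 100, 150)), c(2, 2, 22, 22))
  sin20 <- rate_signal("sinusoid", baseline = 3, amplitude = 20, onset = 50,
                       frequency = 10)
  t <- seq(0, 300, by = 0.1)
  r <- signal_rate(sin20, t)
  expect_equal(r[t == 50], 3)                    # continuous at onset
  expect_equal(max(r), 23, tolerance = 1e-6)     # peak excess = amplitude
  expect_gte(min(r), 0)
  expect_error(rate_signal("step", baseline = 1, amplitude = -5), "negative")
  expect_error(rate_signal("sinusoid", baseline = 0, amplitude = 5), "frequency")
  expect_error(rate_signal("constant", baseline = -1), "baseline")
})

test_that("network validation catches dangling names and external targets", {
  pops <- list(internal_population("a"),
               external_population("x", rate_signal("constant", baseline = 5)))
  expect_error(build_network(pops, list(connection("b", "a", 1, 0.1))),
               "source 'b'")
  expect_error(build_network(pops, list(connection("a", "x", 1, 0.1))),
               "external")
  expect_error(build_network(list(internal_population("a"),
                                  internal_population("a"))),
               "unique")
  expect_error(connection("a", "b", in_degree = 2, weight = 0), "non-zero")
})

test_that("run bookkeeping: duration/dt give the advertised sample count", {
  net <- single_pop_network(n_bins = 100)
  tr <- run_network(net, duration = 200, dt = 0.1)
  expect_equal(length(tr$times), 2000L)
  expect_equal(nrow(tr$rates), 2000L)
  expect_equal(colnames(tr$rates), "p1")
  df <- as.data.frame(tr)
  expect_named(df, c("time", "p1"))
})

test_that("unconnected populations evolve independently", {
  bg <- external_population("bg", rate_signal("constant", baseline = 900))
  two <- build_network(
    list(internal_population("a", n_bins = 100),
         internal_population("b", n_bins = 100), bg),
    list(connection("bg", "a", 1, 1.5), connection("bg", "b", 1, 1.5)))
  one <- build_network(list(internal_population("a", n_bins = 100), bg),
                       list(connection("bg", "a", 1, 1.5)))
  tr2 <- run_network(two, 50, 0.1)
  tr1 <- run_network(one, 50, 0.1)
  expect_equal(tr2$rates[, "a"], tr1$rates[, "a"], tolerance = 1e-12)
  expect_equal(tr2$rates[, "a"], tr2$rates[, "b"], tolerance = 1e-12)
})

test_that("an in-degree of zero is a null coupling", {
  bg <- external_population("bg", rate_signal("constant", baseline = 900))
  base <- build_network(
    list(internal_population("a", n_bins = 100),
         internal_population("b", n_bins = 100), bg),
    list(connection("bg", "a", 1, 1.5), connection("bg", "b", 1, 1.5)))
  nullc <- build_network(
    base$populations[c("a", "b", "bg")],
    c(base$connections, list(connection("a", "b", 0, 0.2))))
  expect_equal(run_network(nullc, 50, 0.1)$rates,
               run_network(base, 50, 0.1)$rates, tolerance = 1e-14)
})

test_that("the effective drive rate is in-degree times source rate", {
  # 100 sources at 100 Hz and 1 source at 10 kHz are the same drive
  mk <- function(in_deg, rate) {
    net <- build_network(
      list(internal_population("p", n_bins = 100),
           external_population("x", rate_signal("constant", baseline = rate))),
      list(connection("x", "p", in_deg, 0.35)))
    run_network(net, 50, 0.1)$rates
  }
  expect_equal(mk(100, 100), mk(1, 10000), tolerance = 1e-14)
})

test_that("delays shift the delivered rate by whole steps", {
  g <- build_grid(-5, 15, 100)
  at_reset <- numeric(100); at_reset[g$reset_index] <- 1
  mk <- function(d) {
    net <- build_network(
      list(internal_population("p", n_bins = 100),
           external_population("x", rate_signal("step", baseline = 0,
                                                amplitude = 2000, onset = 50))),
      list(connection("x", "p", 1, 0.5, delay = d)))
    run_network(net, 100, 0.1,
                initial = list(p = density_state(at_reset)))$rates[, 1]
  }
  r0 <- mk(0)
  r5 <- mk(5)
  shift <- 50L
  expect_equal(r5[(shift + 1):1000], r0[1:(1000 - shift)], tolerance = 1e-12)
  expect_equal(r5[1:shift], r0[1:shift])  # pre-onset: both silent
})

test_that("identical configurations give bit-identical traces", {
  net <- single_pop_network(n_bins = 100)
  expect_identical(run_network(net, 50, 0.1)$rates,
                   run_network(net, 50, 0.1)$rates)
})

test_that("responses are invariant under time translation of the stimulus", {
  mk <- function(onset) {
    net <- build_network(
      list(internal_population("p", n_bins = 100),
           external_population("x", rate_signal("step", baseline = 0,
                                                amplitude = 3000,
                                                onset = onset))),
      list(connection("x", "p", 1, 0.5)))
    g <- build_grid(-5, 15, 100)
    mass <- numeric(100); mass[g$reset_index] <- 1
    run_network(net, 100, 0.1,
                initial = list(p = density_state(mass)))$rates[, 1]
  }
  r20 <- mk(20)
  r40 <- mk(40)
  shift <- 200L
  expect_equal(r40[(shift + 1):1000], r20[1:(1000 - shift)], tolerance = 1e-12)
})

test_that("delay kernels integrate to one and respect truncation", {
  k <- delay_kernel(1.5, 0.75, 0.1)
  expect_equal(sum(k$weight), 1, tolerance = 1e-12)
  expect_gte(min(k$steps), 1)                       # truncated below at dt
  expect_equal(k$steps[which.max(k$weight)], 15L)   # mode at the mean delay
  single <- delay_kernel(1.5, 0, 0.1)
  expect_equal(single, data.frame(steps = 15L, weight = 1))
})

test_that("traces round-trip through the CSV writer", {
  net <- single_pop_network(n_bins = 100)
  tr <- run_network(net, 20, 0.1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_traces(tr, path, header = c(model = "single"))
  lines <- readLines(path, n = 1)
  expect_match(lines, "^# model: single")
  back <- utils::read.csv(path, comment.char = "#")
  expect_equal(back$p1, unname(tr$rates[, "p1"]), tolerance = 1e-8)
})
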