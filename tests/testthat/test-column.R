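test_that("charge-conserving weight conversion matches the printed values", {
  w_exc <- weight_from_charge(87.8, 0.5, 250)
  expect_equal(w_exc, 0.1756, tolerance = 1e-12)
  # printed to coarser precision in the source literature
  expect_lt(abs(w_exc - 0.175), 0.001)
  w_inh <- -4 * w_exc
  expect_equal(w_inh, -0.7024, tolerance = 1e-12)
  expect_lt(abs(w_inh - (-0.7)), 0.005)
  expect_equal(weight_from_charge(100, 1, 100), 1)
})

test_that("weight conversion is linear in current and tau_s, inverse in C_m", {
  base <- weight_from_charge(87.8, 0.5, 250)
  expect_equal(weight_from_charge(2 * 87.8, 0.5, 250), 2 * base)
  expect_equal(weight_from_charge(87.8, 1.0, 250), 2 * base)
  expect_equal(weight_from_charge(87.8, 0.5, 500), base / 2)
  expect_error(weight_from_charge(87.8, 0, 250), "tau_s")
  expect_error(weight_from_charge(87.8, 0.5, -1), "capacitance")
})

test_that("in-degree conventions behave and agree for weak projections", {
  expect_equal(in_degree(0, 1e5), 0)
  expect_equal(in_degree(1, 100), 100)
  expect_equal(in_degree(0.088, 21915), 0.088 * 21915)
  expect_error(in_degree(1.2, 10), "probability")
  # binomial synapse-count formula: ~ -N ln(1-p), always >= p N
  expect_equal(in_degree_binomial(0.01, 1000, 500), 0.01 * 1000,
               tolerance = 1e-2)
  expect_gt(in_degree_binomial(0.373, 1065, 4850), 0.373 * 1065)
  expect_equal(in_degree_binomial(0.373, 1065, 4850), -1065 * log(1 - 0.373),
               tolerance = 1e-3)
  expect_equal(in_degree_binomial(0, 1000, 500), 0)
})

test_that("background rescaling preserves the mean drive exactly", {
  out <- rescale_background(8, 0.1756, 8.54)
  expect_equal(out$rate, 8 / 8.54, tolerance = 1e-12)
  expect_equal(out$weight, 0.1756 * 8.54, tolerance = 1e-12)
  expect_lt(abs(out$rate * out$weight - 8 * 0.1756), 1e-12)
  ident <- rescale_background(8, 0.1756, 1)
  expect_equal(ident, list(rate = 8, weight = 0.1756))
  set.seed(2)
  for (i in 1:20) {
    r <- runif(1, 0.1, 50); w <- runif(1, 0.01, 2); f <- runif(1, 0.1, 20)
    out <- rescale_background(r, w, f)
    expect_lt(abs(out$rate * out$weight - r * w), 1e-12)
  }
  expect_error(rescale_background(8, 0.2, 0), "factor")
})

test_that("the packaged configuration satisfies its invariants", {
  cfg <- default_column_config()
  expect_equal(cfg$populations,
               c("L23e", "L23i", "L4e", "L4i", "L5e", "L5i", "L6e", "L6i"))
  expect_equal(unname(cfg$conn_prob["L23e", "L4e"]), 0.088)
  expect_equal(cfg$synapse$g_inh_ratio, 4)
  expect_true(all(cfg$conn_prob >= 0 & cfg$conn_prob <= 1))
  expect_true(all(cfg$population_sizes > 0))
  expect_equal(cfg$neuron$t_ref, 0)
})

test_that("config validation names the offending field", {
  cfg <- default_column_config()
  bad <- cfg; bad$conn_prob[1, 1] <- 1.5
  expect_error(validate_column_config(bad), "conn_prob")
  bad <- cfg; bad$background$rescale <- -1
  expect_error(validate_column_config(bad), "background.rescale")
  bad <- cfg; bad$neuron$tau_m <- 0
  expect_error(validate_column_config(bad), "tau_m")
  bad <- cfg; bad$conn_prob["L23e", "L4e"] <- 0.044
  expect_error(validate_column_config(bad, packaged = TRUE), "0.088")
  expect_silent(validate_column_config(bad))   # perturbed configs may differ
})

test_that("the built column has the advertised structure", {
  col <- get_column()
  expect_length(col$internal, 8)
  expect_equal(col$external, "background")
  n_recurrent <- sum(default_column_config()$conn_prob > 0)
  expect_length(col$connections, n_recurrent + 8)
  meta <- attr(col, "column_meta")
  expect_equal(meta$w_exc, 0.1756, tolerance = 1e-12)
  expect_equal(meta$w_inh, -0.7024, tolerance = 1e-12)
  # background drive: rate / 8.54, weight x 8.54
  expect_equal(meta$bg_rate * meta$w_bg, 8 * 0.1756, tolerance = 1e-12)
})

test_that("with recurrence removed every population is background-driven", {
  cfg <- default_column_config()
  cfg$conn_prob[] <- 0
  col0 <- build_column(cfg, n_bins = 100, v_min = -5)
  tr <- run_network(col0, 50, 0.1)
  # all populations share tau_m and initial state; only the background
  # in-degree differs, so equal in-degrees give identical traces
  k <- cfg$background$in_degree
  expect_equal(tr$rates[, "L4i"], tr$rates[, "L5i"], tolerance = 1e-12)  # both 1900
  # and each trace equals a hand-built single-population simulation
  meta <- attr(col0, "column_meta")
  single <- build_network(
    list(internal_population("L5e", v_min = -5, n_bins = 100),
         external_population("background",
                             rate_signal("constant", baseline = meta$bg_rate))),
    list(connection("background", "L5e", k[["L5e"]], meta$w_bg)))
  tr1 <- run_network(single, 50, 0.1)
  expect_equal(tr$rates[, "L5e"], tr1$rates[, "L5e"], tolerance = 1e-12)
})

test_that("the column under background reaches a stationary state by 100 ms", {
  tr <- get_bg_traces()
  mid <- colMeans(tr$rates[tr$times > 100 & tr$times <= 110, ])
  late <- colMeans(tr$rates[tr$times > 140 & tr$times <= 150, ])
  end <- final_rates(tr, 10)
  expect_lt(max(abs(end - late)), 0.1)
  expect_lt(max(abs(late - mid)), 0.1)
  expect_true(all(end > 0 & is.finite(end)))
})

test_that("layer labels map to their population pairs", {
  expect_equal(drive_protocol("L2/3", "balanced",
                              rate_signal("step", amplitude = 1))$targets,
               c("L23e", "L23i"))
  expect_equal(drive_protocol("L5", "inhibitory",
                              rate_signal("step", amplitude = 1))$targets,
               "L5i")
  expect_error(drive_protocol("L7", "balanced",
                              rate_signal("step", amplitude = 1)),
               "unknown layer")
})
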