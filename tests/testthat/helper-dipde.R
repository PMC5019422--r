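# Shared fixtures: everything is generated in code at test time.

# per-session cache for expensive simulations shared across test files
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

default_grid <- function(n_bins = 200) build_grid(-5, 15, n_bins)

# the default column, built once
get_column <- function() cached("column", build_column())

# background-only 200 ms run of the default column
get_bg_traces <- function() {
  cached("bg_traces", {
    tr <- run_network(get_column(), duration = 200, dt = 0.1)
    attr(tr, "onset") <- 100
    tr
  })
}

get_bg_rates <- function() final_rates(get_bg_traces(), 20)

# single uncoupled population under constant background shot noise,
# mirroring the strong-weight background regime of the column
single_pop_network <- function(n_bins = 200, v_min = -5, rate = 1100,
                               weight = 1.4996, in_deg = 1) {
  build_network(
    list(internal_population("p1", v_min = v_min, n_bins = n_bins),
         external_population("bg", rate_signal("constant", baseline = rate))),
    list(connection("bg", "p1", in_degree = in_deg, weight = weight)))
}

expect_column_sums_zero <- function(op, tol = 1e-12) {
  expect_lt(max(abs(colSums(op$matrix))), tol)
}

# mean voltage of a density state on its grid
state_mean_voltage <- function(state, grid) {
  centers <- (grid$edges[-1] + grid$edges[-length(grid$edges)]) / 2
  sum(state$mass * centers)
}
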