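test_that("the neuronal derivative matches a term-by-term loop oracle", {
  spec <- build_nonlinear_family(build_pruned_winner())[[1]]
  set.seed(42)
  truth <- auditory_ground_truth(spec)
  x <- rnorm(4, sd = 0.3)
  for (u in list(0, 1, 0.5)) {
    expect_equal(neuronal_derivative(x, u, truth),
                 neuronal_deriv_loops(x, u, truth), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  # bilinear term included
  spec_b <- build_bilinear_family(build_pruned_winner())[[1]]
  pb <- auditory_ground_truth(spec_b, b_value = 0.2)
  expect_equal(neuronal_derivative(x, 1, pb),
               neuronal_deriv_loops(x, 1, pb), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(neuronal_derivative(x[1:2], 1, truth), "length")
})

test_that("rest is a fixed point mapping to zero BOLD", {
  params <- auditory_ground_truth()
  h <- rest_state(4)
  d <- hemodynamic_derivative(h, numeric(4), params)
  expect_equal(unlist(d), rep(0, 16), ignore_attr = TRUE)
  expect_equal(bold_observation(h, params), rep(0, 4))
  expect_error(hemodynamic_derivative(list(s = 0 * 1:4, f = rep(-1, 4),
                                           v = rep(1, 4), q = rep(1, 4)),
                                      numeric(4), params),
               "strictly positive")
})

test_that("the compiled integrator matches the pure-R RK4 mirror", {
  spec <- build_nonlinear_family(build_pruned_winner())[[1]]
  params <- auditory_ground_truth(spec)  # includes gating: full system
  par <- make_paradigm(8, dt = 0.25)
  sim <- integrate_model(spec, params, par)
  orc <- r_integrate_oracle(params, par)
  expect_equal(sim$bold, orc$bold, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(sim$samples, orc$samples, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("linear-model integration matches the matrix-exponential closed form", {
  # constant unit input over the whole span makes the neuronal subsystem an
  # LTI system with known solution x(t) = (e^{At} - I) A^{-1} C
  spec <- build_pruned_winner()
  params <- auditory_ground_truth(spec)
  dur <- 64
  par <- paradigm(stim_onsets = 0, stim_durations = dur + 1,
                  acq_onsets = seq(0, dur - 16, by = 16), dt = 0.125,
                  duration = dur)
  orc <- r_integrate_oracle(params, par)
  xs <- expm_linear_x(params$a, as.numeric(params$c[, 1]), orc$time)
  expect_lt(max(abs(orc$x - xs)), 1e-6)
})

test_that("the sampled response is causal and the boxcar input is correct", {
  params <- auditory_ground_truth()
  par <- make_paradigm(8)
  sim <- integrate_model(params$spec, params, par)
  # first acquisition reference point (t = 2.5 s) precedes the first stimulus
  expect_equal(unname(sim$samples[, 1]), rep(0, 4))
  u <- stimulus_input(par, times = c(0, 9.99, 10, 13, 15.99, 16, 50))
  expect_equal(u, c(0, 0, 1, 1, 1, 0, 0))
})

test_that("sample_acquisitions interpolates the fine grid at reference points", {
  params <- auditory_ground_truth()
  par <- make_paradigm(6)
  sim <- integrate_model(params$spec, params, par)
  got <- sample_acquisitions(sim$bold, par, time = sim$time)
  expect_equal(got, sim$samples, tolerance = 1e-12)
  manual <- approx(sim$time, sim$bold[2, ], xout = par$sample_times)$y
  expect_equal(unname(got[2, ]), manual, tolerance = 1e-12)
  expect_error(sample_acquisitions(sim$bold[, 1:4, drop = FALSE], par,
                                   time = sim$time[1:4]),
               "outside the simulated span")
})

test_that("divergent dynamics are flagged, not returned as numbers", {
  # strong positive gating of a target's own afferents ("hg_incoming")
  # creates a runaway feedback loop that passes the linear stability check
  # but diverges non-linearly
  spec <- build_nonlinear_family(build_pruned_winner())[[4]]
  params <- auditory_ground_truth(spec, d_value = 40)
  par <- make_paradigm(16, dt = 0.5)
  expect_null(predict_bold(params, par))
  expect_error(integrate_model(spec, params, par), "diverged")
})

test_that("BOLD tables round-trip through delimited text", {
  params <- auditory_ground_truth()
  par <- make_paradigm(4)
  sim <- integrate_model(params$spec, params, par)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_bold_table(sim$samples, par$sample_times, path)
  back <- read_bold_table(path)
  expect_equal(back$bold, sim$samples, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(back$time, par$sample_times)
})

test_that("paradigm constructor validates timing", {
  expect_error(paradigm(c(5, 3), 6, c(0, 16)), "strictly increasing")
  expect_error(paradigm(5, -1, c(0, 16)), "positive")
  expect_error(paradigm(5, 6, c(0, 16), TR = -16), "positive")
  expect_error(paradigm(5, 6, c(0, 16), dt = 0.7), "dt must be in")
  p <- make_paradigm(4)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_paradigm(p, path)
  p2 <- read_paradigm(path)
  expect_equal(p2$sample_times, p$sample_times)
  expect_equal(p2$stim_onsets, p$stim_onsets)
})
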