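test_that("vertical step reproduces hand-evaluated values", {
  # s_f = s_h = 0 reduces the map to p(1 - mu)
  expect_equal(vertical_step(0.5, model_params(mu = 0.03)), 0.485)
  # absorbing at zero for any valid parameters
  expect_identical(vertical_step(0, model_params(mu = 0.1, H = 0.3,
                                                 F_rel = 1.2, w = 0.5)), 0)
  # hand evaluation: numerator 0.097, denominator 1 - 0.081 - 0.00027
  expect_equal(vertical_step(0.1, model_params(mu = 0.03, H = 0.1)),
               0.097 / 0.91873, tolerance = 1e-12)
})

test_that("horizontal step adds w k (1 - k), clipping at fixation", {
  expect_equal(horizontal_step(0.3, model_params(w = 0)), 0.3)
  expect_equal(horizontal_step(1, model_params(w = 5)), 1)
  expect_equal(horizontal_step(0.5, model_params(w = 0.06)), 0.515)
  expect_warning(out <- horizontal_step(0.9, model_params(w = 3)),
                 "clipped")
  expect_equal(out, 1)
  expect_error(horizontal_step(1.2, model_params()), "\\[0, 1\\]")
})

test_that("full step composes vertical then horizontal transmission", {
  expect_equal(wolb_step(0, model_params(mu = 0.2, w = 0.5)), 0)
  expect_equal(wolb_step(0.5, model_params(mu = 0.03)), 0.485)
  expect_equal(wolb_step(0.5, model_params(mu = 0.03, w = 0.06)),
               0.485 + 0.06 * 0.485 * 0.515, tolerance = 1e-12)
})

test_that("parameter validation rejects out-of-range values", {
  expect_error(model_params(mu = 1), "mu")
  expect_error(model_params(F_rel = 0), "F_rel")
  expect_error(model_params(H = 1.5), "H")
  expect_error(model_params(w = -0.1), "w")
  expect_error(vertical_step(-0.01, model_params()), "\\[0, 1\\]")
})

test_that("selection coefficients stay consistent with F and H", {
  p <- model_params(F_rel = 1.05, H = 0.1)
  expect_equal(p$s_f, -0.05)
  expect_equal(p$s_h, 0.9)
})

test_that("long trajectories reach the analytically known fates", {
  pars <- model_params(mu = 0.03, w = 0.06)
  tr <- simulate_trajectory(0.01, pars, 10000)
  expect_length(tr$p, 10001)
  expect_equal(tr$p[10001], oracle_neutral_equilibrium(0.03, 0.06),
               tolerance = 1e-6)
  lost <- simulate_trajectory(0.01, model_params(mu = 0.03, w = 0.01), 10000)
  expect_lt(lost$p[10001], 1e-6)
  zero <- simulate_trajectory(0, pars, 100)
  expect_true(all(zero$p == 0))
})

test_that("step maps the unit interval into itself across a parameter grid", {
  grid <- expand.grid(mu = c(0, 0.03, 0.3), F_rel = c(0.5, 1, 1.05, 2),
                      H = c(0, 0.1, 1), w = c(0, 0.06, 1))
  ps <- seq(0, 1, by = 0.05)
  for (i in seq_len(nrow(grid))) {
    pars <- model_params(mu = grid$mu[i], F_rel = grid$F_rel[i],
                         H = grid$H[i], w = grid$w[i])
    out <- suppressWarnings(vapply(ps, wolb_step, numeric(1), params = pars))
    expect_true(all(out >= 0 & out <= 1))
  }
})

test_that("the step output is strictly increasing in w away from the
           boundaries", {
  for (p in c(0.05, 0.3, 0.7)) {
    ws <- seq(0, 0.5, by = 0.05)
    out <- vapply(ws, function(w)
      wolb_step(p, model_params(mu = 0.03, H = 0.5, w = w)), numeric(1))
    expect_true(all(diff(out) > 0))
  }
})

test_that("with no selection the early trajectory follows geometric growth", {
  # with s_f = s_h = 0 and p << 1, p_t ~ p0 [(1+w)(1-mu)]^t; the quadratic
  # horizontal term is O(w p^2), negligible at p0 = 1e-10
  for (w in c(0, 0.06)) {
    tr <- simulate_trajectory(1e-10, model_params(mu = 0.03, w = w), 5)
    expected <- 1e-10 * ((1 + w) * 0.97)^(0:5)
    expect_equal(tr$p, expected, tolerance = 1e-9)
  }
  # w = 0 is exact geometric decay over any horizon
  tr <- simulate_trajectory(0.4, model_params(mu = 0.03), 50)
  expect_equal(tr$p, 0.4 * 0.97^(0:50), tolerance = 1e-12)
})

test_that("fixation persists under perfect transmission without horizontal
           spread", {
  for (Fv in c(1, 1.3)) {
    pars <- model_params(mu = 0, F_rel = Fv)
    expect_equal(wolb_step(1, pars), 1)
  }
})

test_that("canonical scenarios reproduce the qualitative regimes", {
  a <- scenario_trajectories("A", generations = 500)
  expect_named(a, c("w=0", "w=0.01", "w=0.06"))
  # w = 0 in the neutral scenario is a contracting map to zero
  expect_true(all(diff(a[["w=0"]]$p) < 0))
  b <- scenario_trajectories("B", generations = 2000)
  expect_gt(tail(b[["w=0.06"]]$p, 1), 0.9)
  cc <- scenario_trajectories("C", generations = 5000)
  expect_equal(tail(cc[["w=0"]]$p, 1), 0.37, tolerance = 1e-6)
  expect_error(scenario_trajectories("D"), "arg")
})

test_that("trajectory fate classification distinguishes loss, convergence
           and transients", {
  lost <- simulate_trajectory(0.01, model_params(mu = 0.03, w = 0.01), 2000)
  expect_equal(trajectory_fate(lost)$fate, "lost")
  conv <- simulate_trajectory(0.2, model_params(mu = 0.03, w = 0.06), 2000)
  expect_equal(trajectory_fate(conv)$fate, "converged")
  short <- simulate_trajectory(0.01, model_params(mu = 0.03, w = 0.06), 5)
  expect_equal(trajectory_fate(short)$fate, "transient")
})
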