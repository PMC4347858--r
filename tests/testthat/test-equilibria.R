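test_that("fixed points with CI and no horizontal transmission match the
           quadratic oracle", {
  fp <- fixed_points(model_params(mu = 0.03, H = 0.1))
  roots <- oracle_w0_quadratic(0.03, 1, 0.1)
  expect_equal(fp$p_star, c(0, roots), tolerance = 1e-10)
  expect_equal(fp$stability, c("stable", "unstable", "stable"))
})

test_that("the neutral map with moderate horizontal transmission has the
           closed-form interior equilibrium", {
  fp <- fixed_points(model_params(mu = 0.03, w = 0.06))
  expect_equal(fp$p_star, c(0, oracle_neutral_equilibrium(0.03, 0.06)),
               tolerance = 1e-10)
  expect_equal(fp$stability, c("unstable", "stable"))
})

test_that("every returned fixed point satisfies step(p) = p", {
  grid <- list(c(0.03, 1, 0.1, 0), c(0.03, 1, 1, 0.06),
               c(0.05, 1.05, 1, 0), c(0.02, 0.95, 0.3, 0.04))
  for (g in grid) {
    pars <- model_params(mu = g[1], F_rel = g[2], H = g[3], w = g[4])
    fp <- fixed_points(pars)
    for (p in fp$p_star)
      expect_lt(abs(wolb_step(p, pars) - p), 1e-10)
  }
})

test_that("the identity map is flagged degenerate, not enumerated", {
  fp <- fixed_points(model_params())
  expect_true(attr(fp, "degenerate"))
  expect_equal(fp$stability, "degenerate")
  expect_equal(nrow(fp), 1)
})

test_that("interior roots agree with the quadratic oracle across a (mu, H)
           grid at w = 0", {
  for (mu in c(0.01, 0.03, 0.08)) for (H in c(0.05, 0.1, 0.5)) {
    fp <- fixed_points(model_params(mu = mu, H = H))
    interior <- fp$p_star[fp$p_star > 1e-12]
    expect_equal(interior, oracle_w0_quadratic(mu, 1, H),
                 tolerance = 1e-10)
  }
})

test_that("invasion growth factor is (1+w)(1-mu)F and ignores H", {
  expect_equal(invasion_growth_factor(model_params(mu = 0.03, w = 0.06)),
               1.06 * 0.97)
  expect_equal(invasion_growth_factor(model_params(mu = 0.03, w = 0.01)),
               1.01 * 0.97)
  expect_identical(invasion_growth_factor(model_params()), 1)
  expect_equal(invasion_growth_factor(model_params(mu = 0.03, H = 0.1,
                                                   w = 0.06)),
               invasion_growth_factor(model_params(mu = 0.03, H = 0.9,
                                                   w = 0.06)))
})

test_that("CI invasion threshold matches the quadratic's smaller root", {
  expect_equal(ci_threshold(model_params(mu = 0.03, H = 0.1)),
               min(oracle_w0_quadratic(0.03, 1, 0.1)), tolerance = 1e-12)
  expect_equal(ci_threshold(model_params(mu = 0.05, H = 0.1)),
               min(oracle_w0_quadratic(0.05, 1, 0.1)), tolerance = 1e-12)
  # perfect maternal transmission: the constant term vanishes, threshold 0
  expect_equal(ci_threshold(model_params(mu = 0, H = 0.1)), 0)
  expect_error(ci_threshold(model_params(H = 0.1, w = 0.01)), "w = 0")
  expect_error(ci_threshold(model_params(mu = 0.03)), "H < 1")
})

test_that("stability classification matches iteration behaviour", {
  pars <- model_params(mu = 0.03)
  s <- stability_of(0, pars)
  expect_equal(s$derivative, 0.97, tolerance = 1e-4)
  expect_equal(s$stability, "stable")
  pars_ci <- model_params(mu = 0.03, H = 0.1)
  thr <- ci_threshold(pars_ci)
  expect_equal(stability_of(thr, pars_ci)$stability, "unstable")
  # iteration diverges away from the unstable point on both sides
  expect_lt(simulate_trajectory(thr * 0.9, pars_ci, 500)$p[501], thr * 0.5)
  expect_gt(simulate_trajectory(thr * 1.1, pars_ci, 500)$p[501], 0.9)
  pars_w <- model_params(mu = 0.03, w = 0.06)
  pstar <- oracle_neutral_equilibrium(0.03, 0.06)
  expect_equal(stability_of(pstar, pars_w)$stability, "stable")
  expect_equal(simulate_trajectory(0.4, pars_w, 2000)$p[2001], pstar,
               tolerance = 1e-8)
  expect_equal(simulate_trajectory(0.6, pars_w, 2000)$p[2001], pstar,
               tolerance = 1e-8)
  expect_error(stability_of(0.5, pars), "not a fixed point")
})

test_that("invasion from rare occurs iff the growth factor exceeds one", {
  set.seed(101)
  n_ok <- 0
  while (n_ok < 30) {
    mu <- runif(1, 0, 0.1); F_rel <- runif(1, 0.9, 1.1)
    H <- runif(1, 0.1, 1); w <- runif(1, 0, 0.1)
    pars <- model_params(mu = mu, F_rel = F_rel, H = H, w = w)
    lam <- invasion_growth_factor(pars)
    if (abs(lam - 1) < 5e-3) next  # too close to neutral to resolve
    n_ok <- n_ok + 1
    p_end <- simulate_trajectory(1e-4, pars, 3000)$p[3001]
    if (lam > 1) expect_gt(p_end, 1e-3) else expect_lt(p_end, 1e-5)
  }
})

test_that("equilibrium sweep stacks classified fixed points over w", {
  sw <- equilibrium_sweep(mu = 0.03, H = 0.1, w_grid = c(0, 0.06))
  expect_true(all(c("mu", "F", "H", "w", "p_star", "stability") %in%
                    names(sw)))
  expect_equal(sum(sw$w == 0), 3)  # 0 + two interior CI roots
  expect_true(all(sw$p_star >= 0 & sw$p_star <= 1))
})
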