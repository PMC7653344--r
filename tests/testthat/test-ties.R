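make_leg <- function(means, lams = default_lambdas(), leg = "aqueous",
                     n_rep = 1) {
  ti_leg(mapply(function(l, m) {
    lambda_window(l, rep(list(m), n_rep))
  }, lams, means, SIMPLIFY = FALSE), leg = leg)
}

test_that("hybrid potential interpolates linearly between end states", {
  expect_equal(hybrid_potential(0, 10, 20), 10)
  expect_equal(hybrid_potential(1, 10, 20), 20)
  expect_equal(hybrid_potential(0.5, 10, 20), 15)
  expect_error(hybrid_potential(1.2, 1, 2), "lambda")
})

test_that("electrostatic coupling ramps match the schedule", {
  s <- coupling_schedule()
  expect_equal(unname(coupling_scales(0, s)[1, ]), c(1, 0))
  expect_equal(unname(coupling_scales(1, s)[1, ]), c(0, 1))
  expect_equal(unname(coupling_scales(0.5, s)[1, ]),
               c(1 - 0.5 / 0.55, (0.5 - 0.45) / 0.55), tolerance = 1e-12)
  # off beyond the decoupling window, on before the coupling window
  expect_equal(unname(coupling_scales(0.7, s)[1, 1]), 0)
  expect_equal(unname(coupling_scales(0.3, s)[1, 2]), 0)
  expect_equal(coupling_schedule()$lambda_values, default_lambdas())
})

test_that("window mean weights replicas equally regardless of series length", {
  w <- lambda_window(0.3, list(rep(5, 10)))
  expect_equal(window_mean(w), 5)
  w2 <- lambda_window(0.3, list(1, 3))
  expect_equal(window_mean(w2), 2)
  # unbalanced series: replica-mean weighting, not a pooled mean
  w3 <- lambda_window(0.3, list(rep(1, 10), rep(3, 1000)))
  expect_equal(window_mean(w3), 2)
})

test_that("window SEM matches the closed form and is deterministic", {
  # identical replica means: zero SEM
  w0 <- lambda_window(0.1, list(rep(2, 5), rep(2, 3)))
  expect_equal(window_sem(w0, seed = 1), 0)
  # two replica means {0, 2}: classical SEM = 1.0
  w <- lambda_window(0.1, list(0, 2))
  expect_lt(abs(window_sem(w, n_boot = 1e4, seed = 7) - 1.0), 0.1)
  # fixed seed: bit-identical repeats
  expect_identical(window_sem(w, n_boot = 500, seed = 3),
                   window_sem(w, n_boot = 500, seed = 3))
  # single replica: flagged undefined, not silently zero
  expect_true(is.na(window_sem(lambda_window(0.1, list(1:5 / 5)))))
})

test_that("trapezoidal integration is exact for constant and linear integrands", {
  lams <- default_lambdas()
  lc <- make_leg(rep(3.2, length(lams)))
  expect_equal(integrate_leg(lc, n_boot = 1)$dg, 3.2, tolerance = 1e-14)

  ll <- make_leg(2 * lams)
  expect_lt(abs(integrate_leg(ll, n_boot = 1)$dg - 1.0), 1e-12)

  # quadratic integrand: equals the hand-rolled summation oracle, and sits
  # near the analytic 1/3 up to the grid's discretization error
  lq <- make_leg(lams^2)
  got <- integrate_leg(lq, n_boot = 1)$dg
  expect_equal(got, oracle_trapezoid(lams, lams^2), tolerance = 1e-14)
  expect_lt(abs(got - 1 / 3), 0.005)

  # affine exactness on an arbitrary non-uniform grid
  g2 <- c(0, 0.13, 0.41, 0.77, 1)
  la <- make_leg(5 - 3 * g2, lams = g2)
  expect_equal(integrate_leg(la, n_boot = 1)$dg, 5 - 1.5, tolerance = 1e-12)
})

test_that("leg validation rejects broken lambda grids", {
  expect_error(ti_leg(list(lambda_window(0, list(1)),
                           lambda_window(0.5, list(1))), "aqueous"),
               "endpoint")
  expect_error(ti_leg(list(lambda_window(0.2, list(1)),
                           lambda_window(0.2, list(1))), "aqueous"),
               "duplicate")
})

test_that("ddg combines legs with quadrature errors and antisymmetry", {
  aq <- gen_ti_dataset(mu = function(l) 4 * l, sigma = 0.3, seed = 21)
  bd <- gen_ti_dataset(mu = function(l) 7 * l, sigma = 0.3, leg = "bound",
                       seed = 22)
  r <- ties_ddg(aq$leg, bd$leg, n_boot = 800, seed = 5)
  # identity: sigma^2 = sigma_aq^2 + sigma_bound^2, exactly
  expect_equal(r$sigma^2,
               r$legs$aqueous$sigma^2 + r$legs$bound$sigma^2,
               tolerance = 1e-12)
  # sign conventions are exact opposites
  r2 <- ties_ddg(aq$leg, bd$leg, n_boot = 800, seed = 5,
                 sign_convention = "printed")
  expect_equal(r2$ddg, -r$ddg, tolerance = 1e-12)

  # identical legs: self-transformation, ddg = 0
  r0 <- ties_ddg(aq$leg, ti_leg(aq$leg$windows, "bound"), n_boot = 200,
                 seed = 9)
  expect_equal(r0$ddg, 0, tolerance = 1e-12)

  # swapping leg roles flips the sign exactly (same per-leg seeds by
  # symmetry of the quadrature; point estimate only)
  ra <- ties_ddg(aq$leg, bd$leg, n_boot = 1, seed = 1)
  rb <- ties_ddg(ti_leg(bd$leg$windows, "aqueous"),
                 ti_leg(aq$leg$windows, "bound"), n_boot = 1, seed = 1)
  expect_equal(rb$ddg, -ra$ddg, tolerance = 1e-12)
})

test_that("scaled legs expose the exact error quadrature (3-4-5)", {
  base <- gen_ti_dataset(mu = function(l) 2 * l, sigma = 0.4,
                         n_samples = 50, seed = 31)
  scale_leg <- function(leg, c, label) {
    ti_leg(lapply(leg$windows, function(w) {
      lambda_window(w$lam, lapply(w$replicas, function(v) c * v))
    }), label)
  }
  aq3 <- scale_leg(base$leg, 3, "aqueous")
  bd4 <- scale_leg(base$leg, 4, "bound")
  # identical resampling under the same seed makes the bootstrap SEMs scale
  # exactly, so sigma_bound = (4/3) sigma_aq and the combined error obeys
  # the 3-4-5 right triangle
  sa <- integrate_leg(aq3, n_boot = 400, seed = 13)$sigma
  sb <- integrate_leg(bd4, n_boot = 400, seed = 13)$sigma
  expect_gt(sa, 0)
  expect_equal(sb, sa * 4 / 3, tolerance = 1e-12)
  expect_equal(sqrt(sa^2 + sb^2), sa * 5 / 3, tolerance = 1e-12)
})

test_that("adding independent noise does not shrink the combined error", {
  set.seed(99)
  base <- gen_ti_dataset(mu = function(l) l, sigma = 0.2, n_samples = 200,
                         seed = 41)
  noisy <- ti_leg(lapply(base$leg$windows, function(w) {
    lambda_window(w$lam, lapply(w$replicas, function(v) {
      v + rnorm(1, sd = 0.5)  # replica-level offset noise
    }))
  }), "aqueous")
  s0 <- integrate_leg(base$leg, n_boot = 2000, seed = 3)$sigma
  s1 <- integrate_leg(noisy, n_boot = 2000, seed = 3)$sigma
  expect_gt(s1, s0)
})
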