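test_that("forward Euler reproduces the hand-evaluated passive step", {
  f <- cell_field(passive_params(), n = 1, u0 = 1, w0 = 0)
  s <- simulate_field(f, duration = 0.1, spec = integrator_spec("fe", 0.1))
  expect_equal(s$field$u, 1 - 0.1 * 26 / 12.9, tolerance = 1e-14)
})

test_that("forward Euler is first order on the linear decay problem", {
  p <- passive_params()
  lam <- p$ct * p$S
  horizon <- 0.4
  err <- sapply(c(0.1, 0.05), function(dt) {
    f <- cell_field(p, n = 1, u0 = 1, w0 = 0)
    s <- simulate_field(f, duration = horizon, spec = integrator_spec("fe", dt))
    abs(s$field$u - exp(-lam * horizon))
  })
  expect_gt(err[1] / err[2], 1.6)
  expect_lt(err[1] / err[2], 2.4)
})

test_that("backward Euler solves the linear implicit step in closed form", {
  p <- passive_params()
  f <- cell_field(p, n = 1, u0 = 1, w0 = 0)
  dt <- 0.5
  s <- simulate_field(f, duration = dt, spec = integrator_spec("be", dt))
  expect_equal(s$field$u, 1 / (1 + dt * p$S * p$ct), tolerance = 1e-15)
})

test_that("BE and FE one-step updates agree to O(dt^2) on the pAP cell", {
  p <- cell_preset("pAP-0D", b = 0.03)
  gap <- sapply(c(0.01, 0.005), function(dt) {
    ffe <- cell_field(p, n = 1, u0 = 0.3, w0 = 0.5)
    fbe <- cell_field(p, n = 1, u0 = 0.3, w0 = 0.5)
    sfe <- simulate_field(ffe, duration = dt, spec = integrator_spec("fe", dt))
    sbe <- simulate_field(fbe, duration = dt,
                          spec = integrator_spec("be", dt, abs_tol = 1e-13))
    abs(sfe$field$u - sbe$field$u)
  })
  expect_gt(gap[1] / gap[2], 3)   # halving dt shrinks the gap ~4x
  expect_lt(gap[1] / gap[2], 5)
})

test_that("the explicit stability criterion follows D dt / dx^2 < 1/(2N)", {
  sc <- stability_check(0.160, 0.05, 0.002, N = 2)
  expect_true(sc$pass)
  expect_equal(sc$margin, 0.128, tolerance = 1e-12)
  # exactly at the bound fails (strict inequality)
  at <- stability_check(0.160, 0.05, 0.25 * 0.05^2 / 0.160, N = 2)
  expect_false(at$pass)
  # one dimension doubles the admissible dt at fixed d
  expect_true(stability_check(0.160, 0.05, 1.4 * 0.25 * 0.05^2 / 0.160,
                              N = 1)$pass)
})

test_that("backward Euler tolerates steps far beyond the explicit bound", {
  p <- passive_params()
  fe_bound <- 2 / (p$ct * p$S)          # explicit stability limit
  f <- cell_field(p, n = 1, u0 = 1, w0 = 0)
  dt <- 100 * fe_bound
  tr <- numeric(5)
  for (k in 1:5) {
    s <- simulate_field(f, duration = dt, spec = integrator_spec("be", dt))
    f <- s$field
    tr[k] <- f$u
  }
  expect_true(all(is.finite(tr)))
  expect_true(all(diff(c(1, tr)) < 0))   # monotone decay, no oscillation
  expect_true(all(tr > 0))
})

test_that("error norms are zero for identical traces and 100% for doubling", {
  t <- seq(0, 5000, by = 1)
  u <- 0.5 + 0.5 * sin(2 * pi * t / 800)
  ref <- list(time = t, u = u)
  nr <- error_norms(ref, ref)
  expect_equal(nr$L2, 0)
  expect_equal(nr$Linf, 0)
  expect_equal(nr$freq_err, 0)
  nr2 <- error_norms(ref, list(time = t, u = 2 * u))
  expect_equal(nr2$L2, 100, tolerance = 1e-6)
  expect_error(error_norms(list(time = t, u = rep(1, length(t))), ref),
               "no complete cycle")
})

test_that("FE and BE frequency estimates agree below 0.5% at dt = 0.01", {
  p <- cell_preset("pAP-0D", b = 0.03)
  tfe <- simulate_cell(p, 10000, dt = 0.01, scheme = "fe", sample_dt = 0.1)
  tbe <- simulate_cell(p, 10000, dt = 0.01, scheme = "be", sample_dt = 0.1)
  ffe <- trace_frequency(tfe$time, tfe$u[, 1], settle = 2000)
  fbe <- trace_frequency(tbe$time, tbe$u[, 1], settle = 2000)
  expect_lt(100 * abs(ffe - fbe) / fbe, 0.5)
})

test_that("the BE inner loop reports convergence failures instead of clamping", {
  p <- cell_preset("pAP-0D", b = 0.03)
  f <- cell_field(p, n = 1, u0 = 0.3, w0 = 0.5)
  expect_error(
    simulate_field(f, duration = 2000,
                   spec = integrator_spec("be", 2000, max_inner = 2)),
    "converge")
})

test_that("integrator spec and divergence reporting are validated", {
  expect_error(integrator_spec("fe", dt = -1))
  expect_error(integrator_spec("rk4", dt = 0.1))
  # a wildly unstable explicit step reports node and time
  p <- cell_preset("pAP-0D", b = 0.03)
  f <- cell_field(p, n = 1, u0 = 0.5, w0 = 0.1)
  expect_error(simulate_field(f, duration = 5000,
                              spec = integrator_spec("fe", 50)),
               "diverged")
})
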