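test_that("feature extraction recovers the closed form of a sine trace", {
  t <- seq(0, 6000, by = 1)
  tr <- list(time = t, u = 0.5 + 0.5 * sin(2 * pi * t / 1000))
  fs <- extract_features(tr, settle = 0)
  expect_false(fs$quiescent)
  expect_equal(fs$frequency, 1, tolerance = 1e-3)
  expect_equal(fs$CL, 1000, tolerance = 1)
  expect_equal(fs$POP, 1, tolerance = 1e-4)
  expect_equal(fs$MDP, 0, tolerance = 1e-4)
  expect_equal(fs$frequency, 1000 / fs$CL, tolerance = 1e-12)
  # APD90 + DI = CL by construction, within a sample period
  expect_equal(fs$APD90 + fs$DI, fs$CL, tolerance = 1)
})

test_that("constant and too-short traces yield a quiescent result", {
  t <- seq(0, 5000, by = 1)
  fs <- extract_features(list(time = t, u = rep(0.2, length(t))), settle = 0)
  expect_true(fs$quiescent)
  expect_identical(fs$n_cycles, 0L)
  # fewer than 3 complete cycles is quiescent, not an error
  fs2 <- extract_features(list(time = t, u = sin(2 * pi * t / 4000)),
                          settle = 0)
  expect_true(fs2$quiescent)
  expect_error(extract_features(list(time = t, u = sin(t)), settle = 6000),
               "settling")
})

test_that("extracted frequency agrees with an FFT oracle within 1%", {
  for (spec in list(list(pr = "pAP-0D", b = 0.03), list(pr = "pCN-0D", b = 0.3))) {
    tr <- sim_preset(spec$pr, spec$b, duration = 30000)
    fs <- extract_features(tr, settle = 10000)
    keep <- tr$time >= 10000
    f_fft <- fft_peak_frequency(tr$time[keep], tr$u[keep, 1])
    expect_false(fs$quiescent)
    expect_lt(abs(fs$frequency - f_fft) / f_fft, 0.01)
  }
})

test_that("orbit orientation distinguishes the two model families", {
  # analytic circle, counterclockwise by construction
  t <- seq(0, 3 * 2 * pi, length.out = 400)
  circ <- list(time = t, u = cos(t), w = sin(t))
  expect_equal(orbit_orientation(circ), "counterclockwise")
  tr_ap <- sim_preset("pAP-0D", 0.03, duration = 15000)
  expect_equal(orbit_orientation(tr_ap, settle = 10000), "counterclockwise")
  tr_cn <- sim_preset("pCN-0D", 0.3, duration = 15000)
  expect_equal(orbit_orientation(tr_cn, settle = 10000), "clockwise")
  flat <- list(time = t, u = rep(1, length(t)), w = rep(0, length(t)))
  expect_error(orbit_orientation(flat), "quiescent")
})

test_that("per-cycle features satisfy POP > MDP and the CL identity on model traces", {
  tr <- sim_preset("pAP-0D", 0.05, duration = 20000)
  fs <- extract_features(tr, settle = 8000)
  expect_gt(fs$POP, fs$MDP)
  expect_equal(fs$APD90 + fs$DI, fs$CL, tolerance = 1e-9)
  expect_gte(fs$n_cycles, 3L)
})

test_that("an uncoupled strand leaves the follower silent (ratio 0)", {
  s <- simulate_star(cell_preset("pAP-1D", b = 0.05), cell_preset("AP-1D"),
                     n_strands = 1, d = 0, duration = 15000, dt = 0.01,
                     sample_dt = 0.5)
  m <- measure_sync(s, settle = 5000)
  expect_identical(m$n_follower, 0L)
  expect_equal(m$ratio, 0)
  expect_false(m$sync_11)
})

test_that("1:1 verdicts hold under strong coupling and survive window doubling", {
  run <- function(duration)
    measure_sync(simulate_star(cell_preset("pAP-1D", b = 0.4),
                               cell_preset("AP-1D"), 1, d = 1,
                               duration = duration, dt = 0.01,
                               sample_dt = 0.5),
                 settle = 10000)
  m1 <- run(30000)
  expect_true(m1$sync_11)
  expect_equal(m1$ratio, 1)
  # stationarity: doubling the observation window keeps the verdict
  m2 <- run(50000)
  expect_true(m2$sync_11)
})

test_that("sweeping the control parameter brackets the oscillation onset", {
  sw <- sweep_parameter(cell_preset("pAP-0D"), "b",
                        grid = c(-0.02, 0, 0.02, 0.04),
                        duration = 20000, settle = 12000, dt = 0.01,
                        scheme = "fe")
  expect_s3_class(sw, "sweep_result")
  expect_true(all(sw$quiescent[sw$value <= 0]))
  expect_true(all(!sw$quiescent[sw$value >= 0.02]))
  # oscillating points enclose the positive equilibrium: POP > u_EP > MDP
  osc <- sw[!sw$quiescent & !is.na(sw$eq_u), ]
  expect_true(all(osc$POP > osc$eq_u & osc$eq_u > osc$MDP))
  # frequency rises with b over the oscillating range
  expect_true(all(diff(osc$frequency) > 0))
  expect_error(sweep_parameter(cell_preset("pAP-0D"), "zap", 1:2),
               "not a field")
})
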