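test_that("the excitability gradient hits its printed endpoints and asymptote", {
  expect_equal(bcn_gradient(0), 1.70, tolerance = 1e-12)
  expect_equal(round(bcn_gradient(4800, dx = 0.25), 2), 0.62)
  expect_equal(bcn_gradient(1e9), 0.4, tolerance = 1e-6)
  i <- 0:100
  expect_true(all(diff(bcn_gradient(i)) < 0))
  expect_error(bcn_gradient(-1))
})

test_that("conduction-block node sets match an independent coordinate oracle", {
  exp <- intestine_experiment(scale = 1, nx = 176L, ny = 2600L)
  nodes <- block_nodes(exp)   # defaults: x0=0, lx=22, y0=580, ly=40
  # oracle: direct coordinate filter
  N <- exp$nx * exp$ny
  ix <- ((seq_len(N) - 1L) %% exp$nx) + 1L
  iy <- ((seq_len(N) - 1L) %/% exp$nx) + 1L
  x <- (ix - 1) * exp$dx; y <- (iy - 1) * exp$dx
  sel <- which(x >= 0 & x <= 22 & y >= 580 & y <= 620)
  expect_setequal(nodes, c(sel, N + sel))
  # zero-area block touches nothing; whole-domain block resets everything
  expect_length(block_nodes(exp, y0 = 1e6), 0L)
  f <- apply_conduction_block(exp, x0 = 0, lx = 1e6, y0 = 0, ly = 1e6)
  expect_true(all(f$u == 0.001))
  expect_true(all(f$w == 0.5))
  # partial block leaves the outside untouched
  f2 <- apply_conduction_block(exp)
  outside <- setdiff(seq_len(2L * N), nodes)
  expect_true(all(f2$u[outside] == exp$field$u[outside]))
})

test_that("the in-kernel block resets the listed nodes at the block time", {
  f <- cell_field(passive_params(), n = 3, u0 = 1, w0 = 0)
  s <- simulate_field(f, duration = 10, spec = integrator_spec("fe", 1),
                      record = 1:3, sample_dt = 1,
                      block = list(time = 5, nodes = c(1, 3),
                                   u = 0.001, w = 0.5))
  tr <- s$trace
  at6 <- which(tr$time == 6)
  expect_lt(tr$u[at6, 1], 0.01)     # reset and one decay step
  expect_lt(tr$u[at6, 3], 0.01)
  expect_gt(tr$u[at6, 2], 0.2)      # untouched node still decaying from 1
  expect_equal(tr$w[at6, 1], 0.5)   # passive nodes do not evolve w
})

test_that("a decoupled sheet reproduces the pair intrinsic-frequency curve pointwise", {
  exp <- intestine_experiment(scale = 20, nx = 4L, ny = 240L, D1 = 0, D2 = 0)
  run <- run_intestine(exp, duration = 6e5, freq_window = 4.5e5)
  ys <- c(0, 15, 30, 45, 59)
  iy <- round(ys / exp$dx) + 1L
  pair <- pair_intrinsic_frequency(ys, lambda = exp$lambda,
                                   duration = 6e5, settle = 1.5e5)
  pair[is.na(pair)] <- 0
  expect_equal(run$freq_cpm[iy], pair, tolerance = 0.3)
  # the oscillating part of the intrinsic profile decreases distally
  osc <- run$freq_cpm[run$freq_cpm > 0]
  expect_gt(length(osc), 100)
  expect_lt(min(diff(osc)), 0.001)   # non-increasing up to count quantization
  expect_true(all(diff(osc) < 0.14))  # one-count steps at 450-s windows
})

test_that("coupling entrains the sheet into non-increasing frequency plateaus", {
  exp <- intestine_experiment(scale = 20, nx = 4L, ny = 240L)
  # plateau tolerance widened to 0.15 cpm: the per-node rate is counted
  # over 600-s windows, so neighboring nodes differ by quanta of 0.1 cpm
  run <- run_intestine(exp, duration = 1.5e6, freq_window = 6e5,
                       plateau_tol = 0.15)
  # the distal part of the sheet (where the pairs possess a limit cycle)
  # oscillates out to the end of the tube; the proximal high-excitability
  # zone rests at its stable focus (see the vignette's limitations)
  osc <- run$freq_cpm > 0
  expect_gt(mean(osc), 0.5)
  expect_true(osc[length(osc)])
  # the entrained profile is a non-increasing step function up to count
  # quantization (allow isolated one-count dislocations)
  prof <- run$freq_cpm[osc]
  expect_lte(sum(diff(prof) > 0.11), 2L)
  # at least one long constant-frequency plateau, entrained at or above
  # the local intrinsic rate at its distal end
  big <- run$plateaus[run$plateaus$n >= 30 & run$plateaus$freq > 0, ]
  expect_gte(nrow(big), 1L)
  intr <- pair_intrinsic_frequency(pmin(big$y_hi, 59), lambda = exp$lambda)
  intr[is.na(intr)] <- 0
  expect_true(all(big$freq >= intr - 0.2))
  # the muscle layer follows the pacemaker layer cycle for cycle away
  # from the sealed tube end
  interior <- osc & run$y < 0.95 * max(run$y)
  expect_true(all(abs(run$counts_smc[interior] -
                      run$counts_icc[interior]) <= 1))
})

test_that("periodic-seam equivariance: rotating the state rotates the solution", {
  exp <- intestine_experiment(scale = 10, nx = 4L, ny = 40L)
  N <- exp$nx * exp$ny
  set.seed(11)
  u0 <- runif(2 * N, 0, 0.5); w0 <- runif(2 * N, 0.2, 0.8)
  rot <- function(v) {
    m1 <- matrix(v[1:N], exp$nx, exp$ny)
    m2 <- matrix(v[N + 1:N], exp$nx, exp$ny)
    c(as.vector(m1[c(exp$nx, 1:(exp$nx - 1)), ]),
      as.vector(m2[c(exp$nx, 1:(exp$nx - 1)), ]))
  }
  f1 <- exp$field; f1$u <- u0; f1$w <- w0
  f2 <- exp$field; f2$u <- rot(u0); f2$w <- rot(w0)
  # the ICC gradient is constant around the circumference, so the dynamics
  # commute with the rotation
  s1 <- simulate_field(f1, exp$op, duration = 250,
                       spec = integrator_spec("fe", 2.5))
  s2 <- simulate_field(f2, exp$op, duration = 250,
                       spec = integrator_spec("fe", 2.5))
  expect_equal(s2$field$u, rot(s1$field$u), tolerance = 1e-12)
  expect_equal(s2$field$w, rot(s1$field$w), tolerance = 1e-12)
})
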