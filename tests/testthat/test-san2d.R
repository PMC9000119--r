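test_that("the SAN mask geometry matches the prescribed ellipse and regions", {
  m <- san_mask(nx = 200, ny = 200, dx = 0.05, type = 1)
  area_san <- sum(m == "san") * 0.05^2
  expect_equal(area_san, pi * 3 * 1, tolerance = 0.05)  # ellipse area, mm^2
  expect_setequal(unique(as.character(m)), c("san", "atrium"))
  # 30-degree rotation: the ellipse's bounding box is wider in y than x
  idx <- which(m == "san", arr.ind = TRUE)
  expect_gt(diff(range(idx[, 2])), diff(range(idx[, 1])))
  m2 <- san_mask(nx = 200, ny = 200, dx = 0.05, type = 2)
  expect_setequal(unique(as.character(m2)),
                  c("san", "atrium", "passive", "pathway"))
  # the passive ring plus pathways encloses the ellipse
  expect_gt(sum(m2 == "passive"), 0)
  expect_gt(sum(m2 == "pathway"), 0)
})

test_that("a pacemaker-free sheet stays quiescent from standard initial conditions", {
  m <- matrix("atrium", 30, 30)
  op <- build_grid2d(m, Dx = c(atrium = 0.0187), Dy = c(atrium = 0.090),
                     dx = 0.2)
  f <- cell_field(cell_preset("AP-atrium"), labels = as.character(m))
  s <- simulate_field(f, op, duration = 2000,
                      spec = integrator_spec("fe", 0.05),
                      count_window = c(0, 2000))
  expect_lt(max(abs(s$field$u)), 1e-3)
  expect_identical(max(s$counts), 0L)
})

test_that("type-1 tissue paces with the pacemaker leading and fast-axis isochrones", {
  exp <- san_experiment(type = 1, D = 0.090, scale = 4)
  run <- run_san(exp, duration = 2500, rate_window = c(1000, 2500))
  expect_gt(run$counts_san, 0)
  expect_gt(run$counts_atrium, 0)
  act <- activation_sequence(run)
  first <- which(act == 0, arr.ind = TRUE)[1, ]
  expect_equal(exp$mask[first["row"], first["col"]], "san")
  # anisotropy: at equal distance from the center, the fiber (y) direction
  # activates earlier than the transverse (x) direction
  cx <- ceiling(exp$nx / 2); cy <- ceiling(exp$ny / 2)
  off <- round(3.6 / exp$dx)   # 3.6 mm, outside the ellipse
  t_y <- mean(c(act[cx, cy + off], act[cx, cy - off]), na.rm = TRUE)
  t_x <- mean(c(act[cx + off, cy], act[cx - off, cy]), na.rm = TRUE)
  expect_lt(t_y, t_x)
})

test_that("the passive border never activates and pathways carry excitation", {
  exp <- san_experiment(type = 2, D = 0.060, scale = 2.5)
  run <- run_san(exp, duration = 1500, rate_window = c(0, 1500),
                 act_window = c(0, 1500))
  lab <- as.character(exp$mask)
  expect_identical(max(run$sim$counts[lab == "passive"]), 0L)
  expect_true(all(is.na(run$sim$act_time[lab == "passive"])))
  expect_gt(max(run$sim$counts[lab == "san"]), 0)
})

test_that("forward and backward Euler give visually similar fields (<5% max-norm)", {
  mk <- function() san_experiment(type = 1, D = 0.090, scale = 8)
  snap_t <- 1200
  sfe <- simulate_field(mk()$field, mk()$op, duration = 1300,
                        spec = integrator_spec("fe", mk()$dt),
                        snapshot_times = snap_t)
  exp <- mk()
  sbe <- simulate_field(exp$field, exp$op, duration = 1300,
                        spec = integrator_spec("be", exp$dt),
                        snapshot_times = snap_t)
  ufe <- sfe$snapshots[, 1]; ube <- sbe$snapshots[, 1]
  expect_lt(max(abs(ufe - ube)) / max(abs(ube)), 0.05)
})

test_that("halving the time step changes the pacing rate by less than 0.5%", {
  f_at <- function(dt) {
    exp <- san_experiment(type = 1, D = 0.090, scale = 4, dt = dt)
    run <- run_san(exp, duration = 3500, rate_window = c(1500, 3500),
                   act_window = c(3000, 3500), sample_dt = 1)
    line_lab <- as.character(exp$mask)[run$line_nodes]
    node <- which(line_lab == "san")[ceiling(sum(line_lab == "san") / 2)]
    tr <- run$sim$trace
    trace_frequency(tr$time, tr$u[, node], settle = 1500)
  }
  f1 <- f_at(0.032); f2 <- f_at(0.016)
  expect_lt(100 * abs(f1 - f2) / f2, 0.5)
})

test_that("forward Euler refuses steps that violate the stability bound", {
  exp <- san_experiment(type = 1, D = 0.090, scale = 4, dt = 0.2)
  expect_error(run_san(exp, duration = 100), "stability")
})
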