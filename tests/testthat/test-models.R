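test_that("AP-family rates carry the factor-u identity and fix the origin", {
  set.seed(41)
  p <- cell_preset("pAP-0D")
  for (i in 1:20) {
    v <- runif(1, -0.5, 2.5)
    r <- ap_rhs(0, v, p)
    expect_identical(r$du, 0)
  }
  r0 <- ap_rhs(0, 0, p)
  expect_identical(unlist(r0), c(du = 0, dv = 0))
})

test_that("AP recovery rate matches direct hand evaluation", {
  p <- ap_params()  # Table-style defaults: k=8, a=0.13, eps0=0.002,
                    # mu1=0.2, mu2=0.3
  r <- ap_rhs(0, 0.3, p)
  eps <- 0.002 + 0.2 * 0.3 / 0.3
  expect_equal(r$dv, (1 / 12.9) * eps * (-0.3), tolerance = 1e-14)
})

test_that("b = -a reproduces the conventional AP potential equation exactly", {
  p <- ap_params(b = -0.13)  # a = 0.13
  set.seed(42)
  for (i in 1:25) {
    u <- runif(1, -0.3, 1.3); v <- runif(1, 0, 2.5)
    conventional <- p$ct * (p$k * u * (u - p$a) * (1 - u) - v * u)
    expect_identical(ap_rhs(u, v, p)$du, conventional)
  }
})

test_that("CN-family gate algebra: factor-u identity, midpoint, tau limits", {
  p <- cell_preset("pCN-0D")
  expect_identical(cn_rhs(0, 0.7, p, i_ext = 0.2)$du, 0.2)
  expect_equal(cn_hinf(p$u_gate, p), 0.5)
  expect_identical(cn_tau(0, p), p$tau_close)
  # for u far above the gate, h_inf ~ 0 so tau ~ tau_close
  expect_equal(cn_rhs(5, 0.5, p)$dh, (cn_hinf(5, p) - 0.5) / p$tau_close,
               tolerance = 1e-10)
})

test_that("h_inf is a monotone [0,1] sigmoid approaching a Heaviside gate", {
  p <- cn_params(u_s = 0.15, u_gate = 0.1)
  u <- seq(-2, 3, by = 0.01)
  h <- cn_hinf(u, p)
  expect_true(all(h >= 0 & h <= 1))
  expect_true(all(diff(h) <= 0))
  ps <- cn_params(u_s = 1e-6, u_gate = 0.1)
  u2 <- u[abs(u - ps$u_gate) > 1e-2]
  step <- ifelse(u2 <= ps$u_gate, 1, 0)
  expect_true(all(abs(cn_hinf(u2, ps) - step) < 1e-3))
})

test_that("gate time constant rejects parameter domains where it turns negative", {
  # tau_close > 2 tau_open makes the printed interpolation cross zero
  p <- cn_params(tau_open = 100, tau_close = 300, u_s = 0.1, u_gate = 0)
  expect_error(cn_rhs(-2, 0.5, p), "h_inf")
})

test_that("passive tissue decays linearly to rest", {
  p <- passive_params()
  expect_identical(passive_rhs(0, p), 0)
  expect_equal(passive_rhs(1, p), -26 / 12.9, tolerance = 1e-14)
  u <- c(-1, -0.1, 0.3, 2)
  expect_true(all(sign(passive_rhs(u, p)) == -sign(u)))
})

test_that("nullclines have their analytic roots and flag the trivial branch", {
  p <- cell_preset("pAP-0D", b = 0.03)
  nc <- nullclines(p, c(-p$b, 0, 1))
  expect_equal(nc$u_nullcline[c(1, 3)], c(0, 0), tolerance = 1e-14)
  expect_equal(nc$w_nullcline[2], 0)
  expect_true(nc$trivial_u_nullcline)
  q <- cell_preset("pCN-0D")
  expect_equal(nullclines(q, q$u_gate)$w_nullcline, 0.5)
  # CN u-nullcline marks division-by-zero points as NA
  qq <- cn_params(tau_in = 2, tau_out = 1, b = 0)
  # denominator u(1-u) + 2 = 0 at u = 2 (exactly representable)
  expect_true(is.na(nullclines(qq, 2)$u_nullcline))
})

test_that("equilibrium finding matches a scalar bisection oracle", {
  # conventional AP: origin is the resting state
  eq <- find_equilibria(ap_params(), c(-0.3, -0.3), c(1.2, 1.2),
                        n_starts = 15)
  expect_true(any(abs(eq$u) < 1e-8 & abs(eq$w) < 1e-8))
  expect_true(all(eq$residual < 1e-10))
  # pAP with b = 0.03: positive equilibrium at the nullcline intersection,
  # located independently by bisection on k(u+b)(1-u) = -k u (u-a-1)
  p <- cell_preset("pAP-0D", b = 0.03)
  g <- function(u) p$k * (u + p$b) * (1 - u) - (-p$k * u * (u - p$a - 1))
  u_star <- uniroot(g, c(1e-6, 1), tol = 1e-14)$root
  eq2 <- find_equilibria(p, c(-0.3, -0.3), c(1.2, 2.5), n_starts = 25)
  # besides the nullcline intersection, the recovery equation's
  # epsilon = 0 line contributes roots with (unphysiological) negative v;
  # the physiological positive-u equilibrium is unique
  pos <- eq2[eq2$u > 1e-6 & eq2$w > 0, ]
  expect_equal(nrow(pos), 1L)
  expect_equal(pos$u, u_star, tolerance = 1e-8)
  expect_equal(pos$w, p$k * (u_star + p$b) * (1 - u_star), tolerance = 1e-6)
  expect_true(all(eq2$residual < 1e-10))
})

test_that("the conventional resting states are dynamically stable", {
  # AP origin: a 1000-ms run started at the equilibrium stays within 1e-6
  f <- cell_field(ap_params(), n = 1, u0 = 0, w0 = 0)
  s <- simulate_field(f, duration = 1000, spec = integrator_spec("fe", 0.01))
  expect_lt(abs(s$field$u), 1e-6)
  # CN rest (u = 0, h = h_inf(0)) likewise
  p <- cell_preset("CN-1D")
  f2 <- cell_field(p, n = 1, u0 = 0, w0 = cn_hinf(0, p))
  s2 <- simulate_field(f2, duration = 1000, spec = integrator_spec("fe", 0.01))
  expect_lt(abs(s2$field$u), 1e-6)
})

test_that("parameter sets validate fields and round-trip through YAML", {
  expect_error(cell_preset("pAP-0D", nonsense = 1), "unknown parameter")
  expect_error(cell_preset("nope"), "unknown preset")
  expect_error(ap_params(k = -1))
  p <- cell_preset("pCN-ICC")
  q <- params_from_yaml(params_to_yaml(p))
  expect_equal(unclass(q)[names(unclass(p))], unclass(p)[names(unclass(p))],
               tolerance = 1e-12)
  expect_s3_class(q, "cn_params")
  expect_true(all(preset_names() %in% c(
    "pAP-0D", "pAP-1D", "AP-1D", "pAP-SAN1", "pAP-SAN2", "AP-atrium",
    "pCN-0D", "pCN-1D", "CN-1D", "pCN-ICC", "CN-SMC", "passive")))
})
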