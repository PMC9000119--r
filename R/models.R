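#' Model right-hand sides
#'
#' Evaluate the reaction terms of the Aliev-Panfilov family, the Corrado
#' family, or the passive-tissue model at a given state.  All functions are
#' vectorized over the state and return rates per millisecond.
#'
#' For the AP family (recovery variable `v`):
#' \deqn{du/dt = c_t [k u (u + b)(1 - u) - v u] + I_{ext}}
#' \deqn{dv/dt = c_t \varepsilon(u, v) [-v - k u (u - a - 1)],\quad
#'       \varepsilon = \varepsilon_0 + \mu_1 v / (u + \mu_2)}
#'
#' For the CN family (gate `h`):
#' \deqn{du/dt = h u (u + b)(1 - u)/\tau_{in} - (1 - h) u/\tau_{out} + I_{ext}}
#' \deqn{dh/dt = (h_\infty(u) - h)/\tau(u)}
#' with \eqn{h_\infty(u) = [1 - \tanh((u - u_{gate})/u_s)]/2} and
#' \eqn{\tau = \tau_{open}\tau_{close} /
#'       [\tau_{open} - h_\infty(\tau_{close} - \tau_{open})]}.
#'
#' Passive tissue: \eqn{du/dt = -c_t S u + I_{ext}}.
#'
#' @param u transmembrane potential (dimensionless).
#' @param v,h recovery / gating variable.
#' @param p parameter object ([ap_params()], [cn_params()],
#'   [passive_params()]).
#' @param i_ext external or coupling current (per ms).
#' @return A list with components `du` and `dv` (or `dh`); [passive_rhs()]
#'   returns the scalar rate.
#' @examples
#' ap_rhs(0.2, 0.1, cell_preset("pAP-0D"))
#' @export
ap_rhs <- function(u, v, p, i_ext = 0) {
  stopifnot(inherits(p, "ap_params"))
  if (any(!is.finite(u)) || any(!is.finite(v)))
    stop("non-finite state passed to ap_rhs (diverged trajectory?)")
  if (any(u + p$mu2 == 0))
    stop("ap_rhs undefined at u = -mu2 (epsilon denominator is zero)")
  eps <- p$eps0 + p$mu1 * v / (u + p$mu2)
  list(du = p$ct * (p$k * u * (u + p$b) * (1 - u) - v * u) + i_ext,
       dv = p$ct * eps * (-v - p$k * u * (u - p$a - 1)))
}

#' @rdname ap_rhs
#' @export
cn_rhs <- function(u, h, p, i_ext = 0) {
  stopifnot(inherits(p, "cn_params"))
  if (any(!is.finite(u)) || any(!is.finite(h)))
    stop("non-finite state passed to cn_rhs (diverged trajectory?)")
  hinf <- cn_hinf(u, p)
  tau <- cn_tau(hinf, p)
  if (any(tau <= 0)) {
    bad <- hinf[tau <= 0][1]
    stop("gate time constant non-positive for h_inf = ", format(bad),
         " (tau_open/tau_close ratio outside the valid domain of the ",
         "printed interpolation)")
  }
  list(du = h * u * (u + p$b) * (1 - u) / p$tau_in -
            (1 - h) * u / p$tau_out + i_ext,
       dh = (hinf - h) / tau)
}

#' @rdname ap_rhs
#' @export
passive_rhs <- function(u, p, i_ext = 0) {
  stopifnot(inherits(p, "passive_params"))
  -p$ct * p$S * u + i_ext
}

#' Gate steady state and time constant of the CN family
#'
#' `cn_hinf()` is the Boltzmann sigmoid
#' \eqn{h_\infty(u) = [1 - \tanh((u - u_{gate})/u_s)]/2}; as `u_s` shrinks
#' it approaches the Heaviside gate of the original piecewise model.
#' `cn_tau()` interpolates the gate time constant through `h_inf`.
#'
#' @param u potential values.
#' @param hinf gate steady-state values.
#' @param p a [cn_params()] object.
#' @return Numeric vector.
#' @export
cn_hinf <- function(u, p) 0.5 * (1 - tanh((u - p$u_gate) / p$u_s))

#' @rdname cn_hinf
#' @export
cn_tau <- function(hinf, p) {
  if (identical(p$tau_scheme, "convex"))
    hinf * p$tau_open + (1 - hinf) * p$tau_close
  else
    p$tau_open * p$tau_close /
      (p$tau_open - hinf * (p$tau_close - p$tau_open))
}

#' Nullclines of the two-variable models
#'
#' Pointwise evaluation of the non-trivial nullclines in the
#' (u, recovery) phase plane.  For the AP family the u-nullcline is the
#' cubic `v = k (u + b)(1 - u)` and the v-nullcline is
#' `v = -k u (u - a - 1)`.  For the CN family the u-nullcline is
#' `h = tau_in / [tau_out (u + b)(1 - u) + tau_in]` and the h-nullcline is
#' `h = h_inf(u)`.  Both families also possess the trivial u-nullcline
#' `u = 0`, reported as a flag rather than a curve.  Points where the CN
#' u-nullcline denominator vanishes are returned as `NA`.
#'
#' @param p parameter object (AP or CN family).
#' @param u numeric grid of potentials (finite).
#' @return A list with components `u`, `u_nullcline`, `w_nullcline`
#'   (recovery-variable values on each curve) and
#'   `trivial_u_nullcline = TRUE`.
#' @examples
#' nc <- nullclines(cell_preset("pAP-0D"), seq(-0.2, 1.2, 0.01))
#' @export
nullclines <- function(p, u) {
  stopifnot(all(is.finite(u)))
  if (inherits(p, "ap_params")) {
    un <- p$k * (u + p$b) * (1 - u)
    wn <- -p$k * u * (u - p$a - 1)
  } else if (inherits(p, "cn_params")) {
    den <- p$tau_out * (u + p$b) * (1 - u) + p$tau_in
    # mark (near-)singular points undefined rather than returning huge values
    bad <- abs(den) < 1e-9 * max(p$tau_in, p$tau_out)
    un <- ifelse(bad, NA_real_, p$tau_in / den)
    wn <- cn_hinf(u, p)
  } else stop("nullclines are defined for the AP and CN families only")
  list(u = u, u_nullcline = un, w_nullcline = wn,
       trivial_u_nullcline = TRUE)
}

# reaction rates + analytic Jacobian in plain R (used by the Newton
# equilibrium search; time scaling does not move the roots)
reaction_and_jac <- function(p, u, w) {
  if (inherits(p, "ap_params")) {
    r <- ap_rhs(u, w, p)
    eps <- p$eps0 + p$mu1 * w / (u + p$mu2)
    deps_du <- -p$mu1 * w / (u + p$mu2)^2
    deps_dw <- p$mu1 / (u + p$mu2)
    g <- -w - p$k * u * (u - p$a - 1)
    J <- matrix(c(
      p$ct * (p$k * (-3 * u^2 + 2 * (1 - p$b) * u + p$b) - w),
      p$ct * (deps_du * g + eps * (-p$k * (2 * u - p$a - 1))),
      -p$ct * u,
      p$ct * (deps_dw * g - eps)), 2, 2)
    list(f = c(r$du, r$dv), J = J)
  } else {
    r <- cn_rhs(u, w, p)
    th <- tanh((u - p$u_gate) / p$u_s)
    hinf <- 0.5 * (1 - th)
    dhinf <- -0.5 * (1 - th^2) / p$u_s
    tau <- cn_tau(hinf, p)
    dtau <- if (identical(p$tau_scheme, "convex")) {
      dhinf * (p$tau_open - p$tau_close)
    } else {
      den <- p$tau_open - hinf * (p$tau_close - p$tau_open)
      p$tau_open * p$tau_close * (p$tau_close - p$tau_open) * dhinf / den^2
    }
    J <- matrix(c(
      w * (-3 * u^2 + 2 * (1 - p$b) * u + p$b) / p$tau_in -
        (1 - w) / p$tau_out,
      dhinf / tau - (hinf - w) * dtau / tau^2,
      u * (u + p$b) * (1 - u) / p$tau_in + u / p$tau_out,
      -1 / tau), 2, 2)
    list(f = c(r$du, r$dh), J = J)
  }
}

#' Find equilibrium points
#'
#' Locates all equilibria of a single cell inside a search box by dense
#' multi-start damped Newton iteration from a regular grid of starting
#' points.  Converged points with reaction-rate norm below `tol` are kept
#' and duplicates within `merge_tol` merged.  The origin (the resting
#' state of the conventional excitable models) is included whenever it is
#' a root.
#'
#' @param p parameter object (AP or CN family).
#' @param lower,upper numeric length-2 box bounds `(u, w)` (finite).
#' @param n_starts grid resolution per axis (default 50).
#' @param tol residual norm required of a reported equilibrium.
#' @param merge_tol distance below which two roots are considered the same.
#' @param jitter standard deviation of optional random perturbation of the
#'   start grid (0 = deterministic).
#' @return A data.frame with columns `u`, `w`, `residual`, possibly empty.
#' @examples
#' find_equilibria(cell_preset("pAP-0D"), c(-0.2, -0.2), c(1.2, 1.2),
#'                 n_starts = 15)
#' @export
find_equilibria <- function(p, lower = c(-0.5, -0.5), upper = c(1.5, 2.5),
                            n_starts = 50, tol = 1e-10, merge_tol = 1e-6,
                            jitter = 0) {
  stopifnot(all(is.finite(lower)), all(is.finite(upper)),
            length(lower) == 2, length(upper) == 2)
  if (inherits(p, "cn_params")) {
    # gate equilibrium is h = h_inf(u); clamp the box to the unit interval
    lower[2] <- max(lower[2], 0)
    upper[2] <- min(upper[2], 1)
  }
  us <- seq(lower[1], upper[1], length.out = n_starts)
  ws <- seq(lower[2], upper[2], length.out = n_starts)
  starts <- as.matrix(expand.grid(u = us, w = ws))
  if (jitter > 0)
    starts <- starts + matrix(stats::rnorm(length(starts), 0, jitter),
                              ncol = 2)
  roots <- matrix(numeric(0), ncol = 2)
  res <- numeric(0)
  for (s in seq_len(nrow(starts))) {
    x <- starts[s, ]
    ok <- FALSE
    for (it in 1:60) {
      fj <- tryCatch(reaction_and_jac(p, x[1], x[2]), error = function(e) NULL)
      if (is.null(fj) || any(!is.finite(fj$f))) break
      r0 <- sqrt(sum(fj$f^2))
      if (r0 < tol) { ok <- TRUE; break }
      dx <- tryCatch(solve(fj$J, -fj$f), error = function(e) NULL)
      if (is.null(dx) || any(!is.finite(dx))) break
      lam <- 1
      for (h in 1:8) {
        xn <- x + lam * dx
        fn <- tryCatch(reaction_and_jac(p, xn[1], xn[2])$f,
                       error = function(e) rep(Inf, 2))
        if (all(is.finite(fn)) && sqrt(sum(fn^2)) <= r0) break
        lam <- lam / 2
      }
      x <- x + lam * dx
      if (any(abs(x) > 1e3)) break
    }
    if (!ok) next
    if (x[1] < lower[1] - 0.25 || x[1] > upper[1] + 0.25 ||
        x[2] < lower[2] - 0.25 || x[2] > upper[2] + 0.25) next
    if (nrow(roots) > 0 &&
        any(sqrt(rowSums(sweep(roots, 2, x)^2)) < merge_tol)) next
    roots <- rbind(roots, x)
    res <- c(res, sqrt(sum(reaction_and_jac(p, x[1], x[2])$f^2)))
  }
  out <- data.frame(u = roots[, 1], w = roots[, 2], residual = res,
                    row.names = NULL)
  if (nrow(out) > 1) out <- out[order(out$u), , drop = FALSE]
  out
}
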