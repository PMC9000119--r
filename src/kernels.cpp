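// Time-stepping kernels for two-variable excitable / pacemaking cell models
// coupled through a sparse diffusion operator.
//
// Model kinds per node:
//   0  Aliev-Panfilov family (recovery variable v), parameter row
//      [k, a, eps0, mu1, mu2, b, ct]
//   1  Corrado / Mitchell-Schaeffer family (gate h), parameter row
//      [tau_in, tau_out, tau_open, tau_close, u_s, u_gate, b]
//   2  passive tissue, parameter row [S, ct, 0, 0, 0, 0, 0]
//
// The coupling operator (column-compressed sparse, zero row sums for
// conservative boundaries) acts on the potential u only, in 1/ms units.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static inline double cn_tau(double hinf, double tau_open, double tau_close,
                            int tau_scheme) {
  if (tau_scheme == 1)            // convex blend alternative (config switch)
    return hinf * tau_open + (1.0 - hinf) * tau_close;
  // printed interpolation: tau(hinf = 0) = tau_close
  double den = tau_open - hinf * (tau_close - tau_open);
  return tau_open * tau_close / den;
}

static inline void reaction(int kind, const double* p, double u, double w,
                            int tau_scheme, double& du, double& dw) {
  if (kind == 0) {
    const double k = p[0], a = p[1], eps0 = p[2], mu1 = p[3], mu2 = p[4],
                 b = p[5], ct = p[6];
    const double eps = eps0 + mu1 * w / (u + mu2);
    du = ct * (k * u * (u + b) * (1.0 - u) - w * u);
    dw = ct * eps * (-w - k * u * (u - a - 1.0));
  } else if (kind == 1) {
    const double tin = p[0], tout = p[1], topen = p[2], tclose = p[3],
                 us = p[4], ug = p[5], b = p[6];
    const double hinf = 0.5 * (1.0 - std::tanh((u - ug) / us));
    const double tau = cn_tau(hinf, topen, tclose, tau_scheme);
    du = w * u * (u + b) * (1.0 - u) / tin - (1.0 - w) * u / tout;
    dw = (hinf - w) / tau;
  } else {
    du = -p[1] * p[0] * u;   // -ct * S * u
    dw = 0.0;
  }
}

// analytic Jacobian of the reaction term, d(du,dw)/d(u,w)
static inline void reaction_jac(int kind, const double* p, double u, double w,
                                int tau_scheme,
                                double& juu, double& juw,
                                double& jwu, double& jww) {
  if (kind == 0) {
    const double k = p[0], a = p[1], eps0 = p[2], mu1 = p[3], mu2 = p[4],
                 b = p[5], ct = p[6];
    const double eps = eps0 + mu1 * w / (u + mu2);
    const double deps_du = -mu1 * w / ((u + mu2) * (u + mu2));
    const double deps_dw = mu1 / (u + mu2);
    const double g = -w - k * u * (u - a - 1.0);
    juu = ct * (k * (-3.0 * u * u + 2.0 * (1.0 - b) * u + b) - w);
    juw = -ct * u;
    jwu = ct * (deps_du * g + eps * (-k * (2.0 * u - a - 1.0)));
    jww = ct * (deps_dw * g - eps);
  } else if (kind == 1) {
    const double tin = p[0], tout = p[1], topen = p[2], tclose = p[3],
                 us = p[4], ug = p[5], b = p[6];
    const double th = std::tanh((u - ug) / us);
    const double hinf = 0.5 * (1.0 - th);
    const double dhinf = -0.5 * (1.0 - th * th) / us;
    const double tau = cn_tau(hinf, topen, tclose, tau_scheme);
    double dtau;
    if (tau_scheme == 1) {
      dtau = dhinf * (topen - tclose);
    } else {
      double den = topen - hinf * (tclose - topen);
      dtau = topen * tclose * (tclose - topen) * dhinf / (den * den);
    }
    juu = w * (-3.0 * u * u + 2.0 * (1.0 - b) * u + b) / tin -
          (1.0 - w) / tout;
    juw = u * (u + b) * (1.0 - u) / tin + u / tout;
    jwu = dhinf / tau - (hinf - w) * dtau / (tau * tau);
    jww = -1.0 / tau;
  } else {
    juu = -p[1] * p[0];
    juw = 0.0; jwu = 0.0; jww = 0.0;
  }
}

// y = W u  (CSC sparse matvec)
static inline void matvec(const int* Wi, const int* Wp, const double* Wx,
                          int n, const double* u, double* y) {
  for (int i = 0; i < n; ++i) y[i] = 0.0;
  for (int j = 0; j < n; ++j) {
    const double uj = u[j];
    if (uj == 0.0) continue;
    for (int k = Wp[j]; k < Wp[j + 1]; ++k) y[Wi[k]] += Wx[k] * uj;
  }
}

struct Tracker {
  // upward-crossing counting over [count_from, count_to], first-activation
  // time over [act_from, act_to], threshold thr
  double count_from, count_to, act_from, act_to, thr;
  std::vector<int> counts;
  std::vector<double> act;
  bool on;
  Tracker(int n, double cf, double ct_, double af, double at, double thr_)
      : count_from(cf), count_to(ct_), act_from(af), act_to(at), thr(thr_) {
    on = R_finite(cf) || R_finite(af);
    counts.assign(n, 0);
    act.assign(n, NA_REAL);
  }
  inline void update(int i, double uprev, double unew, double tnew) {
    if (uprev < thr && unew >= thr) {
      if (tnew >= count_from && tnew <= count_to) counts[i]++;
      if (tnew >= act_from && tnew <= act_to && ISNA(act[i])) act[i] = tnew;
    }
  }
};

static void check_finite(const std::vector<double>& u, double t) {
  for (size_t i = 0; i < u.size(); ++i)
    if (!R_finite(u[i]))
      stop("state diverged (non-finite u) at node %d, t = %g ms",
           (int)(i + 1), t);
}

// [[Rcpp::export]]
List fe_run_cpp(IntegerVector kind, NumericMatrix P, int tau_scheme,
                NumericVector u0, NumericVector w0, NumericVector iext,
                IntegerVector Wi, IntegerVector Wp, NumericVector Wx,
                bool coupled, double dt, double nsteps_d, double t0,
                IntegerVector rec_nodes, int rec_every,
                NumericVector track,     // count_from, count_to, act_from, act_to, thr
                NumericVector snap_times,
                double block_time, IntegerVector block_nodes,
                double block_u, double block_w) {
  const int n = kind.size();
  const int64_t nsteps = (int64_t)nsteps_d;
  std::vector<double> u(u0.begin(), u0.end()), w(w0.begin(), w0.end());
  std::vector<double> cu(n, 0.0), uprev(n);
  const int nrec = rec_nodes.size();
  const int64_t nsamp = nrec > 0 ? nsteps / rec_every + 1 : 0;
  NumericMatrix tr_u(nsamp, nrec), tr_w(nsamp, nrec);
  NumericVector tr_t(nsamp);
  const int nsnap = snap_times.size();
  NumericMatrix snaps(nsnap > 0 ? n : 0, nsnap);
  int snap_next = 0;
  Tracker trk(n, track[0], track[1], track[2], track[3], track[4]);
  bool block_done = !R_finite(block_time);
  std::vector<double> prow(7);

  int64_t isamp = 0;
  if (nrec > 0) {
    tr_t[0] = t0;
    for (int r = 0; r < nrec; ++r) {
      tr_u(0, r) = u[rec_nodes[r] - 1];
      tr_w(0, r) = w[rec_nodes[r] - 1];
    }
    isamp = 1;
  }

  for (int64_t s = 0; s < nsteps; ++s) {
    const double t = t0 + (double)s * dt;
    if (!block_done && t >= block_time) {
      for (int b = 0; b < block_nodes.size(); ++b) {
        u[block_nodes[b] - 1] = block_u;
        w[block_nodes[b] - 1] = block_w;
      }
      block_done = true;
    }
    if (coupled) matvec(Wi.begin(), Wp.begin(), Wx.begin(), n, u.data(), cu.data());
    const double tnew = t0 + (double)(s + 1) * dt;
    for (int i = 0; i < n; ++i) {
      double du, dw;
      reaction(kind[i], &P(0, i), u[i], w[i], tau_scheme, du, dw);
      uprev[i] = u[i];
      u[i] += dt * (du + cu[i] + iext[i]);
      w[i] += dt * dw;
      if (trk.on) trk.update(i, uprev[i], u[i], tnew);
    }
    while (snap_next < nsnap && tnew >= snap_times[snap_next]) {
      for (int i = 0; i < n; ++i) snaps(i, snap_next) = u[i];
      snap_next++;
    }
    if (nrec > 0 && (s + 1) % rec_every == 0 && isamp < nsamp) {
      tr_t[isamp] = tnew;
      for (int r = 0; r < nrec; ++r) {
        tr_u(isamp, r) = u[rec_nodes[r] - 1];
        tr_w(isamp, r) = w[rec_nodes[r] - 1];
      }
      isamp++;
    }
    if ((s & 1023) == 0) {
      check_finite(u, tnew);
      Rcpp::checkUserInterrupt();
    }
  }
  check_finite(u, t0 + (double)nsteps * dt);

  return List::create(
      _["u"] = NumericVector(u.begin(), u.end()),
      _["w"] = NumericVector(w.begin(), w.end()),
      _["t_end"] = t0 + (double)nsteps * dt,
      _["trace_t"] = tr_t, _["trace_u"] = tr_u, _["trace_w"] = tr_w,
      _["counts"] = IntegerVector(trk.counts.begin(), trk.counts.end()),
      _["act_time"] = NumericVector(trk.act.begin(), trk.act.end()),
      _["snapshots"] = snaps, _["inner_max"] = 0);
}

// one implicit (backward Euler) update of a single node, damped Newton;
// returns iterations used, or -1 on failure
static inline int be_node(int kind, const double* p, int tau_scheme,
                          double ut, double wt, double cu, double dt,
                          double abs_tol, int max_inner,
                          double& uo, double& wo) {
  if (kind == 2) {  // linear: closed form
    uo = (ut + dt * cu) / (1.0 + dt * p[1] * p[0]);
    wo = wt;
    return 1;
  }
  double x = uo, y = wo;  // warm start from caller
  for (int it = 1; it <= max_inner; ++it) {
    double du, dw;
    reaction(kind, p, x, y, tau_scheme, du, dw);
    const double f1 = x - ut - dt * (du + cu);
    const double f2 = y - wt - dt * dw;
    double juu, juw, jwu, jww;
    reaction_jac(kind, p, x, y, tau_scheme, juu, juw, jwu, jww);
    const double a11 = 1.0 - dt * juu, a12 = -dt * juw;
    const double a21 = -dt * jwu, a22 = 1.0 - dt * jww;
    const double det = a11 * a22 - a12 * a21;
    if (det == 0.0 || !R_finite(det)) return -1;
    double dx = -(a22 * f1 - a12 * f2) / det;
    double dy = -(-a21 * f1 + a11 * f2) / det;
    const double r0 = std::fabs(f1) + std::fabs(f2);
    double lam = 1.0;
    for (int h = 0; h < 8; ++h) {
      const double xn = x + lam * dx, yn = y + lam * dy;
      double dun, dwn;
      reaction(kind, p, xn, yn, tau_scheme, dun, dwn);
      const double g1 = xn - ut - dt * (dun + cu);
      const double g2 = yn - wt - dt * dwn;
      if (std::fabs(g1) + std::fabs(g2) <= r0 || h == 7) {
        x = xn; y = yn;
        break;
      }
      lam *= 0.5;
    }
    if (std::fabs(lam * dx) < abs_tol && std::fabs(lam * dy) < abs_tol) {
      uo = x; wo = y;
      return it;
    }
  }
  return -1;
}

// [[Rcpp::export]]
List be_run_cpp(IntegerVector kind, NumericMatrix P, int tau_scheme,
                NumericVector u0, NumericVector w0, NumericVector iext,
                IntegerVector Wi, IntegerVector Wp, NumericVector Wx,
                bool coupled, double dt, double nsteps_d, double t0,
                IntegerVector rec_nodes, int rec_every,
                NumericVector track, NumericVector snap_times,
                double block_time, IntegerVector block_nodes,
                double block_u, double block_w,
                double abs_tol, int max_inner) {
  const int n = kind.size();
  const int64_t nsteps = (int64_t)nsteps_d;
  std::vector<double> u(u0.begin(), u0.end()), w(w0.begin(), w0.end());
  std::vector<double> cu(n, 0.0), un(n), wn(n), uprev(n);
  const int nrec = rec_nodes.size();
  const int64_t nsamp = nrec > 0 ? nsteps / rec_every + 1 : 0;
  NumericMatrix tr_u(nsamp, nrec), tr_w(nsamp, nrec);
  NumericVector tr_t(nsamp);
  const int nsnap = snap_times.size();
  NumericMatrix snaps(nsnap > 0 ? n : 0, nsnap);
  int snap_next = 0;
  Tracker trk(n, track[0], track[1], track[2], track[3], track[4]);
  bool block_done = !R_finite(block_time);
  int inner_max = 0;

  int64_t isamp = 0;
  if (nrec > 0) {
    tr_t[0] = t0;
    for (int r = 0; r < nrec; ++r) {
      tr_u(0, r) = u[rec_nodes[r] - 1];
      tr_w(0, r) = w[rec_nodes[r] - 1];
    }
    isamp = 1;
  }

  for (int64_t s = 0; s < nsteps; ++s) {
    const double t = t0 + (double)s * dt;
    if (!block_done && t >= block_time) {
      for (int b = 0; b < block_nodes.size(); ++b) {
        u[block_nodes[b] - 1] = block_u;
        w[block_nodes[b] - 1] = block_w;
      }
      block_done = true;
    }
    const double tnew = t0 + (double)(s + 1) * dt;
    // fixed-point over the coupling term, pointwise implicit reaction
    for (int i = 0; i < n; ++i) { un[i] = u[i]; wn[i] = w[i]; }
    const int max_outer = coupled ? max_inner : 1;
    for (int outer = 1; outer <= max_outer; ++outer) {
      if (coupled)
        matvec(Wi.begin(), Wp.begin(), Wx.begin(), n, un.data(), cu.data());
      double delta = 0.0;
      for (int i = 0; i < n; ++i) {
        const double up = un[i];
        int it = be_node(kind[i], &P(0, i), tau_scheme, u[i], w[i],
                         cu[i] + iext[i], dt, abs_tol, max_inner,
                         un[i], wn[i]);
        if (it < 0)
          stop("backward-Euler inner loop failed to converge within %d iterations at node %d, t = %g ms",
               max_inner, i + 1, tnew);
        if (it > inner_max) inner_max = it;
        const double d = std::fabs(un[i] - up);
        if (d > delta) delta = d;
      }
      if (!coupled || delta < abs_tol) break;
      if (outer == max_outer)
        stop("backward-Euler coupling iteration failed to converge within %d sweeps at t = %g ms",
             max_outer, tnew);
    }
    for (int i = 0; i < n; ++i) {
      uprev[i] = u[i];
      u[i] = un[i]; w[i] = wn[i];
      if (trk.on) trk.update(i, uprev[i], u[i], tnew);
    }
    while (snap_next < nsnap && tnew >= snap_times[snap_next]) {
      for (int i = 0; i < n; ++i) snaps(i, snap_next) = u[i];
      snap_next++;
    }
    if (nrec > 0 && (s + 1) % rec_every == 0 && isamp < nsamp) {
      tr_t[isamp] = tnew;
      for (int r = 0; r < nrec; ++r) {
        tr_u(isamp, r) = u[rec_nodes[r] - 1];
        tr_w(isamp, r) = w[rec_nodes[r] - 1];
      }
      isamp++;
    }
    if ((s & 1023) == 0) {
      check_finite(u, tnew);
      Rcpp::checkUserInterrupt();
    }
  }
  check_finite(u, t0 + (double)nsteps * dt);

  return List::create(
      _["u"] = NumericVector(u.begin(), u.end()),
      _["w"] = NumericVector(w.begin(), w.end()),
      _["t_end"] = t0 + (double)nsteps * dt,
      _["trace_t"] = tr_t, _["trace_u"] = tr_u, _["trace_w"] = tr_w,
      _["counts"] = IntegerVector(trk.counts.begin(), trk.counts.end()),
      _["act_time"] = NumericVector(trk.act.begin(), trk.act.end()),
      _["snapshots"] = snaps, _["inner_max"] = inner_max);
}
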