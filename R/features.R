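#' Action-potential cycle features
#'
#' Detects cycles in a potential trace after an initial settling period and
#' extracts the standard pacemaker waveform features: peak overshoot
#' potential (POP) and maximum diastolic potential (MDP, the per-cycle
#' maximum and minimum averaged over cycles), action-potential duration at
#' 90% repolarization (APD90, time spent above the level
#' `POP - 0.9 (POP - MDP)` per cycle), diastolic interval
#' (`DI = CL - APD90`), cycle length CL, and frequency `1000/CL` Hz.
#'
#' Cycles are delimited by upward crossings of the mid-amplitude level
#' `MDP + 0.5 (POP - MDP)`, computed iteratively: a first pass uses the
#' global extrema of the settled trace, a second pass re-detects crossings
#' at the level implied by the averaged per-cycle extrema.  A constant
#' trace, or one with fewer than three complete cycles after settling,
#' yields a quiescent result (not an error).
#'
#' @param trace a `pc_trace` (from [simulate_cell()] / [simulate_field()])
#'   or a list with `time` (ms) and `u`.
#' @param settle settling time (ms) discarded before feature extraction
#'   (default 30000; oscillations of these models stabilize within
#'   20-50 s).
#' @param node column of the trace to analyze (default 1).
#' @return An object of class `feature_set`: list with `POP`, `MDP`,
#'   `APD90`, `DI`, `CL`, `frequency`, `n_cycles`, `quiescent`.
#' @examples
#' tr <- list(time = seq(0, 5000, 1), u = sin(2 * pi * seq(0, 5000, 1) / 500))
#' extract_features(tr, settle = 0)
#' @export
extract_features <- function(trace, settle = 30000, node = 1) {
  time <- as.numeric(trace$time)
  u <- if (is.matrix(trace$u)) trace$u[, node] else as.numeric(trace$u)
  keep <- time >= settle
  if (sum(keep) < 10)
    stop("trace shorter than the settling time")
  time <- time[keep]; u <- u[keep]
  quiescent <- structure(list(POP = NA_real_, MDP = NA_real_,
                              APD90 = NA_real_, DI = NA_real_,
                              CL = NA_real_, frequency = NA_real_,
                              n_cycles = 0L, quiescent = TRUE),
                         class = "feature_set")
  if (diff(range(u)) < 1e-8) return(quiescent)
  cr <- crossing_times(time, u, mid_level(u))
  for (pass in 1:2) {
    if (length(cr) < 4) return(quiescent)
    ncyc <- length(cr) - 1
    pop <- mdp <- apd <- numeric(ncyc)
    for (c_i in seq_len(ncyc)) {
      sel <- time >= cr[c_i] & time <= cr[c_i + 1]
      pop[c_i] <- max(u[sel]); mdp[c_i] <- min(u[sel])
    }
    if (pass == 1) {
      level <- mean(mdp) + 0.5 * (mean(pop) - mean(mdp))
      cr <- crossing_times(time, u, level)
      next
    }
    for (c_i in seq_len(ncyc)) {
      sel <- time >= cr[c_i] & time <= cr[c_i + 1]
      lev90 <- pop[c_i] - 0.9 * (pop[c_i] - mdp[c_i])
      apd[c_i] <- time_above(time[sel], u[sel], lev90)
    }
  }
  cl <- mean(diff(cr))
  structure(list(POP = mean(pop), MDP = mean(mdp), APD90 = mean(apd),
                 DI = cl - mean(apd), CL = cl, frequency = 1000 / cl,
                 n_cycles = as.integer(length(cr) - 1), quiescent = FALSE),
            class = "feature_set")
}

# total time a segment spends above `level` (interpolated crossings)
time_above <- function(time, u, level) {
  if (length(time) < 2) return(0)
  above <- u >= level
  dt_seg <- diff(time)
  frac_hi <- numeric(length(dt_seg))
  for (k in seq_along(dt_seg)) {
    if (above[k] && above[k + 1]) frac_hi[k] <- 1
    else if (!above[k] && !above[k + 1]) frac_hi[k] <- 0
    else {
      f <- (level - u[k]) / (u[k + 1] - u[k])
      frac_hi[k] <- if (above[k + 1]) 1 - f else f
    }
  }
  sum(frac_hi * dt_seg)
}

#' @export
print.feature_set <- function(x, ...) {
  if (x$quiescent) {
    cat("<feature_set> quiescent (no sustained oscillation)\n")
  } else {
    cat(sprintf(paste0("<feature_set> POP %.4f  MDP %.4f  APD90 %.1f ms  ",
                       "DI %.1f ms  CL %.1f ms  %.4f Hz  (%d cycles)\n"),
                x$POP, x$MDP, x$APD90, x$DI, x$CL, x$frequency, x$n_cycles))
  }
  invisible(x)
}

#' Orientation of a limit-cycle orbit in the phase plane
#'
#' Sign of the signed (shoelace) area of the closed `(u, w)` loop over the
#' last complete cycle: positive area means counterclockwise traversal.
#' The pacemaking AP cell orbits counterclockwise in `(u, v)`; the
#' pacemaking CN cell orbits clockwise in `(u, h)` because the gate closes
#' while the potential is high.
#'
#' @param trace a `pc_trace` with recorded `u` and `w`, covering at least
#'   one full cycle after `settle`.
#' @param settle transient discarded before analysis (ms).
#' @param node recorded column to analyze.
#' @return `"clockwise"` or `"counterclockwise"`.
#' @export
orbit_orientation <- function(trace, settle = 0, node = 1) {
  time <- as.numeric(trace$time)
  u <- if (is.matrix(trace$u)) trace$u[, node] else as.numeric(trace$u)
  w <- if (is.matrix(trace$w)) trace$w[, node] else as.numeric(trace$w)
  keep <- time >= settle
  time <- time[keep]; u <- u[keep]; w <- w[keep]
  if (diff(range(u)) < 1e-8)
    stop("orbit is quiescent; orientation undefined")
  cyc <- last_cycle(time, u)
  if (is.null(cyc))
    stop("trace contains no complete cycle; orientation undefined")
  sel <- time >= cyc[1] & time <= cyc[2]
  x <- u[sel]; y <- w[sel]
  x <- c(x, x[1]); y <- c(y, y[1])
  area <- 0.5 * sum(x[-length(x)] * y[-1] - x[-1] * y[-length(y)])
  if (area > 0) "counterclockwise" else "clockwise"
}

#' Sweep a bifurcation parameter of an isolated cell
#'
#' For every grid value, simulates one isolated cell (fresh standard
#' initial conditions), extracts cycle features, and locates the
#' equilibrium point with `u > 0` (the nullcline intersection around which
#' the limit cycle forms, when it exists).  A divergent simulation at a
#' grid point is recorded as a failed point and the sweep continues.
#'
#' @param p base `cell_params` object (typically from [cell_preset()]).
#' @param param parameter to sweep: a field name of `p`, or `"i_ext"`.
#' @param grid strictly monotone numeric grid.
#' @param duration,settle simulation length and settling time (ms).
#' @param dt time step (ms).
#' @param scheme integrator (`"be"` by default, as used for final sweeps).
#' @return A `sweep_result` data.frame: one row per grid value with the
#'   feature columns, `quiescent`/`failed` flags and equilibrium
#'   coordinates `eq_u`, `eq_w`.
#' @export
sweep_parameter <- function(p, param, grid, duration = 50000,
                            settle = 30000, dt = 0.01,
                            scheme = c("be", "fe")) {
  scheme <- match.arg(scheme)
  stopifnot(length(grid) >= 1, all(diff(grid) > 0) || all(diff(grid) < 0))
  if (param != "i_ext" && !param %in% names(unclass(p)))
    stop("parameter '", param, "' is not a field of this parameter set")
  rows <- vector("list", length(grid))
  for (g in seq_along(grid)) {
    val <- grid[g]
    pg <- p; iext <- 0
    if (param == "i_ext") iext <- val else pg <- modify_params(p, stats::setNames(list(val), param))
    row <- data.frame(value = val, failed = FALSE, quiescent = NA,
                      POP = NA_real_, MDP = NA_real_, APD90 = NA_real_,
                      DI = NA_real_, CL = NA_real_, frequency = NA_real_,
                      eq_u = NA_real_, eq_w = NA_real_)
    fs <- tryCatch({
      tr <- simulate_cell(pg, duration, dt = dt, scheme = scheme,
                          sample_dt = max(dt, 0.1), i_ext = iext)
      extract_features(tr, settle = settle)
    }, error = function(e) e)
    if (inherits(fs, "error")) {
      row$failed <- TRUE
    } else {
      row$quiescent <- fs$quiescent
      if (!fs$quiescent)
        row[c("POP", "MDP", "APD90", "DI", "CL", "frequency")] <-
          fs[c("POP", "MDP", "APD90", "DI", "CL", "frequency")]
    }
    ep <- tryCatch(find_equilibria(pg, c(1e-4, -0.5), c(1.5, 2.5),
                                   n_starts = 20),
                   error = function(e) NULL)
    if (!is.null(ep) && nrow(ep) > 0) {
      # the physiological branch: positive u, non-negative recovery
      ep <- ep[ep$u > 1e-6 & ep$w > -1e-9, , drop = FALSE]
      if (nrow(ep) > 0) {
        row$eq_u <- ep$u[1]; row$eq_w <- ep$w[1]
      }
    }
    rows[[g]] <- row
  }
  out <- do.call(rbind, rows)
  attr(out, "param") <- param
  class(out) <- c("sweep_result", class(out))
  out
}

#' Simulate a star-coupled pacemaker-strand system
#'
#' @param pacer pacemaker `cell_params` (pAP or pCN).
#' @param excitable strand `cell_params` (AP or CN).
#' @param n_strands load multiplicity (see [build_star()]).
#' @param d coupling coefficient (per ms).
#' @param duration simulated time (ms).
#' @param dt time step (ms).
#' @param scheme integrator scheme.
#' @param cells_per_strand strand length (default 20).
#' @param observe strand cell whose trace is recorded alongside the
#'   pacemaker (default 16, away from the sealed end).
#' @param field optional `cell_field` carried over from a previous run
#'   (hysteresis protocols); must match the topology.
#' @param ... passed to [simulate_field()].
#' @return The `pc_sim` result; recorded nodes are the pacemaker and the
#'   observed strand cell, in that order.
#' @export
simulate_star <- function(pacer, excitable, n_strands, d, duration,
                          dt = 0.01, scheme = "fe", cells_per_strand = 20,
                          observe = 16, field = NULL, ...) {
  op <- build_star(n_strands, cells_per_strand, d)
  if (is.null(field)) {
    labels <- ifelse(op$labels == "pacemaker", "pacer", "strand")
    field <- cell_field(list(pacer = pacer, strand = excitable),
                        labels = labels)
  }
  stopifnot(field$n == op$n, observe >= 1, observe <= cells_per_strand)
  simulate_field(field, op, duration = duration,
                 spec = integrator_spec(scheme, dt),
                 record = c(1L, 1L + as.integer(observe)), ...)
}

#' Pacemaker-follower synchronization ratio
#'
#' Counts upward mid-level crossings of the pacemaker and of the observed
#' strand cell after settling and reports the follower:pacemaker frequency
#' ratio.  Complete 1:1 synchronization is declared when the ratio differs
#' from one by less than the resolution of the count
#' (`|ratio - 1| < 1/n_pacer_cycles`).  A quiescent pacemaker is an error;
#' a quiescent follower yields ratio 0.
#'
#' @param sim a `pc_sim` from [simulate_star()] (pacemaker and follower
#'   recorded).
#' @param settle transient discarded before counting (ms).
#' @return A list (`sync_measure`) with `ratio`, `n_pacer`, `n_follower`,
#'   `sync_11`, and the pacemaker frequency `f_pacer` (Hz).
#' @export
measure_sync <- function(sim, settle = 10000) {
  tr <- sim$trace
  stopifnot(!is.null(tr), ncol(tr$u) >= 2)
  time <- as.numeric(tr$time)
  keep <- time >= settle
  tp <- time[keep]; up <- tr$u[keep, 1]; uf <- tr$u[keep, 2]
  if (diff(range(up)) < 1e-8)
    stop("pacemaker is quiescent; synchronization undefined")
  crp <- crossing_times(tp, up, mid_level(up))
  np <- length(crp) - 1
  if (np < 1) stop("pacemaker completed no full cycle after settling")
  nf <- if (diff(range(uf)) < 1e-8) 0L
        else max(0L, length(crossing_times(tp, uf, mid_level(uf))) - 1L)
  ratio <- nf / np
  structure(list(ratio = ratio, n_pacer = np, n_follower = nf,
                 sync_11 = abs(ratio - 1) < 1 / np,
                 f_pacer = 1000 * np / (crp[np + 1] - crp[1])),
            class = "sync_measure")
}

# is the star system 1:1 synchronized at control-parameter value b?
sync_at_b <- function(pacer, excitable, n_strands, d, b, duration, settle,
                      dt = 0.01, cells_per_strand = 20, scheme = "fe") {
  pac <- modify_params(pacer, list(b = b))
  s <- tryCatch(
    simulate_star(pac, excitable, n_strands, d, duration, dt = dt,
                  scheme = scheme, cells_per_strand = cells_per_strand,
                  sample_dt = max(dt, 0.5)),
    error = function(e) NULL)
  if (is.null(s)) return(list(ok = FALSE, f = NA_real_))
  m <- tryCatch(measure_sync(s, settle = settle), error = function(e) NULL)
  if (is.null(m)) return(list(ok = FALSE, f = NA_real_))
  list(ok = isTRUE(m$sync_11), f = m$f_pacer)
}

#' Scan the 1:1 synchronization limits over the control parameter
#'
#' For each coupling coefficient `d`, samples the control parameter `b` of
#' the pacemaker on a coarse grid, identifies the maximal runs of complete
#' 1:1 synchronization (which may be disjoint), and refines each run
#' boundary by bisection.  Reports the `b` interval(s) and the pacemaker
#' frequency at each boundary, giving the minimal and maximal fully
#' synchronized frequency per coupling value.
#'
#' @inheritParams simulate_star
#' @param d_values coupling coefficients to scan (per ms).
#' @param b_range length-2 range of the control parameter.
#' @param n_coarse coarse-grid resolution over `b_range` (default 13).
#' @param tol_b bisection tolerance on the region boundaries.
#' @param duration,settle per-simulation length and settling time (ms).
#' @return A `sync_scan` data.frame: one row per (d, region) with columns
#'   `d`, `region`, `b_lo`, `b_hi`, `f_lo`, `f_hi`; zero rows for `d`
#'   values with no synchronized `b`.
#' @export
scan_sync_limits <- function(pacer, excitable, n_strands, d_values,
                             b_range, n_coarse = 13, tol_b = 1e-3,
                             duration = 30000, settle = 10000, dt = 0.01,
                             cells_per_strand = 20, scheme = "fe") {
  rows <- list()
  bgrid <- seq(b_range[1], b_range[2], length.out = n_coarse)
  for (d in d_values) {
    probe <- lapply(bgrid, function(b)
      sync_at_b(pacer, excitable, n_strands, d, b, duration, settle,
                dt, cells_per_strand, scheme))
    ok <- vapply(probe, `[[`, logical(1), "ok")
    r <- rle(ok)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    reg <- 0L
    for (k in seq_along(r$values)) {
      if (!r$values[k]) next
      reg <- reg + 1L
      i_lo <- starts[k]; i_hi <- ends[k]
      # refine lower boundary between bgrid[i_lo - 1] (out) and bgrid[i_lo]
      b_lo <- bgrid[i_lo]; f_lo <- probe[[i_lo]]$f
      if (i_lo > 1) {
        lo <- bgrid[i_lo - 1]; hi <- bgrid[i_lo]
        while (hi - lo > tol_b) {
          mid <- (lo + hi) / 2
          pm <- sync_at_b(pacer, excitable, n_strands, d, mid, duration,
                          settle, dt, cells_per_strand, scheme)
          if (pm$ok) { hi <- mid; b_lo <- mid; f_lo <- pm$f } else lo <- mid
        }
      }
      b_hi <- bgrid[i_hi]; f_hi <- probe[[i_hi]]$f
      if (i_hi < length(bgrid)) {
        lo <- bgrid[i_hi]; hi <- bgrid[i_hi + 1]
        while (hi - lo > tol_b) {
          mid <- (lo + hi) / 2
          pm <- sync_at_b(pacer, excitable, n_strands, d, mid, duration,
                          settle, dt, cells_per_strand, scheme)
          if (pm$ok) { lo <- mid; b_hi <- mid; f_hi <- pm$f } else hi <- mid
        }
      }
      rows[[length(rows) + 1]] <-
        data.frame(d = d, region = reg, b_lo = b_lo, b_hi = b_hi,
                   f_lo = f_lo, f_hi = f_hi)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(d = numeric(0), region = integer(0),
                         b_lo = numeric(0), b_hi = numeric(0),
                         f_lo = numeric(0), f_hi = numeric(0))
  class(out) <- c("sync_scan", class(out))
  out
}

#' Pacemaker and follower frequency versus coupling at fixed b
#'
#' The fixed-intrinsic-frequency protocol: with the pacemaker's control
#' parameter held constant, the coupling coefficient is swept and the
#' pacemaker and 16th-cell frequencies recorded.  The field state is
#' carried over between consecutive coupling values so that hysteresis
#' (observed for light loads when sweeping in opposite directions) can be
#' probed by running the scan `direction = "up"` and `"down"`.
#'
#' @inheritParams scan_sync_limits
#' @param b fixed control-parameter value.
#' @param d_values coupling grid (scanned in the order implied by
#'   `direction`).
#' @param direction `"up"` scans `d_values` ascending, `"down"` descending.
#' @return A data.frame with `d`, `f_pacer`, `f_follower`, `ratio`,
#'   `sync_11`.
#' @export
sync_vs_coupling <- function(pacer, excitable, n_strands, b, d_values,
                             duration = 30000, settle = 10000, dt = 0.01,
                             cells_per_strand = 20, scheme = "fe",
                             direction = c("up", "down")) {
  direction <- match.arg(direction)
  d_values <- sort(d_values, decreasing = direction == "down")
  pac <- modify_params(pacer, list(b = b))
  field <- NULL
  rows <- list()
  for (d in d_values) {
    s <- simulate_star(pac, excitable, n_strands, d, duration, dt = dt,
                       scheme = scheme, cells_per_strand = cells_per_strand,
                       sample_dt = max(dt, 0.5), field = field)
    field <- s$field
    m <- tryCatch(measure_sync(s, settle = settle), error = function(e) NULL)
    rows[[length(rows) + 1]] <- data.frame(
      d = d,
      f_pacer = if (is.null(m)) NA_real_ else m$f_pacer,
      f_follower = if (is.null(m)) NA_real_ else m$f_pacer * m$ratio,
      ratio = if (is.null(m)) NA_real_ else m$ratio,
      sync_11 = if (is.null(m)) NA else m$sync_11)
  }
  do.call(rbind, rows)
}
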