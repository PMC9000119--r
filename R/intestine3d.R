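#' Excitability gradient of the intestinal pacemaker layer
#'
#' Exponential longitudinal distribution of the ICC control parameter,
#' `b_CN(i) = base + amp * exp(-i dx / lambda)` with `i` the 0-based cell
#' index counted from the duodenal end.  With the default constants the
#' proximal end has `b_CN = 1.70` and 1200 mm down the gut
#' `b_CN = 0.62` (2 d.p.), producing an intrinsic pacemaker-frequency
#' gradient of roughly 17.5 down to 10.5 counts per minute over the
#' simulated half of the small intestine.
#'
#' @param i 0-based cell index (vectorized).
#' @param dx longitudinal spacing (mm, default 0.25).
#' @param base asymptotic value (default 0.4).
#' @param amp gradient amplitude (default 1.3).
#' @param lambda decay length (mm, default 680).
#' @return Numeric vector of `b_CN` values.
#' @examples
#' bcn_gradient(0)                  # proximal end: 1.70
#' bcn_gradient(4800, dx = 0.25)    # 1200 mm: 0.62
#' @export
bcn_gradient <- function(i, dx = 0.25, base = 0.4, amp = 1.3,
                         lambda = 680) {
  stopifnot(all(i >= 0))
  base + amp * exp(-i * dx / lambda)
}

# two-node ICC-SMC coupling operator (interlayer conductance only)
pair_operator <- function(d_im = 6e-3) {
  W <- Matrix::sparseMatrix(i = c(1, 1, 2, 2), j = c(2, 1, 1, 2),
                            x = c(d_im, -d_im, d_im, -d_im),
                            dims = c(2, 2))
  new_coupling_operator(W, c("layer1", "layer2"), list(kind = "pair"))
}

#' Intrinsic frequency of a decoupled ICC-SMC pair
#'
#' Simulates a single interstitial-cell-of-Cajal / smooth-muscle-cell
#' pair (no intra-layer diffusion, inter-layer coupling `d_im`) with the
#' ICC excitability set by [bcn_gradient()] at longitudinal position `y`,
#' and returns its oscillation frequency in counts per minute.  This is
#' the solid intrinsic-frequency curve against which the entrained
#' profile of the full model is compared.
#'
#' @param y longitudinal position (mm, in `[0, lambda * ...]`); may be a
#'   vector.
#' @param d_im inter-layer coupling (per ms, default 6e-3).
#' @param dt time step (ms, default 2.5).
#' @param duration simulated time (ms, default 1.2e6 = 1200 s).
#' @param settle transient discarded (ms, default 3e5 = 300 s).
#' @param icc,smc layer parameter sets (defaults: presets `pCN-ICC`,
#'   `CN-SMC`).
#' @param lambda gradient decay length passed to [bcn_gradient()]
#'   (mm).
#' @param scheme integrator scheme.
#' @return Numeric vector of frequencies (cpm); `NA` where the pair is
#'   quiescent.
#' @export
pair_intrinsic_frequency <- function(y, d_im = 6e-3, dt = 2.5,
                                     duration = 1.2e6, settle = 3e5,
                                     icc = cell_preset("pCN-ICC"),
                                     smc = cell_preset("CN-SMC"),
                                     lambda = 680, scheme = "fe") {
  op <- pair_operator(d_im)
  vapply(y, function(yy) {
    b <- bcn_gradient(yy, dx = 1, lambda = lambda)
    field <- cell_field(list(layer1 = modify_params(icc, list(b = b)),
                             layer2 = smc),
                        labels = c("layer1", "layer2"))
    s <- simulate_field(field, op, duration = duration,
                        spec = integrator_spec(scheme, dt),
                        record = 1, sample_dt = dt)
    f <- trace_frequency(s$trace$time, s$trace$u[, 1], settle = settle)
    if (is.na(f)) NA_real_ else 60 * f
  }, numeric(1))
}

#' Assemble a dual-layer intestine experiment
#'
#' Cylindrical two-layer sheet (see [build_cylinder()]) with a pacemaking
#' ICC layer carrying the longitudinal excitability gradient of
#' [bcn_gradient()] and an excitable SMC layer, coupled pointwise.  The
#' full-scale geometry is 176 x 4800 nodes at 0.25 mm (44 mm
#' circumference, 1200 mm length); `intestine_experiment()` defaults to a
#' desk-scale variant with the lengths and gradient decay divided by
#' `scale` (default 10) and a narrower circumference, which preserves the
#' frequency range and plateau phenomenology.
#'
#' @param scale length divisor (1 = full scale).
#' @param nx circumferential nodes (default 16 scaled, 176 at
#'   `scale = 1`).
#' @param ny longitudinal nodes (default `4800 / scale`).
#' @param dx spacing (mm, default 0.25).
#' @param D1,D2 intra-layer diffusion (mm^2/ms; ICC 5e-5, SMC 8e-4).
#' @param d_im inter-layer coupling (per ms, default 6e-3).
#' @param lambda gradient decay length (mm, default `680 / scale`).
#' @param dt time step (ms, default 2.5).
#' @param icc,smc parameter sets.
#' @param periodic periodic axis of the seam (default circumferential
#'   `"x"`).
#' @return An `intestine_experiment` list.
#' @export
intestine_experiment <- function(scale = 10,
                                 nx = if (scale == 1) 176L else 16L,
                                 ny = as.integer(round(4800 / scale)),
                                 dx = 0.25, D1 = 5e-5, D2 = 8e-4,
                                 d_im = 6e-3, lambda = 680 / scale,
                                 dt = 2.5,
                                 icc = cell_preset("pCN-ICC"),
                                 smc = cell_preset("CN-SMC"),
                                 periodic = "x") {
  op <- build_cylinder(nx = nx, ny = ny, dx = dx, D1 = D1, D2 = D2,
                       d_im = d_im, periodic = periodic)
  N <- nx * ny
  iy <- rep(seq_len(ny) - 1L, each = nx)        # 0-based row index
  b <- c(0.4 + 1.3 * exp(-(iy * dx) / lambda),  # ICC layer gradient
         rep(NA_real_, N))                      # SMC keeps its preset b
  field <- cell_field(list(layer1 = icc, layer2 = smc),
                      labels = op$labels, b = b)
  structure(list(op = op, field = field, nx = nx, ny = ny, dx = dx,
                 lambda = lambda, dt = dt, d_im = d_im, scale = scale),
            class = "intestine_experiment")
}

#' Conduction-block node set and state reset
#'
#' `block_nodes()` lists the nodes (both layers) of an intestine
#' experiment inside the block rectangle; `apply_conduction_block()`
#' resets their state to `(u, h) = (0.001, 0.5)` in place, as done for
#' one time step to trigger dysrhythmia.  [run_intestine()] applies the
#' block inside the stepping loop via its `block_time` argument; this
#' function is the standalone equivalent.
#'
#' @param exp an [intestine_experiment()].
#' @param x0,lx circumferential origin and height of the rectangle (mm;
#'   defaults 0 and 22).
#' @param y0,ly longitudinal origin and width (mm; full-scale defaults
#'   580 and 40, divided by the experiment's scale).
#' @return `block_nodes()`: integer node indices (both layers);
#'   `apply_conduction_block()`: the modified `cell_field`.
#' @export
block_nodes <- function(exp, x0 = 0, lx = 22, y0 = 580 / exp$scale,
                        ly = 40 / exp$scale) {
  nx <- exp$nx; ny <- exp$ny; dx <- exp$dx
  x <- ((seq_len(nx) - 1L) * dx)
  y <- ((seq_len(ny) - 1L) * dx)
  inx <- which(x >= x0 & x <= x0 + lx)
  iny <- which(y >= y0 & y <= y0 + ly)
  if (!length(inx) || !length(iny)) return(integer(0))
  base <- as.vector(outer(inx, (iny - 1L) * nx, `+`))
  c(base, exp$nx * exp$ny + base)
}

#' @rdname block_nodes
#' @param field the `cell_field` to modify (default the experiment's).
#' @param u,w reset values (defaults 0.001 and 0.5).
#' @export
apply_conduction_block <- function(exp, field = exp$field, x0 = 0,
                                   lx = 22, y0 = 580 / exp$scale,
                                   ly = 40 / exp$scale,
                                   u = 0.001, w = 0.5) {
  nodes <- block_nodes(exp, x0, lx, y0, ly)
  field$u[nodes] <- u
  field$w[nodes] <- w
  field
}

#' Run the intestine experiment
#'
#' Simulates the dual-layer sheet, estimates the per-position frequency
#' of the ICC layer along the mid-circumference line from cycle counts
#' over the final `freq_window` ms, and segments the profile into
#' constant-frequency plateaus (maximal longitudinal intervals over which
#' the frequency varies by less than `plateau_tol` cpm).  An optional
#' transient conduction block is applied at `block_time` (one step long,
#' both layers).
#'
#' @param exp an [intestine_experiment()].
#' @param duration simulated time (ms).
#' @param freq_window counting-window length (ms, default 6e5 = 600 s,
#'   giving 0.1 cpm resolution).
#' @param block_time time of the conduction block (ms) or `NULL`; the
#'   published protocol uses 8.1e6 ms (with 5.1e6 ms as a config
#'   alternative).
#' @param block block geometry overrides passed to [block_nodes()]
#'   (list with `x0`, `lx`, `y0`, `ly`).
#' @param plateau_tol plateau flatness tolerance (cpm, default 0.1).
#' @param scheme integrator scheme.
#' @param record_y longitudinal positions (mm) whose ICC/SMC traces are
#'   recorded (default none).
#' @param snapshot_times optional full-field snapshot times (ms).
#' @return An `intestine_run` list: `y` (mm), `freq_cpm` (entrained ICC
#'   profile), `counts_icc`, `counts_smc` (mid-circumference), `plateaus`
#'   (data.frame `y_lo`, `y_hi`, `freq`, `n`), `sim`, `exp`.
#' @export
run_intestine <- function(exp, duration, freq_window = 6e5,
                          block_time = NULL, block = list(),
                          plateau_tol = 0.1, scheme = "fe",
                          record_y = NULL, snapshot_times = NULL) {
  stopifnot(inherits(exp, "intestine_experiment"),
            duration > freq_window)
  nx <- exp$nx; ny <- exp$ny; N <- nx * ny
  midx <- max(1L, nx %/% 2L)
  mid_line <- (seq_len(ny) - 1L) * nx + midx
  record <- integer(0)
  if (!is.null(record_y)) {
    iy <- pmin(ny, pmax(1L, as.integer(round(record_y / exp$dx)) + 1L))
    record <- c((iy - 1L) * nx + midx, N + (iy - 1L) * nx + midx)
  }
  blk <- NULL
  if (!is.null(block_time)) {
    nodes <- do.call(block_nodes, c(list(exp), block))
    blk <- list(time = block_time, nodes = nodes, u = 0.001, w = 0.5)
  }
  sim <- simulate_field(exp$field, exp$op, duration = duration,
                        spec = integrator_spec(scheme, exp$dt),
                        record = record, sample_dt = exp$dt * 10,
                        count_window = c(duration - freq_window, duration),
                        threshold = 0.5, snapshot_times = snapshot_times,
                        block = blk)
  counts_icc <- sim$counts[mid_line]
  counts_smc <- sim$counts[N + mid_line]
  window_min <- freq_window / 60000
  freq <- counts_icc / window_min
  y <- (seq_len(ny) - 1L) * exp$dx
  plateaus <- segment_plateaus(y, freq, tol = plateau_tol)
  structure(list(y = y, freq_cpm = freq, counts_icc = counts_icc,
                 counts_smc = counts_smc, plateaus = plateaus,
                 sim = sim, exp = exp),
            class = "intestine_run")
}

# maximal y-intervals over which freq varies by less than tol
segment_plateaus <- function(y, freq, tol = 0.1) {
  n <- length(freq)
  out <- list()
  start <- 1L
  fmin <- fmax <- freq[1]
  for (k in 2:n) {
    nmin <- min(fmin, freq[k]); nmax <- max(fmax, freq[k])
    if (nmax - nmin < tol) {
      fmin <- nmin; fmax <- nmax
    } else {
      out[[length(out) + 1]] <- c(start, k - 1L)
      start <- k; fmin <- fmax <- freq[k]
    }
  }
  out[[length(out) + 1]] <- c(start, n)
  do.call(rbind, lapply(out, function(seg) {
    data.frame(y_lo = y[seg[1]], y_hi = y[seg[2]],
               freq = mean(freq[seg[1]:seg[2]]),
               n = seg[2] - seg[1] + 1L)
  }))
}

#' @export
print.intestine_run <- function(x, ...) {
  big <- x$plateaus[x$plateaus$n >= 5, , drop = FALSE]
  cat(sprintf(paste0("<intestine_run> %d x %d nodes/layer; entrained ",
                     "profile %.1f-%.1f cpm, %d plateau segment(s)\n"),
              x$exp$nx, x$exp$ny, max(x$freq_cpm), min(x$freq_cpm),
              nrow(big)))
  invisible(x)
}
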