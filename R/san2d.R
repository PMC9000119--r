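#' Sinoatrial-node tissue geometry
#'
#' Region mask for the 2D SAN experiments: a square sheet of atrial tissue
#' with a central elliptical pacemaker region (half-axes `half_axes` mm,
#' long axis rotated `angle` degrees off the fiber/`y` direction).  The
#' type-2 structure adds a ring of passive tissue of thickness `border` mm
#' around the ellipse, pierced by four symmetric exit pathways of width
#' `pathway_width` mm centered on the ellipse axes.
#'
#' @param nx,ny mesh size.
#' @param dx spatial step (mm).
#' @param type structure type: 1 (bare ellipse, anisotropic tissue) or
#'   2 (insulating border with exit pathways, isotropic tissue).
#' @param half_axes ellipse half-axes (mm), long first.
#' @param angle rotation of the long axis from the y axis (degrees).
#' @param border passive ring thickness (mm, type 2).
#' @param pathway_width exit pathway width (mm, type 2).
#' @return Character matrix (`nx` x `ny`) with entries `"san"`,
#'   `"atrium"`, and for type 2 `"passive"` and `"pathway"`.
#' @export
san_mask <- function(nx = 200, ny = 200, dx = 0.05, type = 1,
                     half_axes = c(3, 1), angle = 30, border = 0.25,
                     pathway_width = 1) {
  stopifnot(type %in% c(1, 2))
  cx <- (nx - 1) / 2 * dx; cy <- (ny - 1) / 2 * dx
  th <- angle * pi / 180
  e1 <- c(sin(th), cos(th))          # long axis, `angle` off the y axis
  e2 <- c(cos(th), -sin(th))
  x <- ((seq_len(nx) - 1) * dx) - cx
  y <- ((seq_len(ny) - 1) * dx) - cy
  X <- matrix(x, nx, ny); Y <- matrix(y, nx, ny, byrow = TRUE)
  xi <- X * e1[1] + Y * e1[2]
  eta <- X * e2[1] + Y * e2[2]
  a <- half_axes[1]; b <- half_axes[2]
  r_in <- (xi / a)^2 + (eta / b)^2
  mask <- matrix("atrium", nx, ny)
  mask[r_in <= 1] <- "san"
  if (type == 2) {
    r_out <- (xi / (a + border))^2 + (eta / (b + border))^2
    ring <- r_in > 1 & r_out <= 1
    mask[ring] <- "passive"
    hw <- pathway_width / 2
    path <- ring & ((abs(eta) <= hw) | (abs(xi) <= hw))
    mask[path] <- "pathway"
  }
  mask
}

#' Assemble a 2D SAN experiment
#'
#' Builds the grid, region mask, coupling operator, cell field and
#' integrator settings of one sinoatrial-node run.
#'
#' Type 1: pacemaker ellipse of pAP cells embedded directly in AP atrial
#' tissue; the whole sheet is anisotropic with `Dy:Dx = 1:0.208` and a
#' single diffusion level `D` (= `Dy`), studied at 0.090 (strong coupling,
#' 1:1 entrainment) and 0.048 mm^2/ms (weak coupling, partial exit block).
#'
#' Type 2: isotropic tissue, atrial diffusion fixed at `D_A = 0.160`;
#' the ellipse is surrounded by a passive border with four exit pathways,
#' and the SAN/pathway diffusion `D` is studied at 0.060 and 0.052.
#' Pathways carry the SAN cell parameters and diffusion.
#'
#' The `scale` argument coarsens the mesh for desk-scale runs: the node
#' count per axis is divided by `scale`, `dx` multiplied by it, and the
#' default time step multiplied by `scale^2` (keeping the stability margin
#' unchanged).
#'
#' @param type structure type 1 or 2.
#' @param D SAN-level diffusion coefficient (mm^2/ms): `Dy` for type 1,
#'   `D_S` for type 2.
#' @param D_atrium atrial diffusion for type 2 (default 0.160).
#' @param anisotropy `Dx/Dy` ratio for type 1 (default 0.208).
#' @param scale mesh coarsening factor (1 = full 200 x 200).
#' @param dt time step (ms); default `0.002 * scale^2`.
#' @param pacer,atrium,passive parameter sets; defaults are the SAN
#'   presets (`pAP-SAN1`/`pAP-SAN2`, `AP-atrium`, `passive`).
#' @param ... passed to [san_mask()] (geometry overrides).
#' @return A `san_experiment` list with `mask`, `op`, `field`, `dt`,
#'   `nx`, `ny`, `dx`, `type`, `D`.
#' @export
san_experiment <- function(type = 1, D = 0.090, D_atrium = 0.160,
                           anisotropy = 0.208, scale = 1,
                           dt = 0.002 * scale^2,
                           pacer = NULL, atrium = NULL, passive = NULL,
                           ...) {
  stopifnot(type %in% c(1, 2), scale >= 1)
  nx <- ny <- as.integer(round(200 / scale))
  dx <- 0.05 * scale
  mask <- san_mask(nx, ny, dx, type = type, ...)
  if (is.null(pacer))
    pacer <- cell_preset(if (type == 1) "pAP-SAN1" else "pAP-SAN2")
  if (is.null(atrium)) atrium <- cell_preset("AP-atrium")
  if (is.null(passive)) passive <- cell_preset("passive")
  regions <- sort(unique(as.character(mask)))
  if (type == 1) {
    Dy <- c(san = D, atrium = D)
    Dx <- anisotropy * Dy
  } else {
    Dy <- c(san = D, pathway = D, passive = D, atrium = D_atrium)
    Dy <- Dy[regions]
    Dx <- Dy
  }
  op <- build_grid2d(mask, Dx = Dx, Dy = Dy, dx = dx)
  params <- list(san = pacer, pathway = pacer, atrium = atrium,
                 passive = passive)[regions]
  field <- cell_field(params, labels = as.character(mask))
  structure(list(type = type, D = D, mask = mask, op = op, field = field,
                 dt = dt, nx = nx, ny = ny, dx = dx),
            class = "san_experiment")
}

# nodes of the line through the ellipse center along its long axis,
# extended to the domain boundary
san_center_line <- function(nx, ny, dx, angle = 30) {
  cx <- (nx - 1) / 2; cy <- (ny - 1) / 2
  th <- angle * pi / 180
  e1 <- c(sin(th), cos(th))
  smax <- sqrt(nx^2 + ny^2)
  s <- seq(-smax, smax, by = 0.5)
  ix <- round(cx + s * e1[1]) + 1L
  iy <- round(cy + s * e1[2]) + 1L
  ok <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
  unique((iy[ok] - 1L) * nx + ix[ok])
}

#' Run a 2D SAN experiment
#'
#' Simulates the assembled experiment from the standard initial conditions
#' (`u = v = 0.01`), counting per-node cycles (upward crossings of
#' `u = 0.5`) over `rate_window`, recording the potential along the line
#' through the SAN long axis, tracking first activation times over
#' `act_window`, and optionally storing full-field snapshots.
#'
#' The SAN-atrium entrainment regime is summarized by the median cycle
#' count in each region: `ratio` is atrial:SAN (1 for full 1:1
#' entrainment, e.g. 2/5 for a 2:5 exit block) and `rate_cpm` converts
#' the atrial count to cycles per minute.
#'
#' @param exp a [san_experiment()].
#' @param duration simulated time (ms, default 4000).
#' @param rate_window window for cycle counting (ms; default the final
#'   2000 ms).
#' @param act_window window for the activation map (ms; default the whole
#'   run, i.e. the map of the first propagated beat — a window opening
#'   mid-cycle would assign different beats to different nodes).
#' @param scheme `"fe"` (default; the Table-2 step sizes satisfy the
#'   stability bound) or `"be"`.
#' @param snapshot_times optional times for full-field snapshots.
#' @param sample_dt line-trace sampling interval (ms).
#' @return A `san_run` list: `sim`, `rate_cpm`, `ratio`, `counts_san`,
#'   `counts_atrium`, `line_nodes`, `exp`.
#' @export
run_san <- function(exp, duration = 4000,
                    rate_window = c(duration - 2000, duration),
                    act_window = c(0, duration),
                    scheme = "fe", snapshot_times = NULL, sample_dt = 1) {
  stopifnot(inherits(exp, "san_experiment"))
  line <- san_center_line(exp$nx, exp$ny, exp$dx)
  sim <- simulate_field(exp$field, exp$op, duration = duration,
                        spec = integrator_spec(scheme, exp$dt),
                        record = line, sample_dt = sample_dt,
                        count_window = rate_window,
                        act_window = act_window, threshold = 0.5,
                        snapshot_times = snapshot_times)
  lab <- as.character(exp$mask)
  cs <- stats::median(sim$counts[lab == "san"])
  ca <- stats::median(sim$counts[lab == "atrium"])
  window_min <- diff(rate_window) / 60000
  structure(list(sim = sim, exp = exp,
                 counts_san = cs, counts_atrium = ca,
                 ratio = if (cs > 0) ca / cs else NA_real_,
                 rate_cpm = ca / window_min,
                 san_rate_cpm = cs / window_min,
                 line_nodes = line),
            class = "san_run")
}

#' @export
print.san_run <- function(x, ...) {
  cat(sprintf(paste0("<san_run> type %d, D = %g: atrial rate %.1f cpm, ",
                     "SAN rate %.1f cpm, atrial:SAN ratio %.3g\n"),
              x$exp$type, x$exp$D, x$rate_cpm, x$san_rate_cpm, x$ratio))
  invisible(x)
}

#' Activation-sequence map
#'
#' Per-node activation times (first upward crossing of the threshold
#' within the activation window of a [run_san()] result), expressed
#' relative to the earliest activation.  Nodes that never activate
#' (e.g. the passive border) are `NA`.
#'
#' @param run a `san_run`.
#' @return Numeric `nx` x `ny` matrix of activation delays (ms).
#' @export
activation_sequence <- function(run) {
  stopifnot(inherits(run, "san_run"))
  at <- run$sim$act_time
  if (all(is.na(at))) stop("no node activated within the activation window")
  m <- matrix(at - min(at, na.rm = TRUE), run$exp$nx, run$exp$ny)
  m
}
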