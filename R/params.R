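#' Aliev-Panfilov family parameters
#'
#' Parameter set for the Aliev-Panfilov (AP) two-variable cardiac model and
#' its pacemaking variant (pAP).  The conventional excitable model uses a
#' cubic source term `k u (u - a)(1 - u)`; the pacemaking variant replaces
#' the threshold `-a` in the potential equation by an independent control
#' parameter `b` (so `b = -a` recovers the conventional model), while the
#' recovery equation keeps `a`.  Positive `b` shifts the left branch of the
#' cubic nullcline into `u < 0`, moves an equilibrium onto the middle
#' branch, and the cell undergoes a Hopf bifurcation into spontaneous
#' oscillation; `b` then controls the intrinsic frequency.
#'
#' @param k current-magnitude coefficient (dimensionless, > 0).
#' @param a recovery-equation threshold (dimensionless).
#' @param eps0 baseline recovery rate (dimensionless, > 0).
#' @param mu1,mu2 recovery-rate shape parameters (dimensionless, `mu2` > 0).
#' @param b excitability / pacemaking control parameter in the potential
#'   equation.  Defaults to `-a` (conventional excitable AP cell).
#' @param ct time-scaling coefficient converting model time to milliseconds;
#'   fixed at 1/12.9 per ms unless explicitly overridden.
#' @return An object of class `"ap_params"`.
#' @seealso [cn_params()], [passive_params()], [cell_preset()]
#' @examples
#' p <- ap_params()            # conventional excitable AP cell
#' q <- ap_params(b = 0.03)    # pacemaking pAP cell
#' @export
ap_params <- function(k = 8, a = 0.13, eps0 = 0.002, mu1 = 0.2, mu2 = 0.3,
                      b = -a, ct = 1 / 12.9) {
  stopifnot(is.numeric(k), k > 0, is.numeric(mu2), mu2 > 0,
            is.numeric(eps0), eps0 > 0, is.numeric(ct), ct > 0)
  structure(list(k = k, a = a, eps0 = eps0, mu1 = mu1, mu2 = mu2,
                 b = b, ct = ct),
            class = c("ap_params", "cell_params"))
}

#' Corrado family parameters
#'
#' Parameter set for the Corrado variant of the Mitchell-Schaeffer
#' two-variable model (CN) and its pacemaking variant (pCN).  The gate
#' steady state is a Boltzmann sigmoid
#' `h_inf(u) = (1 - tanh((u - u_gate)/u_s))/2` with slope factor `u_s`,
#' and the gate time constant interpolates between `tau_open` and
#' `tau_close` through `h_inf`.  As in the AP family, the threshold
#' `-u_gate` in the potential equation is replaced by an independent
#' parameter `b` (`b = -u_gate` recovers the conventional excitable cubic).
#'
#' @param tau_in,tau_out,tau_open,tau_close time constants (ms, all > 0)
#'   shaping depolarization, repolarization, and gate recovery/closure.
#' @param u_s sigmoid slope factor (dimensionless voltage, > 0).  Small
#'   `u_s` approaches the Heaviside gate of the original piecewise model.
#' @param u_gate gate midpoint potential (dimensionless voltage).
#' @param b excitability / pacemaking control parameter; defaults to
#'   `-u_gate` (conventional excitable CN cell).
#' @param tau_scheme `"printed"` uses the published interpolation
#'   `tau = tau_open tau_close / (tau_open - h_inf (tau_close - tau_open))`
#'   (note `tau(h_inf = 0) = tau_close`); `"convex"` selects the plain
#'   convex blend `h_inf tau_open + (1 - h_inf) tau_close` instead.
#' @return An object of class `"cn_params"`.
#' @seealso [ap_params()], [cell_preset()]
#' @examples
#' cn_params(b = 0.3)   # pacemaking pCN cell
#' @export
cn_params <- function(tau_in = 0.3, tau_out = 6, tau_open = 120,
                      tau_close = 150, u_s = 0.15, u_gate = -0.05,
                      b = -u_gate, tau_scheme = c("printed", "convex")) {
  stopifnot(tau_in > 0, tau_out > 0, tau_open > 0, tau_close > 0, u_s > 0)
  tau_scheme <- match.arg(tau_scheme)
  structure(list(tau_in = tau_in, tau_out = tau_out, tau_open = tau_open,
                 tau_close = tau_close, u_s = u_s, u_gate = u_gate, b = b,
                 tau_scheme = tau_scheme),
            class = c("cn_params", "cell_params"))
}

#' Passive tissue parameters
#'
#' Non-excitable tissue with a linear leak `du/dt = -ct S u + I_ext`:
#' it conducts electrotonically but has no regenerative upstroke, so it
#' blocks active propagation.  Used for the insulating border of the
#' type-2 sinoatrial-node structure.
#'
#' @param S decay conductivity (dimensionless, > 0; default 26).
#' @param ct time-scaling coefficient (per ms).
#' @return An object of class `"passive_params"`.
#' @export
passive_params <- function(S = 26, ct = 1 / 12.9) {
  stopifnot(S > 0, ct > 0)
  structure(list(S = S, ct = ct),
            class = c("passive_params", "cell_params"))
}

#' Named parameter presets
#'
#' Returns the parameter set used in the isolated-cell (0D), strand (1D),
#' sinoatrial node (SAN) and intestine experiments.  Range-valued entries
#' (the control parameter `b` for the 0D/1D presets) default to a
#' representative value inside the published range; sweeps supply their own
#' grid.  Some published tissue rows print only the entries that differ
#' from the row above; those presets adopt the inherit-from-row-above
#' reading and every field can be overridden through `...`.
#'
#' Available presets:
#' \describe{
#'   \item{`pAP-0D`, `pAP-1D`, `AP-1D`}{AP family, isolated cell and strand
#'     cells (`k` = 8, `a` = 0.13, `eps0` = 0.002, `mu1` = 0.2,
#'     `mu2` = 0.3); `b` ranges 0-0.08 (0D) and 0-0.5 (1D), conventional
#'     `b` = -0.13.}
#'   \item{`pAP-SAN1`, `pAP-SAN2`}{SAN pacemaker cells (`mu2` = 0.5;
#'     type 1: `b` = 0.120; type 2: `k` = 12, `b` = 0.133).}
#'   \item{`AP-atrium`}{excitable atrial tissue (`a` = 0.045,
#'     `mu2` = 0.3, `b` = -0.13).}
#'   \item{`pCN-0D`, `pCN-1D`, `CN-1D`}{CN family, `tau_in` = 0.3,
#'     `tau_out` = 6, `tau_open` = 120, `tau_close` = 150; pacemaking cells
#'     use a sloped gate (`u_s` = 0.15, `u_gate` = -0.05), the conventional
#'     cell a steep one (`u_s` = 0.01, `u_gate` = 0.13, `b` = -0.13).}
#'   \item{`pCN-ICC`, `CN-SMC`}{intestinal interstitial-cell-of-Cajal
#'     pacemaker (`tau_in` = 16, `tau_out` = 200, `tau_open` = 1500,
#'     `tau_close` = 1800, `u_s` = 0.2, `u_gate` = -0.05, `b` spatially
#'     graded 0.62-1.70) and smooth-muscle cell (`tau_in` = 11,
#'     `u_s` = 0.01, `u_gate` = 0.10, `b` = -0.10).}
#'   \item{`passive`}{passive border tissue, `S` = 26.}
#' }
#'
#' @param name preset name (see Details).
#' @param ... named field overrides, type-checked against the preset's
#'   fields.
#' @return A `cell_params` object with attribute `"preset"`.
#' @examples
#' cell_preset("pAP-0D", b = 0.05)
#' @export
cell_preset <- function(name, ...) {
  p <- switch(name,
    "pAP-0D"   = ap_params(b = 0.03),
    "pAP-1D"   = ap_params(b = 0.05),
    "AP-1D"    = ap_params(b = -0.13),
    "pAP-SAN1" = ap_params(mu2 = 0.5, b = 0.120),
    "pAP-SAN2" = ap_params(k = 12, mu2 = 0.5, b = 0.133),
    "AP-atrium" = ap_params(a = 0.045, mu2 = 0.3, b = -0.13),
    "pCN-0D"   = cn_params(u_s = 0.15, u_gate = -0.05, b = 0.3),
    "pCN-1D"   = cn_params(u_s = 0.15, u_gate = -0.05, b = 0.5),
    "CN-1D"    = cn_params(u_s = 0.01, u_gate = 0.13, b = -0.13),
    "pCN-ICC"  = cn_params(tau_in = 16, tau_out = 200, tau_open = 1500,
                           tau_close = 1800, u_s = 0.2, u_gate = -0.05,
                           b = 1.7),
    "CN-SMC"   = cn_params(tau_in = 11, tau_out = 200, tau_open = 1500,
                           tau_close = 1800, u_s = 0.01, u_gate = 0.10,
                           b = -0.10),
    "passive"  = passive_params(),
    stop("unknown preset: ", name)
  )
  p <- modify_params(p, list(...))
  attr(p, "preset") <- name
  p
}

#' List available parameter presets
#' @return Character vector of preset names accepted by [cell_preset()].
#' @export
preset_names <- function() {
  c("pAP-0D", "pAP-1D", "AP-1D", "pAP-SAN1", "pAP-SAN2", "AP-atrium",
    "pCN-0D", "pCN-1D", "CN-1D", "pCN-ICC", "CN-SMC", "passive")
}

# apply named overrides with field-name checking
modify_params <- function(p, overrides) {
  if (length(overrides) == 0) return(p)
  nm <- names(overrides)
  if (is.null(nm) || any(nm == ""))
    stop("parameter overrides must be named")
  bad <- setdiff(nm, names(unclass(p)))
  if (length(bad))
    stop("unknown parameter field(s): ", paste(bad, collapse = ", "))
  for (f in nm) {
    if (f != "tau_scheme" && !is.numeric(overrides[[f]]))
      stop("field '", f, "' must be numeric")
    p[[f]] <- overrides[[f]]
  }
  revalidate_params(p)
}

revalidate_params <- function(p) {
  if (inherits(p, "ap_params"))
    do.call(ap_params, unclass(p))
  else if (inherits(p, "cn_params"))
    do.call(cn_params, unclass(p))
  else
    do.call(passive_params, unclass(p))
}

#' @export
print.cell_params <- function(x, ...) {
  kind <- if (inherits(x, "ap_params")) "Aliev-Panfilov family"
          else if (inherits(x, "cn_params")) "Corrado family"
          else "passive tissue"
  preset <- attr(x, "preset")
  cat("<cell_params> ", kind,
      if (!is.null(preset)) paste0(" [preset ", preset, "]"), "\n", sep = "")
  flds <- unclass(x)
  for (f in names(flds)) cat("  ", f, " = ", format(flds[[f]]), "\n", sep = "")
  invisible(x)
}

#' Serialize / restore parameter sets
#'
#' Parameter sets round-trip through structured text (YAML) so that runs
#' can be configured from files.
#'
#' @param p a `cell_params` object.
#' @param path file path; for [params_to_yaml()] `NULL` returns the YAML
#'   string instead of writing.
#' @return [params_to_yaml()]: path or YAML string; [params_from_yaml()]:
#'   a `cell_params` object.
#' @export
params_to_yaml <- function(p, path = NULL) {
  stopifnot(inherits(p, "cell_params"))
  family <- if (inherits(p, "ap_params")) "ap"
            else if (inherits(p, "cn_params")) "cn" else "passive"
  txt <- yaml::as.yaml(c(list(family = family), unclass(p)))
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' @rdname params_to_yaml
#' @export
params_from_yaml <- function(path) {
  x <- if (file.exists(path)) yaml::read_yaml(path) else yaml::yaml.load(path)
  family <- x$family
  x$family <- NULL
  ctor <- switch(family, ap = ap_params, cn = cn_params,
                 passive = passive_params,
                 stop("unknown model family: ", family))
  do.call(ctor, x)
}

# internal: 7-column kernel parameter row + integer kind
params_row <- function(p) {
  if (inherits(p, "ap_params"))
    list(kind = 0L,
         row = c(p$k, p$a, p$eps0, p$mu1, p$mu2, p$b, p$ct))
  else if (inherits(p, "cn_params"))
    list(kind = 1L,
         row = c(p$tau_in, p$tau_out, p$tau_open, p$tau_close,
                 p$u_s, p$u_gate, p$b))
  else
    list(kind = 2L, row = c(p$S, p$ct, 0, 0, 0, 0, 0))
}

tau_scheme_code <- function(p) {
  if (inherits(p, "cn_params") && identical(p$tau_scheme, "convex")) 1L else 0L
}
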