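#' Multicell state field
#'
#' A `cell_field` holds, for every node of a topology, the model kind, the
#' kernel parameter row, and the current state `(u, w)` (where `w` is the
#' recovery variable `v` for the AP family and the gate `h` for the CN
#' family), plus the simulated time.
#'
#' @param params either a single `cell_params` object applied to all nodes,
#'   or a named list of `cell_params` keyed by the labels in `labels`.
#' @param n number of nodes (required when `labels` is `NULL`).
#' @param labels per-node region labels selecting the parameter set.
#' @param u0,w0 initial conditions.  Defaults follow the standard protocol:
#'   `u = 0.01` everywhere, `v = 0.01` for AP-family nodes, `h = 0.5` for
#'   CN-family nodes, `0` for passive nodes.
#' @param b per-node override of the control parameter `b` (numeric vector
#'   of length `n`), used e.g. for the spatial excitability gradient of the
#'   intestinal pacemaker layer.  `NA` entries keep the parameter set's
#'   value.
#' @return An object of class `cell_field`.
#' @examples
#' f <- cell_field(cell_preset("pAP-0D"), n = 1)
#' @export
cell_field <- function(params, n = NULL, labels = NULL,
                       u0 = 0.01, w0 = NULL, b = NULL) {
  if (inherits(params, "cell_params")) {
    if (is.null(n)) n <- length(labels)
    stopifnot(n >= 1)
    params <- list(all = params)
    labels <- rep("all", n)
  } else {
    stopifnot(is.list(params), !is.null(labels),
              all(labels %in% names(params)))
    n <- length(labels)
  }
  kind <- integer(n)
  pmat <- matrix(0, n, 7)
  schemes <- integer(0)
  for (lb in unique(labels)) {
    pr <- params_row(params[[lb]])
    sel <- labels == lb
    kind[sel] <- pr$kind
    pmat[sel, ] <- matrix(pr$row, sum(sel), 7, byrow = TRUE)
    if (pr$kind == 1L)
      schemes <- c(schemes, tau_scheme_code(params[[lb]]))
  }
  if (length(unique(schemes)) > 1)
    stop("all CN-family parameter sets in one field must share tau_scheme")
  if (!is.null(b)) {
    stopifnot(length(b) == n)
    repl <- !is.na(b)
    ap_sel <- repl & kind == 0L   # b is kernel column 6 for the AP family
    cn_sel <- repl & kind == 1L   # ... and column 7 for the CN family
    pmat[ap_sel, 6] <- b[ap_sel]
    pmat[cn_sel, 7] <- b[cn_sel]
  }
  u <- rep_len(u0, n)
  if (is.null(w0)) {
    w <- numeric(n)
    w[kind == 0L] <- 0.01
    w[kind == 1L] <- 0.5
  } else w <- rep_len(w0, n)
  structure(list(n = n, kind = kind, pmat = pmat,
                 tau_scheme = if (length(schemes)) schemes[1] else 0L,
                 labels = labels, u = u, w = w, t = 0),
            class = "cell_field")
}

#' @export
print.cell_field <- function(x, ...) {
  cat("<cell_field> ", x$n, " nodes at t = ", x$t, " ms\n", sep = "")
  cat("  kinds: ", paste0(c("AP", "CN", "passive")[sort(unique(x$kind)) + 1],
                          collapse = ", "), "\n", sep = "")
  invisible(x)
}
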