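#' Coupling operators
#'
#' A coupling operator is the discrete electrotonic-coupling structure of a
#' multicell experiment: a sparse matrix `W` (units 1/ms, i.e. entries are
#' `D/dx^2`) acting on the potential field, with zero row sums at interior
#' and no-flux boundary nodes so that a spatially constant field produces
#' no current, plus per-node region labels.  Constructors: [build_star()],
#' [build_grid2d()], [build_cylinder()].
#'
#' @param op a `coupling_operator`.
#' @param u numeric state vector of length `op$n`.
#' @return `apply_coupling()` returns the coupling current `W u` (per ms).
#' @name coupling_operator
NULL

new_coupling_operator <- function(W, labels, geometry = list()) {
  W <- as(as(W, "CsparseMatrix"), "generalMatrix")
  structure(c(list(n = nrow(W), W = W, labels = labels), geometry),
            class = "coupling_operator")
}

#' @rdname coupling_operator
#' @export
apply_coupling <- function(op, u) {
  stopifnot(inherits(op, "coupling_operator"), length(u) == op$n)
  as.numeric(op$W %*% u)
}

#' @export
print.coupling_operator <- function(x, ...) {
  cat("<coupling_operator> ", x$n, " nodes, ",
      length(x$W@x), " nonzeros\n", sep = "")
  if (!is.null(x$labels)) print(table(x$labels))
  invisible(x)
}

#' Star-coupled pacemaker-strand topology
#'
#' One pacemaker cell coupled to `n_strands` identical cables of
#' `cells_per_strand` excitable cells.  Interior strand cells are coupled
#' by the standard second difference `d (u[j-1] - 2 u[j] + u[j+1])`; the
#' far end of each strand is no-flux.  The load need not be an integer:
#' for non-integer `n_strands` a single representative strand is built and
#' the current it draws from the pacemaker is scaled by `n_strands`
#' (`I_p = n d (u1 - u_p)`).  For integer loads with identical strand
#' states this is exactly equivalent to explicit strands, and it extends
#' continuously to fractional loads such as 0.5; integer loads are built
#' as explicit strands.
#'
#' @param n_strands positive load multiplicity (may be fractional).
#' @param cells_per_strand cells per cable (default 20).
#' @param d coupling coefficient `D/dx^2` (per ms, >= 0).
#' @return A [coupling_operator] whose node 1 is the pacemaker; labels are
#'   `"pacemaker"` and `"strand<k>"`.
#' @examples
#' op <- build_star(1, 20, d = 1)
#' range(Matrix::rowSums(op$W))   # conservative: all zero
#' @export
build_star <- function(n_strands, cells_per_strand = 20, d) {
  stopifnot(n_strands > 0, cells_per_strand >= 2, d >= 0)
  L <- as.integer(cells_per_strand)
  explicit <- abs(n_strands - round(n_strands)) < 1e-12
  ns <- if (explicit) as.integer(round(n_strands)) else 1L
  n <- 1L + ns * L
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, x) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, x)
  }
  pscale <- if (explicit) 1 else n_strands
  for (s in seq_len(ns)) {
    base <- 1L + (s - 1L) * L
    first <- base + 1L
    # pacemaker <-> first cell
    add(1L, first, pscale * d); add(1L, 1L, -pscale * d)
    add(first, 1L, d); add(first, first, -d)
    for (j in seq_len(L)) {
      node <- base + j
      if (j > 1) { add(node, node - 1L, d); add(node, node, -d) }
      if (j < L) { add(node, node + 1L, d); add(node, node, -d) }
    }
  }
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  labels <- c("pacemaker",
              rep(paste0("strand", seq_len(ns)), each = L))
  new_coupling_operator(W, labels,
                        list(kind = "star", n_strands = n_strands,
                             cells_per_strand = L, d = d,
                             explicit = explicit))
}

# shared 5-point builder over an nx-by-ny grid (x fastest), arithmetic-mean
# face coefficients, optional periodic wrap in x and/or y (vectorized)
grid_edges <- function(nx, ny, dxco, dyco, dx, periodic_x = FALSE,
                       periodic_y = FALSE, offset = 0L) {
  idx <- function(ix, iy) (iy - 1L) * nx + ix   # local (offset-free) index
  a <- integer(0); b <- integer(0); w <- numeric(0)
  # x-direction faces
  if (nx > 1L) {
    g <- expand.grid(ix = seq_len(nx - 1L), iy = seq_len(ny))
    ea <- idx(g$ix, g$iy); eb <- ea + 1L
    a <- c(a, ea); b <- c(b, eb)
    w <- c(w, 0.5 * (dxco[ea] + dxco[eb]) / dx^2)
  }
  if (periodic_x && nx > 2L) {
    iy <- seq_len(ny)
    ea <- idx(nx, iy); eb <- idx(1L, iy)
    a <- c(a, ea); b <- c(b, eb)
    w <- c(w, 0.5 * (dxco[ea] + dxco[eb]) / dx^2)
  }
  # y-direction faces
  if (ny > 1L) {
    g <- expand.grid(ix = seq_len(nx), iy = seq_len(ny - 1L))
    ea <- idx(g$ix, g$iy); eb <- ea + nx
    a <- c(a, ea); b <- c(b, eb)
    w <- c(w, 0.5 * (dyco[ea] + dyco[eb]) / dx^2)
  }
  if (periodic_y && ny > 2L) {
    ix <- seq_len(nx)
    ea <- idx(ix, ny); eb <- ix
    a <- c(a, ea); b <- c(b, eb)
    w <- c(w, 0.5 * (dyco[ea] + dyco[eb]) / dx^2)
  }
  list(i = offset + c(a, a, b, b), j = offset + c(b, a, a, b),
       x = c(w, -w, w, -w))
}

#' 2D grid coupling operator with region masks and anisotropy
#'
#' Builds the 5-point finite-difference diffusion operator on an
#' `nx` by `ny` grid (spacing `dx` mm, node index `(iy - 1) nx + ix`,
#' x fastest).  Diffusion coefficients are assigned per region label and
#' may differ between the x and y axes (grid-aligned anisotropy).  At
#' heterogeneous interfaces the face coefficient is the arithmetic mean of
#' the two nodes' coefficients, which keeps the operator symmetric and
#' preserves the blocking behavior of passive borders.  The outer boundary
#' is no-flux.
#'
#' @param mask integer or character matrix (`nx` rows, `ny` columns) of
#'   region labels covering every node.
#' @param Dx,Dy named numeric vectors of diffusion coefficients
#'   (mm^2/ms, >= 0) per region label.
#' @param dx grid spacing (mm).
#' @return A [coupling_operator] with `nx`, `ny`, `dx` and per-node
#'   `labels` stored.
#' @examples
#' m <- matrix("tissue", 8, 8)
#' op <- build_grid2d(m, Dx = c(tissue = 0.1), Dy = c(tissue = 0.1),
#'                    dx = 0.05)
#' @export
build_grid2d <- function(mask, Dx, Dy, dx) {
  nx <- nrow(mask); ny <- ncol(mask)
  lab <- as.character(mask)
  stopifnot(all(lab %in% names(Dx)), all(lab %in% names(Dy)),
            all(Dx >= 0), all(Dy >= 0), dx > 0)
  dxco <- unname(Dx[lab]); dyco <- unname(Dy[lab])
  tr <- grid_edges(nx, ny, dxco, dyco, dx)
  W <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x,
                            dims = c(nx * ny, nx * ny))
  new_coupling_operator(W, lab,
                        list(kind = "grid2d", nx = nx, ny = ny, dx = dx))
}

#' Dual-layer cylindrical sheet operator
#'
#' Topology of the two-layer intestine model: a tube of circumference
#' `nx * dx` mm and length `ny * dx` mm, cut along its axis and unrolled
#' into two stacked planes (inner pacemaker layer and outer muscle layer).
#' Each layer carries its own isotropic 5-point diffusion operator;
#' the seam where the tube was cut is periodic (by default along the
#' circumferential x axis; `periodic` selects the axis), the tube ends are
#' no-flux.  The layers are coupled pointwise with coefficient `d_im`
#' (per ms): node `i` of layer 1 receives `d_im (u2[i] - u1[i])` and vice
#' versa.
#'
#' @param nx circumferential nodes (default 176).
#' @param ny longitudinal nodes (default 4800).
#' @param dx spacing (mm, default 0.25).
#' @param D1,D2 intra-layer diffusion coefficients (mm^2/ms) for the inner
#'   (ICC) and outer (SMC) layer.
#' @param d_im inter-layer coupling (per ms, default 6e-3).
#' @param periodic `"x"` (circumference, default) or `"y"`.
#' @return A [coupling_operator] over `2 nx ny` nodes; layer 1 occupies
#'   nodes `1:(nx ny)`.  Labels are `"layer1"` / `"layer2"`.
#' @export
build_cylinder <- function(nx = 176, ny = 4800, dx = 0.25,
                           D1 = 5e-5, D2 = 8e-4, d_im = 6e-3,
                           periodic = c("x", "y")) {
  periodic <- match.arg(periodic)
  stopifnot(nx >= 3, ny >= 2, dx > 0, D1 >= 0, D2 >= 0, d_im >= 0)
  N <- nx * ny
  t1 <- grid_edges(nx, ny, rep(D1, N), rep(D1, N), dx,
                   periodic_x = periodic == "x",
                   periodic_y = periodic == "y", offset = 0L)
  t2 <- grid_edges(nx, ny, rep(D2, N), rep(D2, N), dx,
                   periodic_x = periodic == "x",
                   periodic_y = periodic == "y", offset = N)
  k <- seq_len(N)
  ii <- c(t1$i, t2$i, k, k, N + k, N + k)
  jj <- c(t1$j, t2$j, N + k, k, k, N + k)
  xx <- c(t1$x, t2$x, rep(d_im, N), rep(-d_im, N),
          rep(d_im, N), rep(-d_im, N))
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(2 * N, 2 * N))
  labels <- rep(c("layer1", "layer2"), each = N)
  new_coupling_operator(W, labels,
                        list(kind = "cylinder", nx = nx, ny = ny, dx = dx,
                             d_im = d_im, periodic = periodic))
}
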