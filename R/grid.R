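#' Rectangular cell-centred simulation grid
#'
#' Builds an `nx` by `ny` cell-centred grid for the quarter domain, with node
#' coordinates `x_i = (i - 1/2) dx`, `y_j = (j - 1/2) dy`. All differential
#' operators use 5-point stencils with mirror (zero-flux) boundaries, which
#' realize the symmetry conditions on the two inner edges and isolate the
#' tissue on the outer edges. The constructor precomputes the orthonormal
#' discrete-cosine bases that diagonalize the mirror-boundary Laplacian, so
#' the implicit (Helmholtz and biharmonic) solves in the time steppers reduce
#' to two dense matrix products and a pointwise division.
#'
#' @param nx,ny Node counts in x and y.
#' @param width,height Domain extents in non-dimensional length units.
#'   Defaults are the quarter of a 2100 x 1620 tissue (2625 um x 2025 um at
#'   `L_scale = 1.25`).
#' @return A `sim_grid` object: node counts, spacings, coordinates, and the
#'   spectral factors (`Cx`, `Cy`, Laplacian eigenvalues `lam_x`, `lam_y` and
#'   their outer sum `lam_xy`).
#' @examples
#' g <- sim_grid(64, 48)
#' g$dx * g$nx == g$width
#' @export
sim_grid <- function(nx, ny, width = 1050, height = 810) {
  stopifnot(nx >= 4, ny >= 4, width > 0, height > 0)
  dx <- width / nx
  dy <- height / ny
  g <- list(nx = as.integer(nx), ny = as.integer(ny), dx = dx, dy = dy,
            width = width, height = height,
            x = (seq_len(nx) - 0.5) * dx, y = (seq_len(ny) - 0.5) * dy)
  g$Cx <- dct_matrix(nx)
  g$Cy <- dct_matrix(ny)
  g$lam_x <- -(4 / dx^2) * sin(pi * (seq_len(nx) - 1) / (2 * nx))^2
  g$lam_y <- -(4 / dy^2) * sin(pi * (seq_len(ny) - 1) / (2 * ny))^2
  g$lam_xy <- outer(g$lam_x, g$lam_y, `+`)
  class(g) <- "sim_grid"
  g
}

# Orthonormal DCT-II matrix: rows are the eigenvectors cos(pi*k*(j-1/2)/n) of
# the cell-centred Neumann Laplacian stencil.
dct_matrix <- function(n) {
  k <- seq_len(n) - 1
  j <- seq_len(n) - 0.5
  C <- cos(pi * outer(k, j) / n) * sqrt(2 / n)
  C[1, ] <- sqrt(1 / n)
  C
}

#' @export
print.sim_grid <- function(x, ...) {
  cat(sprintf("sim_grid: %d x %d nodes, %g x %g units (dx = %.3g, dy = %.3g)\n",
              x$nx, x$ny, x$width, x$height, x$dx, x$dy))
  invisible(x)
}

check_field <- function(field, grid) {
  if (!is.matrix(field) || nrow(field) != grid$nx || ncol(field) != grid$ny)
    stop("field must be an nx x ny matrix congruent with the grid")
  invisible(field)
}

#' Five-point Laplacian with mirror boundaries
#'
#' Second-order discrete Laplacian; ghost nodes are mirror reflections of the
#' first interior node, which imposes zero normal flux on every edge.
#'
#' @param field An `nx` by `ny` matrix.
#' @param grid A [sim_grid()].
#' @return Matrix of the same shape.
#' @export
laplacian <- function(field, grid) {
  check_field(field, grid)
  nx <- grid$nx; ny <- grid$ny
  xm <- field[c(1, seq_len(nx - 1)), , drop = FALSE]
  xp <- field[c(seq_len(nx - 1) + 1, nx), , drop = FALSE]
  ym <- field[, c(1, seq_len(ny - 1)), drop = FALSE]
  yp <- field[, c(seq_len(ny - 1) + 1, ny), drop = FALSE]
  (xm + xp - 2 * field) / grid$dx^2 + (ym + yp - 2 * field) / grid$dy^2
}

# Central-difference gradient components with mirror boundaries (normal
# component vanishes at the edges, consistent with zero flux).
gradient_x <- function(field, grid) {
  nx <- grid$nx
  xm <- field[c(1, seq_len(nx - 1)), , drop = FALSE]
  xp <- field[c(seq_len(nx - 1) + 1, nx), , drop = FALSE]
  (xp - xm) / (2 * grid$dx)
}

gradient_y <- function(field, grid) {
  ny <- grid$ny
  ym <- field[, c(1, seq_len(ny - 1)), drop = FALSE]
  yp <- field[, c(seq_len(ny - 1) + 1, ny), drop = FALSE]
  (yp - ym) / (2 * grid$dy)
}

# Forward/backward transforms between nodal and cosine-mode representation.
dct2 <- function(field, grid) grid$Cx %*% field %*% t(grid$Cy)
idct2 <- function(coef, grid) crossprod(grid$Cx, coef) %*% grid$Cy

# Solve (I - alpha * Lap) u = rhs exactly for the discrete mirror-boundary
# Laplacian (alpha >= 0), diagonal in the cosine basis.
solve_helmholtz <- function(rhs, alpha, grid) {
  idct2(dct2(rhs, grid) / (1 - alpha * grid$lam_xy), grid)
}

# Solve (I + a2 * Lap^2 - a1 * Lap) u = rhs (a1, a2 >= 0), used by the
# semi-implicit Cahn-Hilliard update.
solve_biharmonic <- function(rhs, a1, a2, grid) {
  den <- 1 + a2 * grid$lam_xy^2 - a1 * grid$lam_xy
  idct2(dct2(rhs, grid) / den, grid)
}

#' Bundle the four coupled fields into a simulation state
#'
#' @param phi Tumor phase field (values near `[0, 1]`).
#' @param sigma Nutrient field in `[0, 1]`.
#' @param c Capillary phase field (values near `[-1, 1]`).
#' @param f TAF field in `[0, 1]`.
#' @param t Current non-dimensional time.
#' @param grid The [sim_grid()] the fields live on.
#' @return A `field_state` object.
#' @export
field_state <- function(phi, sigma, c, f, t = 0, grid) {
  for (fl in list(phi, sigma, c, f)) check_field(fl, grid)
  structure(list(phi = phi, sigma = sigma, c = c, f = f, t = t),
            class = "field_state")
}

#' Validate field-state ranges
#'
#' Enforces the representation invariants: `sigma` and `f` must lie in
#' `[0, 1]` (tiny numerical overshoot below `clip_tol` is clipped in place;
#' anything larger is an error), while the phase fields are allowed the usual
#' diffuse-interface overshoot: `phi` in `[-0.05, 1.05]`, `c` in
#' `[-1.05, 1.05]`.
#'
#' @param state A [field_state()].
#' @param clip_tol Maximum tolerated overshoot of `sigma`/`f` outside `[0,1]`.
#' @return The (possibly clipped) state.
#' @export
validate_field_state <- function(state, clip_tol = 1e-10) {
  for (nm in c("sigma", "f")) {
    v <- state[[nm]]
    over <- max(0, max(v) - 1, -min(v))
    if (is.na(over)) stop("NaN detected in field '", nm, "'")
    if (over > clip_tol)
      stop(sprintf("field '%s' out of [0,1] by %.3g", nm, over))
    state[[nm]] <- pmin(pmax(v, 0), 1)
  }
  if (anyNA(state$phi) || anyNA(state$c)) stop("NaN detected in phase field")
  if (min(state$phi) < -0.05 || max(state$phi) > 1.05)
    stop("tumor phase field outside [-0.05, 1.05]")
  if (min(state$c) < -1.05 || max(state$c) > 1.05)
    stop("capillary phase field outside [-1.05, 1.05]")
  state
}

# Bilinear interpolation of a nodal field at an arbitrary point, using mirror
# extension beyond the outermost node centres.
interp_field <- function(field, grid, pos) {
  ix <- pos[1] / grid$dx + 0.5
  iy <- pos[2] / grid$dy + 0.5
  i0 <- floor(ix); j0 <- floor(iy)
  tx <- ix - i0; ty <- iy - j0
  cl <- function(i, n) pmin(pmax(i, 1L), n)
  i0c <- cl(i0, grid$nx); i1c <- cl(i0 + 1, grid$nx)
  j0c <- cl(j0, grid$ny); j1c <- cl(j0 + 1, grid$ny)
  (1 - tx) * ((1 - ty) * field[i0c, j0c] + ty * field[i0c, j1c]) +
    tx * ((1 - ty) * field[i1c, j0c] + ty * field[i1c, j1c])
}
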