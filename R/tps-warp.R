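# Thin-plate spline machinery.  Kernel convention: U(r) = r^2 log r^2
# (twice r^2 log r); switching to r^2 log r would halve the nonaffine
# weights but leaves the interpolant unchanged.

tps_kernel <- function(r2) {
  out <- numeric(length(r2))
  pos <- r2 > 0
  out[pos] <- r2[pos] * log(r2[pos])
  out
}

tps_kernel_matrix <- function(A, B) {
  # |a_i - b_j|^2 for all pairs, then U
  d2 <- outer(A[, 1L], B[, 1L], "-")^2 + outer(A[, 2L], B[, 2L], "-")^2
  matrix(tps_kernel(d2), nrow(A), nrow(B))
}

# Bending-energy matrix of a reference configuration: the upper-left
# k x k block of the inverse of the bordered TPS system.  Quadratic form
# d' B d over landmark displacements d gives the bending energy per
# coordinate; also drives bending-energy sliding of semilandmarks.
bending_energy_matrix <- function(reference) {
  k <- nrow(reference)
  K <- tps_kernel_matrix(reference, reference)
  P <- cbind(1, reference)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3L, 3L)))
  Linv <- tryCatch(solve(L), error = function(e)
    stop("singular TPS system: reference landmarks are collinear or duplicated"))
  B <- Linv[seq_len(k), seq_len(k), drop = FALSE]
  (B + t(B)) / 2
}

#' Fit a thin-plate spline warp between two landmark configurations
#'
#' Solves the standard 2-D thin-plate spline interpolation problem with
#' kernel `U(r) = r^2 log r^2`: the warp maps every reference landmark
#' exactly onto its corresponding target landmark and decomposes into an
#' affine part (a 2 x 3 coefficient matrix) and a nonaffine part (one
#' kernel weight per landmark and coordinate).  The bending energy --
#' the quadratic form of the nonaffine weights in the kernel matrix,
#' summed over both coordinates -- is zero exactly when the target is an
#' affine image of the reference.
#'
#' @param reference `k x 2` matrix of reference landmarks (`k >= 3`, not
#'   collinear).
#' @param target `k x 2` matrix of corresponding target landmarks.
#' @return object of class `tps_warp`: list with `reference`, `target`,
#'   `affine` (2 x 3: intercepts in column 1), `weights` (`k x 2`) and
#'   `bending_energy`.
#' @seealso [bending_energy()], [warp_points()], [jacobian_grid()]
#' @export
fit_tps <- function(reference, target) {
  reference <- as.matrix(reference); target <- as.matrix(target)
  if (nrow(reference) < 3L) stop("TPS needs at least 3 landmarks")
  if (!all(dim(reference) == dim(target)))
    stop("'reference' and 'target' must have identical dimensions")
  k <- nrow(reference)
  K <- tps_kernel_matrix(reference, reference)
  P <- cbind(1, reference)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3L, 3L)))
  rhs <- rbind(target, matrix(0, 3L, 2L))
  sol <- tryCatch(solve(L, rhs), error = function(e)
    stop("singular TPS system: reference landmarks are collinear or duplicated"))
  W <- sol[seq_len(k), , drop = FALSE]
  A <- t(sol[k + 1:3, , drop = FALSE])   # 2 x 3, columns: 1, x, y
  be <- sum(W[, 1L] * (K %*% W[, 1L])) + sum(W[, 2L] * (K %*% W[, 2L]))
  structure(list(reference = reference, target = target, affine = A,
                 weights = W, bending_energy = max(0, be)),
            class = "tps_warp")
}

#' Bending energy of a fitted thin-plate spline warp
#'
#' The value of the quadratic form `w' K w` summed over both
#' coordinates, where `K` is the kernel matrix of the reference and `w`
#' the nonaffine weights.  Up to a constant factor (`16 pi` under this
#' kernel convention) it equals the integral of the squared second
#' derivatives of the interpolant over the plane; it is non-negative and
#' zero exactly for affine warps.
#'
#' @param warp a [fit_tps()] result.
#' @return non-negative numeric.
#' @export
bending_energy <- function(warp) {
  stopifnot(inherits(warp, "tps_warp"))
  warp$bending_energy
}

#' Evaluate a thin-plate spline warp at arbitrary points
#'
#' @param warp a [fit_tps()] result.
#' @param points `m x 2` matrix of locations in the reference frame.
#' @return `m x 2` matrix of warped locations.
#' @export
warp_points <- function(warp, points) {
  stopifnot(inherits(warp, "tps_warp"))
  points <- matrix(as.numeric(points), ncol = 2L)
  U <- tps_kernel_matrix(points, warp$reference)
  cbind(1, points) %*% t(warp$affine) + U %*% warp$weights
}

# Analytic Jacobian matrices of the TPS map at given points.
# dU/dx = 2 (x - xi) (log r^2 + 1); returns list of 2x2 matrices
# flattened into an m x 4 matrix (J11, J12, J21, J22) where
# J = d(fx,fy)/d(x,y).
tps_jacobian <- function(warp, points) {
  points <- matrix(as.numeric(points), ncol = 2L)
  dx <- outer(points[, 1L], warp$reference[, 1L], "-")
  dy <- outer(points[, 2L], warp$reference[, 2L], "-")
  r2 <- dx^2 + dy^2
  g <- matrix(0, nrow(points), nrow(warp$reference))
  pos <- r2 > 0
  g[pos] <- log(r2[pos]) + 1
  Gx <- 2 * dx * g          # dU/dx at each (point, landmark)
  Gy <- 2 * dy * g
  A <- warp$affine          # 2 x 3
  W <- warp$weights         # k x 2
  J11 <- A[1L, 2L] + Gx %*% W[, 1L]
  J12 <- A[1L, 3L] + Gy %*% W[, 1L]
  J21 <- A[2L, 2L] + Gx %*% W[, 2L]
  J22 <- A[2L, 3L] + Gy %*% W[, 2L]
  cbind(J11, J12, J21, J22)
}

#' Jacobian expansion-factor deformation grid
#'
#' Evaluates the determinant of the analytic Jacobian of a thin-plate
#' spline warp at the cell centers of a regular grid: values above 1
#' indicate local expansion of the reference into the target, values
#' below 1 contraction.  The identity warp gives exactly 1 in every
#' cell; a pure uniform scaling by `s` gives `s^2`.
#'
#' @param warp a [fit_tps()] result.
#' @param resolution integer vector `c(nx, ny)` of cells per axis (each
#'   `>= 2`); a single number is recycled.
#' @param bbox bounding rectangle `c(xmin, xmax, ymin, ymax)`; default
#'   the range of the reference landmarks expanded by 10%.
#' @return object of class `deformation_grid`: list with `x`, `y`
#'   (cell-center coordinates), `jacobian` (an `nx x ny` matrix of
#'   determinants), `resolution` and `bbox`.
#' @export
jacobian_grid <- function(warp, resolution = c(24L, 24L), bbox = NULL) {
  stopifnot(inherits(warp, "tps_warp"))
  resolution <- rep(as.integer(resolution), length.out = 2L)
  if (any(resolution < 2L)) stop("grid resolution must be at least 2 x 2")
  if (is.null(bbox)) {
    rx <- range(warp$reference[, 1L]); ry <- range(warp$reference[, 2L])
    pad <- 0.1 * c(diff(rx), diff(ry))
    bbox <- c(rx[1L] - pad[1L], rx[2L] + pad[1L],
              ry[1L] - pad[2L], ry[2L] + pad[2L])
  }
  if (bbox[2L] <= bbox[1L] || bbox[4L] <= bbox[3L])
    stop("degenerate bounding box")
  hx <- (bbox[2L] - bbox[1L]) / resolution[1L]
  hy <- (bbox[4L] - bbox[3L]) / resolution[2L]
  xc <- bbox[1L] + hx * (seq_len(resolution[1L]) - 0.5)
  yc <- bbox[3L] + hy * (seq_len(resolution[2L]) - 0.5)
  pts <- cbind(rep(xc, times = resolution[2L]),
               rep(yc, each = resolution[1L]))
  J <- tps_jacobian(warp, pts)
  detJ <- J[, 1L] * J[, 4L] - J[, 2L] * J[, 3L]
  structure(list(x = xc, y = yc,
                 jacobian = matrix(detJ, resolution[1L], resolution[2L]),
                 resolution = resolution, bbox = bbox),
            class = "deformation_grid")
}

#' @export
print.deformation_grid <- function(x, ...) {
  cat("Deformation grid ", x$resolution[1L], " x ", x$resolution[2L],
      ": det J in [", signif(min(x$jacobian), 4), ", ",
      signif(max(x$jacobian), 4), "]\n", sep = "")
  invisible(x)
}

#' Plot a deformation grid with landmark overlay
#'
#' Renders `log2(det J)` on a symmetric grey scale (pale = contraction,
#' dark = expansion), overlays the deformed grid lines and marks the
#' target landmarks.
#'
#' @param x a [jacobian_grid()] result.
#' @param warp the [fit_tps()] warp the grid was computed from (for the
#'   deformed grid lines and landmarks); optional.
#' @param n_lines number of grid lines per axis (default 12).
#' @param ... passed to [graphics::image()].
#' @export
plot.deformation_grid <- function(x, warp = NULL, n_lines = 12, ...) {
  lj <- log2(pmax(x$jacobian, .Machine$double.eps))
  lim <- max(abs(lj), 1e-3)
  graphics::image(x$x, x$y, lj, zlim = c(-lim, lim),
                  col = grDevices::grey.colors(64, start = 0.98, end = 0.05),
                  xlab = "", ylab = "", asp = 1, ...)
  if (!is.null(warp)) {
    gx <- seq(x$bbox[1L], x$bbox[2L], length.out = n_lines)
    gy <- seq(x$bbox[3L], x$bbox[4L], length.out = n_lines)
    fine <- 60
    for (g in gx) {
      p <- warp_points(warp, cbind(g, seq(x$bbox[3L], x$bbox[4L],
                                          length.out = fine)))
      graphics::lines(p, col = "grey40", lwd = 0.5)
    }
    for (g in gy) {
      p <- warp_points(warp, cbind(seq(x$bbox[1L], x$bbox[2L],
                                       length.out = fine), g))
      graphics::lines(p, col = "grey40", lwd = 0.5)
    }
    graphics::points(warp$target, pch = 19, col = "firebrick", cex = 0.8)
  }
  invisible(x)
}

#' Deformation grid along an ordination axis
#'
#' Builds the thin-plate spline warp from the consensus shape to
#' `consensus + c * axis` for a score magnitude `c`, mirroring how shape
#' change along a principal or canonical axis is visualized, and returns
#' its Jacobian grid.
#'
#' @param consensus `k x 2` consensus shape.
#' @param axis length-`2k` loading vector (x block then y block) or
#'   `k x 2` matrix.
#' @param magnitude score value `c` at which to evaluate the deformation.
#' @param ... passed to [jacobian_grid()].
#' @return list with `warp` (the [fit_tps()] object) and `grid`.
#' @export
axis_deformation <- function(consensus, axis, magnitude, ...) {
  if (is.null(dim(axis))) axis <- matrix(axis, ncol = 2L)
  target <- consensus + magnitude * axis
  warp <- fit_tps(consensus, target)
  list(warp = warp, grid = jacobian_grid(warp, ...))
}
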