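#' Centroid size of a landmark configuration
#'
#' The square root of the summed squared distances of the landmarks to
#' their centroid: the standard size measure removed by Procrustes
#' scaling.  Scales linearly with the configuration (homogeneous of
#' degree 1); a configuration of coincident points has size 0.
#'
#' @param config a `k x 2` coordinate matrix, or a [shape_dataset()]
#'   (in which case a vector of sizes, one per configuration, is
#'   returned).
#' @return positive numeric (or numeric vector).
#' @examples
#' centroid_size(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))  # sqrt(2)
#' @export
centroid_size <- function(config) {
  if (inherits(config, "shape_dataset"))
    return(apply(config$coords, 3L, centroid_size))
  config <- as.matrix(config)
  ctr <- colMeans(config)
  sqrt(sum((config[, 1L] - ctr[1L])^2 + (config[, 2L] - ctr[2L])^2))
}

# Optimal 2-D rotation matrix R (det +1, reflections excluded) minimizing
# ||A %*% R - B||_F for centered configurations A, B.
rotation_onto <- function(A, B) {
  M <- crossprod(A, B)
  s <- svd(M)
  d <- sign(det(tcrossprod(s$u, s$v)))
  if (d == 0) d <- 1
  s$u %*% diag(c(1, d)) %*% t(s$v)
}

center_config <- function(X) sweep(X, 2L, colMeans(X))

# Solve A t = b tolerating rank deficiency (SVD pseudo-inverse).
solve_psd <- function(A, b, tol = 1e-10) {
  s <- svd(A)
  pos <- s$d > tol * max(s$d, .Machine$double.eps)
  if (!any(pos)) return(rep(0, length(b)))
  s$v[, pos, drop = FALSE] %*% ((crossprod(s$u[, pos, drop = FALSE], b)) /
                                  s$d[pos])
}

#' Generalized Procrustes analysis
#'
#' Superimposes all configurations of a dataset by iteratively
#' centering, scaling to unit centroid size and rotating each one onto
#' the current consensus with the closed-form orthogonal (rotation-only)
#' Procrustes solution, recomputing the consensus until its
#' root-mean-square change falls below `tol`.  When a slider
#' specification is supplied, each iteration additionally slides the
#' semilandmarks along their neighbour chords so that their spacing has
#' minimal impact on shape differences (see [slide_semilandmarks()]).
#' The final orientation is canonicalized to the principal axes of the
#' consensus, so the result does not depend on the orientation of any
#' input configuration.  By default the aligned shapes are orthogonally
#' projected onto the linear tangent space at the consensus; downstream
#' variance analyses consume these tangent coordinates.
#'
#' @param dataset a [shape_dataset()] with `n >= 2` non-degenerate
#'   configurations.
#' @param sliders a [sliders_spec()], or `NULL` for none.
#' @param max_iter maximum number of superimposition iterations
#'   (default 100).
#' @param tol convergence tolerance on the consensus RMS change
#'   (default 1e-8).
#' @param project_to_tangent orthogonally project aligned shapes onto
#'   the tangent plane at the consensus (default `TRUE`).
#' @param slide_mode sliding criterion, `"bending_energy"` (default) or
#'   `"procrustes_distance"`.
#' @param slide_iters number of initial iterations that include a
#'   sliding pass (default 3); afterwards rotation-only iterations run
#'   to convergence.  Semilandmark spacing stabilizes within a few
#'   passes, while sliding on every iteration lets the whole spacing
#'   pattern drift collectively along the curves (a near-neutral
#'   direction of the criterion) and stalls convergence.
#' @return an object of class `aligned_shapes`: list with `coords`
#'   (`k x 2 x n` aligned coordinates), `centroid_sizes`, `consensus`
#'   (the coordinate-wise mean of the aligned configurations), `rho`
#'   (Procrustes geodesic distances of each configuration to the
#'   consensus), `n_iterations`, `converged_delta`, `converged`,
#'   `tangent` (whether coordinates are tangent-projected), plus the ids
#'   and label table of the input.
#' @seealso [tangent_check()], [relative_warps()]
#' @export
gpa <- function(dataset, sliders = NULL, max_iter = 100, tol = 1e-8,
                project_to_tangent = TRUE,
                slide_mode = c("bending_energy", "procrustes_distance"),
                slide_iters = 3L) {
  stopifnot(inherits(dataset, "shape_dataset"))
  slide_mode <- match.arg(slide_mode)
  if (dataset$n < 2L) stop("GPA needs at least 2 configurations")
  if (!is.null(sliders)) {
    if (!inherits(sliders, "sliders_spec"))
      stop("'sliders' must be a sliders_spec")
    if (attr(sliders, "k") != dataset$k)
      stop("sliders were defined for k = ", attr(sliders, "k"),
           " but the dataset has k = ", dataset$k)
    if (nrow(sliders) == 0L) sliders <- NULL
  }
  k <- dataset$k; n <- dataset$n
  cs <- centroid_size(dataset)
  if (any(cs <= 0))
    stop("degenerate configuration(s) with zero centroid size: ",
         paste(dataset$ids[cs <= 0], collapse = ", "))
  X <- array(0, dim = c(k, 2L, n))
  for (i in seq_len(n))
    X[, , i] <- center_config(dataset$coords[, , i]) / cs[i]

  # initialize: rotate everything onto the first configuration
  for (i in seq_len(n)) X[, , i] <- X[, , i] %*% rotation_onto(X[, , i], X[, , 1L])
  consensus <- apply(X, c(1L, 2L), mean)
  delta <- Inf; iter <- 0L
  while (iter < max_iter && delta > tol) {
    iter <- iter + 1L
    for (i in seq_len(n)) X[, , i] <- X[, , i] %*% rotation_onto(X[, , i], consensus)
    if (!is.null(sliders) && iter <= slide_iters) {
      X <- slide_pass(X, consensus, sliders, slide_mode)
      for (i in seq_len(n)) {
        Xi <- center_config(X[, , i])
        Xi <- Xi / sqrt(sum(Xi^2))
        X[, , i] <- Xi %*% rotation_onto(Xi, consensus)
      }
    }
    new_consensus <- apply(X, c(1L, 2L), mean)
    delta <- sqrt(mean((new_consensus - consensus)^2))
    consensus <- new_consensus
  }
  converged <- delta <= tol
  if (!converged)
    warning("GPA did not converge after ", max_iter,
            " iterations (last consensus RMS change ", signif(delta, 3), ")")

  # canonical orientation: principal axes of the consensus, deterministic sign
  R <- canonical_rotation(consensus)
  for (i in seq_len(n)) X[, , i] <- X[, , i] %*% R
  consensus <- consensus %*% R

  chat <- consensus / sqrt(sum(consensus^2))
  rho <- acos(pmax(-1, pmin(1, vapply(seq_len(n),
                                      function(i) sum(X[, , i] * chat),
                                      numeric(1)))))
  if (project_to_tangent) {
    for (i in seq_len(n)) {
      ip <- sum(X[, , i] * chat)
      X[, , i] <- X[, , i] + (1 - ip) * chat
    }
  }
  consensus <- apply(X, c(1L, 2L), mean)
  dimnames(X) <- list(NULL, c("x", "y"), dataset$ids)
  structure(list(coords = X, centroid_sizes = stats::setNames(cs, dataset$ids),
                 consensus = consensus, rho = rho,
                 n_iterations = iter, converged_delta = delta,
                 converged = converged, tangent = project_to_tangent,
                 sliders = sliders, slide_mode = if (!is.null(sliders)) slide_mode,
                 ids = dataset$ids, labels = dataset$labels, k = k, n = n),
            class = "aligned_shapes")
}

# Rotation that aligns the consensus with its principal axes, with a
# deterministic sign convention (the landmark with the largest |x| gets
# a positive x).  Pure rotation: no reflection is ever introduced.
canonical_rotation <- function(consensus) {
  V <- eigen(stats::cov(consensus), symmetric = TRUE)$vectors
  if (det(V) < 0) V[, 2L] <- -V[, 2L]
  rot <- consensus %*% V
  j <- which.max(abs(rot[, 1L]))
  if (rot[j, 1L] < 0) V <- -V
  V
}

#' @export
print.aligned_shapes <- function(x, ...) {
  cat("Procrustes-aligned dataset: ", x$n, " configurations of ", x$k,
      " landmarks\n", sep = "")
  cat("  iterations: ", x$n_iterations,
      if (x$converged) " (converged)" else " (NOT converged)",
      "; tangent-projected: ", x$tangent, "\n", sep = "")
  if (!is.null(x$sliders))
    cat("  semilandmarks slid: ", nrow(x$sliders), " (", x$slide_mode,
        ")\n", sep = "")
  invisible(x)
}

# One sliding pass: move each configuration's semilandmarks along their
# neighbour-chord tangent directions to minimize either the bending
# energy of the TPS from the consensus to the configuration, or the
# Procrustes (Euclidean) distance to the consensus.
slide_pass <- function(X, consensus, sliders, mode) {
  k <- dim(X)[1L]; n <- dim(X)[3L]
  s_idx <- sliders[, 2L]
  if (!mode %in% c("bending_energy", "procrustes_distance"))
    stop("unknown sliding mode: ", mode)
  E <- if (mode == "bending_energy") bending_energy_matrix(consensus)
       else diag(k)
  for (i in seq_len(n)) {
    Xi <- X[, , i]
    tang <- Xi[sliders[, 3L], , drop = FALSE] - Xi[sliders[, 1L], , drop = FALSE]
    nrm <- sqrt(rowSums(tang^2))
    nrm[nrm == 0] <- 1
    tang <- tang / nrm
    # U maps slider displacements t (s-vector) to coordinate shifts
    Ux <- matrix(0, k, length(s_idx)); Uy <- Ux
    Ux[cbind(s_idx, seq_along(s_idx))] <- tang[, 1L]
    Uy[cbind(s_idx, seq_along(s_idx))] <- tang[, 2L]
    rx <- Xi[, 1L] - consensus[, 1L]
    ry <- Xi[, 2L] - consensus[, 2L]
    A <- crossprod(Ux, E %*% Ux) + crossprod(Uy, E %*% Uy)
    b <- crossprod(Ux, E %*% rx) + crossprod(Uy, E %*% ry)
    tshift <- -solve_psd(A, b)
    Xi[, 1L] <- Xi[, 1L] + Ux %*% tshift
    Xi[, 2L] <- Xi[, 2L] + Uy %*% tshift
    X[, , i] <- Xi
  }
  X
}

#' Slide semilandmarks of an aligned dataset
#'
#' Applies one sliding pass against the current consensus, displacing
#' each semilandmark only along the chord joining its two neighbours,
#' with the displacement chosen to minimize either the bending energy of
#' the thin-plate spline from the consensus to the configuration
#' (`"bending_energy"`) or the Procrustes distance to the consensus
#' (`"procrustes_distance"`).  Each pass is followed by
#' re-superimposition.  [gpa()] calls this internally when given a
#' slider specification; the exported function allows extra passes on an
#' aligned dataset.
#'
#' @param aligned an [gpa()] result (tangent projection is re-applied if
#'   it was on).
#' @param sliders a [sliders_spec()].
#' @param mode `"bending_energy"` (default) or `"procrustes_distance"`.
#' @param passes number of slide/re-superimpose passes (default 1).
#' @return an updated `aligned_shapes` object.
#' @export
slide_semilandmarks <- function(aligned, sliders,
                                mode = c("bending_energy",
                                         "procrustes_distance"),
                                passes = 1L) {
  stopifnot(inherits(aligned, "aligned_shapes"))
  mode <- match.arg(mode)
  if (!inherits(sliders, "sliders_spec"))
    stop("'sliders' must be a sliders_spec")
  if (nrow(sliders) == 0L) return(aligned)
  ds <- shape_dataset(aligned$coords, ids = aligned$ids,
                      labels = aligned$labels)
  out <- suppressWarnings(
    gpa(ds, sliders = sliders, max_iter = passes, tol = 0,
        project_to_tangent = aligned$tangent, slide_mode = mode,
        slide_iters = passes))
  out$centroid_sizes <- aligned$centroid_sizes
  out
}

#' Tangent-space approximation check
#'
#' Assesses how well the curved shape space is represented by its linear
#' tangent-space approximation: for each configuration the geodesic
#' Procrustes distance to the consensus (`rho = arccos` of the inner
#' product with the unit consensus) is compared with its Euclidean
#' distance to the consensus in tangent space.  A through-origin
#' least-squares regression slope close to 1 and a correlation close to
#' 1 indicate that the linear approximation is adequate for downstream
#' multivariate analysis.  The projection shortens distances, so the
#' slope never exceeds 1.
#'
#' @param aligned an [gpa()] result with nonzero shape variation
#'   (`n >= 3`).
#' @return object of class `tangent_check`: list with `slope`,
#'   `correlation`, and the two distance vectors `tangent_distance` and
#'   `procrustes_distance`.
#' @export
tangent_check <- function(aligned) {
  stopifnot(inherits(aligned, "aligned_shapes"))
  if (aligned$n < 3L) stop("tangent check needs at least 3 configurations")
  rho <- aligned$rho
  dt <- vapply(seq_len(aligned$n), function(i)
    sqrt(sum((aligned$coords[, , i] - aligned$consensus)^2)), numeric(1))
  if (all(rho < 1e-6))
    stop("no shape variation: tangent regression is undefined")
  slope <- sum(dt * rho) / sum(rho^2)
  correlation <- if (stats::sd(dt) == 0 || stats::sd(rho) == 0) 1
                 else stats::cor(dt, rho)
  structure(list(slope = slope, correlation = correlation,
                 tangent_distance = dt, procrustes_distance = rho),
            class = "tangent_check")
}

#' @export
print.tangent_check <- function(x, ...) {
  cat(sprintf("Tangent approximation: slope %.5f, correlation %.5f (n = %d)\n",
              x$slope, x$correlation, length(x$procrustes_distance)))
  invisible(x)
}
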