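# Flatten aligned coordinates (or pass score matrices through) to an
# n x m numeric matrix with one row per configuration.
as_score_matrix <- function(x) {
  if (inherits(x, "aligned_shapes")) {
    n <- x$n
    out <- t(vapply(seq_len(n), function(i) as.numeric(x$coords[, , i]),
                    numeric(2L * x$k)))
    rownames(out) <- x$ids
    out
  } else if (inherits(x, "warp_scores")) {
    x$scores
  } else {
    as.matrix(x)
  }
}

label_column <- function(obj, name_or_vec, n) {
  if (length(name_or_vec) == 1L && is.character(name_or_vec)) {
    if (is.null(obj$labels) || !name_or_vec %in% names(obj$labels))
      stop("no label column '", name_or_vec, "' in the dataset")
    v <- obj$labels[[name_or_vec]]
  } else v <- name_or_vec
  if (length(v) != n) stop("grouping vector must have one entry per configuration")
  if (anyNA(v)) stop("missing label(s) in grouping variable")
  factor(v)
}

#' Procrustes ANOVA (Goodall's F) with permutation tests
#'
#' Decomposes the variation of Procrustes-aligned (tangent) coordinates
#' into sequential (Type I) sums of squares for an ordered list of
#' factors, treating the coordinates as one multivariate response whose
#' squared distances are summed over all landmarks.  The test statistic
#' per factor is Goodall's F, the ratio of the factor and residual mean
#' squares of summed squared Procrustes distances.  Significance is
#' assessed by randomized residual permutation (RRPP): for each factor
#' the residuals of the reduced model containing all preceding terms are
#' permuted and added back to the reduced fit, and the statistic is
#' recomputed.  The typical model for digitized datasets is species,
#' then site nested within species, then digitization replicate, which
#' quantifies measurement error last.
#'
#' @param aligned an [gpa()] result with a label table (or a
#'   `shape_dataset`-like object accepted by `as_score_matrix`).
#' @param factors character vector of label columns in model order,
#'   e.g. `c("species", "site", "replicate_id")`.
#' @param n_perm number of permutations (default 999; at least 99).
#' @param seed integer seed making the permutation p-values reproducible.
#' @param nest_site_in_species if `TRUE` (default) a factor named
#'   `"site"` that follows `"species"` is fitted as site-within-species
#'   (the species:site interaction), reflecting that sites are
#'   geographic subsets of species samples.
#' @return object of class `procrustes_anova`: a data frame with one
#'   row per factor plus `Residuals` and `Total`, columns `Df`, `SS`,
#'   `MS`, `Rsq_pct` (percent of total SS), `F` and `p` (permutation),
#'   with attributes `n_perm` and `seed`.
#' @export
procrustes_anova <- function(aligned, factors, n_perm = 999, seed = 1L,
                             nest_site_in_species = TRUE) {
  Y <- as_score_matrix(aligned)
  n <- nrow(Y)
  if (n_perm < 99) stop("n_perm must be at least 99")
  fac <- lapply(factors, function(f) label_column(aligned, f, n))
  names(fac) <- factors
  for (f in factors)
    if (nlevels(droplevels(fac[[f]])) < 2L)
      stop("factor '", f, "' is constant")
  # nesting: site fitted within species
  terms <- fac
  if (nest_site_in_species && "site" %in% factors && "species" %in% factors &&
      match("site", factors) > match("species", factors))
    terms[["site"]] <- droplevels(interaction(fac[["species"]], fac[["site"]],
                                              drop = TRUE))
  Yc <- sweep(Y, 2L, colMeans(Y))
  ss_total <- sum(Yc^2)

  # cumulative QR bases: intercept, then + each term
  designs <- vector("list", length(terms) + 1L)
  designs[[1L]] <- matrix(1, n, 1L)
  D <- designs[[1L]]
  for (j in seq_along(terms)) {
    D <- cbind(D, stats::model.matrix(~ z - 1, data.frame(z = terms[[j]])))
    designs[[j + 1L]] <- D
  }
  qrs <- lapply(designs, function(d) qr(d))
  ranks <- vapply(qrs, function(q) q$rank, integer(1))
  Qs <- lapply(qrs, function(q) qr.Q(q)[, seq_len(q$rank), drop = FALSE])
  rss <- function(Ymat) {
    tot <- sum(Ymat^2)
    vapply(Qs, function(Q) tot - sum(crossprod(Q, Ymat)^2), numeric(1))
  }
  rss_obs <- rss(Y)
  m <- length(terms)
  ss <- rss_obs[seq_len(m)] - rss_obs[-1L]
  df <- ranks[-1L] - ranks[seq_len(m)]
  if (any(df == 0L))
    stop("factor '", factors[which(df == 0L)[1L]],
         "' adds no degrees of freedom (confounded with preceding terms)")
  df_res <- n - ranks[m + 1L]
  if (df_res < 1L) stop("no residual degrees of freedom")
  ss_res <- rss_obs[m + 1L]
  Fobs <- (ss / df) / (ss_res / df_res)

  # RRPP: permute reduced-model residuals per factor
  counts <- rep(1L, m)
  withr::with_seed(as.integer(seed), {
    perms <- replicate(n_perm, sample.int(n), simplify = FALSE)
    for (j in seq_len(m)) {
      Qred <- Qs[[j]]
      Fit_red <- Qred %*% crossprod(Qred, Y)
      Res_red <- Y - Fit_red
      for (p in seq_len(n_perm)) {
        Yp <- Fit_red + Res_red[perms[[p]], , drop = FALSE]
        rp <- rss(Yp)
        Fp <- ((rp[j] - rp[j + 1L]) / df[j]) / (rp[m + 1L] / df_res)
        if (Fp >= Fobs[j] - 1e-12) counts[j] <- counts[j] + 1L
      }
    }
  })
  pvals <- counts / (n_perm + 1)

  tab <- data.frame(
    Df = c(df, df_res, n - 1L),
    SS = c(ss, ss_res, ss_total),
    MS = c(ss / df, ss_res / df_res, NA),
    Rsq_pct = 100 * c(ss, ss_res, ss_total) / ss_total,
    F = c(Fobs, NA, NA),
    p = c(pvals, NA, NA),
    row.names = c(factors, "Residuals", "Total"))
  structure(tab, class = c("procrustes_anova", "data.frame"),
            n_perm = n_perm, seed = seed)
}

#' @export
print.procrustes_anova <- function(x, digits = 4, ...) {
  cat("Procrustes ANOVA (Goodall's F), ", attr(x, "n_perm"),
      " permutations (RRPP)\n", sep = "")
  print.data.frame(round_df(x, digits))
  invisible(x)
}

round_df <- function(x, digits) {
  for (j in seq_along(x)) if (is.numeric(x[[j]])) x[[j]] <- signif(x[[j]], digits)
  as.data.frame(x)
}

#' Relative warps of an aligned dataset
#'
#' Principal components of the Procrustes-aligned tangent coordinates
#' with warp-weighting exponent alpha = 0 and the uniform (affine)
#' component included, in which case the warp scores are exactly the
#' principal-component scores of the tangent coordinates.  The full
#' score space is an isometry of tangent space: pairwise Euclidean
#' distances between score rows equal pairwise tangent-space distances.
#'
#' @param aligned an [gpa()] result (`n >= 3`), or any n x m coordinate
#'   matrix.
#' @return object of class `warp_scores`: list with `scores` (`n x m`),
#'   `eigenvalues` (descending), `percent_variance`, `axes` (loading
#'   columns, orthonormal), `center`, `alpha = 0`,
#'   `uniform_included = TRUE`, plus ids and labels when available.
#' @export
relative_warps <- function(aligned) {
  Y <- as_score_matrix(aligned)
  n <- nrow(Y)
  if (n < 3L) stop("relative warps need at least 3 configurations")
  ctr <- colMeans(Y)
  Yc <- sweep(Y, 2L, ctr)
  sv <- svd(Yc)
  keep <- sv$d > max(sv$d) * 1e-10
  m <- sum(keep)
  axes <- sv$v[, seq_len(m), drop = FALSE]
  # deterministic sign: largest-magnitude loading positive
  for (j in seq_len(m)) {
    i <- which.max(abs(axes[, j]))
    if (axes[i, j] < 0) axes[, j] <- -axes[, j]
  }
  scores <- Yc %*% axes
  ev <- (sv$d[seq_len(m)]^2) / (n - 1L)
  structure(list(scores = scores, eigenvalues = ev,
                 percent_variance = 100 * ev / sum(ev),
                 axes = axes, center = ctr, alpha = 0,
                 uniform_included = TRUE,
                 ids = if (inherits(aligned, "aligned_shapes")) aligned$ids
                       else rownames(Y),
                 labels = if (inherits(aligned, "aligned_shapes")) aligned$labels,
                 consensus = if (inherits(aligned, "aligned_shapes"))
                   aligned$consensus,
                 k = if (inherits(aligned, "aligned_shapes")) aligned$k),
            class = "warp_scores")
}

#' @export
print.warp_scores <- function(x, ...) {
  cat("Relative warps: ", nrow(x$scores), " configurations, ",
      length(x$eigenvalues), " nonzero components\n", sep = "")
  cat("  top components (% variance): ",
      paste(sprintf("%.1f", utils::head(x$percent_variance, 5L)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Between-group principal components analysis
#'
#' Eigen-analysis of the covariance of the (equally weighted) group mean
#' vectors; all individuals are projected onto the resulting axes, so
#' differences between group means are displayed regardless of
#' within-group variation.  With `g` groups at most `g - 1` axes have
#' nonzero eigenvalues.  Percent variance per axis is reported both as
#' the share of group-mean variance (`percent_variance`) and as the
#' share of the total variance of the projected individuals
#' (`percent_total_variance`).
#'
#' @param x an `n x m` score/coordinate matrix, or an
#'   `aligned_shapes`/`warp_scores` object.
#' @param groups grouping vector, or the name of a label column of `x`.
#' @return object of class `bg_pca`: list with `axes` (orthonormal
#'   loadings), `eigenvalues`, `percent_variance`,
#'   `percent_total_variance`, `scores` (all individuals),
#'   `group_means` (in score space), `center` and `groups`.
#' @export
between_group_pca <- function(x, groups) {
  Y <- as_score_matrix(x)
  n <- nrow(Y)
  g <- label_column(x, groups, n)
  g <- droplevels(g)
  if (nlevels(g) < 2L) stop("between-group PCA needs at least 2 groups")
  gm <- rowsum(Y, g) / as.vector(table(g))
  ctr <- colMeans(gm)                     # equal-weight grand mean
  gmc <- sweep(gm, 2L, ctr)
  sv <- svd(gmc)
  keep <- sv$d > max(sv$d, .Machine$double.eps) * 1e-10
  m <- max(1L, sum(keep))
  axes <- sv$v[, seq_len(m), drop = FALSE]
  for (j in seq_len(m)) {
    i <- which.max(abs(axes[, j]))
    if (axes[i, j] < 0) axes[, j] <- -axes[, j]
  }
  ev <- (sv$d[seq_len(m)]^2) / (nlevels(g) - 1L)
  pct <- if (sum(ev) > 0) 100 * ev / sum(ev) else ev
  scores <- sweep(Y, 2L, ctr) %*% axes
  tot_var <- sum(apply(sweep(Y, 2L, colMeans(Y)), 2L, function(v) sum(v^2))) /
    (n - 1L)
  proj_var <- apply(scores, 2L, stats::var)
  structure(list(axes = axes, eigenvalues = ev,
                 percent_variance = pct,
                 percent_total_variance = 100 * proj_var / tot_var,
                 scores = scores, group_means = gmc %*% axes,
                 center = ctr, groups = g),
            class = "bg_pca")
}

#' @export
print.bg_pca <- function(x, ...) {
  cat("Between-group PCA: ", nlevels(x$groups), " groups, ",
      ncol(x$scores), " axis/axes\n", sep = "")
  cat("  % of group-mean variance: ",
      paste(sprintf("%.1f", x$percent_variance), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Scatterplot of an ordination with group colours
#'
#' @param x a `bg_pca` or `cva_result` object.
#' @param axes which two axes to plot (default 1:2).
#' @param ellipse draw 95% normal ellipses per group (default `TRUE`).
#' @param ... passed to [graphics::plot()].
#' @export
plot.bg_pca <- function(x, axes = c(1L, 2L), ellipse = TRUE, ...) {
  plot_ordination(x$scores, x$groups, axes, ellipse,
                  xlab = paste0("PC", axes[1L]), ylab = paste0("PC", axes[2L]),
                  ...)
}

plot_ordination <- function(scores, groups, axes, ellipse, xlab, ylab, ...) {
  if (ncol(scores) < 2L) scores <- cbind(scores, 0)
  cols <- grDevices::hcl.colors(nlevels(groups), "Dark 3")
  graphics::plot(scores[, axes[1L]], scores[, axes[2L]],
                 col = cols[as.integer(groups)], pch = 19,
                 xlab = xlab, ylab = ylab, ...)
  if (ellipse) {
    th <- seq(0, 2 * pi, length.out = 100)
    for (lv in seq_len(nlevels(groups))) {
      sel <- as.integer(groups) == lv
      if (sum(sel) < 3L) next
      S <- stats::cov(scores[sel, axes, drop = FALSE])
      mu <- colMeans(scores[sel, axes, drop = FALSE])
      ei <- eigen(S, symmetric = TRUE)
      rad <- sqrt(pmax(ei$values, 0) * stats::qchisq(0.95, 2))
      pts <- t(mu + ei$vectors %*% rbind(rad[1L] * cos(th), rad[2L] * sin(th)))
      graphics::lines(pts, col = cols[lv])
    }
  }
  graphics::legend("topright", legend = levels(groups), col = cols, pch = 19,
                   cex = 0.8, bty = "n")
  invisible(NULL)
}
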