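# Dimension retention before CVA: keep the leading columns (assumed
# variance-ordered, as warp scores are) explaining `retain` of the total
# variance, bounded by n - g - 1 so the pooled within-group covariance
# stays estimable.  `retain >= 1` is taken as an explicit column count.
retained_dims <- function(Y, g, retain) {
  n <- nrow(Y)
  cap <- max(1L, min(ncol(Y), n - nlevels(g) - 1L))
  if (retain >= 1) return(min(as.integer(retain), cap))
  v <- apply(Y, 2L, stats::var)
  cum <- cumsum(v) / sum(v)
  min(max(1L, which(cum >= retain)[1L]), cap)
}

#' Canonical variates analysis
#'
#' Solves the generalized eigenproblem of the between-group covariance
#' of group means (weighted by group size) against the pooled
#' within-group covariance, yielding canonical axes that maximize
#' among-group relative to within-group variation.  Axes are scaled so
#' the pooled within-group covariance is spherical in canonical space,
#' making Euclidean distance there equivalent to Mahalanobis distance in
#' the input space.  The percent of among-group variance per canonical
#' variate is its eigenvalue share.
#'
#' Input dimensions are truncated first (see `retain`): warp scores are
#' variance-ordered, so the leading columns explaining 99% of variance
#' (bounded by `n - g - 1`) are kept by default, which protects the
#' within-group covariance from singularity.
#'
#' @param scores `n x m` score matrix (e.g. [relative_warps()] scores)
#'   or a `warp_scores`/`aligned_shapes` object.
#' @param groups grouping vector or label column name.
#' @param retain dimension-retention rule: a proportion of variance
#'   (default 0.99) or an explicit column count.
#' @return object of class `cva_result`: list with `axes` (`m' x c`),
#'   `eigenvalues`, `percent_variance`, `scores` (`n x c`),
#'   `group_means` (canonical space), `center`, `retained` (`m'`),
#'   `groups`.
#' @export
cva <- function(scores, groups, retain = 0.99) {
  Y <- as_score_matrix(scores)
  n <- nrow(Y)
  g <- droplevels(label_column(scores, groups, n))
  if (nlevels(g) < 2L) stop("CVA needs at least 2 groups")
  m_ret <- retained_dims(Y, g, retain)
  Y <- Y[, seq_len(m_ret), drop = FALSE]
  ng <- as.vector(table(g))
  gm <- rowsum(Y, g) / ng
  ctr <- colMeans(Y)
  W <- matrix(0, m_ret, m_ret)
  for (lv in levels(g)) {
    sel <- g == lv
    if (sum(sel) > 1L) {
      Z <- sweep(Y[sel, , drop = FALSE], 2L, colMeans(Y[sel, , drop = FALSE]))
      W <- W + crossprod(Z)
    }
  }
  W <- W / (n - nlevels(g))
  ew <- eigen(W, symmetric = TRUE)
  tol <- max(ew$values, 0) * 1e-8
  if (any(ew$values <= tol))
    stop("pooled within-group covariance is singular after retaining ",
         m_ret, " dimensions; use a stronger truncation (smaller 'retain')")
  Tw <- ew$vectors %*% diag(1 / sqrt(ew$values), m_ret)
  gmc <- sweep(gm, 2L, ctr)
  B <- crossprod(gmc * sqrt(ng)) / (nlevels(g) - 1L)
  M <- crossprod(Tw, B %*% Tw)
  em <- eigen((M + t(M)) / 2, symmetric = TRUE)
  n_axes <- min(nlevels(g) - 1L, m_ret)
  axes <- Tw %*% em$vectors[, seq_len(n_axes), drop = FALSE]
  for (j in seq_len(n_axes)) {
    i <- which.max(abs(axes[, j]))
    if (axes[i, j] < 0) axes[, j] <- -axes[, j]
  }
  ev <- pmax(em$values[seq_len(n_axes)], 0)
  sc <- sweep(Y, 2L, ctr) %*% axes
  structure(list(axes = axes, eigenvalues = ev,
                 percent_variance = if (sum(ev) > 0) 100 * ev / sum(ev) else ev,
                 scores = sc, group_means = gmc %*% axes,
                 center = ctr, retained = m_ret, retain_rule = retain,
                 groups = g),
            class = "cva_result")
}

#' @export
print.cva_result <- function(x, ...) {
  cat("CVA: ", nlevels(x$groups), " groups, ", ncol(x$scores),
      " canonical axis/axes on ", x$retained, " retained dimension(s)\n",
      sep = "")
  cat("  % among-group variance: ",
      paste(sprintf("%.1f", x$percent_variance), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' @export
plot.cva_result <- function(x, axes = c(1L, 2L), ellipse = TRUE, ...) {
  plot_ordination(x$scores, x$groups, axes, ellipse,
                  xlab = paste0("CV", axes[1L]), ylab = paste0("CV", axes[2L]),
                  ...)
}

# Project new observations (rows of Ynew, already truncated to the
# retained dimensions) into the canonical space of a fitted CVA and
# assign each to the nearest group mean.
cva_assign <- function(fit, Ynew) {
  sc <- sweep(Ynew, 2L, fit$center) %*% fit$axes
  d2 <- outer(rowSums(sc^2), rowSums(fit$group_means^2), "+") -
    2 * sc %*% t(fit$group_means)
  levels(fit$groups)[max.col(-d2, ties.method = "first")]
}

#' Jackknifed (leave-one-out) classification from canonical variates
#'
#' Estimates the classification accuracy of a shape dataset: each
#' individual in turn is withheld, the CVA is refitted on the remaining
#' individuals, the withheld individual is projected into the refitted
#' canonical space and assigned to the group whose canonical mean is
#' nearest (Euclidean in canonical space, i.e. Mahalanobis in the input
#' space).  Results are tallied into a confusion matrix of true groups
#' (rows) against assigned groups (columns).
#'
#' @inheritParams cva
#' @param refit `"full"` (default) refits the whole CVA per left-out
#'   individual; `"means"` keeps the axes of the all-data CVA and only
#'   recomputes the group means without the individual (cheaper).
#' @return object of class `confusion_matrix`: list with `table`
#'   (counts), `accuracy` (percent), `assigned`, `groups`.
#' @export
jackknife_classify <- function(scores, groups, retain = 0.99,
                               refit = c("full", "means")) {
  refit <- match.arg(refit)
  Y <- as_score_matrix(scores)
  n <- nrow(Y)
  g <- droplevels(label_column(scores, groups, n))
  if (any(table(g) < 2L))
    stop("every group needs at least 2 members for leave-one-out ",
         "classification; too small: ",
         paste(names(which(table(g) < 2L)), collapse = ", "))
  assigned <- character(n)
  if (refit == "full") {
    for (i in seq_len(n)) {
      fit <- cva(Y[-i, , drop = FALSE], g[-i], retain = retain)
      assigned[i] <- cva_assign(fit, Y[i, seq_len(fit$retained), drop = FALSE])
    }
  } else {
    fit <- cva(Y, g, retain = retain)
    sc <- sweep(Y[, seq_len(fit$retained), drop = FALSE], 2L, fit$center) %*%
      fit$axes
    for (i in seq_len(n)) {
      gm <- rowsum(sc[-i, , drop = FALSE], g[-i]) /
        as.vector(table(g[-i]))
      d2 <- colSums((t(gm) - sc[i, ])^2)
      assigned[i] <- rownames(gm)[which.min(d2)]
    }
  }
  assigned <- factor(assigned, levels = levels(g))
  tab <- table(true = g, assigned = assigned)
  structure(list(table = tab,
                 accuracy = 100 * sum(diag(tab)) / n,
                 assigned = assigned, groups = g),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("Jackknifed classification: %.1f%% correctly assigned\n",
              x$accuracy))
  print(x$table)
  invisible(x)
}

# One-way PERMANOVA pseudo-F from a squared-distance matrix and a
# grouping factor (McArdle-Anderson partitioning of summed squared
# interpoint distances).
permanova_F <- function(D2, g) {
  n <- nrow(D2)
  lv <- levels(g)
  sst <- sum(D2) / (2 * n)
  ssw <- 0
  for (l in lv) {
    idx <- which(g == l)
    ssw <- ssw + sum(D2[idx, idx]) / (2 * length(idx))
  }
  ssb <- sst - ssw
  (ssb / (length(lv) - 1L)) / (ssw / (n - length(lv)))
}

#' Pairwise PERMANOVA with Bonferroni correction
#'
#' For every pair of groups, a one-way permutational MANOVA on the
#' Euclidean distances between score rows: the pseudo-F statistic is
#' `(SS_between / (g - 1)) / (SS_within / (n - g))` with `g = 2`,
#' computed from the pairwise distance matrix, and its significance is
#' obtained by permuting group membership.  Raw p-values follow the
#' convention `p = (#\{F_perm >= F_obs\} + 1) / (n_perm + 1)` and are
#' Bonferroni-corrected across all pairs.
#'
#' @inheritParams cva
#' @param n_perm permutations per pair (default 9999; at least 99).
#' @param seed integer seed for reproducible permutations.
#' @param correction multiple-testing correction; only `"bonferroni"`.
#' @return object of class `pairwise_permanova`: list with `tests` (a
#'   data frame: `group1`, `group2`, `n1`, `n2`, `F`, `p`, `p_adj`),
#'   `F_matrix` (symmetric, zero diagonal), `n_perm`, `seed`.
#' @export
pairwise_permanova <- function(scores, groups, n_perm = 9999, seed = 1L,
                               correction = c("bonferroni")) {
  correction <- match.arg(correction)
  if (n_perm < 99) stop("n_perm must be at least 99")
  Y <- as_score_matrix(scores)
  n <- nrow(Y)
  g <- droplevels(label_column(scores, groups, n))
  if (nlevels(g) < 2L) stop("need at least 2 distinct groups")
  small <- names(which(table(g) < 2L))
  if (length(small))
    stop("group(s) with fewer than 2 members: ", paste(small, collapse = ", "))
  lv <- levels(g)
  pairs <- utils::combn(lv, 2L)
  n_pairs <- ncol(pairs)
  res <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                    n1 = NA_integer_, n2 = NA_integer_,
                    F = NA_real_, p = NA_real_, p_adj = NA_real_)
  Fm <- matrix(0, nlevels(g), nlevels(g), dimnames = list(lv, lv))
  withr::with_seed(as.integer(seed), {
    for (j in seq_len(n_pairs)) {
      sel <- g %in% pairs[, j]
      Ys <- Y[sel, , drop = FALSE]
      gs <- droplevels(g[sel])
      ns <- nrow(Ys)
      D2 <- as.matrix(stats::dist(Ys))^2
      Fobs <- permanova_F(D2, gs)
      count <- 1L
      for (p in seq_len(n_perm)) {
        gp <- gs[sample.int(ns)]
        if (permanova_F(D2, gp) >= Fobs - 1e-12) count <- count + 1L
      }
      res$n1[j] <- sum(gs == pairs[1L, j]); res$n2[j] <- sum(gs == pairs[2L, j])
      res$F[j] <- Fobs
      res$p[j] <- count / (n_perm + 1)
      Fm[pairs[1L, j], pairs[2L, j]] <- Fobs
      Fm[pairs[2L, j], pairs[1L, j]] <- Fobs
    }
  })
  res$p_adj <- pmin(1, res$p * n_pairs)
  structure(list(tests = res, F_matrix = Fm, n_perm = n_perm, seed = seed),
            class = "pairwise_permanova")
}

#' @export
print.pairwise_permanova <- function(x, digits = 4, ...) {
  cat("Pairwise PERMANOVA (", x$n_perm,
      " permutations, Bonferroni-corrected)\n", sep = "")
  print(round_df(x$tests, digits))
  invisible(x)
}
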