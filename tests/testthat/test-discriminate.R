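two_cluster_scores <- function(sep, n_per = 20L, m = 5L, seed = 1) {
  withr::with_seed(seed, {
    Y <- rbind(matrix(rnorm(n_per * m), n_per),
               matrix(rnorm(n_per * m), n_per))
    Y[(n_per + 1L):(2L * n_per), 1L] <- Y[(n_per + 1L):(2L * n_per), 1L] + sep
  })
  list(Y = Y, g = rep(c("a", "b"), each = n_per))
}

test_that("CVA percent variance and axis counts behave as expected", {
  d <- two_cluster_scores(3)
  fit <- cva(d$Y, d$g)
  expect_equal(ncol(fit$axes), 1L)
  expect_equal(fit$percent_variance, 100)
  withr::with_seed(2, Y <- matrix(rnorm(60 * 6), 60L))
  g <- rep(letters[1:4], each = 15L)
  fit4 <- cva(Y, g)
  expect_lte(ncol(fit4$axes), 3L)
  expect_equal(sum(fit4$percent_variance), 100, tolerance = 1e-8)
  expect_true(all(diff(fit4$eigenvalues) <= 1e-12))
})

test_that("CVA axes scale to spherical pooled within-group covariance", {
  d <- two_cluster_scores(4, m = 4L, seed = 3)
  fit <- cva(d$Y, d$g, retain = 4)
  W <- matrix(0, 4L, 4L)
  for (lv in unique(d$g)) {
    Z <- scale(d$Y[d$g == lv, ], scale = FALSE)
    W <- W + crossprod(Z)
  }
  W <- W / (nrow(d$Y) - 2L)
  expect_equal(crossprod(fit$axes, W %*% fit$axes), diag(1),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("with identity within-group covariance CVA matches bgPCA axes", {
  # construct exact identity pooled covariance by whitening
  withr::with_seed(4, Y <- matrix(rnorm(40 * 3), 40L))
  g <- rep(c("a", "b"), each = 20L)
  for (lv in unique(g)) {
    Z <- scale(Y[g == lv, ], scale = FALSE)
    C <- chol(crossprod(Z) / (sum(g == lv) - 1L))
    Y[g == lv, ] <- Z %*% solve(C) +
      rep(colMeans(Y[g == lv, , drop = FALSE]), each = sum(g == lv))
  }
  # make the POOLED within covariance the identity too
  W <- matrix(0, 3L, 3L)
  for (lv in unique(g)) W <- W + crossprod(scale(Y[g == lv, ], scale = FALSE))
  W <- W / (nrow(Y) - 2L)
  Yw <- Y %*% solve(chol(W))
  fit <- cva(Yw, g, retain = 3)
  bp <- between_group_pca(Yw, g)
  cosang <- abs(sum(fit$axes[, 1L] * bp$axes[, 1L])) /
    sqrt(sum(fit$axes[, 1L]^2) * sum(bp$axes[, 1L]^2))
  expect_equal(cosang, 1, tolerance = 1e-6)
})

test_that("CVA group separation agrees with MASS::lda scalings", {
  skip_if_not_installed("MASS")
  d <- two_cluster_scores(2, m = 4L, seed = 5)
  fit <- cva(d$Y, d$g, retain = 4)
  ld <- MASS::lda(d$Y, grouping = d$g)
  cosang <- abs(sum(fit$axes[, 1L] * ld$scaling[, 1L])) /
    sqrt(sum(fit$axes[, 1L]^2) * sum(ld$scaling[, 1L]^2))
  expect_equal(cosang, 1, tolerance = 1e-6)
})

test_that("singular within-group covariance is diagnosed with advice", {
  withr::with_seed(6, Y <- matrix(rnorm(20 * 4), 20L))
  Y[, 2L] <- Y[, 1L]               # perfectly collinear retained columns
  g <- rep(c("a", "b"), each = 10L)
  expect_error(cva(Y, g, retain = 2), "truncation")
})

test_that("jackknife classification separates well-separated clusters", {
  d <- two_cluster_scores(10)   # separation 10x within-sd
  cm <- jackknife_classify(d$Y, d$g)
  expect_equal(cm$accuracy, 100)
  expect_equal(unname(rowSums(cm$table)), unname(as.vector(table(d$g))))
  expect_equal(100 * sum(diag(cm$table)) / sum(cm$table), cm$accuracy)
})

test_that("jackknife refuses singleton groups and offers a cheap variant", {
  d <- two_cluster_scores(5)
  g_bad <- d$g; g_bad[1L] <- "c"
  expect_error(jackknife_classify(d$Y, g_bad), "at least 2")
  cm_fast <- jackknife_classify(d$Y, d$g, refit = "means")
  expect_equal(cm_fast$accuracy, 100)
})

test_that("pairwise PERMANOVA pseudo-F obeys the Gower identity", {
  d <- two_cluster_scores(1.5, n_per = 12L, seed = 7)
  pw <- pairwise_permanova(d$Y, d$g, n_perm = 99, seed = 1)
  expect_equal(pw$tests$F[1L], coord_F(d$Y, d$g), tolerance = 1e-8)
})

test_that("pairwise PERMANOVA agrees with vegan::adonis2", {
  skip_if_not_installed("vegan")
  d <- two_cluster_scores(1, n_per = 10L, seed = 8)
  pw <- pairwise_permanova(d$Y, d$g, n_perm = 999, seed = 2)
  av <- vegan::adonis2(dist(d$Y) ~ g, data = data.frame(g = d$g),
                       permutations = 999)
  expect_equal(pw$tests$F[1L], av$F[1L], tolerance = 1e-8)
  expect_lt(abs(pw$tests$p[1L] - av$`Pr(>F)`[1L]), 0.05)
})

test_that("sampled permutation p matches exhaustive enumeration at n = 6", {
  withr::with_seed(9, Y <- matrix(rnorm(12), 6L))
  g <- factor(rep(c("a", "b"), each = 3L))
  D2 <- as.matrix(dist(Y))^2
  Fobs <- morphodelim:::permanova_F(D2, g)
  perms <- combn(6L, 3L)   # all distinct assignments of 'a'
  Fs <- apply(perms, 2L, function(idx) {
    gp <- factor(ifelse(seq_len(6L) %in% idx, "a", "b"))
    morphodelim:::permanova_F(D2, gp)
  })
  p_exact <- mean(Fs >= Fobs - 1e-12)
  pw <- pairwise_permanova(Y, g, n_perm = 4999, seed = 3)
  mc_err <- 3 * sqrt(p_exact * (1 - p_exact) / 4999) + 1 / 4999
  expect_lt(abs(pw$tests$p[1L] - p_exact), mc_err + 0.01)
})

test_that("pairwise tables carry Bonferroni-corrected, reproducible p", {
  withr::with_seed(10, Y <- matrix(rnorm(30 * 4), 30L))
  g <- rep(letters[1:3], each = 10L)
  pw <- pairwise_permanova(Y, g, n_perm = 199, seed = 4)
  expect_equal(nrow(pw$tests), 3L)
  expect_true(all(pw$tests$p_adj >= pw$tests$p))
  expect_true(all(pw$tests$p_adj <= 1))
  expect_equal(pw$tests$p_adj, pmin(1, pw$tests$p * 3))
  expect_true(all(pw$tests$F >= 0))
  expect_true(isSymmetric(pw$F_matrix))
  expect_true(all(diag(pw$F_matrix) == 0))
  pw2 <- pairwise_permanova(Y, g, n_perm = 199, seed = 4)
  expect_identical(pw$tests$p, pw2$tests$p)
  pw3 <- pairwise_permanova(Y, g, n_perm = 199, seed = 5)
  expect_false(identical(pw$tests$p, pw3$tests$p))
  expect_error(pairwise_permanova(Y, g, n_perm = 9, seed = 1), "at least 99")
  expect_error(pairwise_permanova(Y, c(g[-1L], "solo"), n_perm = 99,
                                  seed = 1), "fewer than 2")
})
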