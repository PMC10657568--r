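make_planted <- function(seed, species_scale, sigma = 0.01,
                         n_specimens = 10L, n_replicates = 2L) {
  simulate_shapes(shape_sim_spec(n_species = 2L, n_sites = 2L,
                                 n_specimens = n_specimens,
                                 n_replicates = n_replicates,
                                 species_scale = species_scale,
                                 site_scale = 0.005, sigma = sigma,
                                 sigma_rep = 0.002, seed = seed))
}

test_that("ANOVA table partitions the total sum of squares", {
  al <- gpa(make_planted(31, species_scale = 0.03, n_specimens = 4L))
  tab <- procrustes_anova(al, c("species", "site", "replicate_id"),
                          n_perm = 99, seed = 1)
  n_fac <- nrow(tab) - 2L
  expect_equal(sum(tab$SS[seq_len(n_fac + 1L)]), tab$SS[n_fac + 2L],
               tolerance = 1e-6)
  expect_equal(sum(tab$Rsq_pct[seq_len(n_fac + 1L)]), 100, tolerance = 1e-6)
  expect_true(all(tab$p[seq_len(n_fac)] > 0 & tab$p[seq_len(n_fac)] <= 1))
  expect_equal(tab$Df[n_fac + 2L], al$n - 1L)
  # fixed seed => bit-reproducible p-values
  tab2 <- procrustes_anova(al, c("species", "site", "replicate_id"),
                           n_perm = 99, seed = 1)
  expect_identical(tab$p, tab2$p)
  # and different seeds perturb mid-range p-values (null data)
  al_null <- gpa(null_shape_dataset(30, n_per_species = 10L))
  ps <- vapply(1:4, function(s)
    procrustes_anova(al_null, "species", n_perm = 999,
                     seed = s)["species", "p"], numeric(1))
  expect_gt(length(unique(ps)), 1L)
  expect_lt(max(ps) - min(ps), 0.1)   # but only within Monte-Carlo noise
})

test_that("a planted species effect dominates the decomposition", {
  al <- gpa(make_planted(32, species_scale = 0.1, sigma = 0.01))
  tab <- procrustes_anova(al, c("species", "site", "replicate_id"),
                          n_perm = 999, seed = 5)
  expect_gt(tab["species", "Rsq_pct"], 50)
  expect_lte(tab["species", "p"], 0.001)
  # replicate (digitization) error is a small share, as in real data
  expect_lt(tab["replicate_id", "Rsq_pct"], 5)
})

test_that("species percent SS is monotone in the planted effect size", {
  sigma <- 0.01
  pct <- vapply(c(0, 0.5, 1, 2), function(mult) {
    al <- gpa(make_planted(33, species_scale = mult * sigma, sigma = sigma,
                           n_specimens = 6L))
    procrustes_anova(al, "species", n_perm = 99, seed = 1)["species",
                                                           "Rsq_pct"]
  }, numeric(1))
  expect_true(all(diff(pct) > 0))
})

test_that("ANOVA rejects unusable factor specifications", {
  al <- gpa(make_planted(34, species_scale = 0.02, n_specimens = 3L))
  expect_error(procrustes_anova(al, "nonexistent", seed = 1), "no label")
  al$labels$constant <- "x"
  expect_error(procrustes_anova(al, "constant", seed = 1), "constant")
  expect_error(procrustes_anova(al, "species", n_perm = 10, seed = 1),
               "at least 99")
})

test_that("relative warps conserve variance and are an isometry", {
  al <- gpa(make_planted(35, species_scale = 0.02, n_specimens = 5L))
  w <- relative_warps(al)
  Y <- morphodelim:::as_score_matrix(al)
  Yc <- sweep(Y, 2L, colMeans(Y))
  expect_equal(sum(w$eigenvalues), sum(Yc^2) / (nrow(Y) - 1L),
               tolerance = 1e-10)
  expect_true(all(diff(w$eigenvalues) <= 1e-12))
  expect_equal(sum(w$percent_variance), 100, tolerance = 1e-8)
  # pairwise distances preserved in full score space
  expect_equal(as.matrix(dist(w$scores)), as.matrix(dist(Y)),
               tolerance = 1e-8, ignore_attr = TRUE)
  # agrees with the stats::prcomp eigenvalue spectrum
  pr <- prcomp(Y)
  m <- length(w$eigenvalues)
  expect_equal(w$eigenvalues, pr$sdev[seq_len(m)]^2, tolerance = 1e-8)
})

test_that("warp spectra respect rank bounds and rotation invariance", {
  withr::with_seed(36, {
    ds <- shape_dataset(lapply(1:3, function(i)
      triangle + matrix(rnorm(6, sd = 0.05), 3L, 2L)))
  })
  w <- relative_warps(gpa(ds))
  expect_lte(length(w$eigenvalues), 2L)   # n = 3 => at most 2 components
  # rotating the data in score space leaves eigenvalues unchanged
  al <- gpa(make_planted(37, species_scale = 0.02, n_specimens = 4L))
  Y <- morphodelim:::as_score_matrix(al)
  withr::with_seed(1, Q <- qr.Q(qr(matrix(rnorm(ncol(Y)^2), ncol(Y)))))
  w1 <- relative_warps(Y)
  w2 <- relative_warps(Y %*% Q)
  expect_equal(w1$eigenvalues, w2$eigenvalues, tolerance = 1e-8)
})

test_that("between-group PCA reduces to the group-mean geometry", {
  withr::with_seed(38, {
    Y <- rbind(matrix(rnorm(40, 0, 0.3), 10L),
               matrix(rnorm(40, 2, 0.3), 10L))
  })
  g <- rep(c("a", "b"), each = 10L)
  p <- between_group_pca(Y, g)
  expect_equal(ncol(p$axes), 1L)          # two groups -> one axis
  dmean <- colMeans(Y[g == "b", ]) - colMeans(Y[g == "a", ])
  cosang <- abs(sum(p$axes[, 1L] * dmean)) /
    sqrt(sum(p$axes[, 1L]^2) * sum(dmean^2))
  expect_equal(cosang, 1, tolerance = 1e-10)
  # group means project exactly onto their score-space positions
  proj <- sweep(rowsum(Y, g) / 10, 2L, p$center) %*% p$axes
  expect_equal(unname(proj), unname(p$group_means), tolerance = 1e-10)
  # averaging projected individuals reproduces the group-mean scores
  expect_equal(unname(rowsum(p$scores, g) / 10), unname(p$group_means),
               tolerance = 1e-10)
})

test_that("between-group PCA handles degenerate group structure", {
  Y <- matrix(rnorm(60), 20L)
  expect_error(between_group_pca(Y, rep("a", 20L)), "2 groups")
  # identical group means: all eigenvalues ~ 0
  Y2 <- rbind(diag(3), diag(3))
  p <- between_group_pca(Y2, rep(c("a", "b"), each = 3L))
  expect_lt(max(p$eigenvalues), 1e-20)
  # axes never exceed groups - 1
  withr::with_seed(39, Y3 <- matrix(rnorm(300), 30L))
  g3 <- rep(letters[1:5], each = 6L)
  p3 <- between_group_pca(Y3, g3)
  expect_lte(ncol(p3$axes), 4L)
})
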