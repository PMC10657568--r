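# Shared fixtures and independent oracles, all built in code.

rigid_copy <- function(config, angle, scale = 1, shift = c(0, 0)) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2L, 2L)
  out <- scale * config %*% R
  out[, 1L] <- out[, 1L] + shift[1L]
  out[, 2L] <- out[, 2L] + shift[2L]
  out
}

random_config <- function(k, sd = 1) matrix(rnorm(2L * k, sd = sd), k, 2L)

triangle <- rbind(c(0, 0), c(2, 0), c(0.7, 1.4))

# dataset of rigid/scale/translate copies of one base shape
nuisance_dataset <- function(base, n, seed = 1) {
  withr::with_seed(seed, {
    cfgs <- lapply(seq_len(n), function(i)
      rigid_copy(base, runif(1, 0, 2 * pi), runif(1, 0.5, 2),
                 runif(2, -3, 3)))
  })
  shape_dataset(cfgs)
}

center_unit <- function(config) {
  config <- sweep(config, 2L, colMeans(config))
  config / sqrt(sum(config^2))
}

# grid-search oracle for the optimal rotation of centered A onto B under
# the rigid_copy() parametrization: SS(theta) has a closed form in two
# cross sums, scanned on a fine grid
grid_search_angle <- function(A, B, step = 0.001) {
  th <- seq(0, 2 * pi, by = step)
  c1 <- sum(A * B)
  c2 <- sum(A[, 2L] * B[, 1L] - A[, 1L] * B[, 2L])
  ss <- sum(A^2) + sum(B^2) - 2 * (c1 * cos(th) + c2 * sin(th))
  th[which.min(ss)]
}

# O(n^3) brute-force single-linkage agglomeration (repeated minimum search)
brute_single_linkage <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(Inf, 0, 0)
    for (i in seq_len(length(clusters) - 1L))
      for (j in (i + 1L):length(clusters)) {
        d <- min(D[clusters[[i]], clusters[[j]]])
        if (d < best[1L]) best <- c(d, i, j)
      }
    heights <- c(heights, best[1L])
    clusters[[best[2L]]] <- c(clusters[[best[2L]]], clusters[[best[3L]]])
    clusters[[best[3L]]] <- NULL
  }
  sort(heights)
}

# brute-force threshold clustering: transitive closure of the d <= t relation
brute_threshold_components <- function(D, t) {
  n <- nrow(D)
  adj <- (D <= t)
  diag(adj) <- TRUE
  reach <- adj
  for (v in seq_len(n)) reach <- reach | (reach %*% reach) > 0
  comp <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (comp[i]) next
    cl <- cl + 1L
    comp[reach[i, ] & comp == 0L] <- cl
  }
  comp
}

# Rand index between two partitions (1 iff identical up to relabeling)
rand_index <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  mean(same_a == same_b)
}

# one-way PERMANOVA pseudo-F computed directly from centered coordinates
# (independent of the distance-matrix route)
coord_F <- function(Y, g) {
  g <- factor(g)
  grand <- colMeans(Y)
  ssb <- 0; ssw <- 0
  for (lv in levels(g)) {
    sel <- g == lv
    m <- colMeans(Y[sel, , drop = FALSE])
    ssb <- ssb + sum(sel) * sum((m - grand)^2)
    ssw <- ssw + sum(sweep(Y[sel, , drop = FALSE], 2L, m)^2)
  }
  (ssb / (nlevels(g) - 1L)) / (ssw / (nrow(Y) - nlevels(g)))
}

# null shape dataset: n independent specimens, no species/site effect
null_shape_dataset <- function(seed, n_per_species = 20L, sigma = 0.01) {
  simulate_shapes(shape_sim_spec(n_species = 2L, n_sites = 1L,
                                 n_specimens = n_per_species,
                                 n_replicates = 1L, species_scale = 0,
                                 site_scale = 0, sigma = sigma,
                                 seed = seed))
}
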