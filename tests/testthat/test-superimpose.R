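test_that("centroid size evaluates the defining formula and is homogeneous", {
  expect_equal(centroid_size(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))),
               sqrt(2))
  withr::with_seed(5, cfg <- random_config(7))
  expect_equal(centroid_size(3.7 * cfg), 3.7 * centroid_size(cfg))
  expect_equal(centroid_size(matrix(2, 4, 2)), 0)
})

test_that("exactly superimposable copies align onto the consensus", {
  ds <- nuisance_dataset(triangle, 6, seed = 2)
  al <- gpa(ds)
  spread <- max(abs(sweep(al$coords, c(1L, 2L), al$consensus)))
  expect_lt(spread, 1e-9)
  expect_lt(max(al$rho), 1e-7)
})

test_that("aligned configurations are centered with unit size pre-projection", {
  withr::with_seed(8, {
    ds <- shape_dataset(lapply(1:5, function(i)
      triangle + matrix(rnorm(6, sd = 0.1), 3L, 2L)))
  })
  al <- gpa(ds, project_to_tangent = FALSE)
  for (i in seq_len(al$n)) {
    expect_lt(max(abs(colMeans(al$coords[, , i]))), 1e-9)
    expect_equal(sqrt(sum(al$coords[, , i]^2)), 1, tolerance = 1e-9)
  }
  # consensus is the coordinate-wise mean of the aligned configurations
  expect_equal(apply(al$coords, c(1L, 2L), mean), al$consensus,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("pairwise optimal rotation matches a fine grid search", {
  withr::with_seed(11, {
    for (rep in 1:10) {
      A <- center_unit(random_config(8))
      B <- center_unit(random_config(8))
      R <- morphodelim:::rotation_onto(A, B)
      th_grid <- grid_search_angle(A, B)
      ss_closed <- sum((A %*% R - B)^2)
      ss_grid <- sum((rigid_copy(A, th_grid) - B)^2)
      expect_lt(abs(ss_closed - ss_grid), 1e-5)
      expect_lte(ss_closed, ss_grid + 1e-12)
    }
  })
})

test_that("GPA output is invariant to nuisance transforms of inputs", {
  sim <- simulate_shapes(shape_sim_spec(seed = 7))
  sliders <- attr(sim, "sliders")
  al <- gpa(sim, sliders = sliders)
  tampered <- sim
  withr::with_seed(3, {
    for (i in seq_len(sim$n)) {
      tampered$coords[, , i] <- rigid_copy(sim$coords[, , i],
                                           runif(1, 0, 2 * pi),
                                           runif(1, 0.5, 2),
                                           runif(2, -5, 5))
    }
  })
  al2 <- gpa(tampered, sliders = sliders)
  expect_lt(max(abs(al$coords - al2$coords)), 1e-8)
  expect_lt(max(abs(al$consensus - al2$consensus)), 1e-8)
})

test_that("plain GPA is a fixed point on its own output", {
  withr::with_seed(9, {
    ds <- shape_dataset(lapply(1:8, function(i)
      triangle + matrix(rnorm(6, sd = 0.08), 3L, 2L)))
  })
  al <- gpa(ds, project_to_tangent = FALSE)
  al2 <- gpa(shape_dataset(al$coords, ids = al$ids),
             project_to_tangent = FALSE)
  expect_lt(max(abs(al$coords - al2$coords)), 1e-6)
})

test_that("no single configuration can improve by re-rotation", {
  withr::with_seed(10, {
    ds <- shape_dataset(lapply(1:6, function(i)
      triangle + matrix(rnorm(6, sd = 0.05), 3L, 2L)))
  })
  al <- gpa(ds, project_to_tangent = FALSE)
  for (i in seq_len(al$n)) {
    ss0 <- sum((al$coords[, , i] - al$consensus)^2)
    for (dth in c(-0.01, 0.01)) {
      ss <- sum((rigid_copy(al$coords[, , i], dth) - al$consensus)^2)
      expect_gte(ss, ss0 - 1e-12)
    }
  }
})

test_that("degenerate configurations are rejected by name", {
  cfgs <- lapply(1:3, function(i) triangle)
  cfgs[[2L]] <- matrix(1, 3L, 2L)
  ds <- shape_dataset(cfgs, ids = c("ok1", "flat", "ok2"))
  expect_error(gpa(ds), "flat")
})

test_that("sliding reduces bending energy against the consensus", {
  sim <- simulate_shapes(shape_sim_spec(seed = 13, sigma = 0.01))
  sliders <- attr(sim, "sliders")
  plain <- gpa(sim, project_to_tangent = FALSE)
  B <- morphodelim:::bending_energy_matrix(plain$consensus)
  be <- function(al) {
    vapply(seq_len(al$n), function(i) {
      d <- al$coords[, , i] - al$consensus
      sum(d[, 1L] * (B %*% d[, 1L])) + sum(d[, 2L] * (B %*% d[, 2L]))
    }, numeric(1))
  }
  slid_X <- morphodelim:::slide_pass(plain$coords, plain$consensus, sliders,
                                     "bending_energy")
  be_before <- be(plain)
  be_after <- vapply(seq_len(plain$n), function(i) {
    d <- slid_X[, , i] - plain$consensus
    sum(d[, 1L] * (B %*% d[, 1L])) + sum(d[, 2L] * (B %*% d[, 2L]))
  }, numeric(1))
  expect_true(all(be_after <= be_before + 1e-12))
  expect_lt(mean(be_after), mean(be_before))
})

test_that("sliding is a no-op at the optimum and with empty sliders", {
  sliders <- default_template()$sliders
  ds <- nuisance_dataset(default_template()$points, 4, seed = 21)
  al <- gpa(ds)  # identical shapes: every configuration equals the consensus
  slid <- morphodelim:::slide_pass(al$coords, al$consensus, sliders,
                                   "bending_energy")
  expect_lt(max(abs(slid - al$coords)), 1e-8)
  empty <- sliders_spec(matrix(integer(0), 0L, 3L), ds$k)
  al_e <- slide_semilandmarks(al, empty)
  expect_identical(al_e$coords, al$coords)
  expect_error(
    morphodelim:::slide_pass(al$coords, al$consensus, sliders, "nonsense"))
})

test_that("procrustes_distance sliding projects residuals onto the chord", {
  sim <- simulate_shapes(shape_sim_spec(seed = 17, n_specimens = 3))
  sliders <- attr(sim, "sliders")
  al <- gpa(sim, project_to_tangent = FALSE)
  slid <- morphodelim:::slide_pass(al$coords, al$consensus, sliders,
                                   "procrustes_distance")
  d_before <- sum((al$coords - array(al$consensus, dim = dim(al$coords)))^2)
  d_after <- sum((slid - array(al$consensus, dim = dim(al$coords)))^2)
  expect_lte(d_after, d_before)
})

test_that("tangent distances track Procrustes distances for small variation", {
  withr::with_seed(19, {
    base <- default_template()$points
    ds <- shape_dataset(lapply(1:30, function(i)
      base + matrix(rnorm(66, sd = 0.001), 33L, 2L)))
  })
  tc <- tangent_check(gpa(ds))
  expect_gte(tc$slope, 0.999)
  expect_lte(tc$slope, 1 + 1e-9)
  expect_gt(tc$correlation, 0.9999)
})

test_that("tangent check slope never exceeds 1 and needs variation", {
  al <- gpa(simulate_shapes(shape_sim_spec(seed = 23, sigma = 0.02)))
  tc <- tangent_check(al)
  expect_lte(tc$slope, 1 + 1e-9)
  expect_gte(tc$correlation, 0)
  expect_lte(tc$correlation, 1)
  # zero shape variation leaves the regression undefined
  ds <- nuisance_dataset(triangle, 5, seed = 4)
  expect_error(tangent_check(gpa(ds)), "no shape variation")
  expect_error(tangent_check(gpa(ds[1:2])), "at least 3")
})
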