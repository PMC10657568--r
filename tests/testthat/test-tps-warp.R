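test_that("the TPS warp interpolates landmarks exactly", {
  withr::with_seed(1, {
    ref <- random_config(9)
    tgt <- ref + matrix(rnorm(18, sd = 0.1), 9L, 2L)
  })
  w <- fit_tps(ref, tgt)
  expect_lt(max(abs(warp_points(w, ref) - tgt)), 1e-8)
})

test_that("affine targets have vanishing weights and zero bending energy", {
  withr::with_seed(2, ref <- random_config(8))
  w_id <- fit_tps(ref, ref)
  expect_lt(max(abs(w_id$weights)), 1e-8)
  expect_equal(w_id$bending_energy, 0)
  expect_equal(w_id$affine, cbind(c(0, 0), diag(2)), tolerance = 1e-8)
  A <- matrix(c(1.4, 0.2, -0.3, 0.8), 2L, 2L)
  w_aff <- fit_tps(ref, ref %*% A + 2.5)
  expect_lt(max(abs(w_aff$weights)), 1e-8)
  expect_equal(bending_energy(w_aff), 0)
})

test_that("collinear references are rejected", {
  ref <- cbind(1:5, 2 * (1:5) + 1)
  expect_error(fit_tps(ref, ref + 0.1), "collinear")
})

test_that("bending energy grows with a single landmark displacement", {
  ref <- rbind(c(0, 0), c(1, 0), c(2, 0.1), c(0, 1), c(1, 1.1), c(2, 1),
               c(1, 0.5))
  be <- vapply(c(0.01, 0.02, 0.04), function(d) {
    tgt <- ref
    tgt[7L, 2L] <- tgt[7L, 2L] + d
    fit_tps(ref, tgt)$bending_energy
  }, numeric(1))
  expect_true(all(diff(be) > 0))
})

test_that("bending energy matches quadrature of squared second derivatives", {
  # the integral over the plane of f_xx^2 + 2 f_xy^2 + f_yy^2 equals
  # 16*pi * w'Kw under the r^2 log r^2 kernel.  The oracle differentiates
  # the kernel analytically (independent of the fitted quadratic form)
  # and integrates by nested adaptive quadrature; the integrand has
  # integrable log^2 peaks at the landmarks, which adaptive subdivision
  # handles where a uniform grid cannot.
  withr::with_seed(3, {
    ref <- matrix(runif(12), 6L, 2L)
    tgt <- ref + matrix(rnorm(12, sd = 0.05), 6L, 2L)
  })
  w <- fit_tps(ref, tgt)
  W <- w$weights
  dens <- function(x, y) {
    pts <- cbind(x, y)
    dx <- outer(pts[, 1L], ref[, 1L], "-")
    dy <- outer(pts[, 2L], ref[, 2L], "-")
    u <- pmax(dx^2 + dy^2, 1e-300)
    lu <- log(u)
    fxx <- (2 * lu + 2 + 4 * dx^2 / u) %*% W
    fyy <- (2 * lu + 2 + 4 * dy^2 / u) %*% W
    fxy <- (4 * dx * dy / u) %*% W
    rowSums(fxx^2) + 2 * rowSums(fxy^2) + rowSums(fyy^2)
  }
  half <- 6
  ctr <- colMeans(ref)
  inner <- function(x) vapply(x, function(xx)
    stats::integrate(function(y) dens(xx, y), ctr[2L] - half,
                     ctr[2L] + half, subdivisions = 300L, rel.tol = 1e-5,
                     stop.on.error = FALSE)$value, numeric(1))
  total <- stats::integrate(inner, ctr[1L] - half, ctr[1L] + half,
                            subdivisions = 300L, rel.tol = 1e-5,
                            stop.on.error = FALSE)$value
  expect_equal(total, 16 * pi * w$bending_energy, tolerance = 0.05)
})

test_that("bending energy is rigid-invariant and scales quadratically", {
  withr::with_seed(4, {
    ref <- random_config(7)
    tgt <- ref + matrix(rnorm(14, sd = 0.1), 7L, 2L)
  })
  be0 <- fit_tps(ref, tgt)$bending_energy
  be_rot <- fit_tps(ref, rigid_copy(tgt, 0.7, 1, c(3, -2)))$bending_energy
  expect_equal(be_rot, be0, tolerance = 1e-9)
  # scaling the target scales the nonaffine residual linearly, the
  # quadratic form quadratically
  be_sc <- fit_tps(ref, 2 * tgt)$bending_energy
  expect_equal(be_sc, 4 * be0, tolerance = 1e-9)
})

test_that("the analytic Jacobian matches central finite differences", {
  withr::with_seed(5, {
    ref <- random_config(10)
    tgt <- ref + matrix(rnorm(20, sd = 0.08), 10L, 2L)
    pts <- matrix(runif(200, -1, 1), 100L, 2L)
  })
  w <- fit_tps(ref, tgt)
  J <- morphodelim:::tps_jacobian(w, pts)
  h <- 1e-5
  for (i in seq_len(nrow(pts))) {
    p <- pts[i, ]
    dx <- (warp_points(w, rbind(p + c(h, 0))) -
             warp_points(w, rbind(p - c(h, 0)))) / (2 * h)
    dy <- (warp_points(w, rbind(p + c(0, h))) -
             warp_points(w, rbind(p - c(0, h)))) / (2 * h)
    expect_lt(max(abs(c(J[i, 1L] - dx[1L], J[i, 2L] - dy[1L],
                        J[i, 3L] - dx[2L], J[i, 4L] - dy[2L]))), 1e-4)
  }
})

test_that("deformation grids: identity gives 1, uniform scaling gives s^2", {
  withr::with_seed(6, ref <- random_config(8))
  g_id <- jacobian_grid(fit_tps(ref, ref), c(8L, 8L))
  expect_lt(max(abs(g_id$jacobian - 1)), 1e-9)
  s <- 1.7
  g_sc <- jacobian_grid(fit_tps(ref, s * ref), c(8L, 8L))
  expect_lt(max(abs(g_sc$jacobian - s^2)), 1e-9)
  expect_error(jacobian_grid(fit_tps(ref, ref), c(1L, 8L)), "resolution")
  expect_error(jacobian_grid(fit_tps(ref, ref), c(8L, 8L),
                             bbox = c(0, 0, 0, 1)), "degenerate")
})

test_that("grids along an ordination axis vary smoothly in the magnitude", {
  withr::with_seed(7, {
    ref <- default_template()$points
    axis <- matrix(rnorm(66, sd = 1), 33L, 2L)
    axis <- axis / sqrt(sum(axis^2))
  })
  dets <- lapply(c(-0.02, -0.01, 0.01, 0.02), function(cc)
    axis_deformation(ref, axis, cc, resolution = c(10L, 10L))$grid$jacobian)
  for (d in dets) expect_true(all(d > 0))   # no fold-over at small magnitudes
  # half the magnitude gives roughly half the log-expansion, cell-wise
  expect_lt(mean(abs(log(dets[[4L]]) - 2 * log(dets[[3L]]))),
            0.1 * mean(abs(log(dets[[4L]]))))
})
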