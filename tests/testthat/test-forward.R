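# Dipole forward model: quadratic-LS gradients, transfer matrix, WCT
# referencing.

test_that("quadratic gradient fit is exact for linear and constant fields", {
  m <- small_mesh()
  co <- m$node_coords
  vm_lin <- 2 * co[, 1] + 3 * co[, 2] + 4 * co[, 3]
  for (node in c(1, 57, 200)) {
    g <- fit_quadratic_gradient(m, vm_lin, node)
    expect_equal(g$gradient, c(2, 3, 4), tolerance = 1e-8)
    expect_gte(g$n_stencil, 9)
  }
  g0 <- fit_quadratic_gradient(m, rep(5, nrow(co)), 10)
  expect_equal(g0$gradient, c(0, 0, 0), tolerance = 1e-12)
})

test_that("quadratic gradient matches an independent normal-equations solve", {
  # oracle: explicit normal equations on the same stencil
  m <- small_mesh()
  co <- m$node_coords
  vm <- co[, 1]^2                        # d/dx = 2x
  for (node in c(5, 99)) {
    fit <- fit_quadratic_gradient(m, vm, node)
    stencil <- afdriverloc:::.gradient_stencil(m, node)
    dx <- co[stencil, , drop = FALSE] -
      matrix(co[node, ], length(stencil), 3, byrow = TRUE)
    X <- cbind(dx, dx^2, dx[, 1] * dx[, 2], dx[, 2] * dx[, 3],
               dx[, 1] * dx[, 3])
    b <- vm[stencil] - vm[node]
    cc <- solve(t(X) %*% X, t(X) %*% b)
    # agreement relative to the gradient scale (the normal equations
    # square the stencil's condition number)
    scale <- max(abs(fit$gradient))
    expect_lt(max(abs(fit$gradient - as.numeric(cc[1:3]))) / scale, 1e-6)
    # quadratic fit recovers d/dx = 2 x0
    expect_lt(abs(fit$gradient[1] - 2 * co[node, 1]) / scale, 1e-6)
    expect_lt(max(abs(fit$gradient[2:3])) / scale, 1e-6)
  }
})

test_that("dipole_potential has the right structure", {
  m <- small_mesh()
  n <- nrow(m$node_coords)
  zero_g <- matrix(0, n, 3)
  expect_equal(dipole_potential(m, zero_g, c(300, 0, 0)), 0)
  # single source, fixed gradient: |V| ~ 1/r^2
  g <- matrix(0, n, 3)
  g[1, ] <- c(1, 0, 0)
  w <- rep(0, n); w[1] <- 1
  p0 <- m$node_coords[1, ]
  dir <- c(1, 0, 0)
  v1 <- dipole_potential(m, g, p0 + 200 * dir, weights = w)
  v2 <- dipole_potential(m, g, p0 + 400 * dir, weights = w)
  expect_equal(abs(v1) / abs(v2), 4, tolerance = 1e-9)
  # mirror-symmetric opposite sources cancel on the symmetry plane
  g2 <- matrix(0, 2, 3)
  g2[1, ] <- c(0, 0, 1); g2[2, ] <- c(0, 0, -1)
  mesh2 <- list(node_coords = rbind(c(-10, 0, 0), c(10, 0, 0)))
  class(mesh2) <- "atrial_mesh"
  v <- dipole_potential(mesh2, g2, c(0, 50, 0), weights = c(1, 1))
  expect_equal(v, 0, tolerance = 1e-14)
  expect_error(dipole_potential(m, zero_g, m$node_coords[3, ] + 0.1),
               "guard radius")
})

test_that("transfer matrix equals direct per-frame dipole summation", {
  m <- small_mesh()
  torso <- small_torso()
  tm <- small_tm()
  expect_equal(dim(tm$a), c(nrow(torso$electrode_coords), 256L))
  # uniform vm has zero gradient -> zero output
  expect_lt(max(abs(tm$a %*% rep(3.7, 256))), 1e-10)
  # random frame: matrix path vs direct loop (independent oracle)
  set.seed(4)
  vm <- rnorm(256)
  grads <- t(vapply(seq_len(256), function(k)
    fit_quadratic_gradient(m, vm, k)$gradient, numeric(3)))
  w <- node_area_weights(m)
  direct <- vapply(seq_len(nrow(torso$electrode_coords)), function(e)
    dipole_potential(m, grads, torso$electrode_coords[e, ], weights = w),
    numeric(1))
  got <- as.numeric(tm$a %*% vm)
  expect_lt(max(abs(got - direct)) / max(abs(direct)), 1e-10)
})

test_that("WCT referencing zeroes the WCT mean and matches the two-step path", {
  tm <- small_tm()
  set.seed(9)
  x <- matrix(rnorm(256 * 7), 256)
  y <- wct_reference(tm, x)
  expect_lt(max(abs(colMeans(y[tm$wct_indices, , drop = FALSE]))),
            1e-12 * max(abs(y)))
  # oracle: explicit two-step computation (raw forward minus WCT average)
  raw <- tm$a %*% x
  two_step <- sweep(raw, 2, colMeans(raw[tm$wct_indices, , drop = FALSE]))
  expect_lt(max(abs(y - two_step)) / max(abs(two_step)), 1e-12)
  # idempotence: correcting an already-corrected matrix changes nothing
  again <- wct_correct_matrix(tm$a_wct, tm$wct_indices)
  expect_lt(max(abs(again - tm$a_wct)), 1e-12 * max(abs(tm$a_wct)))
  expect_error(wct_correct_matrix(tm$a, integer(0)), "empty")
})

test_that("forward map is linear and decays with torso radius", {
  tm <- small_tm()
  set.seed(2)
  x <- rnorm(256); y <- rnorm(256)
  lhs <- tm$a_wct %*% (2.5 * x - 1.25 * y)
  rhs <- 2.5 * (tm$a_wct %*% x) - 1.25 * (tm$a_wct %*% y)
  expect_lt(max(abs(lhs - rhs)) / max(abs(rhs)), 1e-12)
  m <- small_mesh()
  set.seed(3)
  vmf <- rnorm(256)
  amp <- vapply(c(120, 160, 220, 300), function(r) {
    to <- build_torso(m, radius_x = r, radius_y = r * 0.8)
    max(abs(build_transfer_matrix(m, to)$a_wct %*% vmf))
  }, numeric(1))
  expect_true(all(diff(amp) < 0))
})

test_that("electrodes inside the guard radius are rejected by name", {
  m <- small_mesh()
  torso <- small_torso()
  torso$electrode_coords[5, ] <- m$node_coords[1, ] + 0.01
  expect_error(build_transfer_matrix(m, torso), "guard radius")
})
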