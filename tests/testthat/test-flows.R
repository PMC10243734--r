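# Velocity fields, flow integration, group action, kernel energy, rigid.

test_that("zero velocity integrates to the identity with unit Jacobian", {
  v <- velocity_field(c(8, 8, 6), c(1, 1, 1), nt = 3)
  m <- integrate_flow(v)
  grid <- identity_map(c(8, 8, 6), c(1, 1, 1))
  expect_equal(m$forward, grid$forward)
  expect_equal(m$inverse, grid$forward)
  expect_equal(m$jacobian, array(1, c(8, 8, 6)))
})

test_that("constant velocity integrates to a translation", {
  c0 <- c(0.8, -0.5, 0.3)
  v <- velocity_field(c(14, 14, 10), c(1, 1, 1), nt = 5)
  for (a in 1:3) v$values[, , , a, ] <- c0[a]
  m <- integrate_flow(v)
  # interior points translate exactly (a constant field has no Euler error)
  ctr <- m$forward[7, 7, 5, ] - c(6, 6, 4)
  expect_equal(ctr, c0, tolerance = 1e-12)
  expect_equal(m$inverse[7, 7, 5, ] - c(6, 6, 4), -c0, tolerance = 1e-12)
  expect_equal(m$jacobian[7, 7, 5], 1, tolerance = 1e-10)
})

test_that("forward and inverse maps compose to the identity within
           0.1 voxel for smooth deformations", {
  set.seed(21)
  dims <- c(16L, 16L, 12L)
  sp <- rep(0.5, 3)
  kern <- kernel_spec(1.5)
  v <- velocity_field(dims, sp, nt = 4, kernel = kern)
  v$values <- smooth_field(dims, sp, kern, dim(v$values), 0.3)
  m <- integrate_flow(v)
  expect_true(all(m$jacobian > 0))
  # push interior lattice points forward, then back
  g <- expand.grid(i = 4:12, j = 4:12, k = 3:9)
  pts <- cbind((g$i - 1) * 0.5, (g$j - 1) * 0.5, (g$k - 1) * 0.5)
  fwd <- flow_points(v, pts, "forward")
  back <- flow_points(v, fwd, "inverse")
  err <- sqrt(rowSums((back - pts)^2))
  expect_lt(max(err), 0.1 * 0.5)
})

test_that("deform_image realizes the group action", {
  set.seed(22)
  dims <- c(12L, 12L, 8L)
  vol <- tiny_template(dims, spacing = 1)
  id <- identity_map(dims, rep(1, 3))
  expect_equal(deform_image(vol, id)$data, vol$data)

  # translation on an affine ramp shifts it exactly
  g <- projlddmm:::lattice_points(vol)
  ramp <- image_volume(array(g %*% c(1, 2, 3), dims), rep(1, 3))
  v <- velocity_field(dims, rep(1, 3), nt = 2)
  v$values[, , , 1, ] <- 1
  m <- integrate_flow(v)
  shifted <- deform_image(ramp, m)
  inner <- 3:10
  expect_equal(shifted$data[inner, inner, , 1],
               ramp$data[inner - 1, inner, , 1], tolerance = 1e-10)

  # (phi2 . (phi1 . I)) agrees with composition within interpolation error
  kern <- kernel_spec(2)
  v1 <- velocity_field(dims, rep(1, 3), nt = 3, kernel = kern)
  v1$values <- smooth_field(dims, rep(1, 3), kern, dim(v1$values), 0.4)
  v2 <- velocity_field(dims, rep(1, 3), nt = 3, kernel = kern)
  set.seed(23)
  v2$values <- smooth_field(dims, rep(1, 3), kern, dim(v2$values), 0.4)
  m1 <- integrate_flow(v1)
  m2 <- integrate_flow(v2)
  step_wise <- deform_image(deform_image(vol, m1), m2)
  # composed map: inverse is m1^-1 o m2^-1
  grid <- projlddmm:::lattice_points(vol)
  src <- projlddmm:::map_at(m1, projlddmm:::map_at(m2, grid, "inverse"),
                            "inverse")
  composed <- array(interpolate(vol, src), dim(vol$data))
  inner_idx <- as.vector(array(seq_len(prod(dims)), dims)[3:10, 3:10, 3:6])
  expect_lt(max(abs(step_wise$data[inner_idx] - composed[inner_idx])),
            0.05 * diff(range(vol$data)))
})

test_that("path energy is a positive-definite quadratic form matching a
           dense kernel-solve oracle", {
  v0 <- velocity_field(c(8, 8), c(1, 1), nt = 2)
  expect_equal(path_energy(v0), 0)

  set.seed(24)
  kern <- kernel_spec(1)
  v <- velocity_field(c(8, 6), c(0.5, 0.5), nt = 2, kernel = kern)
  v$values <- smooth_field(c(8, 6), c(0.5, 0.5), kern, dim(v$values), 1)
  e1 <- path_energy(v)
  expect_gt(e1, 0)
  v2 <- v
  v2$values <- 2 * v$values
  expect_equal(path_energy(v2) / e1, 4, tolerance = 1e-10)

  # oracle: dense K matrix built from unit impulses, then solve
  mult <- projlddmm:::kernel_multiplier(kern, c(8L, 6L), c(0.5, 0.5))
  K <- matrix(0, 48, 48)
  for (i in 1:48) {
    e <- array(0, c(8, 6)); e[i] <- 1
    K[, i] <- as.vector(projlddmm:::kernel_apply(e, mult))
  }
  tot <- 0
  for (t in 1:2) for (a in 1:2) {
    x <- as.vector(v$values[, , a, t])
    tot <- tot + sum(x * solve(K, x))
  }
  expect_equal(e1, 0.5 * 0.25 * tot, tolerance = 1e-8)
})

test_that("hilbert gradient step reduces to plain descent in the
           delta-kernel limit and leaves zero fields unchanged", {
  v <- velocity_field(c(8, 8), c(1, 1), nt = 1, kernel = kernel_spec(0.01))
  out <- hilbert_gradient_step(v, array(0, dim(v$values)), 0.1)
  expect_equal(out$values, v$values)

  set.seed(25)
  g <- array(rnorm(8 * 8 * 2), dim(v$values))
  out2 <- hilbert_gradient_step(v, g, 0.1)
  # with a near-delta kernel, K * g = g: v <- -step * g
  expect_equal(out2$values, -0.1 * g, tolerance = 1e-6)
})

test_that("rigid motions act as rotation plus translation and invert", {
  r <- rigid2d(pi / 6, c(1, -2))
  p <- rbind(c(1, 0), c(0, 1), c(2, 3))
  q <- apply_rigid(r, p)
  expect_equal(q[1, ], c(cos(pi / 6) + 1, sin(pi / 6) - 2))
  back <- apply_rigid(rigid_inverse(r), q)
  expect_equal(back, p, tolerance = 1e-12)
  expect_equal(crossprod(r$linear), diag(2), tolerance = 1e-12)
})
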