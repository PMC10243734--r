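# Boundary meshes, Laplace-Beltrami bases, projection and smoothing.
# (voxel_ball lives in helper-oracles.R)

test_that("tri_mesh lumps vertex areas that sum to the surface area", {
  m <- sphere_mesh(1, 2)
  expect_equal(sum(m$vertex_weights), m$area, tolerance = 1e-10)
  expect_error(tri_mesh(m$vertices, m$faces + 10000L), "out of range")
})

test_that("a voxelized ball meshes to a closed genus-0 surface with
           accurate area, and decimation respects the edge target", {
  ball <- voxel_ball()
  r <- 10 * 0.125
  fine <- mesh_from_labels(ball, 1, target_min_edge = 0.25)
  expect_true(projlddmm:::is_closed_manifold(fine$faces))
  # genus 0: V - E + F = 2
  ne <- nrow(unique(projlddmm:::mesh_edges(fine$faces)))
  expect_equal(nrow(fine$vertices) - ne + nrow(fine$faces), 2)
  expect_lt(abs(fine$area - 4 * pi * r^2) / (4 * pi * r^2), 0.1)
  expect_gte(projlddmm:::min_edge_length(fine), 0.25)

  # the default edge target is 6 voxels
  coarse <- mesh_from_labels(ball, 1)
  expect_gte(projlddmm:::min_edge_length(coarse), 6 * 0.125)
  expect_error(mesh_from_labels(ball, 7), "not present")
})

test_that("the Laplace-Beltrami basis starts with the constant
           eigenfunction and is orthonormal in the vertex inner product", {
  m <- sphere_mesh(1, 2)
  lb <- lb_basis(m, 10)
  expect_equal(lb$values[1], 0, tolerance = 1e-8)
  expect_lt(stats::sd(lb$functions[, 1]) /
              abs(mean(lb$functions[, 1])), 1e-6)
  G <- crossprod(lb$functions, lb$functions * m$vertex_weights)
  expect_lt(max(abs(G - diag(10))), 1e-8)
  expect_true(all(diff(lb$values) > -1e-10))
})

test_that("unit-sphere eigenvalues approximate l(l+1) with the spherical
           multiplicities", {
  m <- sphere_mesh(1, 3)       # 642 vertices
  lb <- lb_basis(m, 9)
  expect_equal(lb$values[2:4], rep(2, 3), tolerance = 0.05)
  expect_equal(lb$values[5:9], rep(6, 5), tolerance = 0.05)
})

test_that("non-manifold meshes are rejected", {
  m <- sphere_mesh(1, 1)
  bad <- rbind(m$faces, m$faces[1, ])        # duplicated face
  expect_error(lb_basis(tri_mesh(m$vertices, bad), 4), "manifold")
})

test_that("particle projection assigns mass to nearest vertices,
           conserves totals, and breaks ties toward the lowest index", {
  m <- sphere_mesh(1, 1)
  set.seed(71)
  pts <- m$vertices[c(3, 7, 7), ] * 1.05
  mu <- particle_measure(pts, c(1, 2, 3),
                         cbind(c(2, 0, 1), c(1, 1, 1)), 1)
  pr <- project_to_surface(mu, m)
  expect_equal(sum(pr$g_tau), 3)
  expect_equal(sum(pr$g_a), 6)
  expect_equal(pr$g_a[7], 5)
  expect_equal(pr$g_tau[3], 2)

  # brute-force nearest oracle on random points
  rp <- matrix(rnorm(30), 10, 3)
  mu2 <- particle_measure(rp, rep(1, 10), cbind(rep(1, 10), rep(1, 10)), 1)
  pr2 <- project_to_surface(mu2, m)
  d2 <- as.matrix(dist(rbind(rp, m$vertices)))[1:10, -(1:10)]
  oracle <- apply(d2, 1, which.min)
  expect_equal(pr2$g_a, tabulate(oracle, nrow(m$vertices)),
               ignore_attr = TRUE)

  # exact tie between two vertices: the lowest vertex index wins
  mtie <- tri_mesh(rbind(c(0, 0, 0), c(2, 0, 0), c(1, 2, 0), c(1, -2, 0)),
                   rbind(c(1, 2, 3), c(1, 4, 2)))
  mu_t <- particle_measure(rbind(c(1, 0, 0)), 1, cbind(1, 1), 1)
  prt <- project_to_surface(mu_t, mtie)
  expect_equal(prt$g_a, c(1, 0, 0, 0))

  empty <- particle_measure(matrix(0, 0, 3), numeric(0),
                            matrix(0, 0, 2), 1)
  pre <- project_to_surface(empty, m)
  expect_equal(sum(pre$g_a), 0)
})

test_that("surface smoothing reproduces g at k = 0 with a full basis,
           preserves constants, and attenuates monotonically", {
  m <- sphere_mesh(1, 2)
  full <- lb_basis(m, nrow(m$vertices))
  set.seed(72)
  g <- rnorm(nrow(m$vertices))
  expect_equal(smooth_on_surface(g, full, 0), g, tolerance = 1e-8)

  const <- rep(3.2, nrow(m$vertices))
  lb <- lb_basis(m, 20)
  expect_equal(smooth_on_surface(const, lb, 5), const, tolerance = 1e-8)

  att <- 1 / (1 + 2 * lb$values)
  expect_true(all(diff(att) <= 1e-12))
  expect_error(smooth_on_surface(g, lb, -1), ">= 0")

  # k = 0 conserves the projected totals exactly
  mu <- particle_measure(m$vertices[5:10, ] * 1.1, rep(2, 6),
                         cbind(rep(1, 6), rep(1, 6)), 1)
  pr <- project_to_surface(mu, m)
  sm <- smooth_on_surface(pr$g_tau, full, 0)
  expect_equal(sum(sm), sum(pr$g_tau), tolerance = 1e-8)
})

test_that("surface densities are pointwise ratios, masked where area
           vanishes, and shared smoothing conserves the density total", {
  m <- sphere_mesh(1, 2)
  g_a <- rep(2, nrow(m$vertices))
  expect_equal(surface_density(2 * g_a, g_a), rep(2, nrow(m$vertices)))
  expect_true(is.na(surface_density(c(1, 0), c(0, 1))[1]))

  # a single hot vertex spreads with k, but the weighted total (the
  # coefficient on the constant harmonic, eigenvalue 0) is conserved
  lb <- lb_basis(m, nrow(m$vertices))
  g_tau <- numeric(nrow(m$vertices)); g_tau[11] <- 7
  st <- smooth_on_surface(g_tau, lb, 0.5)
  w <- m$vertex_weights
  expect_gt(sum(st > 1e-4), 10)                       # it spread
  expect_equal(sum(st * w), sum(g_tau * w), tolerance = 1e-8)
})
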