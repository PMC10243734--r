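# Particle measures: construction from pixels, varifold transport, kernel
# resampling, feature reduction, densities.

test_that("fine-scale particles carry pixel areas and one-hot features", {
  lab <- slice_image(array(c(rep(1, 8), rep(2, 8)), c(4, 4, 1)),
                     c(0.5, 0.5))
  mask <- matrix(TRUE, 4, 4); mask[1, 1] <- FALSE
  pts <- data.frame(x = c(0.5, 1.6), y = c(0.4, 1.5))
  mu <- particles_from_slice(mask, pts, lab, 2)
  expect_equal(sum(mu$weights), 15 * 0.25)
  expect_equal(colSums(mu$features[, 1:2]), c(1, 1), ignore_attr = TRUE)
  # area block one-hot by pixel region; zero-weight pixel has w = 0
  expect_equal(mu$weights[1], 0)
  expect_true(all(rowSums(mu$features[, 3:4]) <= 1 + 1e-9))
  # single tissue pixel in region 2 with one tangle: e2 (+) e2 structure
  lab1 <- slice_image(array(2, c(1, 1, 1)), c(0.5, 0.5))
  mu1 <- particles_from_slice(matrix(TRUE, 1, 1),
                              data.frame(x = 0, y = 0), lab1, 2)
  expect_equal(as.vector(mu1$features), c(0, 1, 0, 1))
  # tangle on a zero-weight pixel is assigned with a warning
  expect_warning(particles_from_slice(matrix(FALSE, 1, 1),
    data.frame(x = 0, y = 0), lab1, 2), "zero-weight")
})

test_that("varifold transport moves points, rescales weights by the
           in-plane Jacobian, and conserves the count block", {
  lab <- slice_image(array(1, c(6, 6, 1)), c(0.5, 0.5))
  set.seed(61)
  pts <- data.frame(x = runif(5, 0.2, 2.3), y = runif(5, 0.2, 2.3))
  mu <- particles_from_slice(matrix(TRUE, 6, 6), pts, lab, 1)

  # identity map leaves the measure unchanged
  id2 <- identity_map(c(6L, 6L), c(0.5, 0.5))
  mu_id <- transport(mu, id2)
  expect_equal(mu_id$points, mu$points)
  expect_equal(mu_id$weights, mu$weights)

  # uniform scaling by s multiplies every weight by s^2
  s <- 1.5
  sc <- rigid2d(linear = diag(2) * s)
  mu_s <- transport(mu, sc)
  expect_equal(mu_s$weights, mu$weights * s^2, tolerance = 1e-12)
  expect_equal(colSums(mu_s$features[, 1, drop = FALSE]),
               colSums(mu$features[, 1, drop = FALSE]))

  # a genuine 2D diffeomorphism: counts conserved exactly, weights follow
  # the interpolated Jacobian; inverse transport restores weights
  kern <- kernel_spec(1)
  v <- velocity_field(c(6L, 6L), c(0.5, 0.5), nt = 3, kernel = kern)
  v$values <- smooth_field(c(6L, 6L), c(0.5, 0.5), kern, dim(v$values),
                           0.12)
  m <- integrate_flow(v)
  mu_d <- transport(mu, m)
  expect_equal(sum(mu_d$features[, 1]), sum(mu$features[, 1]))
  minv <- m
  minv$forward <- m$inverse; minv$inverse <- m$forward
  minv$jacobian <- 1 / m$jacobian   # analytic for the round trip check
  mu_back <- transport(mu_d, minv)
  keep <- mu$weights > 0
  expect_lt(max(abs(mu_back$weights[keep] / mu$weights[keep] - 1)), 2e-2)

  # 2D -> 3D chain: embed at a plane, then a 3D map
  mu3 <- transport(mu, list(z_embed(1.25)))
  expect_equal(ncol(mu3$points), 3L)
  expect_equal(unique(mu3$points[, 3]), 1.25)
})

test_that("resampling is the identity on matched nearest-neighbor targets
           and conserves mass and weighted counts", {
  lab <- slice_image(array(1, c(5, 5, 1)), c(0.4, 0.4))
  set.seed(62)
  pts <- data.frame(x = runif(7, 0.1, 1.5), y = runif(7, 0.1, 1.5))
  mu <- particles_from_slice(matrix(TRUE, 5, 5), pts, lab, 1)

  idk <- resample_kernel(mu$points, "nearest_neighbor")
  mu_id <- resample(mu, idk)
  expect_equal(mu_id$weights, mu$weights)
  expect_equal(mu_id$features, mu$features)

  tg <- as.matrix(expand.grid(x = c(0.3, 1.1), y = c(0.3, 1.1)))
  for (kind in c("nearest_neighbor", "gaussian")) {
    k <- resample_kernel(tg, kind, bandwidth = 0.5)
    out <- resample(mu, k)
    expect_lt(abs(sum(out$weights) - sum(mu$weights)), 1e-10)
    expect_lt(abs(sum(out$weights * out$features[, 1]) -
                  sum(mu$weights * mu$features[, 1])), 1e-10)
  }
  expect_error(resample_kernel(tg[0, , drop = FALSE]), "nrow")

  # merge oracle: two unit-weight particles with counts 0 and 2
  mu2 <- particle_measure(rbind(c(0, 0), c(1, 0)), c(1, 1),
                          rbind(c(0, 1), c(2, 1)), 1)
  merged <- resample(mu2, resample_kernel(rbind(c(0.5, 0)),
                                          "nearest_neighbor"))
  expect_equal(merged$weights, 2)
  expect_equal(as.vector(merged$features), c(1, 1))
})

test_that("feature reduction takes weighted first moments", {
  expect_equal(reduce_features(rbind(c(3, 0.5))), c(3, 0.5))
  expect_equal(reduce_features(rbind(c(1, 0), c(3, 1))), c(2, 0.5))
  expect_equal(reduce_features(rbind(c(0, 0), c(4, 0)), c(1, 3))[1], 3)
  expect_warning(z <- reduce_features(rbind(c(1, 1)), 0), "zero")
  expect_equal(z, c(0, 0))
})

test_that("densities follow the count/area formulas and flag undefined
           region densities", {
  mu <- particle_measure(rbind(c(0, 0)), 2,
                         rbind(c(3, 1, 0, 0.5, 0.5, 0)), 3)
  nd <- nft_density(mu)
  expect_equal(nd$total, 2)
  expect_equal(nd$per_region[1, ], c(3, 1, 0))

  zero <- particle_measure(rbind(c(0, 0)), 1,
                           rbind(c(0, 0, 0, 1, 0, 0)), 3)
  ndz <- nft_density(zero)
  expect_equal(ndz$total, 0)

  # doubling the weight halves every density
  mu2 <- mu; mu2$weights <- 2 * mu$weights
  nd2 <- nft_density(mu2)
  expect_equal(nd2$total, nd$total / 2)
  expect_equal(nd2$per_region[1, 1], nd$per_region[1, 1] / 2)

  # counts in a region with zero recorded area are undefined
  bad <- particle_measure(rbind(c(0, 0)), 1,
                          rbind(c(1, 0, 0, 0, 1, 0)), 3)
  expect_warning(ndb <- nft_density(bad), "undefined")
  expect_true(is.na(ndb$per_region[1, 1]))
})
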