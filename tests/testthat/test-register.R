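# Registration drivers, objective gradients, label mapping, metrics.

test_that("dice overlap matches counting oracles", {
  a <- matrix(FALSE, 20, 20); a[3:12, 3:12] <- TRUE
  expect_equal(dice(a, a), 1)
  b <- matrix(FALSE, 20, 20); b[15:18, 15:18] <- TRUE
  expect_equal(dice(a, b), 0)
  shifted <- matrix(FALSE, 20, 20); shifted[8:17, 3:12] <- TRUE
  expect_equal(dice(a, shifted), 0.5)   # 10x10 squares overlapping 5x10
  expect_true(is.na(dice(b & FALSE, b & FALSE)))
})

test_that("hausdorff95 follows the pairwise-distance oracle and is
           symmetric", {
  a <- matrix(FALSE, 12, 12); a[4, 4] <- TRUE
  b <- matrix(FALSE, 12, 12); b[7, 4] <- TRUE
  expect_equal(hausdorff95(a, b, c(0.5, 0.5)), 1.5)
  expect_equal(hausdorff95(b, a, c(0.5, 0.5)),
               hausdorff95(a, b, c(0.5, 0.5)))
  expect_equal(hausdorff95(a, a, c(0.5, 0.5)), 0)
  expect_error(hausdorff95(a, a & FALSE), "non-empty")

  # block vs dilated block: distances concentrate at 1 pixel
  c1 <- matrix(FALSE, 20, 20); c1[5:12, 5:12] <- TRUE
  c2 <- matrix(FALSE, 20, 20); c2[4:13, 4:13] <- TRUE
  expect_lte(hausdorff95(c1, c2, c(1, 1)), sqrt(2))
})

test_that("objective gradients match central finite differences along
           smooth interior perturbations", {
  state <- tiny_state()
  h <- 1e-4
  g3 <- projlddmm:::gradient_v3(state)
  set.seed(12)
  p3 <- smooth_field(c(20L, 20L, 12L), rep(0.5, 3), state$v3$kernel,
                     dim(g3), 1)
  sp1 <- state; sp1$v3$values <- state$v3$values + h * p3
  sm1 <- state; sm1$v3$values <- state$v3$values - h * p3
  fd <- (projlddmm:::total_objective(sp1) -
         projlddmm:::total_objective(sm1)) / (2 * h)
  expect_lt(abs(fd - sum(g3 * p3)) / abs(fd), 1e-3)

  g2 <- projlddmm:::gradient_v2(state, 1)
  p2 <- smooth_field(c(14L, 14L), rep(0.5, 2), kernel_spec(1), dim(g2), 1)
  s21 <- state
  s21$slices[[1]]$v2$values <- state$slices[[1]]$v2$values + h * p2
  s22 <- state
  s22$slices[[1]]$v2$values <- state$slices[[1]]$v2$values - h * p2
  fd2 <- (projlddmm:::total_objective(s21) -
          projlddmm:::total_objective(s22)) / (2 * h)
  expect_lt(abs(fd2 - sum(g2 * p2)) / abs(fd2), 1e-3)
})

# small single-channel stack cut directly from a template
self_stack <- function(tmpl, zs) {
  slice_stack(lapply(zs, function(z) slice_volume(tmpl, z)))
}

test_that("registering a stack cut from the template itself is a fixed
           point with a non-increasing energy trace", {
  tmpl <- tiny_template(c(24L, 24L, 16L), spacing = 0.5)
  stack <- self_stack(tmpl, c(2.2, 3.7, 5.2))
  res <- register_stack(tmpl, stack, registration_config(
    outer_iters = 3L, levels = 1L, contrast_enabled = FALSE,
    mixture_enabled = FALSE, rigid_enabled = FALSE, n_v = 1L, n_u = 1L))
  # displacements stay tiny: the data term is already at its optimum
  m3 <- res$map3
  g <- identity_map(c(24L, 24L, 16L), rep(0.5, 3))
  disp <- sqrt(apply((m3$forward - g$forward)^2, 1:3, sum))
  expect_lt(sqrt(mean(disp^2)), 0.2 * 0.5)
  expect_true(all(diff(res$energy_trace) <= 1e-8))
})

test_that("with the mixture and contrast channels disabled the objective
           reduces to kernel path energy plus plain least squares", {
  tmpl <- tiny_template(c(24L, 24L, 16L), spacing = 0.5)
  stack <- self_stack(tmpl, c(2.2, 3.7))
  cfg <- registration_config(outer_iters = 1L, levels = 1L,
                             contrast_enabled = FALSE,
                             mixture_enabled = FALSE,
                             rigid_enabled = FALSE, n_v = 0L, n_u = 0L,
                             sigma = rep(1 / sqrt(2), 3))
  res <- register_stack(tmpl, stack, cfg)
  st <- res$state
  total <- projlddmm:::total_objective(st)
  # independent evaluation of the reduced form: sum |J_n - P_n I|^2 over
  # pixels (sigma = 1/sqrt(2) makes 1/(2 sigma^2) = 1), plus constants
  # from the class normalizer and uniform prior
  ssd <- 0; npix <- 0
  for (n in 1:2) {
    obs <- projlddmm:::chain_forward(st, n)$obs
    ssd <- ssd + sum((st$slices[[n]]$pred - obs)^2)
    npix <- npix + length(obs)
  }
  const <- npix * (log(1 / sqrt(2)) * 1 + log(3))
  penalty <- st$w_v * path_energy(st$v3) +
    sum(vapply(st$slices, function(s) st$w_u * path_energy(s$v2),
               numeric(1)))
  expect_equal(total, penalty + ssd + const, tolerance = 1e-10)
})

test_that("map_labels carries labels through the chain with
           nearest-neighbor sampling and creates no new labels", {
  tmpl <- tiny_template(c(24L, 24L, 16L), spacing = 0.5)
  lab <- tmpl
  lab$data <- array(as.double(tmpl$data > 0.5) +
                    as.double(tmpl$data > 0.8), dim(tmpl$data))
  stack <- self_stack(tmpl, c(3.7))
  res <- register_stack(tmpl, stack, registration_config(
    outer_iters = 1L, levels = 1L, contrast_enabled = FALSE,
    mixture_enabled = FALSE, rigid_enabled = FALSE, n_v = 0L, n_u = 0L))
  got <- map_labels(lab, res, 1)
  # identity result: the plain nearest-neighbor plane of the labels
  want <- interpolate(lab, cbind(projlddmm:::lattice_points(
    slice_image(array(0, c(24, 24, 1)), rep(0.5, 2))), 3.7),
    method = "nearest")
  expect_equal(as.vector(got$data), as.vector(want))
  expect_true(all(unique(as.vector(got$data)) %in%
                  unique(as.vector(lab$data))))
  expect_error(map_labels(lab, res, 99), "slice index")

  # a pure translation maps labels by the same translation on-lattice
  res2 <- res
  res2$state$slices[[1]]$rigid <- rigid2d(0, c(0.5, 0))
  got2 <- map_labels(lab, res2, 1)
  expect_equal(got2$data[2:24, , 1], got$data[1:23, , 1])
})

test_that("rigid Gauss-Newton recovers a small in-plane motion", {
  tmpl <- tiny_template(c(24L, 24L, 16L), spacing = 0.5)
  sl0 <- slice_volume(tmpl, 3.7)
  truth <- rigid2d(0.06, c(0.4, -0.3))
  # build the observed slice by pulling the template plane through truth
  geom <- slice_image(array(0, c(24, 24, 1)), rep(0.5, 2))
  pts <- projlddmm:::lattice_points(geom)
  src <- apply_rigid(rigid_inverse(truth), pts)
  obs <- interpolate(sl0, src)
  target <- slice_image(array(obs, c(24, 24, 1)), rep(0.5, 2),
                        z_position = 3.7)
  res <- register_stack(tmpl, slice_stack(list(target)),
    registration_config(outer_iters = 6L, levels = 1L,
                        contrast_enabled = FALSE, mixture_enabled = FALSE,
                        diffeo2d_enabled = FALSE, n_v = 0L, n_u = 0L,
                        n_rigid = 3L))
  est <- res$slices[[1]]$rigid
  expect_lt(abs(est$theta - truth$theta), 0.1 * abs(truth$theta))
  expect_lt(max(abs(est$translation - truth$translation)), 0.05)
})
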