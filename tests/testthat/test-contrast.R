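# Scattering features, PCA basis, and least-squares contrast coefficients.

test_that("scattering path counts follow the path-enumeration formula
           across configurations", {
  for (J in 1:3) for (L in 1:3) for (ord in 1:2) {
    cfg <- scattering_config(J, L, ord)
    # independent enumeration: order 0; all (j1,l1); all (j1,l1)->(j2,l2)
    # with j2 > j1
    n1 <- J * L
    n2 <- if (ord == 2) sum(outer(0:(J - 1), 0:(J - 1), "<")) * L^2 else 0
    expect_equal(scattering_path_count(cfg), 1 + n1 + n2)
  }
  set.seed(41)
  img <- slice_image(array(rnorm(32 * 32 * 2), c(32, 32, 2)),
                     spacing = c(0.05, 0.05))
  st <- scatter(img, scattering_config(2, 2, 2), target_spacing = 0.2)
  expect_equal(n_channels(st), 2 * scattering_path_count(
    scattering_config(2, 2, 2)))
})

test_that("a constant image produces a constant order-0 channel and zero
           higher-order channels", {
  cimg <- slice_image(array(2.5, c(32, 32, 1)), spacing = c(0.05, 0.05))
  st <- scatter(cimg, scattering_config(2, 3, 2), target_spacing = 0.2)
  expect_equal(range(st$data[, , 1]), c(2.5, 2.5), tolerance = 1e-10)
  expect_lt(max(abs(st$data[, , -1])), 1e-6 * 2.5)
  expect_error(scatter(slice_image(matrix(0, 2, 2), c(1, 1)),
                       scattering_config(3, 1, 1)), "smaller than 2")
})

test_that("scattering features are far more translation-stable than raw
           pixels", {
  set.seed(42)
  x <- matrix(rnorm(64 * 64), 64, 64)
  for (i in 1:3)
    x <- (x + rbind(x[-1, ], x[1, ]) + cbind(x[, -1], x[, 1])) / 3
  s0 <- slice_image(array(x, c(64, 64, 1)), c(0.05, 0.05))
  xs <- rbind(x[63:64, ], x[1:62, ])                # translate by 2 px
  s2 <- slice_image(array(xs, c(64, 64, 1)), c(0.05, 0.05))
  f0 <- scatter(s0, scattering_config(2, 3, 1), 0.2)
  f2 <- scatter(s2, scattering_config(2, 3, 1), 0.2)
  rel_feat <- sqrt(sum((f0$data - f2$data)^2)) / sqrt(sum(f0$data^2))
  rel_raw <- sqrt(sum((x - xs)^2)) / sqrt(sum(x^2))
  expect_lt(rel_feat, 0.3 * rel_raw)
})

make_stacks <- function(n = 2, seed = 43) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    scatter(slice_image(array(rnorm(64 * 64 * 3), c(64, 64, 3)),
                        c(0.05, 0.05), z_position = i),
            scattering_config(2, 3, 2), 0.2))
}

test_that("build_basis returns shared orthonormal loadings, slice-order
           invariant up to sign, with the constant element appended", {
  stacks <- make_stacks()
  bs <- build_basis(stacks, m = 6)
  expect_length(bs, 2)
  G <- crossprod(bs[[1]]$loadings)
  expect_lt(max(abs(G - diag(6))), 1e-10)
  expect_equal(range(bs[[1]]$psi$data[, , 1]), c(1, 1))   # psi^0 = 1

  bs_perm <- build_basis(rev(stacks), m = 6)
  ip <- abs(colSums(bs[[1]]$loadings * bs_perm[[1]]$loadings))
  expect_equal(ip, rep(1, 6), tolerance = 1e-8)
})

test_that("rank-deficient pooled features are detected", {
  set.seed(44)
  base <- matrix(rnorm(16 * 16), 16, 16)
  st <- slice_image(array(2.5, c(64, 64, 1)), c(0.05, 0.05))
  f <- scatter(st, scattering_config(2, 3, 2), 0.2)  # constant -> rank 1
  expect_error(build_basis(list(f), m = 6), "rank")
})

test_that("alpha estimation solves the weighted normal equations", {
  stacks <- make_stacks()
  bs <- build_basis(stacks, m = 6)
  b1 <- bs[[1]]
  truth <- c(0.5, 1, -2, 0, 3, 0.2, -1)
  tgt <- predict_contrast(b1, truth)
  # exact recovery on an in-span target
  expect_lt(max(abs(estimate_alpha(b1, tgt) - truth)), 1e-8)

  # weights zero outside a region reproduce the restricted fit
  d <- dim(b1$psi$data)
  w <- matrix(0, d[1], d[2]); w[1:8, ] <- 1
  set.seed(45)
  noisy <- tgt
  noisy$data <- tgt$data + array(rnorm(prod(d[1:2])), c(d[1:2], 1))
  aw <- estimate_alpha(b1, noisy, weights = w)
  # oracle: plain least squares on the selected pixels
  P <- matrix(b1$psi$data, d[1] * d[2], d[3])[as.vector(w) > 0, ]
  yv <- as.vector(noisy$data[, , 1])[as.vector(w) > 0]
  oracle <- qr.solve(P, yv)
  expect_equal(as.vector(aw), as.vector(oracle), tolerance = 1e-6)
  expect_error(estimate_alpha(b1, noisy, weights = w * 0), "zero")

  # out-of-span prediction is the orthogonal projection onto span(psi)
  pred <- predict_contrast(b1, estimate_alpha(b1, noisy))
  resid <- as.vector(noisy$data - pred$data)
  Pfull <- matrix(b1$psi$data, d[1] * d[2], d[3])
  expect_lt(max(abs(crossprod(Pfull, resid))), 1e-6 * nrow(Pfull))
})

test_that("predict_contrast is the linear combination of basis images", {
  stacks <- make_stacks()
  b1 <- build_basis(stacks, m = 6)[[1]]
  one <- predict_contrast(b1, c(1, rep(0, 6)))
  expect_equal(range(one$data), c(1, 1))
  expect_error(predict_contrast(b1, c(1, 2)), "length")
})

test_that("on phantom sections the predicted contrast tracks the template
           while plain grayscale downsampling cannot separate the
           confusable regions", {
  ph <- default_phantom()
  res <- default_registration()
  for (n in 4:5) {
    sl <- res$state$slices[[n]]
    obs <- projlddmm:::chain_forward(res$state, n)$obs
    lab <- ph$sim$truth$labels2d[[n]]$data[, , 1]
    tissue <- as.vector(lab > 0)
    expect_gt(cor(sl$pred[tissue], obs[tissue]), 0.8)

    # regions 1 and 4 are nearly iso-intense in the averaged channels but
    # carry different texture frequencies: grayscale must not separate
    # them, the feature-based prediction must
    fine <- ph$sim$stack$slices[[n]]
    gray <- block_downsample(
      slice_image(array(rowMeans(matrix(fine$data, ncol = 3)),
                        c(dim(fine$data)[1:2], 1)), fine$spacing),
      ph$cfg$spacing)$data[, , 1]
    sep <- function(x, a, b) {
      abs(mean(x[a]) - mean(x[b])) / sqrt((var(x[a]) + var(x[b])) / 2)
    }
    d_gray <- sep(gray, lab == 1, lab == 4)
    d_pred <- sep(sl$pred, as.vector(lab == 1), as.vector(lab == 4))
    expect_lt(d_gray, 0.5)
    expect_gt(d_pred, 4 * d_gray)
  }
})
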