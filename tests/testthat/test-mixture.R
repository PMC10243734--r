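# Three-class conditionally Gaussian model: E-step posteriors, M-step
# nuisance updates, weighted matching cost.

test_that("class means broadcast the predicted contrast and scalar
           nuisance means on the slice lattice", {
  pred <- slice_image(matrix(2, 3, 4), c(1, 1))
  mp <- mixture_params(mu_A = 5, mu_B = -1)
  means <- class_means(pred, mp)
  expect_equal(means$mu1, matrix(2, 3, 4))
  expect_equal(means$mu2, matrix(5, 3, 4))
  expect_equal(means$mu3, matrix(-1, 3, 4))
  # mu_A = mu_B is allowed: classes then differ only via sigma/priors
  mp2 <- mixture_params(mu_A = 5, mu_B = 5, sigma = c(1, 1, 2))
  m2 <- class_means(pred, mp2)
  expect_equal(m2$mu2, m2$mu3)
})

test_that("e_step posteriors follow Bayes' rule and normalize exactly", {
  mp <- mixture_params(mu_A = 1, mu_B = 1, sigma = c(0.5, 0.5, 0.5))
  # observation equidistant from all three means: uniform posteriors
  means <- list(mu1 = matrix(0, 2, 2), mu2 = matrix(1, 2, 2),
                mu3 = matrix(1, 2, 2))
  pf <- e_step(matrix(0.5, 2, 2), means, mp)
  expect_equal(as.vector(pf[1, 1, ]), rep(1 / 3, 3))

  # obs at mu_A with the others far away: class 2 takes all the weight
  mp3 <- mixture_params(mu_A = 0, mu_B = 50, sigma = c(0.1, 0.1, 0.1))
  m3 <- list(mu1 = matrix(-50, 1, 1), mu2 = matrix(0, 1, 1),
             mu3 = matrix(50, 1, 1))
  pf3 <- e_step(matrix(0, 1, 1), m3, mp3)
  expect_equal(pf3[1, 1, 2], 1)

  # direct Bayes oracle: means (0, 1, 2), sigma 1, uniform priors, obs 0.5
  mp4 <- mixture_params(mu_A = 1, mu_B = 2)
  m4 <- list(mu1 = matrix(0, 1, 2), mu2 = matrix(1, 1, 2),
             mu3 = matrix(2, 1, 2))
  pf4 <- e_step(matrix(0.5, 1, 2), m4, mp4)
  lik <- exp(-c(0.5, 0.5, 1.5)^2 / 2)
  expect_equal(as.vector(pf4[1, 1, ]), lik / sum(lik), tolerance = 1e-12)

  # normalization exact to 1e-12 on random fields
  set.seed(51)
  mr <- list(mu1 = matrix(rnorm(30), 5, 6), mu2 = matrix(0.2, 5, 6),
             mu3 = matrix(0.9, 5, 6))
  pr <- e_step(matrix(rnorm(30), 5, 6), mr,
               mixture_params(0.2, 0.9, sigma = c(0.3, 0.5, 0.2)))
  expect_lt(max(abs(pr[, , 1] + pr[, , 2] + pr[, , 3] - 1)), 1e-12)
  expect_true(all(pr >= 0 & pr <= 1))
  expect_error(e_step(matrix(NA_real_, 1, 1), m4, mp4), "finite")
})

test_that("m_step updates nuisance means as weighted observation means", {
  set.seed(52)
  obs <- matrix(rnorm(24, mean = 3), 4, 6)
  mp <- mixture_params(mu_A = 0, mu_B = 0)

  # indicator weights: plain regional mean
  w <- array(0, c(4, 6, 3))
  region <- matrix(FALSE, 4, 6); region[1:2, 1:3] <- TRUE
  w[, , 2][region] <- 1
  w[, , 1][!region] <- 1
  w[4, 6, ] <- c(0, 0, 1)
  out <- m_step_nuisance(obs, structure(w, class = "WeightField"), mp)
  expect_equal(out$mu_A, mean(obs[region]))

  # uniform 1/3 weights: both nuisance means equal the global mean
  wu <- array(1 / 3, c(4, 6, 3))
  out2 <- m_step_nuisance(obs, structure(wu, class = "WeightField"), mp)
  expect_equal(out2$mu_A, mean(obs))
  expect_equal(out2$mu_B, mean(obs))

  # a single unit-weight pixel pins the mean to that pixel's value
  w1 <- array(0, c(4, 6, 3)); w1[2, 2, 2] <- 1; w1[, , 1] <- 1
  w1[4, 6, 3] <- 1
  out3 <- m_step_nuisance(obs, structure(w1, class = "WeightField"), mp)
  expect_equal(out3$mu_A, obs[2, 2])

  # zero-total-weight classes keep their previous values with warnings
  w0 <- array(0, c(4, 6, 3)); w0[, , 1] <- 1
  wrns <- testthat::capture_warnings(
    out4 <- m_step_nuisance(obs, structure(w0, class = "WeightField"),
                            mixture_params(7, 9)))
  expect_length(wrns, 2)
  expect_match(wrns, "zero total weight", all = TRUE)
  expect_equal(out4$mu_A, 7)
  expect_equal(out4$mu_B, 9)
})

test_that("weighted cost matches a brute-force triple sum and scales as
           1/sigma^2", {
  set.seed(53)
  obs <- matrix(rnorm(20), 4, 5)
  mp <- mixture_params(0.5, -0.5, sigma = c(0.7, 1.1, 0.9))
  means <- list(mu1 = matrix(rnorm(20), 4, 5), mu2 = matrix(0.5, 4, 5),
                mu3 = matrix(-0.5, 4, 5))
  pf <- e_step(obs, means, mp)
  got <- weighted_cost(obs, means, pf, mp)
  brute <- 0
  for (k in 1:3) for (i in 1:4) for (j in 1:5)
    brute <- brute + pf[i, j, k] * (means[[k]][i, j] - obs[i, j])^2 /
      (2 * mp$sigma[k]^2)
  expect_equal(got, brute, tolerance = 1e-12)

  # obs identical to mu1 under pure class-1 weights: zero cost
  w1 <- array(0, c(4, 5, 3)); w1[, , 1] <- 1
  expect_equal(weighted_cost(means$mu1, means,
                             structure(w1, class = "WeightField"), mp), 0)

  mp2 <- mp; mp2$sigma <- 2 * mp$sigma
  expect_equal(weighted_cost(obs, means, pf, mp2), got / 4,
               tolerance = 1e-12)
})

test_that("the slice free energy is minimized over weights by the E-step", {
  set.seed(54)
  obs <- matrix(rnorm(12), 3, 4)
  mp <- mixture_params(0.3, -0.2, sigma = c(0.4, 0.6, 0.5))
  means <- list(mu1 = matrix(rnorm(12), 3, 4), mu2 = matrix(0.3, 3, 4),
                mu3 = matrix(-0.2, 3, 4))
  pf <- e_step(obs, means, mp)
  fe_opt <- projlddmm:::mixture_free_energy(obs, means, pf, mp)
  for (rep in 1:5) {
    wr <- array(runif(36), c(3, 4, 3))
    wr <- wr / as.vector(wr[, , 1] + wr[, , 2] + wr[, , 3])
    expect_gte(projlddmm:::mixture_free_energy(obs, means, wr, mp),
               fe_opt - 1e-10)
  }
})
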