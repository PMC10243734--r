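# Three-class conditionally Gaussian model over each section: class 1 is
# matching tissue with spatially varying mean (the slice's predicted
# contrast), classes 2 and 3 are artifact and background with scalar means.
# The E-step produces per-pixel weight fields; the M-step updates the
# nuisance means (and optionally the variances); geometry and contrast are
# then optimized against the weighted least-squares cost, giving a GEM
# iteration that is monotone in the free energy.

#' Mixture model parameters
#'
#' @param mu_A,mu_B artifact and background means (template intensity units)
#' @param sigma length-3 vector of class standard deviations (> 0)
#' @param priors length-3 class prior probabilities (sum 1)
#' @param r range dimension of the template (enters the Gaussian normalizer)
#' @return a `MixtureParams`
#' @export
mixture_params <- function(mu_A, mu_B, sigma = c(1, 1, 1),
                           priors = rep(1 / 3, 3), r = 1L) {
  sigma <- rep(as.numeric(sigma), length.out = 3)
  priors <- as.numeric(priors)
  stopifnot(all(sigma > 0), length(priors) == 3, all(priors >= 0))
  if (abs(sum(priors) - 1) > 1e-8) stop("priors must sum to 1")
  structure(list(mu_A = mu_A, mu_B = mu_B, sigma = sigma, priors = priors,
                 r = as.integer(r)),
            class = "MixtureParams")
}

#' Class mean images
#'
#' Class 1 has the slice's predicted contrast as its (spatially varying)
#' mean; classes 2 (artifact) and 3 (background) have the scalar means
#' `mu_A`, `mu_B` broadcast over the lattice.
#'
#' @param predicted single-channel `SliceImage`, the predicted contrast
#' @param params a [mixture_params()]
#' @return list of three matrices `mu1`, `mu2`, `mu3` on the slice lattice
#' @export
class_means <- function(predicted, params) {
  m1 <- predicted$data[, , 1]
  list(mu1 = m1,
       mu2 = matrix(params$mu_A, nrow(m1), ncol(m1)),
       mu3 = matrix(params$mu_B, nrow(m1), ncol(m1)))
}

#' E-step: posterior class weight fields
#'
#' `pi_k(y)` is proportional to
#' `p_k sigma_k^-r exp(-|mu_k(y) - obs(y)|^2 / (2 sigma_k^2))`, normalized
#' per pixel with log-sum-exp for numerical stability.
#'
#' @param observed matrix or single-channel `SliceImage`: the deformed
#'   projected template on the slice lattice
#' @param means list from [class_means()]
#' @param params a [mixture_params()]
#' @return a `WeightField`: array (nx, ny, 3) of per-pixel class posteriors
#' @export
e_step <- function(observed, means, params) {
  obs <- if (inherits(observed, "SliceImage")) observed$data[, , 1]
         else observed
  if (any(!is.finite(obs))) stop("observed image contains non-finite values")
  d <- dim(obs)
  logp <- array(0, c(d, 3))
  for (k in 1:3) {
    mk <- means[[k]]
    logp[, , k] <- log(params$priors[k]) -
      params$r * log(params$sigma[k]) -
      (mk - obs)^2 / (2 * params$sigma[k]^2)
  }
  mx <- pmax(logp[, , 1], logp[, , 2], logp[, , 3])
  w <- exp(logp - as.vector(mx))
  tot <- w[, , 1] + w[, , 2] + w[, , 3]
  pi_field <- w / as.vector(tot)
  structure(pi_field, class = "WeightField")
}

#' M-step update of the nuisance class means
#'
#' Weighted means of the observation under the artifact and background
#' posteriors; with `update_sigma = TRUE` the class standard deviations are
#' also replaced by the weighted residual scale of each class. Classes with
#' zero total weight keep their previous value (with a warning).
#'
#' @param observed matrix or single-channel `SliceImage`
#' @param weights `WeightField` from [e_step()]
#' @param params current [mixture_params()]
#' @param update_sigma also update `sigma` (default `FALSE`)
#' @param mu1 the class-1 (tissue) mean image; required for the class-1
#'   sigma update when `update_sigma = TRUE`
#' @return the updated `MixtureParams`
#' @export
m_step_nuisance <- function(observed, weights, params, update_sigma = FALSE,
                            mu1 = NULL) {
  obs <- if (inherits(observed, "SliceImage")) observed$data[, , 1]
         else observed
  for (k in 2:3) {
    sw <- sum(weights[, , k])
    if (sw <= 0) {
      warning("class ", k, " has zero total weight; keeping previous mean")
      next
    }
    mu <- sum(weights[, , k] * obs) / sw
    if (k == 2) params$mu_A <- mu else params$mu_B <- mu
  }
  if (update_sigma) {
    means <- list(mu1, matrix(params$mu_A, nrow(obs), ncol(obs)),
                  matrix(params$mu_B, nrow(obs), ncol(obs)))
    for (k in 1:3) {
      sw <- sum(weights[, , k])
      if (sw <= 0 || (k == 1 && is.null(mu1))) next
      s2 <- sum(weights[, , k] * (means[[k]] - obs)^2) / sw
      params$sigma[k] <- sqrt(max(s2, 1e-8))
    }
  }
  params
}

#' Weighted least-squares matching cost
#'
#' `sum_k (1 / 2 sigma_k^2) sum_y pi_k(y) |mu_k(y) - obs(y)|^2` — the
#' Q-surrogate's data term given the weight fields.
#'
#' @param observed matrix or single-channel `SliceImage`
#' @param means list from [class_means()]
#' @param weights `WeightField`
#' @param params [mixture_params()]
#' @return scalar cost
#' @export
weighted_cost <- function(observed, means, weights, params) {
  obs <- if (inherits(observed, "SliceImage")) observed$data[, , 1]
         else observed
  total <- 0
  for (k in 1:3) {
    total <- total + sum(weights[, , k] * (means[[k]] - obs)^2) /
      (2 * params$sigma[k]^2)
  }
  total
}

# Variational free energy of one slice given the weights: the quantity every
# block of the GEM alternation decreases. Entropy and normalizer terms are
# included so the E-step (which minimizes it exactly over pi) is monotone.
mixture_free_energy <- function(observed, means, weights, params) {
  obs <- if (inherits(observed, "SliceImage")) observed$data[, , 1]
         else observed
  total <- 0
  for (k in 1:3) {
    pk <- weights[, , k]
    dk <- (means[[k]] - obs)^2 / (2 * params$sigma[k]^2) +
      params$r * log(params$sigma[k]) - log(params$priors[k])
    ent <- ifelse(pk > 0, pk * log(pk), 0)
    total <- total + sum(pk * dk + ent)
  }
  total
}
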