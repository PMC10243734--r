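# Cross-modality contrast channel: reduce per-slice scattering features to a
# shared discriminating subspace (PCA over pooled tissue pixels), and fit
# per-slice linear coefficients mapping that basis to template intensity.

#' Build per-slice predictive bases from scattering feature stacks
#'
#' Feature channels are standardized (zero mean, unit variance) over the
#' pooled pixels of all slices (optionally restricted to tissue masks), a
#' single set of orthonormal PCA loadings is computed on the pooled
#' pixel-by-channel matrix, and each slice's features are projected on those
#' shared loadings to give `m` basis images per slice, plus the constant
#' image appended as basis element 0.
#'
#' @param stacks list of `FeatureStack`s, one per slice, sharing a lattice
#'   geometry and channel count
#' @param m dimension of the reduced subspace (default 6)
#' @param masks optional list of logical matrices selecting the pixels pooled
#'   for standardization and PCA (e.g. tissue masks)
#' @return a list of `PredictiveBasis` objects (one per slice), each with
#'   `psi` (a `SliceImage` with `m + 1` channels, channel 1 the constant 1),
#'   the shared `loadings` (M x m, orthonormal columns), and the
#'   standardization statistics
#' @export
build_basis <- function(stacks, m = 6L, masks = NULL) {
  stopifnot(length(stacks) >= 1)
  M <- n_channels(stacks[[1]])
  if (m >= M) stop("m must be smaller than the number of feature channels")
  pooled <- do.call(rbind, lapply(seq_along(stacks), function(n) {
    x <- stacks[[n]]$data
    d <- dim(x)
    mat <- matrix(x, d[1] * d[2], d[3])
    if (!is.null(masks)) mat <- mat[as.vector(masks[[n]]), , drop = FALSE]
    mat
  }))
  if (nrow(pooled) < m) stop("fewer pooled pixels than basis dimensions")
  center <- colMeans(pooled)
  scale <- apply(pooled, 2, stats::sd)
  scale[scale < 1e-12] <- 1
  z <- sweep(sweep(pooled, 2, center, "-"), 2, scale, "/")
  sv <- svd(z, nu = 0, nv = min(M, nrow(z)))
  rank <- sum(sv$d > max(sv$d) * 1e-10)
  if (rank < m)
    stop(sprintf("pooled feature matrix has rank %d < m = %d; ", rank, m),
         "reduce m")
  loadings <- sv$v[, seq_len(m), drop = FALSE]
  sdev <- sv$d[seq_len(min(M, length(sv$d)))] / sqrt(max(nrow(z) - 1, 1))
  lapply(stacks, function(st) {
    d <- dim(st$data)
    mat <- matrix(st$data, d[1] * d[2], d[3])
    zz <- sweep(sweep(mat, 2, center, "-"), 2, scale, "/")
    proj <- zz %*% loadings
    psi <- array(cbind(1, proj), c(d[1], d[2], m + 1L))
    structure(list(
      psi = slice_image(psi, spacing = st$spacing, origin = st$origin,
                        z_position = st$z_position),
      loadings = loadings, center = center, scale = scale, sdev = sdev,
      m = m),
      class = "PredictiveBasis")
  })
}

#' Least-squares contrast coefficients for one slice
#'
#' Solves the (weighted) normal equations `K alpha = integral psi * target`
#' with `K = integral psi psi^T` over the slice lattice, i.e. the
#' pseudo-inverse solution of predicting `target` from the basis images.
#' Weights, when given, enter both integrals. A small ridge is added when
#' `K` is poorly conditioned (condition number > 1e8).
#'
#' @param basis a `PredictiveBasis` for the slice
#' @param target a single-channel `SliceImage` on the basis lattice (e.g. the
#'   deformed projected template)
#' @param weights optional non-negative per-pixel weights (matrix)
#' @return numeric vector alpha of length `m + 1` (class `Coefficients`)
#' @export
estimate_alpha <- function(basis, target, weights = NULL) {
  stopifnot(inherits(basis, "PredictiveBasis"))
  psi <- basis$psi$data
  d <- dim(psi)
  tgt <- if (inherits(target, "SliceImage")) target$data else target
  tv <- as.vector(tgt[, , 1][seq_len(d[1] * d[2])])
  if (length(tv) != d[1] * d[2]) stop("target is not on the basis lattice")
  P <- matrix(psi, d[1] * d[2], d[3])
  if (!is.null(weights)) {
    w <- as.vector(weights)
    if (any(w < 0)) stop("weights must be non-negative")
    if (all(w == 0)) stop("all-zero weights: nothing to fit")
    K <- crossprod(P, P * w)
    b <- crossprod(P, tv * w)
  } else {
    K <- crossprod(P)
    b <- crossprod(P, tv)
  }
  if (kappa(K, exact = TRUE) > 1e8) {
    K <- K + diag(1e-8 * mean(diag(K)), nrow(K))
  }
  alpha <- as.vector(solve(K, b))
  structure(alpha, class = "Coefficients")
}

#' Predict template contrast from basis images and coefficients
#'
#' `J^alpha(y) = alpha^T psi(y)` — the linear combination of basis images
#' mapping the slice's features into template intensity units.
#'
#' @param basis a `PredictiveBasis`
#' @param alpha coefficients from [estimate_alpha()] (length `m + 1`)
#' @return a single-channel `SliceImage`
#' @export
predict_contrast <- function(basis, alpha) {
  psi <- basis$psi$data
  d <- dim(psi)
  if (length(alpha) != d[3])
    stop(sprintf("alpha has length %d but the basis has %d elements",
                 length(alpha), d[3]))
  pred <- matrix(psi, d[1] * d[2], d[3]) %*% as.numeric(alpha)
  slice_image(array(pred, c(d[1], d[2], 1L)), spacing = basis$psi$spacing,
              origin = basis$psi$origin, z_position = basis$psi$z_position)
}
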