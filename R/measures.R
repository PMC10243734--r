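# Particle-measure representation of per-section pathology: weighted Dirac
# measures over space crossed with feature Diracs. Weights carry sampled
# tissue area (mm^2); features are 2L-vectors whose first L entries count
# tangles per region and last L entries give the fraction of the particle's
# area in each region. Transport follows the varifold action (positions
# move, weights scale by the in-plane Jacobian determinant, features ride
# along); resampling redistributes mass over target sites with a
# source-normalized kernel and reduces feature mixtures to first moments.

#' Particle measure
#'
#' @param points N x d matrix of particle positions (mm, d = 2 or 3)
#' @param weights non-negative particle weights (mm^2 of sampled tissue)
#' @param features N x 2L matrix: columns 1..L tangle counts per region,
#'   columns L+1..2L area fractions per region
#' @param n_regions L, the region count
#' @param scale integer scale tag (0 = finest, one particle per pixel)
#' @return a `ParticleMeasure`
#' @export
particle_measure <- function(points, weights, features, n_regions,
                             scale = 0L) {
  points <- as.matrix(points)
  features <- as.matrix(features)
  weights <- as.numeric(weights)
  L <- as.integer(n_regions)
  stopifnot(ncol(points) %in% c(2L, 3L), nrow(points) == length(weights),
            nrow(features) == nrow(points), ncol(features) == 2L * L)
  if (any(weights < 0)) stop("weights must be non-negative")
  if (any(!is.finite(features))) stop("features must be finite")
  frac_sum <- rowSums(features[, L + seq_len(L), drop = FALSE])
  if (any(frac_sum > 1 + 1e-9))
    stop("area fractions must sum to at most 1 per particle")
  structure(list(points = points, weights = weights, features = features,
                 n_regions = L, scale = as.integer(scale)),
            class = "ParticleMeasure")
}

#' @export
print.ParticleMeasure <- function(x, ...) {
  cat(sprintf(
    "ParticleMeasure: %d particles (%dD), %d regions, scale %d\n",
    nrow(x$points), ncol(x$points), x$n_regions, x$scale))
  cat(sprintf("  total weight %.6g mm^2, total counts %g\n",
              sum(x$weights), sum(x$features[, seq_len(x$n_regions)])))
  invisible(x)
}

#' Fine-scale particle measure of one section
#'
#' One particle per pixel: the weight is the pixel area for tissue pixels
#' and 0 elsewhere; the count block accumulates the tangle points falling in
#' the pixel (one-hot by the region containing each tangle); the area block
#' is one-hot for the pixel's region. A tangle landing on a zero-weight
#' pixel is still assigned (with a warning).
#'
#' @param tissue_mask logical matrix of tissue pixels
#' @param nft_points data frame with tangle coordinates `x`, `y` (mm)
#' @param region_labels single-channel label `SliceImage` co-registered with
#'   the mask (labels 1..L, 0 background)
#' @param n_regions L
#' @return a `ParticleMeasure` at scale 0
#' @export
particles_from_slice <- function(tissue_mask, nft_points, region_labels,
                                 n_regions) {
  d <- dim(region_labels$data)[1:2]
  lab <- array(region_labels$data[, , 1], d)
  stopifnot(all(dim(tissue_mask) == d))
  sp <- region_labels$spacing
  orig <- region_labels$origin
  pixel_area <- prod(sp)
  g <- expand.grid(i = seq_len(d[1]) - 1, j = seq_len(d[2]) - 1)
  pts <- cbind(orig[1] + g$i * sp[1], orig[2] + g$j * sp[2])
  L <- as.integer(n_regions)
  np <- d[1] * d[2]
  w <- ifelse(as.vector(tissue_mask), pixel_area, 0)
  f <- matrix(0, np, 2L * L)
  labv <- as.vector(lab)
  for (r in seq_len(L)) f[labv == r, L + r] <- 1
  if (nrow(nft_points)) {
    ii <- pmin(pmax(round((nft_points$x - orig[1]) / sp[1]), 0), d[1] - 1)
    jj <- pmin(pmax(round((nft_points$y - orig[2]) / sp[2]), 0), d[2] - 1)
    lin <- ii + jj * d[1] + 1
    if (any(w[lin] == 0))
      warning(sum(w[lin] == 0),
              " tangle point(s) fall on zero-weight pixels; assigned anyway")
    reg <- labv[lin]
    for (t in seq_along(lin)) {
      r <- reg[t]
      if (r >= 1 && r <= L) f[lin[t], r] <- f[lin[t], r] + 1
    }
  }
  particle_measure(pts, w, f, L, scale = 0L)
}

#' Varifold transport of a particle measure
#'
#' Positions move through the map; weights are multiplied by the in-plane
#' Jacobian determinant at each particle (sections carry area, not volume);
#' features are carried unchanged, so the count block is conserved exactly.
#'
#' The map is given as a function chain: either a 2D `DiffeoMap` /
#' `Rigid2D`, a 3D `DiffeoMap` applied to embedded points, or a list of such
#' applied left to right. For the in-plane Jacobian of 2D components the
#' stored determinant field is interpolated at the particle positions; 3D
#' maps applied to embedded section particles contribute their in-plane
#' (x,y sub-block) Jacobian.
#'
#' @param mu a `ParticleMeasure`
#' @param map a `DiffeoMap`, `Rigid2D`, `z_embed(z)` step, or list of these
#' @return the transported `ParticleMeasure`
#' @export
transport <- function(mu, map) {
  steps <- if (inherits(map, c("DiffeoMap", "Rigid2D", "ZEmbed"))) list(map)
           else map
  pts <- mu$points
  w <- mu$weights
  for (st in steps) {
    if (inherits(st, "Rigid2D")) {
      stopifnot(ncol(pts) == 2)
      pts <- apply_rigid(st, pts)
      w <- w * abs(det(st$linear))
    } else if (inherits(st, "ZEmbed")) {
      stopifnot(ncol(pts) == 2)
      pts <- cbind(pts, st$z)
    } else if (inherits(st, "DiffeoMap")) {
      nd <- length(st$spacing)
      stopifnot(ncol(pts) == nd)
      jac <- inplane_jacobian(st, pts)
      if (any(jac <= 0))
        stop("non-positive Jacobian determinant at ", sum(jac <= 0),
             " particle(s)")
      pts <- map_at(st, pts, "forward")
      w <- w * jac
    } else stop("unsupported transport step of class ", class(st)[1])
  }
  particle_measure(pts, w, mu$features, mu$n_regions, scale = mu$scale)
}

#' @rdname transport
#' @param z section plane position (mm) at which 2D particles are embedded
#' @export
z_embed <- function(z) structure(list(z = z), class = "ZEmbed")

# in-plane Jacobian determinant of a map at given points: 2D maps use the
# stored determinant field; 3D maps use the x-y sub-block of the forward
# map's Jacobian, interpolated componentwise
inplane_jacobian <- function(map, pts) {
  nd <- length(map$spacing)
  if (nd == 2) {
    interp_core(array(map$jacobian, c(dim(map$jacobian), 1L)), pts,
                map$spacing, map$origin, fill = 1)$value[, 1]
  } else {
    dims <- dim(map$forward)[1:3]
    grid_geom <- list(data = array(0, c(dims, 1)), spacing = map$spacing,
                      origin = map$origin)
    J <- matrix(0, nrow(pts), 4)
    idx <- 1
    for (a in 1:2) {
      for (b in 1:2) {
        comp <- map$forward[, , , a]
        dfield <- axis_central_diff(comp, b, map$spacing[b])
        J[, idx] <- interp_core(array(dfield, c(dims, 1L)), pts,
                                map$spacing, map$origin,
                                fill = as.numeric(a == b))$value[, 1]
        idx <- idx + 1
      }
    }
    J[, 1] * J[, 4] - J[, 2] * J[, 3]
  }
}

#' Resampling kernel for particle measures
#'
#' Defines how source particles distribute their mass over target sites.
#' The assignment fractions are normalized over targets for each source
#' particle (every source gives away all of its mass), which makes
#' resampling exactly mass- and count-conserving.
#'
#' @param targets M x d matrix of target sites (grid points, mesh vertices)
#' @param kind `"nearest_neighbor"` or `"gaussian"`
#' @param bandwidth Gaussian bandwidth in mm (default 0.125, a typical MRI
#'   resolution)
#' @return a `ResampleKernel`
#' @export
resample_kernel <- function(targets, kind = c("nearest_neighbor", "gaussian"),
                            bandwidth = 0.125) {
  kind <- match.arg(kind)
  targets <- as.matrix(targets)
  stopifnot(nrow(targets) >= 1)
  if (kind == "gaussian") stopifnot(bandwidth > 0)
  structure(list(targets = targets, kind = kind, bandwidth = bandwidth),
            class = "ResampleKernel")
}

#' Resample a particle measure onto target sites
#'
#' Target weights are `w'(x') = sum_x pi(x, x') w(x)` with source-normalized
#' fractions `pi`; the target feature vector is the first moment of the
#' mass-weighted mixture of source features ([reduce_features()]). Nearest-
#' neighbor kernels assign each source wholly to its closest target (ties:
#' lowest target index); Gaussian kernels use
#' `pi(x, x') ∝ exp(-|x - x'|^2 / 2h^2)` normalized over targets.
#'
#' @param mu a `ParticleMeasure`
#' @param kernel a [resample_kernel()] whose targets share `mu`'s dimension
#' @return a `ParticleMeasure` on the target sites (scale incremented)
#' @export
resample <- function(mu, kernel) {
  tg <- kernel$targets
  stopifnot(ncol(tg) == ncol(mu$points))
  M <- nrow(tg)
  N <- nrow(mu$points)
  L2 <- ncol(mu$features)
  w_out <- numeric(M)
  fw_out <- matrix(0, M, L2)   # mass-weighted feature sums
  if (kernel$kind == "nearest_neighbor") {
    nn <- nearest_site(mu$points, tg)
    w_out <- as.vector(rowsum_full(mu$weights, nn, M))
    fw_out <- rowsum_full(mu$features * mu$weights, nn, M)
  } else {
    h2 <- 2 * kernel$bandwidth^2
    # block over sources to bound memory
    bs <- max(1L, floor(2e6 / M))
    for (s0 in seq(1, N, by = bs)) {
      sel <- s0:min(s0 + bs - 1L, N)
      d2 <- outer(rowSums(mu$points[sel, , drop = FALSE]^2), rep(1, M)) +
        outer(rep(1, length(sel)), rowSums(tg^2)) -
        2 * mu$points[sel, , drop = FALSE] %*% t(tg)
      P <- exp(-pmax(d2, 0) / h2)
      P <- P / rowSums(P)
      w_out <- w_out + as.vector(crossprod(P, mu$weights[sel]))
      fw_out <- fw_out + crossprod(P, mu$features[sel, , drop = FALSE] *
                                     mu$weights[sel])
    }
  }
  f_out <- matrix(0, M, L2)
  pos <- w_out > 0
  f_out[pos, ] <- fw_out[pos, , drop = FALSE] / w_out[pos]
  particle_measure(tg, w_out, f_out, mu$n_regions, scale = mu$scale + 1L)
}

nearest_site <- function(pts, targets) {
  M <- nrow(targets)
  N <- nrow(pts)
  out <- integer(N)
  bs <- max(1L, floor(2e6 / M))
  for (s0 in seq(1, N, by = bs)) {
    sel <- s0:min(s0 + bs - 1L, N)
    d2 <- outer(rowSums(pts[sel, , drop = FALSE]^2), rep(1, M)) +
      outer(rep(1, length(sel)), rowSums(targets^2)) -
      2 * pts[sel, , drop = FALSE] %*% t(targets)
    out[sel] <- max.col(-d2, ties.method = "first")
  }
  out
}

rowsum_full <- function(x, group, n) {
  x <- as.matrix(x)
  s <- rowsum(x, group = group)
  out <- matrix(0, n, ncol(x))
  out[as.integer(rownames(s)), ] <- s
  out
}

#' First-moment reduction of a feature mixture
#'
#' Reduces a weighted empirical distribution over feature vectors to its
#' expected value per dimension. Zero total weight returns the zero vector
#' (flagged with a warning).
#'
#' @param features N x 2L matrix of feature atoms
#' @param weights mixture weights (>= 0)
#' @return length-2L numeric vector of first moments
#' @export
reduce_features <- function(features, weights = rep(1, nrow(features))) {
  features <- as.matrix(features)
  stopifnot(length(weights) == nrow(features), all(weights >= 0))
  tw <- sum(weights)
  if (tw == 0) {
    warning("zero total weight; returning zero feature vector")
    return(numeric(ncol(features)))
  }
  as.vector(crossprod(features, weights) / tw)
}

#' Tangle densities of a particle measure
#'
#' Total density at a particle is the sum of the count block divided by the
#' particle weight; the per-region density divides region `j`'s count by the
#' area the particle samples in region `j` (`w * f[L+j]`). Regions where a
#' particle has counts but no recorded area are reported as `NA` (flagged).
#'
#' @param mu a `ParticleMeasure` with positive weights where density is
#'   requested
#' @return list with `total` (length N) and `per_region` (N x L matrix), in
#'   counts / mm^2
#' @export
nft_density <- function(mu) {
  L <- mu$n_regions
  w <- mu$weights
  counts <- mu$features[, seq_len(L), drop = FALSE]
  fracs <- mu$features[, L + seq_len(L), drop = FALSE]
  total <- rep(NA_real_, length(w))
  pos <- w > 0
  total[pos] <- rowSums(counts[pos, , drop = FALSE]) / w[pos]
  per <- matrix(NA_real_, length(w), L)
  for (j in seq_len(L)) {
    ok <- pos & fracs[, j] > 0
    per[ok, j] <- counts[ok, j] / (w[ok] * fracs[ok, j])
    zero <- pos & fracs[, j] == 0 & counts[, j] == 0
    per[zero, j] <- 0
  }
  bad <- pos & rowSums(counts > 0 & fracs == 0) > 0
  if (any(bad))
    warning(sum(bad), " particle(s) have counts in regions with zero ",
            "recorded area; densities undefined (NA)")
  list(total = total, per_region = per)
}

#' Write and read particle tables (CSV)
#'
#' Columns: `x`, `y`(, `z`), `w_mm2`, `count_1..L`, `frac_1..L`, `scale`.
#'
#' @param mu a `ParticleMeasure`
#' @param path CSV path
#' @return `read_particles` returns a `ParticleMeasure`; `write_particles`
#'   returns `path` invisibly.
#' @export
write_particles <- function(mu, path) {
  L <- mu$n_regions
  df <- as.data.frame(mu$points)
  names(df) <- c("x", "y", "z")[seq_len(ncol(mu$points))]
  df$w_mm2 <- mu$weights
  cn <- c(paste0("count_", seq_len(L)), paste0("frac_", seq_len(L)))
  fm <- as.data.frame(mu$features)
  names(fm) <- cn
  df <- cbind(df, fm)
  df$scale <- mu$scale
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_particles
#' @export
read_particles <- function(path) {
  df <- utils::read.csv(path)
  cc <- grep("^count_", names(df))
  ff <- grep("^frac_", names(df))
  if (!length(cc) || length(cc) != length(ff))
    stop("particle CSV must contain matching count_j / frac_j columns")
  pt_cols <- intersect(c("x", "y", "z"), names(df))
  particle_measure(as.matrix(df[pt_cols]), df$w_mm2,
                   as.matrix(df[c(cc, ff)]), n_regions = length(cc),
                   scale = if ("scale" %in% names(df)) df$scale[1] else 0L)
}
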