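#' Phantom configuration
#'
#' Defines the synthetic study conditions: a multi-region 3D template on a
#' 0.125 mm lattice, sections cut every 0.75 mm, an unknown smooth 3D
#' deformation, independent per-section rigid + diffeomorphic distortions,
#' a nonlinear 3-channel contrast change with region-distinguishing texture
#' carriers (so that texture, not mean intensity, separates the confusable
#' regions), optional tear artifacts, and per-region tangle point-process
#' intensities. All stochastic outputs are reproducible from `seed`.
#'
#' @param seed integer RNG seed
#' @param dims template lattice dimensions (voxels)
#' @param spacing template voxel spacing in mm (isotropic)
#' @param intensities per-region template intensity; regions 1 and 4 are
#'   deliberately close (confusable without texture)
#' @param histology_factor fine-scale section lattice refinement factor
#' @param n_sections,z_start,z_step section plane layout in mm
#' @param deform3d_amplitude,deform3d_smoothness max displacement and
#'   Gaussian kernel width of the hidden 3D velocity (mm)
#' @param rigid_max_angle,rigid_max_shift per-section rigid ranges (rad, mm)
#' @param deform2d_amplitude,deform2d_smoothness per-section diffeo ranges
#' @param texture_freqs per-region texture carrier frequency (cycles/mm)
#' @param texture_amp texture amplitude (intensity units)
#' @param tear_fraction fraction of tissue pixels torn (0 disables)
#' @param tear_radius min/max tear disc radius (mm)
#' @param tear_value,background_value stamped channel values for tears and
#'   background
#' @param noise additive Gaussian channel noise sd
#' @param tangle_intensity per-region tangle intensity (counts / mm^2)
#' @return a `PhantomConfig`
#' @export
phantom_config <- function(seed = 1L,
                           dims = c(96L, 96L, 48L), spacing = 0.125,
                           intensities = c(0.35, 0.65, 0.9, 0.38),
                           histology_factor = 4L,
                           n_sections = 8L, z_start = 0.375, z_step = 0.75,
                           deform3d_amplitude = 0.25,
                           deform3d_smoothness = 2.5,
                           rigid_max_angle = 5 * pi / 180,
                           rigid_max_shift = 0.25,
                           deform2d_amplitude = 0.08,
                           deform2d_smoothness = 1.5,
                           texture_freqs = c(6, 3, 9, 12),
                           texture_amp = 0.08,
                           tear_fraction = 0,
                           tear_radius = c(0.2, 0.5),
                           tear_value = 0.95, background_value = 0.04,
                           noise = 0.02,
                           tangle_intensity = c(5, 10, 25, 15)) {
  stopifnot(length(intensities) == 4, length(texture_freqs) == 4,
            length(tangle_intensity) == 4, spacing > 0)
  structure(as.list(environment()), class = "PhantomConfig")
}

#' Build the phantom template, labels and landmarks
#'
#' Deterministic multi-region geometry: an ellipsoidal tissue matrix
#' (region 1) containing a C-shaped band (region 2), a compact core blob
#' (region 3), and a dorsal cap (region 4, nearly iso-intense with region 1).
#' Intensities are lightly smoothed so image gradients are informative.
#'
#' @param cfg a [phantom_config()]
#' @return list with `volume` (`ImageVolume`), `labels` (`ImageVolume` of
#'   integer labels 0..4), and `landmarks` (K x 3 matrix of interior mm
#'   points)
#' @export
make_template <- function(cfg = phantom_config()) {
  d <- cfg$dims
  sp <- rep(cfg$spacing, 3)
  ext <- d * cfg$spacing
  ax <- lapply(1:3, function(a) (seq_len(d[a]) - 1) * sp[a])
  X <- array(rep(ax[[1]], times = d[2] * d[3]), d)
  Y <- array(rep(rep(ax[[2]], each = d[1]), times = d[3]), d)
  Z <- array(rep(ax[[3]], each = d[1] * d[2]), d)
  ctr <- ext / 2
  lab <- array(0L, d)
  # region 1: tissue matrix ellipsoid
  e1 <- ((X - ctr[1]) / (0.40 * ext[1]))^2 +
        ((Y - ctr[2]) / (0.35 * ext[2]))^2 +
        ((Z - ctr[3]) / (0.47 * ext[3]))^2
  lab[e1 <= 1] <- 1L
  # region 2: C-shaped band (notch opening toward +x)
  rr <- sqrt((X - ctr[1])^2 + (Y - ctr[2])^2)
  th <- atan2(Y - ctr[2], X - ctr[1])
  band <- rr >= 0.18 * ext[1] & rr <= 0.27 * ext[1] &
          abs(Z - ctr[3]) <= 0.28 * ext[3] & abs(th) >= pi / 4
  lab[band & lab == 1L] <- 2L
  # region 3: core blob
  e3 <- ((X - 0.58 * ext[1]) / (0.11 * ext[1]))^2 +
        ((Y - 0.46 * ext[2]) / (0.10 * ext[2]))^2 +
        ((Z - ctr[3]) / (0.18 * ext[3]))^2
  lab[e3 <= 1 & lab >= 1L] <- 3L
  # region 4: dorsal cap of the matrix
  cap <- e1 <= 1 & e1 >= 0.55 & Y - ctr[2] >= 0.18 * ext[2]
  lab[cap & lab == 1L] <- 4L
  inten <- array(0.02, d)
  for (r in 1:4) inten[lab == r] <- cfg$intensities[r]
  mult <- kernel_multiplier(kernel_spec(cfg$spacing), d, sp)
  inten <- kernel_apply(inten, mult)
  vol <- image_volume(array(inten, c(d, 1L)), spacing = sp)
  labv <- image_volume(array(as.double(lab), c(d, 1L)), spacing = sp)
  # landmarks: deterministic interior grid restricted to tissue
  gl <- expand.grid(x = ext[1] * seq(0.25, 0.75, length.out = 4),
                    y = ext[2] * seq(0.25, 0.75, length.out = 4),
                    z = ext[3] * seq(0.3, 0.7, length.out = 3))
  lm <- as.matrix(gl)
  inside <- interpolate(labv, lm, method = "nearest")[, 1] > 0
  list(volume = vol, labels = labv, landmarks = lm[inside, , drop = FALSE])
}

# smooth random stationary velocity field with max displacement `amplitude`
random_velocity <- function(dims, spacing, origin, nt, width, amplitude) {
  nd <- length(dims)
  kern <- kernel_spec(width)
  mult <- kernel_multiplier(kern, dims, spacing)
  field <- array(0, c(dims, nd))
  for (a in seq_len(nd)) {
    w <- array(stats::rnorm(prod(dims)), dims)
    sm <- kernel_apply(w, mult)
    if (nd == 3) field[, , , a] <- sm else field[, , a] <- sm
  }
  mag <- sqrt(apply(field^2, seq_len(nd), sum))
  field <- field * (amplitude / max(mag, 1e-12))
  vals <- array(rep(field, nt), c(dims, nd, nt))
  velocity_field(dims, spacing, origin, nt = nt, kernel = kern,
                 values = vals)
}

#' Simulate distorted pseudo-histology sections with full ground truth
#'
#' Applies a hidden smooth 3D diffeomorphism to the template, cuts parallel
#' sections, distorts each section with an independent rigid motion plus a
#' small 2D diffeomorphism, maps intensity through per-channel monotone
#' nonlinearities plus region-specific texture carriers into 3 channels at
#' the fine (histology) resolution, stamps tears and background, and adds
#' noise. Everything needed to score a registration is recorded.
#'
#' @param tmpl output of [make_template()]
#' @param cfg a [phantom_config()]
#' @return list with `stack` (fine 3-channel `SliceStack`), and `truth`:
#'   hidden velocity fields and rigid motions, per-section observed-frame
#'   label images and tissue/tear masks at template in-plane resolution, and
#'   a per-section correspondence table (`y1,y2` observed mm -> `x1,x2,x3`
#'   template mm) for landmark error scoring
#' @export
simulate_sections <- function(tmpl, cfg = phantom_config()) {
  set.seed(cfg$seed)
  vol <- tmpl$volume
  labels <- tmpl$labels
  d <- dim(vol$data)[1:3]
  sp <- vol$spacing
  zs <- cfg$z_start + (seq_len(cfg$n_sections) - 1) * cfg$z_step

  v3_true <- if (cfg$deform3d_amplitude > 0)
    random_velocity(d, sp, vol$origin, nt = 3, width = cfg$deform3d_smoothness,
                    amplitude = cfg$deform3d_amplitude)
  else velocity_field(d, sp, vol$origin, nt = 3)

  fine_sp <- sp[1:2] / cfg$histology_factor
  fine_dims <- d[1:2] * cfg$histology_factor
  gfine <- expand.grid(i = seq_len(fine_dims[1]) - 1,
                       j = seq_len(fine_dims[2]) - 1)
  pts_fine <- cbind(vol$origin[1] + gfine$i * fine_sp[1],
                    vol$origin[2] + gfine$j * fine_sp[2])
  gco <- expand.grid(i = seq_len(d[1]) - 1, j = seq_len(d[2]) - 1)
  pts_co <- cbind(vol$origin[1] + gco$i * sp[1],
                  vol$origin[2] + gco$j * sp[2])

  gamma_c <- c(0.7, 1.0, 1.4)
  gain_c <- c(0.9, 0.8, 0.7)
  off_c <- c(0.05, 0.10, 0.05)
  tex_theta <- c(0.3, 1.2, 2.1, 2.8)
  tex_phase <- c(0.0, 1.0, 2.0, 0.5)

  slices <- vector("list", cfg$n_sections)
  rigid_true <- vector("list", cfg$n_sections)
  v2_true <- vector("list", cfg$n_sections)
  labels2d <- vector("list", cfg$n_sections)
  tear_masks <- vector("list", cfg$n_sections)
  tangle_frames <- vector("list", cfg$n_sections)
  corr <- vector("list", cfg$n_sections)

  for (n in seq_len(cfg$n_sections)) {
    th <- stats::runif(1, -cfg$rigid_max_angle, cfg$rigid_max_angle)
    tr <- stats::runif(2, -cfg$rigid_max_shift, cfg$rigid_max_shift)
    rigid_true[[n]] <- rigid2d(th, tr)
    v2_true[[n]] <- if (cfg$deform2d_amplitude > 0)
      random_velocity(d[1:2], sp[1:2], vol$origin[1:2], nt = 2,
                      width = cfg$deform2d_smoothness,
                      amplitude = cfg$deform2d_amplitude)
    else velocity_field(d[1:2], sp[1:2], vol$origin[1:2], nt = 2)

    pull2 <- function(y) {
      x <- apply_rigid(rigid_inverse(rigid_true[[n]]), y)
      flow_points(v2_true[[n]], x, "inverse")
    }
    # fine lattice: intensity + region through the full true chain
    q2 <- pull2(pts_fine)
    p3 <- cbind(q2, zs[n])
    q3 <- flow_points(v3_true, p3, "inverse")
    inten <- interp_core(vol$data, q3, sp, vol$origin, fill = 0)$value[, 1]
    reg <- interp_core(labels$data, q3, sp, vol$origin, fill = 0,
                       method = "nearest")$value[, 1]
    tissue_f <- reg > 0
    # tears: random discs until the requested tissue fraction is covered
    tearmask_f <- rep(FALSE, length(inten))
    if (cfg$tear_fraction > 0) {
      target <- cfg$tear_fraction * sum(tissue_f)
      guard <- 0L
      while (sum(tearmask_f & tissue_f) < target && guard < 200L) {
        guard <- guard + 1L
        ci <- sample(which(tissue_f), 1)
        cpt <- pts_fine[ci, ]
        rad <- stats::runif(1, cfg$tear_radius[1], cfg$tear_radius[2])
        near <- (pts_fine[, 1] - cpt[1])^2 + (pts_fine[, 2] - cpt[2])^2 <=
          rad^2
        tearmask_f <- tearmask_f | near
      }
    }
    chans <- matrix(0, length(inten), 3)
    for (ch in 1:3) {
      base <- off_c[ch] + gain_c[ch] * pmax(inten, 0)^gamma_c[ch]
      tex <- rep(0, length(inten))
      for (r in 1:4) {
        sel <- reg == r
        if (!any(sel)) next
        ph <- 2 * pi * cfg$texture_freqs[r] *
          (cos(tex_theta[r]) * pts_fine[sel, 1] +
           sin(tex_theta[r]) * pts_fine[sel, 2]) + tex_phase[r]
        tex[sel] <- cfg$texture_amp * sin(ph)
      }
      val <- base + tex * c(1, 0.8, 0.6)[ch]
      val[!tissue_f] <- cfg$background_value
      val[tearmask_f] <- cfg$tear_value
      chans[, ch] <- val + stats::rnorm(length(val), sd = cfg$noise)
    }
    slices[[n]] <- slice_image(array(chans, c(fine_dims, 3L)),
                               spacing = fine_sp, origin = vol$origin[1:2],
                               z_position = zs[n])
    # observed-frame labels / masks at template in-plane resolution
    q2c <- pull2(pts_co)
    q3c <- flow_points(v3_true, cbind(q2c, zs[n]), "inverse")
    regc <- interp_core(labels$data, q3c, sp, vol$origin, fill = 0,
                        method = "nearest")$value[, 1]
    labels2d[[n]] <- slice_image(array(regc, c(d[1:2], 1L)),
                                 spacing = sp[1:2], origin = vol$origin[1:2],
                                 z_position = zs[n])
    tm <- matrix(tearmask_f, fine_dims[1], fine_dims[2])
    tear_masks[[n]] <- block_mean_2d(tm * 1, rep(cfg$histology_factor, 2)) >
      0.5
    # correspondence table on a subsampled tissue lattice
    keep <- which(regc > 0)
    if (length(keep)) keep <- keep[seq(1, length(keep), by = 3)]
    corr[[n]] <- data.frame(y1 = pts_co[keep, 1], y2 = pts_co[keep, 2],
                            x1 = q3c[keep, 1], x2 = q3c[keep, 2],
                            x3 = q3c[keep, 3], region = regc[keep])
  }
  list(stack = slice_stack(slices),
       truth = list(v3 = v3_true, rigid = rigid_true, v2 = v2_true,
                    labels2d = labels2d, tear_masks = tear_masks,
                    correspondences = corr, z = zs))
}

#' Simulate tangle point processes per section
#'
#' Inhomogeneous Poisson process: within each labeled region the expected
#' count is `intensity[region] * region area`, with points placed uniformly
#' over the region's pixels (jittered within pixels).
#'
#' @param labels2d list of single-channel label `SliceImage`s
#' @param intensity per-region intensities (counts / mm^2)
#' @param seed RNG seed
#' @return list of data frames with columns `x`, `y` (mm) and `region`
#' @export
simulate_tangles <- function(labels2d, intensity, seed = 1L) {
  set.seed(seed)
  lapply(labels2d, function(ls) {
    lab <- ls$data[, , 1]
    pixarea <- prod(ls$spacing)
    out <- list()
    for (r in seq_along(intensity)) {
      sel <- which(lab == r)
      if (!length(sel) || intensity[r] <= 0) next
      area <- length(sel) * pixarea
      nn <- stats::rpois(1, intensity[r] * area)
      if (nn == 0) next
      pick <- sample(sel, nn, replace = TRUE)
      ij <- arrayInd(pick, dim(lab))
      x <- ls$origin[1] + (ij[, 1] - 1) * ls$spacing[1] +
        stats::runif(nn, -0.5, 0.5) * ls$spacing[1]
      y <- ls$origin[2] + (ij[, 2] - 1) * ls$spacing[2] +
        stats::runif(nn, -0.5, 0.5) * ls$spacing[2]
      out[[length(out) + 1L]] <- data.frame(x = x, y = y, region = r)
    }
    if (length(out)) do.call(rbind, out)
    else data.frame(x = numeric(0), y = numeric(0), region = integer(0))
  })
}

#' Simulate a tangle probability map
#'
#' Gaussian bumps of width `sigma` at the given points, clipped to 1, plus
#' clamped background noise — a synthetic stand-in for a per-pixel tangle
#' probability image.
#'
#' @param points data frame with `x`, `y` in mm
#' @param dims,spacing,origin output lattice geometry
#' @param sigma bump standard deviation in mm
#' @param noise background noise sd (0 disables)
#' @param z_position carried through to the output
#' @return a single-channel `SliceImage` with values in [0, 1]
#' @export
simulate_probability_map <- function(points, dims, spacing,
                                     origin = c(0, 0), sigma = 0.01,
                                     noise = 0, z_position = 0) {
  spacing <- rep(as.numeric(spacing), length.out = 2)
  map <- matrix(0, dims[1], dims[2])
  halfw <- ceiling(4 * sigma / spacing)
  for (i in seq_len(nrow(points))) {
    u <- (c(points$x[i], points$y[i]) - origin) / spacing
    i0 <- pmax(floor(u - halfw) + 1, 1)
    i1 <- pmin(ceiling(u + halfw) + 1, dims)
    if (any(i0 > i1)) next
    ii <- i0[1]:i1[1]; jj <- i0[2]:i1[2]
    dx <- (ii - 1) * spacing[1] + origin[1] - points$x[i]
    dy <- (jj - 1) * spacing[2] + origin[2] - points$y[i]
    bump <- exp(-outer(dx^2, dy^2, "+") / (2 * sigma^2))
    map[ii, jj] <- map[ii, jj] + bump
  }
  if (noise > 0)
    map <- map + pmax(stats::rnorm(length(map), sd = noise), 0)
  map <- pmin(pmax(map, 0), 1)
  slice_image(array(map, c(dims[1], dims[2], 1L)), spacing = spacing,
              origin = origin, z_position = z_position)
}
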