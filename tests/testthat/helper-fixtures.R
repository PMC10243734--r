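# Shared fixtures. Heavy objects (phantom, registrations) are built once per
# test run and cached; everything is generated in code under fixed seeds.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# a small smooth single-channel template: Gaussian blob, zero at the border
tiny_template <- function(dims = c(20L, 20L, 12L), spacing = 0.5) {
  g <- expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]),
                   k = seq_len(dims[3]))
  ctr <- (dims + 1) / 2
  val <- exp(-((g$i - ctr[1])^2 + (g$j - ctr[2])^2 +
               (g$k - ctr[3])^2) / 18)
  image_volume(array(val, c(dims, 1L)), spacing = rep(spacing, 3))
}

# kernel-smooth random values shaped like a velocity array; tapered to zero
# at the lattice border so the field is continuous across the hull
smooth_field <- function(dims, spacing, kern, shape, amplitude = 1) {
  mult <- projlddmm:::kernel_multiplier(kern, dims, spacing)
  x <- array(stats::rnorm(prod(shape)), shape)
  m <- matrix(x, prod(dims))
  taper <- array(1, dims)
  for (a in seq_along(dims)) {
    r <- pmin((seq_len(dims[a]) - 1) / 3, (dims[a] - seq_len(dims[a])) / 3,
              1)
    shp <- rep(1L, length(dims)); shp[a] <- dims[a]
    taper <- taper * array(rep(r, each = prod(dims[seq_len(a - 1)])),
                           dim = dims)
  }
  for (cc in seq_len(ncol(m)))
    m[, cc] <- as.vector(projlddmm:::kernel_apply(array(m[, cc], dims),
                                                  mult) * taper)
  x <- array(m, shape)
  x * amplitude / max(abs(x))
}

# a small synthetic registration state with all slice pixels interior to the
# template hull (the objective is differentiable there)
tiny_state <- function(seed = 11, v3_amp = 0.15, v2_amp = 0.1) {
  set.seed(seed)
  tmpl <- tiny_template()
  d <- c(20L, 20L, 12L)
  sp <- rep(0.5, 3)
  kern3 <- kernel_spec(1.5)
  v3 <- velocity_field(d, sp, nt = 3, kernel = kern3)
  v3$values <- smooth_field(d, sp, kern3, dim(v3$values), v3_amp)
  slices <- list()
  for (n in 1:2) {
    dims2 <- c(14L, 14L)
    # inset from the hull; z off the voxel-center planes so the chain is
    # locally smooth (trilinear interpolation kinks on lattice planes)
    orig2 <- c(1.53, 1.47)
    geom <- slice_image(array(0, c(dims2, 1L)), sp[1:2], orig2,
                        z_position = 1.53 + 0.93 * n)
    pts <- projlddmm:::lattice_points(geom)
    kern2 <- kernel_spec(1.0)
    v2 <- velocity_field(dims2, sp[1:2], orig2, nt = 2, kernel = kern2)
    v2$values <- smooth_field(dims2, sp[1:2], kern2, dim(v2$values), v2_amp)
    pim <- matrix(stats::runif(nrow(pts) * 3), nrow(pts), 3)
    pim <- pim / rowSums(pim)
    slices[[n]] <- list(
      pts = pts, dims = dims2, spacing = sp[1:2], origin = orig2,
      z = 1.53 + 0.93 * n, basis = NULL, alpha = NULL,
      pred = stats::runif(nrow(pts)), pi = pim,
      params = mixture_params(0.3, 0.05, sigma = c(0.2, 0.3, 0.25)),
      rigid = rigid2d(0.03, c(0.1, -0.05)), v2 = v2)
  }
  projlddmm:::new_proj_state(tmpl, v3, slices, w_v = 1, w_u = 1)
}

default_phantom <- function() {
  fixture("phantom_default", function() {
    cfg <- phantom_config(seed = 1L)
    tm <- make_template(cfg)
    sim <- simulate_sections(tm, cfg)
    list(cfg = cfg, template = tm, sim = sim)
  })
}

# the study configuration for phantom registrations: penalties sized to the
# matching term, and the 3D kernel width set to the phantom's deformation
# correlation scale
phantom_reg_config <- function(outer_iters = 12L) {
  registration_config(outer_iters = outer_iters, levels = 2L,
                      w_v = 30, w_u = 3000, kernel_width_v = 2.5)
}

default_registration <- function() {
  fixture("registration_default", function() {
    ph <- default_phantom()
    register_stack(ph$template$volume, ph$sim$stack, phantom_reg_config())
  })
}

tear_phantom <- function() {
  fixture("phantom_tear", function() {
    cfg <- phantom_config(seed = 1L, tear_fraction = 0.1)
    tm <- make_template(cfg)
    sim <- simulate_sections(tm, cfg)
    list(cfg = cfg, template = tm, sim = sim)
  })
}

tear_registration <- function() {
  fixture("registration_tear", function() {
    ph <- tear_phantom()
    cfg <- phantom_reg_config(outer_iters = 10L)
    cfg$update_sigma <- TRUE     # sharper class separation for artifacts
    cfg$init_irls <- 3L          # robust contrast fit through tears
    register_stack(ph$template$volume, ph$sim$stack, cfg)
  })
}
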