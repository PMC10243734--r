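#' Registration configuration
#'
#' Controls the alternating optimization that solves the projective
#' registration problem: energy-term weights, iteration schedule, step
#' sizes, convergence tolerances and mode flags.
#'
#' @param w_v,w_u weights of the 3D and per-section 2D kernel-norm path
#'   energies (>= 0)
#' @param outer_iters outer alternation iterations per resolution level; a
#'   scalar, or a vector with one entry per level (coarse first)
#' @param n_rigid,n_u,n_v inner steps per block (Gauss-Newton iterations on
#'   the rigid motion; Hilbert gradient steps on each section field u_n and
#'   on the template field v)
#' @param step_v,step_u initial step sizes for the Hilbert updates (adapted
#'   by backtracking line search)
#' @param nt_v,nt_u flow timesteps in 3D and 2D
#' @param kernel_width_v,kernel_width_u Gaussian kernel widths in mm; `NULL`
#'   defaults to 5x the template voxel spacing (3D) and 3x the section pixel
#'   spacing (2D)
#' @param levels resolution levels (2 = one 2x-coarsened pass then full)
#' @param tol relative energy-change convergence tolerance (over 3 outer
#'   iterations)
#' @param rigid_enabled,diffeo2d_enabled,mixture_enabled,contrast_enabled
#'   mode flags
#' @param alpha_refit when to re-estimate the contrast coefficients:
#'   `"level"` (default; once at the start of each resolution level, with
#'   geometry held at its initial conditions — re-fitting every iteration
#'   lets the contrast channel absorb geometric misalignment and stalls the
#'   rigid/diffeomorphic estimates), `"iteration"`, or `"never"`
#' @param init_irls number of reweighted contrast-refit rounds at each
#'   level's initialization (0 disables). For artifact-heavy sections the
#'   unweighted first fit regresses through tears; a few reweighted rounds
#'   exclude them. On clean data the extra reweighting can slightly
#'   down-weight hard-to-predict (texture-separated) regions, so it is off
#'   by default.
#' @param update_sigma also update mixture standard deviations in the M-step
#' @param sigma optional fixed length-3 sigma overriding the robust
#'   initialization
#' @param m contrast subspace dimension (basis has `m + 1` elements)
#' @param scattering a [scattering_config()]
#' @param verbose print per-iteration energies
#' @return a `RegistrationConfig`
#' @export
registration_config <- function(w_v = 1, w_u = 1,
                                outer_iters = 12L, n_rigid = 2L, n_u = 2L,
                                n_v = 2L, step_v = 0.1, step_u = 0.1,
                                nt_v = 5L, nt_u = 3L,
                                kernel_width_v = NULL, kernel_width_u = NULL,
                                levels = 2L, tol = 1e-4,
                                rigid_enabled = TRUE, diffeo2d_enabled = TRUE,
                                mixture_enabled = TRUE,
                                contrast_enabled = TRUE,
                                alpha_refit = c("level", "iteration",
                                                "never"),
                                init_irls = 0L,
                                update_sigma = FALSE, sigma = NULL,
                                m = 6L, scattering = scattering_config(),
                                verbose = FALSE) {
  alpha_refit <- match.arg(alpha_refit)
  stopifnot(w_v >= 0, w_u >= 0, all(outer_iters >= 1), n_rigid >= 0,
            n_u >= 0, n_v >= 0, levels >= 1)
  structure(as.list(environment()), class = "RegistrationConfig")
}

#' Register a section stack onto a 3D template
#'
#' Alternating optimization of the projective registration problem. Each
#' section's in-plane rotation is first initialized by a sweep with the
#' contrast coefficients profiled out (re-fit per candidate angle) — at
#' fixed coefficients the rotation landscape is trapped at the identity
#' because the contrast fit absorbs the misalignment. Then, per outer
#' iteration: (1) the contrast block estimates each section's linear
#' coefficients by weighted least squares (by default once per resolution
#' level, at its initial geometry, then held fixed — see `alpha_refit`),
#' (2) the mixture block recomputes the tissue/artifact/background weight
#' fields (E-step) and nuisance means (M-step), and (3) the geometry block
#' takes Gauss-Newton steps on each in-plane rigid motion and Hilbert
#' gradient steps on each section field u_n and on the template field v,
#' line-searched with a sufficient-decrease condition on the same
#' free-energy objective. The whole alternation is a generalized EM scheme:
#' the recorded energy trace is non-increasing.
#'
#' @param template a single-channel `ImageVolume`
#' @param stack a `SliceStack` of section images (multi-channel fine-scale
#'   pseudo-histology when the contrast channel is enabled, single-channel
#'   template-intensity sections otherwise)
#' @param cfg a [registration_config()]
#' @return a `RegistrationResult`: the 3D `DiffeoMap` `phi`, per-section
#'   rigid motions, 2D `DiffeoMap`s, coefficients, weight fields and mixture
#'   parameters, the velocity fields, and the per-iteration energy trace
#' @export
register_stack <- function(template, stack, cfg = registration_config()) {
  stopifnot(inherits(template, "ImageVolume"), inherits(stack, "SliceStack"))
  if (n_channels(template) != 1L)
    stop("registration template must be single-channel")
  zs <- slice_positions(stack)
  d <- dim(template$data)
  zr <- range(template$origin[3] + (seq_len(d[3]) - 1) * template$spacing[3])
  if (any(zs < zr[1] | zs > zr[2]))
    stop("stack z positions fall outside the template z range")

  # ---- contrast front end: per-section basis images at template in-plane
  # resolution, or the sections themselves when crossing is disabled
  target_sp <- template$spacing[1:2]
  if (cfg$contrast_enabled) {
    stacks <- lapply(stack$slices, scatter, cfg = cfg$scattering,
                     target_spacing = target_sp)
    bases <- build_basis(stacks, m = cfg$m)
  } else {
    if (n_channels(stack$slices[[1]]) != 1L)
      stop("contrast_enabled = FALSE requires single-channel sections")
    bases <- lapply(stack$slices, function(s) {
      fac <- target_sp / s$spacing
      ds <- if (max(abs(fac - round(fac))) < 1e-8 && all(round(fac) >= 1))
        block_downsample(s, target_sp) else resample_slice(s, target_sp)
      structure(list(psi = ds, loadings = NULL, m = 0L),
                class = "PredictiveBasis")
    })
  }

  levels <- rev(seq_len(cfg$levels))  # coarsening factors 2^(level-1)
  iters <- rep(cfg$outer_iters, length.out = cfg$levels)
  state <- NULL
  trace_all <- list()
  for (li in seq_along(levels)) {
    fac <- 2^(levels[li] - 1)
    lvl <- build_level(template, bases, zs, cfg, fac, prev = state)
    state <- lvl$state
    cfg_l <- cfg
    cfg_l$outer_iters <- iters[li]
    res <- run_level(state, cfg_l,
                     init = (li == 1), label = sprintf("level %d", fac))
    state <- res$state
    trace_all[[li]] <- res$trace
  }

  finalize_result(state, cfg, trace_all)
}

# assemble the optimization state at one resolution level
build_level <- function(template, bases, zs, cfg, fac, prev = NULL) {
  tmpl <- if (fac > 1) downsample_volume(template, fac) else template
  kw_v <- cfg$kernel_width_v %||% (5 * min(template$spacing))
  kw_u <- cfg$kernel_width_u %||%
    (3 * min(bases[[1]]$psi$spacing))
  d3 <- dim(tmpl$data)[1:3]
  v3 <- velocity_field(d3, tmpl$spacing, tmpl$origin, nt = cfg$nt_v,
                       kernel = kernel_spec(kw_v))
  if (!is.null(prev))
    v3$values <- prolong_velocity(prev$v3, d3, tmpl$spacing, tmpl$origin)
  slices <- vector("list", length(bases))
  for (n in seq_along(bases)) {
    psi <- bases[[n]]$psi
    ps <- if (fac > 1) block_downsample(psi, psi$spacing * fac) else psi
    dims2 <- dim(ps$data)[1:2]
    geom <- slice_image(array(0, c(dims2, 1)), ps$spacing, ps$origin, zs[n])
    pts <- lattice_points(geom)
    v2 <- if (cfg$diffeo2d_enabled)
      velocity_field(dims2, ps$spacing, ps$origin, nt = cfg$nt_u,
                     kernel = kernel_spec(kw_u))
    else NULL
    if (!is.null(prev) && !is.null(prev$slices[[n]]$v2) && !is.null(v2))
      v2$values <- prolong_velocity(prev$slices[[n]]$v2, dims2,
                                    ps$spacing, ps$origin)
    basis_lvl <- bases[[n]]
    basis_lvl$psi <- ps
    slices[[n]] <- list(
      pts = pts, dims = dims2, spacing = ps$spacing, origin = ps$origin,
      z = zs[n], basis = basis_lvl,
      alpha = if (!is.null(prev)) prev$slices[[n]]$alpha else NULL,
      pred = NULL,
      pi = NULL,
      params = if (!is.null(prev)) prev$slices[[n]]$params else NULL,
      rigid = if (!is.null(prev)) prev$slices[[n]]$rigid else rigid2d(),
      v2 = v2)
  }
  list(state = new_proj_state(tmpl, v3, slices, cfg$w_v, cfg$w_u))
}

# interpolate a coarse velocity field onto a fine lattice (per component and
# timestep; zero-fill beyond the coarse hull)
prolong_velocity <- function(v, dims_f, spacing_f, origin_f) {
  nd <- vf_nd(v)
  cls <- if (nd == 3) "ImageVolume" else "SliceImage"
  geom <- structure(list(data = array(0, c(dims_f, 1)), spacing = spacing_f,
                         origin = origin_f), class = cls)
  pts <- lattice_points(geom)
  out <- array(0, c(dims_f, nd, v$nt))
  for (t in seq_len(v$nt)) {
    field <- if (nd == 3) v$values[, , , , t, drop = FALSE]
             else v$values[, , , t, drop = FALSE]
    dim(field) <- c(v$dims, nd)
    vals <- interp_core(field, pts, v$spacing, v$origin, fill = 0)$value
    if (nd == 3) out[, , , , t] <- array(vals, c(dims_f, nd))
    else out[, , , t] <- array(vals, c(dims_f, nd))
  }
  out
}

# one resolution level of the alternation
run_level <- function(state, cfg, init = FALSE, label = "") {
  ns <- length(state$slices)
  # --- in-plane rotation initialization (first level only): sweep each
  # section's angle with the contrast coefficients profiled out (refit per
  # candidate). Sweeping at fixed alpha is trapped at the identity — the
  # contrast fit absorbs the rotation — whereas the profiled objective's
  # minimizer tracks the true angle.
  if (init && cfg$rigid_enabled && cfg$contrast_enabled) {
    grid <- seq(-0.12, 0.12, by = 0.02)
    for (n in seq_len(ns)) {
      sl <- state$slices[[n]]
      costs <- vapply(grid, function(th) {
        sl2 <- sl
        sl2$rigid <- rigid2d(th, c(0, 0))
        st2 <- state
        st2$slices[[n]] <- sl2
        o <- chain_forward(st2, n)$obs
        a <- estimate_alpha(sl$basis, matrix_to_slice(o, sl))
        p <- as.vector(predict_contrast(sl$basis, a)$data[, , 1])
        sum((p - o)^2)
      }, numeric(1))
      state$slices[[n]]$rigid <- rigid2d(grid[which.min(costs)], c(0, 0))
    }
  }
  # --- initialization: alpha by plain least squares against the projected
  # template at the level's initial geometry; sigma from the robust
  # (tissue-restricted) residual scale; mu_A/mu_B from observation quantiles
  for (n in seq_len(ns)) {
    sl <- state$slices[[n]]
    obs <- chain_forward(state, n)$obs
    if (is.null(sl$alpha)) {
      sl$alpha <- if (cfg$contrast_enabled)
        estimate_alpha(sl$basis, matrix_to_slice(obs, sl))
      else structure(c(1), class = "Coefficients")
    }
    sl$pred <- predict_vec(sl)
    if (is.null(sl$params)) {
      resid <- sl$pred - obs
      # robust residual scale over tissue-like pixels: the background
      # dominates the lattice and would shrink sigma to the noise floor
      tissue <- tryCatch(obs > otsu_threshold(matrix(obs))$threshold,
                         error = function(e) rep(TRUE, length(obs)))
      if (sum(tissue) < 20) tissue <- rep(TRUE, length(obs))
      s0 <- if (!is.null(cfg$sigma)) cfg$sigma
            else rep(max(stats::mad(resid[tissue]), 1e-3), 3)
      sl$params <- mixture_params(
        mu_A = stats::median(obs[tissue]),
        mu_B = stats::quantile(obs, 0.02),
        sigma = s0, r = 1L)
    }
    sl$pi <- init_weights(sl, obs, cfg)
    # optional reweighted refits of the contrast fit at the initial
    # geometry: the unweighted first fit regresses through artifact pixels,
    # and the mixture weights progressively exclude them (block descent on
    # the free energy before any geometry moves)
    if (cfg$contrast_enabled && cfg$mixture_enabled && cfg$init_irls > 0) {
      for (irls in seq_len(cfg$init_irls)) {
        w1 <- sl$pi[, 1]
        if (sum(w1) <= 0) break
        sl$alpha <- estimate_alpha(sl$basis, matrix_to_slice(obs, sl),
                                   weights = matrix(w1, sl$dims[1]))
        sl$pred <- predict_vec(sl)
        obs_m <- matrix(obs, sl$dims[1])
        means <- list(mu1 = matrix(sl$pred, sl$dims[1]),
                      mu2 = matrix(sl$params$mu_A, sl$dims[1], sl$dims[2]),
                      mu3 = matrix(sl$params$mu_B, sl$dims[1], sl$dims[2]))
        pf <- e_step(obs_m, means, sl$params)
        sl$params <- m_step_nuisance(obs_m, pf, sl$params,
                                     update_sigma = cfg$update_sigma,
                                     mu1 = means$mu1)
        pf <- e_step(obs_m, means, sl$params)
        sl$pi <- matrix(pf, length(obs), 3)
      }
    }
    state$slices[[n]] <- sl
  }

  step_v <- cfg$step_v
  step_u <- rep(cfg$step_u, ns)
  trace <- numeric(0)
  e_prev <- total_objective(state)
  for (it in seq_len(cfg$outer_iters)) {
    # (1) contrast block: by default the coefficients are fitted from the
    # level's initial conditions only (it == 1) and then held fixed while
    # geometry moves — per-iteration refits let the contrast channel
    # explain away misalignment
    refit_now <- cfg$contrast_enabled &&
      (cfg$alpha_refit == "iteration" ||
       (cfg$alpha_refit == "level" && it == 1L))
    if (refit_now) {
      for (n in seq_len(ns)) {
        sl <- state$slices[[n]]
        obs <- chain_forward(state, n)$obs
        w1 <- sl$pi[, 1]
        if (sum(w1) > 0) {
          sl$alpha <- estimate_alpha(sl$basis, matrix_to_slice(obs, sl),
                                     weights = matrix(w1, sl$dims[1]))
          sl$pred <- predict_vec(sl)
        }
        state$slices[[n]] <- sl
      }
    }
    # (2) mixture block
    if (cfg$mixture_enabled) {
      for (n in seq_len(ns)) {
        sl <- state$slices[[n]]
        obs <- chain_forward(state, n)$obs
        obs_m <- matrix(obs, sl$dims[1])
        means <- list(mu1 = matrix(sl$pred, sl$dims[1]),
                      mu2 = matrix(sl$params$mu_A, sl$dims[1], sl$dims[2]),
                      mu3 = matrix(sl$params$mu_B, sl$dims[1], sl$dims[2]))
        pf <- e_step(obs_m, means, sl$params)
        sl$pi <- matrix(pf, length(obs), 3)
        sl$params <- m_step_nuisance(obs_m, pf, sl$params,
                                     update_sigma = cfg$update_sigma,
                                     mu1 = means$mu1)
        state$slices[[n]] <- sl
      }
    }
    # (3) geometry block
    if (cfg$rigid_enabled) {
      for (n in seq_len(ns))
        state <- rigid_gauss_newton(state, n, iters = cfg$n_rigid)
    }
    if (cfg$diffeo2d_enabled && cfg$n_u > 0) {
      for (n in seq_len(ns)) {
        for (s in seq_len(cfg$n_u)) {
          upd <- hilbert_update_v2(state, n, step_u[n])
          state <- upd$state
          step_u[n] <- upd$step
        }
      }
    }
    if (cfg$n_v > 0) {
      for (s in seq_len(cfg$n_v)) {
        upd <- hilbert_update_v3(state, step_v)
        state <- upd$state
        step_v <- upd$step
      }
    }
    e_now <- total_objective(state)
    trace <- c(trace, e_now)
    if (cfg$verbose)
      message(sprintf("%s iter %d: energy %.6g", label, it, e_now))
    if (it >= 3) {
      recent <- abs(diff(utils::tail(c(e_prev, trace), 4)))
      if (all(recent < cfg$tol * max(abs(e_now), 1e-12))) break
    }
  }
  list(state = state, trace = trace)
}

init_weights <- function(sl, obs, cfg) {
  if (!cfg$mixture_enabled) {
    pi0 <- matrix(0, length(obs), 3)
    pi0[, 1] <- 1
    return(pi0)
  }
  means <- list(mu1 = matrix(sl$pred, sl$dims[1]),
                mu2 = matrix(sl$params$mu_A, sl$dims[1], sl$dims[2]),
                mu3 = matrix(sl$params$mu_B, sl$dims[1], sl$dims[2]))
  pf <- e_step(matrix(obs, sl$dims[1]), means, sl$params)
  matrix(pf, length(obs), 3)
}

predict_vec <- function(sl) {
  if (is.null(sl$basis$loadings) && sl$basis$m == 0L) {
    as.vector(sl$basis$psi$data[, , 1]) * sl$alpha[1]
  } else {
    as.vector(predict_contrast(sl$basis, sl$alpha)$data[, , 1])
  }
}

matrix_to_slice <- function(obs, sl) {
  slice_image(array(obs, c(sl$dims, 1L)), sl$spacing, sl$origin, sl$z)
}

# Gauss-Newton on the in-plane rigid parameters (theta, tx, ty) with
# Levenberg damping on non-descent; residuals are the weighted class
# residuals, Jacobian by central differences on the 3 parameters.
rigid_gauss_newton <- function(state, n, iters = 2L, fd_eps = NULL) {
  sl <- state$slices[[n]]
  if (is.null(fd_eps)) fd_eps <- c(1e-4, 1e-3 * sl$spacing)
  mats3 <- vf_mats(state$v3)
  mats2 <- if (!is.null(sl$v2)) vf_mats(sl$v2)
  resid_fun <- function(par) {
    sl2 <- sl
    sl2$rigid <- rigid2d(par[1], par[2:3])
    st2 <- state
    st2$slices[[n]] <- sl2
    obs <- chain_forward(st2, n, mats3 = mats3, mats2 = mats2)$obs
    mu <- cbind(sl$pred, sl$params$mu_A, sl$params$mu_B)
    r <- lapply(1:3, function(k)
      sqrt(sl$pi[, k] / (2 * sl$params$sigma[k]^2)) * (obs - mu[, k]))
    do.call(c, r)
  }
  par <- c(sl$rigid$theta, sl$rigid$translation)
  lambda <- 1e-6
  for (gn in seq_len(iters)) {
    r0 <- resid_fun(par)
    cost0 <- sum(r0^2)
    J <- matrix(0, length(r0), 3)
    for (p in 1:3) {
      dp <- numeric(3); dp[p] <- fd_eps[p]
      J[, p] <- (resid_fun(par + dp) - r0) / fd_eps[p]
    }
    JtJ <- crossprod(J)
    g <- crossprod(J, r0)
    ok <- FALSE
    for (try in 1:6) {
      delta <- tryCatch(-solve(JtJ + lambda * diag(diag(JtJ) + 1e-12), g),
                        error = function(e) NULL)
      if (is.null(delta)) { lambda <- lambda * 10; next }
      cand <- par + as.vector(delta)
      if (sum(resid_fun(cand)^2) < cost0) {
        par <- cand
        lambda <- max(lambda / 10, 1e-9)
        ok <- TRUE
        break
      }
      lambda <- lambda * 10
    }
    if (!ok) break
  }
  state$slices[[n]]$rigid <- rigid2d(par[1], par[2:3])
  state
}

# one backtracking Hilbert gradient step on v3; the path-energy change along
# the direction is expanded as a quadratic so trials only re-evaluate the
# matching term; returns the adapted step
hilbert_update_v3 <- function(state, step, max_halve = 8L) {
  step <- min(step, 0.5 * min(state$v3$spacing))   # cap: half a voxel
  gm <- gradient_v3(state, include_penalty = FALSE)
  dir <- hilbert_direction(state$v3, gm, state$w_v)
  m0 <- match_total(state)
  pe_b <- path_energy_bilinear(state$v3, state$v3$values, dir)
  dir_field <- state$v3
  dir_field$values <- dir
  pe_c <- path_energy(dir_field)
  # Armijo slope: <dir, full Euclidean gradient>
  slope <- sum(dir * (gm + path_energy_gradient(state$v3, state$w_v)))
  sc <- step / max(max(abs(dir)), 1e-12)   # step in mm of max displacement
  for (h in seq_len(max_halve)) {
    cand <- state
    cand$v3$values <- state$v3$values - sc * dir
    dpe <- state$w_v * (-2 * sc * pe_b + sc^2 * pe_c)
    if (match_total(cand) + dpe <= m0 - 1e-4 * sc * slope) {
      return(list(state = cand, step = step * 1.3))
    }
    sc <- sc / 2
  }
  list(state = state, step = step / 2)
}

hilbert_update_v2 <- function(state, n, step, max_halve = 8L) {
  sl0 <- state$slices[[n]]
  step <- min(step, 0.25 * min(sl0$v2$spacing))    # cap: quarter pixel
  gm <- gradient_v2(state, n, include_penalty = FALSE)
  sl <- state$slices[[n]]
  dir <- hilbert_direction(sl$v2, gm, state$w_u)
  m0 <- slice_free_energy(sl, chain_forward(state, n)$obs)
  pe_b <- path_energy_bilinear(sl$v2, sl$v2$values, dir)
  dir_field <- sl$v2
  dir_field$values <- dir
  pe_c <- path_energy(dir_field)
  slope <- sum(dir * (gm + path_energy_gradient(sl$v2, state$w_u)))
  sc <- step / max(max(abs(dir)), 1e-12)
  for (h in seq_len(max_halve)) {
    cand <- state
    cand$slices[[n]]$v2$values <- sl$v2$values - sc * dir
    dpe <- state$w_u * (-2 * sc * pe_b + sc^2 * pe_c)
    m1 <- slice_free_energy(cand$slices[[n]],
                            chain_forward(cand, n)$obs)
    if (m1 + dpe <= m0 - 1e-4 * sc * slope)
      return(list(state = cand, step = step * 1.3))
    sc <- sc / 2
  }
  list(state = state, step = step / 2)
}

finalize_result <- function(state, cfg, trace_all) {
  map3 <- integrate_flow(state$v3)
  if (!map3$jacobian_positive)
    warning("final 3D map has non-positive Jacobian determinants")
  per_slice <- lapply(state$slices, function(sl) {
    list(rigid = sl$rigid,
         map2 = if (!is.null(sl$v2)) integrate_flow(sl$v2) else NULL,
         v2 = sl$v2,
         alpha = sl$alpha,
         weights = array(sl$pi, c(sl$dims, 3)),
         params = sl$params,
         predicted = matrix_to_slice(sl$pred, sl),
         z = sl$z, spacing = sl$spacing, origin = sl$origin,
         dims = sl$dims)
  })
  structure(list(map3 = map3, v3 = state$v3, slices = per_slice,
                 energy_trace = utils::tail(trace_all, 1)[[1]],
                 energy_trace_levels = trace_all,
                 template_spacing = state$template$spacing,
                 config = cfg, state = state),
            class = "RegistrationResult")
}

#' @export
print.RegistrationResult <- function(x, ...) {
  cat(sprintf("RegistrationResult: %d sections, final energy %.6g\n",
              length(x$slices), utils::tail(x$energy_trace, 1)))
  invisible(x)
}

#' Map a 3D label volume into a section's frame
#'
#' Labels are carried through the estimated transforms — deformed by the 3D
#' diffeomorphism, sliced at the section plane, deformed by the in-plane
#' transform — with nearest-neighbor sampling throughout (no new label
#' values are created).
#'
#' @param labels3d an `ImageVolume` of integer labels
#' @param result a `RegistrationResult`
#' @param slice_index section index (1-based)
#' @return a single-channel `SliceImage` of labels on the section lattice
#' @export
map_labels <- function(labels3d, result, slice_index) {
  if (slice_index < 1 || slice_index > length(result$slices))
    stop("unknown slice index: ", slice_index)
  sl <- result$state$slices[[slice_index]]
  cf <- chain_forward(result$state, slice_index)
  vals <- interp_core(labels3d$data, cf$q3, labels3d$spacing,
                      labels3d$origin, fill = 0, method = "nearest")$value
  slice_image(array(vals[, 1], c(sl$dims, 1L)), sl$spacing, sl$origin, sl$z)
}

#' Dice overlap of two masks
#'
#' `2 |A & B| / (|A| + |B|)`; 1 for identical non-empty masks, 0 for
#' disjoint ones.
#'
#' @param a,b logical arrays of equal size
#' @return scalar in [0, 1]
#' @export
dice <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  stopifnot(length(a) == length(b))
  denom <- sum(a) + sum(b)
  if (denom == 0) return(NA_real_)
  2 * sum(a & b) / denom
}

#' 95th-percentile symmetric Hausdorff boundary distance
#'
#' Boundary pixels are foreground pixels with at least one 4-neighbor
#' outside the mask (or on the array edge); the statistic is the 95th
#' percentile of the pooled nearest boundary-to-boundary distances in both
#' directions, in mm.
#'
#' @param a,b non-empty logical matrices of equal size
#' @param spacing pixel spacing in mm (length 2)
#' @return distance in mm
#' @export
hausdorff95 <- function(a, b, spacing = c(1, 1)) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!any(a) || !any(b)) stop("hausdorff95 requires non-empty masks")
  pa <- boundary_points(a, spacing)
  pb <- boundary_points(b, spacing)
  dmat <- outer(pa[, 1], pb[, 1], "-")^2 + outer(pa[, 2], pb[, 2], "-")^2
  dab <- sqrt(apply(dmat, 1, min))
  dba <- sqrt(apply(dmat, 2, min))
  as.numeric(stats::quantile(c(dab, dba), 0.95, names = FALSE))
}

boundary_points <- function(mask, spacing) {
  d <- dim(mask)
  pad <- matrix(FALSE, d[1] + 2, d[2] + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1)] <- mask
  inner <- pad[2:(d[1] + 1), 3:(d[2] + 2)] &
           pad[2:(d[1] + 1), 1:d[2]] &
           pad[3:(d[1] + 2), 2:(d[2] + 1)] &
           pad[1:d[1], 2:(d[2] + 1)]
  bnd <- which(mask & !inner, arr.ind = TRUE)
  cbind((bnd[, 1] - 1) * spacing[1], (bnd[, 2] - 1) * spacing[2])
}
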