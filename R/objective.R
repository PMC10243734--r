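# Internal machinery for the projective registration objective.
#
# The observation model chains, for every pixel y of section n:
#   x  = A_n^{-1}(y)                      (in-plane rigid/affine)
#   q2 = psi2d_n(x)                       (inverse 2D diffeo: backward Euler
#                                          flow of the section velocity u_n)
#   p  = (q2, z_n)                        (embed at the section plane)
#   q3 = psi3d(p)                         (inverse 3D diffeo: backward flow
#                                          of the template velocity v)
#   obs(y) = I_temp(q3)                   (trilinear sampling)
# so that obs = phi_n . P_n (I_temp o phi^-1) evaluated on the slice lattice.
# The full objective is
#   w_v * pathE(v) + sum_n w_u * pathE(u_n) + sum_n FE_n
# with FE_n the mixture free energy (weighted matching cost plus weight
# entropy and normalizer terms), so that every block of the alternation -
# E-step, nuisance M-step, contrast least squares, and line-searched
# geometry steps - is non-increasing in the same scalar.
#
# Gradients with respect to the velocity values are the exact reverse-mode
# derivatives of this discretization (interpolation adjoints through every
# Euler step), which is what makes them pass central finite-difference
# checks at 1e-3 relative error and better.

# --- state -----------------------------------------------------------------

new_proj_state <- function(template, v3, slices, w_v = 1, w_u = 1) {
  list(template = template, v3 = v3, slices = slices, w_v = w_v, w_u = w_u)
}

# forward chain for slice n; pts2d defaults to the slice lattice.
# Returns obs plus the per-step point traces needed for backprop.
chain_forward <- function(state, n, pts2d = NULL, with_trace = FALSE,
                          mats3 = NULL, mats2 = NULL) {
  sl <- state$slices[[n]]
  y <- if (is.null(pts2d)) sl$pts else pts2d
  x <- apply_rigid(rigid_inverse(sl$rigid), y)
  trace2 <- NULL
  q <- x
  if (!is.null(sl$v2)) {
    nt2 <- sl$v2$nt; dt2 <- 1 / nt2
    if (with_trace) trace2 <- vector("list", nt2)
    kk <- 0L
    for (t in rev(seq_len(nt2))) {
      kk <- kk + 1L
      if (with_trace) trace2[[kk]] <- q
      q <- q - dt2 * vf_at(sl$v2, t, q,
                           mat = if (!is.null(mats2)) mats2[[t]])$value
    }
  }
  p <- cbind(q, sl$z)
  trace3 <- NULL
  if (!is.null(state$v3)) {
    nt3 <- state$v3$nt; dt3 <- 1 / nt3
    if (with_trace) trace3 <- vector("list", nt3)
    kk <- 0L
    for (t in rev(seq_len(nt3))) {
      kk <- kk + 1L
      if (with_trace) trace3[[kk]] <- p
      p <- p - dt3 * vf_at(state$v3, t, p,
                           mat = if (!is.null(mats3)) mats3[[t]])$value
    }
  }
  ip <- interp_core(state$template$data, p, state$template$spacing,
                    state$template$origin, fill = 0,
                    need_grad = with_trace)
  list(obs = ip$value[, 1], q3 = p, grad_template = ip$grad,
       trace2 = trace2, trace3 = trace3)
}

# mixture free energy of slice n given an obs vector (pi, params, pred fixed)
slice_free_energy <- function(sl, obs) {
  mu <- cbind(sl$pred, sl$params$mu_A, sl$params$mu_B)
  total <- 0
  for (k in 1:3) {
    pk <- sl$pi[, k]
    dk <- (mu[, k] - obs)^2 / (2 * sl$params$sigma[k]^2) +
      sl$params$r * log(sl$params$sigma[k]) - log(sl$params$priors[k])
    ent <- ifelse(pk > 0, pk * log(pk), 0)
    total <- total + sum(pk * dk + ent)
  }
  total
}

# d FE_n / d obs
match_grad_obs <- function(sl, obs) {
  mu <- cbind(sl$pred, sl$params$mu_A, sl$params$mu_B)
  g <- 0
  for (k in 1:3)
    g <- g + sl$pi[, k] * (obs - mu[, k]) / sl$params$sigma[k]^2
  g
}

total_objective <- function(state) {
  state$w_v * path_energy(state$v3) + penalty_v2_total(state) +
    match_total(state)
}

match_total <- function(state) {
  total <- 0
  mats3 <- vf_mats(state$v3)
  for (n in seq_along(state$slices)) {
    cf <- chain_forward(state, n, mats3 = mats3)
    total <- total + slice_free_energy(state$slices[[n]], cf$obs)
  }
  total
}

penalty_v2_total <- function(state) {
  total <- 0
  for (sl in state$slices)
    if (!is.null(sl$v2)) total <- total + state$w_u * path_energy(sl$v2)
  total
}

# bilinear form of the path-energy quadratic: dt * cellvol * sum_t
# <a_t, K^-1 b_t>, evaluated spectrally (a, b arrays shaped like v$values)
path_energy_bilinear <- function(v, a, b) {
  nd <- vf_nd(v)
  mult <- kernel_multiplier(v$kernel, v$dims, v$spacing)
  n <- prod(v$dims)
  total <- 0
  for (t in seq_len(v$nt)) {
    for (cc in seq_len(nd)) {
      fa <- stats::fft(array(if (nd == 3) a[, , , cc, t] else a[, , cc, t],
                             v$dims))
      fb <- stats::fft(array(if (nd == 3) b[, , , cc, t] else b[, , cc, t],
                             v$dims))
      total <- total + sum(Re(Conj(fa) * fb) / mult) / n
    }
  }
  total * prod(v$spacing) / v$nt
}

# backprop dE/d(q_last) through a backward-Euler flow trace.
# Returns the cotangent at the chain input and the per-timestep scatter
# contributions (list of arrays c(dims, nd)) for the velocity gradient.
backprop_flow <- function(v, trace, cot, need_grad_v = TRUE, mats = NULL) {
  nd <- vf_nd(v)
  dt <- 1 / v$nt
  gv <- vector("list", v$nt)
  kk <- length(trace)
  for (t in seq_len(v$nt)) {     # reverse of the backward loop: t = 1..nt
    # step kk used time index t and position trace[[kk]]
    q <- trace[[kk]]
    va <- vf_at(v, t, q, need_grad = TRUE,
                mat = if (!is.null(mats)) mats[[t]])
    if (need_grad_v)
      gv[[t]] <- interp_adjoint(v$dims, q, -dt * cot, v$spacing, v$origin)
    newcot <- cot
    for (b in seq_len(nd))
      newcot[, b] <- cot[, b] - dt * rowSums(va$grad[, b, ] * cot)
    cot <- newcot
    kk <- kk - 1L
  }
  list(cot_in = cot, grad_t = gv)
}

# assemble a full gradient array c(dims, nd, nt) from per-timestep pieces
assemble_grad <- function(v, pieces_list) {
  g <- array(0, dim(v$values))
  nd <- vf_nd(v)
  for (t in seq_len(v$nt)) {
    acc <- NULL
    for (p in pieces_list) {
      if (is.null(p[[t]])) next
      acc <- if (is.null(acc)) p[[t]] else acc + p[[t]]
    }
    if (is.null(acc)) next
    if (nd == 3) g[, , , , t] <- acc else g[, , , t] <- acc
  }
  g
}

# Euclidean gradient of the total objective w.r.t. v3 values (matching part
# scattered through the chain) plus the path-energy part.
gradient_v3 <- function(state, include_penalty = TRUE) {
  v3 <- state$v3
  mats3 <- vf_mats(v3)
  # the 3D chain is shared by every section: push all slice pixels through
  # one batched backward flow and one batched backprop
  emb <- lapply(seq_along(state$slices), function(n) {
    sl <- state$slices[[n]]
    x <- apply_rigid(rigid_inverse(sl$rigid), sl$pts)
    q <- x
    if (!is.null(sl$v2)) {
      mats2 <- vf_mats(sl$v2)
      dt2 <- 1 / sl$v2$nt
      for (t in rev(seq_len(sl$v2$nt)))
        q <- q - dt2 * vf_at(sl$v2, t, q, mat = mats2[[t]])$value
    }
    cbind(q, sl$z)
  })
  p <- do.call(rbind, emb)
  nt3 <- v3$nt; dt3 <- 1 / nt3
  trace3 <- vector("list", nt3)
  kk <- 0L
  for (t in rev(seq_len(nt3))) {
    kk <- kk + 1L
    trace3[[kk]] <- p
    p <- p - dt3 * vf_at(v3, t, p, mat = mats3[[t]])$value
  }
  ip <- interp_core(state$template$data, p, state$template$spacing,
                    state$template$origin, fill = 0, need_grad = TRUE)
  dobs <- do.call(c, lapply(seq_along(state$slices), function(n) {
    sl <- state$slices[[n]]
    obs_n <- ip$value[slice_rows(state, n), 1]
    match_grad_obs(sl, obs_n)
  }))
  gpt <- ip$grad[, , 1] * dobs
  pieces <- backprop_flow(v3, trace3, gpt, mats = mats3)$grad_t
  gmatch <- assemble_grad(v3, list(pieces))
  if (include_penalty) gmatch <- gmatch + path_energy_gradient(v3, state$w_v)
  gmatch
}

# row indices of slice n's pixels within the concatenated point set
slice_rows <- function(state, n) {
  sizes <- vapply(state$slices, function(s) nrow(s$pts), numeric(1))
  ends <- cumsum(sizes)
  (c(0, ends)[n] + 1):ends[n]
}

# same for the section field u_n (requires backprop through the 3D chain
# first to reach the 2D chain output)
gradient_v2 <- function(state, n, include_penalty = TRUE) {
  sl <- state$slices[[n]]
  mats3 <- vf_mats(state$v3)
  mats2 <- vf_mats(sl$v2)
  cf <- chain_forward(state, n, with_trace = TRUE, mats3 = mats3,
                      mats2 = mats2)
  dobs <- match_grad_obs(sl, cf$obs)
  gpt <- cf$grad_template[, , 1] * dobs
  bp3 <- backprop_flow(state$v3, cf$trace3, gpt, need_grad_v = FALSE,
                       mats = mats3)
  cot2 <- bp3$cot_in[, 1:2, drop = FALSE]
  bp2 <- backprop_flow(sl$v2, cf$trace2, cot2, mats = mats2)
  g <- assemble_grad(sl$v2, list(bp2$grad_t))
  if (include_penalty) g <- g + path_energy_gradient(sl$v2, state$w_u)
  g
}

# Euclidean gradient of w * pathE(v) w.r.t. the velocity values
path_energy_gradient <- function(v, w) {
  nd <- vf_nd(v)
  mult <- kernel_multiplier(v$kernel, v$dims, v$spacing)
  cellvol <- prod(v$spacing)
  dt <- 1 / v$nt
  g <- array(0, dim(v$values))
  for (t in seq_len(v$nt)) {
    for (a in seq_len(nd)) {
      comp <- if (nd == 3) v$values[, , , a, t] else v$values[, , a, t]
      ki <- kernel_apply(array(comp, v$dims), mult, inverse = TRUE)
      if (nd == 3) g[, , , a, t] <- 2 * w * dt * cellvol * ki
      else g[, , a, t] <- 2 * w * dt * cellvol * ki
    }
  }
  g
}

# Hilbert (kernel-preconditioned) descent direction from a Euclidean
# matching gradient: 2 w v + K * gmatch / (dt * cellvol)
hilbert_direction <- function(v, gmatch, w) {
  nd <- vf_nd(v)
  mult <- kernel_multiplier(v$kernel, v$dims, v$spacing)
  cellvol <- prod(v$spacing)
  dt <- 1 / v$nt
  dir <- array(0, dim(v$values))
  for (t in seq_len(v$nt)) {
    for (a in seq_len(nd)) {
      g <- if (nd == 3) gmatch[, , , a, t] else gmatch[, , a, t]
      sm <- kernel_apply(array(g, v$dims), mult) / (dt * cellvol)
      cur <- if (nd == 3) v$values[, , , a, t] else v$values[, , a, t]
      upd <- 2 * w * cur + sm
      if (nd == 3) dir[, , , a, t] <- upd else dir[, , a, t] <- upd
    }
  }
  dir
}
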