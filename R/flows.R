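#' Reproducing-kernel specification for the velocity norm
#'
#' The smoothness-enforcing norm on velocity fields is realized through a
#' translation-invariant positive-definite smoothing operator `K`, applied
#' spectrally. Two multipliers are available: `"gaussian"` (periodic
#' convolution with a wrapped, sum-normalized sampled Gaussian) and
#' `"laplacian"`, the power-of-Laplacian multiplier
#' `(1 + (width |omega|)^2)^-order` common in diffeomorphic registration.
#' The Gaussian multiplier decays below floating-point resolution at high
#' frequency, which would make the inverse-norm pairing `<v, K^-1 v>`
#' amplify FFT round-off without bound; its spectrum is therefore floored at
#' `1e-6` of its zero-frequency value. The operator stays strictly positive
#' definite and the energy of kernel-smooth fields is unchanged to
#' round-off.
#'
#' @param width kernel width in mm (> 0); the Gaussian standard deviation,
#'   or the Laplacian length scale
#' @param kind `"gaussian"` (default) or `"laplacian"`
#' @param order Laplacian power (ignored for Gaussian)
#' @return a `KernelSpec`
#' @export
kernel_spec <- function(width, kind = c("gaussian", "laplacian"),
                        order = 2L) {
  stopifnot(is.numeric(width), length(width) == 1, width > 0)
  structure(list(kind = match.arg(kind), width = width,
                 order = as.integer(order)),
            class = "KernelSpec")
}

.kernel_cache <- new.env(parent = emptyenv())

# DFT multiplier of K, normalized to 1 at zero frequency (memoized: the
# same kernel/lattice pair is requested many times per iteration)
kernel_multiplier <- function(kernel, dims, spacing) {
  key <- paste(kernel$kind, kernel$width, kernel$order,
               paste(dims, collapse = "x"),
               paste(signif(spacing, 12), collapse = "x"), sep = "|")
  hit <- .kernel_cache[[key]]
  if (!is.null(hit)) return(hit)
  out <- kernel_multiplier_impl(kernel, dims, spacing)
  if (length(ls(.kernel_cache)) > 32) rm(list = ls(.kernel_cache),
                                         envir = .kernel_cache)
  assign(key, out, envir = .kernel_cache)
  out
}

kernel_multiplier_impl <- function(kernel, dims, spacing) {
  nd <- length(dims)
  if (kernel$kind == "gaussian") {
    mult <- array(1, dims)
    for (a in seq_len(nd)) {
      n <- dims[a]
      x <- (seq_len(n) - 1) * spacing[a]
      x <- pmin(x, n * spacing[a] - x)       # wrapped distance
      g <- exp(-x^2 / (2 * kernel$width^2))
      ma <- pmax(Re(stats::fft(g / sum(g))), 0)
      mult <- mult * array(rep(ma, each = prod(dims[seq_len(a - 1)])),
                           dim = dims)
    }
    pmax(mult, 1e-6)                         # bounded inverse (see docs)
  } else {
    om2 <- array(0, dims)
    for (a in seq_len(nd)) {
      n <- dims[a]
      f <- (seq_len(n) - 1)
      f <- ifelse(f <= n / 2, f, f - n) / (n * spacing[a])
      wa <- (2 * pi * f)^2
      om2 <- om2 + array(rep(wa, each = prod(dims[seq_len(a - 1)])),
                         dim = dims)
    }
    (1 + kernel$width^2 * om2)^(-kernel$order)
  }
}

# apply K (or K^-1 with inverse=TRUE) to one scalar lattice field
kernel_apply <- function(field, mult, inverse = FALSE) {
  fh <- stats::fft(field)
  fh <- if (inverse) fh / mult else fh * mult
  Re(stats::fft(fh, inverse = TRUE)) / length(field)
}

#' Time-indexed velocity field
#'
#' Holds `nt` lattice-sampled vector fields (mm per unit flow time) together
#' with the kernel defining their Hilbert norm. Works in 2D and 3D; the
#' dimensionality is read off `dims`.
#'
#' @param dims lattice dimensions (length 2 or 3)
#' @param spacing,origin lattice geometry in mm
#' @param nt number of timesteps (dt = 1/nt)
#' @param kernel a [kernel_spec()]
#' @param values optional array `c(dims, nd, nt)`; zero if omitted
#' @return a `VelocityField`
#' @export
velocity_field <- function(dims, spacing, origin = rep(0, length(dims)),
                           nt = 1L, kernel = kernel_spec(5 * min(spacing)),
                           values = NULL) {
  nd <- length(dims)
  stopifnot(nd %in% c(2L, 3L), nt >= 1)
  if (is.null(values)) values <- array(0, c(dims, nd, nt))
  stopifnot(all(dim(values) == c(dims, nd, nt)), all(is.finite(values)))
  structure(list(values = values, dims = as.integer(dims),
                 spacing = as.numeric(spacing), origin = as.numeric(origin),
                 nt = as.integer(nt), kernel = kernel),
            class = "VelocityField")
}

vf_nd <- function(v) length(v$dims)

# per-timestep lattice fields of a velocity, as flat matrices ready for
# interp_core (avoids repeated large slice extractions in inner loops)
vf_mats <- function(v) {
  nd <- vf_nd(v)
  lapply(seq_len(v$nt), function(t) {
    x <- if (nd == 3) v$values[, , , , t, drop = TRUE]
         else v$values[, , , t, drop = TRUE]
    dim(x) <- c(prod(v$dims), nd)
    attr(x, "lat_dims") <- v$dims
    x
  })
}

# velocity of timestep t evaluated at points (zero outside the lattice hull)
vf_at <- function(v, t, pts, need_grad = FALSE, mat = NULL) {
  nd <- vf_nd(v)
  if (is.null(mat)) {
    mat <- if (nd == 3) v$values[, , , , t, drop = TRUE]
           else v$values[, , , t, drop = TRUE]
    dim(mat) <- c(prod(v$dims), nd)
    attr(mat, "lat_dims") <- v$dims
  }
  interp_core(mat, pts, v$spacing, v$origin, fill = 0, need_grad = need_grad)
}

#' Integrate points along a flow
#'
#' Forward integration solves dx/dt = v_t(x) by explicit particle-path Euler
#' stepping; inverse integration runs -v in reversed time. This is the
#' discretization that [integrate_flow()], [deform_image()] and the
#' registration objective all share.
#'
#' @param v a `VelocityField`
#' @param pts N x nd matrix of world mm start points
#' @param direction `"forward"` or `"inverse"`
#' @return N x nd matrix of end points
#' @export
flow_points <- function(v, pts, direction = c("forward", "inverse")) {
  direction <- match.arg(direction)
  dt <- 1 / v$nt
  x <- rbind(pts)
  if (direction == "forward") {
    for (t in seq_len(v$nt)) x <- x + dt * vf_at(v, t, x)$value
  } else {
    for (t in rev(seq_len(v$nt))) x <- x - dt * vf_at(v, t, x)$value
  }
  x
}

#' Integrate a velocity field into a diffeomorphism
#'
#' Returns the forward map phi_1, the inverse map (built by integrating the
#' negated field in reversed time), and the Jacobian determinant of the
#' forward map by central differences. A non-positive Jacobian anywhere is
#' flagged with a warning (it signals an overly large deformation step), and
#' recorded in the returned object.
#'
#' @param v a `VelocityField`
#' @return a `DiffeoMap` with fields `forward`, `inverse` (arrays of world
#'   coordinates, dims `c(dims, nd)`), `jacobian`, `spacing`, `origin`.
#' @examples
#' v <- velocity_field(c(8, 8), spacing = c(1, 1), nt = 3)
#' m <- integrate_flow(v)  # identity map
#' @export
integrate_flow <- function(v) {
  nd <- vf_nd(v)
  grid <- lattice_points(structure(
    list(data = array(0, c(v$dims, 1)), spacing = v$spacing,
         origin = v$origin),
    class = if (nd == 3) "ImageVolume" else "SliceImage"))
  fwd <- flow_points(v, grid, "forward")
  inv <- flow_points(v, grid, "inverse")
  fwd_arr <- array(fwd, c(v$dims, nd))
  inv_arr <- array(inv, c(v$dims, nd))
  jac <- map_jacobian_det(fwd_arr, v$spacing)
  ok <- all(jac > 0)
  if (!ok)
    warning(sprintf(
      "non-positive Jacobian at %d of %d lattice points (min %.3g); ",
      sum(jac <= 0), length(jac), min(jac)),
      "deformation step too large")
  structure(list(forward = fwd_arr, inverse = inv_arr, jacobian = jac,
                 spacing = v$spacing, origin = v$origin,
                 jacobian_positive = ok),
            class = "DiffeoMap")
}

#' Invert a diffeomorphic map
#'
#' Swaps the stored forward and inverse lattice maps and recomputes the
#' Jacobian determinant of the (new) forward map by central differences.
#'
#' @param map a `DiffeoMap`
#' @return the inverted `DiffeoMap`
#' @export
invert_map <- function(map) {
  out <- map
  out$forward <- map$inverse
  out$inverse <- map$forward
  out$jacobian <- map_jacobian_det(out$forward, map$spacing)
  out$jacobian_positive <- all(out$jacobian > 0)
  out
}

#' Identity map on a lattice
#'
#' The `DiffeoMap` whose forward and inverse maps are the lattice's own
#' world coordinates (unit Jacobian everywhere).
#'
#' @param dims lattice dimensions (length 2 or 3)
#' @param spacing,origin lattice geometry in mm
#' @return a `DiffeoMap`
#' @export
identity_map <- function(dims, spacing, origin = rep(0, length(dims))) {
  nd <- length(dims)
  cls <- if (nd == 3) "ImageVolume" else "SliceImage"
  grid <- lattice_points(structure(
    list(data = array(0, c(dims, 1)), spacing = spacing, origin = origin),
    class = cls))
  arr <- array(grid, c(dims, nd))
  structure(list(forward = arr, inverse = arr,
                 jacobian = array(1, dims), spacing = spacing,
                 origin = origin, jacobian_positive = TRUE),
            class = "DiffeoMap")
}

# Jacobian determinant field of a lattice-sampled map by central differences
map_jacobian_det <- function(map_arr, spacing) {
  d <- dim(map_arr)
  nd <- length(spacing)
  dims <- d[seq_len(nd)]
  J <- vector("list", nd * nd)
  for (a in seq_len(nd)) {        # component
    for (b in seq_len(nd)) {      # derivative axis
      comp <- if (nd == 3) map_arr[, , , a] else map_arr[, , a]
      J[[(a - 1) * nd + b]] <- axis_central_diff(comp, b, spacing[b])
    }
  }
  if (nd == 2) {
    J[[1]] * J[[4]] - J[[2]] * J[[3]]
  } else {
    J[[1]] * (J[[5]] * J[[9]] - J[[6]] * J[[8]]) -
    J[[2]] * (J[[4]] * J[[9]] - J[[6]] * J[[7]]) +
    J[[3]] * (J[[4]] * J[[8]] - J[[5]] * J[[7]])
  }
}

# central difference along axis `a` with one-sided differences at the ends
axis_central_diff <- function(x, a, h) {
  d <- dim(x)
  n <- d[a]
  idx_p <- pmin(seq_len(n) + 1L, n)
  idx_m <- pmax(seq_len(n) - 1L, 1L)
  denom <- (idx_p - idx_m) * h
  slice_index <- function(ii) {
    args <- rep(list(quote(expr = )), length(d))
    args[[a]] <- ii
    do.call(`[`, c(list(x), args, list(drop = FALSE)))
  }
  out <- (slice_index(idx_p) - slice_index(idx_m))
  shape <- rep(1L, length(d)); shape[a] <- n
  sweep(out, a, denom, "/")
}

# evaluate a stored lattice map at arbitrary points (multilinear on the
# displacement so that identity regions extrapolate as identity)
map_at <- function(map, pts, which = c("inverse", "forward")) {
  which <- match.arg(which)
  arr <- map[[which]]
  nd <- length(map$spacing)
  dims <- dim(arr)[seq_len(nd)]
  cls <- if (nd == 3) "ImageVolume" else "SliceImage"
  grid <- lattice_points(structure(
    list(data = array(0, c(dims, 1)), spacing = map$spacing,
         origin = map$origin), class = cls))
  disp <- arr
  dim(disp) <- c(prod(dims), nd)
  disp <- disp - grid
  dim(disp) <- c(dims, nd)
  pts + interp_core(disp, rbind(pts), map$spacing, map$origin,
                    fill = 0)$value
}

#' Deform an image by a diffeomorphism
#'
#' Implements the group action `phi . I = I o phi^-1`: the output at world
#' point x is the input sampled at `inverse(x)`. Label images should be
#' deformed with `method = "nearest"`.
#'
#' @param image an `ImageVolume` or `SliceImage`
#' @param map a `DiffeoMap` in the same world frame
#' @param method `"linear"` or `"nearest"`
#' @param fill out-of-domain fill value
#' @return an image of the same class and lattice as `image`
#' @export
deform_image <- function(image, map, method = c("linear", "nearest"),
                         fill = 0) {
  method <- match.arg(method)
  nd <- length(image$spacing)
  if (nd != length(map$spacing))
    stop("image and map dimensionality differ")
  grid <- lattice_points(image)
  src <- map_at(map, grid, "inverse")
  vals <- interp_core(image$data, src, image$spacing, image$origin,
                      fill = fill, method = method)$value
  d <- dim(image$data)
  out <- array(vals, d)
  res <- image
  res$data <- out
  res
}

#' Kernel-norm path energy of a velocity field
#'
#' `dt * sum_t <v_t, K^-1 v_t>` with the discrete inner product
#' `<a,b> = prod(spacing) * sum_x a(x) b(x)` summed over components,
#' evaluated spectrally through the Gaussian Fourier multiplier. It is a
#' positive-definite quadratic form: zero iff `v = 0`.
#'
#' @param v a `VelocityField`
#' @return scalar energy
#' @export
path_energy <- function(v) {
  nd <- vf_nd(v)
  mult <- kernel_multiplier(v$kernel, v$dims, v$spacing)
  n <- prod(v$dims)
  total <- 0
  for (t in seq_len(v$nt)) {
    for (a in seq_len(nd)) {
      comp <- if (nd == 3) v$values[, , , a, t] else v$values[, , a, t]
      fh <- stats::fft(array(comp, v$dims))
      total <- total + sum((Mod(fh)^2) / mult) / n   # Parseval
    }
  }
  prod(v$spacing) * total / v$nt
}

#' One Hilbert gradient-descent step on a velocity field
#'
#' The raw (Euclidean) gradient of the data term is smoothed by the kernel
#' before stepping, and the prior contributes `2 v`:
#' `v <- v - step * (2 * v + K * raw_gradient)`. In the limit of a
#' zero-width kernel (lattice delta) this reduces to plain gradient descent
#' on `v` plus the prior term.
#'
#' @param v a `VelocityField`
#' @param raw_gradient array `c(dims, nd, nt)` of data-term gradients
#' @param step step size
#' @return the updated `VelocityField`
#' @export
hilbert_gradient_step <- function(v, raw_gradient, step) {
  stopifnot(all(dim(raw_gradient) == dim(v$values)))
  nd <- vf_nd(v)
  mult <- kernel_multiplier(v$kernel, v$dims, v$spacing)
  out <- v$values
  for (t in seq_len(v$nt)) {
    for (a in seq_len(nd)) {
      g <- if (nd == 3) raw_gradient[, , , a, t] else raw_gradient[, , a, t]
      sm <- kernel_apply(array(g, v$dims), mult)
      cur <- if (nd == 3) v$values[, , , a, t] else v$values[, , a, t]
      upd <- cur - step * (2 * cur + sm)
      if (nd == 3) out[, , , a, t] <- upd else out[, , a, t] <- upd
    }
  }
  v$values <- out
  v
}

#' In-plane rigid (or affine) motion
#'
#' Rotation by `theta` about the world origin followed by translation; the
#' optional `linear` slot generalizes the rotation block to an affine 2x2
#' matrix. Acts on points as `A y + t`.
#'
#' @param theta rotation angle in radians
#' @param translation mm 2-vector
#' @param linear optional 2x2 matrix overriding the rotation block
#' @return a `Rigid2D`
#' @export
rigid2d <- function(theta = 0, translation = c(0, 0), linear = NULL) {
  A <- if (is.null(linear))
    matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  else matrix(as.numeric(linear), 2, 2)
  structure(list(theta = theta, translation = as.numeric(translation),
                 linear = A, rigid = is.null(linear)),
            class = "Rigid2D")
}

#' @rdname rigid2d
#' @param r a `Rigid2D`
#' @param pts N x 2 matrix of points (mm)
#' @export
apply_rigid <- function(r, pts) {
  sweep(rbind(pts) %*% t(r$linear), 2, r$translation, "+")
}

#' @rdname rigid2d
#' @export
rigid_inverse <- function(r) {
  Ai <- solve(r$linear)
  structure(list(theta = -r$theta, translation = as.numeric(-Ai %*%
                   r$translation), linear = Ai, rigid = r$rigid),
            class = "Rigid2D")
}
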