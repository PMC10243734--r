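# Multilinear interpolation on voxel-center lattices, with the two companions
# every adjoint-based method needs: the derivative with respect to the query
# points and the transpose (scatter) operator onto the grid. All functions are
# vectorized over query points; dimension nd is 2 or 3.

# arr: array with dims c(d, nc); pts: N x nd world mm; returns list with
#   value  : N x nc matrix
#   grad   : N x nd x nc array (d value / d world point), if need_grad
#   inside : logical N (FALSE where fill was used)
interp_core <- function(arr, pts, spacing, origin, fill = 0,
                        method = c("linear", "nearest"), need_grad = FALSE) {
  method <- match.arg(method)
  nd <- length(spacing)
  lat_dims <- attr(arr, "lat_dims")
  if (!is.null(lat_dims)) {        # pre-flattened: matrix sites x channels
    dims <- lat_dims
    nc <- ncol(arr)
    arr_mat <- arr
  } else {
    d <- dim(arr)
    nc <- if (length(d) == nd) 1L else d[nd + 1L]
    dims <- d[seq_len(nd)]
    arr_mat <- arr
    dim(arr_mat) <- c(prod(dims), nc)
  }
  npts <- nrow(pts)
  if (any(!is.finite(pts))) stop("query points must be finite")

  # continuous 0-based index
  u <- sweep(sweep(pts, 2, origin, "-"), 2, spacing, "/")
  inside <- rep(TRUE, npts)
  for (a in seq_len(nd))
    inside <- inside & u[, a] >= 0 & u[, a] <= dims[a] - 1

  value <- matrix(fill, npts, nc)
  grad <- if (need_grad) array(0, c(npts, nd, nc)) else NULL
  if (!any(inside)) {
    return(list(value = value, grad = grad, inside = inside))
  }
  ui <- u[inside, , drop = FALSE]
  ni <- nrow(ui)
  stride <- cumprod(c(1, dims))[seq_len(nd)]

  if (method == "nearest") {
    i0 <- round(ui)
    for (a in seq_len(nd)) i0[, a] <- pmin(pmax(i0[, a], 0), dims[a] - 1)
    idx <- 1 + as.vector(i0 %*% stride)
    value[inside, ] <- arr_mat[idx, , drop = FALSE]
    return(list(value = value, grad = grad, inside = inside))
  }

  i0 <- floor(ui)
  for (a in seq_len(nd)) i0[, a] <- pmin(pmax(i0[, a], 0), max(dims[a] - 2, 0))
  tt <- ui - i0
  corners <- as.matrix(expand.grid(rep(list(0:1), nd)))
  acc <- matrix(0, ni, nc)
  gacc <- if (need_grad) array(0, c(ni, nd, nc)) else NULL
  for (ci in seq_len(nrow(corners))) {
    cc <- corners[ci, ]
    w <- rep(1, ni)
    for (a in seq_len(nd))
      w <- w * if (cc[a] == 1) tt[, a] else 1 - tt[, a]
    idx <- 1 + as.vector(sweep(i0, 2, cc, "+") %*% stride)
    vals <- arr_mat[idx, , drop = FALSE]
    acc <- acc + w * vals
    if (need_grad) {
      for (a in seq_len(nd)) {
        dw <- rep(if (cc[a] == 1) 1 else -1, ni)
        for (b in seq_len(nd)) {
          if (b == a) next
          dw <- dw * if (cc[b] == 1) tt[, b] else 1 - tt[, b]
        }
        gacc[, a, ] <- gacc[, a, ] + as.vector(dw) * vals
      }
    }
  }
  value[inside, ] <- acc
  if (need_grad) {
    for (a in seq_len(nd)) gacc[, a, ] <- gacc[, a, ] / spacing[a]
    grad[inside, , ] <- gacc
  }
  list(value = value, grad = grad, inside = inside)
}

# Transpose of multilinear sampling: scatter cotangents at query points back
# onto the lattice. Returns an array with dims c(dims, nc). Out-of-hull points
# contribute nothing (matching the fill behaviour of interp_core).
interp_adjoint <- function(dims, pts, cotan, spacing, origin) {
  nd <- length(spacing)
  cotan <- as.matrix(cotan)
  nc <- ncol(cotan)
  npts <- nrow(pts)
  u <- sweep(sweep(pts, 2, origin, "-"), 2, spacing, "/")
  inside <- rep(TRUE, npts)
  for (a in seq_len(nd))
    inside <- inside & u[, a] >= 0 & u[, a] <= dims[a] - 1
  out <- matrix(0, prod(dims), nc)
  if (!any(inside)) {
    dim(out) <- c(dims, nc)
    return(out)
  }
  ui <- u[inside, , drop = FALSE]
  ct <- cotan[inside, , drop = FALSE]
  ni <- nrow(ui)
  i0 <- floor(ui)
  for (a in seq_len(nd)) i0[, a] <- pmin(pmax(i0[, a], 0), max(dims[a] - 2, 0))
  tt <- ui - i0
  stride <- cumprod(c(1, dims))[seq_len(nd)]
  corners <- as.matrix(expand.grid(rep(list(0:1), nd)))
  for (ci in seq_len(nrow(corners))) {
    cc <- corners[ci, ]
    w <- rep(1, ni)
    for (a in seq_len(nd))
      w <- w * if (cc[a] == 1) tt[, a] else 1 - tt[, a]
    idx <- 1 + as.vector(sweep(i0, 2, cc, "+") %*% stride)
    contrib <- w * ct
    s <- rowsum(contrib, group = idx, reorder = TRUE)
    rows <- sort.int(unique(idx))
    out[rows, ] <- out[rows, , drop = FALSE] + s
  }
  dim(out) <- c(dims, nc)
  out
}

#' Interpolate a volume or slice at world coordinates
#'
#' Multilinear (trilinear/bilinear) interpolation in world mm coordinates.
#' Points outside the lattice hull return `fill`. With `method = "nearest"`
#' the value of the closest lattice site is returned (used for label images).
#'
#' @param x an `ImageVolume` or `SliceImage`
#' @param points N x 3 (or N x 2) matrix of world mm coordinates
#' @param fill value returned outside the lattice hull
#' @param method `"linear"` (default) or `"nearest"`
#' @return N x channels matrix of sampled values
#' @examples
#' v <- image_volume(array(rnorm(27), c(3, 3, 3)))
#' interpolate(v, rbind(c(1, 1, 1), c(0.5, 0.5, 0.5)))
#' @export
interpolate <- function(x, points, fill = 0, method = c("linear", "nearest")) {
  UseMethod("interpolate")
}

#' @export
interpolate.ImageVolume <- function(x, points, fill = 0,
                                    method = c("linear", "nearest")) {
  points <- rbind(points)
  stopifnot(ncol(points) == 3)
  interp_core(x$data, points, x$spacing, x$origin, fill = fill,
              method = match.arg(method))$value
}

#' @export
interpolate.SliceImage <- function(x, points, fill = 0,
                                   method = c("linear", "nearest")) {
  points <- rbind(points)
  stopifnot(ncol(points) == 2)
  interp_core(x$data, points, x$spacing, x$origin, fill = fill,
              method = match.arg(method))$value
}
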