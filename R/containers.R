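#' Image containers
#'
#' `ImageVolume` holds an r-channel scalar field on a 3D voxel lattice;
#' `SliceImage` holds a q-channel field on a 2D pixel lattice at a known
#' section plane `z_position`; `SliceStack` is an ordered list of slices with
#' strictly increasing plane positions.
#'
#' World convention: voxel-center, millimetres, right-handed. The world
#' coordinate of voxel (i,j,k) (1-based R index) is
#' `origin + (i-1, j-1, k-1) * spacing`. Arrays are indexed `[i,j,k(,c)]`
#' along (x,y,z) following R's column-major layout and the NIfTI convention.
#'
#' @param data numeric array. For volumes: dims (nx,ny,nz) or (nx,ny,nz,r).
#'   For slices: dims (nx,ny) or (nx,ny,q).
#' @param spacing mm per voxel/pixel; length 3 (volume) or 2 (slice), all > 0.
#' @param origin world mm coordinate of the center of the first voxel/pixel;
#'   length 3 (volume) or 2 (slice).
#' @param z_position section plane position in mm (slices only).
#' @return An object of class `ImageVolume` / `SliceImage`.
#' @examples
#' v <- image_volume(array(0, c(4, 4, 4)), spacing = c(1, 1, 1))
#' s <- slice_image(matrix(0, 4, 4), spacing = c(1, 1), z_position = 2)
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- as_channel_array(data, nd = 3)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  stopifnot(length(spacing) == 3, length(origin) == 3)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be finite and > 0")
  if (any(!is.finite(origin))) stop("origin must be finite")
  if (any(!is.finite(data))) stop("ImageVolume data must be finite")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "ImageVolume")
}

#' @rdname image_volume
#' @export
slice_image <- function(data, spacing = c(1, 1), origin = c(0, 0),
                        z_position = 0) {
  data <- as_channel_array(data, nd = 2)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  stopifnot(length(spacing) == 2, length(origin) == 2)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be finite and > 0")
  if (any(!is.finite(origin))) stop("origin must be finite")
  if (!is.finite(z_position)) stop("z_position must be finite")
  if (any(!is.finite(data))) stop("SliceImage data must be finite")
  structure(list(data = data, spacing = spacing, origin = origin,
                 z_position = as.numeric(z_position)),
            class = "SliceImage")
}

#' @rdname image_volume
#' @param slices list of `SliceImage` objects, strictly increasing in
#'   `z_position`.
#' @export
slice_stack <- function(slices) {
  stopifnot(is.list(slices), length(slices) >= 1)
  ok <- vapply(slices, inherits, logical(1), "SliceImage")
  if (!all(ok)) stop("all elements must be SliceImage objects")
  z <- vapply(slices, function(s) s$z_position, numeric(1))
  if (any(diff(z) <= 0)) stop("z_position must be strictly increasing")
  structure(list(slices = slices), class = "SliceStack")
}

# promote (nx,ny[,nz]) to an explicit trailing channel axis
as_channel_array <- function(data, nd) {
  data <- unclass(data)
  if (is.null(dim(data))) stop("data must be an array or matrix")
  d <- dim(data)
  if (length(d) == nd) {
    dim(data) <- c(d, 1L)
  } else if (length(d) != nd + 1L) {
    stop(sprintf("data must have %d or %d dimensions", nd, nd + 1L))
  }
  storage.mode(data) <- "double"
  data
}

#' @export
print.ImageVolume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("ImageVolume %dx%dx%d, %d channel(s)\n", d[1], d[2], d[3], d[4]))
  cat(sprintf("  spacing %s mm, origin %s mm\n",
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ", ")))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.SliceImage <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("SliceImage %dx%d, %d channel(s), z = %.4g mm\n",
              d[1], d[2], d[3], x$z_position))
  cat(sprintf("  spacing %s mm, origin %s mm\n",
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ", ")))
  invisible(x)
}

#' @export
print.SliceStack <- function(x, ...) {
  z <- slice_positions(x)
  cat(sprintf("SliceStack of %d sections, z in [%.4g, %.4g] mm\n",
              length(x$slices), min(z), max(z)))
  invisible(x)
}

#' Number of channels of a volume or slice
#' @param x `ImageVolume` or `SliceImage`
#' @return integer channel count
#' @export
n_channels <- function(x) dim(x$data)[length(dim(x$data))]

#' Section plane positions of a stack
#' @param stack a `SliceStack`
#' @return numeric vector of z positions (mm)
#' @export
slice_positions <- function(stack) {
  vapply(stack$slices, function(s) s$z_position, numeric(1))
}

# world coordinates of all lattice sites, as an N x nd matrix (x fastest)
lattice_points <- function(x) {
  d <- dim(x$data)
  if (inherits(x, "ImageVolume")) {
    g <- expand.grid(i = seq_len(d[1]) - 1, j = seq_len(d[2]) - 1,
                     k = seq_len(d[3]) - 1)
    cbind(x$origin[1] + g$i * x$spacing[1],
          x$origin[2] + g$j * x$spacing[2],
          x$origin[3] + g$k * x$spacing[3])
  } else {
    g <- expand.grid(i = seq_len(d[1]) - 1, j = seq_len(d[2]) - 1)
    cbind(x$origin[1] + g$i * x$spacing[1],
          x$origin[2] + g$j * x$spacing[2])
  }
}

# axis coordinate vectors (world mm) of the lattice
axis_coords <- function(x) {
  d <- dim(x$data)
  nd <- length(x$spacing)
  lapply(seq_len(nd), function(a)
    x$origin[a] + (seq_len(d[a]) - 1) * x$spacing[a])
}
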