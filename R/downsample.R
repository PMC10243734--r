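#' Block-average downsampling of a slice image
#'
#' Each output pixel is the unweighted mean of its source block, emulating the
#' average signal of linear downsampling. The target spacing must be an
#' integer multiple of the input spacing on each axis; for non-integer ratios
#' resample via [interpolate()] instead. The origin is adjusted so output
#' pixel centers sit at the centers of their source blocks.
#'
#' @param slice a `SliceImage`
#' @param target_spacing length-1 or length-2 target spacing in mm
#' @return a `SliceImage` at the coarser spacing
#' @examples
#' s <- slice_image(matrix(1:16, 4, 4), spacing = c(1, 1))
#' block_downsample(s, 2)
#' @export
block_downsample <- function(slice, target_spacing) {
  stopifnot(inherits(slice, "SliceImage"))
  target_spacing <- rep(as.numeric(target_spacing), length.out = 2)
  fac <- target_spacing / slice$spacing
  faci <- round(fac)
  if (any(abs(fac - faci) > 1e-8) || any(faci < 1))
    stop("target_spacing must be a positive integer multiple of the input ",
         "spacing (got ratio ", paste(signif(fac, 6), collapse = " x "), ")")
  faci <- as.integer(faci)
  d <- dim(slice$data)
  nout <- d[1:2] %/% faci
  if (any(nout < 1)) stop("image smaller than one block")
  nc <- d[3]
  out <- array(0, c(nout, nc))
  for (ch in seq_len(nc)) {
    x <- slice$data[seq_len(nout[1] * faci[1]), seq_len(nout[2] * faci[2]), ch]
    out[, , ch] <- block_mean_2d(x, faci)
  }
  new_origin <- slice$origin + (faci - 1) / 2 * slice$spacing
  slice_image(out, spacing = faci * slice$spacing, origin = new_origin,
              z_position = slice$z_position)
}

block_mean_2d <- function(x, fac) {
  d <- dim(x)
  nout <- d %/% fac
  dim(x) <- c(fac[1], nout[1], fac[2], nout[2])
  apply(x, c(2, 4), mean)
}

# block-mean coarsening of a volume by an integer factor (multiresolution)
downsample_volume <- function(vol, fac = 2L) {
  fac <- as.integer(rep(fac, length.out = 3))
  d <- dim(vol$data)
  nout <- pmax(d[1:3] %/% fac, 1L)
  nc <- d[4]
  out <- array(0, c(nout, nc))
  for (ch in seq_len(nc)) {
    x <- vol$data[seq_len(nout[1] * fac[1]), seq_len(nout[2] * fac[2]),
                  seq_len(nout[3] * fac[3]), ch]
    dim(x) <- c(fac[1], nout[1], fac[2], nout[2], fac[3], nout[3])
    out[, , , ch] <- apply(x, c(2, 4, 6), mean)
  }
  image_volume(out, spacing = vol$spacing * fac,
               origin = vol$origin + (fac - 1) / 2 * vol$spacing)
}

# bilinear coarsening of a slice to an arbitrary grid (used before scattering
# when the ratio is not integer)
resample_slice <- function(slice, target_spacing, fill = 0) {
  target_spacing <- rep(as.numeric(target_spacing), length.out = 2)
  d <- dim(slice$data)
  extent <- (d[1:2] - 1) * slice$spacing
  nout <- pmax(floor(extent / target_spacing) + 1, 2)
  g <- expand.grid(i = seq_len(nout[1]) - 1, j = seq_len(nout[2]) - 1)
  pts <- cbind(slice$origin[1] + g$i * target_spacing[1],
               slice$origin[2] + g$j * target_spacing[2])
  vals <- interpolate(slice, pts, fill = fill)
  slice_image(array(vals, c(nout, n_channels(slice))),
              spacing = target_spacing, origin = slice$origin,
              z_position = slice$z_position)
}
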