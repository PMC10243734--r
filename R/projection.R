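#' Point-spread projection specification
#'
#' The measurement channel `P_n` that takes a dense 3D volume to 2D section
#' images. `dirac_plane` samples the volume exactly on the planes `z_n`
#' (physical sectioning); `gaussian_z` averages along z with a normalized
#' discrete Gaussian of width `sigma_z`, truncated at 4 sigma (optical
#' sectioning with out-of-plane blur).
#'
#' @param kind `"dirac_plane"` or `"gaussian_z"`
#' @param z_positions section plane positions in mm
#' @param sigma_z z blur standard deviation in mm (`gaussian_z` only, > 0)
#' @return a `PointSpread`
#' @export
point_spread <- function(kind = c("dirac_plane", "gaussian_z"),
                         z_positions, sigma_z = NULL) {
  kind <- match.arg(kind)
  z_positions <- as.numeric(z_positions)
  stopifnot(length(z_positions) >= 1, all(is.finite(z_positions)))
  if (any(diff(z_positions) <= 0) && length(z_positions) > 1)
    stop("z_positions must be strictly increasing")
  if (kind == "gaussian_z") {
    if (is.null(sigma_z) || sigma_z <= 0)
      stop("gaussian_z requires sigma_z > 0")
  }
  structure(list(kind = kind, z_positions = z_positions, sigma_z = sigma_z),
            class = "PointSpread")
}

#' Extract the section of a volume at a given plane
#'
#' Returns `I(.,.,z)` by linear interpolation along z at every in-plane
#' lattice point; at a voxel-center plane the stored plane is returned
#' bit-exactly.
#'
#' @param vol an `ImageVolume`
#' @param z plane position in mm, within the volume's z range
#' @return a `SliceImage` with `z_position = z`
#' @export
slice_volume <- function(vol, z) {
  stopifnot(inherits(vol, "ImageVolume"))
  d <- dim(vol$data)
  zc <- vol$origin[3] + (seq_len(d[3]) - 1) * vol$spacing[3]
  if (z < zc[1] - 1e-9 || z > zc[d[3]] + 1e-9)
    stop(sprintf("z = %g outside volume z range [%g, %g]", z, zc[1], zc[d[3]]))
  u <- (z - vol$origin[3]) / vol$spacing[3]
  k0 <- min(max(floor(u), 0), max(d[3] - 2, 0))
  t <- u - k0
  lower <- vol$data[, , k0 + 1, , drop = FALSE]
  upper <- vol$data[, , min(k0 + 2, d[3]), , drop = FALSE]
  out <- (1 - t) * lower + t * upper
  dim(out) <- c(d[1], d[2], d[4])
  slice_image(out, spacing = vol$spacing[1:2], origin = vol$origin[1:2],
              z_position = z)
}

#' Apply a point-spread projection to a volume
#'
#' `dirac_plane` reduces to [slice_volume()] per plane. `gaussian_z` returns,
#' at each plane `z_n`, the weighted average of in-plane sections with
#' discrete Gaussian weights centered at `z_n`, truncated at 4 sigma and
#' renormalized to sum 1 (so constants are preserved exactly). Both are
#' linear in the volume.
#'
#' @param vol an `ImageVolume`
#' @param psf a [point_spread()]
#' @return a `SliceStack` with one section per `z_position`
#' @export
apply_pointspread <- function(vol, psf) {
  stopifnot(inherits(psf, "PointSpread"))
  d <- dim(vol$data)
  zc <- vol$origin[3] + (seq_len(d[3]) - 1) * vol$spacing[3]
  slices <- lapply(psf$z_positions, function(zn) {
    if (psf$kind == "dirac_plane") {
      slice_volume(vol, zn)
    } else {
      w <- exp(-(zc - zn)^2 / (2 * psf$sigma_z^2))
      w[abs(zc - zn) > 4 * psf$sigma_z] <- 0
      if (sum(w) == 0) stop("no volume planes within 4 sigma of z = ", zn)
      w <- w / sum(w)
      acc <- array(0, c(d[1], d[2], d[4]))
      for (k in which(w > 0)) {
        pk <- vol$data[, , k, , drop = FALSE]
        dim(pk) <- c(d[1], d[2], d[4])
        acc <- acc + w[k] * pk
      }
      slice_image(acc, spacing = vol$spacing[1:2], origin = vol$origin[1:2],
                  z_position = zn)
    }
  })
  slice_stack(slices)
}
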