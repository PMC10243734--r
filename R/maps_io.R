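#' Serialize a diffeomorphic map as displacement NIfTIs
#'
#' Writes `<prefix>_fwd.nii.gz` and `<prefix>_inv.nii.gz` (displacement
#' fields, one channel per coordinate), `<prefix>_jac.nii.gz` (Jacobian
#' determinant of the forward map) and `<prefix>.json` (frame metadata:
#' dimensionality, spacing, origin, direction convention).
#'
#' @param map a `DiffeoMap`
#' @param prefix output path prefix
#' @return `read_map` returns a `DiffeoMap`; `write_map` returns `prefix`
#'   invisibly.
#' @export
write_map <- function(map, prefix) {
  nd <- length(map$spacing)
  dims <- dim(map$forward)[seq_len(nd)]
  grid <- array(identity_map(dims, map$spacing, map$origin)$forward,
                dim(map$forward))
  sp3 <- c(map$spacing, rep(1, 3 - nd))
  or3 <- c(map$origin, rep(0, 3 - nd))
  wr <- function(arr, path) {
    a <- arr
    if (nd == 2) dim(a) <- c(dims, 1L, dim(arr)[length(dim(arr))])
    write_volume(image_volume(a, spacing = sp3, origin = or3), path)
  }
  wr(map$forward - grid, paste0(prefix, "_fwd.nii.gz"))
  wr(map$inverse - grid, paste0(prefix, "_inv.nii.gz"))
  jac <- map$jacobian
  if (nd == 2) dim(jac) <- c(dims, 1L)
  write_volume(image_volume(array(jac, c(dim(jac), 1L)), spacing = sp3,
                            origin = or3), paste0(prefix, "_jac.nii.gz"))
  jsonlite::write_json(
    list(ndim = nd, spacing = map$spacing, origin = map$origin,
         storage = "displacement", direction = "world_mm",
         jacobian_positive = map$jacobian_positive),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_map
#' @export
read_map <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  nd <- meta$ndim
  rd <- function(path) {
    v <- read_volume(path)
    a <- v$data
    d <- dim(a)
    if (nd == 2) dim(a) <- c(d[1], d[2], d[4])
    a
  }
  fwd <- rd(paste0(prefix, "_fwd.nii.gz"))
  inv <- rd(paste0(prefix, "_inv.nii.gz"))
  dims <- dim(fwd)[seq_len(nd)]
  grid <- array(identity_map(dims, meta$spacing, meta$origin)$forward,
                dim(fwd))
  jac <- rd(paste0(prefix, "_jac.nii.gz"))
  dim(jac) <- dims
  structure(list(forward = fwd + grid, inverse = inv + grid, jacobian = jac,
                 spacing = meta$spacing, origin = meta$origin,
                 jacobian_positive = isTRUE(meta$jacobian_positive)),
            class = "DiffeoMap")
}

#' Write a registration result directory
#'
#' Displacement NIfTIs for the 3D map and each section map, JSON files for
#' rigid motions and contrast coefficients, per-section weight-field TIFFs
#' for QC, and the energy trace as CSV.
#'
#' @param result a `RegistrationResult`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_registration_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_map(result$map3, file.path(dir, "map3d"))
  for (n in seq_along(result$slices)) {
    sl <- result$slices[[n]]
    tag <- sprintf("slice_%03d", n)
    if (!is.null(sl$map2)) write_map(sl$map2, file.path(dir, tag))
    jsonlite::write_json(
      list(theta = sl$rigid$theta, translation = sl$rigid$translation,
           alpha = as.numeric(sl$alpha), z_position = sl$z,
           mu_A = sl$params$mu_A, mu_B = sl$params$mu_B,
           sigma = sl$params$sigma),
      file.path(dir, paste0(tag, ".json")), auto_unbox = TRUE, digits = NA)
    write_slice(slice_image(sl$weights, sl$spacing, sl$origin, sl$z),
                file.path(dir, paste0(tag, "_weights.tif")))
    write_slice(sl$predicted, file.path(dir, paste0(tag, "_predicted.tif")))
  }
  utils::write.csv(data.frame(iteration = seq_along(result$energy_trace),
                              energy = result$energy_trace),
                   file.path(dir, "energy_trace.csv"), row.names = FALSE)
  invisible(dir)
}
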