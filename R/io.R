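# File formats. Volumes travel as NIfTI; 2D rasters as TIFF (float32,
# multi-page = channels) or PNG (8-bit) with a JSON sidecar holding the world
# metadata that raster dialects cannot be trusted to carry; point sets and
# particle tables as CSV; meshes as ASCII PLY.

sidecar_path <- function(path) paste0(path, ".json")

#' Read and write image volumes (NIfTI)
#'
#' The voxel spacing is stored in `pixdim` and the world origin in the sform.
#' Multi-channel volumes use a fourth dimension.
#'
#' @param path file path (`.nii` or `.nii.gz`)
#' @param vol an `ImageVolume`
#' @return `read_volume` returns an `ImageVolume`; `write_volume` returns
#'   `path` invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "ImageVolume"))
  d <- dim(vol$data)
  data <- vol$data
  if (d[4] == 1L) dim(data) <- d[1:3]
  img <- RNifti::asNifti(data)
  mat <- diag(c(vol$spacing, 1))
  mat[1:3, 4] <- vol$origin
  img <- RNifti::`sform<-`(img, structure(mat, code = 2L))
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such volume file: ", path)
  img <- RNifti::readNifti(path)
  mat <- RNifti::xform(img)
  spacing <- abs(diag(mat)[1:3])
  if (any(spacing == 0)) spacing <- RNifti::pixdim(img)[1:3]
  origin <- mat[1:3, 4]
  data <- as.array(img)
  attributes(data) <- list(dim = dim(data))   # drop RNifti header attrs
  d <- dim(data)
  if (length(d) == 2L) dim(data) <- c(d, 1L)
  image_volume(data, spacing = spacing, origin = origin)
}

#' Read and write 2D section images (TIFF/PNG + JSON sidecar)
#'
#' Raster formats do not reliably carry physical metadata, so spacing, origin,
#' the section plane `z_position`, and per-channel affine rescaling (values
#' are stored mapped into [0,1]) live in a JSON sidecar `<path>.json` written
#' and required alongside the raster. TIFF samples are 32-bit fixed point:
#' round trips are exact to about 1e-9 of the channel range (integer label
#' images should be `round()`ed after reading).
#'
#' @param slice a `SliceImage`
#' @param path file path ending in `.tif`/`.tiff` (float32) or `.png` (8-bit)
#' @return `read_slice` returns a `SliceImage`; `write_slice` returns `path`
#'   invisibly.
#' @export
write_slice <- function(slice, path) {
  stopifnot(inherits(slice, "SliceImage"))
  nc <- n_channels(slice)
  lo <- apply(slice$data, 3, min)
  hi <- apply(slice$data, 3, max)
  scale <- ifelse(hi > lo, hi - lo, 1)
  pages <- lapply(seq_len(nc), function(ch)
    t((slice$data[, , ch] - lo[ch]) / scale[ch]))  # rasters are row-major
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  } else if (ext == "png") {
    if (nc == 1L) png::writePNG(pages[[1]], path)
    else if (nc %in% c(2L, 3L, 4L)) {
      png::writePNG(aperm(array(unlist(pages), c(dim(pages[[1]]), nc)),
                          c(1, 2, 3)), path)
    } else stop("PNG supports at most 4 channels; use TIFF")
  } else stop("unsupported slice format: .", ext)
  meta <- list(spacing = slice$spacing, origin = slice$origin,
               z_position = slice$z_position,
               channel_offset = lo, channel_scale = scale)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = FALSE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_slice
#' @export
read_slice <- function(path) {
  if (!file.exists(path)) stop("no such slice file: ", path)
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop("slice sidecar ", sc, " is missing; cannot recover z_position, ",
         "spacing, origin")
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  for (field in c("spacing", "origin", "z_position"))
    if (is.null(meta[[field]]))
      stop("slice sidecar is missing required field: ", field)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
  } else if (ext == "png") {
    raw <- png::readPNG(path)
    pages <- if (length(dim(raw)) == 2L) list(raw)
             else lapply(seq_len(dim(raw)[3]), function(ch) raw[, , ch])
  } else stop("unsupported slice format: .", ext)
  off <- meta$channel_offset %||% rep(0, length(pages))
  scl <- meta$channel_scale %||% rep(1, length(pages))
  data <- array(0, c(rev(dim(pages[[1]])), length(pages)))
  for (ch in seq_along(pages))
    data[, , ch] <- t(pages[[ch]]) * scl[ch] + off[ch]
  slice_image(data, spacing = meta$spacing, origin = meta$origin,
              z_position = meta$z_position)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write point sets (CSV)
#'
#' Columns `x,y[,z]` in world mm; any further columns are carried through as
#' attributes in a data frame.
#'
#' @param points matrix or data frame with columns `x,y[,z]`
#' @param path CSV file path
#' @return `read_points` returns a data frame; `write_points` returns `path`
#'   invisibly.
#' @export
write_points <- function(points, path) {
  df <- as.data.frame(points)
  if (!all(c("x", "y") %in% names(df))) {
    if (ncol(df) %in% 2:3)
      names(df) <- c("x", "y", "z")[seq_len(ncol(df))]
    else stop("points must have columns x, y and optionally z")
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_points
#' @export
read_points <- function(path) {
  if (!file.exists(path)) stop("no such points file: ", path)
  df <- utils::read.csv(path)
  if (!all(c("x", "y") %in% names(df)))
    stop("points CSV must contain columns named x and y")
  df
}

#' Read and write triangle meshes (ASCII PLY)
#'
#' Vertex positions in mm, triangular faces, plus any per-vertex scalar
#' attributes (stored as extra float vertex properties).
#'
#' @param mesh a `TriMesh` (see [tri_mesh()])
#' @param path `.ply` file path
#' @param attributes optional named list of per-vertex numeric vectors
#' @return `read_mesh` returns a `TriMesh` (attributes, if any, in
#'   `$attributes`); `write_mesh` returns `path` invisibly.
#' @export
write_mesh <- function(mesh, path, attributes = NULL) {
  v <- mesh$vertices
  f <- mesh$faces
  nv <- nrow(v)
  props <- c("x", "y", "z", names(attributes))
  header <- c("ply", "format ascii 1.0",
              sprintf("element vertex %d", nv),
              sprintf("property float %s", props),
              sprintf("element face %d", nrow(f)),
              "property list uchar int vertex_indices",
              "end_header")
  vmat <- cbind(v, do.call(cbind, attributes))
  vlines <- apply(vmat, 1, function(r)
    paste(formatC(r, format = "g", digits = 9), collapse = " "))
  flines <- apply(f - 1L, 1, function(r) paste(c(3L, r), collapse = " "))
  writeLines(c(header, vlines, flines), path)
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("no such mesh file: ", path)
  lines <- readLines(path)
  if (length(lines) < 3 || lines[1] != "ply")
    stop("not an ASCII PLY file (missing 'ply' magic): ", path)
  endh <- match("end_header", lines)
  if (is.na(endh)) stop("malformed PLY: no end_header")
  header <- lines[seq_len(endh)]
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", header, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", header, value = TRUE)[1]))
  if (is.na(nv) || is.na(nf)) stop("malformed PLY: element counts missing")
  props <- sub("^property float ", "",
               grep("^property float", header, value = TRUE))
  vdat <- utils::read.table(text = lines[endh + seq_len(nv)])
  names(vdat) <- props
  fdat <- utils::read.table(text = lines[endh + nv + seq_len(nf)])
  faces <- as.matrix(fdat[, 2:4]) + 1L
  mesh <- tri_mesh(as.matrix(vdat[, c("x", "y", "z")]), faces)
  extra <- setdiff(props, c("x", "y", "z"))
  if (length(extra)) mesh$attributes <- as.list(vdat[extra])
  mesh
}
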