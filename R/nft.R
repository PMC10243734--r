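# Segmentation of tangle probability maps into discrete records, and
# per-region density tables. The heavy lifting (distance transform, seeded
# region propagation, shape moments) is delegated to EBImage; thresholding
# follows the classic 256-bin maximum between-class-variance rule.

#' Otsu threshold of an image
#'
#' Maximizes the between-class variance over a 256-bin histogram of the
#' intensity range; the mask is `image > threshold`. Inverting the image
#' inverts the mask (up to the threshold bin itself).
#'
#' @param image numeric matrix (or single-channel `SliceImage`) with at
#'   least two distinct values
#' @param n_bins histogram resolution (default 256)
#' @return list with `threshold` (intensity units) and `mask` (logical)
#' @export
otsu_threshold <- function(image, n_bins = 256L) {
  x <- if (inherits(image, "SliceImage")) image$data[, , 1] else image
  rng <- range(x)
  if (diff(rng) == 0)
    stop("constant image: Otsu threshold is undefined")
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(pmin(findInterval(x, edges, rightmost.closed = TRUE),
                     n_bins), n_bins)
  p <- h / sum(h)
  centers <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  omega <- cumsum(p)
  mu <- cumsum(p * centers)
  mu_t <- mu[n_bins]
  bcv <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  bcv[!is.finite(bcv)] <- 0
  kstar <- which.max(bcv[-n_bins])          # threshold between bins k, k+1
  thr <- edges[kstar + 1L]
  list(threshold = thr, mask = x > thr)
}

#' Watershed segmentation of a binary mask into tangle records
#'
#' The distance transform of the foreground is treated as topography;
#' local maxima separated by at least `min_distance_px` seed the basins,
#' which are grown by Voronoi-style propagation on the distance map. Each
#' basin yields one record with its centroid (mm), area (mm^2) and
#' roundness `4 pi A / P^2`; basins smaller than `min_area_px` pixels are
#' discarded as noise.
#'
#' @param mask logical matrix (foreground = tangle candidate)
#' @param min_distance_px minimum peak separation in pixels (default 10,
#'   i.e. 20 micrometres at 2 micrometre pixels)
#' @param spacing pixel spacing in mm
#' @param origin lattice origin in mm
#' @param min_area_px discard basins below this pixel count (default 3)
#' @return data frame with columns `x`, `y`, `area_mm2`, `roundness`,
#'   `n_pixels` (one row per detected tangle; zero rows for an empty mask)
#' @export
watershed_segment <- function(mask, min_distance_px = 10,
                              spacing = c(1, 1), origin = c(0, 0),
                              min_area_px = 3L) {
  mask <- as.matrix(mask) * 1
  empty <- data.frame(x = numeric(0), y = numeric(0),
                      area_mm2 = numeric(0), roundness = numeric(0),
                      n_pixels = integer(0))
  if (!any(mask > 0)) return(empty)
  dist <- EBImage::distmap(mask)
  dm <- EBImage::imageData(dist)
  seeds <- local_maxima(dm, radius = max(1L, as.integer(min_distance_px)))
  seed_lab <- matrix(0L, nrow(dm), ncol(dm))
  seed_lab[seeds] <- seq_len(nrow(seeds))
  lab <- EBImage::imageData(EBImage::propagate(
    EBImage::Image(max(dm) - dm), EBImage::Image(seed_lab), mask = mask > 0))
  records <- lapply(seq_len(max(lab)), function(id) {
    sel <- lab == id
    npx <- sum(sel)
    if (npx < min_area_px) return(NULL)
    ij <- which(sel, arr.ind = TRUE)
    ctr <- colMeans(ij) - 1
    per <- boundary_perimeter(sel, spacing)
    area <- npx * prod(spacing)
    data.frame(x = origin[1] + ctr[1] * spacing[1],
               y = origin[2] + ctr[2] * spacing[2],
               area_mm2 = area,
               roundness = min(4 * pi * area / per^2, 1),
               n_pixels = npx)
  })
  records <- do.call(rbind, records)
  if (is.null(records)) empty else records
}

# local maxima of a distance map with a minimum separation radius: a pixel
# is a peak if it attains the maximum of its (2r+1)^2 window; among plateau
# ties within a window, the first (lowest linear index) survives
local_maxima <- function(dm, radius) {
  d <- dim(dm)
  # separable running max over the (2r+1)^2 window
  mx <- dm
  for (dx in seq_len(radius)) {
    mx <- pmax(mx, shift_matrix(mx, 1, 0))
    mx <- pmax(mx, shift_matrix(mx, -1, 0))
  }
  for (dy in seq_len(radius)) {
    mx <- pmax(mx, shift_matrix(mx, 0, 1))
    mx <- pmax(mx, shift_matrix(mx, 0, -1))
  }
  cand <- which(dm > 0 & dm >= mx, arr.ind = TRUE)
  if (nrow(cand) <= 1) return(cand)
  # enforce the separation among surviving candidates (plateaus)
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    later <- seq_len(nrow(cand)) > i
    close <- abs(cand[, 1] - cand[i, 1]) <= radius &
      abs(cand[, 2] - cand[i, 2]) <= radius
    keep[later & close] <- FALSE
  }
  cand[keep, , drop = FALSE]
}

shift_matrix <- function(x, dx, dy) {
  d <- dim(x)
  out <- matrix(-Inf, d[1], d[2])
  xs <- max(1, 1 + dx):min(d[1], d[1] + dx)
  ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
  out[xs, ys] <- x[xs - dx, ys - dy]
  out
}

# boundary chain length in mm: Moore-neighbor contour tracing of the outer
# boundary, steps weighted by their physical length (diagonals sqrt 2)
boundary_perimeter <- function(sel, spacing) {
  d <- dim(sel)
  pad <- matrix(FALSE, d[1] + 2, d[2] + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1)] <- sel
  fg <- which(pad, arr.ind = TRUE)
  b0 <- fg[order(fg[, 2], fg[, 1]), , drop = FALSE][1, ]
  # Moore neighborhood in clockwise cyclic order, starting west
  moves <- rbind(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                 c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  b <- b0
  c_dir <- 1L   # west neighbor of b0 is background by construction
  total <- 0
  steps <- 0L
  max_steps <- 4L * sum(pad)
  repeat {
    found <- FALSE
    for (s in 0:7) {
      dn <- (c_dir + s - 1L) %% 8L + 1L
      nb <- b + moves[dn, ]
      if (pad[nb[1], nb[2]]) {
        total <- total + sqrt(sum((moves[dn, ] * spacing)^2))
        prev_dn <- (dn - 2L) %% 8L + 1L          # background just before
        cpos <- b + moves[prev_dn, ]
        rel <- cpos - nb
        nd <- which(moves[, 1] == rel[1] & moves[, 2] == rel[2])
        c_dir <- if (length(nd)) nd else 1L
        b <- nb
        found <- TRUE
        break
      }
    }
    steps <- steps + 1L
    if (!found) return(4 * mean(spacing))         # isolated pixel
    if (all(b == b0) || steps > max_steps) break
  }
  max(total, 4 * mean(spacing))
}

#' Per-region tangle counts and densities
#'
#' Each record is assigned to the region at its center (nearest pixel, with
#' a warning if the center falls off-lattice); region area is the tissue
#' pixel count times the pixel area.
#'
#' @param records data frame from [watershed_segment()]
#' @param tissue_mask logical matrix of tissue pixels
#' @param region_labels single-channel label `SliceImage`
#' @param n_regions number of regions L (labels 1..L)
#' @return data frame with one row per region: `region`, `count`,
#'   `area_mm2`, `density_per_mm2`
#' @export
region_density_table <- function(records, tissue_mask, region_labels,
                                 n_regions) {
  lab <- region_labels$data[, , 1]
  sp <- region_labels$spacing
  orig <- region_labels$origin
  d <- dim(lab)
  counts <- integer(n_regions)
  if (nrow(records)) {
    ii <- round((records$x - orig[1]) / sp[1])
    jj <- round((records$y - orig[2]) / sp[2])
    off <- ii < 0 | ii > d[1] - 1 | jj < 0 | jj > d[2] - 1
    if (any(off)) {
      warning(sum(off), " record center(s) off-lattice; ",
              "snapped to nearest pixel")
      ii <- pmin(pmax(ii, 0), d[1] - 1)
      jj <- pmin(pmax(jj, 0), d[2] - 1)
    }
    reg <- lab[cbind(ii + 1, jj + 1)]
    for (r in seq_len(n_regions)) counts[r] <- sum(reg == r)
  }
  areas <- vapply(seq_len(n_regions), function(r)
    sum(tissue_mask & lab == r) * prod(sp), numeric(1))
  data.frame(region = seq_len(n_regions), count = counts,
             area_mm2 = areas,
             density_per_mm2 = ifelse(areas > 0, counts / areas, NA_real_))
}
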