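#' Score a registration against phantom ground truth
#'
#' Computes (i) the landmark error: RMS distance in mm between the true and
#' estimated template-space positions of the recorded section-frame sample
#' points, (ii) per-region Dice overlap between mapped template labels and
#' the true observed-frame section labels, pooled over sections, and (iii)
#' the per-region 95th-percentile Hausdorff boundary distance with boundary
#' distances pooled over sections.
#'
#' @param result a `RegistrationResult`
#' @param truth the `truth` component of [simulate_sections()]
#' @param labels3d the template label `ImageVolume`
#' @param n_regions number of regions
#' @return list with `landmark_rms_mm`, `dice` (per region),
#'   `hausdorff95_mm` (per region), and the per-section mapped label images
#' @export
evaluate_registration <- function(result, truth, labels3d, n_regions = 4L) {
  ns <- length(result$slices)
  sq_err <- numeric(0)
  mapped <- vector("list", ns)
  inter <- matrix(0, ns, n_regions)
  sz_a <- matrix(0, ns, n_regions)
  sz_b <- matrix(0, ns, n_regions)
  bdist <- vector("list", n_regions)
  for (n in seq_len(ns)) {
    co <- truth$correspondences[[n]]
    est <- chain_forward(result$state, n,
                         pts2d = cbind(co$y1, co$y2))$q3
    sq_err <- c(sq_err, rowSums((est - cbind(co$x1, co$x2, co$x3))^2))
    mapped[[n]] <- map_labels(labels3d, result, n)
    ml <- mapped[[n]]$data[, , 1]
    tl <- truth$labels2d[[n]]$data[, , 1]
    for (r in seq_len(n_regions)) {
      a <- ml == r
      b <- tl == r
      inter[n, r] <- sum(a & b)
      sz_a[n, r] <- sum(a)
      sz_b[n, r] <- sum(b)
      if (any(a) && any(b)) {
        sp <- truth$labels2d[[n]]$spacing
        pa <- boundary_points(a, sp)
        pb <- boundary_points(b, sp)
        dm <- outer(pa[, 1], pb[, 1], "-")^2 + outer(pa[, 2], pb[, 2], "-")^2
        bdist[[r]] <- c(bdist[[r]], sqrt(apply(dm, 1, min)),
                        sqrt(apply(dm, 2, min)))
      }
    }
  }
  dice_r <- vapply(seq_len(n_regions), function(r) {
    denom <- sum(sz_a[, r]) + sum(sz_b[, r])
    if (denom == 0) NA_real_ else 2 * sum(inter[, r]) / denom
  }, numeric(1))
  hd_r <- vapply(seq_len(n_regions), function(r) {
    if (is.null(bdist[[r]])) NA_real_
    else as.numeric(stats::quantile(bdist[[r]], 0.95, names = FALSE))
  }, numeric(1))
  list(landmark_rms_mm = sqrt(mean(sq_err)), dice = dice_r,
       hausdorff95_mm = hd_r, mapped_labels = mapped)
}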