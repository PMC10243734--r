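#' Scattering transform configuration
#'
#' A cascade of Morlet wavelet convolutions and modulus nonlinearities across
#' `J` dyadic scales and `L` orientations, followed by a Gaussian low-pass.
#' Order-2 scattering retains all paths `(j1,l1) -> (j2,l2)` with `j2 > j1`,
#' so each input channel expands to `1 + J*L + L^2 * J*(J-1)/2` feature
#' images. The defaults `(J = 2, L = 3, order = 2)` give 16 paths per
#' channel, i.e. 48 filtered images for a 3-channel stain.
#'
#' @param J number of dyadic scales (>= 1)
#' @param L number of orientations (>= 1)
#' @param order scattering order, 1 or 2
#' @return a `ScatteringConfig`
#' @export
scattering_config <- function(J = 2L, L = 3L, order = 2L) {
  stopifnot(J >= 1, L >= 1, order %in% c(1L, 2L))
  structure(list(J = as.integer(J), L = as.integer(L),
                 order = as.integer(order), family = "morlet"),
            class = "ScatteringConfig")
}

#' Number of scattering paths per input channel
#' @param cfg a [scattering_config()]
#' @return integer path count
#' @export
scattering_path_count <- function(cfg) {
  n <- 1L + cfg$J * cfg$L
  if (cfg$order == 2L) n <- n + as.integer(cfg$L^2 * cfg$J * (cfg$J - 1) / 2)
  n
}

# Morlet filter bank in the Fourier domain on an nx x ny pixel grid.
# psi_{j,l}: Gaussian bump at center frequency xi0/2^j rotated by theta_l,
# corrected to exactly zero mean; phi_J: Gaussian low-pass at scale 2^J.
morlet_bank <- function(nx, ny, J, L, xi0 = 3 * pi / 4, sigma0 = 0.8) {
  wx <- 2 * pi * ifelse(seq_len(nx) - 1 <= nx / 2, seq_len(nx) - 1,
                        seq_len(nx) - 1 - nx) / nx
  wy <- 2 * pi * ifelse(seq_len(ny) - 1 <= ny / 2, seq_len(ny) - 1,
                        seq_len(ny) - 1 - ny) / ny
  WX <- matrix(wx, nx, ny)
  WY <- matrix(wy, nx, ny, byrow = TRUE)
  psi <- vector("list", J * L)
  meta <- data.frame(j = integer(0), l = integer(0))
  for (j in seq_len(J) - 1L) {
    sj <- sigma0 * 2^j
    xj <- xi0 / 2^j
    for (l in seq_len(L) - 1L) {
      th <- pi * l / L
      cx <- xj * cos(th); cy <- xj * sin(th)
      g1 <- exp(-((WX - cx)^2 + (WY - cy)^2) * sj^2 / 2)
      g0 <- exp(-(WX^2 + WY^2) * sj^2 / 2)
      # beta makes the filter exactly zero-mean: psi_hat(0) = 0
      beta <- exp(-(cx^2 + cy^2) * sj^2 / 2)
      psi[[j * L + l + 1L]] <- g1 - beta * g0
      meta <- rbind(meta, data.frame(j = j, l = l))
    }
  }
  sJ <- sigma0 * 2^J
  phi <- exp(-(WX^2 + WY^2) * sJ^2 / 2)
  list(psi = psi, phi = phi, meta = meta)
}

fft2 <- function(x) stats::fft(x)
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

#' Scattering-transform feature expansion of a section image
#'
#' Expands each channel of `slice` into translation-stable, texture-sensitive
#' filtered images at the (coarser) target resolution: the low-passed input
#' (order 0), low-passed wavelet moduli (order 1), and low-passed moduli of
#' moduli for scale-increasing paths (order 2). Channels of multi-channel
#' inputs are expanded independently and concatenated.
#'
#' @param slice a `SliceImage` (fine resolution, e.g. histology)
#' @param cfg a [scattering_config()]
#' @param target_spacing output pixel spacing in mm (>= input spacing)
#' @return a `FeatureStack`: a `SliceImage` whose channels are the feature
#'   images, with a `$paths` data frame (input channel, order, j1, l1, j2, l2)
#' @export
scatter <- function(slice, cfg = scattering_config(),
                    target_spacing = max(slice$spacing)) {
  stopifnot(inherits(slice, "SliceImage"))
  d <- dim(slice$data)
  if (any(target_spacing < slice$spacing - 1e-12))
    stop("target_spacing must be >= the input spacing")
  if (any(d[1:2] < 2^cfg$J))
    stop(sprintf("image (%dx%d) smaller than 2^J = %d", d[1], d[2], 2^cfg$J))
  bank <- morlet_bank(d[1], d[2], cfg$J, cfg$L)
  sub <- 2^cfg$J
  lowpass_out <- function(x) {
    lp <- Re(ifft2(fft2(x) * bank$phi))
    ii <- seq(1, d[1], by = sub)
    jj <- seq(1, d[2], by = sub)
    lp[ii, jj, drop = FALSE]
  }
  out <- list()
  paths <- data.frame(channel = integer(0), order = integer(0),
                      j1 = integer(0), l1 = integer(0),
                      j2 = integer(0), l2 = integer(0))
  for (ch in seq_len(d[3])) {
    x <- slice$data[, , ch]
    xh <- fft2(x)
    out[[length(out) + 1L]] <- lowpass_out(x)
    paths <- rbind(paths, data.frame(channel = ch, order = 0L, j1 = NA,
                                     l1 = NA, j2 = NA, l2 = NA))
    for (p1 in seq_len(nrow(bank$meta))) {
      u1 <- Mod(ifft2(xh * bank$psi[[p1]]))
      out[[length(out) + 1L]] <- lowpass_out(u1)
      paths <- rbind(paths, data.frame(channel = ch, order = 1L,
                                       j1 = bank$meta$j[p1],
                                       l1 = bank$meta$l[p1],
                                       j2 = NA, l2 = NA))
      if (cfg$order < 2L) next
      u1h <- fft2(u1)
      for (p2 in seq_len(nrow(bank$meta))) {
        if (bank$meta$j[p2] <= bank$meta$j[p1]) next
        u2 <- Mod(ifft2(u1h * bank$psi[[p2]]))
        out[[length(out) + 1L]] <- lowpass_out(u2)
        paths <- rbind(paths, data.frame(channel = ch, order = 2L,
                                         j1 = bank$meta$j[p1],
                                         l1 = bank$meta$l[p1],
                                         j2 = bank$meta$j[p2],
                                         l2 = bank$meta$l[p2]))
      }
    }
  }
  sub_dims <- dim(out[[1]])
  feat <- slice_image(array(unlist(out), c(sub_dims, length(out))),
                      spacing = slice$spacing * sub,
                      origin = slice$origin,
                      z_position = slice$z_position)
  # bring the subsampled low-pass outputs to the requested lattice
  target_spacing <- rep(as.numeric(target_spacing), length.out = 2)
  if (any(abs(target_spacing - feat$spacing) > 1e-9)) {
    fac <- target_spacing / feat$spacing
    feat <- if (max(abs(fac - round(fac))) < 1e-8 && all(round(fac) >= 1))
      block_downsample(feat, target_spacing)
    else resample_slice(feat, target_spacing)
  }
  feat$paths <- paths
  class(feat) <- c("FeatureStack", class(feat))
  feat
}
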