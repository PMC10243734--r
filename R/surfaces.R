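#' Triangle mesh with lumped vertex areas
#'
#' Subregion boundary surfaces carry per-vertex weights `w(y)` (mm^2):
#' one third of the total area of the triangles incident to each vertex
#' (barycentric lumping), so the weights sum exactly to the surface area.
#'
#' @param vertices V x 3 matrix of positions (mm)
#' @param faces F x 3 integer matrix of 1-based vertex indices
#' @return a `TriMesh` with `$vertex_weights` and `$area`
#' @export
tri_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  stopifnot(ncol(vertices) == 3)
  if (any(faces < 1) || any(faces > nrow(vertices)))
    stop("face indices out of range")
  fa <- face_areas(vertices, faces)
  w <- numeric(nrow(vertices))
  for (c in 1:3) {
    s <- rowsum(fa / 3, faces[, c])
    idx <- as.integer(rownames(s))
    w[idx] <- w[idx] + s
  }
  structure(list(vertices = vertices, faces = faces,
                 vertex_weights = w, area = sum(fa)),
            class = "TriMesh")
}

face_areas <- function(v, f) {
  e1 <- v[f[, 2], ] - v[f[, 1], ]
  e2 <- v[f[, 3], ] - v[f[, 1], ]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' @export
print.TriMesh <- function(x, ...) {
  cat(sprintf("TriMesh: %d vertices, %d faces, area %.4g mm^2\n",
              nrow(x$vertices), nrow(x$faces), x$area))
  invisible(x)
}

mesh_edges <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

min_edge_length <- function(mesh) {
  e <- unique(mesh_edges(mesh$faces))
  min(sqrt(rowSums((mesh$vertices[e[, 1], ] - mesh$vertices[e[, 2], ])^2)))
}

# each undirected edge must border exactly two faces for a closed manifold
is_closed_manifold <- function(faces) {
  e <- mesh_edges(faces)
  key <- e[, 1] * (max(e) + 1) + e[, 2]
  all(table(key) == 2)
}

#' Geodesic icosphere
#'
#' Icosahedron refined by `subdivisions` rounds of midpoint subdivision with
#' projection to the sphere; 4 subdivisions give 2562 vertices. Used for
#' analytic checks of the Laplace-Beltrami machinery.
#'
#' @param radius sphere radius (mm)
#' @param subdivisions refinement rounds (>= 0)
#' @param center sphere center
#' @return a `TriMesh`
#' @export
sphere_mesh <- function(radius = 1, subdivisions = 3L, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    nv <- nrow(v)
    e <- unique(mesh_edges(f))
    mid <- (v[e[, 1], ] + v[e[, 2], ]) / 2
    mid <- mid / sqrt(rowSums(mid^2))
    ekey <- e[, 1] * (nv + 1) + e[, 2]
    lookup <- function(a, b) {
      key <- pmin(a, b) * (nv + 1) + pmax(a, b)
      nv + match(key, ekey)
    }
    m12 <- lookup(f[, 1], f[, 2])
    m23 <- lookup(f[, 2], f[, 3])
    m31 <- lookup(f[, 3], f[, 1])
    v <- rbind(v, mid)
    f <- rbind(cbind(f[, 1], m12, m31), cbind(f[, 2], m23, m12),
               cbind(f[, 3], m31, m23), cbind(m12, m23, m31))
  }
  tri_mesh(sweep(v * radius, 2, center, "+"), f)
}

#' Extract and decimate a subregion boundary surface
#'
#' The region's indicator is lightly smoothed and its 0.5 level set
#' extracted by marching tetrahedra (six tetrahedra per lattice cell),
#' giving a closed triangulated boundary at voxel scale. The mesh is then
#' decimated — vertex clustering at the target edge scale followed by
#' collapse of any remaining short edges — until the minimum triangle edge
#' reaches `target_min_edge` (default 6 voxels).
#'
#' @param labels3d an `ImageVolume` of integer labels
#' @param region label value to extract
#' @param target_min_edge minimum triangle edge in mm; default
#'   `6 * min(spacing)`
#' @return a `TriMesh`
#' @export
mesh_from_labels <- function(labels3d, region,
                             target_min_edge = NULL) {
  stopifnot(inherits(labels3d, "ImageVolume"))
  if (is.null(target_min_edge))
    target_min_edge <- 6 * min(labels3d$spacing)
  ind <- labels3d$data[, , , 1] == region
  if (!any(ind)) stop("region ", region, " not present in labels")
  d <- dim(ind)
  sp <- labels3d$spacing
  mult <- kernel_multiplier(kernel_spec(min(sp)), d, sp)
  f <- kernel_apply(ind * 1, mult)
  mesh <- marching_tetrahedra(f, 0.5, sp, labels3d$origin)
  mesh <- decimate_mesh(mesh, target_min_edge)
  mesh
}

# the 6-tetrahedron decomposition of the unit cube (corner ids 1..8 in
# binary order: 1=(0,0,0), 2=(1,0,0), 3=(0,1,0), 4=(1,1,0), 5=(0,0,1), ...)
tet_table <- rbind(c(1, 2, 4, 8), c(1, 4, 3, 8), c(1, 3, 7, 8),
                   c(1, 7, 5, 8), c(1, 5, 6, 8), c(1, 6, 2, 8))

marching_tetrahedra <- function(f, iso, spacing, origin) {
  d <- dim(f)
  corner_off <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  # mixed cells only
  above <- f > iso
  cs <- array(0L, d - 1L)
  for (c in 1:8) {
    o <- corner_off[c, ]
    cs <- cs + above[(1:(d[1] - 1)) + o[1], (1:(d[2] - 1)) + o[2],
                     (1:(d[3] - 1)) + o[3]]
  }
  mixed <- which(cs > 0L & cs < 8L, arr.ind = TRUE)
  if (!nrow(mixed)) stop("no level-set crossing found")
  nvox <- prod(d)
  tri_keys <- vector("list", 4096)
  ntri <- 0L
  lin_of <- function(ijk) (ijk[, 1]) + (ijk[, 2] - 1) * d[1] +
    (ijk[, 3] - 1) * d[1] * d[2]
  for (mi in seq_len(nrow(mixed))) {
    base <- mixed[mi, ]
    cid <- integer(8); cval <- numeric(8)
    for (c in 1:8) {
      ijk <- base + corner_off[c, ]
      cid[c] <- ijk[1] + (ijk[2] - 1) * d[1] + (ijk[3] - 1) * d[1] * d[2]
      cval[c] <- f[cid[c]]
    }
    for (t in 1:6) {
      tc <- tet_table[t, ]
      pos <- cval[tc] > iso
      np <- sum(pos)
      if (np == 0L || np == 4L) next
      # edge key between global corners a < b
      ekey <- function(a, b) pmin(cid[a], cid[b]) * nvox +
        pmax(cid[a], cid[b])
      if (np == 1L || np == 3L) {
        a <- if (np == 1L) tc[pos] else tc[!pos]   # cube corner id of apex
        o <- setdiff(tc, a)
        keys <- c(ekey(a, o[1]), ekey(a, o[2]), ekey(a, o[3]))
        ntri <- ntri + 1L
        tri_keys[[ntri]] <- keys
      } else {
        pp <- tc[pos]; nn <- tc[!pos]
        k11 <- ekey(pp[1], nn[1]); k12 <- ekey(pp[1], nn[2])
        k21 <- ekey(pp[2], nn[1]); k22 <- ekey(pp[2], nn[2])
        ntri <- ntri + 2L
        tri_keys[[ntri - 1L]] <- c(k11, k12, k21)
        tri_keys[[ntri]] <- c(k12, k22, k21)
      }
      if (ntri + 2L > length(tri_keys))
        tri_keys <- c(tri_keys, vector("list", length(tri_keys)))
    }
  }
  keys <- do.call(rbind, tri_keys[seq_len(ntri)])
  uk <- sort(unique(as.vector(keys)))
  fidx <- matrix(match(as.vector(keys), uk), ncol = 3)
  # vertex positions: linear interpolation along each crossing edge
  a_lin <- floor(uk / nvox)
  b_lin <- uk - a_lin * nvox
  to_ijk <- function(lin) {
    lin0 <- lin - 1
    i <- lin0 %% d[1]
    j <- (lin0 %/% d[1]) %% d[2]
    k <- lin0 %/% (d[1] * d[2])
    cbind(i, j, k)
  }
  pa <- to_ijk(a_lin); pb <- to_ijk(b_lin)
  fa <- f[a_lin]; fb <- f[b_lin]
  tt <- (iso - fa) / (fb - fa)
  tt[!is.finite(tt)] <- 0.5
  tt <- pmin(pmax(tt, 0), 1)
  pij <- pa + tt * (pb - pa)
  verts <- sweep(sweep(pij, 2, spacing, "*"), 2, origin, "+")
  # drop degenerate faces (repeated vertex)
  good <- fidx[, 1] != fidx[, 2] & fidx[, 2] != fidx[, 3] &
    fidx[, 1] != fidx[, 3]
  tri_mesh(verts, fidx[good, , drop = FALSE])
}

# vertex clustering + short-edge collapse until min edge >= target
decimate_mesh <- function(mesh, target_min_edge) {
  v <- mesh$vertices
  f <- mesh$faces
  # cluster vertices on a grid of cell size ~ target edge
  h <- target_min_edge
  cell <- floor(sweep(v, 2, apply(v, 2, min), "-") / h)
  key <- cell[, 1] + 1e4 * cell[, 2] + 1e8 * cell[, 3]
  uk <- unique(key)
  grp <- match(key, uk)
  nv <- length(uk)
  newv <- matrix(0, nv, 3)
  for (c in 1:3) {
    s <- rowsum(v[, c], grp)
    newv[as.integer(rownames(s)), c] <- s / tabulate(grp, nv)
  }
  nf <- cbind(grp[f[, 1]], grp[f[, 2]], grp[f[, 3]])
  nf <- nf[nf[, 1] != nf[, 2] & nf[, 2] != nf[, 3] & nf[, 1] != nf[, 3], ,
           drop = FALSE]
  nf <- dedupe_faces(nf)
  m <- list(vertices = newv, faces = nf)
  m <- collapse_short_edges(m, target_min_edge)
  keep <- sort(unique(as.vector(m$faces)))
  remap <- match(seq_len(nrow(m$vertices)), keep)
  tri_mesh(m$vertices[keep, , drop = FALSE],
           matrix(remap[m$faces], ncol = 3))
}

dedupe_faces <- function(f) {
  fs <- t(apply(f, 1, sort))
  key <- paste(fs[, 1], fs[, 2], fs[, 3])
  f[!duplicated(key) & !(key %in% key[duplicated(key)]), , drop = FALSE]
}

# shortest-edge collapses, batched: each pass collapses a maximal
# vertex-disjoint set of short edges (shortest first) to their midpoints
collapse_short_edges <- function(m, target, max_pass = 200L) {
  v <- m$vertices
  f <- m$faces
  for (pass in seq_len(max_pass)) {
    e <- unique(mesh_edges(f))
    len <- sqrt(rowSums((v[e[, 1], ] - v[e[, 2], ])^2))
    short <- which(len < target)
    if (!length(short)) break
    short <- short[order(len[short])]
    used <- rep(FALSE, nrow(v))
    remap <- seq_len(nrow(v))
    for (ei in short) {
      a <- e[ei, 1]; b <- e[ei, 2]
      if (used[a] || used[b]) next
      v[a, ] <- (v[a, ] + v[b, ]) / 2
      remap[b] <- a
      used[a] <- TRUE; used[b] <- TRUE
    }
    f <- matrix(remap[f], ncol = 3)
    f <- f[f[, 1] != f[, 2] & f[, 2] != f[, 3] & f[, 1] != f[, 3], ,
           drop = FALSE]
    f <- dedupe_faces(f)
  }
  list(vertices = v, faces = f)
}

#' Laplace-Beltrami basis of a closed surface
#'
#' Solves the generalized eigenproblem of the cotangent Laplacian with
#' lumped (barycentric) vertex-area mass: eigenfunctions are orthonormal
#' under the weighted vertex inner product
#' `<g, h>_V = sum_y g(y) h(y) w(y)`, eigenvalues are sorted ascending with
#' the constant eigenfunction at eigenvalue 0 first.
#'
#' @param mesh a closed manifold `TriMesh`
#' @param N number of eigenpairs (at most the vertex count; the full basis
#'   `N = nrow(vertices)` makes k = 0 smoothing the identity)
#' @return an `LBBasis` with `functions` (V x N), `values` (length N), and
#'   the mesh
#' @export
lb_basis <- function(mesh, N) {
  nv <- nrow(mesh$vertices)
  stopifnot(N >= 1, N <= nv)
  if (!is_closed_manifold(mesh$faces))
    stop("mesh is not a closed manifold (an edge borders != 2 faces)")
  L <- cotan_laplacian(mesh)
  w <- mesh$vertex_weights
  s <- 1 / sqrt(w)
  S <- L * outer(s, s)
  S <- (S + t(S)) / 2
  eg <- eigen(S, symmetric = TRUE)
  ord <- seq(nv, nv - N + 1L)
  vals <- pmax(eg$values[ord], 0)
  funs <- eg$vectors[, ord, drop = FALSE] * s
  # fix the sign convention: first nonzero entry positive
  for (i in seq_len(N)) {
    nz <- which(abs(funs[, i]) > 1e-12)[1]
    if (!is.na(nz) && funs[nz, i] < 0) funs[, i] <- -funs[, i]
  }
  structure(list(functions = funs, values = vals, mesh = mesh),
            class = "LBBasis")
}

cotan_laplacian <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  nv <- nrow(v)
  L <- matrix(0, nv, nv)
  corners <- rbind(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2))
  for (c in 1:3) {
    i <- f[, corners[c, 1]]; j <- f[, corners[c, 2]]
    k <- f[, corners[c, 3]]
    # cotangent at corner k, opposite edge (i, j)
    u <- v[i, ] - v[k, ]
    wv <- v[j, ] - v[k, ]
    dot <- rowSums(u * wv)
    crs <- sqrt(pmax(rowSums(u^2) * rowSums(wv^2) - dot^2, 1e-300))
    ct <- dot / crs
    for (t in seq_along(i)) {
      L[i[t], j[t]] <- L[i[t], j[t]] - ct[t] / 2
      L[j[t], i[t]] <- L[j[t], i[t]] - ct[t] / 2
      L[i[t], i[t]] <- L[i[t], i[t]] + ct[t] / 2
      L[j[t], j[t]] <- L[j[t], j[t]] + ct[t] / 2
    }
  }
  L
}

#' Project particle mass to surface vertices
#'
#' Nearest-neighbor kernel: each particle is assigned wholly to its closest
#' vertex (ties: lowest vertex index), accumulating the tangle counts
#' (`g_tau`) and tissue areas (`g_a`); totals are conserved exactly.
#'
#' @param mu a 3D `ParticleMeasure` in the mesh's frame
#' @param mesh a `TriMesh`
#' @return list with per-vertex `g_tau` (counts) and `g_a` (mm^2)
#' @export
project_to_surface <- function(mu, mesh) {
  nv <- nrow(mesh$vertices)
  if (nrow(mu$points) == 0)
    return(list(g_tau = numeric(nv), g_a = numeric(nv)))
  stopifnot(ncol(mu$points) == 3)
  nn <- nearest_site(mu$points, mesh$vertices)
  counts <- rowSums(mu$features[, seq_len(mu$n_regions), drop = FALSE])
  list(g_tau = as.vector(rowsum_full(counts, nn, nv)),
       g_a = as.vector(rowsum_full(mu$weights, nn, nv)))
}

#' Smooth a vertex function in the Laplace-Beltrami basis
#'
#' Expands `g` in the basis and attenuates each coefficient, by default with
#' the Tikhonov factor `1 / (1 + k lambda_i)` (the minimizer of
#' `||ghat - g||^2 + k ||grad ghat||^2` in the truncated basis). The
#' spatially varying printed variant `1 / (1 - k lambda_i w(y))` is
#' available for comparison as `form = "printed"`.
#'
#' @param g per-vertex values on the basis mesh
#' @param basis an [lb_basis()]
#' @param k smoothing constant (>= 0); 0 with a full basis reproduces `g`
#' @param form `"tikhonov"` (default) or `"printed"`
#' @return smoothed per-vertex values
#' @export
smooth_on_surface <- function(g, basis, k, form = c("tikhonov", "printed")) {
  form <- match.arg(form)
  if (k < 0) stop("smoothing constant k must be >= 0")
  w <- basis$mesh$vertex_weights
  stopifnot(length(g) == length(w))
  coef <- crossprod(basis$functions, g * w)   # <g, beta_i>_V
  if (form == "tikhonov") {
    as.vector(basis$functions %*% (coef / (1 + k * basis$values)))
  } else {
    acc <- numeric(length(g))
    for (i in seq_along(basis$values)) {
      denom <- 1 - k * basis$values[i] * w
      if (any(abs(denom) < 1e-8))
        stop("printed attenuation form is singular at this k")
      acc <- acc + coef[i] * basis$functions[, i] / denom
    }
    acc
  }
}

#' Per-vertex surface density
#'
#' Pointwise ratio of smoothed counts to smoothed area, masked (`NA`) where
#' the smoothed area is at or below `eps`.
#'
#' @param g_tau_hat,g_a_hat smoothed per-vertex counts and areas
#' @param eps positivity threshold for the denominator (mm^2)
#' @return per-vertex density in counts / mm^2
#' @export
surface_density <- function(g_tau_hat, g_a_hat, eps = 1e-9) {
  out <- rep(NA_real_, length(g_tau_hat))
  ok <- g_a_hat > eps
  out[ok] <- g_tau_hat[ok] / g_a_hat[ok]
  out
}
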