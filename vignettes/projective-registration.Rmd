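---
title: "Projective diffeomorphic registration of 2D sections to 3D volumes"
author: "projlddmm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projective diffeomorphic registration of 2D sections to 3D volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(projlddmm)
```

## The problem

Histological sections are sparse, distorted, 2D snapshots of a 3D organ.
Reconstructing where each section sits in the dense 3D anatomy — for
example, placing tau-stained sections of a medial temporal lobe into the
coordinate system of a postmortem MRI — requires solving three coupled
problems at once:

1. **Geometry across dimensions.** The 3D anatomy deforms smoothly
   (fixation, atrophy relative to a template), and each cut section is then
   further distorted *independently* in its own plane (mounting, stretch,
   rigid placement on the slide). The observation is not an element of the
   3D orbit; it is a *projection* of it.
2. **Contrast across modalities.** A stained section (q = 3 RGB channels at
   micron scale) and an MRI template (r = 1 channel at 0.125 mm) have no
   shared intensity scale, and structures that are distinct under the
   microscope can be iso-intense after naive downsampling.
3. **Artifacts.** Tears, folds and background are not noise around a mean;
   they are pixels where the tissue model simply does not apply.

This package implements a registration model that addresses all three: a
large-deformation diffeomorphic (LDDMM) flow in 3D composed with a planar
(or blurred) projection operator and per-section 2D rigid + diffeomorphic
motions; a wavelet-scattering feature expansion of each section, reduced by
PCA to a small predictive basis whose linear combination predicts template
contrast; and a three-class conditionally Gaussian mixture
(tissue/artifact/background) whose posterior weight fields gate the
matching term. Downstream, detected pathology (tangle points) is carried
into 3D as weighted particle measures under the varifold action, resampled
across scales with mass-conserving kernels, and smoothed on subregion
boundary surfaces in a Laplace–Beltrami eigenbasis.

## The observation model

Write the template as $I_{\mathrm{temp}}:\mathbb{R}^3\to\mathbb{R}$ and the
unknown 3D diffeomorphism as $\varphi$, generated by integrating a
time-dependent velocity field $v_t$ ($\dot\varphi_t=v_t(\varphi_t)$,
$\varphi_0=\mathrm{Id}$) with $v_t$ in a reproducing-kernel Hilbert space.
The deformed anatomy $I=I_{\mathrm{temp}}\circ\varphi_1^{-1}$ is observed
only on section planes $z_n$ through a point-spread projection $P_n$ —
either exact planar sampling (physical sectioning) or a normalized Gaussian
average along $z$ (optical sectioning) — and each projected section is then
moved by its own in-plane map $\phi_n = A_n\circ\psi_n$ (rigid/affine
$A_n$, small 2D diffeomorphism $\psi_n$ with its own kernel-norm penalty).

On the other side of the channel, each observed section $J_n$ is expanded
by a Morlet scattering transform (2 dyadic scales, 3 orientations, order 2
by default: 16 paths per channel, 48 feature images for an RGB stain) at
the template's in-plane resolution. The pooled standardized features of all
sections are reduced once by PCA to shared orthonormal loadings; each
section's projections on those loadings, plus a constant image, form its
predictive basis $\psi_n^0\equiv 1,\psi_n^1,\dots,\psi_n^m$ ($m=6$). A
per-section coefficient vector $\alpha_n$ maps features to template
intensity, $J^\alpha_n=\alpha_n^\top\psi_n$, fitted by (weighted) least
squares through the normal equations.

The per-pixel mixture treats the deformed projected template
$\phi_n\cdot P_n I$ as the observation: class 1 has the spatially varying
mean $J_n^\alpha(y)$ (matching tissue), classes 2 and 3 have scalar means
$\mu_A,\mu_B$ (artifact, background). The E-step posterior weight fields
$\pi_{n,k}$ gate a weighted least-squares matching cost; the M-step updates
$\mu_A,\mu_B$ (and optionally the $\sigma_k$) in closed form.

## The objective and its optimization

All blocks are alternated against one scalar: the variational free energy

$$F=w_v\int_0^1\lVert v_t\rVert_V^2\,dt
  +\sum_n w_u\int_0^1\lVert u_{n,t}\rVert_U^2\,dt
  +\sum_{n,y,k}\pi_{n,k}(y)\Big[\tfrac{|\mu_k(y)-\mathrm{obs}_n(y)|^2}
  {2\sigma_k^2}+r\log\sigma_k-\log p_k\Big]+\pi_{n,k}\log\pi_{n,k}.$$

The E-step minimizes $F$ exactly over the weights, the M-step and the
contrast least squares minimize it over their parameters, and the geometry
blocks (Gauss–Newton on each rigid motion; kernel-preconditioned "Hilbert"
gradient steps on each $u_n$ and on $v$) only accept steps passing an
Armijo sufficient-decrease test — a generalized EM scheme, so the recorded
energy trace is non-increasing by construction. `register_stack()` runs
this alternation on a two-level multiresolution schedule (one 2x-coarsened
pass, then full resolution).

Two interactions between the contrast channel and the geometry deserve
emphasis, because both were found the hard way on the phantom:

* **The coefficients must not chase the geometry.** Re-fitting $\alpha_n$
  at every iteration lets the contrast prediction absorb geometric
  misalignment (the fit reproduces whatever the current — wrong — projected
  template looks like), and the rigid estimates stall at the identity. By
  default the coefficients are fitted once per resolution level, at that
  level's initial geometry, and held fixed while geometry moves
  (`alpha_refit = "level"`).
* **Rotations need a profiled initialization.** The pair
  $(\theta_n,\alpha_n)$ has a coordinate-descent fixed point at
  $\theta_n=0$: each is the partial minimizer given the other. The rotation
  is therefore initialized by a sweep over angles with $\alpha_n$ profiled
  out (re-fit in closed form per candidate); the profiled landscape's
  minimizer tracks the true angle where the fixed-$\alpha$ landscape does
  not.

Gradients with respect to the velocity values are the **exact reverse-mode
derivatives of the discretized objective**. The chain for a section pixel
$y$ is: inverse rigid, backward Euler flow of $u_n$, embedding at $z_n$,
backward Euler flow of $v$, trilinear sampling of the template. Every step
is an interpolation whose adjoint (scatter) and positional derivative are
available in closed form, so the backpropagated gradient matches central
finite differences to ~1e-10 along smooth interior perturbations (see the
test suite). Two caveats define where "interior" matters: trilinear
interpolation kinks on lattice planes (a section placed exactly on a
voxel-center plane has a genuine one-sided derivative in $z$), and the
velocity fields are zero-filled outside their lattice hull (a field that
does not decay toward the hull is discontinuous across it). Neither affects
optimization — the line search guards every step — but finite-difference
checks are meaningful only away from those sets.

### Numerical choices

* **Kernels.** The velocity norm uses a Gaussian multiplier (width 5x voxel
  spacing in 3D, 3x pixel spacing in 2D) applied spectrally on the periodic
  lattice. The raw Gaussian spectrum underflows double precision at high
  frequency, which would let $\langle v,K^{-1}v\rangle$ amplify FFT
  round-off without bound; the multiplier is therefore floored at 1e-6 of
  its DC value. This keeps the form positive definite and leaves
  kernel-smooth fields' energies unchanged to round-off. A
  power-of-Laplacian multiplier (`kernel_spec(kind = "laplacian")`) is
  available where polynomial spectral decay is preferred.
* **Flows.** Particle-path Euler stepping with nt = 5 timesteps in 3D and
  3 in 2D; inverses integrate the negated field in reversed time; Jacobian
  determinants by central differences, with non-positive values flagged.
* **Mixture defaults.** Uniform class priors; $\sigma_1=\sigma_2=\sigma_3$
  set to the robust (MAD) residual scale over tissue-like pixels at
  initialization — the Otsu-gated restriction matters, because the
  background dominates the lattice and would shrink $\sigma$ to the noise
  floor — and held fixed ($\sigma$ updates per class are available via
  `update_sigma`, and sharpen artifact localization considerably); $\mu_A$
  initialized at the median tissue observation, $\mu_B$ at the 2nd
  percentile, both re-fitted each M-step. For artifact-heavy sections,
  `init_irls` interleaves a few reweighted refits of the contrast
  coefficients with E/M steps at initialization (the first, unweighted fit
  regresses straight through tears); on clean data this reweighting can
  slightly down-weight the hard-to-predict texture-separated regions, so
  it is off by default and enabled in the tear studies together with
  `update_sigma`.
* **Penalty balance.** The kernel-norm weights must be sized against the
  matching term — with weights near 1 the per-section 2D fields balloon an
  order of magnitude beyond plausible section distortions while the free
  energy still decreases. The phantom studies use `w_v = 30`,
  `w_u = 3000`, and a 3D kernel width equal to the phantom's deformation
  correlation scale (2.5 mm); the exported defaults are intentionally more
  generic.
* **What the artifact class can and cannot see.** The mixture observes the
  deformed projected template, with the section's predicted contrast as
  the tissue mean. A torn pixel is detectable exactly where the
  prediction (driven by tear-like features) disagrees with the overlaid
  template intensity; tears lying over tissue whose intensity happens to
  match the contrast image of tear features are invisible to the weights,
  which bounds how sharply the posteriors can concentrate on tear masks.
* **Contrast initialization.** Plain least squares of the basis against the
  undeformed projected template (geometry at identity). The
  cubic-polynomial cross-modality initializer used in earlier rigid-motion
  pipelines is out of scope here; on the phantom the plain fit initializes
  reliably because geometry is near identity at the coarse level.
* **Line searches.** Backtracking with per-field adaptive steps; the
  path-energy change along a direction is expanded as an exact quadratic so
  trial steps only re-evaluate the matching term.
* **Label mapping.** Nearest-neighbor throughout; at an exact midpoint the
  lower-index lattice site wins (the deterministic `floor`-based tie).

## The phantom: what it emulates, what it does not

`phantom_config()` defines the synthetic study conditions: a 96x96x48
template at 0.125 mm with four regions (an ellipsoidal tissue matrix, a
C-shaped band, a compact core, and a dorsal cap), 8 sections cut 0.75 mm
apart, a hidden smooth 3D deformation (max 0.25 mm = 2 voxels, 2.5 mm
kernel), per-section rigid motions (up to 5 degrees and 0.25 mm) and small
2D diffeomorphisms (0.08 mm), a three-channel monotone nonlinear contrast
map with **region-specific texture carriers**, optional tear discs stamped
at a bright artifact value, background replacement, and additive Gaussian
noise. Two regions (the matrix and the cap) are deliberately nearly
iso-intense: their template intensities differ by 0.03 while their texture
carrier frequencies differ by a factor 2, so mean intensity cannot separate
them but the scattering channel can — the phenomenon that motivates
cross-modality matching through textures rather than averaged signal.
Tangles are an inhomogeneous per-region Poisson process (default
intensities 5/10/25/15 per mm^2, in the range of advanced-stage tangle
densities); probability maps are clipped Gaussian bumps plus clamped noise.

What passing the phantom does **not** show: real stain variability and
lighting fields, true tear/fold topology changes (tears here replace
intensity but do not displace tissue), out-of-plane section flex (sections
are planar), block-face seams, or a trained per-pixel tangle classifier
(probability maps are synthetic stand-ins). Results on real specimens
depend on all of these.

Problem sizes used throughout the tests were chosen for a laptop-scale run:
the default phantom registration (two levels, 15 outer iterations) takes on
the order of 10 minutes on one CPU; the spectral checks on a 2562-vertex
sphere take under two minutes.

## Particle measures and surfaces

Each section pixel becomes a particle with weight equal to its sampled
tissue area (pixel area on tissue, 0 elsewhere — the micron-scale analogue
of the 4 um^2 fine-scale weight) and a 2L-dimensional feature: tangle
counts per region, then area fractions per region. Transport under an
estimated map moves the points, multiplies weights by the **in-plane**
Jacobian determinant (sections carry area, not volume), and carries
features unchanged — so total counts are conserved exactly. Resampling onto
a grid or mesh distributes each source particle's mass over targets with a
source-normalized kernel (nearest-neighbor or Gaussian, default bandwidth
0.125 mm), which conserves total weight and weighted counts to round-off;
feature mixtures are reduced to their mass-weighted first moments. Two
printed conventions meet here: the density formulas (`nft_density()`)
divide raw collected counts by sampled area and are exact for scale-0 and
transported measures, while resampled measures carry *mean* features, for
which densities should be derived from the conserved totals
(weight x feature). The kernel normalization direction is fixed as
source-normalized (each particle gives away all its mass); the transposed
reading of the printed normalization is not mass-conserving and is not
used.

Subregion boundary surfaces are extracted by marching tetrahedra on a
lightly smoothed region indicator and decimated (vertex clustering plus
shortest-edge collapses) until the minimum triangle edge reaches 6 voxels
(0.75 mm at 0.125 mm) — a substitute construction for restricted Delaunay
triangulation with the same edge-length contract. The Laplace–Beltrami
basis uses the cotangent Laplacian with lumped barycentric vertex areas as
the mass; eigenfunctions are orthonormal under the area-weighted vertex
inner product, with the constant eigenfunction at eigenvalue 0. Smoothing
attenuates coefficients by the Tikhonov factor $1/(1+k\lambda_i)$; the
spatially varying printed variant $1/(1-k\lambda_i w(y))$ is available as
`form = "printed"` for comparison, but its sign is ambiguous under the
$\lambda\ge 0$ convention and it can be singular, so it is not the default.
The default smoothing constant puts the half-attenuation wavelength at
about 2 mm; the basis size defaults to `min(200, vertices - 1)`.

## A worked sketch

```{r, eval = FALSE}
cfg <- phantom_config(seed = 1)
tm  <- make_template(cfg)
sim <- simulate_sections(tm, cfg)

res <- register_stack(tm$volume, sim$stack,
                      registration_config(outer_iters = 12, levels = 2,
                                          w_v = 30, w_u = 3000,
                                          kernel_width_v = 2.5))
ev  <- evaluate_registration(res, sim$truth, tm$labels)
ev$landmark_rms_mm; ev$dice; ev$hausdorff95_mm

tangles <- simulate_tangles(sim$truth$labels2d, cfg$tangle_intensity,
                            seed = 2)
mu0 <- particles_from_slice(sim$truth$labels2d[[4]]$data[, , 1] > 0,
                            tangles[[4]], sim$truth$labels2d[[4]], 4)
sl  <- res$slices[[4]]
mu3 <- transport(mu0, list(rigid_inverse(sl$rigid), invert_map(sl$map2),
                           z_embed(sl$z), invert_map(res$map3)))

mesh  <- mesh_from_labels(tm$labels, 2)
proj  <- project_to_surface(mu3, mesh)
basis <- lb_basis(mesh, min(200, nrow(mesh$vertices) - 1))
dens  <- surface_density(smooth_on_surface(proj$g_tau, basis, 1),
                         smooth_on_surface(proj$g_a, basis, 1))
```

## Known limitations

* The 2D-to-3D problem is ill-posed in the through-plane direction between
  sections; the kernel prior interpolates there, and through-plane accuracy
  is correspondingly the weakest part of landmark recovery.
* Tears are modeled photometrically (a mixture class), not topologically;
  a physically torn section violates the diffeomorphism assumption.
* The scattering front end assumes the section fully covers its lattice;
  heavy background regions dilute the pooled PCA unless tissue masks are
  supplied to `build_basis()`.
* Rigid motions are estimated per section with a local Gauss–Newton; a
  section whose true rotation is far outside the phantom's range (about
  5 degrees) may need an initialization aid.
* Dense eigendecomposition limits Laplace–Beltrami bases to meshes of a
  few thousand vertices; decimate first for larger surfaces.
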