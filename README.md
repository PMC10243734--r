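# projlddmm

Registration of sparse, independently distorted 2D section images onto a
dense 3D volume — projective diffeomorphic mapping — with the machinery
needed to carry quantitative pathology along: cross-modality contrast
prediction through wavelet scattering features, Gaussian-mixture weighting
of tears and background, varifold transport of particle measures,
multiscale kernel resampling, and Laplace–Beltrami smoothing of densities
on subregion boundary surfaces.

The intended user is someone reconstructing histology (or other sectioned /
optically sectioned data) in the coordinates of a 3D reference volume such
as a postmortem MRI: aligning stained sections to the volume, scoring the
alignment against manual 2D labels, and mapping per-section detections
(e.g., neurofibrillary tangles) into 3D as densities per mm².

## The model

The anatomy is a deformation `I = I_temp ∘ φ₁⁻¹` of a template under a
diffeomorphism generated by a flow `φ̇_t = v_t(φ_t)` with kernel-norm
penalty `∫‖v_t‖²_V dt`. Sections are projections `P_n I` (planar Dirac
sampling at `z_n`, or a normalized Gaussian along z), each further moved by
its own in-plane rigid motion and 2D diffeomorphism `φ_n` with penalty
`∫‖u_{n,t}‖²_U dt`. Each observed section `J_n` is expanded by a Morlet
scattering transform into 48 feature images (3 channels × 16 paths at the
default `J = 2, L = 3`, order 2), reduced by pooled PCA to a shared
6-dimensional predictive basis plus a constant; per-section coefficients
`α_n` map the basis to template intensity, `J^α_n = α_nᵀ ψ_n`. A
three-class conditionally Gaussian mixture (means `J^α_n`, `μ_A`, `μ_B` for
tissue / artifact / background) supplies per-pixel posterior weights
`π_{n,k}` that gate the matching cost

```
min over v, {u_n}, {A_n}, {α_n}:
  w_v ∫‖v_t‖²_V dt + Σ_n w_u ∫‖u_{n,t}‖²_U dt
  + Σ_{n,k} (1 / 2σ_k²) Σ_y π_{n,k}(y) | μ_k(y) − φ_n·P_n I(y) |²
```

optimized by a generalized-EM alternation (contrast least squares → E/M
steps → line-searched geometry) whose free-energy trace is non-increasing.
Detected pathology is represented as weighted particles
`Σ_i w_i δ_{y_i} ⊗ δ_{f_i}` (weights = sampled tissue area, features =
per-region counts and area fractions); maps act by the varifold action
(positions move, weights scale by the in-plane Jacobian, features ride),
and nearest-vertex projection plus Laplace–Beltrami Tikhonov smoothing
`⟨g,β_i⟩_V /(1+kλ_i)` turns counts and areas into smooth surface density
maps.

## Worked example

Everything is testable without downloads through the built-in phantom: a
four-region template at 0.125 mm, 8 sections 0.75 mm apart, a hidden smooth
3D deformation (up to 2 voxels), per-section rigid (≤5°) and diffeomorphic
distortions, a nonlinear 3-channel contrast map in which two regions are
separable only by texture, and optional tears.

```r
library(projlddmm)
cfg <- phantom_config(seed = 1)
tm  <- make_template(cfg)
sim <- simulate_sections(tm, cfg)
res <- register_stack(tm$volume, sim$stack,
                      registration_config(outer_iters = 12, levels = 2,
                                          w_v = 30, w_u = 3000,
                                          kernel_width_v = 2.5))
ev  <- evaluate_registration(res, sim$truth, tm$labels)
round(ev$landmark_rms_mm, 4)
#> [1] 0.1223
round(ev$dice, 3)
#> [1] 0.965 0.953 0.949 0.907
round(ev$hausdorff95_mm, 3)
#> [1] 0.177 0.125 0.177 0.177
```

The landmark error is the RMS distance between the true and estimated
template-space positions of section tissue points — here 0.122 mm, just
under one voxel, down from 0.60 mm before registration (the 3D kernel width
is set to the phantom's deformation correlation scale, and the penalty
weights size the kernel-norm terms against the matching term; the
`registration_config()` defaults are more generic). Dice and
95th-percentile Hausdorff compare template labels mapped through the
estimated transforms with the ground-truth section labels: all four regions
overlap at ≥ 0.90 with boundary disagreement at or near one in-plane pixel
(0.125–0.177 mm). The run takes about ten minutes on one CPU.

A command-line front end wraps the same functions:

```sh
exec/projlddmm phantom  --config cfg.yaml --seed 1 --out-dir phantom/
exec/projlddmm register --config reg.yaml --out-dir result/
exec/projlddmm evaluate --config eval.yaml --out-dir result/
```

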