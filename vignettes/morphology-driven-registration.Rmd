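---
title: "Morphology-driven registration of serial-section EM stacks"
author: "morphoreg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphology-driven registration of serial-section EM stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphoreg)
```

## The problem

Serial-section electron microscopy cuts tissue into 30–100 nm slices that
are imaged independently and must be registered back into a volume. The
difficulty is intrinsic: consecutive images show *different* cross-sections
of the same 3-D structures, so naive feature matching chases anatomical
change rather than imaging deformation, and sequential pairwise alignment
accumulates that error along the stack. `morphoreg` addresses both problems:
it selects image regions whose shape makes their correspondences
trustworthy, and it adjusts all correspondences of the whole stack in one
constrained optimization.

## The spherical deformation model

A local neuronal structure (a bouton, a tube segment) is modeled as a
random star-shaped surface about an interior origin,

$$r(\theta,\varphi) \;=\; 1+\sum_{n= 2}^{n_{\max}}\sum_{m=-n}^{n}
  a_{nm}\,\varphi_{nm}(\theta,\varphi),
\qquad a_{nm}\sim N(0,\lambda_n),$$

with real orthonormal spherical harmonics $\varphi_{nm}$ (cosine branch for
$m<0$, sine for $m>0$; normalizers satisfy the addition theorem
$\sum_m \varphi_{nm}^2=(2n+1)/4\pi$) and the isotropic variance law

$$1/\lambda_n = \alpha+\beta\,(n^p-2^p),\qquad p>2 .$$

Parameters and units:

* `p` (dimensionless, default 4): smoothness; fits of this model to real
  neurons report values near 4, and `p = 4` makes $\lambda_n\sim n^{-4}$.
* `alpha` (> 0): precision of the low-degree, global shape. $1/\alpha$ is
  exactly $\lambda_2$.
* `beta` (> 0): precision of the high-degree, local detail.
* `nMax` (default 40): series truncation. At `p = 4` the tail beyond 40
  contributes under $10^{-5}$ of the total radial variance.
* `meanRadius` (pixels, default 150): scales the normalized radius; with
  the package's synthetic-data convention of 1 px ≈ 1 nm this is a typical
  neurite calibre, and the default section thickness 40 px matches common
  ultramicrotome settings.

Cutting the surface with two parallel planes at distance $d$ produces an
adjacent-section contour pair. The paper-level analysis requires the two
cuts to subtend equal sine-latitudes; the model never says *where* the
planes sit, so the package places them symmetrically about the equator,
$\cos\varphi_{S,T} = \pm d/2\bar r$, which satisfies that assumption
exactly rather than approximately. Contour radii are
$\rho_i = \bar r \sin\varphi\; r(\theta_i,\varphi)$ at equally spaced
longitudes, and landmarks pair by longitude index — never by proximity.

Note one regime caveat: the Gaussian series admits negative radius
excursions when the variances are large (e.g. $\alpha\le 1$). The
translation estimator and all second-moment theory are linear and remain
exact there, but rendered images and roundness scores are only meaningful
in the small-fluctuation regime; `Contour` validity therefore does not
enforce positivity.

## Registration accuracy and the roundness index

The translation estimator is the closed-form minimizer of the summed
squared landmark differences, $\hat{\Delta t}=\mathrm{mean}(x_{iT}-x_{iS})$.
Its error second moment has the closed form implemented in
`theoreticalTranslationVariance()`: a double sum over landmark pairs of
same-section minus cross-section radial covariances, where
$\mathrm{Cov}(r_1,r_2)=\sum_n \lambda_n \frac{2n+1}{4\pi}P_n(\cos\psi)$
depends only on the spatial angle $\psi$. Everything scales with
$\lambda_n$: rounder structures register better. The package verifies the
closed form against Monte-Carlo simulation (the tests use 1000–2000
replicate pairs at several $(\alpha,\beta)$ settings and require agreement
within three standard errors).

For measured contours the same information is read off the Fourier power of
the normalized radius profile: $b_n = (b_n^c)^2+(b_n^s)^2 \sim
\kappa_n\chi^2(2)$ with $\kappa_n=\sin^2\varphi_0\sum_{l\ge n}
(k_l^n P_l^n(\cos\varphi_0))^2\lambda_l$. Two implementation decisions:

* The $\kappa_n$ constant is used *without* an extra factor of $\pi$: with
  the orthonormal-harmonic convention fixed by the covariance formula
  above, Monte Carlo confirms $\mathrm{Var}(b^s_n)$ equals the series as
  written here (a factor-$\pi$ variant overshoots threefold).
* `kappaApprox()` defaults to the leading $l=n$ term. The $l=n+1$ term
  vanishes at the equator by parity, but the $l=n+2$ correction carries
  weight $\approx (n/(n+2))^p$, so the leading term is excellent at
  $n=2$ and progressively underestimates at higher degrees;
  `exact = TRUE` sums the truncated series and is what the statistical
  tests compare against.

The roundness index is $R=-\log\sum_{n\ge 1}b_n$ (natural log; the $n=1$
term is included as it captures origin offset and is negligible for
centroid origins). $R$ is scale-invariant because the radius profile is
normalized by its mean — without that, large regions would systematically
look less round. A numerically perfect circle is capped at
$R=-\log 10^{-12}\approx 27.6$ to stay finite and orderable. The default
selection threshold is $R_{\mathrm{thres}}=6$ on this natural-log scale;
on clean test shapes a disc scores ≈ 9 and a 6-armed star ≈ 2.4.

## Region selection

`selectRegions()` implements the selection loop: membrane probability map →
watershed (after suppressing basins shallower than `h = 0.1` on the [0,1]
scale, 4-connectivity, watershed lines labeled 0) → per-region radial
profile → Fourier spectrum → threshold on $R$. Deep membrane segmentation
is deliberately an *interface*: networks are trained and run outside R, and
their probability maps enter through `segmentMembranes(method =
"external")`; the built-in `"classical"` method is a difference-of-Gaussians
dark-ridge detector adequate for phantoms and quick looks, not a substitute
for a trained network on real tissue.

Region profiling uses the centroid as origin and the *maximum* boundary
distance per angular bin: for non-star-convex regions this inflates
high-order Fourier content, which is exactly the penalty the index is meant
to apply. Defaults recorded in the configuration rather than inferred from
anywhere: minimum area 64 px² (the quadrature needs boundary samples;
smaller regions are segmentation noise), border-touching regions excluded
(their contour is a field-of-view artifact), 64 angular bins, 20 Fourier
degrees (higher degrees are numerically negligible at `p = 4`), at most 25%
interpolated (empty) bins.

## Dense correspondence and whole-stack adjustment

Adjacent sections are matched by dense per-pixel descriptors (4×4 spatial
cells × 8 orientation bins over a 16×16 support, L2-normalized, clipped at
0.2, renormalized) under a discrete energy with a truncated-L1 data term,
an L1 displacement-magnitude term ($\eta$), and a truncated-L1
4-neighborhood smoothness term. The energy weights are not prescribed by
any reference: defaults ($t=20.48$, $\eta=0.01$, smoothness weight 2
truncated at 40, search radius 16 px, 3 pyramid levels) were fixed once on
phantom stacks and live in `flowParams()`.

The optimizer is deliberately simple and auditable: per level, iterated
conditional improvement sweeps in a fixed raster order, each accepted move
strictly lowering the energy, initialized from both the upsampled coarser
flow and the best constant displacement (the latter evaluated on a
subsampled grid). On small instances it additionally applies joint
two-pixel and 2×2-block moves, which remove the pairwise-coupled local
minima single-site sweeps cannot escape. The package also ships an *exact*
reference solver, `flowGlobalEnergy()`: a frontier dynamic program over
scanline label states, made tractable by provably-safe label pruning (any
label whose unary excess exceeds the gap between a feasible labeling's
energy and the sum of per-pixel unary minima cannot be optimal). It
certifies optimality on tiny instances (8×8, search radius 1) and is the
oracle the test suite compares against; it is never used inside
`matchFlow()` itself.

Correspondences are sampled at grid vertices (default stride 16 px,
vertices at 0-based multiples of the stride) that fall inside the selected
regions; the flow itself is computed on full frames so the data term keeps
its context, and the mask gates only which correspondences are *emitted*.

All correspondences of all sections are then adjusted simultaneously:
minimize $\sum_i\sum_p (u^2+v^2) + \sum \frac{\lambda}{\mathrm{dist}(p,q)}
((u_p-u_q)^2+(v_p-v_q)^2)$ subject to matched points coinciding. The
neighborhood is mutual 4-nearest-neighbors within 3× the grid spacing
(the reference formulation leaves it unspecified), and the weight is
$\lambda/\mathrm{dist}$ — closer points are coupled more strongly, the
standard smoothness behavior; a `invDist = FALSE` switch flips to
$\lambda\cdot\mathrm{dist}$ for comparison. Equality constraints compose
transitively, so each matched chain is eliminated into a single shared
target position; chains that end up holding two points of one section are
contradictions, merged toward the chain mean and counted in the solution
object. The reduced system is sparse, symmetric positive definite, and
separable in x and y; it is solved exactly by a sparse Cholesky
factorization, and the tests require parity with a dense KKT oracle to
$10^{-6}$ relative and constraint residuals below $10^{-8}$. No reference
section exists: the magnitude term itself fixes the global gauge, which is
what prevents error accumulation along the stack (reversing the section
order provably negates every displacement).

Sections are finally warped by rigid moving least squares (weights
$1/|p-v|^{2}$, i.e. falloff exponent 1; deformation evaluated on an 8-px
grid and bilinearly interpolated — exact for rigid motions since they are
affine; backward mapping with bilinear resampling everywhere, no forward
splatting). Rigid MLS reproduces any global rigid motion of its control
points exactly, which the acceptance test quantifies at < 0.05 px on a
dense grid for a 17° rotation plus translation.

## The phantom generator

`generatePhantomStack()` emulates the geometry the method is designed for:
tubular structures rendered as sequences of sphere-like cross-sections
(one harmonic surface per tube, latitude wobbling slowly along the stack),
dark 2-px membranes, textured interiors whose texture rides along with the
tube (so descriptors have matchable content), a lightly textured noisy
background, and full ground truth (labels, membranes, per-pair dense flow,
per-section transforms, tube center tracks). By construction the round
tubes (large α, small drift) are straighter than the irregular ones
(small α, large drift) — the synthetic analogue of round structures being
the stable ones in tissue, and the basis of the mask-stability test.

`applySerialDeformation()` implements two protocols: per-section random
rotation (uniform ±90°) and shift (uniform ±100 px) with an additional
four-control-point rigid-MLS distortion on every fifth section (0-based
indices ≡ 0 mod 5; control points ≥ 50 px inside their quadrant,
displacements uniform in ±20 px — a bound the protocol leaves open and the
configuration exposes), and a thin-plate-spline protocol with Gaussian
random vectors (σ = 10 px by default, likewise a configuration choice) at
uniform positions. Ground-truth flow is composed analytically from the
per-section backward maps, inverting them by a vectorized Newton iteration
(finite-difference Jacobians, tolerance $10^{-8}$), never by re-estimating
from images.

What the phantom does *not* emulate: charging and knife artifacts, staining
variation, section folds, anisotropic point-spread, and genuinely novel
anatomy appearing between sections. Passing end-to-end tests on phantoms
therefore demonstrates the pipeline's internal consistency and its recovery
of known geometric deformation — not segmentation robustness on real EM
contrast, for which an externally trained membrane network is expected.

## Study sizes and numerical choices

The simulation design enumerates 121 parameter subsets — an 11×11
logarithmic grid, α from $10^1$ to $10^5$ and β from $10^{-4}$ to $10^0$ at
`p = 4` — spanning visibly irregular through near-circular structures; the
exact axis values are a package choice recorded in
`sphericalDatasetGrid()`. Monte-Carlo checks in the tests use 500–5000
replicates depending on the statistic, always compared at three standard
errors; the end-to-end check registers a 6-section 220² phantom with shifts
up to 8 px (inside the default 16-px search radius) and requires the mean
ground-truth correspondence residual to drop below 25% of its
pre-registration value with SSIM against the undeformed stack strictly
increasing. SSIM uses the standard 11×11 Gaussian window (σ 1.5,
$K_1=0.01$, $K_2=0.03$). Ties in the discrete optimizer are broken toward
the first candidate in a fixed enumeration order; all stochastic components
are pure functions of their seed, and the pipeline itself is deterministic
for a fixed configuration.

Two honest caveats worth restating: SSIM between doubly-resampled images is
bounded away from 1 by the interpolation low-pass alone, so warp-recovery
checks smooth the pixel noise before comparing; and gross rotations (±90°)
exceed what a 16-px descriptor flow can recover — the optional
phase-correlation pre-alignment is plumbing for the translation component
only and is off by default.

## Limitations

* Translation-only accuracy theory: rotation and scale errors are outside
  the closed form.
* The classical membrane detector is a fallback; the intended production
  path is an external probability map.
* The exact flow solver is certified only on tiny instances; on full
  frames the optimizer guarantees monotone descent, not global optimality.
* Roundness scoring assumes the equatorial convention
  $\sin\varphi_0 = 1$ for real regions, where the true cutting latitude is
  unobservable; this is recorded in every report.
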