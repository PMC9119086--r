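# morphoreg

Registration of serial-section electron microscopy (ssEM) stacks, driven by
a stochastic model of local neuronal morphology.

Reconstructing neural tissue in 3-D from serial ultra-thin sections requires
registering consecutive 2-D EM images whose content is similar but never
identical: neuronal structures change shape from section to section, and the
slicing/imaging process adds rotations, shifts, and nonlinear distortion.
`morphoreg` is built around one observation: **round ("sphere-like")
structures change least between sections and make the most reliable
landmarks**. The package provides both the theory that makes that statement
quantitative and a full registration pipeline that exploits it. It is aimed
at connectomics labs aligning ssTEM / FIB-SEM section series and at anyone
studying how structure shape limits registration accuracy.

## The model and the method

**Spherical deformation model.** A local structure is a random star-shaped
surface with normalized radius

    r(theta, phi) = 1 + sum_{n>=2} sum_{m=-n..n} a_nm phi_nm(theta, phi),

where `phi_nm` are real orthonormal spherical harmonics and
`a_nm ~ N(0, lambda_n)` with the variance law

    1 / lambda_n = alpha + beta (n^p - 2^p),    p > 2.

`alpha` controls global and `beta` local shape precision; `p` (default 4)
sets smoothness. Cutting the surface with two parallel planes at distance
`d` yields an adjacent-section contour pair.

**Accuracy theory.** For contours registered by the closed-form
translation estimator (the minimizer of the summed squared landmark
differences), the x-axis error has second moment

    E[(dt_hat - dt)^2] = rbar^2 sin^2(phi) / N^2 *
        sum_ij 2 cos(theta_i) cos(theta_j) (Cov_iTjT - Cov_iSjT),

an explicit function of the `lambda_n` — so rounder structures (smaller
`lambda_n`) register more accurately. On real images `lambda_n` is not
observable, but the Fourier power `b_n` of a region's normalized radius
profile is `kappa_n * chi-squared(2)` with `kappa_n ∝ lambda_n`, giving the
**roundness index** `R = -log(sum_n b_n)`; regions with `R >= 6` are kept
as stable landmarks.

**Pipeline.** Per section: membrane probability map (external network
output, or a classical ridge detector) → watershed → roundness-based region
selection. Per adjacent pair: dense gradient-descriptor flow (truncated-L1
discrete energy, coarse-to-fine improvement sweeps) → grid-vertex
correspondences inside the selected regions. Whole stack: all
correspondence positions adjusted **simultaneously** under equality
constraints (matched points must coincide), avoiding sequential error
accumulation. Each section is finally warped by rigid moving least squares.
A synthetic EM-like phantom generator with full ground truth supports
end-to-end validation.

## Worked example

```r
library(morphoreg)

params <- shapeParams(p = 4, alpha = 1000, beta = 0.01, meanRadius = 150)
spec   <- sectionPairSpec(thickness = 40, translation = c(4.5, 4.5))

pair <- makeSectionPair(params, spec, seed = 3)
estimateTranslation(pair$S, pair$T)
#> TranslationEstimate: (5.2047, -0.9672) px from 64 landmarks, cost 111675.5

theoreticalTranslationVariance(params, spec)
#> [1] 23.42312

em <- empiricalErrorMoment(params, spec, reps = 500, seed = 2)
c(mean = em$meanDt, secondMoment = em$secondMoment, se = em$seMoment)
#>         mean secondMoment           se
#>     4.683095    21.435390     1.357861
```

A single simulated pair is noisy (here the estimate is 5.20 px against a
true shift of 4.5 px), but the estimator is unbiased — the Monte-Carlo mean
is 4.68 ± 0.21 — and its measured second moment (21.4 ± 1.4) agrees with
the closed form (23.4). Making the structure rounder (larger `alpha`)
shrinks both.

Region selection on a rasterized disc and 6-armed star:

```r
sel <- selectRegions(labelMap)           # watershedRegions() output
sel@report
#>   label area       cx cy        R capped border  kept
#> 1     1 1793  48.0000 64 8.956133  FALSE  FALSE  TRUE
#> 2     2 1893 140.0127 64 2.370157  FALSE  FALSE FALSE
```

The disc scores `R = 8.96` (kept at the default threshold 6), the star
`R = 2.37` (rejected).

End-to-end on a phantom (6 sections, random shifts up to 8 px):
`registerStack()` reduces the mean ground-truth correspondence residual
from 8.1 px to 1.2 px and raises mean SSIM against the undeformed stack
from 0.43 to 0.48.

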