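---
title: "Variational registration of longitudinal brain MRI with ngfreg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variational registration of longitudinal brain MRI with ngfreg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

After neurosurgical tumor resection, follow-up MRI must be compared with
the pre-operative scan to judge resection completeness and detect
recurrence. Rigid alignment is not enough: resection, mass effect and
tissue relaxation deform the brain by several millimetres, concentrated
near the pathology. Two further properties make this registration problem
unusual:

* **Intensities are not comparable.** Longitudinal acquisitions differ in
  scanner, sequence tuning and contrast uptake, so distances built on raw
  intensities (SSD, plain correlation) are unreliable across time points.
* **Correspondence is incomplete.** The resection cavity exists only in
  the post-operative image; tissue that was removed has no counterpart.
  A distance that tries to explain the cavity drags surrounding healthy
  tissue into physically meaningless deformations.

`ngfreg` implements a deformable registration pipeline built around these
two constraints, together with the landmark-based evaluation protocol used
to measure registration quality, and a synthetic phantom generator so the
whole pipeline can be exercised and validated without any clinical data.

## The model

The fixed (post-operative) image $R$ and moving (pre-operative) image $T$
are functions $\mathbb{R}^3 \to \mathbb{R}$. We estimate a deformation
$y(x) = x + u(x)$ minimizing

$$J(u) \;=\; D\!\left(R,\, T(y)\right) \;+\; \alpha\, S(u)
\;\;[\;+\; \gamma\, V(u)\;],$$

with three ingredients:

**Masked normalized-gradient-fields (NGF) distance.** Two images are
considered aligned where intensity *changes* occur at the same locations
with parallel orientation, regardless of the intensity values themselves.
Per voxel,

$$\rho(x) = \frac{\langle \nabla R(x), \nabla T(y(x))\rangle
  + \varepsilon_R\,\varepsilon_T}
  {\|\nabla T(y(x))\|_{\varepsilon_T}\; \|\nabla R(x)\|_{\varepsilon_R}},
  \qquad \|g\|_\varepsilon = \sqrt{\|g\|^2 + \varepsilon^2},$$

and the distance integrates $\tfrac12\,(1 - \rho^2) \in [0, \tfrac12]$
over the field of view **excluding the pathology mask** $\Sigma$: masked
voxels contribute exactly zero to the value and the gradient, so the
cavity cannot attract the deformation. The edge parameters
$\varepsilon_R, \varepsilon_T$ decide which gradient magnitudes count as
edges and which as noise.

**Curvature regularization.** $S(u)$ integrates
$\sum_k \|\Delta u_k\|^2$, penalizing bending rather than stretching; any
affine deformation has zero energy, so the regularizer does not resist
the residual rigid/affine mismatch left by pre-registration.

**Volume-change control (optional).** $V(u)$ integrates
$\psi(\det \nabla y)$ with $\psi(t) = (t-1)^2/t$ for $t > 0$ and
$\psi = \infty$ for $t \le 0$ — a convex barrier that is zero at volume
preservation and infinite at folding. It is disabled by default for the
iterative solve (the solve is well-behaved without it on our phantoms)
and can be enabled with `volumeControl = TRUE`, weight `gamma` (default
0.01); the optimizer's line search treats the $\infty$ sentinel as "step
rejected", so iterates never fold when the term is active.

## Discretization and optimization

The package follows discretize-then-optimize: all integrals become
midpoint-rule sums on the voxel grid (cell-centered, world coordinates in
mm at voxel centers), image gradients are spacing-aware central
differences (one-sided at boundary faces), the warp is trilinear with
clamp-to-edge extension, and the Laplacian is the 7-point stencil with a
natural boundary (second differences formed only at interior points, so
affine fields are exactly harmonic). The objective gradient with respect
to every displacement component is computed **analytically** by chaining
the NGF integrand, the gradient-stencil adjoints and the derivative of
the trilinear interpolant; the test suite verifies it against central
finite differences to a relative error below $10^{-3}$ (in practice
around $10^{-7}$).

Minimization uses limited-memory BFGS (memory 5) with Armijo backtracking
(halving, slope $10^{-4}$). Iteration stops at the first satisfied
criterion: absolute objective decrease below `minProgress`, gradient norm
below `minGradient` (absolute) or below `minRelativeGradient` times the
level's initial gradient norm, largest displacement update below
`minStepLength` (mm), or `maxIterations`. All thresholds default to
0.001 and the iteration cap to 100; "progress" is interpreted as absolute
objective decrease per accepted iteration and "relative gradient" as the
ratio to the starting gradient norm of the level, stated here because the
names alone do not pin the definitions down.

The solve runs coarse-to-fine on $L = 3$ levels: inputs are first brought
onto a cubic working grid (default $160^3$, configurable down to desk
scale), then restricted $L-1$ times by 2×2×2 average pooling, so the
coarsest level is downsampled by $2^{L-1}$. The coarsest solve starts
from the zero field (inputs are assumed rigidly pre-aligned); each finer
level starts from the trilinearly prolonged field of the previous level.
Because displacements are stored in world millimetres at every level,
prolongation transfers them without magnitude rescaling. We deliberately
optimize the *total* displacement at each level, initialized with the
prolonged coarse field, rather than warping the moving image once and
estimating an additive correction on the warped image: the two schemes
estimate the same correction, but the total-field form avoids an extra
interpolation approximation and keeps every level minimizing the same
well-defined objective. The pathology mask moves across levels by average
pooling followed by re-binarization at 0.5, approximately preserving the
pathology volume. The final field is prolonged back to the input volumes'
original grid.

The whole solve is deterministic — there is no randomness anywhere in
the pipeline — so identical inputs and configuration reproduce results
bit for bit.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.1 | curvature weight (dimensionless), balances edge alignment against bending |
| `gamma` | 0.01 | volume-control weight, only with `volumeControl = TRUE` |
| `levels` | 3 | resolution levels; working edge must divide by $2^{L-1}$ |
| `workingSize` | 160 | cubic working grid edge (voxels); `NA` keeps the input grid |
| `epsEta` | 0.8 | edge parameters as a fraction of the mean gradient magnitude, re-estimated per level and per channel |
| stopping thresholds | 0.001 / 100 | see above |

**On the edge parameters.** $\varepsilon$ is the one tunable the distance
is genuinely sensitive to. The automatic estimate is
$\varepsilon = \eta \cdot \mathrm{mean}\,\|\nabla v\|$ per image. The
estimate must land **at or above the noise-gradient magnitude**: if
$\varepsilon$ sits well below it, the normalized gradients of pure-noise
voxels look like legitimate edges, and the optimizer can (and does)
reduce the distance by aligning noise — on synthetic pairs with known
ground truth this manifests as an estimated field essentially
uncorrelated with the true one, while the objective happily decreases.
With 1–3% noise (typical of modern acquisitions after preprocessing)
the mean gradient magnitude is itself dominated by the noise floor, so a
small $\eta$ underestimates the threshold severely; $\eta = 0.8$ places
$\varepsilon$ just under the mean and comfortably above the noise level,
and recovered ground-truth deformations confirm the calibration (see the
acceptance suite). Explicit `eps` values override the estimate entirely
and are the right choice when the noise level is known.

Multi-sequence input uses an equal-weight sum of per-channel NGF terms,
each with channel-specific $\varepsilon$; a single estimated field then
warps every acquisition of the time point.

## Evaluation protocol

Registration quality is measured on paired anatomical landmarks
annotated in both time points: each fixed-space landmark is mapped
through the estimated field (trilinear interpolation of $u$ at the
point), the Euclidean distance to its moving-space counterpart is the
TRE, the per-case mean and the cohort mean of case means (mTRE) summarize
a dataset, and conditions are compared with a two-sided Wilcoxon
signed-rank test on the paired per-case means (exact over all $2^n$ sign
assignments up to $n = 25$, with midrank ties; normal approximation with
tie-corrected variance and continuity correction beyond). Zero
differences are discarded, following the test's classical form. Mapping
fixed-space landmarks forward through $y$ matches the direction in which
the field warps the moving image onto the fixed grid.

## The synthetic phantom

The generator produces everything the pipeline consumes, deterministically
per seed: a brain-like anatomy (smooth ellipsoidal head, brighter
cortical shell, ventricle-like interior structures, band-passed noise
texture standing in for sulci) on an isotropic 1 mm grid; per-sequence
channels as monotone intensity remappings of that shared anatomy with
independent Gaussian noise (2% of the intensity range by default —
emulating contrast differences between T1/T1-CE/T2/FLAIR without any MR
physics); a smooth ground-truth deformation (Gaussian-filtered white
noise, default length-scale 8 voxels, rescaled to a 4 mm maximum and
verified fold-free, with automatic damping if the determinant check
fails); an optional spherical resection cavity written into the fixed
image only (background interior, thin bright rim), with the pathology
mask as the cavity dilated by one voxel; and paired landmarks at
high-gradient healthy-tissue voxels, at least two voxels from the border,
outside the dilated cavity and — when a cavity exists — within a 40 mm
band around it, mirroring near-pathology landmark placement.

The fixed image is constructed *by warping the moving image with the
known field*, so the truth is exact in the direction the solver
estimates and no field inversion error enters the evaluation: moving
landmarks are fixed landmarks mapped through the truth exactly, and the
baseline TRE equals the mean true displacement at the landmarks by
construction.

What the phantom does **not** emulate: bias fields, k-space/undersampling
artifacts, anisotropic slice profiles, real sulcal geometry, tumor
infiltration or mass effect beyond the smooth deformation, and
inter-subject anatomical variability. Passing the synthetic validation
therefore demonstrates the correctness and calibration of the machinery —
not clinical-grade accuracy on real data.

## Problem sizes used in validation

The packaged validation runs at desk scale, chosen as the package's own
test conditions: gradient checks on $12^3$ grids, self-registration at
$48^3$, ground-truth recovery and masking cohorts of 10 seeded pairs at
$64^3$ with 20 landmarks each, and the contrast-to-noise experiment on
two-sequence $48^3$ phantoms with a 4× noise difference between channels.
At these sizes the full multi-level solve takes seconds to a few tens of
seconds per pair on one CPU; the clinical-scale $160^3$ default runs the
identical code path, only larger.

## Numerical choices and edge cases

* Out-of-domain warp samples clamp to the nearest edge value —
  skull-stripped volumes have zero background, and clamping introduces no
  artificial gradients at the border. The derivative of the interpolant
  is zero along axes where the sample point left the domain, consistent
  with the clamped (constant) extension.
* The trilinear interpolant is only piecewise differentiable; at exact
  cell boundaries the implementation uses the right-sided cell, i.e. a
  valid subgradient. Gradient-vs-finite-difference checks are run at
  fractional displacements away from cell boundaries.
* An all-constant channel makes NGF degenerate; the solver rejects a
  constant fixed image, and the $\varepsilon$ estimator falls back to a
  fixed small constant (`1e-3`) on constant input.
* Masks resample with nearest-neighbour interpolation only, and stay
  strictly binary across pyramid levels.
* The $\psi$ barrier returns an `Inf` sentinel (with no gradient) as soon
  as any voxel folds; the line search rejects such steps, so the barrier
  is never differentiated at invalid states.
* The l-BFGS memory is reset whenever the two-loop direction fails to be
  a descent direction (a rare safeguard); curvature pairs are only stored
  when $s^\top y > 10^{-12}$.

## Known limitations

* Only fixed-image masking is implemented; a moving-image mask (e.g. for
  pre-operative tumor bulk) is not supported.
* The transformation model is a dense displacement field without
  diffeomorphic guarantees; without volume control, small folding
  fractions can occur in strongly deformed regions.
* The NGF distance is blind to pure contrast inversions only insofar as
  $\rho^2$ ignores gradient sign; genuinely uncorrelated structure
  (e.g. FLAIR-specific edema boundaries) degrades its guidance, which is
  exactly the sequence-sensitivity effect the evaluation tooling is built
  to measure.
* Orientation handling reorients axes to RAS and then treats the grid as
  axis-aligned; residual oblique rotations in the NIfTI transform are
  discarded.
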