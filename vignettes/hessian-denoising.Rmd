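---
title: "Hessian-regularized split-Bregman denoising of 3D stacks: model, numerics, and the two execution paths"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hessian-regularized split-Bregman denoising of 3D stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hessdenoise)
```

## The model

Superresolution fluorescence stacks — structured-illumination reconstructions
in particular — carry substantial pixel-level noise, while the biological
structures of interest (filaments, membranes, vesicle tracks) are smooth and
continuous in all three dimensions.  Penalizing second-order spatial
derivatives expresses exactly that prior: a penalty on curvature leaves
straight and gently bending bright structures alone while suppressing
voxel-scale fluctuation.  Writing $f$ for the observed stack and $u$ for the
estimate, the package solves

$$
\min_u \; \frac{\mu}{2}\lVert u - f\rVert_2^2
 \;+\; \sum_{d} w_d \lVert D_d u \rVert_1 ,
\qquad d \in \{xx, xy, xz, yy, yz, zz\},
$$

where $D_d$ is the discrete second difference for one of the six independent
components of the 3D Hessian and $w_d \ge 0$ weights it.  The $\ell_1$ norm
keeps genuine edges; the quadratic data term with fidelity weight $\mu > 0$
anchors the estimate to the measurement.

The off-diagonal Hessian entries occur twice in the symmetric Hessian, and
axial ($z$) resolution in fluorescence microscopy differs from lateral
resolution, so the default weight mapping is

$$
w_{xx} = w_{yy} = 1,\quad w_{xy} = 2,\quad
w_{xz} = w_{yz} = 2\sigma,\quad w_{zz} = \sigma^2 ,
$$

one factor of the axial weight $\sigma \ge 0$ per $z$-derivative
(`default_hessian_weights()`).  $\sigma = 0$ degenerates to frame-by-frame 2D
regularization.  All six weights are individually overridable, because the
right axial coupling is sample- and optics-dependent and we did not want the
mapping hard-wired.

## The split-Bregman iteration

The $\ell_1$ terms are decoupled with one auxiliary array $d_d$ and one
Bregman (residual) array $b_d$ per direction, all zero-initialized.  One
iteration performs six *independent* directional tasks

$$
s_d = D_d u + b_d,\qquad
d_d' = \mathrm{shrink}(s_d,\; w_d/\lambda),\qquad
b_d' = s_d - d_d',\qquad
c_d = w_d\, D_d^{\mathsf T}(d_d' - b_d'),
$$

with $\mathrm{shrink}(v, t) = \mathrm{sign}(v)\max(|v| - t, 0)$, followed by
the image update

$$
u' = \mathrm{Re}\,\mathcal{F}^{-1}\!\left[
 \frac{\mathcal{F}\!\left(\mu f + \lambda \sum_d c_d\right)}
      {\mu + \lambda S}
\right],
\qquad
S(k) = \sum_d w_d^2 \prod_{a \in d}\bigl(2 - 2\cos(2\pi k_a/n_a)\bigr) .
$$

$S$ is the Fourier-domain spectrum of the composite operator
(`build_spectrum()`).  Shrinkage is applied per direction (anisotropic),
which is what makes the six tasks independent given $u$; an isotropic
(coupled) shrinkage would serialize them.  Iterations are strictly
sequential — each consumes the previous image — and run for a fixed count
(default 100) with no early stopping; an optional diagnostics mode records
the objective and $\max|\Delta u|$ per iteration for convergence inspection,
but never alters control flow.

Two structural consequences are worth noting because the test suite pins
them.  First, $S(0) = 0$ and every $c_d$ has zero spatial sum (each row of
$D_d$ sums to zero, hence each column of $D_d^{\mathsf T}$ does), so the DC
component of $u$ equals that of $f$ exactly: the stack mean is preserved to
round-off, and a constant stack is a fixed point.  Second, on the reference
path each directional task applies exactly four first-difference operators
(two in $D_d$, two in $D_d^{\mathsf T}$), i.e. 24 difference calls and 6
shrinkage executions per iteration — 2400 and 600 in a default run — which
the call counters reproduce exactly.

## Difference operators and the zero-fill convention

`forward_diff` writes $a_{i+1}-a_i$ into positions $1..n-1$ and zeros the
*last* slice; `back_diff` writes $a_i - a_{i-1}$ into $2..n$ and zeros the
*first*.  Diagonal directions compose backward-after-forward
(`back_diff(forward_diff(a, ax), ax)`, the classical $[1,-2,1]$ interior
stencil); cross directions compose two forward differences, keeping the
operator symmetric in its two axes.  The boundary split between the two
operators is a genuine design choice — the shape-restoring zero-fill could
put zeros on either side — and we fixed it by requiring that the adjoint
pair works out cleanly; the adjoints (`adjoint_second_diff`) implement the
exact matrix transposes under this convention, which the suite verifies by
materializing the operators column-by-column on small grids and comparing
matrices `identical()`-exactly.

The FFT update treats the operator as periodic (circulant) even though the
spatial differences zero-fill rather than wrap.  This is the standard
practice for quadratic solves of this type: the exact zero-fill normal
equations are not diagonalized by the DFT, the circulant surrogate is, and
the discrepancy is confined to the boundary voxels.  We accept a boundary
approximation in exchange for an exact, fast, pointwise solve; the tests
therefore check mean preservation and fixed points (which the surrogate
preserves exactly) rather than asserting an energy-descent property at the
boundary.

The spectrum depends only on (shape, $\sigma$, weights), so it is built once
and persisted under a shape-keyed filename (`"128-256-180.rds"` for a
128×256×180 stack) with a format version, the generating parameters, and the
values; `load_or_build()` returns a cached spectrum bit-identical to a fresh
build, silently rebuilds when the stored $\sigma$/weights disagree with the
request, and rebuilds with a warning when the file is corrupt.

## The two execution paths

`denoise_reference()` is deliberately plain: every difference goes through an
operator function call whose naive implementation materializes shifted
copies slice-by-slice before subtracting, nothing is reused within an
iteration, the six tasks run serially, the spectrum is rebuilt per run, and
arithmetic is binary64.  It exists to be read, to be instrumented (its call
counters are fully populated), and to serve as the equality baseline.

`denoise_optimized()` applies, together, every optimization the package is
organized around:

* **vectorized, preallocated differences** — one slab subtraction into a
  zero-filled output instead of loop-copied temporaries;
* **inlined operator bodies** — the per-direction difference and adjoint
  arithmetic written out in the task body with direct indexing, eliminating
  operator function calls (observable: the difference-call counters of an
  optimized run read 0);
* **de-duplication** — the first forward differences of $u$ along the three
  axes are shared (axis 1 feeds xx, xy, xz; axis 2 feeds yy, yz; axis 3
  feeds zz), 9 first differences per iteration instead of 12 on the forward
  side;
* **persisted spectrum** — `load_or_build()` instead of a per-run build;
* **uniform precision** — binary32 by default (below);
* **six-task backends** — `cpu_serial`, `cpu_parallel` (the six tasks on up
  to six cores via fork), or `device`.

The central contract, enforced by the test suite on random phantoms, is:
at binary64 on a CPU backend the optimized output is **bit-identical** to
the reference output.  Every reordering the optimizations introduce was
chosen to preserve the exact floating-point operation sequence — in
particular the six contributions $c_d$ are summed in the fixed direction
order xx, xy, xz, yy, yz, zz regardless of which parallel task finishes
first.  At binary32 the outputs differ byte-wise but agree to a max relative
error of at most 1e-4 on unit-scale stacks (`max|a-b| / max|b|`; the
denominator avoids dividing by near-zero background voxels).  That bound is
deliberately generous relative to binary32 machine epsilon (≈1.19e-7)
accumulated over 100 iterations; observed discrepancies on the package's own
phantoms sit around 1e-7 (recomputed, not asserted, by
`scripts/acceptance.R`), and the bound is a named constant in the benchmark
harness so it can be tightened.

### Precision policy

R has no native 32-bit float arithmetic, so the binary32 path stores every
array at binary32 (doubles holding exactly binary32-representable values,
enforced by a round trip through a 4-byte buffer) and rounds the result of
every array-valued stage — each difference, shrinkage, Bregman update,
right-hand side, and FFT output — back to binary32.  Elementwise arithmetic
*within* a stage runs at double precision before rounding, so this emulates
a single-precision pipeline with slightly higher internal accuracy (as a
float pipeline with fused or extended-precision intermediates would).  Mixed
declared precision inside a run is not possible by construction: one cast
function is chosen at entry and applied uniformly, which is the policy the
two-path equivalence contract needs.

### Device backend

The `device` backend is a dispatch contract, not a bundled driver: all
arrays are uploaded in one bulk transfer before the loop, the loop runs on
device-held arrays, and results become observable only after a single
gather, which any timing must bracket.  Drivers register through
`register_device_backend()`; requesting the backend with none available
raises a distinct capability error (or falls back to `cpu_serial` with a
warning when `fallback = TRUE`).  `simulated_device_backend()` is an
in-memory synthetic driver — host arrays plus real transfer accounting —
used by the tests to pin the single-upload/single-gather behavior; it makes
no performance claim.

## The phantom generator

`make_phantom()` emulates the relevant features of a SIM-style test stack:
sparse bright curvilinear structure on a dark background.  Filaments are
random 3D polylines with smoothly wandering direction, rasterized and
blurred by a periodic separable Gaussian PSF (`psf_sigma`, voxels), peak
scaled to `filament_intensity` over a constant `background`.  Noise is
additive Gaussian (`gaussian_noise_sd`) and, optionally, Poisson shot noise
at `photon_scale` photons per intensity unit replacing the signal term.
Defaults (shape 128×256×180, unit peak over 0.05 background, PSF σ 1.5
voxels, Gaussian SD 0.1) describe a unit-scale, visibly noisy stack; tests
pass explicit smaller shapes.  Generation is a pure function of the seed:
the global RNG state is saved and restored, and the same spec is
byte-reproducible.

What the phantom does *not* model: patterned-illumination reconstruction
artifacts, an anisotropic or measured OTF, camera offset and fixed-pattern
noise, depth-dependent aberrations.  Passing quality tests on phantoms
therefore demonstrates that the algorithm removes the declared noise from
the declared structure — not that parameter defaults transfer to any given
microscope's data, where μ and σ should be tuned by inspection.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `mu` | 1 | fidelity weight (intensity$^{-2}$ scale); larger trusts the data more |
| `sigma` | 1 | axial weight; scales z-coupled directions as above |
| `lambda` | 1 | Bregman penalty weight; shrinkage threshold is $w_d/\lambda$ |
| `iterations` | 100 | fixed count, no early stopping |
| `precision` | path default | binary64 (reference) / binary32 (optimized) |
| `backend` | `cpu_serial` | task mapping, see above |

Only μ and σ are exposed as the primary scientific knobs; λ exists because
the split-Bregman construction has it, and its default of 1 folds it into
the weights.  The package declares `mu_working_range()` of [0.5, 20] for
unit-scale stacks under Gaussian noise of SD ≈ 0.1: the range was
characterized on 64×64×32 filament phantoms, where every μ in it improves
RMSE against ground truth while exhibiting the expected monotone behavior —
RMSE to the *input* falls as μ grows.  Both properties are recomputed by the
acceptance script and the test suite rather than quoted as fixed numbers.

## Numerical choices and degenerate inputs

* `sign(0) = 0`, so shrinkage maps exact zeros to exact zeros; no tie-break
  is needed.
* A length-1 axis makes every difference along it exactly zero (not an
  error); the 1×1×1 stack is valid and is a fixed point.
* Non-finite values are rejected at stack construction, and a non-finite
  image during iteration raises an error carrying the iteration index
  (diverging parameter combinations fail loudly, not silently).
* Spectrum values are exactly 0 at DC by construction (the cosine factor is
  evaluated at angle 0), not merely small.
* binary32 TIFF payloads round-trip bit-exactly through the package's own
  writer and the independent libtiff reader; binary64 payloads use the
  documented `.rawstack` container because classic TIFF readers do not
  accept 64-bit float samples.

## Problem sizes used in the characterization

The equivalence and counter checks run at full iteration count (100) on
small grids (16×16×8 and 10×9×7 phantoms), where one run takes about a
second; denoising-quality checks use 64×64×32 phantoms at 20 iterations,
where the split-Bregman estimate is already stable on these fields.  These
sizes are the package's own test design: every claim they support is
shape-independent (operator identities, counter arithmetic, bit-equality,
mean preservation), and the one full-size fact — the 127×256×180 shape of
the size-reducing first difference of a 128×256×180 stack — is checked at
full size.

## Known limitations

* The circulant/zero-fill boundary mismatch above: voxels within a couple of
  slices of the stack boundary are regularized slightly differently from the
  interior.
* The binary32 path emulates storage precision, not a bit-exact replay of
  any particular single-precision hardware pipeline; two *different*
  single-precision implementations will generally differ from each other at
  the same order as from the binary64 reference.
* `cpu_parallel` uses fork-based parallelism and degrades gracefully to
  serial execution on platforms without fork; determinism is unaffected.
* No out-of-core support: a stack and its twelve state arrays must fit in
  memory (a 128×256×180 binary64 run holds ~0.7 GB of state).
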