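---
title: "Spatiotemporal atlas construction with stationary velocity fields: models and methods"
author: "svfatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatiotemporal atlas construction with stationary velocity fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A developing brain changes shape and appearance week by week. To describe
"typical" anatomy at, say, 28 gestational weeks, one averages many subjects —
but a voxelwise average of unaligned images is a blur, and an average aligned
to one subject inherits that subject's anatomy. A spatiotemporal atlas solves
both problems at once: it estimates, for every age `t`, a template image
`I(t)` and a set of diffeomorphic mappings taking each subject into the
template's space, constructed so that the template is an unbiased
(deformation-centered) average of the subjects near that age.

`svfatlas` implements this construction, the multi-atlas segmentation that
the templates enable, the evaluation metrics used to judge both, reference
implementations of lightweight 3D segmentation building blocks, and an
age-parameterized phantom generator that stands in for a real fetal cohort
so every part of the pipeline can be exercised and verified on synthetic
data with known ground truth.

# Deformation model

All deformations are parameterized by **stationary velocity fields** (SVFs):
a dense vector field `v` (voxel units) generates the diffeomorphism
`phi = exp(v)` as the unit-time flow of `v`. The zero field is the identity,
the group inverse is `exp(-v)`, and compositions can be approximated in the
Lie algebra by the Baker–Campbell–Hausdorff (BCH) series

    log(exp(v) o exp(w)) = v + w + [v, w]/2 + ...

with the Lie bracket `[v, w] = (Jv) w - (Jw) v` evaluated by central
differences. Working in the algebra has a decisive practical consequence:
every map carries its own logarithm, so inverses (negation) and weighted
Log-Euclidean means (`exp` of the weighted mean of logs) are exact algebraic
operations, never numerical inversions of dense maps. Dense displacement
fields on the image grid are used rather than a spline parameterization, for
transparency; smoothness comes from the registration's regularization and
smoothed updates.

## Numerical choices in the exponential

`exp_svf()` uses scaling and squaring: scale `v` by `1/2^N`, build the small
deformation, and square (self-compose) `N` times. Two details matter at the
tolerances this package tests itself against:

* **Second-order initial step.** Initializing the small deformation as
  `h v` (with `h = 1/2^N`) leaves a truncation error that decays only
  linearly in `h`; measured against an explicit Euler flow integrator on
  32-cubed smooth fields the endpoint error plateaued near 1e-2 voxels.
  Initializing at second order, `h v + (h^2/2)(Jv)v`, brings the median
  endpoint disagreement with a 1000-step Euler oracle below 1e-3 voxels
  already at `max_step = 0.5`; the default policy (`max_step = 0.25`,
  at most 12 squarings) adds margin.
* **Cubic resampling during squaring.** Each squaring resamples the
  displacement field at displaced positions. Catmull-Rom (cubic) sampling
  keeps the per-squaring resampling error far below the linear-interpolation
  error, which otherwise accumulates with the number of squarings.
  Iterative registration uses a documented fast path (linear resampling,
  `max_step = 0.5`, first-order initialization): inside a descent loop the
  exponential is evaluated hundreds of times and its error is dominated by
  the optimization state, not the integrator.

A third detail concerns the test fixtures rather than the operator: a
"smooth random field" on a bounded grid must decay toward the grid faces.
A field that is large at the boundary drives trajectories out of the domain,
where no discretization can represent the flow, and `exp(v) o exp(-v) = Id`
becomes unattainable near the faces regardless of interpolation order.
`random_svf()` therefore applies a smooth squared-sine taper (width a
quarter of the smallest axis by default) — the synthetic analogue of the
fact that anatomical deformations act on anatomy inside the field of view,
not on the air at the image border.

# Kernel regression on age

Subjects contribute to the template at age `t` with normalized Gaussian
weights `g_i(t) = N(t_i; t, sigma_t^2)`, truncated to zero beyond one week
and renormalized on the realized support (truncate first, then normalize,
so weights always sum to one). The bandwidth adapts to the local age
density: `adapt_sigma()` returns the smallest `sigma >= 0.25` weeks whose
effective sample size `(sum g)^2 / sum g^2` inside the window reaches 5,
capped at 1 week. The rule guarantees a minimum effective cohort behind
every template while keeping the kernel as age-specific as the data allow;
the specific constants are package defaults, exposed as arguments.

# Pairwise registration

`register()` estimates the SVF `v` minimizing

    E(v) = Sim(moving o exp(v), fixed) + lambda * ||grad v||^2

with `Sim` either local normalized cross-correlation (LNCC, box radius 2,
the default — robust to residual intensity differences between a subject
and a blurred average template) or plain SSD (appropriate for same-contrast,
noise-matched pairs, and cheaper), and a first-order (diffusion)
regularizer. Minimization is multiresolution gradient descent: at each
pyramid level the demons-style force `(dSim/dW) * grad W` plus the
regularizer gradient is smoothed and applied with a backtracking line
search, so the accepted-step energy sequence is non-increasing by
construction — including at the exact fixed point of identical images,
where the zero field is returned unchanged.

Two implementation notes, both load-bearing:

* The update smoothing is a two-pass box filter (triangular kernel) with
  running-sum passes, O(N) at any scale. The pass count must be even: an
  odd number of box passes has a sign-oscillating frequency response
  (sinc^k with odd k), which can turn the smoothed force into an ascent
  direction and stall the line search; an even count yields a positive
  semidefinite preconditioner and descent is preserved.
* The smoothing scale is specified in level voxels (its physical support
  grows at coarse levels, the usual demons convention) and may be given
  per level.

What registration can and cannot recover on the phantoms deserves honesty:
inside large homogeneous tissue regions the images carry no information
about the deformation, so any energy-minimizing method interpolates the
interior from edge evidence, and amplitude there is systematically shrunk
relative to a smooth ground-truth field. The known-warp recovery checks in
the acceptance suite measure the median endpoint error over the phantom
foreground — edges and flat interiors together — and the configuration used
there (`levels = 4`, SSD, `smooth_update_sigma = c(1, 2, 4, 8)`) was chosen
as the best trade-off between edge accuracy and interior interpolation.

# Atlas construction

`build_atlas()` alternates, per iteration `k`:

1. **Templates at observed ages** — kernel-weighted voxelwise means of the
   subjects pulled back through the inverse total maps of the previous
   iteration (identity maps at `k = 1`; the first template is a plain
   weighted mean, the initialization being a free choice).
2. **Registration** — every subject is registered, from a zero initial
   field, to the template at its own age, giving `phi_i = exp(v_i)`
   (subject into atlas space).
3. **Longitudinal maps** — `psi_i(t)`, relating the atlas space at the
   subject's age to any other supported age, is assembled from the history
   of residual means: `psi_i(t) = [prod_s phibar_s(t)] o
   [prod_s phibar_s(t_i)]^{-1}`, with every composition done by BCH on the
   stored SVFs so the result stays inside the stationary-velocity model.
   The age-specific deformation is `phi_i(t) = psi_i(t) o phi_i`.
4. **Residual Log-Euclidean mean** — `phibar_k(t) =
   exp(-sum_i w_i(t) log phi_i(t))`. Composing it onto the per-subject
   maps re-centers the atlas: the weighted mean log of the corrected total
   transforms `T_i(t) = phibar_k(t) o phi_i(t)` is (to BCH order) zero.

The **drift diagnostic** recorded per age and iteration is the mean voxel
norm of `sum_i w_i(t) log phi_i(t)` — the quantity the residual mean
removes. On a centered atlas it is zero; across iterations it should fall,
and its trajectory is the package's convergence measure (an honest one: it
is computed from freshly estimated registrations each iteration, not from
the correction that will cancel it).

Default iteration count is 4; the acceptance-scale runs use 6 iterations at
32-cubed with 9 subjects over 3 ages, which is where the drift contraction
and the end-to-end segmentation are measured (the drift keeps contracting
geometrically, so extra iterations sharpen the centering measurement). Subjects contributing several
scans are treated as independent images. Output templates can be requested
at any continuous age with at least one subject in kernel support; weights
are recomputed per requested age.

# Multi-atlas segmentation and STAPLE

`mas_segment()` implements the three-step procedure: select atlas
timepoints within one week of the query's age (the age-matching rule for
atlas-based fetal segmentation — a query outside every atlas's window is an
error, not a silent extrapolation), register each selected template to the
query, propagate the template labels through the estimated map
(nearest-neighbor), and fuse with probabilistic STAPLE.

`staple_fuse()` is the multi-category STAPLE EM: voxelwise categorical
truth, per-rater row-stochastic confusion matrices `theta_j`, E-step
posterior proportional to `prior(l) * prod_j theta_j(l, d_j)`, M-step
re-estimating `theta_j` from posterior-weighted counts. Two deliberate
departures from the textbook minimum, both forced by identifiability:

* **Class priors are re-estimated** in the M-step (mean posterior per
  label), making the model a standard finite mixture. The tempting
  alternative — fixing the prior at pooled rater label frequencies —
  overweights rare labels by up to an order of magnitude (a rare label's
  pooled frequency is dominated by off-diagonal noise from the abundant
  classes), which measurably biases every confusion row.
* **A weak Dirichlet prior** (one pseudo-voxel, centered on the
  initialization) regularizes the M-step. Confusion rows of labels that
  carry no posterior mass are unidentifiable; unregularized EM drifts to
  label-swapped degenerate solutions even in a three-rater, two-label
  majority-vote example. One pseudo-voxel is negligible against any real
  region but pins the degenerate rows.

The observed-data log-likelihood trace is returned and is non-decreasing;
consensus is the posterior argmax with ties to the smallest label id, and
the full posterior is returned alongside the hard labels.

# Evaluation metrics

Dice is the usual overlap ratio, with the both-empty case defined as 1
(with a message). The Hausdorff distance is the symmetrized maximum (or
95th-percentile) of directed surface distances, with surfaces taken as
6-connectivity boundary voxels and distances computed exactly (chunked
brute force — the volumes this package targets keep surfaces comfortably
small; the unit tests pin the implementation to an all-pairs oracle).
Edge sharpness — the atlas-quality score — is the median gradient magnitude
over detected edge voxels, with edges defaulting to the 90th percentile of
nonzero foreground gradient magnitudes; the detector is a package
definition (exposed via `detector` for replacement) since sharpening
metrics differ across the literature, and only its directional behavior
(blur strictly lowers it) is asserted, never a published table value.

# Segmentation building blocks

`dwconv()`, `param_count()`, `rvm_block()`, `decoder_softmax()`,
`skip_add()` and `hybrid_loss()` are reference implementations of the
building blocks of a lightweight 3D segmentation network: depthwise
(per-channel) convolution with zero padding; the parameter-count
comparison of depthwise-separable versus standard convolution (the printed
formulas use `k^2`; a `cubic = TRUE` flag gives the `k^3` variant for fully
3D kernels); a residual block combining layer normalization, a linear
projection, and self-similarity mixing `F' + S F'` where
`S = softmax(F_i . F_j / sqrt(d))` is computed from the block input — the
mixing operator is applied to the projected features while the similarity
is measured on the input, the literal reading of the defining equations;
channel softmax; trilinear-upsampling skip additions; and the hybrid
cross-entropy + soft-Dice loss (a class absent from both prediction and
truth counts as perfect Dice).

Because no automatic differentiation is available to this package, the toy
two-level network assembled from these blocks (`train_toy_network()`)
ships with hand-derived analytic gradients for every block — attention,
layer norm, depthwise convolution, pooling and trilinear-upsampling
adjoints — verified against central finite differences in the unit tests.
Training uses heavy-ball descent with a nonmonotone bold-driver step
control (accept while within 5% of the best loss seen; on a worse step
roll back, reset the momentum and halve the rate), returning the best
iterate and its running-best loss trace, which is monotone by
construction; the overfit sanity check drives the hybrid loss on a single
noise-free 16-cubed phantom (three classes: background, white matter with
ventricles merged in, cortex — the raw ventricle class at this resolution
is ~24 voxels, too small to carry a meaningful Dice term) below 10% of its
initial value within 500 steps.

# The phantom generator

`make_phantom()` builds an ellipsoidal "brain" whose radius grows linearly
with age, an inner ellipsoid ("ventricles"), and a surface ribbon
("cortex") perturbed by a sinusoidal folding pattern whose amplitude grows
linearly from zero at 21 weeks — a caricature of gyrification onset. Tissue
classes get distinct mean intensities plus Gaussian noise (sd 0.02 by
default); geometric defaults scale with the grid so the same cohort model
exists at any resolution. `make_warped_pair()` returns two phantoms related
by a known smooth random SVF confined to the head region by a smooth
window — deformations without intensity support are unrecoverable by any
registration, so leaving them in the background would only measure the
generator against itself. `make_cohort()` adds per-subject anatomical
jitter (a small random smooth warp, default maximum 4% of the grid) and an
intensity scale; `simulate_raters()` draws voxelwise rater labels from
known confusion matrices, the generative model under which STAPLE's
parameters are identifiable.

What the phantoms do **not** emulate: MRI physics (bias fields, partial
volume beyond interpolation), motion or reconstruction artifacts, real
anatomical variability (the jitter is a stationary smooth field, not
development), or real cortical folding geometry. Tests passing on phantoms
therefore certify the algorithms' contracts — convergence, centering,
parameter recovery, metric correctness — not clinical segmentation
accuracy.

# Problem sizes and limitations

The verification suite runs the algebra at 32-cubed, known-warp recovery
at 64-cubed (three generator seeds), atlas construction at 32-cubed with
nine subjects over three ages and three iterations, STAPLE recovery at
64-cubed, and the toy network at 16-cubed — sizes chosen so the full suite
completes on a single CPU in well under half an hour while still exercising
every multiresolution code path.

Known limitations, stated plainly: interior deformation amplitude is
shrunk wherever images are locally homogeneous (discussed above); BCH
truncation at order 2 degrades for compositions of large non-commuting
fields; the residual-mean correction assumes all per-subject maps carry
SVFs (dense maps without logarithms are rejected, by design); and the CLI
is a thin convenience layer — the R API is the interface of record.
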