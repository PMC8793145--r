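---
title: "Methods: contour descriptors, shape-space statistics, and the overlap-gated search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contour descriptors, shape-space statistics, and the overlap-gated search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanoshape)
library(dplyr)
```

`nanoshape` treats a nanoparticle synthesis as a *shape ensemble*: a
distribution of individually varying particle outlines, summarised and
compared statistically rather than by a representative micrograph. This
vignette is the package's own account of each methodological choice, its
assumptions, and its limits.

## From image to contour

Segmentation assumes well-spread, dark particles on a bright background with
an approximately bimodal intensity histogram — the standard situation for
TEM fields prepared for shape analysis. A single **global Otsu threshold** is
used rather than adaptive thresholding: on bimodal fields the two are
equivalent, and the global rule is deterministic and has no tuning
parameters. Components are 4-connected, interior holes are filled (a
particle's projection is simply connected), and two classes of components
are discarded: those touching the image border (their shapes are censored;
including them biases shape statistics) and those below `min_area_px`
(default 64 px, debris and noise speckle). Touching particles are *not*
split: a watershed cut would fabricate boundary where the data has none, so
overlapping aggregates are left to the border/area filters or to the
operator. Masks are returned ordered by decreasing area with a deterministic
tie-break (top-left-most pixel) so downstream particle ids are stable.

Boundaries are traced by **marching squares at the 0.5 iso-level of a
lightly smoothed mask** (Gaussian, sigma = 1 px). The smoothing is what
makes the trace sub-pixel: the 0.5-crossing of the blurred indicator
interpolates the true edge position, whereas tracing the raw binary mask
yields the mid-crack staircase polygon, which overestimates a circle's
perimeter by ~5.5% on average. With smoothing, perimeter and area of discs
and squares of radius ≥ 30 px are reproduced within 2% (the corner rounding
introduced by the blur costs a few pixels of perimeter on sharp right
angles, which is why the contract is stated for particles at that scale and
above). Inner holes are ignored at this stage too: of all traced loops, the
largest-area one is the outer boundary. Orientation is forced
counterclockwise by the signed-area test.

Every contour is then **resampled to N points at equal arc length**
(N a power of two, default 1024, at least 64). Equal-arc interpolation is
iterated to its fixed point so that the output polygon's own edge lengths
are uniform to 1e-9 relative — a single interpolation pass leaves
O(curvature²) spread where samples straddle input vertices, and the fixed
point makes resampling idempotent, which in turn makes descriptors stable
under repeated processing. The start point is canonical: the vertex farthest
from the curve centroid, ties broken by smallest polar angle. This removes
start-point ambiguity *before* the Fourier stage, so even phase-bearing
coefficients are comparable across particles. Perimeter is preserved well
within 0.1% at the default N.

## The radial Fourier descriptor

The shape signal is the **radial signature** r(t): the distance from the
contour's centroid to each of the N resampled points. The forward transform
uses the 1/N convention,

c_k = (1/N) Σ_t r(t) e^(−2πi k t / N),  k = 0 … N/2,

so c_0 is exactly the mean radius (real and positive for any non-degenerate
contour) and all quoted tolerances refer to this normalisation. Parseval's
identity, (1/N) Σ r² = |c_0|² + 2 Σ_{k=1}^{N/2−1} |c_k|² + |c_{N/2}|², holds
to 1e-9 and is tested.

The **feature vector** is |c_1|/c_0 … |c_K|/c_0 (default K = N/2 = 512,
putting the retained coefficient count in the hundreds-to-thousands range
appropriate for these particles). Invariances, each by construction and each
verified to 1e-9 over random generator shapes: translation (centroid
subtraction), rotation and start index (magnitudes discard phase), uniform
scale (division by c_0). A perfect circle maps to the zero vector.

The radial signature was chosen over elliptic Fourier descriptors because
branched nanoparticles are star-shaped about their centroid — spikes are
radial excursions — so a single real-valued function captures the outline,
and its magnitudes are naturally rotation/start invariant without the
normalisation conventions EFD requires. The trade-off is that genuinely
non-star-shaped outlines (deep concavities, crescents) fold the signature:
the arc-length parameterisation remains well defined, but r is no longer a
function of angle. Such contours are **flagged with a warning, not
rejected** — their descriptors are still usable for clustering, but
`reconstruct_contour()` (which re-embeds the signature at equal angles) is
then only approximate. Elliptic Fourier descriptors are the documented
alternative backend if such shapes dominate a dataset.

## Shape space, center of gravity, dispersity

PCA is fit on the **pooled feature matrix of the ensembles under
comparison** — centring, never per-feature rescaling, because all harmonics
share units (fractions of mean radius) and standardising would inflate the
high-frequency noise floor into the leading components. Pooling per
comparison (rather than one fixed global basis) means coordinates are
comparison-specific; this is deliberate and documented, matching how the
comparisons are actually read: each analysis gets the basis that best
spreads *its* ensembles. Component signs follow a fixed convention (largest
loading positive) so runs are bit-reproducible across platforms.

Working dimension is **m = 3 PCs** by default (plots and ellipses use 2).
The m = 3 default reflects the empirical structure of these descriptors:
correlated spike/bump features dominate, and the first three components
typically carry the large majority of variance for branched-particle
ensembles.

Each ensemble's **center of gravity** is the arithmetic mean of its
projected coordinates, and `representative_particle()` names the measured
particle nearest to it (deterministic tie-break: first index) — the honest
version of "typical shape". The 95% **confidence ellipse** uses the sample
mean and covariance with semi-axes √(λ_i · χ²₂(level)); for Gaussian clouds
its coverage is calibrated (verified at levels 0.5/0.9/0.95 within
Monte-Carlo error on 10,000-point clouds). Collinear or identical point
clouds have no ellipse and raise an explicit degeneracy error.

Ensemble dispersity is the **distance PDF**: per-particle distance to the
own-ensemble center in the first m PCs, smoothed with a Gaussian KDE. The
bandwidth is Silverman's rule of thumb (`stats::bw.nrd0`). Because distances
are non-negative and can sit within a few bandwidths of zero, the KDE is
**reflected at the origin**; without reflection the density leaks mass below
zero and fails to integrate to one. The grid is 512 points from 0 to the
maximum distance plus three bandwidths, and the trapezoidal integral is 1
within 1e-3 by construction.

## The overlap coefficient and independence

Two ensembles are compared along **the line joining their centers of
gravity**: both point clouds are projected onto that axis, each projected
sample gets a Gaussian KDE with its own Silverman bandwidth, both densities
are evaluated on one shared 512-point grid spanning the joint range ± 3
maximal bandwidths, and the **overlap coefficient** is the trapezoidal
integral of the pointwise minimum. OVL is the estimated fraction of
particles common to both distributions: 1 for identical ensembles, 0 for
disjoint ones, symmetric in its arguments, and invariant to rigid rotations
of the shape-space coordinates. Against the equal-variance Gaussian closed
form OVL = 2Φ(−Δ/2) it is accurate to well under 0.02 at n = 20,000 (the
KDE inflates each density's variance by bw², a bias of ~0.004 at that n).
The Bhattacharyya coefficient ∫√(f_a f_b) is reported alongside as a
secondary statistic — it is always ≥ OVL and less interpretable, which is
why OVL is primary. If the two centers coincide exactly the axis is
undefined; the implementation falls back to PC1 and flags the result.

**Independence**: two ensembles count as statistically distinct shapes when
OVL ≤ 0.05 (boundary inclusive). The 0.05 value is a declared convention —
at most 5% of particles shared — configurable everywhere it is used and
surfaced in every report. The construction is deliberately one-dimensional:
the inter-centroid axis is where two unimodal clouds differ most, and a full
multivariate KDE overlap in 3 PCs would need far more data for the same
stability.

## The synthetic generator as study system

The generator emulates branched-particle outlines:
r(θ) = R·(1 + A·Σ_j g((θ−θ_j)/s) + ρ·η(θ)) with g a periodic
von-Mises-style unit bump exp((cos x − 1)/s²) — smooth, band-limited, and
sharpness-tunable from broad flower lobes to urchin needles — spike centres
equally spaced plus Gaussian jitter, and η a smooth unit-variance random
low-order Fourier series. Parameters and defaults: base radius R (nm; preset
30–35, typical of branched gold cores), spike count k (the family identity:
5 star, 9 flower, 40 urchin, 0 sphere), fractional amplitude A ∈ [0, 0.9]
(0.2–0.55 across presets), sharpness s (0.12–0.5 rad), jitter (0.04–0.06
rad) and roughness ρ (0.02–0.03). Particle-to-particle variability draws
each particle's continuous parameters lognormally around the ensemble mean
(exact mean, default CV 0.10 — a realistic batch heterogeneity for seeded
growth) and, when requested, a rounded truncated-normal spike count.
Seeding is hierarchical (ensemble seed → per-particle seeds), so any single
particle is reproducible in isolation.

A note on spectra: the bump train of k spikes has harmonic content only at
multiples of k, with envelope e^(−(ks)²/2)-like decay, so the dominant
harmonic equals the spike count when k·s ≈ 1 (well-resolved spikes). The
12-spike end-to-end recovery benchmark uses s = 0.12 for that reason — it is
a property of the shape family being emulated, not a tuning of the test.

The renderer places particles at rejection-sampled non-overlapping positions
(bounding-disc clearance, ≥ 5 px margins) — overlap is rejected rather than
drawn because the imaging protocol being emulated uses well-spread
particles — fills polygons dark on a bright background, and adds Gaussian
pixel noise. What it deliberately does **not** model: TEM image formation
(defocus, astigmatism, contrast transfer), 3D projection effects (a 2D
outline is already a projection; the generator draws outlines directly),
aggregation, and growth kinetics. Passing the end-to-end suites therefore
shows the *computational* pipeline is faithful on images with realistic
geometry and noise; it does not validate segmentation against the full
physics of real micrographs.

## The overlap-gated discovery loop

The search emulates inductive navigation of a synthesis space: iterate small
parameter changes, watch the ensemble move in shape space, and spend the
expensive readout only where it is informative. The implementation is
deliberately the minimal faithful version — coordinate ascent with
step-halving — rather than surrogate-model optimisation, which is the
natural future extension.

Mechanics per proposal: synthesise the ensemble, project it into the
trajectory's chart, and measure OVL against the previously accepted
ensemble. If OVL < `backtrack_ovl` (default 0.01) the jump was discontinuous
— too far to attribute the shape change to the parameter direction — so the
step is halved and the search returns close to the previous coordinates.
Otherwise the step is accepted; and if the OVL against the *last-queried*
ensemble has fallen to `ovl_gate` (default 0.05, the independence threshold)
the readout is queried. An improved readout keeps the direction; a
deterioration reverses it; a second deterioration on the same parameter
rotates to the next one. The run stops at `max_steps` or when all step
scales have shrunk below a floor. The gating invariant — no readout at a
step whose OVL to the last-queried ensemble exceeds the gate — is
machine-checkable from the record, and `structure_function_table()` distils
the run into the pairwise-independent subsequence (greedy, in step order)
that constitutes a defensible structure–function series.

Two design points deserve emphasis. First, the **chart is fixed**: the shape
space is fit once on the starting ensemble and reused for every step, unlike
the refit-per-comparison rule used for ordinary ensemble comparisons. A
sequential search needs a stable coordinate system — refitting per step
would move the landscape under the optimiser. Second, the paper-facing
readout is abstracted as a deterministic function over shape-space
coordinates (`readout_landscape()`, sums of Gaussian bumps); a table of real
assay results keyed by ensemble could replace it without touching the loop.
The reverse-then-rotate direction heuristic is likewise a declared choice:
nothing quantitative dictates the next direction after a readout, so the
simplest memoryless rule was preferred.

## Numerical choices and degenerate inputs

* Transform convention forward-1/N; all tolerances quoted against it.
* Resampling requires N a power of two, N ≥ 64; contours need ≥ 16 vertices,
  no duplicated consecutive vertices, positive perimeter; orientation is
  normalised, not rejected.
* Blank images segment to an empty list (not an error); non-finite pixels
  are an error at construction.
* Zero-area contours, identical-point clouds (no ellipse, no distance PDF),
  zero-variance projections (no bandwidth) and coincident centroids (axis
  fallback + flag) all fail loudly or are flagged — never silently patched.
* Ensemble statistics require ≥ 20 particles (KDE stability at Silverman
  bandwidths); ellipses require ≥ 3; the trajectory relaxes the per-ensemble
  floor via `min_n` since its ensembles are compared repeatedly, not
  reported singly.
* Problem sizes in the shipped suites — 200 particles per ensemble for
  family comparisons, 100 rendered particles for end-to-end recovery, 40
  particles × 20 steps × 20 seeds for trajectory statistics, N = 256
  signatures inside the search loop versus N = 1024 for analysis — were
  chosen as the smallest sizes at which the statistics they exercise are
  stable.

## Known limitations

* 2D projections only: a single outline under-determines a 3D branched
  particle; systematic orientation bias in deposition would bias the
  descriptor ensemble, and nothing here corrects for it.
* Star-shaped assumption: strongly concave outlines get a warning and an
  approximate reconstruction; EFD would serve them better.
* No touching-particle splitting; dense fields lose particles to the
  border/area filters.
* OVL is estimated along one axis; two ensembles differing only in a
  direction orthogonal to their centroid separation (e.g., equal means,
  different variances) will look more similar than a multivariate comparison
  would report.
* The discovery loop is a local hill-climber: multimodal landscapes are
  explored only as far as its backtracking and direction rotation allow.
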