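---
title: "Quantifying gastruloid polarization: methods and design notes"
author: "gastrukit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying gastruloid polarization: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gastrukit)
```

Gastruloids — 3-D aggregates of mouse embryonic stem cells — break
symmetry after a Wnt-agonist pulse: they elongate into a teardrop, a
pole of E-cadherin/T-Brachyury expression emerges at the forming tip,
islands of E-cadherin-retaining cells are carried there by a
tissue-scale flow, and differential junction tension keeps those islands
cohesive while they sort into an endoderm-like region. `gastrukit`
implements the quantitative machinery behind each of those observations:
shape morphometry of binary aggregate masks, a fluorescence polarization
statistic, neighborhood-graph statistics over labeled cell centroids,
optic-flow reconstruction of tissue velocity, and contact-angle tension
inference — together with seeded generators that emulate each class of
input so the whole pipeline is testable at desk scale.

## Shape morphometry

**Elongation.** The foreground's second central moments give the
inertia tensor; with eigenvalues $\lambda_1 \ge \lambda_2$ the best-fit
ellipse has axis ratio $a/b = \sqrt{\lambda_1/\lambda_2}$ and we report

$$e = \frac{a}{b} - 1,$$

which is 0 for a disk, 1 for a 2:1 ellipse, and invariant under rigid
motions and uniform rescaling. Aggregates with $e > 0.125$ are
conventionally classified as elongated. The raw ratio is available via
`elongation(mask, ratio = TRUE)` because the literature is not uniform
about which scalar sits behind that threshold; the offset form is the
one for which 0.125 is a meaningful boundary.

**Contours.** The boundary is the 0.5 iso-level of the mask, traced by
marching squares with linear interpolation. The binary grid is first
smoothed with a small Gaussian whose width scales with the shape
($\sigma = \mathrm{clamp}(\sqrt{A_{px}}/50,\ 0.6,\ 2)$ pixels). The 0.5
level of a blurred step stays on the step, so this costs almost no area
(curvature shifts the level set by $\approx \sigma^2/2r$), but it
removes the axis-aligned pixel staircase which otherwise injects a
systematic, orientation-dependent bias into the Fourier descriptors
below. Areas of extracted contours agree with foreground pixel counts
to well under 1% on disks, rectangles and noisy teardrops.

**Elliptic Fourier descriptors.** Contours are decomposed with the
Kuhl–Giardina elliptic Fourier transform under arc-length
parameterization, each harmonic $n$ carrying four coefficients
$(a_n, b_n, c_n, d_n)$ in micrometres; no rotation or size
normalization is applied because absolute physical scale is the point.
The number of harmonics is chosen by an area rule: the smallest $N$
whose reconstruction differs from the mask area by less than 2%
(`efdSelectOrder`), falling back to the maximum fitted order with a
warning.

Two properties of the arc-length convention are worth knowing. First,
only a circle is exactly a one-harmonic shape; an ellipse traversed at
constant speed acquires odd higher harmonics, and its harmonic-1
ellipse under-covers the true area by an amount that grows with
eccentricity (about 0.7% at 1.5:1, 1.9% at 2:1, 3% at 2.5:1). The 2%
area rule therefore selects order 1 for mildly eccentric shapes and may
legitimately select order 3 for strongly elongated ones. Second, the
reconstruction's *L2* error is non-increasing in $N$ (Fourier partial
sums), but the *area* error need not decrease monotonically; the
guarantee attached to the selected order is only that its own area
error is below the threshold.

**Tip magnitude.** The second harmonic is an ellipse whose axis lengths
are twice the singular values of the $2\times2$ coefficient matrix
$\begin{pmatrix} a_2 & b_2 \\ c_2 & d_2\end{pmatrix}$; `tipMagnitude`
returns the product of the two full axis lengths ($4 s_1 s_2$, µm²),
a proxy for how far a localized protrusion has developed. Full axis
lengths are a fixed scale convention; only relative and temporal
comparisons are meaningful. The statistic is exactly invariant under
90° grid rotations and invariant to a few percent under oblique
rotations at typical resolutions; the residual is rasterization noise
and halves when the pixel size halves.

```{r shape}
mask <- syntheticPreset("elongated_chi", seed = 1)
shapeMetrics(mask)
```

## Fluorescence polarization

The mask is split by a line through its centroid; the contrast between
the two halves is $(I_{max} - I_{min})/(I_{max} + I_{min})$ where each
$I$ is the *mean* intensity over the half's foreground pixels (means,
not sums, so halves of unequal size compare fairly). The first cut lies
along the major inertia eigenvector; the cut is then rotated in 5°
steps over $[0°, 180°)$ (sufficient by symmetry) and the maximum is
reported, with ties broken toward the smaller angle and on-line pixels
deterministically assigned to the positive-normal side. The statistic
is invariant to multiplying the intensity by a positive constant and
strictly decreases when a constant offset is added to a non-uniform
field — background subtraction matters.

## Cell-neighborhood graphs

Labeled centroid tables (2-D or 3-D) are triangulated (Delaunay; the
3-D triangulation is an in-package Bowyer–Watson implementation,
verified in the test suite against brute-force empty-circumsphere
enumeration) and edges longer than 12 µm — the average cell size — are
pruned, so surviving edges connect cells that plausibly touch. On this
graph the package computes per-type connected components (a compact
island yields one dominant component; a sparse population fragments),
majority-neighborhood typing (a cell is *homotypic* when the most
common type among its neighbors is its own; ties and isolated cells are
recorded explicitly and counted as heterotypic, a conservative choice
the summaries report separately), and radial population profiles:
distances from the aggregate centroid, a user point, or the mask tip
(defined as the major-axis contour end farthest from the centroid),
optionally normalized to a unit sphere by the maximum cell distance;
per-type fractions in half-open distance bins; and a per-type Gaussian
kernel density over distance with Silverman's bandwidth, reflected at
both domain boundaries so it integrates to 1 on the bounded domain, its
cumulative integral giving probability-vs-distance. `poolAggregates`
registers several aggregates by their origins, unit-normalizes each,
and concatenates them with provenance for pooled profiles.

```{r graph}
cells <- syntheticPreset("island_shell", seed = 11)
nt <- neighborhoodTyping(buildCellGraph(cells, pruneLength = 12), cells)
nt$perType
```

## Tissue flow

Velocity fields come from dye-channel (extracellular sulforhodamine B)
time-lapses in three stages.

1. **Prefilter** (`prefilterBrightObjects`): dead cells and vesicles are
   much brighter than cell contours; pixels above a threshold (default:
   the 99.5% quantile) are replaced by the median of sub-threshold
   pixels in a 15-px window, leaving contour statistics unbiased.
   Clipping is available as an alternative.
2. **Rigid registration** (`registerRigid`): each consecutive frame
   pair's rotation is initialized by phase correlation along the
   angular axis of the polar-resampled spectrum magnitude and the
   translation by windowed phase correlation with subpixel parabolic
   interpolation, then both are refined by Gauss–Newton minimization of
   the intensity residual. Pair transforms are composed analytically so
   every frame is resampled exactly once (Catmull–Rom) into frame-1
   coordinates; pixels outside a warped frame's support are NA, not
   fabricated. A translation-only re-initialization guards against
   false peaks in the angular correlation. On rigidly moving synthetic
   stacks the residual apparent motion after registration is below
   0.01 px/frame.
3. **Pyramidal Lucas–Kanade** (`kltFlow`): per window (default: a
   square of 2 cells by 2 cells, `round(2 * 12 µm / pixelSize)` px,
   clamped to ≥ 8; 50% overlap), iterative least-squares displacement
   (≤ 20 iterations, 0.01 px convergence) refined coarse-to-fine over a
   2-level pyramid (full + half resolution, Gaussian antialiasing).
   Windows with an ill-conditioned structure tensor (condition number
   > 10⁴), runaway displacements, or less than 70% in-support pixels
   are flagged invalid. Displacements convert to µm/min via the pixel
   size and frame interval.

A flow field that is itself a global rigid motion is mathematically
indistinguishable from camera motion, so registration absorbs it; the
decomposition into "global motion" and "internal flow" is only
well-posed when the internal field has no net rigid component. The
synthetic vortex fixture is built accordingly (below). Flow is 2-D: the
imaging protocol captures thin sub-volumes near the aggregate midplane,
and a slice or projection is analyzed; no volumetric flow is attempted.

## Junction tension

At a three-way junction between two island (E-cad⁺/E-cad⁺) cells and a
neighbor, force balance along the homotypic interface gives

$$\frac{\gamma^{+-}}{\gamma^{++}} = \frac{1}{\cos\theta_1 + \cos\theta_2},$$

with $\theta_i$ the contact angles of the two heterotypic interfaces
measured from the reversed homotypic direction. The ratio is symmetric,
strictly increasing in each angle (wider contact angles mean
proportionally tenser island boundaries), equals 1 at
$\theta_1 = \theta_2 = 60°$ and 0.5 at $0°, 0°$; angles approaching 90°
make the balance degenerate and raise an error. Group summaries use
type-7 quantiles so small-sample values are deterministic. The figure
axis construction of the source box plots is not guessed beyond this
formula; the package reports the ratio itself.

```{r tension}
tensionRatio(60, 60)
summarizeJunctions(tensionRatio(c(40, 55, 62), c(35, 50, 60)), "96h")
```

## What the synthetic data emulate — and what they do not

Every generator is a pure function of its arguments including the seed,
and each preset reproduces one qualitative regime of the imaging data:

* **Masks** (`generateAggregateMask`): a one-parameter teardrop — an
  ellipse stretched by $1 + a/2$ along the tip direction times a single
  $\cos^4(\Delta\phi/2)$ radial lobe. Both elongation and tip magnitude
  increase strictly with $a$; elongation crosses the 0.125 threshold
  near $a = 0.2$, so the "elongated" preset uses $a = 0.55$ and the
  spherical control $a = 0$ (plus mild band-limited boundary noise).
  This family was chosen over a Gaussian radial bump deliberately: the
  Gaussian bump's second-harmonic content is *not* monotone in its
  amplitude under arc-length parameterization, which would make a
  growing tip unquantifiable by the very statistic designed for it.
* **Intensity fields** (`generatePolarizedIntensity`): a two-level
  field split at a line through the centroid with levels $1 \pm c$, so
  the analytic two-half contrast equals the target exactly; optional
  Gaussian noise.
* **Cell populations** (`generateCellPopulation`): dart-throwing packs
  a core at 8.5 µm minimum spacing (below the 12 µm pruning length, so
  the core connects) inside the smallest feasible ball, and scatters a
  shell at ≥ 14 µm spacing (above it, so the shell fragments) — the
  island-plus-wrapping structure seen in stained aggregates.
* **Flow sequences** (`generateFlowSequence`): band-limited texture
  (Gaussian-filtered white noise, σ = 2 px — contour-scale features
  without modeling cells) advected by an analytic field with an exact
  or RK4-integrated flow map, so every frame is a single resampling of
  one texture. The vortex field is a compact stream-function dipole
  (a directed jet with peripheral backflow, the qualitative analogue of
  tip-ward flow with recirculation) plus an optional Gaussian sink;
  compact support means zero net rigid component, keeping imposed
  drift separable by registration. Bright-spot contamination and
  cumulative rigid drift exercise the prefilter and registration.
* **Junctions** (`generateJunction`): inverts the tension formula —
  symmetric solution $\arccos(1/2\rho)$, an asymmetry parameter that
  splits the cosines at fixed sum, Gaussian angle noise added last.

What passing tests on these fixtures shows is that each statistic
recovers the structure it was designed for under controlled conditions:
they do not certify segmentation quality, cell-type calling, 3-D flow,
or imaging artifacts beyond bright spots and rigid drift, and real
SRB texture is not Gaussian noise. The headline counts of the original
study (e.g. 126-of-131-cell components, n = 28/54 junction groups)
derive from manually tagged microscopy that is not reproducible from
printed text; the generators reproduce the *qualitative regimes* and
the tests assert the corresponding properties (core holding > 90% of
its cells in one component, > 80% homotypic, fragmented shell).

## Numerical choices and problem sizes

Tolerances and tie rules that matter: contrast scan step 5° with ties
to the smaller angle; prune length is a closed bound (edges exactly
12 µm survive); distance bins are half-open with the last right edge
closed; LK convergence 0.01 px, condition cutoff 10⁴, ≥ 70% window
support; registration Gauss–Newton tolerance 10⁻⁵; KDE bandwidth
`bw.nrd0`, reported in the output; quantiles type 7; degenerate inputs
(empty masks, collinear point sets, constant channels, force-balance
degeneracies) raise typed errors rather than returning numbers.

The test-suite problem sizes were chosen as the smallest that exercise
each property cleanly: masks of radius 20–60 µm at 0.5–1 µm/px,
cell tables of 15–200 cells (brute-force Delaunay oracles cap at ~50
points in 3-D), flow stacks of 3–20 frames at 256² px, and 10⁴
replicates for the junction-noise bias. `scripts/acceptance.R` re-runs
the same pipeline end to end and writes its headline numbers as JSON.

## Known limitations

* No segmentation: masks are inputs (the source study trained a UNET;
  a threshold is plumbing, not science).
* Flow is 2-D and window-averaged; divergence/curl estimates inherit
  the window scale.
* Fourier descriptors at 1 µm/px carry percent-level rasterization
  noise in high harmonics; compare tip magnitudes within a series, not
  across imaging setups.
* The tip origin heuristic needs a teardrop-like mask; for ambiguous
  shapes supply the origin explicitly.
* Delaunay edges near co-spherical point configurations are
  tie-broken by floating-point tolerance; jittered fixtures avoid the
  degenerate set.
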