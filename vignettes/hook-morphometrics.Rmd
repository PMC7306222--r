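---
title: "Outline morphometrics of parasite attachment hooks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Outline morphometrics of parasite attachment hooks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hookmorph)
```

## The problem

Cymothoid isopods attach to fishes with hook-shaped dactyli — the claw-like
distal elements of their pereopods. The hooks are smooth, landmark-free
curves, so comparisons across attachment sites (mouth, gill, external
surface) and across ontogeny (immature versus adult) have to work from the
closed outline as a whole. This package implements that workflow: outlines
in, elliptic Fourier descriptors (EFDs), a PCA morphospace, per-group
occupation measures and ontogenetic change vectors out.

## Elliptic Fourier descriptors

For a closed polygonal outline parameterized by arc length $t \in [0, T)$,
each coordinate is expanded as a truncated Fourier series with per-harmonic
coefficients $(a_n, b_n, c_n, d_n)$ and offsets $A_0, C_0$. `compute_efd()`
evaluates the Kuhl–Giardina closed-form segment sums, which are exact for
piecewise-linear curves — the unit tests check them against dense
trapezoidal quadrature of the same integrals to $10^{-6}$.

Two consequences of arc-length parameterization are worth knowing:

- A parametric ellipse $(2\cos t, \sin t)$ is *not* a pure first harmonic
  under arc length: the quadrature oracle gives $a_1 = 1.82841$,
  $d_1 = 1.07302$ (normalized $d_1 = 0.58686$), not the parametric
  $2, 1, 0.5$. Tests freeze the oracle values.
- Reconstructing from truncated coefficients and re-analyzing does not
  return the identical coefficients, because the truncated curve's own
  arc length differs slightly from the original parameter. The
  discrepancy shrinks with the harmonic count and is at the $10^{-4}$
  level only for smooth, nearly band-limited shapes.

### Normalization

`normalize_efd()` standardizes on the first-harmonic ellipse: the start
point is re-phased onto the semi-major axis, the axis is rotated onto $x$,
and all coefficients are divided by its length, leaving $a_1 = 1$,
$b_1 = c_1 = 0$. Two discrete ambiguities are resolved deterministically:

- the half-angle phase formula may land on the minor axis; if
  $|a_1| < |d_1|$ after rotation the start is advanced a quarter period;
- the two ends of the major axis are equivalent start points, differing by
  a sign flip of every even harmonic. The flip is chosen so that the first
  coefficient in the fixed order $d_2, c_2, b_2, a_2, d_4, \dots$ with
  magnitude above $10^{-9}$ is positive. A fixed order keeps the canonical
  form continuous across a shape family as long as its leading
  discriminant stays away from zero — on the synthetic hook family
  $|d_2| \ge 0.05$ throughout. For centrally symmetric shapes all even
  harmonics vanish and the ambiguity is immaterial.

Outlines are canonicalized counterclockwise before analysis, so $d_1 > 0$;
mirrored (left-side) specimens are handled by `mirror_outline()` /
`mirror_efd()` ($(a_n,b_n,c_n,d_n) \to (-a_n,b_n,c_n,-d_n)$ plus
re-normalization), an involution that commutes with normalization.

### Harmonic count

The harmonic count defaults to $N = 20$. On synthetic hooks the cumulative
harmonic power reaches 0.9999 by roughly $N = 10$, so 20 is comfortably
past the resolution of the shapes while keeping the coefficient matrix
(77 columns) well-conditioned for 60 specimens; `harmonic_power()` reports
the spectrum if a different truncation is wanted.

## Outline preparation

- **Canonical form** — counterclockwise orientation; the start vertex is
  rotated to the minimum-$y$ (then minimum-$x$) vertex. The published
  drawings' digitization start points are unknown; since normalization
  removes start-point dependence anyway, the canonical start exists for
  reproducibility, not correctness.
- **Resampling** — equal arc-length spacing (default 256 points) before
  EFD computation, so differently digitized outlines are comparable;
  coefficients at 256 versus 512 points differ below $10^{-3}$.
- **Base capping** — the proximal articulation of a drawn dactylus is
  concave and unstable under outline analysis; `cap_base()` closes the
  open curve with a convex circular arc bulging away from the interior.
  The sagitta is `arc_bulge` × chord; the default semicircle
  (`arc_bulge = 0.5`) matches the plain reading of a "rounded" cap, and
  the shallower-arc option exists for sensitivity analysis.
- **Smoothing** — (1/4, 1/2, 1/4) closed-curve averaging, default 0
  iterations: the source drawings are assumed already cleaned (setae
  removed at the drawing stage), so smoothing is opt-in.

## Morphospace

`assemble_coefficient_matrix()` lays out columns $a_2..a_N, b_2..b_N,
c_2..c_N, d_1..d_N$ — the post-normalization constants $a_1, b_1, c_1$ are
excluded rather than carried as near-zero columns; $d_1$ varies and is
kept. `run_pca()` is covariance PCA (`stats::prcomp`, centered, unscaled):
normalized coefficients are already commensurate, and rescaling to
correlations would inflate the noise-dominated high harmonics. Loading
signs are fixed (largest-magnitude loading positive) so scores are
reproducible across eigen-solvers. No truncation rule is imposed; variance
tables report all components.

Group occupation is operationalized as the convex-hull area of a group's
scores in a PC plane (default PC1 × PC2), with degenerate groups (< 3
points, collinear) assigned area 0; pairwise occupation overlap is the
area of the convex polygon intersection (Sutherland–Hodgman clipping).
Hull area is a deliberate, simple operationalization of "occupies a
larger/smaller morphospace" — convex hulls are sensitive to extreme
individuals, which is acceptable at $n = 10$ per group but worth
remembering when reading the tables.

Ontogenetic change is the displacement from a species' immature score to
its adult score in the PC plane, per appendage. The dispersion summary is
the circular concentration $\bar R$ = length of the mean unit vector:
$\bar R \to 1$ when all species change in the same direction (a shared
developmental trajectory), $\bar R \to 0$ when directions are scattered.

## The synthetic hook generator

The generator is the package's testbed: a circular-arc centerline of
curvature $\kappa$ and length $L$ (so $\kappa L$ is the total turn), a
width profile $w(s) = \tau L (1 - s/L)^{taper} + w_{min}$ tapering to a
rounded tip, and the convex base cap. Its two free shape parameters map
onto the empirical reading of hook morphospaces — PC1 as degree of
curvature, PC2 as relative thickness — which is what makes
axis-interpretation tests meaningful. Defaults: $\kappa = 1.5/L$,
$\tau = 0.25$, taper 1.5, $w_{min} = 0.02L$.

Vertex noise models redrawing error as a *low-frequency* radial wobble:
Gaussian displacements (sd = `noise_sd` × L, default 0.005) at 48 equally
spaced knots, interpolated periodically around the outline. Independent
per-vertex noise at the same amplitude would exceed half the vertex
spacing and routinely self-intersect; the knot form keeps every generated
outline simple, which the generator asserts.

The default study design mirrors the real sampling structure: 5 species
per attachment site × 3 sites × 2 stages × 2 appendages = 60 outlines,
with additive site effects (mouth +0.3, gill 0, external −0.3 on $\kappa$;
−0.02, +0.02, 0 on $\tau$), a coherent adult effect (+0.2 on $\kappa$,
−0.03 on $\tau$: adults more curved and relatively thinner), and
per-species Gaussian effects (sd 10% of the parameter means) shared across
a species' four outlines. What the generator does *not* emulate: real
digitization artifacts, allometry beyond the additive stage shift,
phylogenetic covariance among species, and within-species individual
variation — so passing recovery tests demonstrates that the machinery
measures what it claims on shapes of this kind, not that real hook data
are this clean.

## The independent curvature/thickness estimator

Axis-interpretation tests need a shape measure that does not reuse the
generator's parameters or the EFD pipeline. `estimate_curvature_thickness()`
splits the outline at its farthest vertex pair (tip versus base), pairs
each side's core against the nearest points of the other side, and takes
pair midpoints as a medial-axis approximation. Curvature is the mean
signed circumcurvature of wide point triples along the medial curve,
averaged over both pairing directions — the signed average cancels the
$O(\text{slope}^2)$ bias that nearest-point pairing introduces on tapered
shapes (an algebraic least-squares circle fit was rejected here: its
well-known small-arc bias produced spurious curvature ≈ 0.18/L on an
exactly straight blade, versus ≈ 0.002/L for the triple method). The whole
estimate is additionally averaged over the outline and its mirror image,
making reflection invariance exact by construction. On noise-free hooks
with $\kappa L \in [0.5, 2.5]$ the estimator is within ~1% at the default
thickness and within ~8% at $\tau = 0.35$.

## Numerical and testing choices

- Doubles throughout; closed-form EFD sums, no quadrature in the
  implementation (quadrature is the test oracle only).
- Simplicity is checked by an $O(n^2)$ segment-intersection scan — used in
  generation and tests, not on bulk data.
- Boundary tracing is Moore-neighbor with Jacob's stopping criterion in
  state form: the walk stops when a (pixel, entry-direction) state
  repeats, which terminates for every mask and reduces to the classic
  criterion on simple blobs.
- The trajectory contrast test compares the coherent-effect $\bar R$
  (single dataset) against the mean $\bar R$ of three replicate
  randomized-direction datasets: a single 30-pair $\bar R$ under the null
  has mean $\approx 1/\sqrt{30} \approx 0.18$ but non-trivial spread, and
  averaging replicates tests the logical contrast rather than one draw.
- Problem sizes in tests and the acceptance script — 60-hook studies at
  256 outline points and $N = 20$, 30-hook single-parameter sweeps —
  match the scale of the emulated study design; the full suite runs in
  about a minute.

## Known limitations

- The `.chc`/`.nef` readers implement a fixed, documented text dialect
  (with a permissive `#`-comment flag), not any legacy binary project
  format of historical digitizing software.
- `hull_overlap()` assumes convex inputs (guaranteed for hulls).
- The medial-axis estimator expects hook-like topology (one dominant
  concavity, a single tapering blade); it is an oracle for the synthetic
  family, not a general-purpose skeletonizer.
- Group-separation claims are descriptive (hull areas, overlaps); no
  hypothesis tests are attached, and no phylogenetic correction is
  attempted.
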