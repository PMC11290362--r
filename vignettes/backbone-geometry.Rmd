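---
title: "Differential geometry descriptors for protein backbones: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential geometry descriptors for protein backbones: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protgeom)
```

## The model

A protein backbone, reduced to its C-alpha trace, is treated as a smooth
space curve. protgeom fits each contiguous stretch of a chain with an
interpolating parametric cubic spline

$$r(t) = \big(x(t),\, y(t),\, z(t)\big),$$

one spline per coordinate, with the residue position within the stretch as
the (unitless) curve parameter: $t = 0, 1, 2, \dots$ at consecutive
residues. From this curve the package computes, at every residue,

* **curvature** $\kappa = |\dot r \times \ddot r| / |\dot r|^3$
  (1/Å) — the local rate of turning, a non-negative magnitude;
* **torsion** $\tau = (\dot r \times \ddot r)\cdot\dddot r / |\dot r
  \times \ddot r|^2$ (1/Å) — the signed rate at which the curve leaves its
  osculating plane; mirror reflection flips its sign;
* **arc length** $\int |\dot r|\,dt$ (Å), accumulated along the chain; and
* the **writhing number** Wr of the five-residue window centred on the
  residue — a knot-theory "pseudo-curvature" of the local polygonal trace,
  signed by handedness, computed from the Gauss linking integral.

Curvature and torsion are invariant under rigid motions and under
reparameterization of the curve; together with Wr they are sensitive to
small conformational changes, and the weighted Euclidean distance over
(κ, τ, Wr) is a true metric (it satisfies the triangle inequality, which
RMSD does not), so the descriptors plug directly into clustering
algorithms.

## Why derivatives go through a Chebyshev series

A cubic spline is only piecewise cubic: its third derivative is a step
function with jumps at every knot, precisely where the torsion formula
needs $\dddot r$ at the residues. Differentiating the spline directly is
therefore unstable at the points of interest. Instead, the spline is
*sampled* at 50 Chebyshev points of the first kind on the window
$[t-1,\,t+1]$ around the residue, a Chebyshev series is fitted to the
samples, and the series — a single global polynomial on the window — is
differentiated analytically. Because the sample points are Chebyshev nodes
the least-squares fit reduces, by discrete orthogonality, to weighted sums:
there is no linear system to condition, and the whole scheme is
deterministic.

**Degree of the fitted series.** The fit degree is the one real tuning
knob. It must be at least 3 (so that cubics — and hence every spline piece
— are differentiated exactly) and should stay well below the number of
samples so the truncated series acts as a low-pass filter over the
knot-scale artefacts of the spline. The package default is **degree 5**,
calibrated on analytic benchmark curves where the answer is known in
closed form:

| benchmark | degree 5 | degree 16 |
|---|---|---|
| circle, 0.5 rad/step: relative κ error at knots | 0.35% | 1.70% |
| dense helix (2.5°/residue): relative κ error | 2.0e-5 | 1.2e-4 |
| dense helix (2.5°/residue): relative τ error | 1.8e-4 | 2.8e-4 |
| cubic test curve, all three derivatives | exact (1e-11) | exact |

Lower degree filters the spline's interpolation ripple more strongly and
is uniformly more accurate on these benchmarks while remaining exact for
cubics; degree is exposed as an argument throughout for users who want
less smoothing. The window half-width (1 residue) and the 50 sample
points are likewise arguments.

## What the descriptors measure — and what they do not

An important subtlety, documented here because it affects how absolute
descriptor values should be read: **the descriptors are properties of the
spline interpolant, not of whatever smooth curve the C-alpha points were
sampled from.** Any number of smooth curves pass through the same points;
the cubic spline with residue-index parameterization is the one this
package (deliberately, for reproducibility) standardizes on.

For densely sampled curves the distinction vanishes: on a helix sampled
every 2.5° the pipeline reproduces the smooth-helix closed forms
$\kappa = a/(a^2+c^2)$, $\tau = c/(a^2+c^2)$ to about 1e-4 relative error
(tested). But an ideal α-helix places only 3.6 residues per turn
(100°/residue), far below the density at which a cubic spline can track a
circle-like curve faithfully. At that sampling the interpolant is a
genuinely different curve: its curvature at the knots is *higher* than the
smooth helix through the same atoms. Concretely, for the canonical
α-helix (radius 2.3 Å, rise 1.5 Å/residue):

| quantity | smooth helix closed form | spline pipeline (this package) |
|---|---|---|
| κ (1/Å) | 0.3815 | 0.4569 |
| τ (1/Å) | 0.1426 | 0.1107 |
| Wr (5-residue window) | — | +0.2349 |
| arc length/residue (Å) | 4.285 | 4.197 |

The pipeline values are stable (identical at every interior residue, and
confirmed against an independent implementation of the same scheme in
scipy/numpy), they are simply *the spline's* differential geometry. This
is a known property of spline representations of coarsely sampled curves,
not a numerical defect; comparisons between structures are unaffected
because every structure is represented the same way. Users comparing
against textbook helix values should expect the table above.

The secondary-structure boxes used by `classify_geometry()` are therefore
anchored to the *measured* descriptor values of ideal geometries at the
default settings, not to smooth-curve closed forms: helix
$|\kappa - 0.46| \le 0.10$ and $\tau \in [0.02, 0.20]$ (right-handed
only); strand $\kappa \in [0.60, 0.95]$ and $|\tau| \le 0.16$ (an
extended 2-residue repeat with 3.3 Å rise and 0.94 Å pleat measures
κ ≈ 0.67–0.73 with small |τ|). Both boxes are configurable, and any
user-defined similarity criterion can be substituted.

## Spline details and degenerate cases

* **End condition**: not-a-knot by default (third-derivative continuity
  across the first and last interior knots). It is the condition under
  which data sampled from a single cubic are reproduced exactly, which the
  test suite exploits; the natural condition (zero end curvature of each
  coordinate spline) is available as an option because descriptor values
  near termini depend measurably on the choice.
* **Chain breaks**: a residue-numbering gap (> 1 by default) or a C-alpha
  to C-alpha distance above 4.5 Å starts a new independent segment; both
  thresholds are arguments. Segments shorter than four residues cannot
  support a cubic spline; `describe_structure()` keeps their residues in
  the output with all descriptors undefined.
* **Termini**: the derivative window is clipped at segment boundaries.
  A clipped window still spanning at least 1.0 parameter units is
  accepted (so terminal residues get one-sided derivative estimates); a
  shorter window flags the residue's κ/τ undefined.
* **Locally straight curve**: when $|\dot r \times \ddot r|^2 <$ 1e-12
  the torsion quotient is numerically meaningless and τ is flagged
  undefined rather than returned as a large unstable number.
* **Writhe at termini**: the five-residue window needs two residues on
  each side; the two first and last residues of every segment have Wr
  undefined.
* **Undefined values** are `NA` in the geometry table and empty fields in
  the CSV export; they are never silently replaced by numbers (the PDB
  b-factor writer, whose fixed-width format has no notion of missingness,
  uses an explicit, configurable sentinel of 0.00).

## Writhe

The writhing number of the five-residue window is the standard polygonal
double sum: for every pair of non-adjacent directed edges the exact
closed-form Gauss-integral contribution (the signed solid angle of the
tetrahedron spanned by the two segments, divided by $4\pi$) is evaluated
and the sum doubled. Adjacent edge pairs contribute exactly zero for
straight segments sharing a vertex and are excluded. Right-handed
crossings count positive, the standard knot-theory convention; a
right-handed α-helical window measures Wr ≈ +0.235 and its mirror image
the exact negative. The test suite retains an independent brute-force
double-quadrature evaluator of the Gauss integral and checks the closed
form against it on random segment pairs (composite Gauss-Legendre panels;
a single panel is not accurate enough when segments pass close to each
other).

## Alignment annotation and clustering

`cluster_alignment_columns()` maps per-residue descriptors onto the
columns of a multiple sequence alignment (sequences must match their
structures exactly; mismatches are reported with sequence name and
position) and clusters, per column, the present sequences on their
(κ, τ, Wr) vectors. Design choices, all exposed as arguments:

* complete-linkage agglomerative clustering, cut at height `cutoff`
  (default 1.0) — complete linkage bounds the diameter of a cluster,
  which is the natural notion of "a block of equivalent geometry";
* descriptors are standardized by the family's pooled mean/sd per
  descriptor, with unit weights by default, so the cutoff is in
  comparable units across families;
* per-column labels are deterministic (the cluster containing the first
  present sequence is label 1) and the label-to-colour map is a fixed
  palette, so the plain-text report and the PyMOL script are
  colour-consistent by construction;
* runs of fewer than `min_block_len = 3` consecutive columns with an
  identical partition are relabelled unclustered — single-column
  coincidences are not "blocks";
* columns with fewer than two present sequences, or any undefined mapped
  descriptor, are never labelled.

## Descriptor densities

`build_descriptor_pdf()` estimates, per environment class, a bivariate
Gaussian kernel density over (κ, τ) with Scott's-rule bandwidths
$h_k = \hat\sigma_k\, n^{-1/6}$ (floored at 1e-9 so zero-variance classes
stay well defined). The density evaluates deterministically, integrates
to 1 (checked numerically in the tests), and samples reproducibly under a
caller-supplied seed. Classes with fewer than 20 residues are skipped
with a warning — a kernel density on fewer points is not meaningful.
Propensity tables ship as a documented plain-text format (header of 20
amino-acid codes, one row per environment class) with a loader, writer
and row-normalization; the package deliberately contains no published
table values, only synthetic fixtures.

## The fixture generator

All tests and examples run on synthetic fixtures built in code:
ideal helices (α-helix defaults: radius 2.3 Å, rise 1.5 Å/residue,
100°/residue), straight lines (3.8 Å spacing), planar circles (default
radius 7.5 Å so the 0.5-radian sampling step stays within C-alpha bonding
distance), extended β-strand-like repeats (3.3 Å rise, 0.94 Å pleat),
planar zigzags, twisted cubics, and Gaussian-perturbed versions of any of
these with a seeded RNG (same spec + seed = byte-identical PDB). The
noiseless kinds carry closed-form truth tables of the smooth generating
curve where they exist.

What the fixtures do *not* emulate: real backbone irregularity
(loops, kinks, proline distortions), side-chain environments, crystal
contacts, missing density, or alternate conformations beyond simple
altloc records. Passing tests demonstrate the mathematics and the file
contracts; they do not validate any biological interpretation of
descriptor values on real structures.

## Problem sizes and determinism

The test suite and the acceptance script run entirely on fixtures at desk
scale: traces of 10–1000 residues, 200 random segment pairs for the
writhe oracle, 100 random rigid motions, 10^4 metric triples, families of
three structures. A 1000-residue trace is described in about one second
on a single core. Everything outside the explicitly seeded samplers is
deterministic; identical inputs give bit-identical descriptor tables, and
fixture generation restores the caller's RNG state.

## Known limitations

* PDB input only (no mmCIF) and C-alpha geometry only.
* Absolute κ/τ values depend on the standardized curve representation, as
  discussed above; they are directly comparable within and between
  protgeom analyses, but not with pipelines that use a different backbone
  parameterization (e.g. arc-length splines or quintic smoothing
  splines).
* Descriptor values within roughly three residues of a segment end feel
  the spline end condition; treat them with care.
* The alignment annotator consumes alignments; it does not compute them.
* No structure superposition is performed — the generated PyMOL script
  delegates `align` to the viewer.
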