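---
title: "Methods: geometric and network analysis of epithelial tessellations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geometric and network analysis of epithelial tessellations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epitess)
```

## The model of an epithelium

`epitess` treats a segmented epithelial monolayer as a planar tessellation:
cells are labeled pixel regions, an *edge* is the shared interface between
two cells, and a *vertex* a point where three or more cells meet.  In
generic (trivalent) tessellations every vertex has degree three, and the
Euler relation then forces the mean polygon class to be exactly six — so
the frequencies of cells with fewer and with more than six sides must
balance.  The package reports that balance deviation alongside the full
polygon-class distribution and cell-area morphometry.

Two samples with identical geometry statistics can still be organized
differently; the network view captures this.  The cell-contact graph (one
node per cell, one edge per touching pair) is profiled by the counts, per
node, of all 73 automorphism orbits of the 30 connected graphlets on two to
five nodes.  Two graphs are compared by the graphlet degree distribution
agreement distance (GDD): for orbit $j$, $d_j(k)$ counts nodes touching the
orbit $k \ge 1$ times, $S_j(k) = d_j(k)/k$, $N_j(k) = S_j(k)/\sum_k S_j(k)$,
and

$$D_j(a, b) = \frac{1}{\sqrt 2}\Big(\sum_k \big[N_j^a(k)-N_j^b(k)\big]^2\Big)^{1/2} \in [0,1],$$

aggregated (arithmetically by default) over a configurable orbit subset.
Orbits absent from both graphs are skipped; an orbit present in only one
graph contributes the maximal distance 1.

### Orbit numbering

The graphlet/orbit catalog is generated programmatically: graphs are
encoded as bit codes over node pairs, canonicalized by minimization over
all relabelings, and ordered by (node count, edge count, maximum degree,
degree sequence, canonical code); orbits within a graphlet are ordered by
degree, then neighbor-degree signature.  This reproduces the classic
numbering of orbits 0–14 exactly (orbit 0 is the node degree; orbit 3 the
triangle), which the tests assert.  For the 5-node orbits (15–72) the
package's canonical order may permute the traditional labels within ties; every statistic the package computes (GDD, triplets, MANOVA)
is invariant under orbit relabeling, so no result depends on the
convention.

Orbit counting runs in compiled code as a single-pass ESU enumeration of
connected induced subgraphs, each visited exactly once and classified via a
code lookup.  A deliberately independent brute-force oracle — exhaustive
subsets, connectivity test, classification by explicit permutation
minimization — recomputes the matrix in pure R, and the suite asserts
equality on random and lattice graphs.

## The reference scale

Samples are placed as triplets of GDD distances to three reference
patterns: a periodic hexagonal lattice, a random-seed Voronoi diagram
(iteration 0, i.e. before any relaxation), and the fifth noiseless Lloyd
iteration.  Realizing "random" as iteration 0 and "Voronoi-5" as iteration
5 follows the naming of the reference tool the field uses; the lattice uses
the nearest even-rows grid to the requested cell count.

The CVTn scale is an ensemble of noisy Lloyd paths: at each iteration every
seed moves to its cell centroid and is then displaced by an isotropic
vector of fixed length `noise_amplitude` × mean inter-seed spacing
(uniform random direction, amplitude fixed).  Noise is applied every
iteration.  The per-iteration ensemble mean traces a curve in triplet
space; the replicate spread provides a covariance.

**Noise amplitude.**  The amplitude is the one genuinely open parameter.
Measured on 200-seed paths, amplitudes near 0.5 × spacing overwhelm the
Lloyd contraction — the hexagon fraction does not rise and the distance to
the hexagonal reference does not fall, so the "scale" would not order
tessellations at all.  At 0.15 the path still orders (hexagon fraction
0.35 → ≈0.55, d_hex 0.76 → ≈0.66 before plateauing) while retaining
visible disorder, so 0.15 is the default; it is exposed on every entry
point.

**Off-path significance.**  Whether a sample lies on the CVTn path is
tested by a randomization procedure: the ensemble replicates at the
closest iteration define a Gaussian (mean, covariance; ridge-regularized
if near-singular), `n_draws` draws give the null distribution of
Mahalanobis distances, and the p-value is the fraction of draws at least
as extreme as the sample, with the usual $+1$ correction.  This is one
concrete realization of an ensemble-comparison idea that admits several;
the calibration test (p uniform for samples drawn from the ensemble)
pins its statistical behavior.  Group differences use MANOVA (Wilks'
lambda with the standard F approximation) on the three GDD coordinates —
the natural multivariate response here.

## Border interdigitation

Wavy, interdigitated borders are quantified two ways.  The *peak count* of
a border is the number of local extrema — of either sign, since fingers of
the two cells alternate, so one full sine period contributes two — of the
border's perpendicular deviation from its chord, counted when their
topographic prominence reaches a threshold.  The *redundancy index* is the
traced arc length divided by the chord (1.0 = straight).  Defaults:
deviation smoothing window 1 µm, prominence 0.5 µm, both exposed because a
human observer's counting criterion cannot be recovered exactly.

Pixel-chain borders are resampled at 0.25 µm and their coordinates smoothed
with a 4-pixel moving average before analysis.  This matters: a raw crack
boundary is a staircase whose arc length overestimates diagonal runs by up
to 27% and whose pixel-scale zigzag would register as spurious prominent
extrema.  With the smoothing, recovered peak counts match the synthetic
ground truth exactly on essentially all borders and redundancy indices
agree to about 0.01.

## The synthetic generator

Validation needs ground truth that real montages cannot supply, so all of
it is synthetic:

* Voronoi/Lloyd tessellations via half-plane clipping (compiled), bounded
  or periodic (periodic is the default for reference graphs since it has
  no boundary artifacts and is exactly trivalent); the quantization energy
  $\sum_i \int_{V_i} \lVert x - s_i\rVert^2\,dx$ is tracked and is
  non-increasing under noiseless Lloyd steps, which the tests assert.
  Degenerate lattices (square grids) are perturbed by $10^{-9}$ before
  tessellating to guarantee trivalent vertices.
* Wavy ground truth: sufficiently long shared borders are replaced by
  $A \sin(\pi p t)$ oscillations about the straight segment ($p$ extrema,
  amplitude $A$, random sign per border), with per-border truth records.
  Since the deviation vanishes at the endpoints, collisions can only occur
  mid-edge; amplitudes above 0.35 × the smallest centroid-to-edge
  clearance are rejected as self-intersecting.  Borders too short to carry
  the waveform stay straight with truth zero.
* Rasterization labels each pixel by its containing polygon (wrapped
  copies on periodic domains) and resolves numerically unclaimed border
  pixels to a labeled neighbor; label images round trip losslessly
  through 16-bit TIFF.  Fixtures default to 0.25 µm/px, a typical
  high-magnification camera sampling, so pixel artifacts sit well below
  the 0.5 µm prominence threshold.
* Boundary-stain rendering (bright ridges + Gaussian noise) validates the
  watershed stage: background flattening, median smoothing, ridge gain,
  grayscale closing to bridge gaps, and a tolerance watershed on the
  inverted ridge map (an h-minima style marker extraction).  On renders
  with noise at 10% of the ridge contrast the per-cell IoU against truth
  exceeds 0.9.

What the generator does *not* emulate: curved global anatomy, staining
inhomogeneity, segmentation errors other than additive noise, cell-size
gradients, and multi-layer regions.  Passing tests therefore certify the
measurement machinery on idealized monolayers, not robustness to every
imaging artifact.

## Quality control and exclusion rules

Gap pixels (label 0) represent discontinuities: any cell 4-connected to a
gap is excluded, and a montage whose gap fraction exceeds 8% of the raster
is rejected outright.  Cells touching the image border are flagged and
never enter polygon or area statistics, since their sidedness is
unknowable.  In the contact graph this cordon is graph-metric: nodes
within 4 edges (default) of a border- or gap-touching cell remain as
neighbors for counting but are excluded from graphlet degree
distributions.  Neighbor detection requires at least 3 shared boundary
pixel pairs under 4-connectivity, which rejects corner-point contacts;
polygon class is the neighbor count over *all* touching cells so QC does
not distort topology.

## Numerical choices and scales

* Adjacency symmetry is enforced after clipping (micro-edges at floating
  tolerance can be seen from one side only); ring areas must tile the
  domain to $10^{-6}$ relative.
* Ties in closest-CVTn selection resolve to the lowest iteration;
  zero-variance responses give $R^2 = 0$ in the peaks-vs-length
  regression.
* Rasterization preserves adjacency only for borders spanning at least the
  neighbor threshold (3 px); the round-trip tests therefore use
  tessellations whose shortest shared edge resolves to ≥ 4 px, a
  precondition checked from the geometry itself.
* Test and example problem sizes — a 196-cell reference set, 120–400-cell
  samples, scale ensembles of 3–20 replicates over tens of iterations,
  100-iteration Lloyd paths — are the package's default desk scale; the
  full-protocol sizes (700 iterations, 20 replicates, >1000-cell
  montages) are plain parameter changes.

## Known limitations

* The graphlet exclusion list ("redundant or biologically implausible"
  graphlets) is configuration, not code: the default uses all 73 orbits,
  and any subset can be passed everywhere a GDD is computed.
* The watershed stage is a reasonable re-creation of a commercial recipe
  described only in outline; it is validated against synthetic renders,
  not against the original software.
* Sub-pixel vertex localization is out of scope: vertices sit on the pixel
  corner lattice.
* `brute_force_orbits` is limited to 60 nodes by combinatorial cost; it is
  a testing oracle, not a production counter.
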