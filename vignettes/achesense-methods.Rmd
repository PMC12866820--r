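---
title: "Methods: colorimetric AChE biosensing and framework morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: colorimetric AChE biosensing and framework morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(achesense)
```

## The assay and its models

An Ellman-type AChE biosensor reads pesticide concentration through
enzyme inhibition: AChE hydrolyzes acetylthiocholine, the thiocholine
product turns DTNB into yellow TNB (412 nm), and an organophosphate
inhibitor suppresses that color in a dose-dependent way. This package
implements the four computational layers such a study needs.

### Color digitization

A smartphone photograph of an assay well is reduced to one RGB triple —
the per-channel arithmetic mean over a rectangular ROI — and then to a
scalar color index. The catalog covers the single channels R, G, B,
their sum, the three pairwise ratios (`G/(R+B)` and its permutations),
BT.601 grayscale, and the HSV components. Two conventions matter and are
fixed deliberately:

* Indices are computed **on the ROI-mean channels**, not averaged over
  per-pixel indices. The mean triple is what a plate reader of pixels
  would report, and a ratio of means is far less noise-sensitive than a
  mean of ratios. (The per-pixel variant exists only inside
  `pseudo_color_map()`, whose purpose is visualization.)
* Channel means stay fractional; rounding to 8-bit before the index
  would inject quantization bias into the calibration.

A ratio index with an exactly zero denominator is a hard error, not an
epsilon-padded value: a patch with R + B = 0 means broken acquisition,
and silently distorting it would corrupt the calibration invisibly.
Grayscale uses the BT.601 luma weights (0.299, 0.587, 0.114), the
default of common imaging software. ROI rectangles are 0-based and
half-open, `[x0, x1) × [y0, y1)`. 16-bit TIFF samples map to 8-bit by
integer division by 257 so that 65535 lands exactly on 255.

### Calibration, quantification, LOD

The concentration-response model is log-linear, `y = a·log10(c) + b`,
fitted by unweighted ordinary least squares ("log" is read as log10 —
the decade-spaced concentration series make any other base
unnatural; no replicate variances are available to justify weights).
Blanks (c = 0) are excluded from the fit — the regressor is undefined
there — and serve only the detection limit. Responses may be negative:
the index is interpreted on a difference-map scale, so no sign
constraint or clipping is applied before fitting. A response constant in
concentration has SS_tot = 0; its R² is reported as 0 (not NaN) so that
algorithm rankings stay total, and its slope is forced to exactly zero
rather than left at least-squares roundoff.

Quantification inverts the line, `c = 10^((y − b)/a)`, flagging
predictions outside the fitted range as extrapolations. The detection
limit uses the k·σ blank convention (k = 3 by default): the critical
response is the blank mean displaced by k blank standard deviations in
the direction of the slope, projected through the calibration. At least
three blank replicates are required — a standard deviation from fewer is
not an estimate. `compare_algorithms()` ranks indices by ascending LOD,
ties by descending R², then by name, with zero-slope indices assigned an
infinite LOD so they sort last.

The inhibition-efficiency readout is
`IE% = (A − A1)/(A − A0) × 100`; it is invariant under any common affine
rescaling of the three absorbances, which the tests assert numerically.

### Point-spacing morphometry

Framework porosity is scored from junction points on micrographs:
Delaunay triangulation (no input point inside any triangle's
circumcircle), Euclidean edge lengths as inter-point distances, and the
mean length of retained edges as the spacing statistic — shorter spacing
reads as a denser, more porous surface. When a field contains many
discrete particles, the triangulation necessarily bridges them with long
spurious edges; the correction fits a normal distribution to all edge
lengths (sample mean, n−1 standard deviation) and prunes, in a single
pass, every edge longer than μ + z₀.₉₇₅σ (z = 1.959964).

The phrase "upper bound of the 95% confidence interval" admits two
readings, and the choice matters. The interval **of the mean**
(μ + 1.96σ/√n) shrinks with the number of edges; on a large mesh it
converges to the mean itself and would prune nearly half of all genuine
edges — the opposite of a correction aimed at rare, erroneously long
connections. The upper **quantile of the fitted normal** (μ + 1.96σ)
targets exactly the tail where spurious edges live, so it is the
default; the mean-CI variant remains available via
`prune_edges_ci(..., method = "mean_ci")` for comparison. Pruning is
single-pass by design: the threshold is computed once on all edges and
applied once, mirroring a one-step artifact correction rather than an
iterative trimming scheme (which would need its own stopping theory).

Duplicate points are rejected at ingestion — zero-length edges would
drag the normal fit toward zero and poison the threshold. Cocircular
degeneracies (four points of a square) accept either diagonal; tests
assert only edge counts and length multisets valid for both. Junction
detection on images is a deliberately simple local-maxima detector
(strict 8-neighborhood maximum, relative intensity floor, greedy
minimum-distance suppression, brightest first); how junction points were
marked on real SEM images is not specified by the underlying protocol,
and manual marking is common, so the detector is a convenience surrogate
whose output can always be replaced by a point CSV.

One caveat of the separation guarantee: it presumes the spurious edges
are a minority of the edge population. If inter-particle edges approach
~20% of all edges (many small particles in one frame), they inflate μ
and σ enough that the threshold can drift into the inter-particle length
range. The tests therefore exercise fields where genuine edges dominate,
which is the regime the statistic is meant for.

### Enzyme kinetics

The Michaelis–Menten law `v = Vmax·S/(Km + S)` is fitted directly by
Levenberg–Marquardt nonlinear least squares on the untransformed model —
a Lineweaver–Burk double-reciprocal fit would weight the smallest,
noisiest rates most heavily. Starting values are Vmax₀ = max(v) and
Km₀ = median(S); convergence is a relative residual-sum-of-squares
change below 1e-10 within 500 iterations, with box constraints keeping
both parameters non-negative. Non-convergence returns a flagged fit, not
an error; rate sets dominated by non-positive values are rejected as not
Michaelis–Menten data. Simulated substrate grids span 0.2×Km to 20×Km
(log-spaced, 10 points by default): sampling well below and well above
half-saturation is what makes Km and Vmax jointly identifiable.

## The synthetic-data generator

The generator produces every input the pipeline consumes, with recorded
ground truth. Its defaults are the study conditions of the assay being
modeled:

| Parameter | Default | Units | Why |
|---|---|---|---|
| calibration slope `a` | 0.823 | response per decade | reference G/(R+B) line |
| calibration intercept `b` | 0.745 | response | reference G/(R+B) line |
| concentration grid | 8 points, 0.05–500 | ng/mL | full working range, log-spaced |
| response noise sd | 0.05 | response | replicate scatter of a few % of the dynamic range; not stated by the protocol, declared here |
| inhibition IC50 / Hill slope | 5 / 1 | ng/mL / — | no functional form is given for the dose-response; a unit-slope logistic centered inside the range spans it smoothly |
| absorbance A, A0 | 1.0, 0.1 | AU | typical 412 nm Ellman window |
| Km (composite / free / crystalline host) | 0.04645 / 0.02955 / 0.2015 | mmol/L | reference substrate affinities |
| particle field | lattice clusters, inter/intra > 3 | px | creates the spurious-edge failure mode the pruning exists for |

Noise is additive Gaussian on the response or absorbance scale — the
simplest model consistent with unspecified error bars. Every generator
takes one explicit integer seed and restores the global RNG state
afterwards; a fixed seed reproduces output byte for byte.

The image renderer encodes a response into a solid patch with fixed
R = B = 100 and `G = round((gain·y + offset)·(R+B))`, an affine
convention chosen so that the G/(R+B) index inverts it exactly up to
8-bit quantization (decode error ≤ 1/(400·gain)). It is explicitly *not*
a spectral model of the TNB chromophore: no Beer–Lambert rendering, no
illumination or white-balance variation, no ROI localization error.
Consequently, passing recovery tests demonstrate correctness of the
digitization → calibration → inversion chain, not robustness to the
photographic nuisances a real smartphone assay faces. The same is true
of the point-field generator: lattice clusters with optional Gaussian
jitter emulate the geometry of junction fields, not SEM texture,
focus gradients or detector noise.

A note on the response scale: the reference calibration line crosses
zero near 0.13 ng/mL, so raw channel ratios (non-negative by
construction) cannot literally follow it at the low end. The generator
therefore treats y as an abstract difference-map response, and the image
encoding shifts it affinely into the valid channel range. Parameter
recovery stays faithful to the printed line while every rendered image
remains a legal 8-bit PNG.

## Numerical and testing choices

* OLS estimates are checked against the closed-form normal equations at
  1e-10; the triangulation is checked against a brute-force
  empty-circumcircle construction for n ≤ 12; ROI means against a naive
  pixel loop; edge lengths against direct pairwise distances.
* Monte-Carlo problem sizes: 200 calibration replicates (noise sd 0.05,
  8 concentrations) for slope bias and 95% CI coverage; 500 kinetics
  replicates at 2% rate noise for median Km recovery. These sizes give
  Monte-Carlo standard errors comfortably below the asserted bounds
  while keeping the default suite around a few seconds.
* Scale equivariance (coordinates ×k scale spacing and threshold ×k) and
  rigid-motion invariance are asserted at 1e-9; HSV roundtrips at one
  8-bit count.
* The CI-coverage band [90%, 99%] is asymmetric around 95% on purpose:
  with 200 replicates the binomial fluctuation of a nominal 95% interval
  stays well inside it, so an excursion indicates a real error model
  mismatch, not sampling noise.

## Command-line use

`run_pipeline()` wires simulate → render → extract → calibrate → LOD
from a schema-validated YAML config (unknown keys are rejected by name;
missing required keys name themselves; all randomness flows from
explicit seeds; each run writes a log with package version, config hash
and seed). `inst/cli/achesense.R` is a thin Rscript wrapper exposing
`simulate`, `extract`, `calibrate`, `quantify`, `spacing`, `kinetics`
and `demo` subcommands with exit codes 0 (ok), 1 (runtime failure), 2
(config error). All functionality is available — and tested — through
the package functions; the wrapper adds no logic.

## Known limitations

* The LOD convention (k·σ of blanks through the calibration) is one of
  several in use; no attempt is made to reverse-engineer which
  convention produced any particular published detection limit.
* Wet-lab observables — activity retention percentages, fold-change
  enhancements, spike-recovery rates, storage stability — are
  measurements, not computable quantities; the package only provides the
  arithmetic (`relative_activity()`, `inhibition_efficiency()`) that
  processes such measurements.
* The junction detector assumes bright, roughly isotropic blobs; real
  SEM junction marking may be manual and is not emulated.
* Delaunay degeneracies beyond cocircularity (e.g. exactly duplicated
  points) are rejected rather than resolved.
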