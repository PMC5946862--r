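---
title: "Mapping DNA minor groove width from hydroxyl radical cleavage electropherograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping DNA minor groove width from hydroxyl radical cleavage electropherograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grooveprint)
```

## The measurement

Hydroxyl radicals cleave the DNA backbone by abstracting deoxyribose
hydrogens, and the cleavage rate at each nucleotide tracks the solvent
accessibility of the sugar — which in turn tracks the width of the minor
groove at that position. When a singly end-labeled duplex is cleaved
under single-hit conditions and the fragments are separated by capillary
electrophoresis, the fluorescence trace is a train of peaks, one per
fragment length, whose areas are proportional to per-position cleavage
probability. Averaging the two strands' normalized cleavage values
across the minor groove (the two positions staggered 3 nt toward the
partner strand's 3' end face each other directly across the groove)
yields the ORChID2 pattern, an experimental per-nucleotide proxy for
minor groove width. `grooveprint` implements everything downstream of
the instrument: trace deconvolution, per-position normalization, adenine
calling from a deuterated sample, cross-strand averaging, smoothing, a
geometric groove-width calculation from duplex coordinates,
pentamer-model prediction, and rank-correlation comparison of profiles.

## Signal model and the three-pass fit

An electropherogram channel is modeled as a baseline plus a sum of
Gaussians,

$$G(x) = b + \sum_{i=1}^{n} a_i \exp\!\left(-\tfrac12
\left(\frac{x - c_i}{w_i}\right)^2\right),$$

with amplitude $a_i \ge 0$, center $c_i$ (data-point index) and width
$w_i > 0$ per peak. Baseline handling is deliberately simple: the global
minimum intensity is subtracted from every sample, and $b$ is then held
at zero during fitting.

The size-standard ladder anchors the fit. Ladder apexes are found by a
simple local-maximum detector with a sensitivity threshold expressed as
a fraction of the global maximum; the trace is first lightly smoothed
(5-sample moving average) and candidate maxima closer than 10 data
points to a taller one are suppressed, because after global-minimum
subtraction the noisy baseline sits a few standard deviations above
zero and would otherwise contribute spurious apexes. Detected centers
are paired with the known ladder lengths in rank order, the ladder is
fit jointly as a Gaussian sum, and fitted width is regressed linearly on
fitted center. Initial widths for the ladder fit come from each apex's
half-maximum crossing — a coarse width initialization (e.g. a fixed
fraction of the peak spacing) can drag an end peak into a wrong local
minimum and corrupt the width regression.

Cleavage peaks are initialized from the ladder: centers by linear
interpolation in fragment length between bracketing ladder peaks (no
extrapolation outside the ladder span), amplitude as the trace value at
the rounded center, width from the ladder width regression. The fit then
proceeds in three passes over sliding windows (default 600 data points,
roughly 40–60 peaks, stepped by 300):

1. amplitude, center and width all free, after which the
   width-versus-center regression is refreshed globally across all
   fitted peaks;
2. amplitude and center free with each width box-bounded inside the 95%
   prediction interval of that regression (a width that is *constrained*
   but immobile would make this pass identical to the next, so the width
   stays a bounded free parameter);
3. amplitude and center free with widths held fixed.

Each window's first and last five fitted peaks are discarded and
retained from the overlapping neighbor window; peaks near the trace ends
that are only ever edge peaks keep the single available estimate and are
flagged. The optimizer is bounded Levenberg–Marquardt
(`minpack.lm::nls.lm`) with the analytic Jacobian, $a \ge 0$, $w > 0$,
$c$ within half the inter-peak spacing of its initialization, cost
tolerance $10^{-8}$, and at most 200 iterations per window;
non-convergence in any window is an error naming the window. With fewer
than three peaks the width regression is undefined and pass 2 falls back
to free widths.

Each optimized peak is integrated by the trapezoidal rule at unit grid
step over $c \pm 6w$ truncated to the trace (the $\pm 6w$ reading of
"the entire fitted range" was chosen over the window because it makes
the area independent of where window boundaries happen to fall). Areas
are normalized within consecutive non-overlapping 50-nt blocks by the
block median — the only reading under which the median normalized area
in every block equals 1.000 exactly, which the package asserts at
machine precision — preserving each peak's dynamic range.

## Nucleotide assignment

A second sample PCR-amplified with 5',5''-dideuterated dATP cleaves
roughly two-fold more slowly at adenines. The ratio of deuterated to
normal *normalized* area (normalized, so separate reactions with
different loadings compare cleanly) is thresholded at 0.75 — midway
between no effect (1.0) and the ~0.5 isotope effect — to call adenines.
The calls are then registered onto the known sequence by scanning
offsets within ±10 of the nominal labeling registration (fragment
length $k$ = strand position $k$) for the maximum agreement between
called and actual adenine positions; peaks pushed outside the sequence
by an offset count as disagreements, which breaks the degenerate ties a
ratio-of-matches score allows. Registration below 0.9 agreement is an
error. All peaks are finally labeled by reading the sequence.

## ORChID2 construction

With both strands' profiles keyed by forward coordinates (a
reverse-strand fragment of length $k$ maps to forward coordinate
$L - k + 1$), the cross-strand average is a pure index shift:
$\mathrm{ORChID2}(i) = \tfrac12\,(\mathrm{fwd}(i) + \mathrm{rev}(i +
\delta))$. The reverse strand's 3' direction runs toward decreasing
forward coordinates, so the default stagger is $\delta = -3$; the sign
is configurable because the direction convention, not the signed offset
in a shared frame, is what the underlying geometry fixes. Positions
missing either partner are absent from the output, never zero-filled.

Smoothing is minimal loess (`stats::loess.smooth`, locally linear,
tricube weights, Gaussian family) with span 0.015 evaluated at 300 grid
points and mapped back to integer positions by linear interpolation,
applied to the averaged ORChID2 profile only — never to single-strand
profiles. At these parameters a linear profile is reproduced to well
below $10^{-6}$, so the smoother cannot invent trends.

## Groove width from coordinates, and from sequence

From 3D coordinates, minor groove width is computed geometrically: for
each forward-strand phosphate, the minimum distance to an
opposite-strand phosphate whose paired position lies within ±5 bp,
minus 5.8 Å for the two phosphate groups' van der Waals extent,
clamped at zero. Each minimum-distance pair contributes to the midpoint
position (rounding half down — the assignment rule is this package's
choice), and contributions to the same position are averaged. This is
an intentionally simple geometric measure, not a curvilinear
helical-axis analysis: it has no notion of groove direction, so on
strongly bent or locally melted duplexes it can pick a cross-strand
pair that does not span the minor groove. The ±5 bp stagger cap
suppresses spurious minima at duplex ends. `ideal_backbone()` generates
a synthetic straight B-form phosphate helix for tests and examples; its
default strand phase (138°) was set once so the interior groove width
lands near the canonical ~5.8 Å.

From sequence, `predict_pentamer_mgw()` slides a 5-nt window and
assigns each pentamer's table value to its central position, covering
positions $3..L-2$. The table is pluggable (two-column TSV, optional
reverse-complement closure), so any externally derived pentamer model
can be used; `toy_pentamer_table()` is a synthetic stand-in whose
widths narrow with A/T content, for tests only.

## Comparison statistics

Profiles are compared by Spearman's $\rho$ (mid-ranks for ties) over
the intersection of defined positions within each site window, with
significance from the standard approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ degrees of freedom,
two-sided by default (the sidedness convention is not forced by the
method; one-sided is available). Stars follow the ladder
$\alpha = 0.1$ (\*), 0.05 (\*\*), 0.01 (\*\*\*), 0.001 (\*\*\*\*).
Sites with fewer than three common positions are excluded with a
warning, and the cross-site summary is the unweighted mean of per-site
$\rho$. For overlay plots, `calibrate_scale()` fits the least-squares
affine map from ORChID2 units to Å over a reference window (a naked-DNA
reference duplex with crystallographically known widths, such as the
Drew–Dickerson dodecamer); being affine, it cannot change any rank
statistic, which the test suite asserts.

## The simulator: what it emulates, and what it does not

`sim_spec()`/`simulate_trace()` generate ladder and cleavage channels
with full ground truth. Migration is affine-plus-quadratic in fragment
length (defaults $c(\ell) = 50 + 11\ell + 2\times10^{-4}\ell^2$ data
points, giving the ~11-point peak spacing and slowly stretching ladder
a CE run shows); peak width grows linearly with data point
($w = 3 + 3\times10^{-4}c$); true intensities are user-supplied (tests
use log-normal values around 100 with $\sigma_{\log} = 0.4$, a
realistic cleavage dynamic range); noise is additive Gaussian per
sample (default sd 1, i.e. ~1% of a typical amplitude) plus independent
per-peak 5% amplitude jitter; the deuterated variant multiplies
adenine amplitudes by $f_D = 0.5$. A fixed seed reproduces a trace bit
for bit; normal/deuterated pairs representing separate reactions use
separate seeds. Not modeled: electrophoretic physics, dye mobility
shifts, signal saturation or decay, incomplete denaturation, and
single-hit kinetics violations — so green tests demonstrate that the
algorithmic chain is faithful under its stated signal model, not that
it is robust to every instrument artifact.

## Problem sizes and numerical choices

The test suite validates the fit on a noiseless 50-peak trace
(parameter recovery within $10^{-3}$ relative), a 200-peak trace at 1%
additive noise (center RMSE below half a data point), a 100-seed
adenine-calling study at 5% amplitude noise (exact precision and recall
in ≥95% of seeds; this study isolates the calling stage by building
peak sets from simulator ground truth areas, the fitting stage being
covered separately), and a 300-nt two-strand end-to-end run whose
recovered ORChID2 profile rank-correlates at $\rho \ge 0.99$ with the
profile computed directly from the true intensities. Exhaustive
permutation checks (all orderings of $n \le 6$) pin the rank
correlation to the closed-form $1 - 6\sum d^2 / (n(n^2-1))$.

Known limitations: fragments outside the ladder span are refused rather
than extrapolated; the groove calculation is geometric, as above; no
dye mobility-shift correction is applied between channels; and no
multiple-testing correction is applied across sites (each site is
reported with its own $P$).
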