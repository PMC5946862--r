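# grooveprint

Nucleotide-resolution mapping of DNA minor groove width from hydroxyl
radical cleavage electropherograms.

Hydroxyl radicals cleave the DNA backbone at a rate set by the solvent
accessibility of each deoxyribose, which tracks the local width of the
minor groove. When a singly end-labeled duplex is cleaved under
single-hit conditions and run on a capillary sequencer, the fluorescence
trace is a train of Gaussian peaks — one per fragment length — whose
areas report per-position cleavage. `grooveprint` turns a pair of such
traces (one per strand) into the experimental **ORChID2** profile, a
per-nucleotide proxy for minor groove width, and compares it against
groove widths measured from co-crystal structures or predicted by
pentamer sequence models. The package is aimed at structural
bioinformaticians and nucleic-acid chemists doing quantitative
footprinting.

## What it computes

The trace is modeled as a baseline plus a sum of Gaussians,

> G(x) = b + Σᵢ aᵢ · exp(−½ ((x − cᵢ)/wᵢ)²),

fit in three passes over sliding 600-point windows (amplitude/center/
width free; widths bounded inside the 95% prediction interval of the
width-vs-position regression; widths fixed), with the first and last
five peaks of each window discarded in favor of the overlapping window.
Peak areas (trapezoidal, ±6w) are normalized by the median within
consecutive 50-nt blocks, so every block's median cleavage value is
exactly 1.000. Adenines are called from a 5′,5″-dideuterated sample
(cleavage drops ~2-fold at adenines; ratio threshold 0.75) and
registered onto the known sequence. The two strands are averaged across
the minor groove — position *i* with the partner strand's position
staggered 3 nt toward its 3′ end:

> ORChID2(i) = ½ · (fwd(i) + rev(i − 3)),

optionally loess-smoothed (span 0.015, 300 evaluation points). Groove
width from 3D coordinates is the minimum cross-strand phosphate
distance minus 5.8 Å of van der Waals radii; profiles are compared by
Spearman's ρ with t-approximation significance and the star ladder
α = 0.1 (\*), 0.05 (\*\*), 0.01 (\*\*\*), 0.001 (\*\*\*\*).

A synthetic-electropherogram simulator with full ground truth
(`sim_spec()`, `simulate_trace()`, `simulate_deuterated()`) makes the
whole chain testable without instrument data.

## Worked example

Simulate both strands of a 120-bp duplex, fit the traces, build the
ORChID2 profile, and check it against the profile implied by the
planted cleavage intensities:

```r
library(grooveprint)
set.seed(20)
seqd <- duplex_sequence(paste(sample(c("A","C","G","T"), 120, TRUE),
                              collapse = ""))
lad <- seq(10, 110, by = 10)
run_strand <- function(strand, seed) {
  set.seed(seed + 1000)
  inten <- exp(rnorm(119, log(100), 0.4))
  spec <- sim_spec(seqd, strand = strand, intensity = inten,
                   fragments = 10:110, ladder = lad,
                   noise_add = 1, noise_mult = 0.05, seed = seed)
  sim  <- simulate_trace(spec, "cleavage")
  ladt <- simulate_trace(spec, "ladder")
  fit  <- fit_channel(sim$trace, ladt$trace, lad, 10:110)
  list(rec = peaks_to_profile(fit, strand, seqd),
       tru = peaks_to_profile(
         normalize_areas(peakset_from_truth(sim$truth)), strand, seqd))
}
f <- run_strand("forward", 1); r <- run_strand("reverse", 2)
recovered <- exp_orchid2(f$rec, r$rec)   # fitted from the noisy traces
planted   <- exp_orchid2(f$tru, r$tru)   # directly from ground truth
sites <- list(site_annotation("left", 15, 45),
              site_annotation("mid", 46, 75),
              site_annotation("right", 76, 105))
compare_sites(recovered, planted, sites)
```

```
   site  n       rho         t            P stars
1  left 31 0.9979839  84.67737 2.766413e-36  ****
2   mid 30 0.9991101 125.34553 4.755359e-40  ****
3 right 30 0.9973304  72.27154 2.250028e-33  ****
mean rho over 3 sites: 0.998
```

Each row is one site window: `n` paired positions, Spearman's `rho`
between the two profiles, the t statistic and two-sided `P`, and the
significance stars. Here the deconvolution recovers the planted
cleavage pattern essentially perfectly (ρ ≈ 0.998 under 1% sample
noise and 5% peak amplitude jitter); with real data the same table
quantifies how well a naked-DNA ORChID2 pattern matches the groove
geometry seen in a protein–DNA complex. The bundled 399-bp study insert
is available as `insert_399()`.

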