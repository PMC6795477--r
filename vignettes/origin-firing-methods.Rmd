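---
title: "Models and methods behind originfire"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind originfire}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(originfire)
```

`originfire` studies replication-origin firing efficiency in budding yeast
with two population readouts — marker frequency analysis of sequencing
depth, and ssDNA profiling of hydroxyurea-stalled forks — plus a stochastic
per-cell simulator that generates both from known ground truth. This
vignette explains the models, the parameters that matter, the numerical
choices, and what the synthetic data can and cannot establish.

## The per-cell firing and fork model

Each origin carries three parameters: a *competence* `c` in [0, 1] — the
intrinsic probability that the origin assembles everything needed to fire
in a given cell cycle — and a firing-time distribution Normal(`t_mean`,
`t_sd`) truncated at zero, in minutes into S phase. Competence is
deliberately distinct from observed *efficiency*: a fully competent origin
may still be passively replicated by a fork arriving from a neighbour
before its own scheduled time, and then contributes no initiation.

Passive replication is resolved by a first-arrival rule. Fired-origin
candidates are processed in firing-time order (ties broken by coordinate);
a candidate at position `x` scheduled at time `t` is demoted to passively
replicated if any already-fired origin `j` satisfies
`t_j + |x - x_j| / v <= t`, with `v` the fork speed. Because replicated DNA
is the union of fork sweeps, first arrival is exact no matter where
converging forks actually meet, so no event queue of fork collisions is
needed. In hydroxyurea the demotion step is disabled: forks stall within a
few kb and never reach a neighbouring origin.

Fork progression is deterministic at `fork_speed` (default 1.5 kb/min, a
mid-range yeast fork rate). In HU mode a per-cell dNTP budget `D` (kb) is
split equally over the `2k` forks of a cell that initiated `k` origins, so
each fork travels at most `d_max = D / (2k)`. This is the simplest
functional form that makes "fewer active origins per cell, farther travel
per fork" quantitative, and it is exact in the package's tests: halving the
number of fired origins doubles the cap.

### Why the HU defaults look the way they do

`hu_sim_params()` scales the budget to 24 kb of synthesis per Mb of genome
(about 2.5% of the genome replicated before forks stall). With the
wild-type-like fixture density of ~8 origins per Mb and typical competences,
a cell initiates ~6 origins per Mb, so forks stall ~2 kb from their origin.
The ssDNA footprint of a stalled fork is modelled as a Gaussian with
`ssdna_footprint_sd = 2000` bp. Two fork footprints at ±s merge into a
single mode exactly when `s <= sd`; the defaults therefore put an
unperturbed early sample just inside the single-peak regime, and any
perturbation that reduces initiation per cell (raising `d_max`) pushes
peaks into the split regime. That geometry — single centered peaks in the
reference, splitting under depletion — is the qualitative behaviour the
assay is known for, and it emerges from the budget model rather than being
drawn directly.

The asynchronous-population mix for marker frequency is (G1, S, G2) =
(0.3, 0.5, 0.2), a log-phase culture enriched in S-phase cells; S-phase
cells are sampled uniformly over an `s_duration` of 50 minutes. Pooled
copy number per 1 kb bin then lies on the G1-normalized marker-frequency
scale [1, 2] by construction.

### The tandem-array (rDNA-like) model

The rDNA is modelled separately because its replication is effectively
unidirectional: the replication fork barrier blocks forks moving against
35S transcription, so each initiation contributes one productive fork
moving toward the next repeat. Each of `n_repeats` repeats (9 kb) fires
independently with probability `p_fire`; a span between consecutive
initiations is completed only if the upstream fork covers it within the
time budget, and one extra fork enters at the array's left edge standing in
for the last flanking unique-sequence origin. Mean spacing between active
origins is `repeat_len / p_fire` analytically — 45 kb at the wild-type
1-in-5 firing rate — and the Monte-Carlo mean converges to it; note that
short arrays under-sample long gaps, so the empirical mean on a 90-repeat
array sits a few percent below the analytic value, while the ~250-repeat
wild-type array agrees within ~2%. Completion probability collapses as
`p_fire` falls (`analysis/05_rdna_model.R` tabulates this), which is the
mechanistic reading of why a long array of identical inefficient origins
is the first casualty of reduced initiation.

## Noise models, and what they do not emulate

Sequencing depth is Poisson per bin at `mean_depth × copy number`, with
~800 reads per 1 kb bin representing a 10-million-read sample. Microarray
ratios get multiplicative log-normal noise (`log_sd = 0.1`, a ~10%
coefficient of variation) plus rare extreme spikes (rate 0.001, 30–100×
the genome mean) so the outlier filter has realistic work. Probe positions
are a jittered ~1 kb grid.

Not emulated: mappability structure (the real pipeline masks subtelomeres,
Ty elements and ohnologs from curated lists — the masking operation is
implemented, the lists are inputs), probe-specific hybridization biases,
checkpoint suppression of late origins in HU (perturbations act only
through competence and firing-time parameters), replisome biochemistry,
and rDNA fork-barrier pausing beyond unidirectionality. Passing the
synthetic tests therefore shows the *pipeline arithmetic and the
inferential logic* are sound on data whose generating process is known; it
does not validate the biological parameter values themselves.

## Pipeline numerical choices

**LOESS.** Both smoothers are tricube-weighted local *linear* regressions
with a fixed bandwidth in bp (window = full width; weights vanish at
±window/2), not a fraction-of-data span: 50 kb for marker frequency on 1 kb
bins, 6 kb for ssDNA probes onto a 0.25 kb output grid (9 kb for noisier
overexpression-like samples). Local linear with a fixed genomic bandwidth
keeps the smoother's resolution uniform along the chromosome and
reproduces straight lines exactly. Missing values are excluded per local
fit; a fit with fewer than 3 contributing points returns missing. Each
evaluated point is checked in tests against an independent brute-force
weighted `lm()` to 1e-9.

**Outlier filter.** Mean and sample (n−1) SD are computed once genome-wide
before any removal; values above mean + 8 SD or below mean − 2 SD are
dropped. The asymmetry reflects that hybridization artifacts spike high
while the informative signal sits just above baseline.

**Rescaling.** The baseline is the mode of all smoothed values, estimated
as the argmax of a Gaussian kernel density with Silverman's rule-of-thumb
bandwidth (`bw.nrd0`); the transform maps baseline to 1 and the
genome-wide maximum to 2 and is affine, hence rank-preserving, so
within-sample peak ranking is unaffected by it.

**Peak calling.** Raw peaks are interior grid points where the first
difference changes sign from positive to negative; significance is the top
5% of raw peak heights (the 95th-percentile threshold, ranked by smoothed
height — the only per-peak scalar available before areas exist). The
single-instance shoulder exclusion is generalized into a rule: significant
peaks closer than 5 kb are merged keeping the taller, leftmost on ties, so
behaviour is defined for all inputs. Peak calling operates on smoothed but
un-rescaled values; rescaling precedes window extraction and areas. Note an
arithmetic consequence of the top-5% rule: the number of significant peaks
is ~5% of all raw maxima, so it recovers a true origin set only when
origins are roughly that fraction of local maxima — which is the case at
realistic noise densities (tens of small baseline maxima per origin).

**Windows and areas.** Windows are inclusive of both endpoints (41 grid
points for 10 kb at 0.25 kb; 65 for the 16 kb variant), centers snap to the
nearest grid point, and missing points contribute the baseline value 1.0
with their count recorded. Coordinates are 1-based inclusive internally;
conversion to 0-based half-open happens only at BED/bedGraph boundaries.

**Residual diagnostics.** The regressions of per-origin areas report a
sign-runs (Wald–Wolfowitz) z-statistic on residuals in fitted-value order
and a curvature p-value (F-test for adding a quadratic term). The naive
choice — correlating residuals with fitted values — is identically zero for
any OLS fit with an intercept, so it cannot carry the signal; it is still
reported for transparency. Uniform competence scaling leaves both
diagnostics unremarkable; depletion biased against weak origins (modelled
as a sigmoidal competence map in which origins below competence ~0.8 are
severely compromised, per the observed phenotype of Sld3 loss) produces a
negative runs z and small curvature p; fully equalized competence
decorrelates areas from a variable-competence reference.

## Problem sizes

The test suite and acceptance script run everything at desk scale, chosen
to keep Monte-Carlo error well inside the asserted margins: 1 Mb
chromosomes with 8 origins each (1, 3 or 5 chromosomes), 400–800 cells per
ssDNA condition, 2000–2500 cells for marker-frequency pooling, 10,000 cells
for rDNA spacing, and 50,000–100,000 for tail probabilities. Origin
localization from the noisy sequencing pipeline is asserted at 5 kb — at
10-million-read depth the smoothed apex of a marker-frequency peak jitters
by a few kb because the post-smoothing noise is comparable to the profile's
slope — while localization from pooled noiseless profiles and from the
ssDNA pipeline is asserted at 2 kb and 1 kb respectively.

## Known limitations

* Efficiency changes are modelled through competence only; the data the
  package is designed around cannot distinguish reduced competence from
  extended firing-time staggering, so both knobs exist but the shipped
  scenarios vary competence.
* The top-5% significance rule ties the significant-peak count to the raw
  maxima count; on genomes whose origins are a much larger fraction of
  local maxima the threshold will clip true origins.
* The dNTP budget model is an idealization: equal division among active
  forks, no fork death, no checkpoint feedback.
* Tornado color scales are shared within a sample group as ranges; no
  rendering beyond simple base-graphics output in the analysis scripts is
  provided.
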