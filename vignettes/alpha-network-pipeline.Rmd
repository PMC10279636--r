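---
title: "Alpha-band phase-locking networks: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alpha-band phase-locking networks: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis in one paragraph

`alphanet` implements a parcel-level EEG connectivity analysis for a
within-subject design in which faces carrying one of four emotional
expressions (fear, sad, happy, neutral) are processed either *overtly*
(categorise the expression) or *covertly* (attend to a colour patch on the
face).  For every subject x condition x emotion cell, alpha-band (8-12 Hz)
phase-locking values (PLV) between all pairs of 148 cortical parcels
(Destrieux atlas) form a connectivity matrix; the 20% strongest connections
are retained; and three statistics summarise the thresholded weighted
graph: modularity Q (how segregated the network is), global efficiency
(how integrated it is) and the routing efficiency between the core and
extended systems of the face-processing network (how well the two
subsystems communicate).  A linear mixed-effects model with condition,
emotion and their interaction as fixed effects and a subject random
intercept tests each metric, with Satterthwaite F tests and
Benjamini-Hochberg-corrected pairwise contrasts.  Because raw EEG for the
original design is not publicly available, the package ships a synthetic
generator of phase-coupled oscillations whose coupling structure is fully
controlled, so every stage can be validated by parameter recovery.

## The generator: von Mises phase coupling

Each node carries a 10 Hz cosine of amplitude $A$ plus Gaussian sample
noise.  Phase relations are imposed per epoch through a hierarchy:

* a shared epoch phase $\theta_e \sim \mathrm{Unif}(-\pi,\pi]$;
* a module offset $\eta_{m,e} \sim \mathrm{vM}(0,\kappa_m)$ for each
  module of the planted community structure;
* a node jitter $\xi_{i,e} \sim \mathrm{vM}(0,\kappa_i)$.

Node $i$'s epoch phase is $\theta_e + \eta_{m(i),e} + \xi_{i,e}$.  Because
the mean resultant length of $\mathrm{vM}(0,\kappa)$ is
$A_1(\kappa) = I_1(\kappa)/I_0(\kappa)$ and offsets are independent, the
expected cross-trial PLV of a within-module pair is
$A_1(\kappa_i) A_1(\kappa_j)$ and that of a cross-module pair is
$A_1(\kappa_m) A_1(\kappa_n) A_1(\kappa_i) A_1(\kappa_j)$.  Calibration is
therefore exact for block-structured targets: node concentrations solve
$A_1(\kappa_i) = \sqrt{w_m}$ (within-block target $w_m$) and module
concentrations absorb the ratio of between- to within-block coupling.
`plv_to_kappa()` inverts $A_1$ with a piecewise starting value and Newton
refinement (accurate to $10^{-9}$; for $\kappa > 5000$ the asymptotic
expansion of $I_1/I_0$ replaces the Bessel ratio, which loses accuracy
there).  Arbitrary target matrices without a module structure are honoured
approximately, through their best rank-one factorisation on the log scale;
this is exact for uniform matrices and for any matrix of the form
$a_i a_j$.

What the generator deliberately does *not* emulate: volume conduction and
field spread (no forward model), 1/f background spectra, non-stationary
within-epoch dynamics, and amplitude-phase coupling.  Passing tests
therefore demonstrate the correctness of the estimators and the
statistical chain under a known truth, not robustness to every property of
real EEG.

## Why cross-trial PLV is the default

Two PLV conventions exist: average the phase-difference phasors over time
within an epoch and then average moduli across epochs, or average phasors
across epochs at each time point and then average the modulus over time
(the classical cross-trial definition).  With narrow-band signals whose
phase offsets are stable within a trial -- exactly the generator's regime,
and a good approximation for stimulus-locked narrow-band activity -- the
within-epoch phase difference is constant, so the time-first estimator
returns values near 1 for every pair regardless of coupling: all the
information about trial-to-trial phase consistency lives across epochs.
The cross-trial scheme (`average = "trials"`, the default of
`plv_matrix()`) is the one under which the generator's calibration is
recoverable; the time-first scheme remains available as
`average = "time"`.  By default 100 ms at each epoch border is excluded
before estimation to suppress Hilbert edge artifacts, and the analysis
window is the post-stimulus interval.

## Graph conventions

* **Thresholding.**  `proportional_threshold()` keeps the
  `round(0.2 * n(n-1)/2)` largest off-diagonal weights (round-half-up; for
  n = 148 that is 2176 edges) and keeps them *weighted* -- the modularity
  formula used here involves edge weights and weighted degrees, so
  binarising would change the statistic (a `binarize` flag exists).  Ties
  straddling the cutoff are resolved by node-index order, deterministically,
  with a warning.
* **Path lengths.**  Edge length is the inverse weight, the standard
  transform for affinity-type weights such as PLV; all-pairs shortest
  paths use Floyd-Warshall.  Unreachable pairs have infinite length and
  contribute zero efficiency.
* **Global efficiency** is the mean inverse shortest path length over
  ordered pairs; with PLV weights (at most 1) it lies in [0, 1].
* **Routing matrix / efficiency.**  The routing matrix holds inverse
  shortest path lengths off the diagonal and 1 on the diagonal; the
  core-extended routing efficiency is the *maximum* entry over (core,
  extended) pairs -- the single best communication channel, hence very
  sensitive to coupling changes between the subsystems.
* **Modularity.**  Weighted Louvain with `n_restarts` random node orders
  (default 100) at resolution $\gamma = 1$; the best partition's Q is
  always re-evaluated by the direct formula
  $Q = \frac{1}{2m}\sum_{ij}\left[A_{ij} - \frac{k_i k_j}{2m}\right]
  \delta(c_i, c_j)$, so the reported value cannot drift from its
  definition.  Fixed seed and restart count give deterministic results.

The core/extended assignment of Destrieux parcels ships as an editable
two-column CSV (`destrieux_face_systems.csv`): fusiform,
inferior-occipital and superior-temporal-sulcus parcels form the core
system; superior and inferior frontal gyri, temporal poles, insular and
subcentral/paracentral (secondary sensorimotor) parcels the extended
system.  This is a curated reading of the canonical region lists, not a
ground truth -- any analysis can substitute its own table via
`read_node_sets()`.

## The epoch grid

Epochs run from -500 ms to 800 ms around stimulus onset at 256 Hz.  The
package uses the truncation convention `floor((tmax - tmin) * fs) + 1`
samples starting exactly at `tmin` (333 samples for the default window;
205 for an 0.8 s window), with the last sample on the largest grid point
not beyond `tmax`.

## Statistics

Each metric is modelled as
`value ~ condition * emotion + (1 | subject)`, fitted by REML (the
conventional choice for variance-component estimation in balanced
repeated-measures designs).  F tests use the Satterthwaite approximation
for denominator degrees of freedom; pairwise emotion contrasts within each
condition (6 pairs x 2 conditions = 12 per metric) are adjusted together
with Benjamini-Hochberg.  The FDR family choice (12 within-condition
contrasts per metric) is recorded in the run manifest.

A useful arithmetic check: with 52 subjects the metric table has
52 x 8 = 416 rows, and the Satterthwaite denominator df for the fixed
effects approaches 416 - 8 (fixed-effect parameters) - 51 (subject
effects) = 357 whenever the subject variance is clearly positive -- the
package's own simulations at that size reproduce df = 357.

## Study conditions for the simulation experiments

All operating-characteristic experiments use a scaled-down study: **10
subjects, 20 nodes (6 core / 7 extended / 7 other), 40 epochs per cell**,
with base coupling within = 0.45, between = 0.20, subject random
intercepts of sd 0.05 on the coupling scale (metrics are coupling-derived,
so subject variability is placed there rather than on amplitudes), carrier
10 Hz, amplitude 1, noise sd 1.  Calibration experiments use 200 epochs
and 20 seeds per target.  These sizes keep a 500-replicate null study and
a 100-replicate power study tractable on one CPU while leaving all
estimators in their asymptotic regime.

The reference planted effect (`planted_study_effect()`) emulates the full
condition x emotion pattern of integration changes: overt-fear,
overt-sad *and* covert-neutral cells receive a +0.15 increment on
core-extended couplings plus a +0.13 increment on all couplings.  Two
design facts motivated the two components and their sizes, established by
a sensitivity analysis before the operating characteristics were frozen:

* at a fixed retained-edge count, whole-brain global efficiency is nearly
  invariant to a *cross-subsystem-only* increment (elevated cross edges
  displace within-module edges of similar weight), so a whole-brain
  coupling component is required for the global-efficiency effect that the
  analysis is meant to detect -- which is also the more faithful
  generative account, since increased whole-network integration is a
  distinct phenomenon from improved core-extended communication;
* with 10 subjects instead of 52, per-cell standardised effects near 1.2
  are needed for 80% interaction power, roughly double what the full-scale
  design would require.

Community-recovery experiments plant **four modules of five nodes**
(within-PLV 0.8, between 0.1).  The module count matters at a 20%
threshold: 38 of 190 edges are retained, and a planted structure is only
recoverable when its within-module pair count fits that budget.  Two
modules of ten would demand 90 within-module pairs from 38 retained
edges; because estimator noise is correlated within a node (a node's
unlucky phase draws depress its whole row), some node then loses all its
edges in a sizeable fraction of runs and ends up a singleton community,
capping the adjusted Rand index regardless of epoch count.  With four
modules of five the within-module demand (40 pairs) matches the budget
and recovery is essentially perfect.

Under these frozen conditions the verified operating characteristics are:
interaction power 0.92 (global efficiency) and 1.0 (routing efficiency) at
100 replicates, directional pattern (fear/sad above happy/neutral within
overt, all four oriented contrasts positive) in ~100% of replicates for
both metrics, null interaction type-I error within sampling error of
the nominal 5% (0.060 / 0.064 for global and routing efficiency over 500
replicates), and planted-community recovery with adjusted Rand index 1 in
all 20 seeded runs (see `scripts/acceptance.R`, which recomputes all of
these from scratch).

## Numerical choices and degenerate inputs

* Zero-phase filtering is forward-backward Butterworth (order 4), so the
  realised magnitude response is the squared design response
  (`filter_response()` reports it); zero phase matters because filtered
  signals feed phase estimation.
* Analytic signals come from the frequency-domain Hilbert construction;
  all-zero traces are rejected (`degenerate-input`) since their phase is
  undefined.
* `plv_to_kappa(1)` is an error (the concentration diverges); the
  generator realises exact unit coupling by setting the jitter to zero.
* Louvain ties and restart order are controlled by an explicit seed;
  threshold ties break by node index.  Both are logged or warned, never
  silent randomness.
* Degenerate mixed-model fits (boundary variance estimates with
  non-positive-definite covariance) are caught per replicate in the
  simulation loops and excluded from rates, with a reported count.

## Known limitations

* The generator's rank-one fallback honours arbitrary (non-block) target
  matrices only approximately; planted analyses should use block
  structures, which are exact in expectation.
* Cross-trial PLV carries the Rayleigh small-sample bias
  ($\mathbb{E}[\mathrm{PLV}] \approx \sqrt{\pi/(4n)}$ under independence);
  with 40 epochs the floor is ~0.14, which is why operating
  characteristics are stated for the full chain rather than for raw PLV
  values.
* Whole-brain global efficiency at fixed density is a blunt instrument
  for subsystem-specific effects (see above); the routing efficiency is
  the sensitive metric for core-extended communication, as intended.
* The preprocessing stage implements the deterministic EEGLab-style chain
  (resampling, average reference, band-pass, epoching, peak-to-peak
  rejection, bad-channel flags); ICA-based artifact classification and
  source reconstruction are out of scope, and parcel time courses enter
  the pipeline directly (in real data, via the user's source model).
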