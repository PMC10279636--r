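# alphanet

Alpha-band phase-locking network analysis of epoched EEG, built as a
validated, fully simulatable pipeline.

## The problem

When people look at an emotional face, does paying attention to the
expression (overt processing) versus ignoring it (covert processing)
reorganise large-scale cortical communication in the alpha band
(8–12 Hz)?  Network neuroscience phrases this as a graph problem: estimate
phase-locking connectivity between cortical parcels, threshold the
matrix, and summarise the resulting weighted graph with

- **modularity**
  `Q = 1/(2m) * sum_ij [A_ij − k_i k_j/(2m)] δ(c_i, c_j)`
  (segregation into communities; weighted Louvain maximisation),
- **global efficiency**
  `E_glob = 1/(n(n−1)) * sum_{i≠j} 1/d_ij`
  (integration; `d_ij` are Floyd–Warshall shortest path lengths on edge
  lengths `1/weight`),
- **routing efficiency**
  `R_eff = max R_mat(CS, ES)`, the largest inverse shortest path length
  between the **core system** (fusiform, inferior occipital, superior
  temporal sulcus parcels) and the **extended system** (frontal, anterior
  temporal, insular, secondary sensorimotor parcels) of the
  face-processing network,

then tests each metric with a linear mixed model
`value ~ condition * emotion + (1 | subject)` (Satterthwaite F tests,
Benjamini–Hochberg-corrected pairwise contrasts).

Raw EEG for this design is not publicly deposited, so the package pairs
the analysis chain with a **coupled-oscillator generator**: parcels carry
10 Hz carriers whose per-epoch phase offsets follow a von Mises hierarchy
calibrated so any block-structured target PLV matrix is realised exactly
in expectation.  Every pipeline stage is thereby testable by parameter
recovery, and the statistical chain by type-I-error and power simulation.

## Who this is for

EEG/MEG researchers who want a transparent, dependency-light reference
implementation of PLV + graph-metric + mixed-model analyses, and
methodologists who want a controllable testbed for connectivity
estimators and network statistics.

## Worked example

The `analysis/` directory is a numbered walk through the whole study
(simulate → connectivity → graph metrics → statistics → operating
characteristics), writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_connectivity.R
Rscript analysis/03_graph_metrics.R
Rscript analysis/04_stats.R
Rscript analysis/05_operating_characteristics.R
```

Stage 1 checks the generator's calibration; it prints (abridged):

```
dominant frequency of a demo trace: 9.99 Hz (carrier 10 Hz)
 target estimate abs_error
    0.1   0.0983  0.001682
    0.5   0.4897  0.010291
    0.9   0.9010  0.000966
max |estimate - target| = 0.010
```

i.e. requested pairwise phase locking is reproduced to ~0.01 across the
whole coupling range.  Stage 4 fits the mixed models to the simulated
10-subject study, which carries a planted integration increase for
negative expressions under overt attention (and for neutral faces under
covert attention); its F table shows the planted condition × emotion
interaction:

```
            term      f df1 df2        p             metric
       condition  0.475   1  72 0.493    global_efficiency
         emotion  1.335   3  72 0.270    global_efficiency
condition:emotion 5.569   3  72 0.0017   global_efficiency
condition:emotion 19.62   3  63 4.3e-09  routing_efficiency
```

and the oriented within-overt contrasts recover the planted direction
(fear/sad above happy/neutral), e.g. for routing efficiency:

```
       contrast estimate    t        p    p_adj
   fear - happy    0.494 5.68 3.65e-07 3.45e-06
 fear - neutral    0.436 5.01 4.63e-06 1.85e-05
    sad - happy    0.484 5.56 5.74e-07 3.45e-06
  sad - neutral    0.425 4.89 7.16e-06 2.15e-05
```

A positive estimate means the negative expression's network was more
efficiently integrated than the happy/neutral one — the planted pattern.

The same chain is available as single calls: `study_config()` →
`simulate_study_metrics()` → `analyze_metrics()`, or end-to-end with
outputs and a JSON manifest via `run_study()`.

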