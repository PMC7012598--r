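# ck1switch

Quantitative analysis of the activation-loop conformational switch in
Casein Kinase 1 δ/ε (CK1δ/ε) and its coupling to PER2 substrate
selectivity and stability.

CK1δ/ε sets circadian period by phosphorylating PER2 at two antagonistic
sites: the stabilizing FASP cassette and the degradation-promoting
Degron (the *phosphoswitch*). Substrate choice is gated by the kinase's
activation loop, which toggles between a "loop down" conformation
(anion-bound, FASP-directed) and a "loop up" conformation
(Degron-directed, favoured by the short-period *tau* mutation R178C).
`ck1switch` provides the full computational toolchain around this model:

* **Loop-switch metric** — the two-distance reporter
  (d(L173 CD2, L152 CD2) vs d(L173 CD2, Y225 OH)) with a relative
  classifier (`up` iff `d_L152 < d_Y225 − margin`, `down` for the
  reverse, indeterminate inside the margin) and library surveys with
  skip-list bookkeeping.
* **Superposition & RMSD traces** — Kabsch least-squares superposition
  and per-frame segment RMSD (activation loop 168–175 against up/down
  references; loop L-EF 213–224 against the initial structure), with
  segment-fit and core-fit conventions and replica averaging.
* **Pocket volumetrics** — grid-based free volume inside a union of
  (default three) spheres covering the substrate cleft and anion sites;
  per-frame volumes, ensemble open-fraction maps, contouring at 0.1,
  OpenDX export.
* **Essential dynamics** — backbone Cartesian-covariance PCA over
  concatenated, superposed ensembles; per-system projections,
  histograms, mode-endpoint structures.
* **Enzymology** — pseudo-first-order efficiency
  kcat/Km = −ln(1 − P/S₀)/(E·t), initial rates, NMR site ratios with
  error propagation, one-phase decay half-lives
  (Y(t) = (Y₀ − plateau)·e^(−kt) + plateau, t½ = ln 2/k), and the
  half-life vs FASP/Degron-efficiency-ratio regression with 95% CI.
* **Conservation** — reference-anchored percent identity of residue
  patches across a FASTA alignment.
* **Synthetic data** — generators with exact ground truth for every
  input class (two-state switch ensembles, mode-dominated trajectories,
  pocket scenes with analytic volumes, progress curves, decays, mutant
  panels, alignments).
* **Pipeline** — `run_pipeline()` drives any subset of stages from one
  YAML config, with a run record for reproducibility.

## Worked example

```r
library(ck1switch)

# a 5-frame two-state ensemble with 0.2 A coordinate noise
sw <- make_switch_ensemble(n_up = 3, n_down = 2, noise_sigma = 0.2, seed = 7)
sv <- survey_ensemble(sw$ensemble, margin = 1.0)
sv$rows
#>               source_id chain frame d_L152_A d_Y225_A label
#> 1 switch_ensemble_seed7     A     1     3.91     9.46    up
#> 2 switch_ensemble_seed7     A     2     4.11    10.23    up
#> 3 switch_ensemble_seed7     A     3     3.81    10.13    up
#> 4 switch_ensemble_seed7     A     4    10.14     4.60  down
#> 5 switch_ensemble_seed7     A     5    10.07     4.10  down
```

All five frames are recovered with their generated labels: the first
distance is short and the second long in "loop up" frames, and vice
versa in "loop down".

```r
# reporter stability: one-phase decay after cycloheximide at t = 2 hr
d <- simulate_decay(t_half = 3.5, noise_frac = 0.02, n_replicates = 1,
                    seed = 1)$table
fit_one_phase_decay(d$time_hr, d$signal, t_chx = 2)
#> <decay_fit> half-life 3.51 hr (k = 0.198 /hr, plateau 9.97, span 90.3)

# phosphoswitch: half-life vs FASP/Degron efficiency ratio
p <- simulate_phosphoswitch_panel(slope = 1.5, intercept = 1,
                                  n_mutants = 8, noise_sd = 0.2, seed = 2)
efficiency_halflife_regression(p$table$ratio, p$table$half_life_hr)
#> <regression_fit> slope 1.52 [1.35, 1.7], intercept 0.968, R^2 0.987,
#>   p = 7.61e-07 (n = 8)
```

The decay fit recovers the generating half-life (3.5 hr) within noise,
and the regression recovers the generating slope (1.5 hr per unit
efficiency ratio) with the truth inside the 95% CI: mutants whose
kinase retains relatively more FASP than Degron activity stabilize the
reporter.

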