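---
title: "Methods: quantifying the CK1 activation-loop switch and its coupling to PER2 stability"
author: "ck1switch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying the CK1 activation-loop switch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ck1switch)
```

# The scientific problem

Casein Kinase 1 delta/epsilon (CK1δ/ε) sets the pace of the circadian
clock by phosphorylating the PERIOD2 (PER2) protein at two antagonistic
sites: the stabilizing FASP cassette (priming at S659 followed by
downstream consensus sites) and the degradation-promoting Degron (S478,
recruiting β-TrCP). The balance of these two activities — the
*phosphoswitch* — controls PER2 half-life and hence circadian period.
The kinase side of this balance is governed by a conformational switch in
the CK1 activation loop: a "loop down" conformation associated with anion
binding at a conserved site (Site 2) and FASP-directed activity, and a
"loop up" conformation that favours Degron phosphorylation. The
short-period *tau* mutation (R178C) perturbs anion binding and biases the
loop toward "up".

`ck1switch` implements the complete quantitative toolchain around that
model: a geometric classifier for the loop state in crystal structures
and simulation snapshots, loop-stability RMSD traces, grid-based
free-volume maps of the substrate-binding cleft, backbone
essential-dynamics PCA, the enzymology layer (efficiency, half-life,
efficiency–half-life regression), patch conservation, and synthetic-data
generators that make every stage testable without any downloads.

# The two-distance switch metric

The loop state is reported by the side chain of L173. Two interatomic
distances are measured per chain (author numbering of the CK1δ ΔC
construct, residues 1–317, which is never renumbered):

* `d_L152`: L173 CD2 ↔ L152 CD2 — short in "loop up", long in "loop down";
* `d_Y225`: L173 CD2 ↔ Y225 OH — long in "loop up", short in "loop down".

Classification is *relative* with an indeterminate margin `m` (default
1.0 Å): "up" iff `d_L152 < d_Y225 − m`, "down" iff `d_Y225 < d_L152 − m`,
otherwise indeterminate. We chose a relative rule rather than absolute
distance cut-offs because the two conformational clusters in surveyed
structure libraries are well separated but no numeric boundary is
canonical, and a relative rule transfers to CK1 family homologs, where
absolute distances shift. The probe mapping is configurable
(`DEFAULT_SWITCH_PROBES`) so equivalent positions in CK1ε/CK1γ can be
surveyed. Chains missing any probe atom (disordered loops are common) are
skipped with a warning and recorded in the survey's skip list, never
silently dropped, because silent omission would bias survey counts.

```{r switch}
s <- make_toy_kinase(seed = 1, state = "up")
classify_conformation(measure_switch_distances(s, "A"))$label
```

# Superposition and segment RMSD traces

Loop stability along an ensemble is measured as the RMSD of a residue
segment (activation loop 168–175 against crystallographic "up"/"down"
references; loop L-EF 213–224 against the initial structure) after
least-squares rigid superposition of each frame (Kabsch algorithm, proper
rotations only, implemented on a base-R SVD).

Two conventions are exposed because published descriptions rarely state
which was used: *segment fit* (default; superpose on the analysed segment
itself, the default of common trajectory tools) and *core fit* (superpose
on a user-specified stable core, then measure the segment without
refitting). The backbone atom set defaults to the four heavy backbone
atoms N, CA, C, O — the stricter common reading of "backbone" — and can
be narrowed to N, CA, C. RMSDs are unweighted: mass weighting is an extra
assumption the analysis does not need, and unweighted values are directly
comparable between crystal and simulation frames. Replicas are combined
by a pointwise arithmetic mean with the per-replica traces retained.

# Pocket volumetrics

The substrate-binding cleft and the adjacent anion sites are enclosed in
a union of three overlapping spheres. Because the sphere placement is
defined only pictorially in structural figures, the package derives
reproducible defaults from named residues: centres at the heavy-atom
centroids of Site 1 (R178, K224) and Site 2 (R127, K154, K171) and their
midpoint, radius 8 Å each, all configurable (`default_pocket_spec()`).

A regular grid (default spacing 1.0 Å) is restricted to the sphere union.
Per frame, a grid point is *closed* iff it lies within the van der Waals
radius (Bondi table) of any protein heavy atom — no probe inflation by
default, with an optional probe padding; hydrogens are excluded so
crystal structures (which lack them) and MD frames are treated
identically. The free volume is the open-point count times the voxel
volume; averaging per-frame open indicators over frames (at a stride
corresponding to, e.g., one frame every 2 ns via `stride_for_interval()`)
gives an open-fraction map, contoured at 0.1 by convention to display
regions consistently open. The contour level is interpreted as a frame
fraction, not a smoothed density. Waters, counter-ions and sulfates must
be stripped first (`strip_nonprotein()`), and frames are assumed
pre-superposed: a centroid drift above 2 Å triggers a warning rather than
an error, since drift is a symptom, not proof, of a missing superposition.

Numerical behaviour: at 1.0 Å spacing the voxelized volume of an 8 Å
sphere is within ~2% of (4/3)πr³ and within ~0.5% at 0.5 Å; the dominant
error for planar occlusion boundaries is the half-voxel bias at the
boundary.

# Essential dynamics

Trajectories are reduced to backbone atoms, superposed to a single
reference, concatenated across systems, and the covariance of Cartesian
fluctuations about the concatenated mean is diagonalized (dense symmetric
eigensolver for 3N ≤ 4000; thin SVD of the centred data matrix above
that, keeping the top 20 modes). One shared eigenbasis for all systems,
with per-system projections afterwards, keeps wild-type and mutant
trajectories comparable in the same PC space. The covariance uses the
population divisor n, so a two-frame trajectory at ±a along one direction
has leading eigenvalue exactly a². No mass weighting is applied;
projections are in Å. Eigenvector signs are fixed deterministically
(largest-magnitude component positive). Histograms of projections use
bins centred on integer multiples of the bin width, so the axis is
symmetric about zero and counts always sum to the frame count.

# Enzymology

**Efficiency.** Under the depletion design (10 µM substrate ≪ Km, 0.2 µM
kinase, 3 hr), product follows
P(t) = S₀·(1 − e^{−(kcat/Km)·E·t}) and a single endpoint inverts exactly:
kcat/Km = −ln(1 − P/S₀)/(E·t). The estimator is exact on noiseless
generative data by construction, scale-consistent (doubling E and halving
t changes nothing), and replicates are summarized as mean ± s.d. A
progress-curve variant (`initial_rate()`, restricted to <10% conversion)
covers multi-timepoint data.

**Half-life.** Reporter decays are fitted as one-phase exponentials
Y(t) = (Y₀ − plateau)·e^{−k(t − t_chx)} + plateau from the treatment time
(cycloheximide addition) to the observed minimum, on raw signal.
Initialization is deterministic — Y₀ from the first post-treatment point,
plateau from the window minimum, k from a log-linear fit — and the
optimization is Levenberg–Marquardt (minpack.lm) with non-negativity
bounds. Half-life is ln 2/k and is invariant to rescaling the series.

**Phosphoswitch regression.** Half-life is regressed on the FASP/Degron
efficiency ratio by ordinary least squares; the slope's 95% CI uses the
t-distribution and a pointwise confidence band is exported for plotting.

**Site ratios.** NMR phosphosite ratios (e.g. pS662/pS659) propagate a
common spectral noise s.d. to first order; the ratio is flagged undefined
where the denominator is below three times the noise floor.

```{r kinetics}
d <- simulate_decay(t_half = 3.5, noise_frac = 0.02, n_replicates = 1,
                    seed = 1)$table
fit_one_phase_decay(d$time_hr, d$signal, t_chx = 2)
```

# Conservation

Patch conservation is *reference-anchored*: per patch position, the
percentage of aligned sequences carrying the reference residue
(CK1δ-anchored, matching how surface-patch conservation claims are
stated), with gaps counted as mismatches — the conservative choice. A
19/20 match reports exactly 95.0%.

# What the synthetic generators emulate — and what they do not

The generators provide every input class with exact ground truth:

* `make_toy_kinase()` / `make_switch_ensemble()`: a minimal polypeptide
  (backbone for residues 140–240) carrying the three probe atoms at an
  exact two-state geometry — "up" at d_L152 = 4 Å, d_Y225 = 10 Å and
  "down" reversed (6 Å built-in separation, the construction implied by
  the loop geometry), with the two distance gradients orthogonal so
  isotropic coordinate noise (the noise model throughout) propagates
  independently into both distances.
* `make_mode_trajectory()`: frames displaced along prescribed collective
  modes with Gaussian amplitudes. Modes are projected out of the
  six-dimensional rigid-body subspace before use, because superposition
  during PCA removes the best-fit rigid component of every displacement;
  recovery of variances is only well-posed for internal modes.
* `make_pocket_scene()`: occlusion scenarios with closed-form expected
  volumes (none / single centre atom / half-space slab).
* `simulate_progress_curves()` / `simulate_decay()` /
  `simulate_phosphoswitch_panel()`: pseudo-first-order product curves,
  one-phase decays with plateau, and mutant panels with a linear
  ratio–half-life law, all with multiplicative Gaussian signal noise and
  figure-legend-style replicate structure (n = 4; triplicates for
  efficiency endpoints). The default generator efficiency (10³ M⁻¹s⁻¹)
  gives ~88% conversion over the 3-hr endpoint — an informative,
  non-saturated assay.

These are deliberately idealized: no force-field physics, no anharmonic
coupling between modes, no correlated spectral noise, no photobleaching
or luminescence drift. Passing the recovery tests therefore demonstrates
the *estimators and pipeline plumbing* are correct at realistic noise
levels; it does not validate conclusions about real trajectories, which
would require the original multi-microsecond enhanced-sampling runs.
Those trajectories are not publicly deposited, so trajectory-dependent
observations (loop-up instability in wild type, L-EF disorganization in
*tau*, PC histogram shifts) are out of reach at desk scale; the package
reproduces the *methods*, and validates them on synthetic ground truth
and deposited crystal structures.

# Numerical choices and problem sizes

* Kabsch: degenerate inputs (collinear/coincident points) are rejected;
  reflections excluded; verified against an independent quaternion
  (Horn) oracle to 1e−8 Å on 200 random instances.
* PCA eigenvalues are clipped at zero; eigen/SVD agreement is held to
  1e−8 relative on test instances.
* Classification boundaries are strict inequalities; ties fall into the
  indeterminate band.
* Decay fits bound k, span and plateau below by 0; a constant series is
  a no-decay error, not a zero-rate fit.
* Test and acceptance problem sizes — 2000-frame PCA trajectories,
  200-seed decay recovery, 2000 regression panels, 10⁶-sample
  Monte-Carlo volume oracles — were chosen so the full suite runs in a
  few minutes on one CPU while keeping sampling error well below the
  tolerances tested.

# Known limitations

* mmCIF support relies on bio3d's reader; exotic mmCIF categories are
  not handled. Binary trajectory formats (DCD/XTC) are out of scope.
* The OpenDX writer stores values on the full bounding grid; the
  sphere-union mask is not part of the DX format and is not recoverable
  on re-read.
* `union_volume_analytic()` refuses sphere triples with a common triple
  overlap (no elementary closed form is used); the grid or a Monte-Carlo
  estimate covers that case.
* The efficiency estimator assumes S₀ ≪ Km; it reports only the ratio
  kcat/Km, never the separated constants.
* Accession-based checks (1CKJ/6PXN chain classification, the ≤3.7 Å
  L-EF starting-spread bound) require locally staged coordinate files;
  see `?locate_accession`.
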