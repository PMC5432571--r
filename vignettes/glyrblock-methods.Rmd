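---
title: "Models and methods behind glyrblock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind glyrblock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glyrblock)
```

glyrblock quantifies voltage-dependent open-channel block of glycine-receptor
(GlyR) chloride channels by anionic blockers such as niflumic acid (NFA).
This vignette documents the models, the tunable parameters, the synthetic
data generator, the numerical choices, and the design decisions a maintainer
would want justified. Nothing here states an empirical result that the test
suite or the acceptance script does not itself compute.

## The kinetic model of gating and block

The core object is a continuous-time Markov scheme built by
`build_block_scheme()`. Agonist gating is collapsed to a single
concentration-dependent opening step against a constant closing rate:

* opening: `beta([A]) = beta_max * [A]^n / ([A]^n + EC50_gate^n)` (1/s)
* closing: `alpha` (1/s)

With one blocking site the states are C (closed), O (open) and OB
(open-blocked, non-conducting): an open-channel blocker can only reach its
site through the open pore. With two sites an OB2 state is appended; by
default only the doubly-occupied state is non-conducting
(`g_singly_blocked = 1`), the simplest scheme consistent with block by two
molecules meeting above the pore constriction. Stepwise macroscopic
dissociation constants `K1 >= K2` may differ.

Voltage dependence of block follows the Woodhull picture of a charged
blocker binding at a fractional electrical distance `delta` (measured from
the external membrane surface) inside the transmembrane field:

```
Kd(V) = Kd(0) * exp(-delta * F * V / (R * T))
```

with V the membrane potential (intracellular minus extracellular). For an
external anion and `delta > 0` this makes block stronger at positive
potentials. Kinetically the factor is split between the association and
dissociation rates by `voltage_split` (default 0.5). The split leaves every
equilibrium quantity untouched — only dwell times feel it — and no
equilibrium measurement can constrain it, which is why it is an explicit
convention rather than an estimated parameter. The default temperature is
295.15 K (room temperature; RT/F = 25.43 mV).

### Rectification

Macroscopic GlyR currents rectify (outwardly for alpha1-like, inwardly for
alpha2-like channels). The package models rectification as a Boltzmann
permeation factor in (0, 1] applied to the conducting occupancy when
converting it to current (`rectification_factor()`), not as a
voltage-dependent opening rate inside the scheme. The distinction matters: a
voltage-dependent gating ratio `alpha/beta(V)` would propagate into the
apparent IC50(V) and bias the recovered fractional electrical distance,
whereas a permeation factor cancels exactly in the drug/control ratio that
every downstream analysis consumes. Since the experiments fit no gating
mechanism to the rectification, the package chooses the representation that
keeps the blocker analysis exact.

### Apparent IC50 versus Kd

With a resting state in the scheme, the equilibrium fraction of current
remaining under blocker is exactly Hill-shaped with

```
IC50_app(V) = Kd(V) * (1 + alpha / beta([A]))
```

so the apparent IC50 exceeds the microscopic Kd by a factor set by the
resting/open balance. Two consequences shape the defaults:

* `delta` recovery is *exact* regardless of the gating ratio, because a
  V-independent factor shifts `log IC50(V)` uniformly and the Woodhull slope
  is unaffected. This is also why raising the agonist concentration
  increases apparent potency without changing the fitted depth.
* absolute IC50 values equal Kd only in the high-open-probability limit.
  Test fixtures that assert `IC50 == Kd` to 0.1% therefore use near-saturating
  gating (`beta/alpha ~ 1e4`); the realistic cohort presets use
  `beta/alpha ~ 19` at the working glycine concentration, where the ~5%
  offset is documented and irrelevant to `delta`.

## The synthetic data generator

`generate_cohort()` stands in for the raw patch-clamp recordings, which are
not publicly deposited; all analysis stages therefore run against simulated
data with known ground truth.

* **Protocols.** The ramp protocol holds 500 ms at one extreme, sweeps
  -80 to +80 mV (or the mirror) in 1 s and holds 500 ms; the long protocol
  applies glycine for 2 s, glycine + blocker for 10 s and glycine for 5 s.
  Solution exchange is instantaneous (real exchange is 3-5 ms, negligible at
  these timescales).
* **Whole-cell forward model.** The master equation is integrated along the
  protocols (`deSolve::lsoda` for ramp segments; an exact eigendecomposition
  propagator for constant-voltage windows, which is robust to arbitrarily
  stiff rate constants). Current is
  `N * i_unit(V) * rect(V) * sum(g_i p_i(t)) * amp + noise`, with the
  unitary current anchored at 2.8 pA at -30 mV and scaled linearly with
  driving force around a 0 mV reversal potential (near-symmetric chloride).
* **Noise model.** Additive Gaussian recording noise (default 2 pA) plus a
  per-sweep lognormal gain factor (default log-SD 0.05, the "5% amplitude
  noise" of the study conditions) and a lognormal cell-to-cell maximal
  current factor (log-SD 0.2). No 1/f, seal-leak or capacitive terms: the
  generator emulates block pharmacology, not every artifact of a rig, so
  passing tests speak to the analysis chain, not to artifact robustness on
  real recordings.
* **Cell metadata.** Input resistance ~ lognormal around 500 MOhm and
  run-down ~ uniform(0, 0.2) supply the quality filter (drop below 150 MOhm
  or above 30% run-down); channel count defaults to 100 per cell. Channel
  counts and gating rates per cell are conventions — only equilibrium
  quantities are constrained by the reported data.
* **Determinism.** One master seed; per-cell and per-sweep substream seeds
  are drawn from it, so a (config, seed) pair regenerates a cohort
  bit-identically, and every manifest records the seed.
* **Single channels.** `simulate_single_channel()` is an exact Gillespie
  simulation of the same scheme, rendered into a sampled trace; blocker
  binding appears as flicker: brief blocked sojourns of mean `1/koff(V)`
  interrupting openings.

## The analysis chain

1. `ramp_fraction_remaining()` bins control and drug ramps on a 5 mV voltage
   grid, averages up- and down-ramps (hysteresis is reported as a
   diagnostic) and masks grid points where the control current is within
   5 noise-SD of zero — the ratio is undefined around the reversal
   potential; the study protocols give no rule for this band, so the mask is
   the package's own convention.
2. `measure_inhibition_long()` quantifies block in long-protocol sweeps as
   `100 * (1 - I1/I2)` with `I1` the mean over the final 10% of the
   co-application window and `I2` the quasi-stationary post-washout plateau
   (final 40% of the washout window). Referencing to the washout rather than
   the initial response is deliberate: desensitising receptors never return
   to the first peak, and the published measurement is defined the same way.
   The exact "final 10%" window is a package convention; the source analysis
   does not state one.
3. `fit_hill_inhibition()` fits `f = 1/(1 + (c/IC50)^nH)` by bounded
   Levenberg-Marquardt least squares (`minpack.lm`), multi-started over
   `nH in {0.5, 1, 2}` with `nH` bounded to [0.2, 4] to stabilise sparse
   grids; `Imax` is fixed at 1 for fraction-remaining data (already
   normalised to control) and free for activation fits.
4. `ic50_voltage_table()` repeats the fit per cell and voltage (default grid
   -80, -70, -50, -30, 30, 50, 70, 80 mV); per-cell fitting followed by
   aggregation is the default because reported n counts cells, but a pooled
   mode exists since the published per-voltage summaries are ambiguous about
   pooling.
5. `fit_woodhull()` regresses `log IC50` on V — the conventional
   log-linearised Woodhull plot — giving `delta = -slope * RT/F`; a
   nonlinear variant on the IC50 scale is provided for sensitivity analysis.
   `aggregate_delta()` reports mean ± SEM over cells (SEM undefined, not
   zero, for a single cell).
6. `infer_stoichiometry()` translates mean Hill coefficients into an
   apparent number of blocking molecules (mean `nH > 1.3` suggests two).
   This is labelled a heuristic: Hill coefficients have no strict
   mechanistic reading, and the threshold (with ties resolving to one site)
   is configurable.

`run_pipeline()` chains all of this from a subtype preset. The presets
(`glyr_preset()`) encode the qualitative behaviour of the studied receptor
variants — site depth, zero-voltage IC50 anchor, rectification direction,
one- versus two-molecule block, desensitisation for the alpha3-like variant
— with kinetic rates set by convention.

### Problem sizes

The recovery studies in the test-suite and acceptance script use 8-9 cells,
six blocker concentrations (3-1000 uM), eight analysis voltages and 1 kHz
ramp sampling, which the package treats as its standard cohort; at these
sizes a full recovery runs in well under a minute on one core. The
single-channel property checks use 40-60 s simulated recordings (thousands
of events).

## Single-channel quantification

`idealize()` uses half-amplitude threshold crossing with a two-sample
minimum event width — a deliberate choice of the field's simplest robust
idealizer over hidden-Markov approaches. `fit_dwell_exponentials()` fits
exponential (mixtures) by maximum likelihood (closed form for one
component, EM for two). `detect_bursts()` classifies shut periods shorter
than `t_crit` as intra-burst flicker gaps; the default `t_crit` is the
equal-misclassification intersection of the two fitted shut-time components
(no criterion is given in the source analysis, so the standard one is
used). `estimate_block_rates()` then reads `koff` as the reciprocal mean
flicker gap and `kon` as the flicker frequency per open second per unit
concentration. These estimators presuppose the flicker regime (blocked
sojourns much shorter than closed sojourns) and no missed-event correction
is applied.

## The pore-scanning module

The structural module rationalises the electrophysiology: where in the pore
can the anion bind, and why do the alpha1 and alpha2 pores differ when their
lining differs only at level 2'?

* **Ligand.** `build_nfa()` constructs the 28-atom NFA anion from standard
  bond lengths and angles with four rotatable torsions. The aryl-carboxylate
  bond carries the published 2-fold potential (3 kcal/mol barrier, minima at
  ±90°); the two conjugated bridge bonds carry 8 kcal/mol 2-fold planar
  potentials; the CF3 group is a nearly free rotor. The internal force field
  adds intramolecular van der Waals (small ECEPP-style hydrogen radii), a
  classic distance-only 10-12 hydrogen-bond term — deep (5 kcal/mol) for the
  charge-assisted N-H...O(-) bond, weak (1.5 kcal/mol) for the aromatic
  C-H...N(pyridine) contact that stabilises planar 2-anilinopyridines.
  Minimisation multi-starts over both carboxylate twists and both ring
  orientations. The resulting conformer is near-planar with the
  intramolecular H-bond closed; its maximal interatomic span is computed by
  the acceptance script rather than quoted here.
* **Pore.** `build_pore()` makes an idealized TM2-only pentamer: ideal
  alpha-helices (1.5 Å rise, 100°/residue), five-fold symmetric, bundle
  radius tuned so the 9' leucine ring leaves ~3.3 Å of free radius, and a
  funnel flare above the 9' constriction (the open pore widens toward the
  extracellular mouth; without it no level above 9' can hold two ligands, or
  even one without strain). Each
  residue contributes a backbone bead at the C-alpha and a typed side-chain
  bead (hydrophobic, hydroxyl donor/acceptor, +1 arginine). Glycine — the 2'
  difference between the two subtypes — contributes no side chain; its
  exposed backbone is modelled as an implicitly hydrated bead: bulky
  (C-alpha plus a ~1.2 Å structured-water shell) but with a shallow
  dispersion well and no H-bond term. This is deliberate: in vacuo, a polar
  exposed backbone would *attract* the ligand and invert the
  alanine/glycine ordering, whereas the physical picture is that water
  bound at the glycine ring is displaced at a cost and offers a hydrophobic
  molecule nothing in return. Arginine side chains point into the lumen
  regardless of helix phase (they are long and flexible). A PDB file with
  the five TM2 segments can replace the idealized geometry (`bio3d`); the
  default stays self-contained so nothing must be downloaded. The M1/M3
  helices are omitted: whether they contact the ligand in the original runs
  is not stated, and the TM2 bundle carries all the features the qualitative
  claims rest on.
* **Energy.** The published interaction energies come from a force field
  this package does not reproduce; `interaction_energy()` is the package's
  own stand-in: 12-6 van der Waals, Coulomb with distance-dependent
  dielectric (eps = r), a 10-12 H-bond term, 8 Å switched cutoff, capped
  repulsion with a clash flag. Only profile *shape and ordering* claims are
  therefore testable, never kcal/mol values — the tests and acceptance
  criteria respect that boundary (sign-only comparisons).
* **Search.** `mc_minimize()` alternates random perturbation (≤1 Å
  translation, ≤30° rotation/torsion; occasional larger kicks to escape
  jammed poses), local BFGS minimisation and Metropolis acceptance at 600 K,
  stopping when 100 consecutive minimisations fail to improve the best
  energy. `pull_profile()` drags the central nitrogen N1 plane-by-plane
  (0.5 Å default) from below the -2' ring to the 20' ring under a stiff
  plane constraint (400 kcal/mol/Å², effectively a hard holder: at a
  constrained minimum the residual penalty scales as F²/4k, so a stiff
  holder is what keeps reported constraint energies near zero), a 6 Å
  flat-bottom radial constraint and C-alpha pins (free to 1 Å,
  10 kcal/mol/Å beyond). Each level runs a second short search from a fresh
  axis-aligned placement (jammed poses must not propagate down the scan)
  and is polished with a long local minimisation so the reported point is a
  true constrained minimum. The backbone is rigid by default (pins then
  hold trivially); the pin energy is still evaluated so that displaced or
  PDB-derived models are penalised correctly.
* **Paired subtype comparison.** `compare_profiles()` scans two pore models
  over the same levels with pose sharing: each level's best poses from both
  models (plus a fresh placement) are re-minimised in each model and the
  best wins. The alpha2-minus-alpha1 ordering rests on a few kcal/mol at
  the 2'-6' levels; independent stochastic scans at test-scale sampling
  carry more per-level search noise than that, while the paired design
  cancels it and isolates the 2' substitution.
* **Two-molecule complex.** `dock_two_ligands()` builds the complex the way
  the protocol describes: the first anion is MC-minimised at the 13' level,
  the second is then MC-minimised with small local moves in the field of
  pore-plus-first-ligand (both N1 atoms confined above the 9' ring and
  within the docking band of the site), and the pair is jointly refined.
  Ligand-ligand electrostatics are screened fourfold relative to
  ligand-protein terms (eps = 4r): like-charge pairs in a water-filled pore
  are strongly screened, and with unscreened eps = r no two-anion complex
  is stable in any distance-dependent-dielectric model. The function
  reports the inter-ligand van der Waals energy and the hydrogen-bond
  inventory of the complex.

Reduced problem sizes are used in the automated checks (1 Å steps over the
2'-6' window, stop-after-25 with capped local iterations); these settings
are the package's reduced-scan defaults for property verification, while
`stop_after = 100` with 0.5 Å steps reproduces the full protocol.

## Numerical choices and degenerate inputs

* Stationary distributions solve the augmented least-squares system
  `[t(Q); 1] p = [0; 1]`; disconnected or degenerate schemes are reported
  as errors, and an independent eigendecomposition cross-checks the solver
  in the test suite.
* Ramp integration restarts at every solution-window boundary; sample times
  are constructed as integer multiples of the sampling period so boundary
  samples are hit exactly.
* Hill fits refuse fewer than three distinct concentrations; voltages with
  sparse coverage are skipped with a warning rather than fitted badly.
* Exact (zero-residual) regression fits are legitimate in round-trip tests;
  their standard errors are reported as NA where undefined (two-point
  Woodhull fits).
* Torsion rotations re-measure each dihedral immediately before applying it,
  because the two bridge torsions share defining atoms.

## Known limitations

* The generator does not emulate series-resistance or liquid-junction
  artifacts, leak currents, or multi-channel patch statistics; conclusions
  about those failure modes cannot be drawn from its tests.
* The apparent-IC50 offset `1 + alpha/beta` means absolute IC50 values from
  low-open-probability presets sit a few percent above the microscopic Kd;
  fractional-distance estimates are immune by construction.
* The stoichiometry call is a threshold heuristic on Hill coefficients.
* The pore energetics are qualitative by design; the coarse side-chain
  representation cannot resolve hydration effects (e.g. water ordering at
  the 2' glycine backbone), which the original discussion flags as a likely
  contributor.
* No missed-event correction in single-channel analysis; estimates degrade
  when blocked dwells approach the sampling interval.

## Command-line use

The package is a library first: the functions compose with the pipe, and
`run_pipeline()` plus the I/O helpers (`write_cohort()`, `read_trace()`,
`write_trace()`, `write_profile_tsv()`, `write_pore_pdb()`) cover scripted
use. `scripts/acceptance.R` in the source repository is a worked example of
a fully scripted end-to-end run.
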