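---
title: "Comparative MD trajectory analysis with mdcompare"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative MD trajectory analysis with mdcompare}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdcompare)
```

## The problem

A protein complex is simulated in several states — say a drug-bound
heterodimer in unmodified, point-mutated and phosphorylated forms —
with a handful of independent replicates per state. The scientific
questions are comparative: which residues become more flexible, which
hydrogen bonds change occupancy, how much does the binding free energy
shift, and which interfacial residues carry the difference between
states. `mdcompare` implements that comparison pipeline. It does not
run simulations and it does not solve the Poisson–Boltzmann equation;
it consumes trajectories (multi-model PDB, with the topology read from
the first model) plus a per-atom parameter table, and produces the
comparison tables.

## Data model and sampling conventions

Trajectories bind an `A × 3 × F` coordinate stack to a topology whose
author residue numbering is preserved and used in every report (so a
residue prints as, e.g., `A:GLY 323`). Frame times are in nanoseconds;
multi-model PDB carries no clock, so times are synthesized from a
configurable frame spacing (default 0.1 ns). All analyses run on
windowed, evenly spaced frame samples (`window_frames()`), mirroring
the common practice of analyzing the final, equilibrated portion of
each replicate with stage-specific sample sizes (hundreds of frames
for energetics, thousands for contact features, tens to hundreds for
secondary structure and water bridges). `concatenate_trajectories()`
joins replicates while retaining per-frame provenance, so the
concatenation is losslessly invertible.

## Flexibility

Superposition is the analytic Kabsch solution (SVD of the
cross-covariance with reflection correction). RMSF is measured, per
residue, as the root-mean-square deviation of the Cα position from the
**fixed reference structure** after per-frame backbone fitting — not
from the trajectory-mean position. The reference convention matters:
it folds systematic displacement into the profile, which is the
behaviour wanted when the reference is a common equilibrated starting
structure for all states. A `mode = "mean"` option provides the other
convention for comparison. Between two states, residues are flagged
when |ΔRMSF| meets the inclusive thresholds of 1 Å for ordered and 3 Å
for disordered residues; maximal runs of flagged residues are reported
as regions.

## Secondary structure

Full eight-class DSSP is more than the downstream comparison consumes,
so assignment is a simplified four-code scheme: backbone hydrogen
bonds are scored with the Kabsch–Sander electrostatic model
(`E = 27.888·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN)` kcal/mol is the
standard form; a bond exists iff `E < −0.5` kcal/mol), two
consecutive i→i+4 turns give helix (H), mutual or staggered bridge
patterns give strand (E), isolated 3/4/5-turns give turn (T),
everything else coil (C). G/I helices map into H, isolated bridges
into E, bends into C. Missing amide hydrogens are reconstructed on the
N–H bisector at 1.01 Å. Per-residue code fractions over a frame sample
always sum to 100 %.

## Hydrogen bonds and water bridges

Detection is geometric: donor–acceptor distance ≤ 3.5 Å and the angle
between the donor→hydrogen and donor→acceptor vectors ≤ 30° — the
out-of-linearity convention of the widely used visualization tool's
H-bond module, adopted here because the cutoff is quoted as a
"donor–acceptor angle" without a formula. Polar atoms are N, O, S (and
P) plus their bonded hydrogens. Occupancy is the percentage of
windowed frames in which a specific donor–hydrogen–acceptor triple
satisfies the criteria; the filter keeps a triple if it reaches 10 %
(inclusive) in at least one replicate of either compared state, and
cells below 1 % are flagged so reports can grey them out. A water
bridge requires one water hydrogen-bonded to both a ligand atom and a
protein atom in the same frame, in either donor/acceptor role on each
leg.

## Energetics

The binding-energy layer follows the MM/PBSA end-state decomposition
under the single-trajectory convention (complex and partners evaluated
on the same frames), which reduces the molecular-mechanics term to the
explicit cross-group interaction energy: Coulomb
`f·q_i·q_j/(ε_r·r_ij)` with `f = 138.935458 kJ·mol⁻¹·nm·e⁻²` and 12-6
Lennard-Jones with Lorentz–Berthelot combining, no cutoff, vacuum
dielectric by default. Those defaults favour exact reproducibility of
closed-form checks; ε_r and a cutoff are configurable. The nonpolar
solvation term is the linear surface-area model `g = γ·SASA + b` per
species (`γ = 0.0226778 kJ·mol⁻¹·Å⁻²`, `b = 3.84928 kJ/mol`), using an
in-package Shrake–Rupley SASA with deterministic golden-spiral sphere
points (element radii C 1.7, N 1.55, O 1.52, S 1.8, H 1.2, P 1.8 Å,
overridable). The polar term is **ingested, not solved**: external
Poisson–Boltzmann tables (including the g_mmpbsa contribution-file
dialect) can be attached per frame, per residue, or as a constant;
with no source it is zero and the run log says so prominently.
Re-implementing a PB solver would be out of proportion to the
comparison pipeline, and the solver's grid parameters are rarely
reported well enough to reproduce anyway.

Per-residue decomposition attributes each cross-group atom pair's
energy half to the residue of each of its two atoms, so the sum over
all residues equals the total exactly — the conservation property the
tests enforce at 10⁻⁶ kJ/mol. (The alternative convention, full
attribution to both sides, double-counts the total.) The per-residue
nonpolar share is γ times the residue's buried area; the per-species
offset −b lives in a table attribute rather than being smeared over
residues.

Replicate summaries report mean ± sd with the n−1 denominator at the
replicate level. State deltas are reported under two conventions: the
raw difference of means, and the difference of means rounded to one
decimal. The rounded convention exists because published summary
tables print means to one decimal and compute their deltas from the
printed values; reproducing a printed table therefore requires
differencing after rounding (e.g. a raw difference of −203.52 prints
as Δ = −203.6 = −1410.0 − (−1206.4)). Both are always reported.

## Exact Mann–Whitney U test

With five replicates per state, asymptotic rank tests are the wrong
tool. The one-tailed Mann–Whitney U statistic counts pairs in which
the second sample beats the first in the direction of the alternative;
its exact null distribution over all `choose(n1+n2, n1)` labelings is
computed by the count-of-partitions recursion
`N(m, n, u) = N(m−1, n, u−n) + N(m, n−1, u)` (supported to
n1+n2 ≤ 40), and the p-value is the exact upper tail. The direction of
each comparison is supplied by the caller and recorded — the test
itself never guesses a hypothesis. Ties fall back to midranks with a
tie-corrected continuity-corrected normal approximation, flagged in
the result; the printed tables this package ships contain no ties. At
n1 = n2 = 5 the smallest attainable one-tailed p is exactly
1/252 ≈ 0.004.

## Ensemble ML residue importance

For an interface (a pair of domains), every cross-interface residue
pair whose minimum heavy-atom distance drops below 10 Å in at least
one frame of any replicate of either state becomes a feature: the
inverse of that per-frame distance, standardized over all frames of
both states to mean 0, sd 1. "Contact distance" is taken as minimum
heavy-atom distance; the convention is recorded in the run log since
atom-level definitions vary across the literature. The procedure then
repeats 20 times (seeds `seed+0 … seed+19`): greedy removal of
features correlated above |r| = 0.9 in a freshly shuffled visiting
order, then training of three classifiers on all frames — ridge
logistic regression (small fixed penalty, which keeps coefficients
finite under the perfect separation the procedure demands), a random
forest with impurity importance, and a single-hidden-layer perceptron.
Training accuracy is checked against 1.0; the perceptron is
re-initialized (up to 5 restarts) until it reproduces the training
labels, since the procedure is defined by training *to* accuracy 1.0,
and a warning is raised when any model cannot separate the states
(this is the expected outcome under a null difference, and a test
asserts it). There is no held-out split: the models are per-run
diagnostics of separability, not predictive deliverables.

Per model, a residue's importance is the sum of the importances of the
surviving pairs containing it (pruned pairs contribute zero), averaged
over the 20 iterations and normalized so the per-model maximum within
the interface is 1. The perceptron's importance is the mean absolute
first-layer weight per input — conventions for MLP attribution vary,
and permutation importance would be an equally defensible choice;
mean first-layer weight was chosen for determinism and speed, and the
choice is recorded in results. The 0.8 importance threshold is applied
per interface (normalization makes the threshold meaningful only on a
bounded scale).

Categories combine three per-residue criteria: ml_flag (importance
strictly > 0.8 in ≥ 1 model), energy_flag (|ΔΔG_Total| ≥ 2 kJ/mol
between states), and rmsf_flag (the 1/3 Å order-dependent RMSF
thresholds). Category 3 = all three; category 2 = ml_flag plus exactly
one of the other two; category 1 = ml_flag alone. The ML criterion is
strict (0.8 exactly does not flag) while the energy and RMSF criteria
are inclusive, following the ≥/> distinction in how the cutoffs are
stated.

## The synthetic generator and what passing tests mean

`synthetic_spec()` defines a toy complex of two ideal α-helices
(backbone N, CA, C, O, H; 5 atoms per residue) facing each other
across a flat interface, with toy charges (per-residue neutral) and
element-based LJ parameters. Ensembles are generated per state and
replicate from independent RNG streams: every residue receives an
independent rigid per-frame Gaussian displacement (default per-axis sd
0.6 Å, i.e. a realistic Cα RMSF of about 1 Å), so hydrogen-bond and
secondary-structure geometry survive the noise. Planted signal comes
in three forms with exact ground truth:

- **Contacts**: a (chain A, chain B) residue pair is placed so its
  CA–CA distance is Normal(state mean, jitter) each frame, the
  displacement shared symmetrically by both residues so each carries
  the pair's distance signal into the ML features.
- **Fluctuations**: per-residue, per-state jitter sd; the expected
  ΔRMSF is approximately √3·|σ_b − σ_a| (approximate because fitting
  and residue averaging shrink it slightly).
- **Hydrogen bonds**: the acceptor is placed inside the geometric
  criteria in a Bernoulli(q) fraction of frames and at 5.5 Å
  otherwise, so occupancy recovers q within binomial error.

Defaults mirror the replicate structure of the targeted study design
(5 replicates per state); desk-scale analyses in the tests use 8–10
residues per chain and 30–1000 frames per replicate, sizes chosen so
the full suite runs in minutes on one CPU while every statistical
bound retains its stated margin. The generator emulates the
*statistical* structure the pipeline assumes — state-separable
distances, Gaussian positional noise, controlled occupancies — and
deliberately not the physics: there is no force field, no solvent
box, no correlated backbone motion, no side chains. Passing its tests
demonstrates that the estimators recover what was planted under the
assumed noise model; it says nothing about force-field accuracy or
sampling convergence on real systems.

One design consequence worth spelling out: moving a residue to plant a
contact necessarily perturbs its distances to *all* nearby partners,
so neighbours of planted residues acquire a genuine (leaked) share of
the separating signal. The planted jitter (0.6 Å) and state separation
(3 Å) were chosen so that distinct planted pairs remain below the 0.9
pruning correlation while each planted pair still separates the states
perfectly in combination — the regime the end-to-end recovery tests
exercise. Recovery is asserted as a ranking (all planted-pair residues
above all noise residues) rather than as exact importance values,
which is the property the method actually promises.

## Numerical choices and degenerate inputs

- Kabsch superposition refuses collinear or coincident selections
  (second singular value ≈ 0) rather than returning an arbitrary
  rotation.
- Shrake–Rupley points exactly on a neighbour's sphere count as buried
  for the lower-indexed atom only, so coincident identical atoms
  contribute their shared surface exactly once.
- Energy evaluation raises a singularity error below 10⁻⁶ Å
  separation and names the first atoms missing parameters.
- Correlation pruning treats an all-constant column (zero variance) as
  uncorrelated rather than NA.
- `window_frames()` refuses to duplicate frames when asked for more
  samples than the window contains.
- Occupancy denominators always use the windowed frame count, never
  the full trajectory.

## Command-line use

`inst/scripts/mdcompare.R` is a thin wrapper exposing `run` (full
configuration-driven pipeline), `tables` (replicate-table
reproduction), `simulate` (write a synthetic ensemble set) and `mwu`
(one exact test) from the shell. The R functions remain the primary
interface; every stage is independently callable.

## Known limitations

- The polar solvation term is only as good as the ingested table; with
  none, ΔG_total omits polar screening entirely (logged, but easy to
  overlook when comparing absolute values across publications).
- The four-code secondary-structure scheme will disagree with full
  DSSP at helix termini and isolated bridges by construction.
- XTC/DCD readers are not bundled; trajectories arrive as multi-model
  PDB (converters are ubiquitous).
- The exact Mann–Whitney implementation targets small replicate
  counts; beyond n1+n2 = 40 it switches to the normal approximation.
- Entropy terms (normal-mode, quasi-harmonic) are out of scope, as is
  any force-field parameter derivation.
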