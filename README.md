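# mdcompare

Comparative analysis of molecular dynamics trajectories across protein
states.

`mdcompare` is an R toolkit for the question "what changed?" between
molecular dynamics ensembles of the same protein complex simulated in
several states — for example a drug-bound heterodimer in its
unmodified, point-mutated and phosphorylated forms, each sampled as
five independent replicates. It implements the full comparative
pipeline downstream of the simulations themselves:

- **Flexibility profiling** — Kabsch least-squares superposition,
  per-frame RMSD, Cα-RMSF against a fixed reference structure, and
  flagging of residues whose RMSF changes by ≥ 1 Å (ordered) or ≥ 3 Å
  (disordered) between states.
- **Secondary structure** — a simplified four-code (H/E/T/C)
  Kabsch–Sander assignment (backbone H-bond energy
  `E = 27.888·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN)` kcal/mol, bond iff
  `E < −0.5`), summarized as per-residue percent-of-frames tables.
- **Hydrogen bonds** — geometric detection (donor–acceptor distance
  ≤ 3.5 Å, donor–hydrogen/donor–acceptor angle ≤ 30°, polar atoms
  only), per-replicate occupancy tables with a 10 % filter, and
  ligand–water–protein bridge scanning.
- **Energetics** — MM/PBSA-style binding-energy summaries under the
  single-trajectory convention: explicit Coulomb
  (`f = 138.935458 kJ·mol⁻¹·nm·e⁻²`) + Lennard-Jones cross-group
  interaction energy, a SASA-based nonpolar solvation term
  (`γ = 0.0226778 kJ·mol⁻¹·Å⁻²`, `b = 3.84928 kJ/mol`, Shrake–Rupley
  SASA), ingestion of externally solved polar terms, and per-residue
  decomposition whose residue contributions sum to the total.
- **Ensemble ML residue importance** — standardized inverse minimum
  heavy-atom distances of interfacial residue pairs (eligible if ever
  < 10 Å), shuffled pruning of correlated features (|r| > 0.9), ridge
  logistic regression + random forest + multilayer perceptron trained
  to separate two states at training accuracy 1.0, importances summed
  onto residues, averaged over 20 iterations and normalized to max 1;
  residues are then classified into categories 1/2/3 by combining
  importance > 0.8, |ΔΔG_Total| ≥ 2 kJ/mol and the RMSF thresholds.
- **Exact statistics** — the one-tailed Mann–Whitney U test with the
  exact small-sample null distribution (count-of-partitions
  recursion), replicate mean ± sd summaries and printed-table delta
  conventions.
- **Synthetic ground truth** — a generator of toy two-chain helical
  complexes with planted contact separations, fluctuation amplitudes
  and hydrogen-bond occupancies, used to validate every stage
  end-to-end.

## Worked example

Reproduce the replicate summary of a printed binding-free-energy table
(five replicate means per state, kJ/mol) together with its exact
one-tailed Mann–Whitney p-values:

```r
library(mdcompare)

t2 <- reproduce_tables(
  system.file("extdata", "table2_belzutifan_bfe.csv", package = "mdcompare"),
  comparisons = data.frame(reference  = c("holo", "holo", "holo-p"),
                           modified   = c("holo-G323E", "holo-p", "holo-G323E"),
                           alternative = "greater"))
t2
#> Replicate table summary (kJ/mol)
#>   holo             mean   -124.4 +/-  10.0 (n = 5)
#>   holo-G323E       mean    -72.7 +/-  10.1 (n = 5)
#>   holo-p           mean   -101.0 +/-  17.5 (n = 5)
#>   Delta holo -> holo-G323E:   51.7   one-tailed exact p = 0.004 (greater)
#>   Delta holo -> holo-p:   23.4   one-tailed exact p = 0.028 (greater)
#>   Delta holo-p -> holo-G323E:   28.3   one-tailed exact p = 0.008 (greater)
```

The ligand is destabilized by 51.7 kJ/mol in the mutant state and
23.4 kJ/mol in the phosphorylated state, both significant at the exact
one-tailed 5 % level with five replicates per state (the smallest
attainable p at n = 5 vs 5 is 1/252 ≈ 0.004, i.e. complete
separation).

A synthetic end-to-end run with planted signal:

```r
spec <- synthetic_spec(
  residues_per_chain = 8, replicates_per_state = 2,
  frames_per_replicate = 40,
  planted_contacts = data.frame(resno_a = 4, resno_b = 104,
                                mean_a = 6, mean_b = 9, jitter = 0.6))
g <- generate_ensembles(spec)
feats <- extract_pair_features(g$ensemble_a, g$ensemble_b,
                               toy_domain_map(spec), interface_id = 1)
residue_importance(feats, n_iter = 5, seed = 1)
#> importance_table: 16 residues (interface 1)
#>    residue    lr    rf   mlp
#>  B:ALA 104 1.000 1.000 1.000
#>    A:ALA 4 0.951 0.878 0.940
#>  B:ALA 105 0.281 0.127 0.340
#>  B:ALA 102 0.284 0.139 0.324
#>    A:ALA 7 0.270 0.103 0.321
```

The two residues of the planted contact rank first in every model;
their neighbours pick up the leaked share of the signal.

A configuration-driven run of the full pipeline
(`run_pipeline(config, outdir, seed)`) writes per-stage CSV tables, a
manifest and a run log; `inst/scripts/mdcompare.R` exposes the same
entry points from the shell (`run`, `tables`, `simulate`, `mwu`
subcommands).

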