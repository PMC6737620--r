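# hbstrength

Hydrogen bonds decide binding affinities, solubilities and membrane
permeation of drug-like molecules. The strength of a hydrogen-bond
acceptor (HBA) or donor (HBD) site is naturally expressed as the Gibbs
free energy ΔG of 1:1 complex formation with a monofunctional reference
partner in CCl₄ — 4-fluorophenol for acceptors, acetone for donors.
Experimental scales of this kind are small (roughly a thousand acceptors,
a few dozen donors); quantum-chemically computed free energies can
substitute for experiment after an affine calibration, and a machine-learned
model on top of such a database predicts site strengths instantly.

`hbstrength` is an R toolkit for building and applying that modelling
stack, for computational and medicinal chemists:

* **Site perception** on kekulized molecular graphs: every O, every N not
  bound to O as acceptors; R–OH, R–NH₂, R¹–NH–R², R–SH and terminal
  alkyne C–H as donors.
* **Fragment generation** by topological shells: the substructure up to
  the 4th shell around each site, with ring / ring+sidechain / chain
  cases, hydrogen capping, organic-subset filtering (elements, ≤3 rings,
  MW < 300 Da, ≤4 sites, neutral), canonical-SMILES deduplication and
  MACCS/Tanimoto diversity selection.
* **Radial atomic descriptors** of the site atom: charge shell (CS),
  priority-sorted shell, mass shell (MS), topological charge
  autocorrelation (GACF), spatial charge RDF (CRDF) and spatial charge
  autocorrelation split by sign (CACF), combinable into a combinatorial
  descriptor.
* **Energetics**: composition of ΔG<sub>sol,QC</sub> = ΔE<sub>high-level
  DFT</sub> + ΔG<sub>RRHO</sub> + Δ δG<sub>solv</sub> from
  (complex, molecule, reference) triples, and the affine calibrations
  onto the experimental scales,

  HBA: ΔG = 0.56·ΔG<sub>sol,QC</sub> − 20.12 kJ/mol  
  HBD: ΔG = 0.63·ΔG<sub>sol,QC</sub> − 20.94 kJ/mol,

  plus OLS refitting with fold-stability reporting (`hb_calibration()`).
* **Curation & statistics** for strength databases: X–H distance cutoffs
  (2.40 Å HBA / 2.65 Å HBD), imaginary-mode cutoff (−50 cm⁻¹),
  per-class summaries, histograms and distance–energy Pearson
  correlations.
* **Gaussian-process regression** (`hbgpr()`) with the combined kernel
  K = C·Matérn(ν) + white(0.05), seeded multi-restart marginal-likelihood
  optimization, ten-fold CV, learning curves, and an applicability domain
  gated on the GPR variance estimate (1.96·σ) against 4.2 / 3.2 kJ/mol
  role thresholds.
* **Synthetic fixtures** so the entire pipeline is testable without any
  quantum chemistry or external download.

SDF (V2000) and SMILES I/O uses a configurable property-tag dictionary
matching the dialect of published HBA/HBD strength databases; OpenBabel
(via ChemmineOB) backs SMILES interpretation, canonical SMILES and MACCS
keys.

## Worked example

```r
library(hbstrength)

mol <- smiles_to_mol("CC(=O)NCCO", names = "N-acetylethanolamine")[[1]]
sites_table(list(mol))
#>   record atom_index role  site_kind donated_h_index
#> 1      1          3  HBA O_acceptor              NA
#> 2      1          4  HBA N_acceptor              NA
#> 3      1          7  HBA O_acceptor              NA
#> 4      1          4  HBD   NH_donor              11
#> 5      1          7  HBD   OH_donor              16
```

The amide molecule exposes three acceptor sites (carbonyl O, amide N,
hydroxyl O) and two donor sites (amide N–H, hydroxyl O–H). Extracting the
4th-shell fragment around the carbonyl oxygen gives an N-ethylacetamide
fragment, a pure chain case:

```r
extract_fragment(mol, find_sites(mol, "HBA")[[1]])
#> <hb_fragment> HBA O_acceptor (chain) key=CCNC(=O)C incidence=1
```

A quantum-chemically composed free energy of −22.5 kJ/mol calibrates to
the experimental acceptor scale as:

```r
calibrate(-22.5, role = "HBA")
#> [1] -32.72
```

Refitting the calibration on 425 synthetic pairs drawn from the published
regime (slope 0.56, intercept −20.12, residual sd 2.6 kJ/mol) recovers it
and shows the fold stability:

```r
pairs <- make_calibration_pairs(n = 425, seed = 1)
hb_calibration(pairs$dg_qc, pairs$dg_exp, "HBA")
#> HBA calibration: dG = 0.5534 * dG(sol,QC) -20.3486 kJ/mol  [data]
#>   10-fold stability: slope rel. sd 0.508%, RMSE 12.92 -> 2.66 kJ/mol
```

The pre-calibration RMSE (~13 kJ/mol here) is the systematic
quantum-chemistry offset; calibration collapses it to the residual scale.
A GPR strength model over descriptor vectors returns means with variance
estimates and applicability flags:

```r
cfg  <- fixture_config(n_molecules = 120, seed = 7)
dat  <- make_synthetic_strength_data(make_toy_molecules(cfg), cfg = cfg)
fit  <- hbgpr(dat$X, dat$y, kernel_config(nu = 1.5), role = "HBA", seed = 1)
fit
#> <hbgpr> HBA model: n = 185, p = 10; Matern kernel (nu = 1.5), C = 0.6232,
#>   l = 0.01722, noise = 0.05
predict(fit, dat$X[1:3, ])[, c("mean", "variance_estimate")]
#>     mean variance_estimate
#> 1 -27.75              5.86
#> 2 -27.75              5.86
#> 3 -49.52              5.86
```

Fixture targets are deliberately independent of the descriptors, so the
variance estimates exceed the 4.2 kJ/mol acceptor threshold and the
predictions are flagged outside the applicability domain — the correct
response to uninformative features (see the vignette).

A command-line front end ships at `inst/cli/hbstrength`
(`convert`, `sites`, `fragment`, `describe`, `calibrate`, `curate`,
`stats`, `simulate`, `train`, `predict`, `cv`).

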