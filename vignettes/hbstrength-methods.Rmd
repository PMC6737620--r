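---
title: "Modelling hydrogen-bond acceptor and donor strengths with hbstrength"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling hydrogen-bond acceptor and donor strengths with hbstrength}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

The strength of a hydrogen-bond acceptor (HBA) or donor (HBD) site can be
expressed as the Gibbs free energy of 1:1 complex formation with a
monofunctional reference partner in an apolar solvent: 4-fluorophenol for
acceptors and acetone for donors, both in CCl4.  Experimental scales of this
kind (such as the FTIR-derived pK_BHX basicity scale) cover on the order of a
thousand acceptors and only a few dozen donors.  Quantum chemistry can
substitute for experiment: composing a high-level electronic energy
difference, a rigid-rotor/harmonic-oscillator (RRHO) thermal correction and
an implicit-solvation contribution gives a reaction free energy in solution,

$$\Delta G_{sol,QC} = \Delta E_{\text{high-level DFT}}
  + \Delta G_{\text{RRHO}} + \Delta\delta G_{\text{solv}},
\qquad \Delta X = X(\text{complex}) - X(\text{molecule}) - X(\text{reference}),$$

which, after an affine calibration against experiment, yields strengths on
the experimental scale for arbitrarily many computed sites.  On top of such
a database, a Gaussian-process regression (GPR) over radial atomic
descriptors of the site atom predicts strengths instantly, with a
predictive-variance estimate that doubles as an applicability-domain gate.

`hbstrength` implements everything around the quantum chemistry: site
perception, fragment generation, descriptors, calibration, database
curation and statistics, the GPR model, and a synthetic fixture generator.
The quantum chemistry itself (semi-empirical charges, DFT energies,
Hessians, solvation) is out of scope; its outputs are consumed as numbers
from SDF property tags.

## Molecules and I/O

All molecular graphs are kekulized: bond orders are the integers 1–3, never
an aromatic type.  Heteroaromatic fragments are the mainstay of acceptor
chemistry, and aromaticity perception differs between toolkits while
explicit alternating bonds do not.  SDF input with aromatic-typed (order 4)
bonds is kekulized on read by perfect matching; records admitting no kekulé
structure are quarantined with their ordinal and reason rather than
silently dropped, mirroring the loss accounting a curated database needs.
SMILES input is interpreted by OpenBabel, which emits kekulized molblocks.

Strength databases are SDF files whose property tags carry per-site free
energies, site indices, complex geometry metadata and optionally the three
energy-component triples.  Tag names differ between database dialects, so
the readers take a tag dictionary (JSON-configurable, see
`default_tag_dict()`) and fail loudly listing the tags actually present
when a required tag is missing.  Energies are stored internally in kJ/mol;
Hartree or kcal/mol inputs are converted on read (1 Hartree = 2625.4996
kJ/mol).  When energy triples are present, the composed value is checked
against any stored total to 1e-6 kJ/mol.

Atom indices are 1-based throughout and coincide with V2000 SDF numbering,
so the internal/serialized index conversion is the identity; round-trip
identity is asserted in the test suite on randomized molecules.

## Site perception

Acceptors: every oxygen, and every nitrogen except those covalently bound
to an oxygen (any bond order).  The exclusion removes nitro, N-oxide and
nitroso nitrogens while keeping both nitro oxygens — a nitro group
contributes two acceptor sites and no nitrogen site.  Donors follow
R-substituted patterns: R–OH, R–NH2, R1–NH–R2 (secondary amines,
heterocyclic and amide N–H), R–SH and terminal alkyne C–H.  The R
requirement (at least one heavy-atom neighbor; for alkynes, a substituent
on the triple-bond partner) excludes bare water, ammonia and acetylene.
An NH2 group yields one site whose donated hydrogen is the lowest-index
attached H.  Charge states are taken as given; neutrality is enforced
later by the fragment filter, not here.

A carboxylic acid therefore contributes two acceptor sites and one donor
site, which is why acid moieties top both fragment incidence lists when a
large compound collection is fragmented.

## Fragment generation

Around each site, the substructure up to the fourth topological shell is
extracted, with three cases decided in priority order:

* **ring** — the site atom is in a ring: its complete fused ring system
  plus all atoms within 4 bonds.
* **ring + sidechain** — a ring atom occurs within 3 bonds of the site:
  the complete fused ring system(s) of those atoms plus all atoms within
  4 bonds.
* **chain** — otherwise: all atoms within 4 bonds; ring atoms appearing
  exactly in the 4th shell are element-substituted by an sp³ carbon cap,
  preserving shell occupancy without importing ring context.  (The
  substitution target is a design choice; preserving the original element
  would leak ring chemistry into an otherwise acyclic fragment.)

Fused ring systems are connected components of the subgraph of ring bonds.
Severed bonds are capped with hydrogens, one per bond-order unit, so
valences stay saturated.  Fragments are deduplicated by canonical SMILES
(computed by OpenBabel, isomorphism-invariant), with incidences summed and
provenance concatenated.

The filter keeps a fragment iff its elements are within the organic set
{H, C, N, O, F, Cl, S, Br, I}, its ring count is at most 3, its molecular
weight is strictly below 300 Da, it has at most 4 sites of its role, and
its net formal charge is zero.  The weight correction is plain molecular
weight by default; an optional halogen-corrected mode discounts Br/I to
chlorine weight, for workflows that do not want heavy halogens to consume
the weight budget.  Each rejection reports its first failing rule, and
tightening any threshold can only shrink the kept set (a tested
invariant).

Classes combine the site element (O, N for acceptors; O, N, S, Csp for
donors) with the topology case.  Within each class, diversity selection
computes 166-bit MACCS structural keys, clusters under Tanimoto distance
into `max(1, floor(N/25))` clusters by maximum-dissimilarity seeding with
medoid refinement, and keeps the most central members of each cluster
(3 by default, hard-capped at 30).  The published workflow used a
proprietary clusterer; this deterministic, seeded replacement favors
reproducibility over fidelity to an unpublished implementation.  Whether
the 30-fragment cap applies per cluster or per class is ambiguous in the
source description; both counts are exposed as parameters
(`keep_central`, `cluster_cap`) and no intent is guessed.  Note that the
`N/25` divisor presumes classes of thousands of fragments; on small sets
(tens of fragments) it degenerates to a single cluster whose central
members are deliberately *similar*, so small-scale diversity work should
lower `k_divisor` and/or `keep_central`.

## Radial atomic descriptors

Six families encode the electronic and steric environment of the site
atom, all centered there, hydrogens included:

| family | content | length |
|---|---|---|
| CS | mean partial charge per topological shell | K |
| sorted-shell | per-shell charges in substituent-priority order, padded to W slots | K·W |
| MS | summed atomic masses per shell | K |
| GACF | topological charge autocorrelation: per shell k, the sum of q_center·q_j | K |
| CRDF | spatial charge RDF: g(r) = Σ_j q_j exp(−β(r−d_cj)²) on a grid | grid |
| CACF | spatial charge autocorrelation of q_center·q_j products, split into positive and negative parts | 2·grid |

Defaults: K = 4 shells and W = 4 slots (matching the 4-shell fragment
radius), grid 1.0–8.0 Å in 0.5 Å steps, β = 4 Å⁻².  The exact tuned
parameter sets behind the published 151-/115-dimensional combinatorial
descriptors are not printed in the main text; every constant is therefore
exposed in `descriptor_spec()` and the forms above are this package's
normative contract.  The spatial autocorrelation is center-anchored
(products against the site atom only), consistent with the atomic —
rather than whole-molecule — framing of the descriptors.

The "CIP" ordering of the sorted-shell descriptor is implemented as
deterministic substituent priority: descending atomic number, then
recursively compared neighbor environments (depth 3), ties broken by
descending charge then input index.  Full stereochemical CIP machinery is
unnecessary for ordering shell members and would add nothing testable.

Charges come from the record's `ATOM_CHARGES` tag (in the published
databases, CM5 charges from a semi-empirical tight-binding calculation);
without stored charges the package falls back, with a warning, to
electronegativity-difference pseudo-charges so that desk-scale runs work
without any quantum chemistry.

Empty shells make the averaging families undefined (division by zero).
Strict mode — the default — marks the whole site descriptor-inapplicable,
which is exactly how sites drop out of training sets (a molecule with no
4th shell cannot fill a K = 4 charge-shell block); `zero_fill` is opt-in.
`combine_blocks()` concatenates chosen families in order and records the
block layout, so any slice of the combinatorial descriptor can be
attributed to its family.

## Calibration

Composed free energies are systematically off against experiment — the
RRHO and solvation contributions are too repulsive — and are mapped onto
the experimental scales by affine calibration.  The canonical models,
stored at the printed 2-decimal precision, are

$$\text{HBA: } \Delta G = 0.56\,\Delta G_{sol,QC} - 20.12 \text{ kJ/mol},
\qquad
\text{HBD: } \Delta G = 0.63\,\Delta G_{sol,QC} - 20.94 \text{ kJ/mol}.$$

`hb_calibration()` refits by ordinary least squares (unweighted — no
weighting scheme is published) and reports k-fold stability: relative
standard deviations of per-fold slopes and intercepts, and RMSE before and
after calibration.  Refitting never silently replaces the canonical
defaults; `calibrate()` uses the published models unless handed a fitted
one.  Under the published regime (425 pairs, residual scale 2.6 kJ/mol)
the fitted slope's fold-wise relative standard deviation stays below 1%,
which the tests assert by simulation.

## Curation and statistics

Complex entries are rejected when the optimization did not converge, when
the hydrogen-bond X–H distance in the optimized complex exceeds 2.40 Å
(acceptors) or 2.65 Å (donors), or when an imaginary normal mode is more
negative than −50 cm⁻¹ (an incompletely optimized structure).  The X–H
cutoff is read as the H···heavy-atom contact distance, consistent with the
1.7–2.6 Å range such contacts span (a covalent X–H stretch would sit near
1 Å and the cutoffs would be vacuous).  Distances are taken from a tag
when stored and otherwise recomputed from the complex 3D coordinates via
tagged atom indices.

`database_summary()` reports per-class and total n/mean/sd/min/max of the
calibrated free energy and the X–H distance plus histogram counts (1
kJ/mol and 0.05 Å default bin widths); group means weighted by n
reproduce the total mean to numerical precision (tested).
`distance_energy_correlation()` is the plain Pearson coefficient,
restrictable by site element — element subsetting is unambiguous where
functional-class strings are not.

## Gaussian-process regression

The covariance is K = C·M + W: a constant factor C (optimized on a log
scale in [1e−3, 1e3]), a Matérn kernel M with fixed smoothness ν ∈ {0.5,
1.5, 2.5} and length scale l optimized in [1e−2, 1e2], and a white kernel
W with fixed noise 0.05.  The Matérn form carries a fixed non-negative
scale γ (default 1, under which ν = 3/2 reduces to the textbook
(1+√3 d/l)exp(−√3 d/l)).  RBF and rational-quadratic kernels are
available for kernel scans.

Targets are standardized before fitting, so the fixed 0.05 noise lives on
the standardized scale; 0.05 kJ/mol of absolute noise would be physically
negligible against the ~2.6 kJ/mol uncertainty of the underlying data,
while 0.05 in standardized units is a sensible observation-noise floor.
Hyperparameters maximize the log marginal likelihood via L-BFGS-B from
five log-uniform restarts under the run seed — the published bounds
constrain the search space, not the optimizer protocol, so a deterministic
seeded multi-restart is used.

Predictions return the posterior mean (back-transformed to kJ/mol) and a
*variance estimate* defined as 1.96 × the posterior standard deviation —
the 95% interval half-width, which is the reporting convention the
applicability-domain thresholds are stated in; the raw standard deviation
is also exposed.  A prediction is outside the applicability domain when
its variance estimate exceeds 4.2 kJ/mol (acceptors) or 3.2 kJ/mol
(donors) — the floors the training-set variance estimates fall to with
full data; the boundary is inclusive.

`kfold_cv()` does seed-deterministic shuffled ten-fold cross-validation
with per-fold and pooled RMSE / R² / Spearman / mean variance estimate.
`learning_curve()` evaluates nested training fractions 0.1–1.0 on the
training fraction itself, tracking how the variance estimate tightens
with data — the behavior that justifies variance-gated applicability in
the first place.

## The synthetic fixture generator

`make_toy_molecules()` enumerates small molecules from a template grammar
(seven functional families × alkyl growth), assigns deterministic
electronegativity-difference pseudo-charges (κ = 0.1, Pauling scale;
antisymmetric per bond, so molecular charge is conserved exactly) and
embeds deterministic stand-in 3D coordinates (seeded BFS placement with
clash avoidance).  `make_synthetic_strength_data()` draws latent composed
free energies Uniform(−60, 10) kJ/mol — the span of the composed-energy
scale — and maps them to "experimental" targets through a configurable
linear model defaulting to the acceptor calibration regime (slope 0.56,
intercept −20.12, residual sd 2.6 kJ/mol).  It also emits energy-component
triples that compose exactly to the latent values, and hydrogen-bond
distances coupled to the targets by a Gaussian copula (normal scores of
the targets, correlated latent normal, normal distance marginal) at
Pearson ρ = 0.5, the magnitude of the acceptor database's
distance–energy correlation.  The coupling coefficient compensates the
normal-scores attenuation of the non-normal target marginal so that the
realized Pearson correlation is ρ itself.

What the generator does *not* emulate matters for interpreting green
tests: charges and geometries are not physical, and the targets are
independent of the descriptors by construction — so a GPR trained on
fixture data learns nothing, its training RMSE approaches the target
standard deviation, and its variance estimates flag almost everything as
outside the applicability domain.  That is the correct behavior on
uninformative features and is reported as such by the acceptance script.
Passing tests demonstrate the correctness of the machinery (composition,
calibration recovery, copula structure, kernel algebra, curation
monotonicity), not predictive performance on real chemistry.

## Numerical choices and degenerate inputs

* Kernel matrices get a 1e−10 jitter on top of the white noise before
  Cholesky; a factorization failure raises an error with conditioning
  diagnostics rather than silently regularizing further.
* Calibration refuses fewer than 3 pairs or an x-variance below 1e−12;
  correlation refuses zero variance in either variable.
* Strict empty-shell failures propagate through `combine_blocks()` so a
  site is either fully applicable or fully excluded — never a partially
  fabricated row.
* Ties in the diversity clustering (equal distances) resolve to the
  lowest index; the seeding RNG is isolated so library calls do not
  disturb the caller's RNG state.
* Boundary semantics: curation cutoffs reject strictly beyond the
  threshold; the applicability domain is inclusive at the threshold; the
  fragment weight filter is strict ("below 300 Da").
* The fragment-count filter admits up to 4 sites (inclusive): the
  published methods text says "less than four" but the shipped databases
  are described as containing fragments with one to four acceptor sites;
  the database description wins and the bound is a parameter anyway.

## Problem sizes in the shipped tests

The suite exercises SDF round-trips on 100 randomized molecules,
descriptor oracles on 50 random graphs, calibration recovery at the
published n = 425 over 20 replicates, GP length-scale recovery at n = 120
over 10 seeds, learning curves at n = 90, and copula validation on ~2000
synthetic sites — sizes chosen so the whole suite runs in a few minutes
on one core while still pinning every contract.

## Known limitations

* The published 151-/115-dimensional descriptor parameterizations, the
  exact ChEMBL23 fragment sets (162,732 / 50,268 unique fragments) and
  the internal-CV RMSEs depend on unpublished inputs and are explicitly
  not reproduced; the machinery to recompute all of them from the
  original inputs is here.
* Validation against the published databases (4426 acceptor / 1036 donor
  entries, means −7.72 / −2.08 kJ/mol, distance–energy correlations
  0.52 / 0.60 / 0.42) requires the article's supplementary SDF files,
  which are too large to ship with the package: place them under
  `inst/extdata/supplementary/` and reinstall to activate those checks.
* Tautomers, pKa-based protonation and C–H donors other than terminal
  alkynes are out of scope, as are SDF V3000 and reaction formats.
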