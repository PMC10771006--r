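---
title: "Property-profile drug-likeness scoring: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Property-profile drug-likeness scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the hybrid property-profile representation, the drug-likeness classifier
built on it, the evaluation machinery, and the places where the design was
genuinely open and a choice had to be made.

## 1. The representation

A molecule enters the model as 26 numbers:

* **Physicochemical block (6 values).** Molecular weight, Wildman–Crippen
  logP, Ertl topological polar surface area, hydrogen-bond acceptor and
  donor counts, and rotatable bonds.  These are computed natively from the
  molecular graph: logP by per-atom typing against the published
  atom-contribution table (first-matching-pattern semantics, hydrogens
  typed by their heavy neighbour), TPSA from the published N/O fragment
  contributions (S/P contributions optional and off by default, matching
  the convention of the QED desirability functions).  Both calculators
  were validated during development against an independent reference
  implementation on a 57-molecule panel (logP agreement to 1e-14, TPSA
  exact), and the packaged QED reference values
  (`inst/extdata/qed_reference.csv`) keep that cross-check in the test
  suite permanently.
* **ADMET block (20 values).** An ordered panel of binary classifiers,
  each emitting the probability of an unfavourable (or favourable —
  direction is endpoint-specific) outcome: absorption (HIA, Caco-2), oral
  bioavailability, metabolism/clearance (clearance plus two CYP-inhibition
  slots), excretion, six transporter-inhibition endpoints (OATP1B1,
  OATP1B3 and four placeholder slots), and seven toxicity endpoints
  (mitochondrial membrane potential, hepatotoxicity, mutagenicity, oral
  acute toxicity, genotoxicity, carcinogenicity, respiratory toxicity).
  The exact identity of every published endpoint model is not public;
  slots marked `placeholder = TRUE` in `default_panel()` make this
  explicit and are replaceable through a YAML panel configuration without
  touching the 20-slot contract.

The two blocks are combined with a weighting parameter γ ∈ [0, 1]:

$$\mathrm{Profile}(\gamma) = \big[(2-2\gamma)\,\mathrm{PC}_{scaled},\;\; 2\gamma\,\mathrm{ADMET}\big]$$

γ = 0.5 gives both blocks unit weight; γ = 1 silences the physicochemical
block.  The default γ = 0.6 tilts slightly toward the ADMET block and is
re-derivable on any dataset with `gamma_sweep()`.

**Why min–max scaling of the PC block is mandatory.**  Raw physicochemical
values live on wildly different scales (MW in hundreds, counts in units)
while ADMET values are probabilities in [0, 1].  Without a common scale
the γ weighting would be meaningless — a 1.2× factor on MW ≈ 350 would
always dominate a 0.8× factor on a probability.  The package therefore
min–max scales the PC block on the *training* ranges (queries outside the
range are clipped to [0, 1]) and stores those ranges with the model.  The
block-scaling invariance test (an unpenalized logistic fit absorbs any
positive block rescaling into its weights) verifies the weighting is
applied exactly where claimed.

## 2. The classifier layer

Three families are supported, mirroring common practice for 26-dimensional
tabular data: regularized logistic regression (glmnet, ridge; the grid is
expressed as C ∈ {0.01, 0.1, 1, 10, 100} with λ = 1/(nC)), RBF support
vector machines (e1071, same C grid, Platt-scaled probabilities), and
gradient-boosted trees (xgboost, 100 rounds, learning rate 0.1,
`max_depth` ∈ {3, 5, 7, unlimited} × `max_leaves` ∈ {15, 31, 63} under a
leaf-wise growth policy — the tree-shape grid of leaf-wise boosting
frameworks).  Grid search is seeded stratified 5-fold CV on AUC, ties
broken toward the first grid row.  All fits are single-threaded and
seeded, so a fixed seed reproduces byte-identical score files.

The default family for the shipped model is gradient-boosted trees — the
strongest general performer on small tabular problems; the other two
remain one keyword away.

## 3. Evaluation machinery

* **Metrics.**  Accuracy, recall, specificity and precision from the
  confusion counts; F1 as the harmonic mean of precision and recall (the
  profile evaluation tables report F1 alongside AUC without further
  definition, so the standard harmonic mean is used).  Any metric with a
  zero denominator is `NA`, never silently 0.  AUC is computed by rank
  statistics — exactly the Mann–Whitney U scaled by \(n_+ n_-\), ties
  counted half — and is checked against exhaustive pair counting in the
  tests.
* **Cross-validation.**  Stratified by label (the protocol says "ten-fold"
  only; stratification is the field default for balanced designs), seeded
  fold assignment, every preprocessing step (PC ranges, descriptor
  scalers, grid search) re-fitted inside each training fold.  `k = n` is
  supported as leave-one-out, where stratification is vacuous and
  single-observation folds report `NA` AUC.
* **γ sweep.**  Cross-validated AUC and F1 per candidate γ; the selection
  maximizes their unweighted mean ("according to the AUC and F1 values"
  leaves the combination open; the unweighted mean is the least-informative
  choice), with exact ties broken toward 0.5, the most balanced weighting.
* **Mann–Whitney comparisons.**  Two-sided, normal approximation with tie
  correction (`wilcox.test(exact = FALSE)`); the score-distribution report
  carries per-set n, mean and quartiles plus all pairwise tests, and keeps
  the raw score vectors for violin plotting.
* **PU spy analysis.**  The positive-unlabeled procedure is realized as
  the standard two-step spy technique: hide a fraction (default 15%) of
  positives among the unlabeled set, train positive-vs-unlabeled, set the
  reliability threshold at the 5th percentile of spy scores, report the
  fraction of unlabeled samples above it, averaged over replicates.  This
  is an interpretation — the source protocol names the approach but not
  its parameters — and both the spy fraction and the quantile are
  arguments.
* **Shapley attributions.**  For tree models the package ships a
  double-precision implementation of the polynomial-time tree-path
  Shapley algorithm (Rcpp); attribution row sums plus the base value
  reconstruct the model margin to ~1e-15, and the implementation is
  cross-checked against the booster's built-in (float32) attribution
  engine to 1e-4.  For linear models the closed form
  \(\phi_j = w_j (x_j - \bar{x}_j)\) is used, whose importance ranking
  equals the ranking of \(|w_j|\,\mathrm{sd}(x_j)\) up to the
  normal-distribution constant.  SVM models have no attribution path.

## 4. Standardization rules

Three steps, applied to every molecule that enters any model: (1) in
multi-fragment records, fragments on a fixed counterion/solvate list are
stripped and the survivor neutralized to the parent acid/base (Open
Babel's neutralization operation; quaternary ammoniums and other permanent
charges are left intact); (2) records that still contain several organic
fragments are rejected as mixtures, and records without a carbon atom as
inorganic — "inorganic" is operationalized as the no-carbon rule, the
standard cheminformatics convention; (3) the survivor is written as the
package-wide canonical SMILES (one fixed Open Babel canonicalization
routine; equality of these strings defines molecular identity everywhere,
including deduplication and caching).  When every fragment of a record is
on the salt list, the largest fragment is kept — this makes
`ethanol·HCl → ethanol` behave as expected even though ethanol itself is
a listed solvate.  Deduplication keeps the first occurrence; structures
carrying both labels keep the drug record (curated positives outrank
sampled negatives), and the number of such conflicts is reported.

## 5. Featurization choices

* **200-descriptor vector.**  The published descriptor set is named after
  a package whose exact member list is not printed, so the vector here is
  pinned by the package's own manifest: 72 native physicochemical,
  constitutional, hybridization and topological descriptors plus 128
  functional-group SMARTS counts (`inst/extdata/fragment_smarts.tsv`).
  Positions are stable; `descriptor_names()` is the contract.
  Normalization is z-scoring fitted on training data only, zero-variance
  descriptors mapping to 0.
* **Fingerprints.**  MACCS (166 structural keys, via Open Babel), Morgan
  radius-2 (ECFP4 folded to 2048 bits by OR), hashed atom pairs (2048),
  a path-based fingerprint (all simple bond paths of length 1–7, canonical
  direction, FNV-1a hashed into 2048 bits) and topological torsions
  (4-atom linear paths, same hashing).  Bit positions are internally
  consistent and deterministic but not bit-compatible with other
  toolkits; Tanimoto statistics and model inputs only ever compare the
  package's own fingerprints with each other.  The mean pairwise Tanimoto
  is taken over the off-diagonal upper triangle.
* **Murcko scaffolds.**  Ring systems plus linkers, obtained by
  iteratively pruning terminal atoms; terminal atoms attached to the
  framework by a double or triple bond are retained (benzophenone keeps
  its carbonyl).  The framework subgraph is serialized by a native SMILES
  writer and canonicalized, so scaffold identity shares the package-wide
  canonical dialect.  Scaffolds were validated against an independent
  implementation on a 40-molecule panel during development.
* **QED.**  The weighted quantitative estimate of drug-likeness: the
  geometric mean of asymmetric-double-sigmoid desirabilities of eight
  properties (MW, logP, acceptor SMARTS counts, donors, TPSA, strict
  rotatable bonds, aromatic rings, structural-alert hits), using the
  published coefficient tables.  Aromatic ring count is the cycle rank of
  the aromatic-bond subgraph.  The packaged 40-molecule reference table
  pins agreement with an independent implementation to 1e-3 in the
  acceptance tests; the panel intentionally consists of well-behaved,
  common structures whose aromaticity perception is identical across
  toolkits, so the tests certify the calculator, not the rare corner
  cases where aromaticity models legitimately diverge.

## 6. The synthetic-data generator

`generate_profiles()` emulates the drug-vs-non-drug profile structure:
drug-class physicochemical values are drawn from plausible drug-like
distributions (lognormal MW with median 350 g/mol and log-sd 0.35, normal
logP centred at 2.5, gamma-distributed TPSA with mean 80 Å², Poisson
counts for HBA/HBD/rotors), the non-drug class is shifted by `pc_effect`
in units of each coordinate's nominal spread; ADMET coordinates are
inverse-logit transforms of class-dependent normals (drug mean +1 on the
logit scale, i.e. mostly favourable predictions), the non-drug class
shifted down by `admet_effect`, so each coordinate's generative AUC is
`pnorm(effect / (sqrt(2) * noise_sd))` in closed form.
`generate_endpoint_dataset()` produces two-class Gaussian tables over the
200 descriptor names with the class shift carried by a seeded random
subset of 20 features.  These distribution choices are fixture
conventions: they create controllable class separation with realistic
marginal shapes, but they do not reproduce the correlation structure,
multimodality or chemistry-induced constraints of real compound
collections.  Passing tests on these fixtures therefore certifies the
machinery (representation, training, evaluation, attribution), not
real-world screening performance, which depends on the user's endpoint
models and training compounds.

Reference study conditions used by the acceptance suite: strong signal =
`admet_effect = 2`, 1000 profiles, ten-fold CV (AUC ≥ 0.95 expected);
null = all effects 0 (AUC in [0.45, 0.55]); γ directionality at
`admet_effect = 1` vs `pc_effect = 0.8` with an RBF-SVM over five seeds —
the kernel geometry makes the SVM genuinely sensitive to block weighting,
whereas tree models are split-scale-invariant and feel γ only at the
degenerate endpoints; PU analysis at 300 + 300 profiles with a 15% spy
fraction.  Problem sizes were chosen to make each property statistically
unambiguous at interactive runtimes.

## 7. Numerical and degenerate-input decisions

* Probabilities are never hard-thresholded inside the panel: the ADMET
  block keeps full probability information (a "bit vector" reading would
  discard the very gradations the γ weighting acts on).
* The druggability call uses a strict `score > threshold` comparison, so
  a compound scoring exactly at the threshold is not recommended.
* Zero-variance descriptors z-score to 0; constant PC ranges scale to 0
  and clip; single-class folds report `NA` metrics rather than 0.
* Molecules without heavy-atom bonds (water, monoatomic ions) get
  explicit hydrogens before SMARTS matching so their connection tables
  are non-empty; SMARTS semantics for the profile properties are
  otherwise evaluated on hydrogen-suppressed graphs.
* Tree-model comparisons reproduce the float32 split semantics of the
  booster (thresholds compared in single precision), which makes the
  compiled attribution path agree with the booster's own predictions at
  boundary cases.
* The seeded down-sampling of negatives uses `seed XOR replicate_id`, so
  the three parallel replicates are individually reproducible and
  pairwise distinct.

## 8. Known limitations

* The twenty endpoint models shipped by `train_synthetic_panel()` are
  demonstrations on synthetic data; scientific use requires training the
  panel on real endpoint datasets via the panel configuration.
* The 0.736 druggability threshold is a published calibration constant;
  on a user's own reference drug set `derive_threshold()` should be
  preferred.
* Canonicalization, aromaticity perception and fingerprints follow Open
  Babel's chemistry model; structures whose aromaticity is perceived
  differently by other toolkits may featurize differently.
* Tautomers are not canonicalized and stereochemistry is neither repaired
  nor used by any descriptor (the representation is 2-D topological).
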