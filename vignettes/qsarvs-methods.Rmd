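---
title: "Ligand-based virtual screening with qsarvs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ligand-based virtual screening with qsarvs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsarvs)
```

## The problem

High-throughput screening (HTS) campaigns test on the order of $10^5$–$10^6$
small molecules against a protein target and typically confirm only a few
hundred actives — hit rates of 0.05–0.7%, active:inactive ratios of 1:100 to
1:1000. Quantitative structure–activity relationship (QSAR) models learn the
mapping from molecular structure to activity on such data and then rank
unscreened libraries *in silico*, so that a small, activity-enriched subset
can be tested experimentally. `qsarvs` implements the full ligand-based
pipeline: curation of active/inactive sets from primary, confirmatory and
counter screens; fixed-length molecular descriptor encoding; stratified
cross-validation with separate training, monitoring and independent roles;
four orthogonal learners; descriptor-set selection; and evaluation through
specificity–sensitivity curves, enrichment factors and consensus
predictions.

## Activity scale

All models regress a single continuous target, the negative decadic
logarithm of the half-maximal inhibitory (or effective) concentration in
molar units,
$\mathrm{pIC}_{50} = -\log_{10}(\mathrm{IC}_{50}/1\,\mathrm{M})$.
Three conventions make heterogeneous assay records usable
(`p_activity_transform()`):

* an active with a measured potency uses it directly (25 µM → 4.6,
  0.1 µM → 7);
* an active without a reported potency is assigned a representative 1 µM
  (pIC~50~ = 6), inside the range where confirmed HTS actives typically
  fall (0.1–25 µM);
* every inactive is set to 1 mM (pIC~50~ = 3).

The scale therefore runs from 3 upward, differential potency information is
kept where it exists, and a hard active/inactive label can be recovered by
thresholding (the package default cutoff is 3.5 where one is needed).

## Molecular descriptors

A molecule is an atom/bond graph with optional 3D coordinates
(`molecule()`, `read_sdf()`). The encoded feature vector is fragment
independent and transformation invariant: its length never depends on atom
count, and permuting atoms or rigidly moving coordinates cannot change it
(both properties are tested).

**Per-atom properties.** Nine chemical properties are computed per atom
(`atom_property_table()`): atomic number; σ-, π- and total partial charges;
σ-, π- and lone-pair orbital electronegativities; effective polarizability;
and a total-charge variant kept as a separate catalogue slot. σ charges use
damped partial equalisation of orbital electronegativity: six iterations of
per-bond charge transfer $\Delta q = (\chi_j - \chi_i)/\chi^+ \cdot (1/2)^k$
with the published orbital-electronegativity polynomials
$\chi(q) = a + bq + cq^2$. Implicit hydrogens are expanded into pseudo-atoms
for the iteration and their charge folded back into the parent, so per-atom
total charges sum exactly to the molecular formal charge (a tested
invariant). Heteroatoms whose lone pair conjugates into an adjacent π
system (amide N, carboxyl OH oxygen) take sp² parameters, which is what
brings carboxyl charges in line with reference implementations; on a small
reference set our σ charges agree with RDKit's to < 0.005 e. π charges run
the same damped scheme over bonds of order ≥ 1.5 starting from zero. The π
and lone-pair electronegativity polynomial tables are not part of the
published σ set; the versioned CSVs shipped under `inst/extdata/params/`
are package-defined approximations and are flagged as such there. The
ninth property (labelled `vc2003_charge`) is served as the total
partial-equalisation charge — a deliberate, documented substitute, since
the parameters of the original charge model it stands in for are not
available. Effective polarizability is the distance-damped sum
$\alpha_i = \sum_j \alpha_j (1/2)^{d_{ij}}$ over topological distances.
Per-atom van der Waals surface areas (sphere area minus spherical caps of
bonded neighbours) provide the weighting variant below; parity with any
specific reference implementation is explicitly a non-goal.

**Encoders.** Three encoding functions turn a property vector $p$ into a
fixed-length fingerprint:

* 2D autocorrelation, $\mathrm{ac}(d) = \sum_{i \le j,\ d_{ij} = d} p_i p_j$
  over topological distance $d = 0 \ldots 10$ (11 bins; self-pairs in
  bin 0, unordered pairs once);
* 3D autocorrelation, the same sum binned on Euclidean distance over
  half-open 1 Å bins covering 0–12 Å (12 bins);
* radial distribution function,
  $g(r_k) = \sum_{i<j} p_i p_j e^{-B (r_k - d_{ij})^2}$ on the grid
  $r_k = 0.1, 0.2, \ldots, 4.8$ Å with $B = 100\,\text{Å}^{-2}$ (48 values).

Each fingerprint is computed unweighted and once more with per-atom VdW
surface areas as weights. With six scalar descriptors (molecular weight,
H-bond donors and acceptors, logP, net formal charge, topological polar
surface area) the default catalogue is
$6 + 9 \times 2 \times (11 + 12 + 48) = 1284$ values in 60 groups. The
published description of this catalogue fixes only those two totals, not
the per-encoder bin counts; the bin counts above are this package's
defaults, chosen to match the totals, and everything is configuration
driven (`descriptor_config()`), so alternative resolutions remain
available. Hydrogens participate in pair encoders according to a documented
policy (`participating_atoms()`): heavy atoms plus polar hydrogens by
default; implicit hydrogens contribute to property values but never appear
as pair partners since they carry no geometry.

logP and TPSA are reduced atomic-contribution implementations:
Wildman–Crippen-style per-element logP terms and published Ertl fragment
values for the N/O/S/P environments this molecule model can express. They
are deliberately coarse — adequate as descriptor columns, not as reference
property predictors — and molecules outside the supported element set fail
loudly rather than silently contributing zeros.

## Dataset curation

Active sets of real campaigns are defined by set algebra over assay
outcomes: confirmatory screens validate primary hits, counter screens
remove artefacts and non-selective binders. `curate()` evaluates a recipe —
a nested union/intersect/subtract expression over named assays' active or
inactive sets — and takes inactives from a designated primary assay minus
any curated active, so the sets are disjoint by construction. Nine recipe
files matching the benchmark campaigns of the public PubChem collection
ship under `inst/extdata/recipes/`; the raw assay tables themselves are
external inputs, so tests exercise the engine on synthetic tables with
planted overlaps (`generate_assay_tables()`) against a brute-force set
enumeration. `dataset_stats()` reports hit rate (two decimals, percent) and
the inactives-to-actives ratio (nearest integer), the presentation used
throughout.

## Cross-validation design

`partition_dataset()` splits actives and inactives separately into $k$
near-equal partitions (stratification keeps the rare class represented
everywhere), keyed by a seeded hash of the compound id so the assignment is
reproducible across row orderings. A full plan (`make_cv_plan(10, "full")`)
designates every ordered pair of distinct partitions as (independent,
monitoring) and trains on the remaining eight — $10 \times 9 = 90$
configurations, 80% of the data training each model, every compound
independent at least once. The reduced plan used during descriptor
selection fixes the independent partition and cycles monitoring over the
rest; the wording "five-fold with one independent configuration" does not
pin down the partition count, and this package resolves the ambiguity as
$k = 6$ (five splits, monitoring over partitions 2–6), configurable.

Because inactives dominate, two rebalancing steps apply:
`reduce_inactives()` caps the inactives in training and monitoring
partitions (defaults 30,000 and 10,000, never touching the independent
partition), and `oversample_actives()` replicates actives cyclically until
they match inactives — applied only to ANN/SVR training partitions; trees
and Kohonen maps train unbalanced, and evaluation data are never
oversampled.

## Learners

All four learners sit behind `qsar_train(x, y, method, ...)`, which
min-max-normalises features on the training rows only and returns a classed
model with `predict`/`print`/`summary` methods. Reference hyperparameters
live in `model_spec()`; where the methodology this package follows leaves a
value unstated (hidden-layer size, SVR tube width, Kohonen grid), the
defaults below are this package's choices, picked once on monitoring
performance of the synthetic fixtures.

* **ANN** — one hidden layer of 32 sigmoid units, sigmoid output on the
  min-max-scaled target, full-batch "simple propagation" weight updates
  with learning rate η = 0.2 and momentum α = 0.5. The monitoring
  partition's full-range TNR-TPR integral is checked every 5 epochs;
  training stops after 10 checks without improvement and the
  best-on-monitor weights are returned, so early termination can never
  yield a model worse than its best checkpoint (tested). Training is
  bit-reproducible from the seed.
* **SVR** — ε-insensitive support vector regression with RBF kernel via
  `e1071::svm`; C = 1 and γ = 0.1 during descriptor selection, ε = 0.1. A
  constant training target is answered by a constant model (the SV problem
  is degenerate there). `grid_search_svm()` optimises (C, γ) exhaustively
  over powers of two (C ∈ 2^−3^…2^9^, γ ∈ 2^−9^…2^1^) by monitoring
  objective, ties to smaller C then smaller γ.
* **DT** — CART via `rpart` with Gini splitting on the binary labels
  (pIC~50~ > 3). A leaf scores by its training active fraction $s$, mapped
  onto the activity scale as $3 + 4s$ so that thresholding and consensus
  averaging operate on one scale for all methods.
* **KN** — a Kohonen self-organising map (10 × 10 default grid, 100
  epochs). Each epoch assigns every sample to its winning node and pulls
  node weights toward the Gaussian-neighbourhood-weighted batch means; the
  neighbourhood width decays linearly from half the grid diagonal to 0.5
  and the learning rate from 0.5 to 0.01. A node predicts the mean
  training pIC~50~ of its members; empty nodes inherit the nearest
  populated node's value. The batch formulation keeps training
  deterministic given the seed.

The ANN and the Kohonen map are implemented in-package because the
monitoring-driven early termination, per-check training log and
node-regression layer they need are not available in the installed
alternatives; both are small, tested implementations, not ports of any
reference code.

## Descriptor selection

Three routes produce a reduced descriptor set, all operating on groups (a
scalar, or one property × encoder × weighting fingerprint) as atomic units:

* **Information gain** — for each column, $H(\text{labels})$ minus the best
  weighted conditional entropy over single binary thresholds (midpoints of
  consecutive distinct values). This discretisation admits an exact
  exhaustive oracle, against which the implementation is property-tested.
* **F-score** — $((\bar x^+ - \bar x)^2 + (\bar x^- - \bar x)^2)/(s_+^2 +
  s_-^2)$ with class sample variances; an exactly zero denominator reports
  0 for coincident class means and `Inf` otherwise.
* **SFFS** — deterministic greedy forward selection: each round trains a
  reduced-CV model set for every candidate addition and keeps the group
  with the best mean objective, stopping after ten consecutive rounds
  without improvement (or `max_rounds`, a compute-budget cap) and
  returning the best cumulative set ever seen. Ties break to the lower
  group index; failed candidates are skipped and logged.

A group's filter score is the maximum over its member columns — any single
discriminating bin should promote its group, and appending a duplicated
column can never change a score (tested). The filter rankings do not decide
how many top groups to keep; `select_top_groups()` evaluates nested
prefixes (sizes 1, 2, 4, …, 60) with the reduced CV and keeps the argmax,
since the source methodology leaves the set size unstated.

## Evaluation

With actives rare, accuracy is meaningless; the package's objective is the
curve of true-negative rate (specificity) against true-positive rate
(sensitivity) — the ROC curve rotated 90° clockwise — swept over score
thresholds with tied scores handled atomically. Its trapezoidal integral
over the full range equals the AUC (0.5 for a random ranking, 1 for a
perfect one; verified against an independent concordance computation), and
the partial integral over TPR ∈ [0, 0.25] (`integral_to_cutoff()`) focuses
on the early ranking that matters in virtual screening: a perfect model
scores 0.25 there, a random one 0.21875. `enrichment()` reports the
complementary experimentalist's view: at the largest threshold reaching the
target sensitivity, precision divided by the baseline active fraction —
bounded above by $(P+N)/P$.

`consensus_predict()` averages predicted pIC~50~ values over all
cross-validation models of any set of methods (Eq.-style unweighted mean
over models). `consensus_ranking()` evaluates every non-empty method subset
(15 for four methods) on independent data, ranks by enrichment (ties:
fewer methods first), and reports the gain of the best multi-method
consensus over the best single method normalised by the
inactives-to-actives ratio, in percent. The rounded integer ratio is used
in that normalisation, matching the presentation convention.

## Synthetic fixtures and what they show

`generate_library()` builds valence-valid random molecules (C/N/O/S/F/Cl
alphabet, 5–14 heavy atoms) with template geometry: atoms placed at ideal
covalent bond lengths in directions repelled from existing neighbours. No
conformer search is performed — template geometry is sufficient to exercise
the 3D encoders, which is its only job. `generate_activity()` makes
activity a threshold on a named descriptor group (defaulting to the first
bin of the polarizability 2D autocorrelation), drawing active potencies
log-uniformly from 0.1–25 µM, with optional label noise.
`standard_fixture()` bundles the package's end-to-end benchmark: 5,000
compounds at a 1:100 active:inactive ratio with one informative group.

These fixtures emulate the *shape* of HTS data — extreme class imbalance,
activity driven by structure-derived descriptors, heterogeneous potencies —
but not its difficulty: real pharmacophores are not single-descriptor
thresholds, real labels are noisier, and real chemistry is far more
diverse. A passing end-to-end suite therefore demonstrates that the
machinery (featurisation → selection → training → evaluation) is correct
and that the learners can recover a known signal; it does not predict
performance on real campaigns.

## Numerical choices and degenerate inputs

* Min-max normalisation maps constant columns to zero rather than dividing
  by zero; fitting statistics come from training rows only.
* Curve sweeps treat tied scores as one step; integrals are trapezoidal;
  interpolation at the partial-integral cutoff is linear.
* Quantities are deterministic given seeds: every stochastic step
  (partitioning, sampling, weight initialisation, fixture generation)
  takes an explicit seed, and derived per-split seeds stay below 2³¹.
* Single-atom molecules are legal: pair encoders return self-pair-only
  (or zero) fingerprints; the SDF reader accepts bond-free records (a
  reason its record parser is in-package).
* Molecules without coordinates raise an explicit no-geometry error from
  3D encoders instead of computing on fake geometry; during matrix
  assembly such molecules are excluded with a per-molecule report.
* Unknown elements and absent parameter rows are hard errors, never
  silent zeros.

## Problem sizes used by the test suite

The shipped tests favour depth over size: unit fixtures use tens to
hundreds of rows, the end-to-end benchmark uses the standard fixture at its
defining 5,000-compound scale with the reduced (five-split) plan, the
decision tree as the SFFS objective learner, and a capped SFFS round count
— the round-1 selection the benchmark asserts is unaffected by the cap,
and the ten-round stopping rule is exercised separately on a cheap
fixture. The Monte Carlo check of the random-predictor integral uses
100,000 compounds at 1% actives.

## Known limitations

* Aromaticity is taken from input bond flags; no perception, no
  stereochemistry, no conformer generation.
* The π/lone-pair electronegativity tables and the logP/TPSA reductions
  are package-defined approximations, suitable for descriptor columns
  rather than property prediction.
* Numerical parity with any closed-source descriptor implementation is a
  non-goal; totals, conventions and invariants are what is guaranteed.
* Headline benchmark results on the real PubChem campaigns require the
  original assay tables (hundreds of thousands of outcomes each) and
  thousands of model trainings, and are out of scope for the shipped
  suite; the package reports whatever its inputs yield.
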