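---
title: "Re-ranking nanobody-antigen docking poses: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Re-ranking nanobody-antigen docking poses: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbrank)
```

## The problem and the model

Rigid-body docking of a nanobody (Nb) onto its antigen (Ag) returns a list
of *parent* poses; local refinement expands each parent into several
*refined* children. The program's native ranking of parents is often poor
for Nb–Ag complexes, whose interfaces differ systematically from general
protein–protein and conventional antibody interfaces (heavier CDR3 use,
framework residues in the paratope). `nbrank` learns a *nativeness* score
for refined poses and uses it to re-order the parents.

The pipeline has four stages.

**Labelling.** A refined pose is compared with the native complex through
DockQ, the continuous [0, 1] combination of three classical docking-quality
components:

$$\mathrm{DockQ} = \tfrac13\left(F_\mathrm{nat}
 + \frac{1}{1 + (\mathrm{iRMS}/d_1)^2}
 + \frac{1}{1 + (\mathrm{LRMS}/d_2)^2}\right),\qquad d_1 = 1.5,\; d_2 = 8.5.$$

$F_\mathrm{nat}$ is the preserved fraction of native cross-chain residue
contacts (any heavy-atom pair within 5 Å, inclusive); iRMS is the backbone
(N, CA, C, O) RMSD over the native interface residues (both chains, 10 Å
heavy-atom shell) after least-squares superposition on exactly those atoms;
LRMS is the nanobody (ligand) backbone RMSD after superposing on the
antigen (receptor) backbone. The binary label is 0 (non-native-like) iff
DockQ < 0.23 and 1 otherwise; the CAPRI bands are [0, 0.23) Incorrect,
[0.23, 0.49) Acceptable, [0.49, 0.80) Medium, [0.80, 1] High. The boundary
convention is deliberate: 0.23 itself is native-like, because the
non-native condition is the strict inequality.

**Features (248 columns).** `feature_schema()` fixes the order
contact (52) | Rosetta (20) | FoldX (44) | property (132):

* *Contact block*: paratope and epitope sizes; per-CDR interacting-residue
  counts and loop lengths; the fraction of the paratope lying inside the
  CDRs; the fraction of each CDR loop that is interacting; and 20 + 20
  per-amino-acid interface composition counts. The interface is
  distance-defined (5 Å heavy-atom, inclusive) — the same contact notion
  used by the $F_\mathrm{nat}$ label component, so features and labels
  cannot disagree about what "contact" means. A buried-surface-area
  definition would be a defensible alternative; the distance form was
  chosen for this consistency and because it needs no SASA engine.
* *Energy blocks*: canonical column sets of Rosetta's InterfaceAnalyzer
  (20 terms, including the interface energy density `dG_cross/dSASAx100`)
  and FoldX's AnalyseComplex (44 terms: the pairwise interaction
  decomposition plus per-group terms). The two programs are never run by
  the package; their score files are parsed by column name. An absent term
  is an explicit `NA`, never a silent zero — the tree learner handles
  missingness natively, and poses without energy runs remain usable in a
  contact+property schema (184 columns).
* *Property block*: element-wise sums of a 66-column amino-acid descriptor
  table over paratope residues and over epitope residues (132 columns;
  non-standard residues contribute zero).

**Classifier.** XGBoost with a logistic objective maps feature vectors to
labels. Defaults: 300 trees, depth 6, learning rate 0.1, subsample 0.8,
single thread, fixed seed (identical inputs give bitwise-identical
predictions). The positive class is up-weighted by
$n_\mathrm{neg}/n_\mathrm{pos}$ of the training side by default, since
realistic docking sets are heavily imbalanced toward incorrect poses; the
weight can be overridden or disabled. No feature scaling is applied — tree
ensembles are invariant to monotone rescaling.

**Re-ranking and evaluation.** A parent's score is the arithmetic mean of
its children's predicted probabilities; parents are sorted descending
within each docking run (complex × docking mode). Ties break by the
maximum child probability, then by parent id, so rankings are
deterministic. Evaluation pools the ranks of native-like parents over the
repeated partitions and reports median/75th/95th percentiles (type-7
linear-interpolation quantiles — stated because percentile conventions
differ), PR-AUC over refined poses, and a two-sided Wilcoxon matched-pairs
signed-rank test against a comparator ranking of the same parents.
SHAP-style additive attributions (TreeSHAP, on the log-odds scale, where
the base value plus the per-feature contributions reproduce each margin
prediction) give per-pose explanations; mean |contribution| gives global
importance.

## Grouped partitioning

Data are split by *complex identifier*, never by pose: all refined poses of
one complex land on one side of every partition. Children of a single
parent are near-duplicates in feature space, so pose-level splits would
leak and inflate test performance. "5-fold cross-validation" is
implemented as five repeated, independently seeded 80/20 grouped
partitions (seeds `seed + 0..4`) — repeated random partitions rather than
five disjoint folds, matching the repeated-partition description of the
procedure this package implements. The leakage invariant (zero shared
complexes per repeat) is asserted in the test suite.

Two further conventions were genuinely open and are fixed as follows:
a parent is *native-like* for evaluation iff its **own** DockQ is ≥ 0.23
(not a function of its children's labels), and the averaged probability
runs over the refined **children only** (the parent pose itself is not
among them). PR-AUC is computed per refined pose, matching the framing of
the classifier as a pose-level nativeness predictor.

## CDR annotation

Exact CDR spans are accepted from the user (JSON/YAML,
`{complex: {cdr1: [s, e), ...}}`, 0-based half-open) and returned verbatim
after validation. Without user spans, a built-in anchor heuristic is used:
the two conserved framework cysteines are located (first `C` in positions
16–30 and 85–110), CDR1/CDR2 are placed at fixed Chothia-like offsets from
the first cysteine (+4..+10 and +30..+35), and CDR3 runs from two residues
after the second cysteine to the first `WG.G` J-segment anchor.
Structures for which any loop cannot be resolved are rejected, mirroring
the exclusion of complexes with missing CDR loops. The heuristic
substitutes for an external CDR-conformation database so the package has no
network dependency; on real sequences user spans are preferred and exact.

Internally all residue positions are 1-based (idiomatic R); only the
external span format is 0-based half-open, converted on read. Residues are
matched across poses by author numbering (chain, residue number, insertion
code) with no alignment fallback — poses of one complex are expected to
share numbering, and a mismatch is an error rather than a silent guess.

## The descriptor table

The property block is patterned on the ten published amino-acid descriptor
families — Cruciani properties (3), Kidera factors (10), z-scales (5),
FASGAI (6), T-scales (5), VHSE (8), ProtFP (8), ST-scales (8), BLOSUM
indices (10), MS-WHIM (3); 66 descriptors in total. The original published
tables are not redistributed with the package. Instead
`aa_descriptor_table()` derives, deterministically at runtime, a stand-in
with the same family names and sizes: each family is a set of unit-variance
principal components of a hardcoded matrix of classical residue constants
(Kyte–Doolittle hydropathy, residue mass, pI, van der Waals volume,
Grantham polarity, net charge, aromaticity, Chou–Fasman helix/sheet
propensities, side-chain rotatable bonds, H-bond donor/acceptor counts,
maximal ASA) under family-specific emphasis weights, and the `blosum`
family is the true first ten principal components of BLOSUM62. Components
are orthogonal within a family and sign-fixed, so sums over interface
residues behave like the published scale sums (hydrophobicity-dominated
components track interface hydrophobicity, size components track bulk).
These values are **not** the original published scales; analyses that need
the literature tables should substitute them via the `table` argument of
`property_profile()`.

## What the synthetic generator emulates — and what it does not

`simulate_dataset()` stands in for the external structure-preparation and
docking stages. Chains are ideal helical mini-domains with a pseudo-backbone
(N, CA, C, O, CB): an antigen of 60 residues and a nanobody of ~110–125
residues whose sequence carries the planted anchor motifs, crossed so that
the CDR3 segment forms the interface (placement is accepted only with ≥ 5
native contacts at 5 Å and no atom pair below 2 Å; the antigen orientation
is re-drawn up to the retry cap if needed). Parents are rigid-body
perturbations of the nanobody cycling through translation scales
(1, 3, 8, 16, 32 Å paired with 3, 8, 20, 45, 90°); parents at the two
smallest scales are rejection-sampled until native-like and the rest until
non-native-like — rejection sampling is used because DockQ is not
analytically invertible in rotation — so every docking run contains both
bands and re-ranking evaluation is never degenerate. Children add small
secondary perturbations (≤ 0.5 Å, ≤ 3°). Everything is reproducible from
the seed: identical configurations give byte-identical manifests, and
manifest labels equal labels recomputed from the emitted PDB files.

The defaults (12 complexes × 10 parents × 5 children = 600 refined poses;
the test suite uses 10 × 8 × 4 over three seeds) keep a full study in the
minutes range on one CPU. The generator deliberately does **not** emulate:
backbone or side-chain flexibility (decoys are rigid-body only), physically
realistic energetics (when the energy blocks are exercised they are filled
with documented pseudo-energy fixtures — affine functions of DockQ plus
seeded noise — or left missing), sequence realism beyond the planted
anchors, or the label imbalance of real docking output (bands are
deliberately populated, roughly 40% native-like, where a real self-docking
study is closer to 1–2%). Consequently, passing end-to-end tests shows the
machinery is correct and that a known signal is recovered — planted-feature
attribution ranks first, re-ranked native-like parents beat a seeded random
baseline — not that the learned model transfers to real Nb–Ag docking
decoys; the published-scale benchmark numbers cannot be reproduced without
the external docking and energy programs.

## Numerical choices and degenerate inputs

* Superposition is Kabsch via SVD with the determinant correction
  (proper rotations only); the test suite cross-checks against an
  independent quaternion (Horn) oracle at 1e-6 Å.
* All distance comparisons are inclusive (≤), so a pair exactly at a cutoff
  counts as a contact.
* A native complex with no cross-chain contacts (or an empty 10 Å
  interface) is a *degenerate native* error, not $F_\mathrm{nat}=0$:
  quality against such a reference is meaningless.
* Fewer than 3 shared backbone atoms for any superposition is an error.
* `frac_cdr_in_paratope` is the proportion **of the paratope** that lies in
  the CDRs (denominator $|\mathrm{paratope}|$, 0 for an empty paratope);
  the per-loop fractions use the loop length as denominator.
* The signed-rank test drops zero differences (p = 1 if all are zero), uses
  the exact distribution for ≤ 25 untied pairs and otherwise a normal
  approximation with continuity and tie corrections.
* PR-AUC uses the average-precision step form (sum of precision ×
  incremental recall over descending score thresholds); constant scores
  give the class prevalence.
* Structure reading keeps heavy atoms only (docking and refinement outputs
  vary in protonation), the first model of multi-model files, the first
  conformer per (chain, residue, atom name), and `HETATM` records only for
  common non-standard amino acids (sequence code `X`); chain ids default to
  `A` (antigen) and `H` (nanobody) and are configurable everywhere.

## Known limitations

Only two-chain complexes are supported (no light chains, no multi-chain
antigens, no mmCIF). The CDR heuristic targets well-behaved VHH framework
sequences; unusual frameworks need user spans. The canonical 20/44 energy
column lists fix one reasonable selection from each program's standard
output; score files with renamed columns need remapping before parsing.
The descriptor table is a documented package-derived stand-in, not the
published scales. Probability calibration is out of scope — predicted
probabilities order poses well before they mean calibrated frequencies,
and the re-ranking rule uses only their ordering within a docking run.
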