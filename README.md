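# nbrank

Machine-learning re-ranking of nanobody–antigen docking poses.

Rigid-body docking of a nanobody (VHH, the single variable domain of a
camelid heavy-chain antibody) onto its antigen produces tens of candidate
binding poses, and the docking program's own ranking often buries the
native-like ones. `nbrank` re-ranks the poses of a docking run with a
learned nativeness score:

1. **Label.** Every refined pose is scored against the native complex with
   DockQ,

   DockQ = ( Fnat + 1 / (1 + (iRMS/1.5)²) + 1 / (1 + (LRMS/8.5)²) ) / 3,

   where Fnat is the fraction of native cross-chain residue contacts (5 Å
   heavy-atom), iRMS the backbone RMSD over the native interface residues
   (10 Å shell) after superposing on them, and LRMS the nanobody backbone
   RMSD after superposing on the antigen. A pose with DockQ < 0.23 is
   non-native-like (CAPRI *Incorrect*, label 0); otherwise it is native-like
   (pooling *Acceptable*/*Medium*/*High*, label 1).
2. **Describe.** Each pose is turned into a 248-column profile: 52 contact
   features (paratope/epitope sizes, per-CDR interacting-residue counts and
   fractions, per-amino-acid interface composition), 20 Rosetta
   InterfaceAnalyzer terms and 44 FoldX AnalyseComplex terms ingested from
   externally produced score files (absent values stay explicitly missing),
   and 132 interface-property features (66 amino-acid descriptor sums for
   the paratope and for the epitope).
3. **Learn.** An XGBoost binary classifier maps profiles to labels under
   repeated grouped 80/20 partitions — complexes, never poses, are split, so
   no pose of a test complex is ever seen in training. Class imbalance is
   handled with a positive-class weight.
4. **Re-rank.** Each parent pose is scored by the arithmetic mean of its
   refined children's predicted native-like probabilities; parents of a
   docking run are sorted by that mean. Evaluation reports pooled rank
   percentiles of native-like parents, PR-AUC, and a Wilcoxon matched-pairs
   signed-rank comparison against a baseline ranking; per-feature
   SHAP-style attributions explain the model.

A synthetic-study generator builds toy two-chain complexes (helical
mini-domains with planted CDR anchor motifs) and seeded rigid-body decoys
spanning all DockQ classes, so the whole pipeline runs without any external
docking or energy program.

## Worked example

```r
library(nbrank)

cfg <- synthetic_config(n_complexes = 6, parents_per_complex = 8,
                        refined_per_parent = 4, seed = 42)
ds <- simulate_dataset(cfg)
ds
#> pose_dataset: 192 refined poses, 6 complexes, 184 features (96 native-like)

# docking quality of one perturbed pose against its native
nat <- make_native(cfg, 1)
pose_quality(nbrank:::perturb_nanobody(nat$native, 4, 15), nat$native)
#> DockQ 0.236 (Fnat 0.125, iRMS 4.47 A, LRMS 8.83 A) -> Acceptable, label 1

# plant a known informative feature, then train / re-rank / evaluate
ds <- plant_signal(ds, strength = 5)
report <- evaluate_reranking(ds, n_repeats = 3, seed = 42)
report
#> eval_report: 3 repeats, 12 pooled native-like parent ranks
#>   model    median 2.5  p75 3.2  p95 4.0
#>   baseline median 4.5  p75 6.0  p95 6.9
#>   Wilcoxon p = 0.0651; PR-AUC per repeat: 1.000, 1.000, 0.906

head(attribute_best(report, ds)$importance, 3)
#>                feature  mean_abs
#> 1       para_cruciani1 3.3819166
#> 2 frac_cdr_in_paratope 0.9430294
#> 3          epi_mswhim3 0.3670244
```

The report says: over the pooled test-side docking runs, half of the
native-like parents are ranked in the top ~2–3 by averaged child
probability, versus ~4–5 under a random permutation of the same runs; the
planted feature (`para_cruciani1`) is correctly identified as the dominant
signal, with the CDR-in-paratope fraction — a genuinely informative contact
feature on this generator — second.

Real structures enter through `read_complex()` (two-chain PDB files),
`quality_table()` (batch manifest of model/native paths), `annotate_cdrs()`
(user spans or built-in anchor heuristic), and the energy parsers
`parse_rosetta_scores()` / `parse_foldx_complex()`.

A thin command-line front end ships at `inst/exec/nbrank`
(`simulate`, `label`, `evaluate`, `attribute`).

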