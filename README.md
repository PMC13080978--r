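# rnapose

Post-docking analysis for RNA-targeted ensemble docking campaigns.

Ensemble docking of a congeneric small-molecule series against a flexible
RNA target leaves you with tens of thousands of poses across many receptor
conformations — and the question of *which binding mode, described by which
contacts, explains the measured affinity trend*. `rnapose` implements the
analysis half of such a campaign for structural bioinformaticians and
RNA-drug-discovery modellers:

* **Ensemble curation** — nucleotide base reference frames, pairwise
  **g-vectors** and the RNA-specific **eRMSD** metric
  \(\varepsilon(a,b) = \sqrt{\tfrac{1}{N}\sum_{j\neq k}
  |\mathbf G^{a}_{jk}-\mathbf G^{b}_{jk}|^2}\),
  with Quality-Threshold (QT) clustering at a 0.7 cutoff and retention of
  cluster medoids mutually farther than 0.7 to maximize structural
  variability of the docking ensemble.
* **Pose clustering** — symmetry-corrected scaffold RMSD
  \(d(a,b)=\min_{\pi\in\mathrm{Aut}}
  \sqrt{\tfrac{1}{m}\sum_i |\mathbf x^a_i-\mathbf x^b_{\pi(i)}|^2}\)
  (no superposition: poses share the receptor frame), automorphisms
  enumerated from the scaffold's colored bond graph, QT at 5 Å, and
  selection of the most populated clusters covering 50% of poses.
* **Interaction fingerprints** — geometric detection of hydrogen bonds,
  halogen bonds, lipophilic contacts, cation–anion, π-stacking, π-cation
  and π-anion, histogrammed by contact distance over 2–8 Å in 80 bins.
* **Trend analysis** — PCA on fingerprint bin populations, per-category
  PC-loading distance spans, per-(cluster, ligand) mean PC1 scores,
  ordinary least squares of log10(CD50) on mean PC1, and ranking of
  clusters by R² to name the binding mode that rationalizes affinity.
* **A seeded synthetic benchmark** — idealized helices, perturbed
  ensembles, a two-fold-symmetric congeneric series and pose sets with a
  *planted* interaction–affinity structure, so the entire pipeline is
  testable end to end with known ground truth.

## Worked example

Generate a planted benchmark and run the full pipeline on it:

```r
library(rnapose)

fx <- write_scenario_fixtures("fixtures", seed = 1)
cfg <- pipeline_config(
  rna        = fx$paths$rna,        # multi-MODEL PDB ensemble
  poses      = fx$paths$poses,      # SDF with ligand/site/conf/program tags
  affinities = fx$paths$affinities, # CSV with CD50 [uM], ">500" allowed
  manifest   = fx$paths$manifest,   # docking design YAML
  scaffold   = fx$paths$scaffold,   # ordered scaffold atom map YAML
  out_dir    = "fixtures/out",
  sites      = list(S1 = 10:27))    # binding-region residues
report <- run_pipeline(cfg)
report
#> <run_report>
#>   models: 10  poses: 3000  ligands: 15
#>   retained centroids: S1=1
#>   top cluster: S1/1 (R^2 = 0.858)
report$ranking
#>   cluster  r_squared      slope n_ligands
#> 1    S1/1 0.85828598 -0.2406860        13
#> 2    S1/2 0.02104366  0.3077553        13
```

Reading the output: the 3000 poses fall into three spatial binding modes
(QT at 5 Å); the two largest cover 75% of poses and enter the trend stage.
Cluster `S1/1` — the mode in which the generator planted
affinity-dependent polar contacts — ranks first with R² = 0.86 between
per-ligand mean PC1 and log10(CD50) over the 13 in-range ligands (the two
">500 µM" compounds are excluded by default). The negative slope says
higher PC1 (more hydrogen-bond / cation–anion contacts, fewer lipophilic)
means lower CD50, i.e. stronger binding; `report$pca$S1$loading_spans`
shows exactly those category signs and distance ranges.

Design bookkeeping uses the same machinery: the shipped study-shaped
manifest (11 + 6 conformations × 2 programs × 250 poses) gives

```r
expected_pose_counts(read_docking_manifest(
  system.file("extdata", "manifest_study.yaml", package = "rnapose")))
#> $per_site
#>   S1   S2
#> 5500 3000
#> $per_ligand_total
#> [1] 8500
#> $per_conformation
#> [1] 500
#> $grand_total
#> [1] 178500
```

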