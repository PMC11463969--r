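# thalamap

Tools for tracking how **first-order (FO)** and **higher-order (HO)**
thalamic neuron identities emerge from single-cell RNA-seq data of the
developing thalamus — for developmental neuroscientists who have mature
(postnatal) marker genes for the identities they care about, but embryonic
cells that do not yet express them.

FO nuclei (LG for vision, VB for somatosensation) relay peripheral input to
primary cortex; HO nuclei (LP, Po) sit in cortico-thalamo-cortical loops.
Mature markers separate the two cleanly after birth but are silent during
embryogenesis, so naive marker scoring cannot date the emergence of either
identity.

## The core algorithm

`identity_bootstrap()` implements an iterative **seed-cell marker
bootstrap**. For each category *c* with mature marker set
*M<sub>c</sub>*:

1. score every cell with the *pseudogene*
   *s<sub>c</sub>(i) = mean<sub>g∈M<sub>c</sub></sub> x<sub>ig</sub>*
   (mean log-normalized expression over the markers);
2. define **seed cells** as the terminal-stage cells with
   *s<sub>c</sub> ≥ Q<sub>0.99</sub>(s<sub>c</sub>)*;
3. re-derive stage-appropriate markers by one-vs-rest Wilcoxon rank-sum
   contrasts between seed groups, keeping the top 15 genes per category by
   log₂ fold-change;
4. assign each post-mitotic cell to
   *argmax<sub>c</sub> z(s′<sub>c</sub>)* over the derived pseudogenes
   (ties → the HO-side ground state), retaining only cells whose winning
   raw pseudogene reaches its 0.70 quantile.

Around it the package provides QC (cells < 200 detected genes, genes in
< 3 cells), log-normalization to 10⁴ counts, variance-stabilized selection
of 2,000 variable genes, 20-dimensional PCA, shared-nearest-neighbor
Louvain clustering, a kNN-graph geodesic pseudotime, clustering of
developmentally regulated genes into ordered transcriptional waves
(silhouette-selected k-means), a control-versus-input-deprived comparison
(condition DE, activity-dependent gene overlap, permutation-tested
maturation lag, subcluster label transfer), and a negative-binomial
synthetic-data generator with complete ground truth.

## Worked example

Simulate a six-age embryonic dataset (~2,000 cells), fit pseudotime, and
bootstrap FO/HO identities from the mature marker table:

```r
library(thalamap)

gcfg <- generator_config(seed = 42)
sim  <- simulate_dataset(gcfg)
cfg  <- pipeline_config()
mat  <- lognormalize(qc_filter(sim$matrix, cfg), cfg)
hvg  <- select_hvg(mat, pipeline_config(n_hvg = 1100))
emb  <- embed_pca(mat, hvg, cfg)
prog <- subset(sim$truth$genes, !is.na(wave) & wave == 1)$gene_id
pt   <- compute_pseudotime(emb, root_cell(mat, prog), cfg)
ref  <- reference_marker_table(sim$truth, 15)

fit <- identity_bootstrap(mat, ref,
                          terminal_mask = mat$cell_meta$age == "E18.5",
                          cells = cell_ids(mat)[pt >= 0.5], pt = pt,
                          cfg = cfg, categories = c("FO", "HO"))
fit
#> Seed-cell bootstrapped identity fit
#>   categories : FO vs HO (ground state HO)
#>   seed cells : FO=4, HO=4
#>   calls      : FO=256, HO=256, unassigned=339
#>   onset      : FO=0.879, HO=0.723
```

Four E18.5 cells per category seeded the marker re-derivation; 512 of 851
post-mitotic cells were confidently labeled. The onsets — the pseudotime at
which a category reaches half of its cumulative labeled cells — show HO
identity emerging well before FO (0.723 vs 0.879), the expected ordering
when the HO program opens early and persists while the FO program is late
and transient. `plot(fit)` draws the cumulative emergence curves;
`coef(fit)` returns the derived marker table.

Wave analysis on the same pseudotime recovers the four planted activation
programs in order:

```r
wa <- cluster_waves(smooth_profiles(mat, pt,
        subset(sim$truth$genes, !is.na(wave))$gene_id))
wa
#> WaveAssignment: 240 genes in 4 waves
#>   wave 1:  60 genes, mean peak t = 0.00
#>   wave 2:  60 genes, mean peak t = 0.27
#>   wave 3:  60 genes, mean peak t = 0.58
#>   wave 4:  60 genes, mean peak t = 0.89
```

For the postnatal comparison, `simulate_deprivation()` builds a deprived
twin cohort in which FO glutamatergic cells lag, and
`deprivation_report()` quantifies condition DE, the activity-dependent
share of the developmental program, and the permutation-tested maturation
lag per region and for interneurons.

`run_stage()` orchestrates all of this through files
(`simulate`, `deprive`, `preprocess`, `pseudotime`, `waves`, `identity`,
`deprivation-report`, or `all`), writing CSV/MTX/JSON outputs plus a
manifest per stage from a single YAML config.

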