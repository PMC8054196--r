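# ligandkit

Post-identification analysis of HLA ligandome (immunopeptidomics)
datasets, for researchers who have peptide identification tables from an
upstream database search and need everything that comes after it:
harmonized binder classification, sample quality control, dataset-level
FDR, similarity structure, source-protein coverage, target
prioritization, spectral validation and post-excision stability
analysis. A bundled synthetic-data generator produces all inputs with
planted structure, so the complete pipeline runs and is tested without
external downloads.

## What it computes

* **Harmonized binder categories.** A peptide–allotype pair is a
  *strong* binder if any predictor meets its strong percentile-rank
  threshold (NetMHCpan ≤ 0.5; NetMHCIIpan ≤ 1.0; MixMHC2pred ≤ 1.0),
  else *weak* if any meets its weak threshold (≤ 2.0 / ≤ 5.0 / ≤ 5.0, or
  SYFPEITHI score s_SYF ≥ 0.5 for class I), else *non*. One peptide may
  bind several of a donor's allotypes; all qualifying associations are
  kept.
* **Replicate QC.** Keep a technical replicate iff its predicted-binder
  fraction is ≥ 50% (HLA-I) / ≥ 10% (HLA-II) **and** its length-mode is
  9 (HLA-I) / within [12, 18] (HLA-II).
* **Global FDR.** With per-sample unique counts n_s filtered at local
  level q, the pooled estimate is `q · Σ n_s / n_unique` — equal to q
  without inter-sample redundancy, larger with it.
* **Sample similarity.** Jaccard index j = |A∩B| / |A∪B| between
  samples at peptide or source-protein level (optionally restricted to
  shared-allotype binders), UPGMA clustering on 1 − j, and
  subject-versus-tissue group contrasts.
* **Coverage and hotspots.** Per-residue stacks of class-I/II ligands
  over each source protein, four-group protein binning, proteome-wide
  coverage fractions, and hotspot calls (maximal covered runs with
  configurable minimum coverage, gap bridging and length).
* **Yields, enrichment, targets.** Median peptide yield per tissue; OLS
  of log10 yield on log10 RPKM one gene at a time (R², F-test p,
  Spearman rho); Fisher-exact over-representation against GMT gene
  sets; tumor-versus-benign set subtraction with patient frequencies;
  cancer-testis antigen cross-referencing (≥ 2 distinct ligands).
* **Spectral validation.** Intensity encoding over theoretical b/y ion
  slots (label-aware, ±0.02 Da), normalized spectral contrast angle
  λ(S₁,S₂) = 1 − 2·arccos(S₁·S₂)/π, and a 1000-pair random null; plus
  99% prediction-interval evaluation of retention-time predictions
  (interval width `pi`, contained fraction `frac`).
* **Time series.** Per-run z-scores (population SD), first-time-point
  median baselining, and seeded k-means trajectory clustering.

## Worked example

The numbered scripts under `analysis/` run the full workflow on a
synthetic atlas (6 subjects × 4 tissues, paired HLA-I/II samples, two
technical replicates each):

```sh
Rscript analysis/01_simulate.R      # writes results/bundle/
Rscript analysis/02_annotate_qc_fdr.R
Rscript analysis/03_similarity.R
# ... through analysis/07_timeseries.R
```

Output of stages 2–3 on the default seed:

```
annotated 9438 records; 96/96 replicates pass QC
HLA-I: 1771 unique peptides across 24 samples; global FDR 1.48%
HLA-II: 2312 unique peptides across 24 samples; global FDR 1.23%
HLA-I median j: same-subject 0.113 | same-tissue 0.018 | other 0.000
HLA-I: samples cluster by subject (adjusted Rand 1.00 at k = 6)
```

Reading: every simulated replicate passes both QC gates (binder
fractions are planted at 0.82/0.62, well above the cutoffs, with the
correct length modes); pooling 24 samples inflates the 1% local FDR to
1.5%/1.2% through inter-sample redundancy; and samples are far more
similar to the same subject's other tissues (median j = 0.113) than to
other subjects' same tissue (0.018), so the dendrogram recovers the six
subjects perfectly — the planted subject-dominant sharing. Stage 6
prints the spectral validation (`matched pairs: median lambda 0.762;
null 99th percentile 0.232`) and stage 7 the trajectory clustering
(`planted trajectory shapes recovered: ARI 1.00`).

The same computations are available directly, e.g.:

```r
library(ligandkit)
classify_binder(c(netmhcpan = 0.3), hla_class = "I")   # "strong"
global_fdr(counts = c(100, 300), total = 380)          # 0.0105
jaccard(c("a", "b", "c"), c("b", "c", "d"))            # 0.5
```

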