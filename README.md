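# accsig

Paired tumor–normal expression signatures and exon-level MYB rearrangement
calling for adenoid cystic carcinoma (ACC).

ACC is an aggressive salivary gland tumor recurrently driven by a t(6;9)
translocation fusing the 5′ exons of the MYB transcription factor to a
terminal NFIB exon. Profiling ACC tumors against matched normal tissue
yields a characteristic mRNA/miRNA signature — MYB strongly induced,
extracellular-matrix genes (VCAN, HAPLN1, …) up-regulated — that is present
even in fusion-negative and MYB-low tumors, implying parallel MYB-dependent
and MYB-independent programs. `accsig` implements that analysis chain as a
tested, reusable R package for transcriptomics analysts:

* **Paired signature derivation** — quantile normalization
  (`quantile_normalize`), baseline intensity filter (≥ 50 mRNA / ≥ 800
  miRNA) and paired |fold-change| ≥ 2 filter, per-probe paired t-tests
  (t = mean(d)/(sd(d)/√n), df = n−1) with Benjamini–Hochberg FDR at 0.05
  (`derive_signature`), plus fusion-group comparison, Ward clustering and
  PCA of samples.
* **Exon-level rearrangement calling** — the "exon plot" made algorithmic:
  on each tumor's per-exon log2 delta vector d, a two-segment scan
  statistic S(k) = (mean(d₁..k) − mean(d₍k+1..E₎)) / (s_p(k)·√(1/k+1/(E−k)))
  localizes the breakpoint (last retained 5′ exon) and `call_fusion`
  classifies tumors positive / negative / indeterminate, with a
  wildtype/reciprocal-allele assessment from terminal exon signal.
* **MYB-dependence classification** — tumors stratified by MYB level
  against the normal baseline (`stratify_by_marker`); genes activated in
  both strata are MYB-independent, genes activated only in MYB-high tumors
  are MYB-dependent candidates when backed by a ChIP-Seq target set
  (`classify_myb_dependence`).
* **Integration** — Fisher exact gene-set enrichment over the filtered
  universe, intersection of the up-signature with damaging somatic
  mutations, and inverse miRNA→target linking.
* **Synthetic cohort generator** (`generate_cohort`) — paired log-normal
  cohorts with planted fold changes (MYB 18×, ECM genes 2–30×), planted
  fusion breakpoints, one MYB-low tumor retaining the rest of the
  signature, planted down-regulated miRNAs, and full ground-truth tables,
  so every stage is testable without any download.

## Worked example

The `analysis/` directory holds the numbered drivers; running them in order
reproduces the whole analysis on a simulated cohort and writes its tables
under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_preprocess.R
Rscript analysis/03_signature.R
Rscript analysis/04_fusion_calls.R
Rscript analysis/05_integration.R
```

Output (abridged) from a run:

```
cohort: 5000 genes x 24 samples; 160 planted signature genes
fusion-positive tumors: 6; MYB-low tumor: ACC12_T
mRNA: 5000 probes; 4685 pass baseline >= 50; 188 also pass |fc| >= 2
mRNA signature: 188 significant probe sets at FDR 0.05
miRNA signature: 22 significant probes
fusion-pos vs fusion-neg: 0 significant probes at FDR 0.05
6/12 tumors called fusion-positive; breakpoints: ACC02_T@exon11, ACC04_T@exon11,
  ACC05_T@exon10, ACC08_T@exon14, ACC10_T@exon14, ACC11_T@exon13
terminal alleles silent in 6 of 6 positives
MYB-low tumors: ACC12_T
top enriched set: ECM (q = 9.6e-23, 16/16 genes)
up-regulated and mutated (candidate co-drivers): RUNX1
inverse miRNA-target links: hsa-miR-150 -| MYB (3.0-fold down, target 11.2-fold up);
  hsa-miR-29 -| HAPLN1 (2.5-fold down, target 15.6-fold up)
```

Reading it: the paired test recovers the planted signature (188 significant
probe sets for 160 planted genes — the excess reflects quantile
normalization's mild distortion of null genes, discussed in the methods
vignette); fusion-positive and fusion-negative tumors show *no* expression
difference; the exon scan recovers all six planted breakpoints and calls
the MYB-low tumor negative; the ECM set tops the enrichment ranking; and
the planted inverse miRNA regulators are linked to their targets.

Equivalently in R, one call runs the whole chain on a cohort object:

```r
library(accsig)
cohort <- generate_cohort(sim_config(seed = 1))
res <- run_pipeline(cohort, out_dir = "results/run1")
head(res$signature_mrna)
res$fusion_calls
```

Real data enters through the same readers the drivers use:
`read_expression_matrix()` (probe × sample TSV),
`read_sample_sheet()` (tumor/normal pairing), `read_exon_profile()`,
`read_gene_sets()` (GMT), `read_mirna_targets()`, `read_mutations()`.

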