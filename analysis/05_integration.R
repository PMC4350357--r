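#!/usr/bin/env Rscript
# Post-signature integration: stratify tumors by MYB level, classify
# signature genes as MYB-dependent candidates vs MYB-independent using the
# MYB-low stratum and the ChIP-Seq target set, run gene-set enrichment over
# the filtered universe, intersect the up-signature with somatic mutations,
# and link down-regulated miRNAs to inversely regulated targets.

library(accsig)

mrna <- read_expression_matrix("results/mrna_normalized.tsv", "linear", "mRNA")
sheet <- read_sample_sheet("results/cohort/sample_sheet.tsv")
sig_mrna <- utils::read.delim("results/signature_mrna.tsv", comment.char = "#")
sig_mirna <- utils::read.delim("results/signature_mirna.tsv", comment.char = "#")
annotation <- read_gene_sets("results/cohort/annotation.gmt")
chip <- read_gene_sets("results/cohort/chip_targets.gmt")$MYB_chip_targets
map <- read_mirna_targets("results/cohort/mirna_targets.tsv")
mutations <- read_mutations("results/cohort/mutations.tsv")

## MYB stratification and dependence classification
lg <- log2_transform(mrna)
strata <- stratify_by_marker(lg, sheet, "MYB", k_sd = 2)
low <- strata$sample_id[strata$stratum == "marker-low"]
message(sprintf("MYB-low tumors: %s", paste(low, collapse = ", ")))
sheet_df <- as.data.frame(sheet)
pat <- function(s) sheet_df$patient_id[match(s, sheet_df$sample_id)]
sig_high <- derive_signature(mrna, subset_sheet(
  sheet, pat(strata$sample_id[strata$stratum == "marker-high"])))
sig_low <- descriptive_signature(mrna, sheet, patients = pat(low))
labels <- classify_myb_dependence(sig_high, sig_low, chip)
write_result_table(labels, "results/dependence_labels.tsv")
message(sprintf("dependence labels: %s",
                paste(names(table(labels$label)), table(labels$label),
                      sep = "=", collapse = ", ")))

## enrichment over the baseline-filtered universe
hits <- sig_mrna$probe_id[sig_mrna$significant]
universe <- sig_mrna$probe_id[sig_mrna$passed_baseline]
enr <- fisher_enrichment(hits, annotation, universe)
write_result_table(enr, "results/enrichment.tsv")
message(sprintf("top enriched set: %s (q = %.2g, %d/%d genes)",
                enr$set[1], enr$q[1], enr$overlap[1], enr$set_size[1]))
message(sprintf("ChIP-Seq target overlap: %.0f%% of the signature",
                100 * chipseq_overlap_fraction(hits, chip)))

## mutation intersection and miRNA links
cand <- integrate_mutations(sig_mrna, mutations)
write_result_table(cand, "results/mutation_candidates.tsv")
message("up-regulated and mutated (candidate co-drivers): ",
        paste(cand$gene, collapse = ", "))
links <- mirna_mrna_links(sig_mirna, sig_mrna, map)
write_result_table(links, "results/mirna_links.tsv")
message("inverse miRNA-target links: ",
        paste(sprintf("%s -| %s (%.1f-fold down, target %.1f-fold up)",
                      links$mirna_id, links$target_gene,
                      links$mirna_fold_change, links$target_fold_change),
              collapse = "; "))
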