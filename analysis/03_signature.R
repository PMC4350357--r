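#!/usr/bin/env Rscript
# Derive the paired tumor-vs-normal signatures: per-probe paired t-tests on
# the filtered log2 matrix with Benjamini-Hochberg FDR at 0.05, for mRNA and
# miRNA. Then show the cohort structure the signature induces: Ward
# clustering of samples over the signature probes and sample PCA.

library(accsig)

mrna <- read_expression_matrix("results/mrna_normalized.tsv", "linear", "mRNA")
mirna <- read_expression_matrix("results/mirna_normalized.tsv", "linear", "miRNA")
sheet <- read_sample_sheet("results/cohort/sample_sheet.tsv")

sig_mrna <- derive_signature(mrna, sheet, alpha = 0.05, min_fold = 2,
                             min_intensity = 50)
sig_mirna <- derive_signature(mirna, sheet, alpha = 0.05, min_fold = 2,
                              min_intensity = 800)
write_signature_table(sig_mrna, "results/signature_mrna.tsv")
write_signature_table(sig_mirna, "results/signature_mirna.tsv")

top <- sig_mrna[sig_mrna$significant, ][1:5, c("probe_id", "fold_change")]
message(sprintf("mRNA signature: %d significant probe sets at FDR 0.05",
                sum(sig_mrna$significant)))
message("top by q then fold change: ",
        paste(sprintf("%s (%.1f-fold)", top$probe_id, top$fold_change),
              collapse = ", "))
message(sprintf("miRNA signature: %d significant probes",
                sum(sig_mirna$significant)))

# fusion-positive vs fusion-negative tumors: no expression difference expected
lg <- log2_transform(mrna)
grp <- group_comparison(lg, sheet, alpha = 0.05)
write_result_table(grp, "results/group_comparison.tsv")
message(sprintf("fusion-pos vs fusion-neg: %d significant probes at FDR 0.05",
                sum(grp$significant)))

cl <- hierarchical_cluster(lg, sig_mrna$probe_id[sig_mrna$significant])
writeLines(cl$newick, "results/sample_dendrogram.nwk")
pc <- pca_samples(lg)
utils::write.table(data.frame(sample_id = rownames(pc$scores),
                              round(pc$scores[, 1:3], 4)),
                   "results/pca_scores.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
message(sprintf("PCA: PC1 explains %.0f%% of variance; leaf order splits %s",
                100 * pc$var_fraction[1],
                paste(utils::head(cl$leaf_order, 3), collapse = ",")))
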