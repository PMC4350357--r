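#!/usr/bin/env Rscript
# Normalize the simulated cohort and apply the two expression filters:
# quantile normalization (all samples forced onto the common rank-mean
# reference), then the baseline intensity filter (mRNA >= 50, miRNA >= 800)
# and the paired |fold-change| >= 2 filter on the log2 scale.

library(accsig)

mrna <- read_expression_matrix("results/cohort/mrna.tsv", "linear", "mRNA")
mirna <- read_expression_matrix("results/cohort/mirna.tsv", "linear", "miRNA")
sheet <- read_sample_sheet("results/cohort/sample_sheet.tsv")

qn_mrna <- quantile_normalize(mrna)
qn_mirna <- quantile_normalize(mirna)
write_expression_matrix(qn_mrna, "results/mrna_normalized.tsv",
                        comment = "quantile normalized, linear scale")
write_expression_matrix(qn_mirna, "results/mirna_normalized.tsv",
                        comment = "quantile normalized, linear scale")

bf <- baseline_filter(qn_mrna, 50)
vf <- variation_filter(log2_transform(bf$matrix), sheet, min_fold = 2)
report <- merge(bf$report, vf$report, by = "probe_id", all.x = TRUE,
                suffixes = c("", ".v"))
report$passed_variation <- report$passed_variation.v
report$passed_variation.v <- NULL
utils::write.table(report[order(report$probe_id), ],
                   "results/filter_report_mrna.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

message(sprintf("mRNA: %d probes; %d pass baseline >= 50; %d also pass |fc| >= 2",
                nrow(mrna$values), sum(bf$report$passed_baseline),
                sum(vf$report$passed_variation)))
bf8 <- baseline_filter(qn_mirna, 800)
message(sprintf("miRNA: %d probes; %d pass baseline >= 800",
                nrow(mirna$values), sum(bf8$report$passed_baseline)))
message("wrote results/mrna_normalized.tsv, results/filter_report_mrna.tsv")
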