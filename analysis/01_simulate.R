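#!/usr/bin/env Rscript
# Generate the synthetic paired ACC cohort used by the downstream analyses:
# 12 tumor/normal pairs, 5000 probe sets with 160 planted signature genes
# (MYB at 18-fold; VCAN, HAPLN1 and 14 further ECM genes among the top
# up-regulated), 6 fusion-positive tumors with planted MYB 3' breakpoints,
# one MYB-low tumor that retains the rest of the signature, and an 847-probe
# miRNA matrix with 22 planted down-regulated miRNAs (hsa-miR-150;
# hsa-miR-29 at 2.5-fold, targeting HAPLN1).

library(accsig)

cfg <- sim_config(seed = 20140913 %% 10000)
cohort <- generate_cohort(cfg)
write_cohort(cohort, "results/cohort")

message(sprintf("cohort: %d genes x %d samples; %d planted signature genes",
                nrow(cohort$mrna$values), ncol(cohort$mrna$values),
                sum(cohort$truth$genes$planted)))
message(sprintf("fusion-positive tumors: %d; MYB-low tumor: %s",
                sum(cohort$truth$fusion$status == "positive"),
                cohort$truth$myb_low_sample))
message("wrote results/cohort/")
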