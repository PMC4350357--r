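test_that("identical configs give bit-identical cohorts", {
  cf <- small_config(seed = 5)
  a <- generate_cohort(cf)
  b <- generate_cohort(cf)
  expect_identical(a$mrna$values, b$mrna$values)
  expect_identical(a$mirna$values, b$mirna$values)
  expect_identical(a$exon$values, b$exon$values)
  expect_identical(a$truth, b$truth)
  # and a different seed gives different draws
  c2 <- generate_cohort(small_config(seed = 6))
  expect_false(identical(a$mrna$values, c2$mrna$values))
})

test_that("noise-free cohorts realize planted fold changes exactly", {
  cf <- small_config(noise_sd = 0, seed = 9)
  co <- generate_cohort(cf)
  pairs <- sample_pairs(co$sheet)
  truth <- co$truth$genes
  low <- co$truth$myb_low_sample
  for (i in seq_len(nrow(pairs))) {
    ratio <- co$mrna$values[, pairs$tumor[i]] / co$mrna$values[, pairs$normal[i]]
    planted <- truth$planted
    expected <- ifelse(truth$direction == "up", truth$fc, 1 / truth$fc)
    if (identical(pairs$tumor[i], low)) expected[truth$gene == "MYB"] <- 1
    expect_equal(unname(ratio[planted]), expected[planted], tolerance = 1e-12)
    # null genes are exchangeable: ratio exactly 1 without noise
    expect_equal(unname(ratio[!planted]), rep(1, sum(!planted)),
                 tolerance = 1e-12)
  }
  expect_equal(unname(ratio["MYB"]), 1, tolerance = 1e-12)  # last pair is MYB-low
})

test_that("the MYB-low tumor retains every non-MYB planted effect by default", {
  co <- generate_cohort(small_config(noise_sd = 0, seed = 3))
  pairs <- sample_pairs(co$sheet)
  low <- co$truth$myb_low_sample
  i <- which(pairs$tumor == low)
  ratio <- co$mrna$values[, pairs$tumor[i]] / co$mrna$values[, pairs$normal[i]]
  truth <- co$truth$genes
  others <- truth$planted & truth$gene != "MYB"
  expect_equal(unname(ratio[truth$gene[others]]),
               ifelse(truth$direction[others] == "up", truth$fc[others],
                      1 / truth$fc[others]),
               tolerance = 1e-12)
})

test_that("truth tables are consistent with the emitted matrices", {
  co <- generate_cohort(small_config(seed = 21))
  expect_true(all(co$truth$genes$gene %in% rownames(co$mrna$values)))
  expect_true(all(co$truth$mirna$mirna_id %in% rownames(co$mirna$values)))
  bp <- co$truth$fusion$breakpoint
  cf <- co$config
  expect_true(all(is.na(bp) | (bp >= cf$breakpoint_range[1] &
                                 bp <= cf$breakpoint_range[2])))
  expect_equal(sum(co$truth$fusion$status == "positive"), cf$n_fusion_pos)
  # the MYB-low tumor is never fusion-positive
  expect_identical(
    co$truth$fusion$status[co$truth$fusion$sample_id == co$truth$myb_low_sample],
    "negative")
  # every annotation/chip gene exists in the matrix
  expect_true(all(unlist(co$truth$annotation) %in% rownames(co$mrna$values)))
  expect_true(all(co$truth$chip_targets %in% rownames(co$mrna$values)))
})

test_that("n_fusion_pos = 0 plants no breakpoints anywhere", {
  co <- generate_cohort(small_config(n_fusion_pos = 0, seed = 2))
  expect_true(all(co$truth$fusion$status == "negative"))
  expect_true(all(is.na(co$truth$fusion$breakpoint)))
})

test_that("generated exon profiles follow the planted step construction", {
  # noise-free positive: delta vector is exactly delta5 then delta3
  p <- generate_exon_profile("positive", breakpoint = 14, delta5 = 2,
                             delta3 = 0, noise_sd = 0, seed = 1)
  d <- delta_profile(p, "T", "N", pseudocount = 0)
  expect_equal(unname(d), c(rep(2, 14), 0), tolerance = 1e-12)
  # noise-free negative: constant delta
  n <- generate_exon_profile("negative", delta5 = 1, delta3 = 1,
                             noise_sd = 0, seed = 1)
  expect_equal(unname(delta_profile(n, "T", "N", pseudocount = 0)),
               rep(1, 15), tolerance = 1e-12)
  # same seed, same profile
  p2 <- generate_exon_profile("positive", breakpoint = 9, noise_sd = 0.3, seed = 4)
  p3 <- generate_exon_profile("positive", breakpoint = 9, noise_sd = 0.3, seed = 4)
  expect_identical(p2$values, p3$values)
  # config errors
  expect_error(generate_exon_profile("positive", breakpoint = 15), "breakpoint")
  expect_error(generate_exon_profile("positive", breakpoint = 1), "breakpoint")
  expect_error(generate_exon_profile("positive", breakpoint = 8,
                                     delta5 = 0, delta3 = 0), "delta5")
})

test_that("invalid configurations fail before any sampling", {
  expect_error(sim_config(n_genes = 50, n_signature_up = 40,
                          n_signature_down = 20), "fewer than n_genes")
  expect_error(sim_config(n_fusion_pos = 13), "n_fusion_pos")
  expect_error(sim_config(breakpoint_range = c(8, 15)), "breakpoint_range")
  expect_error(sim_config(myb_low_index = 20), "myb_low_index")
  expect_error(sim_config(n_signature_up = 10), "n_signature_up")
  expect_error(small_config(n_myb_dependent = 20, n_myb_associated = 20),
               "generic up-genes")
})

test_that("null cohorts carry no planted structure and are seed-stable", {
  co <- generate_null_cohort(sim_config(n_genes = 600, n_pairs = 8, seed = 4))
  expect_true(all(!co$truth$genes$planted))
  expect_true(all(co$truth$fusion$status == "negative"))
  expect_true(all(!co$truth$mirna$planted))
  co2 <- generate_null_cohort(sim_config(n_genes = 600, n_pairs = 8, seed = 4))
  expect_identical(co$mrna$values, co2$mrna$values)
})

test_that("written cohorts read back through the io layer", {
  co <- generate_cohort(small_config(seed = 14))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  m <- read_expression_matrix(file.path(dir, "mrna.tsv"), "linear", "mRNA")
  expect_identical(m$values, co$mrna$values)
  sheet <- read_sample_sheet(file.path(dir, "sample_sheet.tsv"))
  expect_identical(as.data.frame(sheet), as.data.frame(co$sheet))
  sets <- read_gene_sets(file.path(dir, "annotation.gmt"))
  expect_identical(lapply(sets, as.character),
                   lapply(co$truth$annotation, function(s) as.character(s)))
  chip <- read_gene_sets(file.path(dir, "chip_targets.gmt"))
  expect_identical(as.character(chip$MYB_chip_targets), co$truth$chip_targets)
  map <- read_mirna_targets(file.path(dir, "mirna_targets.tsv"))
  expect_equal(map, co$truth$target_map, ignore_attr = TRUE)
  mut <- read_mutations(file.path(dir, "mutations.tsv"))
  expect_equal(mut, co$truth$mutations, ignore_attr = TRUE)
})
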