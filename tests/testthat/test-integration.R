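test_that("enrichment p-values match hypergeometric enumeration and fisher.test", {
  universe <- sprintf("g%02d", 1:20)
  sets <- structure(list(S = universe[1:5]), class = "GeneSetCollection")
  signature <- universe[c(1:4, 10)]
  res <- fisher_enrichment(signature, sets, universe)
  expect_equal(res$overlap, 4L)
  expect_equal(res$p_enrichment, 76 / 15504, tolerance = 1e-12)
  expect_equal(res$p_enrichment, oracle_hyper_p1(4, 5, 5, 20), tolerance = 1e-12)
  expect_equal(res$p_two_sided, oracle_hyper_p2(4, 5, 5, 20), tolerance = 1e-12)
  ft <- fisher.test(matrix(c(4, 1, 1, 14), 2))
  expect_equal(res$p_two_sided, ft$p.value, tolerance = 1e-10)

  # random tables agree with stats::fisher.test (independent route)
  set.seed(5)
  for (i in 1:40) {
    N <- sample(8:60, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    lo <- max(0, n + K - N); hi <- min(n, K)
    a <- if (lo == hi) lo else sample(lo:hi, 1)
    p2 <- accsig:::hypergeom_p2(a, K, n, N)
    tab <- matrix(c(a, n - a, K - a, N - K - n + a), 2)
    expect_equal(p2, fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("enrichment handles independence and degenerate tables", {
  universe <- sprintf("g%03d", 1:100)
  sets <- structure(list(S = universe[1:20]), class = "GeneSetCollection")
  # overlap at expectation: OR near 1, p near 1
  signature <- c(universe[1:2], universe[21:28])   # 2/10 vs 20/100
  res <- fisher_enrichment(signature, sets, universe)
  expect_equal(res$odds_ratio, 1, tolerance = 0.25)
  expect_gt(res$p_two_sided, 0.9)
  # signature = universe: forced full overlap, p = 1
  res2 <- fisher_enrichment(universe, sets, universe)
  expect_equal(res2$overlap, 20L)
  expect_equal(res2$p_two_sided, 1)
  expect_error(fisher_enrichment(character(), sets, universe), "empty")
  expect_error(fisher_enrichment(c("zzz"), sets, universe), "outside")
})

test_that("chip overlap fraction is a plain monotone intersection share", {
  sig <- sprintf("g%d", 1:10)
  expect_equal(chipseq_overlap_fraction(sig, sig[1:5]), 0.5)
  expect_equal(chipseq_overlap_fraction(sig, c("x", "y")), 0)
  expect_equal(chipseq_overlap_fraction(sig, c(sig, "extra")), 1)
  # monotone under growing target set
  set.seed(2)
  targets <- character()
  last <- 0
  for (g in sample(sig)) {
    targets <- c(targets, g)
    f <- chipseq_overlap_fraction(sig, targets)
    expect_gte(f, last)
    last <- f
  }
  expect_error(chipseq_overlap_fraction(character(), sig), "empty")
})

test_that("marker stratification thresholds against the normal baseline", {
  sheet <- make_sheet(4)
  sn <- as.data.frame(sheet)$sample_id
  vals <- matrix(8, 2, 8, dimnames = list(c("MYB", "other"), sn))
  normals <- sn[seq(2, 8, 2)]
  vals["MYB", normals] <- c(7.9, 8.0, 8.1, 8.0)
  vals["MYB", "P01_T"] <- 8.0      # at the normal mean: low
  vals["MYB", "P02_T"] <- 12.0     # + 4 log2: high
  vals["MYB", "P03_T"] <- 8.05     # inside mean + 2 sd: low
  vals["MYB", "P04_T"] <- 9.0      # above: high
  st <- stratify_by_marker(expression_matrix(vals, "log2", "mRNA"),
                           sheet, "MYB")
  expect_identical(st$stratum,
                   c("marker-low", "marker-high", "marker-low", "marker-high"))
  expect_error(stratify_by_marker(expression_matrix(vals, "log2", "mRNA"),
                                  sheet, "KIT"), "absent")
})

test_that("the planted MYB-low tumor is the unique low-stratum member", {
  co <- generate_cohort(small_config(seed = 33))
  lg <- log2_transform(quantile_normalize(co$mrna))
  st <- stratify_by_marker(lg, co$sheet, "MYB")
  expect_identical(st$sample_id[st$stratum == "marker-low"],
                   co$truth$myb_low_sample)
})

test_that("dependence classification applies the two-strata rule table", {
  mk <- function(genes, up) {
    # minimal SignatureTable-shaped frame over a fixed universe
    data.frame(probe_id = genes,
               significant = genes %in% up,
               direction = ifelse(genes %in% up, "up", "down"),
               fold_change = ifelse(genes %in% up, 4, 1),
               stringsAsFactors = FALSE)
  }
  genes <- c("both", "chiponly", "nochip", "neither")
  labs <- classify_myb_dependence(mk(genes, c("both", "chiponly", "nochip")),
                                  mk(genes, "both"),
                                  chip_targets = c("both", "chiponly"))
  expect_identical(labs$label[labs$gene == "both"], "MYB-independent")
  expect_identical(labs$label[labs$gene == "chiponly"], "MYB-dependent-candidate")
  expect_identical(labs$label[labs$gene == "nochip"], "MYB-associated-unclassified")
  expect_false("neither" %in% labs$gene)
  expect_error(classify_myb_dependence(mk(genes, "both"),
                                       mk(genes[1:3], "both"), "both"),
               "universe")
})

test_that("noise-free planted dependence labels are recovered exactly", {
  cf <- small_config(noise_sd = 0, n_myb_dependent = 5, n_myb_associated = 4,
                     seed = 71)
  co <- generate_cohort(cf)
  lg <- log2_transform(co$mrna)
  st <- stratify_by_marker(lg, co$sheet, "MYB")
  expect_identical(st$sample_id[st$stratum == "marker-low"],
                   co$truth$myb_low_sample)
  sheet_df <- as.data.frame(co$sheet)
  pat <- function(s) sheet_df$patient_id[match(s, sheet_df$sample_id)]
  high <- st$sample_id[st$stratum == "marker-high"]
  sig_high <- derive_signature(co$mrna, subset_sheet(co$sheet, pat(high)))
  sig_low <- descriptive_signature(co$mrna, co$sheet,
                                   patients = pat(co$truth$myb_low_sample))
  labs <- classify_myb_dependence(sig_high, sig_low, co$truth$chip_targets)
  truth <- co$truth$genes
  expected <- truth[truth$direction == "up", c("gene", "dependence")]
  labs <- labs[match(expected$gene, labs$gene), ]
  expect_identical(labs$label, expected$dependence)
})

test_that("mutation integration intersects up-signature with damaging classes", {
  sig <- data.frame(probe_id = c("RUNX1", "NOTCH1", "VCAN", "LOSS1", "TP53"),
                    significant = c(TRUE, TRUE, TRUE, TRUE, FALSE),
                    direction = c("up", "up", "up", "down", "up"),
                    fold_change = c(3, 2.5, 29, 4, 1.2),
                    log2_fc = log2(c(3, 2.5, 29, 1 / 4, 1.2)),
                    stringsAsFactors = FALSE)
  mut <- data.frame(gene = c("RUNX1", "NOTCH1", "TP53", "LOSS1"),
                    sample_id = paste0("s", 1:4),
                    mutation_class = c("missense", "truncating", "missense",
                                       "missense"),
                    stringsAsFactors = FALSE)
  cand <- integrate_mutations(sig, mut)
  expect_identical(cand$gene, c("RUNX1", "NOTCH1"))  # sorted by fold change
  expect_identical(integrate_mutations(sig, mut[0, ])$gene, character())
  # 'other' class excluded by default
  mut2 <- data.frame(gene = "VCAN", sample_id = "s9", mutation_class = "other",
                     stringsAsFactors = FALSE)
  expect_identical(integrate_mutations(sig, mut2)$gene, character())
})

test_that("miRNA links require significance, opposite direction, and the map", {
  mi <- data.frame(probe_id = c("miR-29", "miR-150", "miR-x", "miR-dd"),
                   significant = c(TRUE, TRUE, FALSE, TRUE),
                   direction = c("down", "down", "down", "down"),
                   fold_change = c(2.5, 3, 2, 2),
                   stringsAsFactors = FALSE)
  mg <- data.frame(probe_id = c("HAPLN1", "MYB", "VCAN", "DN1"),
                   significant = c(TRUE, TRUE, TRUE, TRUE),
                   direction = c("up", "up", "up", "down"),
                   fold_change = c(7, 18, 29, 4),
                   stringsAsFactors = FALSE)
  map <- data.frame(
    mirna_id = c("miR-29", "miR-150", "miR-x", "miR-dd", "miR-29"),
    target_gene = c("HAPLN1", "MYB", "VCAN", "DN1", "ABSENT"),
    stringsAsFactors = FALSE)
  links <- mirna_mrna_links(mi, mg, map)
  expect_setequal(paste(links$mirna_id, links$target_gene),
                  c("miR-29 HAPLN1", "miR-150 MYB"))
  expect_equal(links$mirna_fold_change[links$mirna_id == "miR-29"], 2.5)
  # same-direction pair never links even if mapped
  expect_false("miR-dd" %in% links$mirna_id)
})

test_that("ECM enrichment dominates on the planted cohort", {
  co <- generate_cohort(small_config(seed = 83))
  sig <- derive_signature(co$mrna, co$sheet)
  hits <- sig$probe_id[sig$significant]
  res <- fisher_enrichment(hits, co$truth$annotation,
                           sig$probe_id[sig$passed_baseline])
  expect_identical(res$set[1], "ECM")
  expect_equal(res$q[res$set == "ECM"], min(res$q))
})
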