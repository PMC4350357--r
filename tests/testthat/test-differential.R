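test_that("paired t statistics match the defining formula and reference CDF", {
  sheet <- make_sheet(3)
  m <- make_paired_matrix(matrix(c(1, 2, 3), 1, dimnames = list("g1", NULL)))
  res <- paired_t_test(m, sheet)
  expect_equal(res$t, sqrt(3) * 2, tolerance = 1e-10)        # 3.4641016
  expect_equal(res$df, 2)
  expect_equal(res$p, 2 * pt(2 * sqrt(3), 2, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(res$p, 0.0742, tolerance = 1e-3)

  # near-null deltas give p near 1
  sheet4 <- make_sheet(4)
  m2 <- make_paired_matrix(matrix(c(0, 0, 1e-4, -1e-4), 1,
                                  dimnames = list("g1", NULL)))
  expect_gt(paired_t_test(m2, sheet4)$p, 0.9)

  # symmetry: d and -d give identical p, opposite t
  d <- matrix(rnorm(8), 2, dimnames = list(c("a", "b"), NULL))
  r1 <- paired_t_test(make_paired_matrix(d), sheet4)
  r2 <- paired_t_test(make_paired_matrix(-d), sheet4)
  expect_equal(r1$p, r2$p, tolerance = 1e-12)
  expect_equal(r1$t, -r2$t, tolerance = 1e-12)

  # agreement with stats::t.test across random probes
  set.seed(31)
  dd <- matrix(rnorm(40, 0.5), 10)
  rr <- paired_t_test(make_paired_matrix(dd), sheet4)
  for (i in 1:10) {
    ref <- t.test(dd[i, ])
    expect_equal(rr$t[i], unname(ref$statistic), tolerance = 1e-10)
    expect_equal(rr$p[i], ref$p.value, tolerance = 1e-10)
  }
})

test_that("zero-variance paired differences are flagged, not given p = 0", {
  sheet <- make_sheet(4)
  m <- make_paired_matrix(matrix(2, 1, 4, dimnames = list("const", NULL)))
  res <- paired_t_test(m, sheet)
  expect_true(res$zero_variance)
  expect_true(is.na(res$p))
  expect_error(paired_t_test(make_paired_matrix(matrix(1, 1, 1), 1),
                             make_sheet(1)), "2 pairs")
})

test_that("BH q-values follow the step-up rule", {
  p <- c(0.001, 0.01, 0.02, 0.04, 0.2)
  res <- bh_fdr(p, alpha = 0.05)
  expect_equal(res$q, c(0.005, 0.025, 0.02 * 5 / 3, 0.05, 0.2),
               tolerance = 1e-12)
  expect_identical(res$significant, c(TRUE, TRUE, TRUE, TRUE, FALSE))

  expect_equal(bh_fdr(rep(1, 6))$q, rep(1, 6))
  expect_false(any(bh_fdr(rep(1, 6))$significant))

  r1 <- bh_fdr(0.03)
  expect_equal(r1$q, 0.03)
  expect_true(r1$significant)

  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")

  # property: ties in p receive equal q; q monotone in p
  set.seed(8)
  for (i in 1:20) {
    p <- round(runif(30), 2)
    q <- bh_fdr(p)$q
    expect_true(all(tapply(q, p, function(v) max(v) - min(v)) < 1e-15))
    expect_true(all(diff(q[order(p)]) > -1e-15))
  }
})

test_that("bh_fdr equals the brute-force step-up oracle", {
  set.seed(99)
  for (i in 1:50) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_fdr(p)$q, oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("derive_signature recovers exactly the planted genes noise-free", {
  cf <- sim_config(n_genes = 510, n_pairs = 8, n_signature_up = 0,
                   n_signature_down = 10, noise_sd = 0, n_fusion_pos = 0,
                   myb_low_index = NA, n_mirna = 20, n_mirna_down = 0,
                   fc_range = c(4, 4), seed = 17)
  co <- generate_cohort(cf)
  sig <- derive_signature(co$mrna, co$sheet)
  planted <- co$truth$genes$gene[co$truth$genes$planted]
  expect_setequal(sig$probe_id[sig$significant], planted)
  # degenerate (noise-free) rows are flagged rather than given p = 0
  expect_true(all(sig$zero_variance[sig$significant]))
  expect_true(all(is.na(sig$p[sig$significant])))
})

test_that("MYB tops the signature when planted highest", {
  cf <- small_config(fc_range = c(2, 8), seed = 12)
  co <- generate_cohort(cf)  # MYB at 18-fold, everything else <= 8-fold
  sig <- derive_signature(co$mrna, co$sheet)
  hits <- sig[sig$significant, ]
  expect_identical(hits$probe_id[which.max(hits$fold_change)], "MYB")
})

test_that("signature table invariants hold on a default-style cohort", {
  co <- generate_cohort(small_config(seed = 30))
  sig <- derive_signature(co$mrna, co$sheet)
  ok <- !is.na(sig$q)
  expect_true(all(sig$significant[ok] == (sig$q[ok] <= 0.05)))
  expect_true(all(sig$direction[ok & sig$log2_fc > 0] == "up"))
  expect_true(all(sig$direction[ok & sig$log2_fc < 0] == "down"))
  # q monotone when ordered by p
  tested <- sig[!is.na(sig$p), ]
  expect_true(all(diff(tested$q[order(tested$p)]) > -1e-15))
  # a probe in the significant set passed both filters
  expect_true(all(sig$passed_baseline[sig$significant] &
                    sig$passed_variation[sig$significant]))
})

test_that("group comparison is null for exchangeable groups, powered for shifts", {
  sheet <- make_sheet(12)
  set.seed(55)
  vals <- matrix(rnorm(200 * 24, 8, 1), 200,
                 dimnames = list(sprintf("g%03d", 1:200),
                                 as.data.frame(sheet)$sample_id))
  m <- expression_matrix(vals, "log2", "mRNA")
  tum <- as.data.frame(sheet)$sample_id[as.data.frame(sheet)$tissue == "tumor"]
  grp <- setNames(rep(c("positive", "negative"), each = 6), tum)
  res <- group_comparison(m, sheet, grouping = grp)
  expect_false(any(res$significant))

  # equal means, balanced groups: F at 0
  m0 <- expression_matrix(matrix(rep(c(1, 2), 6), 1,
                                 dimnames = list("g", names(grp))),
                          "log2", "mRNA")
  expect_lt(group_comparison(m0, sheet, grouping = grp)$F[1], 1e-20)

  # a +4 log2 shift in one group is found
  vals["g001", names(grp)[grp == "positive"]] <-
    vals["g001", names(grp)[grp == "positive"]] + 4
  res2 <- group_comparison(expression_matrix(vals, "log2", "mRNA"),
                           sheet, grouping = grp)
  expect_true(res2$significant[res2$probe_id == "g001"])
  expect_error(group_comparison(m, sheet,
                                grouping = setNames(c("a", "a", "b"), tum[1:3])),
               "at least 2")
})

test_that("ward clustering separates planted classes and is order-invariant", {
  co <- generate_cohort(small_config(noise_sd = 0.1, seed = 44))
  lg <- log2_transform(quantile_normalize(co$mrna))
  sig_genes <- co$truth$genes$gene[co$truth$genes$planted]
  cl <- hierarchical_cluster(lg, sig_genes)
  cut2 <- cutree(cl$hclust, 2)
  sheet <- as.data.frame(co$sheet)
  tissue <- sheet$tissue[match(names(cut2), sheet$sample_id)]
  expect_true(all(tapply(cut2, tissue, function(v) length(unique(v)) == 1)))
  expect_length(unique(cut2), 2L)

  # permuting input column order changes nothing
  perm <- sample(ncol(lg$values))
  lg2 <- expression_matrix(lg$values[, perm], "log2", "mRNA")
  cl2 <- hierarchical_cluster(lg2, sig_genes)
  expect_identical(cl2$leaf_order, cl$leaf_order)
  expect_identical(cl2$newick, cl$newick)

  # duplicated sample merges first at height 0
  v <- lg$values[sig_genes, 1:4]
  v <- cbind(v, dup = v[, 1])
  cl3 <- hierarchical_cluster(expression_matrix(v, "log2", "mRNA"),
                              sig_genes)
  expect_equal(cl3$hclust$height[1], 0, tolerance = 1e-12)
  expect_error(hierarchical_cluster(lg, c("nope1", "nope2")), "disjoint")
})

test_that("sample PCA satisfies its defining properties", {
  co <- generate_cohort(small_config(noise_sd = 0.2, seed = 77))
  lg <- log2_transform(quantile_normalize(co$mrna))
  pc <- pca_samples(lg)
  expect_true(all(diff(pc$var_fraction) < 1e-12))
  expect_equal(sum(pc$var_fraction), 1, tolerance = 1e-8)
  # sign convention: dominant loading positive
  for (j in seq_len(ncol(pc$loadings)))
    expect_gt(pc$loadings[which.max(abs(pc$loadings[, j])), j], 0)
  # PC1 separates tumors from normals with a margin
  sheet <- as.data.frame(co$sheet)
  s1 <- pc$scores[, 1]
  tum <- s1[sheet$sample_id[sheet$tissue == "tumor"]]
  nor <- s1[sheet$sample_id[sheet$tissue == "normal"]]
  expect_true(min(tum) > max(nor) || min(nor) > max(tum))

  # identical samples get identical scores
  v <- lg$values[, c(1, 1, 2, 3)]
  colnames(v) <- c("a", "b", "c", "d")
  pc2 <- pca_samples(expression_matrix(v, "log2", "mRNA"))
  expect_equal(pc2$scores["a", ], pc2$scores["b", ], tolerance = 1e-8)

  # constant matrix: all zero
  cm <- expression_matrix(matrix(5, 3, 4, dimnames = list(letters[1:3],
                                                          LETTERS[1:4])),
                          "log2", "mRNA")
  pc0 <- pca_samples(cm)
  expect_true(all(pc0$scores == 0) && all(pc0$var_fraction == 0))
})
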