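#' Per-probe paired t-tests
#'
#' For each probe, tests the paired tumor-minus-normal log2 differences:
#' t = mean(d) / (sd(d)/sqrt(n)), df = n - 1, two-sided p from the t
#' distribution. Probes whose differences have exactly zero variance cannot
#' be assigned a p-value; they are flagged (`zero_variance = TRUE`) and carry
#' missing t and p rather than p = 0.
#'
#' @param x an [expression_matrix()] on the log2 scale.
#' @param sheet a `SampleSheet`; pairs are resolved with [sample_pairs()].
#' @return data.frame with columns `probe_id`, `mean_delta`, `t`, `df`, `p`,
#'   `zero_variance`.
#' @export
paired_t_test <- function(x, sheet) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (x$scale != "log2")
    stop("paired_t_test expects a log2-scale matrix", call. = FALSE)
  pairs <- sample_pairs(sheet)
  pairs <- pairs[pairs$tumor %in% sample_ids(x) & pairs$normal %in% sample_ids(x), ]
  n <- nrow(pairs)
  if (n < 2L) stop("paired design needs at least 2 pairs", call. = FALSE)
  d <- x$values[, pairs$tumor, drop = FALSE] - x$values[, pairs$normal, drop = FALSE]
  m <- rowMeans(d)
  s <- sqrt(rowSums((d - m)^2) / (n - 1))
  zero <- s == 0
  tt <- ifelse(zero, NA_real_, m / (s / sqrt(n)))
  p <- 2 * stats::pt(abs(tt), df = n - 1, lower.tail = FALSE)
  data.frame(probe_id = probe_ids(x), mean_delta = m, t = tt,
             df = n - 1, p = p, zero_variance = zero,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg FDR control
#'
#' Step-up adjusted p-values: `q_i` is the minimum over all `p_(j) >= p_(i)`
#' of `m * p_(j) / j`, clipped at 1; ties in p receive equal q. A probe is
#' significant iff `q <= alpha`.
#'
#' @param pvalues numeric vector in \[0, 1\] (NA allowed; propagated).
#' @param alpha FDR level (default 0.05).
#' @return list with `q` (adjusted p-values) and `significant` (logical;
#'   FALSE where p is NA).
#' @export
bh_fdr <- function(pvalues, alpha = 0.05) {
  if (!is.numeric(pvalues)) stop("p-values must be numeric", call. = FALSE)
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  q <- stats::p.adjust(pvalues, method = "BH")
  list(q = q, significant = !is.na(q) & q <= alpha)
}

#' Derive the paired tumor-vs-normal signature
#'
#' The full filtering-and-testing composition: baseline intensity filter (on
#' the linear scale), log2 transform, paired fold-change filter, per-probe
#' paired t-test, and Benjamini-Hochberg FDR control. All input probes are
#' retained in the output table with per-filter pass flags; statistics are
#' computed only for probes passing both filters, and the BH correction runs
#' over exactly those tested probes.
#'
#' Zero-variance probes that passed the fold-change filter (possible only in
#' the noise-free limit, where every pair shows the identical above-threshold
#' difference) are marked significant with missing p and q and
#' `zero_variance = TRUE`; see the methods vignette.
#'
#' @param x an [expression_matrix()]; linear scale (normalized upstream).
#' @param sheet a `SampleSheet`.
#' @param alpha FDR level (default 0.05).
#' @param min_fold linear fold-change threshold (default 2).
#' @param min_intensity baseline intensity threshold (default 50; use 800 for
#'   miRNA arrays); `NULL` skips the baseline filter.
#' @param log2_floor floor for the log2 transform (default 1).
#' @return A `SignatureTable`: data.frame with columns `probe_id`,
#'   `passed_baseline`, `passed_variation`, `log2_fc`, `fold_change`
#'   (signed linear fold change, negative values meaning down-regulation are
#'   reported as the linear magnitude with `direction = "down"`), `t`, `df`,
#'   `p`, `q`, `direction`, `zero_variance`, `significant`; rows sorted by q,
#'   then |fold change| descending, then probe ID. Attributes record the
#'   parameters.
#' @export
derive_signature <- function(x, sheet, alpha = 0.05, min_fold = 2,
                             min_intensity = 50, log2_floor = 1) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (x$scale != "linear")
    stop("derive_signature expects a linear-scale matrix", call. = FALSE)
  all_probes <- probe_ids(x)

  if (is.null(min_intensity)) {
    base_pass <- rep(TRUE, length(all_probes))
    x_base <- x
  } else {
    bf <- baseline_filter(x, min_intensity)
    base_pass <- bf$report$passed_baseline
    x_base <- bf$matrix
  }
  lg <- log2_transform(x_base, floor = log2_floor)

  # paired mean delta over *all* baseline-passing probes (the filter statistic)
  pairs <- sample_pairs(sheet)
  pairs <- pairs[pairs$tumor %in% sample_ids(lg) & pairs$normal %in% sample_ids(lg), ]
  if (nrow(pairs) < 2L) stop("paired design needs at least 2 pairs", call. = FALSE)
  dmat <- lg$values[, pairs$tumor, drop = FALSE] - lg$values[, pairs$normal, drop = FALSE]
  mean_delta <- rowMeans(dmat)
  var_pass_sub <- abs(mean_delta) >= log2(min_fold)

  tested <- probe_ids(lg)[var_pass_sub]
  tab <- data.frame(probe_id = all_probes, stringsAsFactors = FALSE)
  tab$passed_baseline <- base_pass
  tab$passed_variation <- FALSE
  tab$passed_variation[match(probe_ids(lg), all_probes)] <- var_pass_sub
  tab$log2_fc <- NA_real_
  tab$log2_fc[match(probe_ids(lg), all_probes)] <- mean_delta

  tab$t <- NA_real_; tab$df <- NA_real_; tab$p <- NA_real_; tab$q <- NA_real_
  tab$zero_variance <- FALSE
  tab$significant <- FALSE

  if (length(tested)) {
    sub <- expression_matrix(lg$values[tested, , drop = FALSE],
                             scale = "log2", assay = x$assay)
    tt <- paired_t_test(sub, sheet)
    fdr <- bh_fdr(tt$p, alpha = alpha)
    idx <- match(tested, all_probes)
    tab$t[idx] <- tt$t
    tab$df[idx] <- tt$df
    tab$p[idx] <- tt$p
    tab$q[idx] <- fdr$q
    tab$zero_variance[idx] <- tt$zero_variance
    # noise-free limit: identical above-threshold delta in every pair
    tab$significant[idx] <- fdr$significant | tt$zero_variance
  }

  tab$fold_change <- 2^abs(tab$log2_fc)
  tab$direction <- ifelse(is.na(tab$log2_fc), NA_character_,
                          ifelse(tab$log2_fc >= 0, "up", "down"))

  qkey <- tab$q
  qkey[tab$zero_variance & tab$significant] <- -1  # degenerate rows sort first
  qkey[is.na(qkey)] <- Inf
  fckey <- abs(tab$log2_fc)
  fckey[is.na(fckey)] <- -Inf
  ord <- order(qkey, -fckey, tab$probe_id)
  tab <- tab[ord, c("probe_id", "passed_baseline", "passed_variation",
                    "log2_fc", "fold_change", "t", "df", "p", "q",
                    "direction", "zero_variance", "significant")]
  rownames(tab) <- NULL
  structure(tab,
            params = list(alpha = alpha, min_fold = min_fold,
                          min_intensity = min_intensity,
                          n_pairs = nrow(pairs), method = "paired_t"),
            class = c("SignatureTable", "data.frame"))
}

#' Descriptive fold-change signature (for strata too small to test)
#'
#' When a stratum holds a single tumor/normal pair (the MYB-low stratum), a
#' t-test is undefined (n = 1); genes are instead called by the paired fold
#' change alone: significant iff both filters pass and
#' |log2 fc| >= log2(min_fold). Output schema matches [derive_signature()]
#' with `p`, `q`, `t` missing and attribute `method = "descriptive_fc"`.
#'
#' @inheritParams derive_signature
#' @param patients patient IDs defining the stratum (default: all pairs in
#'   `sheet` present in the matrix).
#' @return A `SignatureTable` (see [derive_signature()]).
#' @export
descriptive_signature <- function(x, sheet, patients = NULL, min_fold = 2,
                                  min_intensity = 50, log2_floor = 1) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (x$scale != "linear")
    stop("descriptive_signature expects a linear-scale matrix", call. = FALSE)
  all_probes <- probe_ids(x)
  if (is.null(min_intensity)) {
    base_pass <- rep(TRUE, length(all_probes))
    x_base <- x
  } else {
    bf <- baseline_filter(x, min_intensity)
    base_pass <- bf$report$passed_baseline
    x_base <- bf$matrix
  }
  lg <- log2_transform(x_base, floor = log2_floor)
  pairs <- sample_pairs(sheet, patients = patients)
  pairs <- pairs[pairs$tumor %in% sample_ids(lg) & pairs$normal %in% sample_ids(lg), ]
  if (!nrow(pairs)) stop("no resolvable tumor/normal pairs in stratum", call. = FALSE)
  dmat <- lg$values[, pairs$tumor, drop = FALSE] - lg$values[, pairs$normal, drop = FALSE]
  mean_delta <- rowMeans(dmat)
  var_pass_sub <- abs(mean_delta) >= log2(min_fold)

  tab <- data.frame(probe_id = all_probes, stringsAsFactors = FALSE)
  tab$passed_baseline <- base_pass
  tab$passed_variation <- FALSE
  tab$passed_variation[match(probe_ids(lg), all_probes)] <- var_pass_sub
  tab$log2_fc <- NA_real_
  tab$log2_fc[match(probe_ids(lg), all_probes)] <- mean_delta
  tab$t <- NA_real_; tab$df <- NA_real_; tab$p <- NA_real_; tab$q <- NA_real_
  tab$zero_variance <- FALSE
  tab$significant <- tab$passed_variation
  tab$fold_change <- 2^abs(tab$log2_fc)
  tab$direction <- ifelse(is.na(tab$log2_fc), NA_character_,
                          ifelse(tab$log2_fc >= 0, "up", "down"))
  fckey <- abs(tab$log2_fc)
  fckey[is.na(fckey)] <- -Inf
  ord <- order(!tab$significant, -fckey, tab$probe_id)
  tab <- tab[ord, c("probe_id", "passed_baseline", "passed_variation",
                    "log2_fc", "fold_change", "t", "df", "p", "q",
                    "direction", "zero_variance", "significant")]
  rownames(tab) <- NULL
  structure(tab,
            params = list(min_fold = min_fold, min_intensity = min_intensity,
                          n_pairs = nrow(pairs), method = "descriptive_fc"),
            class = c("SignatureTable", "data.frame"))
}

#' Two-group comparison over tumor samples
#'
#' Per-probe fixed-effect comparison of two tumor groups (fusion-positive vs
#' fusion-negative): pooled-variance F statistic (the square of the two-sample
#' t), p from F(1, n1 + n2 - 2), Benjamini-Hochberg correction across probes.
#'
#' @param x an [expression_matrix()] on the log2 scale.
#' @param sheet a `SampleSheet` (used to restrict to tumor samples).
#' @param grouping named character/factor vector over tumor sample IDs with
#'   exactly two levels; defaults to the sheet's `fusion_annotation` over
#'   tumors annotated positive/negative.
#' @param alpha FDR level (default 0.05).
#' @return A `GroupComparisonTable` data.frame: `probe_id`, group means, `F`,
#'   `p`, `q`, `significant`.
#' @export
group_comparison <- function(x, sheet, grouping = NULL, alpha = 0.05) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (x$scale != "log2")
    stop("group_comparison expects a log2-scale matrix", call. = FALSE)
  sheet <- as.data.frame(sheet)
  if (is.null(grouping)) {
    tum <- sheet[sheet$tissue == "tumor" &
                   sheet$fusion_annotation %in% c("positive", "negative"), ]
    grouping <- stats::setNames(tum$fusion_annotation, tum$sample_id)
  }
  grouping <- grouping[names(grouping) %in% sample_ids(x)]
  lev <- sort(unique(as.character(grouping)))
  if (length(lev) != 2L)
    stop("grouping must have exactly two levels", call. = FALSE)
  g1 <- names(grouping)[grouping == lev[1]]
  g2 <- names(grouping)[grouping == lev[2]]
  if (length(g1) < 2L || length(g2) < 2L)
    stop("each group needs at least 2 tumors", call. = FALSE)
  v1 <- x$values[, g1, drop = FALSE]
  v2 <- x$values[, g2, drop = FALSE]
  n1 <- length(g1); n2 <- length(g2)
  m1 <- rowMeans(v1); m2 <- rowMeans(v2)
  ss1 <- rowSums((v1 - m1)^2); ss2 <- rowSums((v2 - m2)^2)
  sp2 <- (ss1 + ss2) / (n1 + n2 - 2)
  Fstat <- ifelse(sp2 == 0, ifelse(m1 == m2, 0, Inf),
                  (m1 - m2)^2 / (sp2 * (1 / n1 + 1 / n2)))
  p <- stats::pf(Fstat, 1, n1 + n2 - 2, lower.tail = FALSE)
  fdr <- bh_fdr(p, alpha = alpha)
  out <- data.frame(probe_id = probe_ids(x),
                    mean_1 = m1, mean_2 = m2,
                    F = Fstat, p = p, q = fdr$q,
                    significant = fdr$significant,
                    stringsAsFactors = FALSE, row.names = NULL)
  names(out)[2:3] <- paste0("mean_", lev)
  structure(out, groups = lev,
            class = c("GroupComparisonTable", "data.frame"))
}

#' Ward hierarchical clustering of samples
#'
#' Agglomerative clustering of samples with the Ward criterion on Euclidean
#' distance over a probe subset (typically the derived signature). Samples
#' are pre-sorted by ID so the tree is invariant to input column order.
#'
#' @param x an [expression_matrix()] on the log2 scale.
#' @param probes character vector of probe IDs to cluster on.
#' @return list with `hclust` (the tree), `leaf_order` (sample IDs in
#'   dendrogram order) and `newick` (Newick string via [ape::as.phylo()]).
#' @export
hierarchical_cluster <- function(x, probes) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  probes <- intersect(probes, probe_ids(x))
  if (!length(probes))
    stop("probe subset is disjoint from the matrix", call. = FALSE)
  if (ncol(x$values) < 2L) stop("need at least 2 samples", call. = FALSE)
  v <- x$values[probes, order(sample_ids(x)), drop = FALSE]
  hc <- stats::hclust(stats::dist(t(v)), method = "ward.D2")
  nwk <- ape::write.tree(ape::as.phylo(hc))
  list(hclust = hc, leaf_order = hc$labels[hc$order], newick = nwk)
}

#' Principal component analysis of samples
#'
#' Probes (variables) are centered across samples; components are ordered by
#' decreasing explained variance, and each component's sign is fixed so its
#' largest-magnitude probe loading is positive. A constant matrix yields zero
#' scores and zero variance fractions.
#'
#' @param x an [expression_matrix()] on the log2 scale.
#' @param n_components number of components to return (default: full rank).
#' @return list with `scores` (samples x components), `loadings`
#'   (probes x components) and `var_fraction`.
#' @export
pca_samples <- function(x, n_components = NULL) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (ncol(x$values) < 2L) stop("need at least 2 samples", call. = FALSE)
  xc <- x$values - rowMeans(x$values)
  sv <- svd(t(xc))  # samples x probes
  tot <- sum(sv$d^2)
  if (tot == 0) {
    k <- if (is.null(n_components)) 1L else n_components
    return(list(scores = matrix(0, ncol(x$values), k,
                                dimnames = list(sample_ids(x), paste0("PC", seq_len(k)))),
                loadings = matrix(0, nrow(x$values), k,
                                  dimnames = list(probe_ids(x), paste0("PC", seq_len(k)))),
                var_fraction = rep(0, k)))
  }
  rank <- sum(sv$d > max(sv$d) * 1e-12)
  k <- if (is.null(n_components)) rank else min(n_components, rank)
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {  # sign convention
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  dimnames(scores) <- list(sample_ids(x), paste0("PC", seq_len(k)))
  dimnames(loadings) <- list(probe_ids(x), paste0("PC", seq_len(k)))
  list(scores = scores, loadings = loadings,
       var_fraction = sv$d[seq_len(k)]^2 / tot)
}
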