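# Independent oracles, deliberately naive: literal definitions with explicit
# loops, sharing no code with the package implementations they check.

# Benjamini-Hochberg step-up by its defining formula:
# q_i = min over { j : p_(j) >= p_i } of m * p_(j) / j, clipped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- Inf
    for (j in seq_len(m)) {
      if (ps[j] >= p[i]) cand <- min(cand, m * ps[j] / j)
    }
    q[i] <- min(cand, 1)
  }
  q
}

# Exact hypergeometric tail/two-sided p by binomial-coefficient enumeration.
# a = overlap, K = set size, n = signature size, N = universe size.
oracle_hyper_p1 <- function(a, K, n, N) {
  lo <- max(0, n + K - N); hi <- min(n, K)
  tot <- choose(N, n)
  sum(vapply(a:hi, function(k) choose(K, k) * choose(N - K, n - k), 0)) / tot
}

oracle_hyper_p2 <- function(a, K, n, N) {
  lo <- max(0, n + K - N); hi <- min(n, K)
  tot <- choose(N, n)
  probs <- vapply(lo:hi, function(k)
    choose(K, k) * choose(N - K, n - k) / tot, 0)
  obs <- probs[(lo:hi) == a]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Exhaustive two-segment changepoint enumeration: recompute the scan
# statistic at every admissible split with plain mean()/sum() arithmetic and
# return the argmax (smallest k on ties).
oracle_scan <- function(d, min_seg = 1, sd_floor = 0.05) {
  E <- length(d)
  best_k <- NA; best_S <- -Inf
  for (k in min_seg:(E - min_seg)) {
    s5 <- d[1:k]; s3 <- d[(k + 1):E]
    m5 <- mean(s5); m3 <- mean(s3)
    sp <- max(sqrt((sum((s5 - m5)^2) + sum((s3 - m3)^2)) / (E - 2)), sd_floor)
    S <- (m5 - m3) / (sp * sqrt(1 / k + 1 / (E - k)))
    if (S > best_S) { best_S <- S; best_k <- k }
  }
  list(k = best_k, S = best_S)
}

# Small paired cohort built directly (no generator): log2 values chosen so
# paired deltas are known exactly.
make_paired_matrix <- function(deltas, n_pairs = ncol(deltas),
                               baseline = 10) {
  # deltas: probes x pairs matrix of tumor-minus-normal log2 differences
  probes <- rownames(deltas)
  if (is.null(probes)) probes <- paste0("p", seq_len(nrow(deltas)))
  tumors <- sprintf("P%02d_T", seq_len(n_pairs))
  normals <- sprintf("P%02d_N", seq_len(n_pairs))
  vals <- matrix(baseline, nrow(deltas), 2 * n_pairs)
  vals[, seq(1, 2 * n_pairs, 2)] <- baseline + deltas
  dimnames(vals) <- list(probes, as.vector(rbind(tumors, normals)))
  expression_matrix(vals, scale = "log2", assay = "mRNA")
}

make_sheet <- function(n_pairs, subtype = "ACC") {
  pts <- sprintf("P%02d", seq_len(n_pairs))
  sample_sheet(data.frame(
    sample_id = as.vector(rbind(paste0(pts, "_T"), paste0(pts, "_N"))),
    patient_id = rep(pts, each = 2),
    tissue = rep(c("tumor", "normal"), n_pairs),
    subtype = subtype,
    fusion_annotation = "unknown",
    stringsAsFactors = FALSE))
}

small_config <- function(...) {
  defaults <- list(n_genes = 400, n_pairs = 8, n_signature_up = 30,
                   n_signature_down = 15, n_fusion_pos = 4, n_mirna = 60,
                   n_mirna_down = 5, myb_low_index = 8)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# Larger cohort for end-to-end runs through quantile normalization: keeps the
# planted fraction small (~2%) so normalization does not distort the nulls.
pipeline_config <- function(...) {
  defaults <- list(n_genes = 2000, n_pairs = 8, n_signature_up = 30,
                   n_signature_down = 15, n_fusion_pos = 4, n_mirna = 300,
                   n_mirna_down = 10, myb_low_index = 8)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}
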