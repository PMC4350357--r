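# Two-sided conditional p for a 2x2 enrichment table via the hypergeometric
# distribution (the Fisher exact rule: sum all tables no more probable than
# the observed one, with the standard relative tolerance).
hypergeom_p2 <- function(a, set_size, sig_size, universe) {
  support <- max(0L, sig_size + set_size - universe):min(sig_size, set_size)
  dens <- stats::dhyper(support, set_size, universe - set_size, sig_size)
  obs <- dens[support == a]
  min(1, sum(dens[dens <= obs * (1 + 1e-7)]))
}

hypergeom_p1 <- function(a, set_size, sig_size, universe) {
  stats::phyper(a - 1, set_size, universe - set_size, sig_size,
                lower.tail = FALSE)
}

#' Gene-set enrichment by Fisher's exact test
#'
#' For each annotation set, builds the 2x2 table (in/out signature x in/out
#' set) over the analysis universe and scores it with the exact
#' hypergeometric (Fisher) test; two-sided p-values are BH-corrected across
#' sets, and a one-sided (enrichment) p is reported alongside. Each set is
#' intersected with the universe before testing. The universe should be the
#' tested background — the probes surviving the baseline filter — not the
#' genome.
#'
#' @param signature character vector of signature genes (must be a subset of
#'   `universe`).
#' @param annotation a `GeneSetCollection` (named list of gene vectors).
#' @param universe character vector: all tested genes.
#' @param alpha FDR level for the significance flag (default 0.05).
#' @return An `EnrichmentResult` data.frame: `set`, `overlap`, `set_size`,
#'   `signature_size`, `universe_size`, `odds_ratio`, `p_two_sided`,
#'   `p_enrichment`, `q`, `significant`; rows ordered by q then p.
#' @export
fisher_enrichment <- function(signature, annotation, universe, alpha = 0.05) {
  universe <- unique(universe)
  signature <- unique(signature)
  if (!length(universe)) stop("empty universe", call. = FALSE)
  if (!length(signature)) stop("empty signature", call. = FALSE)
  out <- setdiff(signature, universe)
  if (length(out))
    stop("signature gene(s) outside the universe: ",
         paste(utils::head(out, 5), collapse = ", "), call. = FALSE)
  N <- length(universe)
  n <- length(signature)
  rows <- lapply(names(annotation), function(nm) {
    s <- intersect(unique(annotation[[nm]]), universe)
    K <- length(s)
    a <- length(intersect(signature, s))
    p2 <- if (K == 0) 1 else hypergeom_p2(a, K, n, N)
    p1 <- if (K == 0) 1 else hypergeom_p1(a, K, n, N)
    b <- n - a; cc <- K - a; dd <- N - K - b
    or <- ((a + 0.5) * (dd + 0.5)) / ((b + 0.5) * (cc + 0.5))
    data.frame(set = nm, overlap = a, set_size = K, signature_size = n,
               universe_size = N, odds_ratio = or, p_two_sided = p2,
               p_enrichment = p1, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  fdr <- bh_fdr(res$p_two_sided, alpha = alpha)
  res$q <- fdr$q
  res$significant <- fdr$significant
  res <- res[order(res$q, res$p_two_sided, res$set), ]
  rownames(res) <- NULL
  structure(res, class = c("EnrichmentResult", "data.frame"))
}

#' Fraction of a signature covered by ChIP-Seq targets
#'
#' `|signature intersect chip_targets| / |signature|` — the candidate
#' MYB-related share of the signature.
#'
#' @param signature non-empty character vector of signature genes.
#' @param chip_targets character vector of ChIP-Seq target genes.
#' @return A fraction in \[0, 1\].
#' @export
chipseq_overlap_fraction <- function(signature, chip_targets) {
  signature <- unique(signature)
  if (!length(signature)) stop("empty signature", call. = FALSE)
  length(intersect(signature, unique(chip_targets))) / length(signature)
}

#' Stratify tumors by a marker gene's expression
#'
#' A tumor is marker-low iff its log2 marker value does not exceed
#' `mean(normals) + k_sd * sd(normals)` — i.e. it is indistinguishable from
#' the normal-tissue baseline; otherwise marker-high.
#'
#' @param x an [expression_matrix()] on the log2 scale.
#' @param sheet a `SampleSheet` (needs >= 2 normal samples in the matrix).
#' @param marker probe/gene ID present in the matrix (e.g. `"MYB"`).
#' @param k_sd SD multiplier (default 2).
#' @return data.frame with `sample_id`, `marker_value`, `stratum`
#'   (`"marker-high"`/`"marker-low"`); attribute `threshold`.
#' @export
stratify_by_marker <- function(x, sheet, marker, k_sd = 2) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (x$scale != "log2")
    stop("stratify_by_marker expects a log2-scale matrix", call. = FALSE)
  if (!marker %in% probe_ids(x))
    stop("marker '", marker, "' absent from the matrix", call. = FALSE)
  sheet <- as.data.frame(sheet)
  normals <- intersect(sheet$sample_id[sheet$tissue == "normal"], sample_ids(x))
  tumors <- intersect(sheet$sample_id[sheet$tissue == "tumor"], sample_ids(x))
  if (length(normals) < 2L) stop("need at least 2 normal samples", call. = FALSE)
  nv <- x$values[marker, normals]
  thr <- mean(nv) + k_sd * stats::sd(nv)
  tv <- x$values[marker, tumors]
  structure(data.frame(sample_id = tumors, marker_value = as.numeric(tv),
                       stratum = ifelse(tv <= thr, "marker-low", "marker-high"),
                       stringsAsFactors = FALSE, row.names = NULL),
            threshold = thr, marker = marker)
}

#' Classify signature genes as MYB-dependent or MYB-independent
#'
#' Applies the MYB-low stratification logic: a gene activated (significant
#' and up at >= `min_fold`) in \emph{both} the MYB-high and MYB-low strata is
#' \strong{MYB-independent}; a gene activated only in the MYB-high stratum is
#' a \strong{MYB-dependent-candidate} if it is a ChIP-Seq MYB target, else
#' \strong{MYB-associated-unclassified}. Genes activated in neither stratum
#' are excluded.
#'
#' @param sig_high `SignatureTable` for the MYB-high stratum.
#' @param sig_low `SignatureTable` for the MYB-low stratum (typically a
#'   [descriptive_signature()], the stratum holding a single pair).
#' @param chip_targets character vector of ChIP-Seq MYB target genes.
#' @param min_fold linear fold threshold defining "activated" (default 2).
#' @return data.frame with `gene`, `label`, and evidence flags `up_high`,
#'   `up_low`, `in_chip`.
#' @export
classify_myb_dependence <- function(sig_high, sig_low, chip_targets,
                                    min_fold = 2) {
  if (!setequal(sig_high$probe_id, sig_low$probe_id))
    stop("the two signature tables must share one probe universe", call. = FALSE)
  activated_up <- function(tab) {
    ok <- tab$significant & !is.na(tab$direction) & tab$direction == "up" &
      !is.na(tab$fold_change) & tab$fold_change >= min_fold
    tab$probe_id[ok]
  }
  up_h <- activated_up(sig_high)
  up_l <- activated_up(sig_low)
  genes <- sort(union(up_h, up_l))
  if (!length(genes))
    return(data.frame(gene = character(), label = character(),
                      up_high = logical(), up_low = logical(),
                      in_chip = logical(), stringsAsFactors = FALSE))
  in_h <- genes %in% up_h
  in_l <- genes %in% up_l
  in_c <- genes %in% chip_targets
  label <- ifelse(in_h & in_l, "MYB-independent",
                  ifelse(in_h & !in_l & in_c, "MYB-dependent-candidate",
                         "MYB-associated-unclassified"))
  data.frame(gene = genes, label = label, up_high = in_h, up_low = in_l,
             in_chip = in_c, stringsAsFactors = FALSE)
}

#' Intersect the up-regulated signature with somatic mutations
#'
#' Candidate co-driver genes: significantly up-regulated in the signature and
#' carrying at least one mutation of an allowed class (default missense or
#' truncating — the potential gain-of-function classes). Output is sorted by
#' fold change, descending.
#'
#' @param signature a `SignatureTable`.
#' @param mutations data.frame from [read_mutations()].
#' @param classes allowed mutation classes.
#' @return data.frame with `gene`, `fold_change`, `log2_fc`,
#'   `mutation_classes` (comma-joined), `n_mutations`.
#' @export
integrate_mutations <- function(signature, mutations,
                                classes = c("missense", "truncating")) {
  up <- signature[signature$significant & !is.na(signature$direction) &
                    signature$direction == "up", ]
  mut <- mutations[mutations$mutation_class %in% classes, , drop = FALSE]
  genes <- intersect(up$probe_id, unique(mut$gene))
  if (!length(genes))
    return(data.frame(gene = character(), fold_change = numeric(),
                      log2_fc = numeric(), mutation_classes = character(),
                      n_mutations = integer(), stringsAsFactors = FALSE))
  idx <- match(genes, up$probe_id)
  out <- data.frame(gene = genes,
                    fold_change = up$fold_change[idx],
                    log2_fc = up$log2_fc[idx],
                    mutation_classes = vapply(genes, function(g)
                      paste(sort(unique(mut$mutation_class[mut$gene == g])),
                            collapse = ","), ""),
                    n_mutations = vapply(genes, function(g)
                      sum(mut$gene == g), 1L),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$fold_change, out$gene), , drop = FALSE]
}

#' Link down-regulated miRNAs to inversely regulated target genes
#'
#' Emits (miRNA, target) pairs from the prediction map where both members are
#' significant in their respective signatures and their directions are
#' opposite, annotated with both fold changes.
#'
#' @param mi_sig `SignatureTable` for the miRNA signature.
#' @param m_sig `SignatureTable` for the mRNA signature.
#' @param map data.frame from [read_mirna_targets()].
#' @return data.frame with `mirna_id`, `target_gene`, `mirna_direction`,
#'   `target_direction`, `mirna_fold_change`, `target_fold_change`.
#' @export
mirna_mrna_links <- function(mi_sig, m_sig, map) {
  mi <- mi_sig[mi_sig$significant, ]
  mg <- m_sig[m_sig$significant, ]
  i <- match(map$mirna_id, mi$probe_id)
  j <- match(map$target_gene, mg$probe_id)
  keep <- !is.na(i) & !is.na(j) &
    mi$direction[i] != mg$direction[j]
  out <- data.frame(mirna_id = map$mirna_id[keep],
                    target_gene = map$target_gene[keep],
                    mirna_direction = mi$direction[i[keep]],
                    target_direction = mg$direction[j[keep]],
                    mirna_fold_change = mi$fold_change[i[keep]],
                    target_fold_change = mg$fold_change[j[keep]],
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$mirna_id, out$target_gene), , drop = FALSE]
}
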