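#' Write a result table as deterministic TSV
#'
#' `#`-prefixed parameter header, fixed significant-digit formatting, no
#' timestamps — byte-stable for a given input.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param params optional named list written as `# key=value` header lines.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(df, path, params = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(params)) {
    kv <- vapply(names(params), function(k)
      paste0(k, "=", paste(format(params[[k]], digits = 15), collapse = ",")), "")
    writeLines(paste0("# ", kv), con)
  }
  df <- as.data.frame(df)
  for (j in seq_along(df))
    if (is.numeric(df[[j]]) && !is.integer(df[[j]]))
      df[[j]] <- sprintf("%.10g", df[[j]])
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a signature table (TSV with parameter header)
#' @param sig a `SignatureTable`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signature_table <- function(sig, path) {
  write_result_table(sig, path, attr(sig, "params"))
}

#' Write fusion calls (TSV with parameter header)
#' @param calls a `FusionCallTable`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fusion_calls <- function(calls, path) {
  write_result_table(calls, path, attr(calls, "params"))
}

#' Run the full analysis pipeline on a cohort
#'
#' The end-to-end composition, each stage delegating to the corresponding
#' exported function: quantile normalization of the mRNA and miRNA matrices;
#' signature derivation (baseline filter 50 / 800, paired fold filter,
#' paired t-tests, BH FDR); fusion-group comparison; MYB exon changepoint
#' calls; MYB-level stratification and dependence classification (when a
#' marker-low tumor exists); gene-set enrichment over the baseline-filtered
#' universe; mutation intersection; and miRNA-mRNA inverse links. If
#' `out_dir` is given, every result is written as TSV plus a
#' `run_summary.json`; outputs are byte-deterministic for a given cohort.
#'
#' @param cohort an `AccCohort` from [generate_cohort()], or a `SimConfig`
#'   (which is generated first).
#' @param out_dir optional output directory.
#' @param alpha FDR level (default 0.05).
#' @param min_fold fold-change filter threshold (default 2).
#' @param min_intensity_mrna,min_intensity_mirna baseline thresholds
#'   (defaults 50 and 800).
#' @param marker stratification marker gene (default `"MYB"`).
#' @param render_plots write the exon SVG plot (default FALSE).
#' @return list with `signature_mrna`, `signature_mirna`, `group_comparison`,
#'   `fusion_calls`, `strata`, `signature_high`, `signature_low`,
#'   `dependence`, `enrichment`, `chip_overlap`, `mutation_candidates`,
#'   `mirna_links`, `clustering`, `pca`.
#' @export
run_pipeline <- function(cohort, out_dir = NULL, alpha = 0.05, min_fold = 2,
                         min_intensity_mrna = 50, min_intensity_mirna = 800,
                         marker = "MYB", render_plots = FALSE) {
  if (inherits(cohort, "SimConfig")) cohort <- generate_cohort(cohort)
  stopifnot(inherits(cohort, "AccCohort"))
  sheet <- cohort$sheet

  qn_mrna <- quantile_normalize(cohort$mrna)
  qn_mirna <- quantile_normalize(cohort$mirna)

  sig_mrna <- derive_signature(qn_mrna, sheet, alpha = alpha,
                               min_fold = min_fold,
                               min_intensity = min_intensity_mrna)
  sig_mirna <- derive_signature(qn_mirna, sheet, alpha = alpha,
                                min_fold = min_fold,
                                min_intensity = min_intensity_mirna)

  lg <- log2_transform(qn_mrna)
  grp <- tryCatch(group_comparison(lg, sheet, alpha = alpha),
                  error = function(e) NULL)

  calls <- call_fusion(cohort$exon, sheet)

  strata <- NULL; sig_high <- NULL; sig_low <- NULL; dependence <- NULL
  if (marker %in% rownames(qn_mrna$values)) {
    strata <- stratify_by_marker(lg, sheet, marker)
    low_tumors <- strata$sample_id[strata$stratum == "marker-low"]
    high_tumors <- strata$sample_id[strata$stratum == "marker-high"]
    sheet_df <- as.data.frame(sheet)
    pat_of <- function(s) sheet_df$patient_id[match(s, sheet_df$sample_id)]
    if (length(low_tumors) >= 1 && length(high_tumors) >= 2) {
      sig_high <- derive_signature(qn_mrna, subset_sheet(sheet, pat_of(high_tumors)),
                                   alpha = alpha, min_fold = min_fold,
                                   min_intensity = min_intensity_mrna)
      sig_low <- descriptive_signature(qn_mrna, sheet,
                                       patients = pat_of(low_tumors),
                                       min_fold = min_fold,
                                       min_intensity = min_intensity_mrna)
      chip <- cohort$truth$chip_targets
      if (length(chip))
        dependence <- classify_myb_dependence(sig_high, sig_low, chip,
                                              min_fold = min_fold)
    }
  }

  sig_genes <- sig_mrna$probe_id[sig_mrna$significant]
  universe <- sig_mrna$probe_id[sig_mrna$passed_baseline]
  enrichment <- NULL
  if (!is.null(cohort$truth$annotation) && length(sig_genes))
    enrichment <- fisher_enrichment(sig_genes, cohort$truth$annotation,
                                    universe, alpha = alpha)
  chip_overlap <- if (length(cohort$truth$chip_targets) && length(sig_genes))
    chipseq_overlap_fraction(sig_genes, cohort$truth$chip_targets) else NA_real_

  mut_cand <- if (!is.null(cohort$truth$mutations))
    integrate_mutations(sig_mrna, cohort$truth$mutations) else NULL
  links <- if (!is.null(cohort$truth$target_map))
    mirna_mrna_links(sig_mirna, sig_mrna, cohort$truth$target_map) else NULL

  clustering <- if (length(sig_genes) >= 2)
    hierarchical_cluster(lg, sig_genes) else NULL
  pca <- pca_samples(lg)

  res <- list(signature_mrna = sig_mrna, signature_mirna = sig_mirna,
              group_comparison = grp, fusion_calls = calls, strata = strata,
              signature_high = sig_high, signature_low = sig_low,
              dependence = dependence, enrichment = enrichment,
              chip_overlap = chip_overlap, mutation_candidates = mut_cand,
              mirna_links = links, clustering = clustering, pca = pca)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(f) file.path(out_dir, f)
    write_signature_table(sig_mrna, fp("signature_mrna.tsv"))
    write_signature_table(sig_mirna, fp("signature_mirna.tsv"))
    if (!is.null(grp)) write_result_table(grp, fp("group_comparison.tsv"))
    write_fusion_calls(calls, fp("fusion_calls.tsv"))
    if (!is.null(strata))
      write_result_table(strata, fp("strata.tsv"),
                         list(marker = marker,
                              threshold = attr(strata, "threshold")))
    if (!is.null(dependence))
      write_result_table(dependence, fp("dependence_labels.tsv"))
    if (!is.null(enrichment))
      write_result_table(enrichment, fp("enrichment.tsv"))
    if (!is.null(mut_cand))
      write_result_table(mut_cand, fp("mutation_candidates.tsv"))
    if (!is.null(links)) write_result_table(links, fp("mirna_links.tsv"))
    if (!is.null(clustering))
      writeLines(clustering$newick, fp("sample_dendrogram.nwk"))
    summary <- list(
      seed = cohort$config$seed,
      n_pairs = cohort$config$n_pairs,
      alpha = alpha, min_fold = min_fold,
      n_significant_mrna = sum(sig_mrna$significant),
      n_significant_mirna = sum(sig_mirna$significant),
      n_fusion_positive = sum(calls$status == "positive"),
      chip_overlap = chip_overlap)
    jsonlite::write_json(summary, fp("run_summary.json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
    if (render_plots)
      render_exon_plot(cohort$exon, sheet, calls, fp("exon_plot.svg"))
    return(invisible(res))
  }
  res
}

#' Restrict a sample sheet to the given patients (both pair members)
#' @param sheet a `SampleSheet`.
#' @param patients character vector of patient IDs to keep.
#' @return A `SampleSheet` with only those patients' rows.
#' @export
subset_sheet <- function(sheet, patients) {
  df <- as.data.frame(sheet)
  sample_sheet(df[df$patient_id %in% patients, , drop = FALSE])
}
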