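#' Construct and validate a sample sheet
#'
#' Per-sample metadata for a paired tumor/normal cohort. Controlled
#' vocabularies are enforced: `tissue` is `"tumor"` or `"normal"`, `subtype`
#' is `"ACC"`, `"MEC"` or `"ADC"`, `fusion_annotation` is `"positive"`,
#' `"negative"` or `"unknown"`.
#'
#' @param df data.frame with columns `sample_id`, `patient_id`, `tissue`,
#'   `subtype`, `fusion_annotation`.
#' @return A validated `SampleSheet` (a data.frame subclass).
#' @export
sample_sheet <- function(df) {
  need <- c("sample_id", "patient_id", "tissue", "subtype", "fusion_annotation")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("sample sheet missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df <- as.data.frame(df[, need], stringsAsFactors = FALSE)
  for (col in need) df[[col]] <- as.character(df[[col]])
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "),
         call. = FALSE)
  check_vocab <- function(col, allowed) {
    bad <- setdiff(unique(df[[col]]), allowed)
    if (length(bad))
      stop(sprintf("invalid %s value(s): %s (allowed: %s)", col,
                   paste(bad, collapse = ", "), paste(allowed, collapse = ", ")),
           call. = FALSE)
  }
  check_vocab("tissue", c("tumor", "normal"))
  check_vocab("subtype", c("ACC", "MEC", "ADC"))
  check_vocab("fusion_annotation", c("positive", "negative", "unknown"))
  class(df) <- c("SampleSheet", "data.frame")
  df
}

#' Read a sample sheet from TSV
#'
#' @param path TSV with columns `sample_id`, `patient_id`, `tissue`,
#'   `subtype`, `fusion_annotation`; `#` comment lines ignored.
#' @return A `SampleSheet`.
#' @export
read_sample_sheet <- function(path) {
  tab <- read_tsv_table(path)
  df <- as.data.frame(tab$rows, stringsAsFactors = FALSE)
  names(df) <- tab$header
  sample_sheet(df)
}

#' Write a sample sheet to TSV
#' @param sheet a `SampleSheet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(as.data.frame(sheet), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Resolve tumor/normal pairs from a sample sheet
#'
#' Builds the patient -> (tumor sample, normal sample) pairing index used by
#' every paired analysis. Patients with a tumor row but no matching normal
#' (or vice versa) raise an error listing the orphan patients.
#'
#' @param sheet a `SampleSheet`.
#' @param patients optional character vector restricting to these patient IDs.
#' @return data.frame with columns `patient_id`, `tumor`, `normal`.
#' @export
sample_pairs <- function(sheet, patients = NULL) {
  sheet <- as.data.frame(sheet)
  if (!is.null(patients)) sheet <- sheet[sheet$patient_id %in% patients, ]
  tum <- sheet[sheet$tissue == "tumor", ]
  nrm <- sheet[sheet$tissue == "normal", ]
  pts <- unique(c(tum$patient_id, nrm$patient_id))
  orphan <- pts[!(pts %in% tum$patient_id & pts %in% nrm$patient_id)]
  if (length(orphan))
    stop("unpaired patient(s): ", paste(sort(orphan), collapse = ", "),
         call. = FALSE)
  multi <- pts[tabulate(factor(tum$patient_id, pts), length(pts)) > 1 |
                 tabulate(factor(nrm$patient_id, pts), length(pts)) > 1]
  if (length(multi))
    stop("patient(s) with multiple tumor or normal rows: ",
         paste(sort(multi), collapse = ", "), call. = FALSE)
  pts <- unique(tum$patient_id)
  data.frame(patient_id = pts,
             tumor = tum$sample_id[match(pts, tum$patient_id)],
             normal = nrm$sample_id[match(pts, nrm$patient_id)],
             stringsAsFactors = FALSE)
}
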