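#' Read gene sets from a GMT file
#'
#' Standard GMT semantics: one set per line — name, description, then
#' tab-separated member symbols. Members are deduplicated preserving first
#' occurrence; empty sets and duplicated set names are format errors.
#' Gene identifiers are opaque, case-sensitive strings.
#'
#' @param path GMT file path.
#' @return A `GeneSetCollection`: a named list of character vectors with a
#'   `description` attribute on each set.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 1L) < 3L)
  if (length(short)) {
    nm <- vapply(fields[short], `[`, "", 1L)
    stop("gene set with empty member list: ", paste(nm, collapse = ", "),
         call. = FALSE)
  }
  nms <- vapply(fields, `[`, "", 1L)
  if (anyDuplicated(nms))
    stop("duplicate gene set name: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  sets <- lapply(fields, function(f) {
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members))
      stop("gene set with empty member list: ", f[1], call. = FALSE)
    attr(members, "description") <- f[2]
    members
  })
  names(sets) <- nms
  structure(sets, class = "GeneSetCollection")
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors (a `GeneSetCollection` or any
#'   named list).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("all gene sets must be named", call. = FALSE)
  lines <- vapply(seq_along(sets), function(i) {
    desc <- attr(sets[[i]], "description")
    if (is.null(desc)) desc <- names(sets)[i]
    paste(c(names(sets)[i], desc, sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path, useBytes = FALSE)
  invisible(path)
}

#' Read a miRNA -> target-gene map
#'
#' Two-column TSV (`mirna_id`, `target_gene`); duplicate pairs are dropped
#' after loading.
#'
#' @param path TSV path.
#' @return data.frame with columns `mirna_id`, `target_gene`.
#' @export
read_mirna_targets <- function(path) {
  tab <- read_tsv_table(path)
  if (length(tab$header) < 2L)
    stop("miRNA target map needs columns mirna_id, target_gene", call. = FALSE)
  df <- data.frame(mirna_id = tab$rows[, 1], target_gene = tab$rows[, 2],
                   stringsAsFactors = FALSE)
  if (any(!nzchar(df$mirna_id)) || any(!nzchar(df$target_gene)))
    stop("empty mirna_id or target_gene in ", path, call. = FALSE)
  df[!duplicated(df[, c("mirna_id", "target_gene")]), , drop = FALSE]
}

#' Read a somatic mutation table
#'
#' TSV with columns `gene`, `sample_id`, `mutation_class`; the class must be
#' one of `missense`, `truncating`, `other`.
#'
#' @param path TSV path.
#' @return data.frame with columns `gene`, `sample_id`, `mutation_class`.
#' @export
read_mutations <- function(path) {
  tab <- read_tsv_table(path)
  if (length(tab$header) < 3L)
    stop("mutation table needs columns gene, sample_id, mutation_class",
         call. = FALSE)
  df <- data.frame(gene = tab$rows[, 1], sample_id = tab$rows[, 2],
                   mutation_class = tab$rows[, 3], stringsAsFactors = FALSE)
  if (any(!nzchar(df$gene)) || any(!nzchar(df$sample_id)))
    stop("empty gene or sample_id in ", path, call. = FALSE)
  bad <- setdiff(unique(df$mutation_class), c("missense", "truncating", "other"))
  if (length(bad))
    stop("invalid mutation_class value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  df
}
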