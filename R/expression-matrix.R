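#' Construct an expression matrix
#'
#' The basic container for probe-set-level intensities: a numeric matrix with
#' probe sets as rows and samples as columns, an explicit scale flag
#' (`"linear"` or `"log2"`), and an assay tag. Linear-scale values must be
#' non-negative; all values must be finite; probe and sample identifiers must
#' be unique.
#'
#' @param values numeric matrix with rownames (probe IDs) and colnames
#'   (sample IDs).
#' @param scale `"linear"` or `"log2"`.
#' @param assay assay tag, one of `"mRNA"`, `"miRNA"`, `"exon"`.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `scale`, `assay`.
#' @export
expression_matrix <- function(values, scale = c("linear", "log2"),
                              assay = c("mRNA", "miRNA", "exon")) {
  scale <- match.arg(scale)
  assay <- match.arg(assay)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry probe rownames and sample colnames", call. = FALSE)
  dup_p <- rownames(values)[duplicated(rownames(values))]
  if (length(dup_p))
    stop("duplicate probe ID: ", paste(unique(dup_p), collapse = ", "), call. = FALSE)
  dup_s <- colnames(values)[duplicated(colnames(values))]
  if (length(dup_s))
    stop("duplicate sample ID: ", paste(unique(dup_s), collapse = ", "), call. = FALSE)
  if (any(!is.finite(values)))
    stop("all values must be finite", call. = FALSE)
  if (scale == "linear" && any(values < 0))
    stop("linear-scale values must be non-negative", call. = FALSE)
  structure(list(values = values, scale = scale, assay = assay),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d probes x %d samples [%s, %s]\n",
              nrow(x$values), ncol(x$values), x$assay, x$scale))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

probe_ids <- function(x) rownames(x$values)
sample_ids <- function(x) colnames(x$values)

# Read a tab-separated table with '#' comment lines; returns list(header, rows)
# where rows is a character matrix. Shared by all readers.
read_tsv_table <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines)) stop("empty file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  rows <- fields[-1]
  n <- length(header)
  bad <- which(vapply(rows, length, 1L) != n)
  if (length(bad))
    stop(sprintf("malformed row %d in %s: expected %d fields", bad[1] + 1L, path, n),
         call. = FALSE)
  list(header = header,
       rows = if (length(rows)) do.call(rbind, rows) else
         matrix(character(), 0, n))
}

#' Read an expression matrix from TSV
#'
#' Expects a tab-separated file whose header row names the samples and whose
#' first column holds probe IDs. `#`-prefixed comment lines are ignored.
#' Duplicate IDs and non-numeric cells are rejected with messages naming the
#' offending identifier or coordinates, never silently coerced.
#'
#' @param path file path.
#' @inheritParams expression_matrix
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, scale = c("linear", "log2"),
                                   assay = c("mRNA", "miRNA", "exon")) {
  tab <- read_tsv_table(path)
  samples <- tab$header[-1]
  probes <- tab$rows[, 1]
  dup <- probes[duplicated(probes)]
  if (length(dup))
    stop("duplicate probe ID in ", path, ": ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  raw <- tab$rows[, -1, drop = FALSE]
  vals <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw)))
  if (any(is.na(vals))) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric value '%s' at probe '%s', sample '%s' in %s",
                 raw[idx[1], idx[2]], probes[idx[1]], samples[idx[2]], path),
         call. = FALSE)
  }
  dimnames(vals) <- list(probes, samples)
  expression_matrix(vals, scale = scale, assay = assay)
}

#' Write an expression matrix to TSV
#'
#' @param x an [expression_matrix()].
#' @param path output path.
#' @param comment optional character vector written as leading `#` lines.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path, comment = NULL) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(comment)) writeLines(paste0("# ", comment), con)
  writeLines(paste(c("probe_id", sample_ids(x)), collapse = "\t"), con)
  # %.17g round-trips doubles exactly, keeping write->read the identity
  chr <- matrix(sprintf("%.17g", x$values), nrow = nrow(x$values))
  body <- apply(chr, 1L, paste, collapse = "\t")
  writeLines(paste(probe_ids(x), body, sep = "\t"), con)
  invisible(path)
}
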