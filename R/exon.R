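#' Construct an exon intensity profile
#'
#' Ordered (5' to 3') exon-level linear intensities for one focal gene across
#' the cohort samples — the substrate of the "exon plot" rearrangement caller.
#' Missing exons (e.g. an exon absent from the tumor transcript annotation)
#' are simply dropped upstream and never imputed; indices always refer to the
#' profile's own post-drop ordering.
#'
#' @param gene gene identifier.
#' @param values numeric matrix, exons (rownames, ordered 5'->3') x samples
#'   (colnames), linear scale, >= 5 exons.
#' @return An `ExonIntensityProfile` object.
#' @export
exon_profile <- function(gene, values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (nrow(values) < 5L)
    stop("an exon profile needs at least 5 exons", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry exon rownames and sample colnames", call. = FALSE)
  if (any(!is.finite(values)) || any(values < 0))
    stop("exon intensities must be finite and non-negative", call. = FALSE)
  structure(list(gene = gene, exon_ids = rownames(values), values = values),
            class = "ExonIntensityProfile")
}

#' @export
print.ExonIntensityProfile <- function(x, ...) {
  cat(sprintf("ExonIntensityProfile: gene %s, %d exons x %d samples\n",
              x$gene, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Read / write an exon profile TSV
#'
#' Format: columns `gene`, `exon_id`, then one column per sample; rows in 5'
#' to 3' order.
#'
#' @param path file path.
#' @return An [exon_profile()].
#' @export
read_exon_profile <- function(path) {
  tab <- read_tsv_table(path)
  if (length(tab$header) < 3L || any(tab$header[1:2] != c("gene", "exon_id")))
    stop("exon profile TSV needs columns gene, exon_id, <samples...>", call. = FALSE)
  gene <- unique(tab$rows[, 1])
  if (length(gene) != 1L)
    stop("exon profile must describe a single gene, found: ",
         paste(gene, collapse = ", "), call. = FALSE)
  raw <- tab$rows[, -(1:2), drop = FALSE]
  vals <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw)))
  if (any(is.na(vals))) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric value at exon '%s', sample '%s' in %s",
                 tab$rows[idx[1], 2], tab$header[-(1:2)][idx[2]], path),
         call. = FALSE)
  }
  dimnames(vals) <- list(tab$rows[, 2], tab$header[-(1:2)])
  exon_profile(gene, vals)
}

#' @rdname read_exon_profile
#' @param profile an [exon_profile()].
#' @export
write_exon_profile <- function(profile, path) {
  stopifnot(inherits(profile, "ExonIntensityProfile"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("gene", "exon_id", colnames(profile$values)),
                   collapse = "\t"), con)
  chr <- matrix(sprintf("%.17g", profile$values), nrow = nrow(profile$values))
  writeLines(paste(profile$gene, rownames(profile$values),
                   apply(chr, 1L, paste, collapse = "\t"), sep = "\t"), con)
  invisible(path)
}

#' Per-exon tumor-minus-normal log2 delta
#'
#' `d_e = log2(tumor_e + pseudocount) - log2(normal_e + pseudocount)`,
#' ordered 5' to 3'. The pseudocount keeps zero intensities finite.
#'
#' @param profile an [exon_profile()].
#' @param tumor,normal sample IDs present in the profile.
#' @param pseudocount small positive constant (default 1).
#' @return Numeric vector named by exon ID.
#' @export
delta_profile <- function(profile, tumor, normal, pseudocount = 1) {
  stopifnot(inherits(profile, "ExonIntensityProfile"))
  miss <- setdiff(c(tumor, normal), colnames(profile$values))
  if (length(miss))
    stop("sample(s) missing from exon profile: ", paste(miss, collapse = ", "),
         call. = FALSE)
  d <- log2(profile$values[, tumor] + pseudocount) -
    log2(profile$values[, normal] + pseudocount)
  stats::setNames(as.numeric(d), rownames(profile$values))
}

#' Two-segment changepoint scan over an exon delta vector
#'
#' Formalizes the visual "relative drop in intensities immediately after the
#' breakpoint": for every admissible split k the statistic
#' `S(k) = (mean(d[1..k]) - mean(d[k+1..E])) / (s_p(k) * sqrt(1/k + 1/(E-k)))`
#' is computed, with `s_p(k)` the pooled within-segment standard deviation
#' floored at `sd_floor` (so noise-free steps give large finite statistics
#' rather than 0/0). The reported breakpoint is the argmax of S — the last
#' retained 5' exon (1-based) — taking the smallest k on ties.
#'
#' @param d numeric delta vector (5' to 3').
#' @param min_seg minimum exons per segment (default 1, admitting a terminal
#'   single-exon 3' segment — the most common rearrangement site lies one
#'   exon from the 3' end).
#' @param sd_floor lower bound on the pooled within-segment SD in log2 units
#'   (default 0.05).
#' @return list with `k` (breakpoint index), `S` (scan statistic at k),
#'   `seg5_mean`, `seg3_mean`, and `S_all` (the full statistic vector, named
#'   by k).
#' @export
scan_breakpoint <- function(d, min_seg = 1, sd_floor = 0.05) {
  E <- length(d)
  if (E < 2 * min_seg || E < 3)
    stop("delta vector too short for min_seg = ", min_seg, call. = FALSE)
  ks <- min_seg:(E - min_seg)
  m5 <- m3 <- S <- numeric(length(ks))
  for (i in seq_along(ks)) {       # E <= a few dozen: direct arithmetic
    k <- ks[i]
    s5 <- d[1:k]; s3 <- d[(k + 1):E]
    m5[i] <- mean(s5); m3[i] <- mean(s3)
    sp <- max(sqrt((sum((s5 - m5[i])^2) + sum((s3 - m3[i])^2)) / (E - 2)),
              sd_floor)
    S[i] <- (m5[i] - m3[i]) / (sp * sqrt(1 / k + 1 / (E - k)))
  }
  i <- which.max(S)  # which.max takes the first (smallest k) on ties
  list(k = ks[i], S = S[i], seg5_mean = m5[i], seg3_mean = m3[i],
       S_all = stats::setNames(S, ks))
}

#' Call MYB 3' rearrangement status for every tumor
#'
#' For each tumor/matched-normal pair, computes the exon delta vector, runs
#' the changepoint scan, and calls:
#' \itemize{
#'   \item \strong{positive} — `S(k) >= tau` and `seg5_mean >= min_delta5`
#'     and `seg3_mean <= max_delta3` (elevated 5' exons, lost 3' exons);
#'   \item \strong{negative} — `S(k) < tau` (consistent intensities across
#'     the gene, whether elevated or not: uniform overexpression is not a
#'     rearrangement call);
#'   \item \strong{indeterminate} — a strong changepoint whose segment means
#'     do not fit the rearrangement pattern (e.g. elevated 3' segment).
#' }
#' Positives additionally get a terminal-allele assessment
#' ([assess_terminal_alleles()]).
#'
#' @param profile an [exon_profile()] covering all cohort samples.
#' @param sheet a `SampleSheet` pairing tumors to normals.
#' @param tau scan-statistic threshold (default 4).
#' @param min_delta5 minimum 5'-segment mean log2 delta for a positive
#'   (default 1.0, i.e. 2-fold elevation).
#' @param max_delta3 maximum 3'-segment mean log2 delta for a positive
#'   (default 0.5).
#' @param silent_margin margin for the terminal-allele call (default 0.5).
#' @param min_seg,sd_floor,pseudocount passed to [scan_breakpoint()] /
#'   [delta_profile()].
#' @return A `FusionCallTable` data.frame: `sample_id`, `status`,
#'   `breakpoint` (last retained 5' exon index, NA for non-positives),
#'   `scan_stat`, `seg5_mean`, `seg3_mean`, `terminal_allele` (`"silent"`,
#'   `"residual"`, or NA for non-positives).
#' @export
call_fusion <- function(profile, sheet, tau = 4, min_delta5 = 1.0,
                        max_delta3 = 0.5, silent_margin = 0.5,
                        min_seg = 1, sd_floor = 0.05, pseudocount = 1) {
  stopifnot(inherits(profile, "ExonIntensityProfile"))
  pairs <- sample_pairs(sheet)
  pairs <- pairs[pairs$tumor %in% colnames(profile$values), ]
  miss <- setdiff(pairs$normal, colnames(profile$values))
  if (length(miss))
    stop("matched normal(s) missing from exon profile: ",
         paste(miss, collapse = ", "), call. = FALSE)
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    d <- delta_profile(profile, pairs$tumor[i], pairs$normal[i], pseudocount)
    sc <- scan_breakpoint(d, min_seg = min_seg, sd_floor = sd_floor)
    if (sc$S >= tau && sc$seg5_mean >= min_delta5 && sc$seg3_mean <= max_delta3) {
      status <- "positive"
    } else if (sc$S < tau) {
      status <- "negative"
    } else {
      status <- "indeterminate"
    }
    data.frame(sample_id = pairs$tumor[i], status = status,
               breakpoint = if (status == "positive") sc$k else NA_integer_,
               scan_stat = sc$S, seg5_mean = sc$seg5_mean,
               seg3_mean = sc$seg3_mean,
               terminal_allele = if (status == "positive")
                 assess_terminal_allele_value(sc$seg3_mean, silent_margin)
               else NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  structure(out,
            params = list(tau = tau, min_delta5 = min_delta5,
                          max_delta3 = max_delta3, silent_margin = silent_margin,
                          min_seg = min_seg, sd_floor = sd_floor,
                          breakpoint_convention = "last retained 5' exon, 1-based"),
            class = c("FusionCallTable", "data.frame"))
}

assess_terminal_allele_value <- function(seg3_mean, silent_margin = 0.5) {
  if (seg3_mean <= silent_margin) "silent" else "residual"
}

#' Assess wildtype/reciprocal allele expression at the 3' terminus
#'
#' For a rearrangement-positive tumor, 3' exons at or below the matched
#' normal baseline (`seg3_mean <= silent_margin`, inclusive boundary) imply
#' no detectable wildtype or reciprocal transcript (`"silent"`); elevated 3'
#' signal implies `"residual"` expression.
#'
#' @param call one row of a `FusionCallTable` (or a list with `status` and
#'   `seg3_mean`).
#' @param silent_margin log2 margin above baseline (default 0.5).
#' @return `"silent"` or `"residual"`.
#' @export
assess_terminal_alleles <- function(call, silent_margin = 0.5) {
  if (is.data.frame(call)) call <- as.list(call[1, ])
  if (!identical(call$status, "positive"))
    stop("terminal-allele assessment applies only to positive calls",
         call. = FALSE)
  assess_terminal_allele_value(call$seg3_mean, silent_margin)
}

#' Render a multi-panel exon plot
#'
#' One panel per tumor: tumor and matched-normal exon traces on the log2
#' scale, with the called breakpoint marked for positives. Output is SVG
#' (deterministic layout; no timestamps).
#'
#' @param profile an [exon_profile()].
#' @param sheet a `SampleSheet`.
#' @param calls a `FusionCallTable` from [call_fusion()].
#' @param path output file (`.svg`).
#' @param pseudocount as in [delta_profile()].
#' @return `path`, invisibly.
#' @export
render_exon_plot <- function(profile, sheet, calls, path, pseudocount = 1) {
  stopifnot(inherits(profile, "ExonIntensityProfile"))
  pairs <- sample_pairs(sheet)
  pairs <- pairs[pairs$tumor %in% calls$sample_id, ]
  n <- nrow(pairs)
  nc <- ceiling(sqrt(n))
  nr <- ceiling(n / nc)
  grDevices::svg(path, width = 3 * nc, height = 2.4 * nr)
  on.exit(grDevices::dev.off())
  op <- graphics::par(mfrow = c(nr, nc), mar = c(2.5, 2.5, 2, 0.5),
                      mgp = c(1.5, 0.5, 0))
  on.exit(graphics::par(op), add = TRUE, after = FALSE)
  E <- nrow(profile$values)
  for (i in seq_len(n)) {
    tu <- log2(profile$values[, pairs$tumor[i]] + pseudocount)
    no <- log2(profile$values[, pairs$normal[i]] + pseudocount)
    call_i <- calls[calls$sample_id == pairs$tumor[i], ]
    graphics::matplot(seq_len(E), cbind(tu, no), type = "l", lty = 1,
                      col = c("red", "blue"), xlab = "exon (5' to 3')",
                      ylab = "log2 intensity",
                      main = sprintf("%s [%s]", pairs$tumor[i], call_i$status))
    if (nrow(call_i) && !is.na(call_i$breakpoint))
      graphics::abline(v = call_i$breakpoint + 0.5, lty = 2, col = "grey30")
  }
  invisible(path)
}
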