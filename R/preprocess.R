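#' Quantile-normalize a linear-scale expression matrix
#'
#' Forces every sample's value distribution onto the common reference of
#' across-sample mean order statistics (the normalization used after robust
#' multichip averaging on expression arrays). Ties within a sample receive the
#' mean of the normalized values they span. Delegates to
#' [limma::normalizeQuantiles()].
#'
#' @param x an [expression_matrix()] on the linear scale with >= 1 sample.
#' @return A quantile-normalized `ExpressionMatrix`, still linear scale.
#'   A single-sample matrix is returned unchanged with a warning.
#' @export
quantile_normalize <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (x$scale != "linear")
    stop("quantile_normalize expects a linear-scale matrix", call. = FALSE)
  if (ncol(x$values) < 2L) {
    warning("single-sample matrix: quantile normalization is a no-op")
    return(x)
  }
  v <- limma::normalizeQuantiles(x$values, ties = TRUE)
  dimnames(v) <- dimnames(x$values)
  # numerical guard: normalization of non-negative input stays non-negative
  v[v < 0] <- 0
  expression_matrix(v, scale = "linear", assay = x$assay)
}

#' Log2-transform a linear-scale matrix
#'
#' Values are floored at `floor` before taking log2, so zeros map to
#' `log2(floor)` rather than -Inf.
#'
#' @param x an [expression_matrix()] on the linear scale.
#' @param floor small positive constant (default 1).
#' @return An `ExpressionMatrix` with `scale = "log2"`.
#' @export
log2_transform <- function(x, floor = 1) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (x$scale != "linear")
    stop("matrix is already on the log2 scale", call. = FALSE)
  if (!is.numeric(floor) || floor <= 0)
    stop("`floor` must be positive", call. = FALSE)
  v <- log2(pmax(x$values, floor))
  expression_matrix(v, scale = "log2", assay = x$assay)
}

filter_report <- function(probe_id, passed_baseline, passed_variation,
                          thresholds) {
  structure(data.frame(probe_id = probe_id,
                       passed_baseline = passed_baseline,
                       passed_variation = passed_variation,
                       stringsAsFactors = FALSE),
            thresholds = thresholds,
            class = c("FilterReport", "data.frame"))
}

#' Baseline intensity filter
#'
#' A probe set is retained iff its maximum intensity across samples reaches
#' `min_intensity` (so a probe expressed in any sample survives — including
#' tumor-specific genes expressed in a single sample). The conventional
#' thresholds are 50 for mRNA arrays and 800 for miRNA arrays.
#'
#' @param x an [expression_matrix()] on the linear scale.
#' @param min_intensity positive intensity threshold.
#' @return list with elements `matrix` (filtered, original probe order
#'   preserved) and `report` (a `FilterReport` over all input probes).
#' @export
baseline_filter <- function(x, min_intensity = 50) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (x$scale != "linear")
    stop("baseline_filter expects a linear-scale matrix", call. = FALSE)
  if (!is.numeric(min_intensity) || min_intensity <= 0)
    stop("`min_intensity` must be positive", call. = FALSE)
  keep <- apply(x$values, 1L, max) >= min_intensity
  rep <- filter_report(probe_ids(x), keep, NA,
                       list(min_intensity = min_intensity))
  list(matrix = expression_matrix(x$values[keep, , drop = FALSE],
                                  scale = "linear", assay = x$assay),
       report = rep)
}

#' Paired fold-change (variation) filter
#'
#' A probe set is retained iff the absolute mean over tumor/normal pairs of
#' the paired log2 difference reaches `log2(min_fold)` — the same statistic
#' the downstream paired t-test evaluates. `method = "max"` instead requires
#' any single pair to reach the threshold.
#'
#' @param x an [expression_matrix()] on the log2 scale.
#' @param sheet a `SampleSheet` resolving tumor/normal pairs.
#' @param min_fold linear fold-change threshold (default 2).
#' @param method `"mean"` (default) or `"max"` aggregation over pairs.
#' @return list with elements `matrix` and `report` as in [baseline_filter()].
#' @export
variation_filter <- function(x, sheet, min_fold = 2, method = c("mean", "max")) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  method <- match.arg(method)
  if (x$scale != "log2")
    stop("variation_filter expects a log2-scale matrix", call. = FALSE)
  pairs <- sample_pairs(sheet)
  pairs <- pairs[pairs$tumor %in% sample_ids(x) & pairs$normal %in% sample_ids(x), ]
  if (!nrow(pairs)) stop("no resolvable tumor/normal pairs", call. = FALSE)
  d <- x$values[, pairs$tumor, drop = FALSE] - x$values[, pairs$normal, drop = FALSE]
  stat <- switch(method,
                 mean = abs(rowMeans(d)),
                 max = apply(abs(d), 1L, max))
  keep <- stat >= log2(min_fold)
  rep <- filter_report(probe_ids(x), NA, keep,
                       list(min_fold = min_fold, method = method))
  list(matrix = expression_matrix(x$values[keep, , drop = FALSE],
                                  scale = "log2", assay = x$assay),
       report = rep)
}
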