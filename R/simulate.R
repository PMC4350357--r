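#' Simulation configuration for a synthetic paired ACC cohort
#'
#' Defines the statistical structure of a generated cohort: matched
#' tumor/normal pairs with log-normal intensities, planted differential
#' genes on the linear scale (MYB fixed at 18-fold by default, with c-KIT,
#' FGFR1, RUNX1, NOTCH1 and a 16-gene extracellular-matrix block among the
#' up-regulated genes), one optional MYB-low tumor that retains the rest of
#' the signature, per-tumor MYB exon profiles with a 3' intensity drop at a
#' planted breakpoint for fusion-positive tumors, and a miRNA matrix with
#' planted down-regulated regulators (hsa-miR-150; hsa-miR-29 paired with
#' the up-regulated target HAPLN1).
#'
#' @param n_pairs tumor/normal patient pairs (default 12).
#' @param n_genes total mRNA probe sets (default 5000).
#' @param n_signature_up,n_signature_down planted up/down genes (defaults
#'   100 and 60). `n_signature_up` must be 0 or >= 21 (the named genes plus
#'   the ECM block).
#' @param fc_range linear fold-change range for generic planted genes
#'   (default c(2, 30), drawn uniformly).
#' @param myb_fc planted MYB fold change (default 18).
#' @param noise_sd per-sample log2 noise SD (default 0.4).
#' @param baseline_log2_mean,baseline_log2_sd per-gene baseline distribution
#'   (defaults 7 and 1.5).
#' @param patient_sd SD of the per-patient log2 shift added to both members
#'   of a pair (default 0.2); this is what makes the design paired.
#' @param planted_baseline_min lower clamp on planted genes' baselines
#'   (log2; default 6.7, just above the mRNA intensity filter) so that
#'   planted signal is expressed, not filter fodder.
#' @param n_fusion_pos tumors carrying a 3' breakpoint (default 6).
#' @param myb_low_index index (1..n_pairs) of the tumor whose MYB level
#'   stays at normal baseline; NA for none. Default: the last pair.
#' @param n_myb_dependent,n_myb_associated planted up-genes whose effect is
#'   absent in the MYB-low tumor and that are in / not in the ChIP target
#'   set (defaults 0: by default the MYB-low tumor retains every non-MYB
#'   effect).
#' @param exon_count exons in the focal-gene model (default 15).
#' @param breakpoint_range allowed planted breakpoints, last retained 5'
#'   exon (default c(8, 14); must lie in \[2, exon_count - 1\]).
#' @param exon_delta5,exon_delta3 log2 elevation of retained 5' / lost 3'
#'   exons in fusion-positive tumors (defaults 2 and 0).
#' @param exon_noise_sd exon-level log2 noise SD (default 0.3).
#' @param exon_baseline_log2 mean exon baseline (default 7).
#' @param n_mirna miRNA probes (default 847, one per mature species).
#' @param n_mirna_down planted down-regulated miRNAs (default 22; 0 or >= 2 —
#'   hsa-miR-150 and hsa-miR-29 are always among them when > 0).
#' @param mirna_fc_range fold-change range for generic planted miRNAs
#'   (default c(2, 6)).
#' @param mir29_fc planted hsa-miR-29 down-regulation (default 2.5).
#' @param mirna_baseline_log2_mean,mirna_baseline_log2_sd miRNA baseline
#'   distribution (defaults 11 and 1).
#' @param chip_fraction target fraction of planted signature genes included
#'   in the ChIP-Seq target truth set (default 0.5).
#' @param chip_null_fraction fraction of null genes included in the ChIP set
#'   (default 0.1).
#' @param seed random seed.
#' @return A validated `SimConfig` list.
#' @export
sim_config <- function(n_pairs = 12, n_genes = 5000,
                       n_signature_up = 100, n_signature_down = 60,
                       fc_range = c(2, 30), myb_fc = 18,
                       noise_sd = 0.4,
                       baseline_log2_mean = 7, baseline_log2_sd = 1.5,
                       patient_sd = 0.2, planted_baseline_min = 6.7,
                       n_fusion_pos = 6, myb_low_index = n_pairs,
                       n_myb_dependent = 0, n_myb_associated = 0,
                       exon_count = 15, breakpoint_range = c(8, 14),
                       exon_delta5 = 2, exon_delta3 = 0,
                       exon_noise_sd = 0.3, exon_baseline_log2 = 7,
                       n_mirna = 847, n_mirna_down = 22,
                       mirna_fc_range = c(2, 6), mir29_fc = 2.5,
                       mirna_baseline_log2_mean = 11,
                       mirna_baseline_log2_sd = 1,
                       chip_fraction = 0.5, chip_null_fraction = 0.1,
                       seed = 1) {
  if (is.null(myb_low_index)) myb_low_index <- NA_integer_
  cfg <- as.list(environment())
  fail <- function(...) stop("invalid SimConfig: ", ..., call. = FALSE)
  if (n_pairs < 2) fail("need at least 2 pairs")
  if (n_signature_up + n_signature_down >= n_genes)
    fail("planted genes must number fewer than n_genes")
  if (n_signature_up != 0 && n_signature_up < length(planted_gene_ids()$up_named))
    fail("n_signature_up must be 0 or >= ", length(planted_gene_ids()$up_named))
  if (noise_sd < 0 || patient_sd < 0 || exon_noise_sd < 0)
    fail("noise SDs must be non-negative")
  if (!is.na(myb_low_index) &&
      (myb_low_index < 1 || myb_low_index > n_pairs))
    fail("myb_low_index out of range")
  if (!is.na(myb_low_index) && n_signature_up > 0 && n_fusion_pos > n_pairs - 1)
    fail("n_fusion_pos must leave the MYB-low tumor fusion-negative")
  if (n_fusion_pos > n_pairs) fail("n_fusion_pos exceeds n_pairs")
  if (exon_count < 5) fail("exon_count must be >= 5")
  if (breakpoint_range[1] < 2 || breakpoint_range[2] > exon_count - 1 ||
      breakpoint_range[1] > breakpoint_range[2])
    fail("breakpoint_range must lie within [2, exon_count - 1]")
  if (n_myb_dependent + n_myb_associated >
      max(0, n_signature_up - length(planted_gene_ids()$up_named)))
    fail("not enough generic up-genes for the requested dependence labels")
  if (n_mirna_down != 0 && n_mirna_down < 2)
    fail("n_mirna_down must be 0 or >= 2")
  if (n_mirna_down >= n_mirna) fail("n_mirna_down must be < n_mirna")
  structure(cfg, class = "SimConfig")
}

# Named planted genes and their fixed linear fold changes. The ECM block
# (VCAN/HAPLN1 plus 14 generic ECM genes) is planted up in every tumor.
planted_gene_ids <- function() {
  ecm <- c("VCAN", "HAPLN1", sprintf("ECM%02d", 3:16))
  list(ecm = ecm,
       up_named = c("MYB", "KIT", "FGFR1", "RUNX1", "NOTCH1", ecm),
       fixed_fc = c(MYB = NA, KIT = 5, FGFR1 = 4, RUNX1 = 3, NOTCH1 = 2.8,
                    VCAN = 29, HAPLN1 = 25))
}

#' Generate a synthetic paired tumor/normal cohort
#'
#' Draws, deterministically from `config$seed`: a linear-scale mRNA matrix
#' (`normal = 2^(b_g + a_p + eps)`, `tumor = 2^(b_g + a_p + s_g log2(fc_g) +
#' eps)` for planted genes, with per-gene baseline `b_g`, per-patient shift
#' `a_p` common to both pair members, and i.i.d. log2 noise `eps`); a miRNA
#' matrix with planted down-regulation; a per-tumor MYB exon profile with a
#' 3' drop at the planted breakpoint in fusion-positive tumors; the sample
#' sheet; and ground-truth tables for every planted entity. The MYB-low
#' tumor has MYB fold change 1; with the default config every other planted
#' effect is intact there (genes planted via `n_myb_dependent` /
#' `n_myb_associated` lose their effect in that tumor).
#'
#' @param config a [sim_config()].
#' @return An `AccCohort` list: `mrna`, `mirna` ([expression_matrix()]s),
#'   `exon` ([exon_profile()]), `sheet` (`SampleSheet`), `truth` (list of
#'   truth tables: `genes`, `fusion`, `myb_low_sample`, `mirna`,
#'   `mirna_links`, `chip_targets`, `annotation`, `target_map`,
#'   `mutations`), and `config`.
#' @export
generate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "SimConfig"))
  cf <- config
  set.seed(cf$seed)
  ids <- planted_gene_ids()

  patients <- sprintf("ACC%02d", seq_len(cf$n_pairs))
  tumors <- paste0(patients, "_T")
  normals <- paste0(patients, "_N")
  myb_low_tumor <- if (!is.na(cf$myb_low_index) && cf$n_signature_up > 0)
    tumors[cf$myb_low_index] else NA_character_

  ## ---- gene bookkeeping -------------------------------------------------
  n_generic_up <- max(0, cf$n_signature_up - length(ids$up_named))
  up_ids <- if (cf$n_signature_up > 0)
    c(ids$up_named, sprintf("UP%04d", seq_len(n_generic_up))) else character()
  down_ids <- if (cf$n_signature_down > 0)
    sprintf("DN%04d", seq_len(cf$n_signature_down)) else character()
  n_null <- cf$n_genes - length(up_ids) - length(down_ids)
  null_ids <- sprintf("G%05d", seq_len(n_null))
  genes <- c(up_ids, down_ids, null_ids)

  fc <- stats::setNames(rep(1, cf$n_genes), genes)
  if (length(up_ids)) {
    fc["MYB"] <- cf$myb_fc
    # named genes keep their canonical fold changes, clamped into fc_range
    fixed <- ids$fixed_fc[!is.na(ids$fixed_fc)]
    fc[names(fixed)] <- pmin(pmax(fixed, cf$fc_range[1]), cf$fc_range[2])
    free_ecm <- setdiff(ids$ecm, names(fixed))
    fc[free_ecm] <- stats::runif(length(free_ecm), cf$fc_range[1], cf$fc_range[2])
    gen_up <- setdiff(up_ids, ids$up_named)
    fc[gen_up] <- stats::runif(length(gen_up), cf$fc_range[1], cf$fc_range[2])
  }
  if (length(down_ids))
    fc[down_ids] <- stats::runif(length(down_ids), cf$fc_range[1], cf$fc_range[2])
  sign_g <- stats::setNames(rep(0, cf$n_genes), genes)
  sign_g[up_ids] <- 1
  sign_g[down_ids] <- -1

  gen_up <- setdiff(up_ids, ids$up_named)
  dep_genes <- if (cf$n_myb_dependent > 0) gen_up[seq_len(cf$n_myb_dependent)] else character()
  assoc_genes <- if (cf$n_myb_associated > 0)
    gen_up[cf$n_myb_dependent + seq_len(cf$n_myb_associated)] else character()
  # effect absent in the MYB-low tumor: MYB itself + planted dependent/associated
  low_off <- c(if (length(up_ids)) "MYB", dep_genes, assoc_genes)

  dependence <- stats::setNames(rep(NA_character_, cf$n_genes), genes)
  dependence[up_ids] <- "MYB-independent"
  dependence[dep_genes] <- "MYB-dependent-candidate"
  dependence[assoc_genes] <- "MYB-associated-unclassified"
  if (length(up_ids)) dependence["MYB"] <- "MYB-dependent-candidate"
  dependence[down_ids] <- NA_character_

  ## ---- ChIP-Seq target truth set ---------------------------------------
  planted <- c(up_ids, down_ids)
  chip <- character()
  if (length(planted)) {
    core <- c(if (length(up_ids)) "MYB", dep_genes)
    pool <- setdiff(planted, c(core, assoc_genes))
    want <- max(0, round(cf$chip_fraction * length(planted)) - length(core))
    chip <- c(core, sample(pool, min(want, length(pool))))
  }
  chip <- c(chip, sample(null_ids, round(cf$chip_null_fraction * n_null)))

  ## ---- annotation sets (ECM + diluted decoy localizations) -------------
  annotation <- NULL
  if (length(up_ids)) {
    pick <- function(v, n) if (n <= 0 || !length(v)) character() else
      sample(v, min(n, length(v)))
    other_up <- setdiff(up_ids, ids$ecm)
    annotation <- list(
      ECM = ids$ecm,
      membrane = c(pick(other_up, 20), pick(null_ids, round(0.06 * n_null))),
      cytoplasm = c(pick(other_up, 10), pick(down_ids, 10),
                    pick(null_ids, round(0.12 * n_null))),
      nucleus = c(pick(other_up, 5), pick(null_ids, round(0.15 * n_null))))
    annotation <- lapply(annotation, unique)
    class(annotation) <- "GeneSetCollection"
  }

  ## ---- mRNA matrix ------------------------------------------------------
  b <- stats::rnorm(cf$n_genes, cf$baseline_log2_mean, cf$baseline_log2_sd)
  names(b) <- genes
  b[planted] <- pmax(b[planted], cf$planted_baseline_min)
  a <- stats::rnorm(cf$n_pairs, 0, cf$patient_sd)
  eff <- outer(sign_g * log2(fc), rep(1, cf$n_pairs))
  if (length(low_off) && !is.na(cf$myb_low_index))
    eff[low_off, cf$myb_low_index] <- 0
  epsN <- matrix(stats::rnorm(cf$n_genes * cf$n_pairs, 0, cf$noise_sd),
                 cf$n_genes)
  epsT <- matrix(stats::rnorm(cf$n_genes * cf$n_pairs, 0, cf$noise_sd),
                 cf$n_genes)
  normal_v <- 2^(b + rep(a, each = cf$n_genes) + epsN)
  tumor_v <- 2^(b + rep(a, each = cf$n_genes) + eff + epsT)
  vals <- matrix(0, cf$n_genes, 2 * cf$n_pairs)
  vals[, seq(1, 2 * cf$n_pairs, 2)] <- tumor_v
  vals[, seq(2, 2 * cf$n_pairs, 2)] <- normal_v
  cols <- character(2 * cf$n_pairs)
  cols[seq(1, 2 * cf$n_pairs, 2)] <- tumors
  cols[seq(2, 2 * cf$n_pairs, 2)] <- normals
  dimnames(vals) <- list(genes, cols)
  mrna <- expression_matrix(vals, scale = "linear", assay = "mRNA")

  ## ---- miRNA matrix ------------------------------------------------------
  mir_down <- character()
  mir_fc <- numeric()
  if (cf$n_mirna_down > 0) {
    mir_down <- c("hsa-miR-150", "hsa-miR-29",
                  if (cf$n_mirna_down > 2)
                    sprintf("hsa-miR-d%03d", seq_len(cf$n_mirna_down - 2)))
    mir_fc <- stats::setNames(
      c(3, cf$mir29_fc,
        if (cf$n_mirna_down > 2)
          stats::runif(cf$n_mirna_down - 2, cf$mirna_fc_range[1],
                       cf$mirna_fc_range[2])),
      mir_down)
  }
  mir_null <- sprintf("hsa-miR-n%03d", seq_len(cf$n_mirna - length(mir_down)))
  mirs <- c(mir_down, mir_null)
  mfc <- stats::setNames(rep(1, cf$n_mirna), mirs)
  mfc[mir_down] <- mir_fc[mir_down]
  msign <- stats::setNames(rep(0, cf$n_mirna), mirs)
  msign[mir_down] <- -1
  mb <- stats::rnorm(cf$n_mirna, cf$mirna_baseline_log2_mean,
                     cf$mirna_baseline_log2_sd)
  names(mb) <- mirs
  mb[mir_down] <- pmax(mb[mir_down], log2(800) + 0.7)
  ma <- stats::rnorm(cf$n_pairs, 0, cf$patient_sd)
  meff <- outer(msign * log2(mfc), rep(1, cf$n_pairs))
  mepsN <- matrix(stats::rnorm(cf$n_mirna * cf$n_pairs, 0, cf$noise_sd), cf$n_mirna)
  mepsT <- matrix(stats::rnorm(cf$n_mirna * cf$n_pairs, 0, cf$noise_sd), cf$n_mirna)
  mN <- 2^(mb + rep(ma, each = cf$n_mirna) + mepsN)
  mT <- 2^(mb + rep(ma, each = cf$n_mirna) + meff + mepsT)
  mvals <- matrix(0, cf$n_mirna, 2 * cf$n_pairs)
  mvals[, seq(1, 2 * cf$n_pairs, 2)] <- mT
  mvals[, seq(2, 2 * cf$n_pairs, 2)] <- mN
  dimnames(mvals) <- list(mirs, cols)
  mirna <- expression_matrix(mvals, scale = "linear", assay = "miRNA")

  ## ---- fusion truth and exon profile ------------------------------------
  eligible <- seq_len(cf$n_pairs)
  if (!is.na(cf$myb_low_index) && cf$n_signature_up > 0)
    eligible <- setdiff(eligible, cf$myb_low_index)
  pos_idx <- if (cf$n_fusion_pos > 0)
    sort(sample(eligible, cf$n_fusion_pos)) else integer()
  bp <- rep(NA_integer_, cf$n_pairs)
  if (length(pos_idx))
    bp[pos_idx] <- sample(seq(cf$breakpoint_range[1], cf$breakpoint_range[2]),
                          length(pos_idx), replace = TRUE)
  status <- ifelse(seq_len(cf$n_pairs) %in% pos_idx, "positive", "negative")

  E <- cf$exon_count
  be <- stats::rnorm(E, cf$exon_baseline_log2, 0.5)
  # flat MYB elevation for fusion-negative tumors; none for the MYB-low tumor
  flat_delta <- if (cf$n_signature_up > 0) log2(cf$myb_fc) else 0
  exon_vals <- matrix(0, E, 2 * cf$n_pairs, dimnames = list(
    sprintf("exon_%02d", seq_len(E)), cols))
  for (i in seq_len(cf$n_pairs)) {
    nv <- 2^(be + stats::rnorm(E, 0, cf$exon_noise_sd))
    delta <- if (status[i] == "positive") {
      c(rep(cf$exon_delta5, bp[i]), rep(cf$exon_delta3, E - bp[i]))
    } else if (identical(tumors[i], myb_low_tumor)) {
      rep(0, E)
    } else {
      rep(flat_delta, E)
    }
    tv <- nv * 2^(delta + stats::rnorm(E, 0, cf$exon_noise_sd))
    exon_vals[, normals[i]] <- nv
    exon_vals[, tumors[i]] <- tv
  }
  exon <- exon_profile("MYB", exon_vals)

  ## ---- sample sheet ------------------------------------------------------
  sheet <- sample_sheet(data.frame(
    sample_id = cols,
    patient_id = rep(patients, each = 2),
    tissue = rep(c("tumor", "normal"), cf$n_pairs),
    subtype = "ACC",
    fusion_annotation = as.vector(rbind(status, "unknown")),
    stringsAsFactors = FALSE))

  ## ---- miRNA target map (planted inverse pairs + decoys) -----------------
  links <- NULL
  target_map <- NULL
  if (cf$n_mirna_down > 0 && length(up_ids)) {
    links <- data.frame(mirna_id = c("hsa-miR-29", "hsa-miR-150"),
                        target_gene = c("HAPLN1", "MYB"),
                        stringsAsFactors = FALSE)
    decoys <- data.frame(
      mirna_id = c("hsa-miR-29", mir_null[1], mir_null[2]),
      target_gene = c(if (length(down_ids)) down_ids[1] else null_ids[1],
                      "VCAN", null_ids[1]),
      stringsAsFactors = FALSE)
    target_map <- rbind(links, decoys)
    target_map <- target_map[!duplicated(target_map), ]
  }

  ## ---- mutation truth table ----------------------------------------------
  mutations <- NULL
  if (length(up_ids)) {
    mut_genes <- c("RUNX1", "NOTCH1", "TP53",
                   if (length(down_ids)) down_ids[1])
    mutations <- data.frame(
      gene = mut_genes,
      sample_id = tumors[(seq_along(mut_genes) - 1) %% cf$n_pairs + 1],
      mutation_class = c("missense", "truncating", "missense",
                         if (length(down_ids)) "missense"),
      stringsAsFactors = FALSE)
  }

  truth <- list(
    genes = data.frame(gene = genes,
                       direction = ifelse(sign_g > 0, "up",
                                          ifelse(sign_g < 0, "down", "null")),
                       fc = as.numeric(fc),
                       planted = sign_g != 0,
                       is_ecm = genes %in% ids$ecm & length(up_ids) > 0,
                       in_chip = genes %in% chip,
                       dependence = as.character(dependence),
                       stringsAsFactors = FALSE),
    fusion = data.frame(sample_id = tumors, patient_id = patients,
                        status = status, breakpoint = bp,
                        stringsAsFactors = FALSE),
    myb_low_sample = myb_low_tumor,
    mirna = data.frame(mirna_id = mirs,
                       direction = ifelse(msign < 0, "down", "null"),
                       fc = as.numeric(mfc), planted = msign != 0,
                       stringsAsFactors = FALSE),
    mirna_links = links,
    chip_targets = sort(chip),
    annotation = annotation,
    target_map = target_map,
    mutations = mutations)

  structure(list(mrna = mrna, mirna = mirna, exon = exon, sheet = sheet,
                 truth = truth, config = cf),
            class = "AccCohort")
}

#' Generate a null cohort (no planted effects)
#'
#' Tumors and normals are exchangeable for every gene: no differential genes,
#' no fusions, no MYB-low tumor, no planted miRNAs. Used as the type-I-error
#' harness.
#'
#' @param config a [sim_config()]; its planting fields are zeroed.
#' @return An `AccCohort` (see [generate_cohort()]).
#' @export
generate_null_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "SimConfig"))
  cfg <- unclass(config)
  cfg$n_signature_up <- 0
  cfg$n_signature_down <- 0
  cfg$n_fusion_pos <- 0
  cfg$myb_low_index <- NA
  cfg$n_myb_dependent <- 0
  cfg$n_myb_associated <- 0
  cfg$n_mirna_down <- 0
  generate_cohort(do.call(sim_config, cfg[names(formals(sim_config))]))
}

#' Generate a single tumor/normal exon profile
#'
#' One pair of exon traces for the focal gene: the normal sample is
#' `2^(baseline + eps)`; the tumor is the normal value times
#' `2^(delta + eps)`, where delta is `delta5` for exons up to the breakpoint
#' and `delta3` after it (positives), or the single value `delta5` across
#' all exons (negatives).
#'
#' @param status `"positive"` or `"negative"`.
#' @param breakpoint last retained 5' exon (required for positives; must lie
#'   in \[2, exon_count - 1\]).
#' @param delta5,delta3 log2 elevations (positives need `delta5 > delta3`).
#' @param noise_sd log2 noise SD.
#' @param seed random seed.
#' @param exon_count number of exons (default 15).
#' @param baseline_log2 mean exon baseline (default 7).
#' @param gene gene label (default `"MYB"`).
#' @return An [exon_profile()] with samples `"T"` and `"N"`.
#' @export
generate_exon_profile <- function(status = c("positive", "negative"),
                                  breakpoint = NULL, delta5 = 2, delta3 = 0,
                                  noise_sd = 0.3, seed = 1,
                                  exon_count = 15, baseline_log2 = 7,
                                  gene = "MYB") {
  status <- match.arg(status)
  if (status == "positive") {
    if (is.null(breakpoint))
      stop("positive profiles need a breakpoint", call. = FALSE)
    if (breakpoint < 2 || breakpoint > exon_count - 1)
      stop("breakpoint must lie in [2, exon_count - 1]", call. = FALSE)
    if (delta5 <= delta3)
      stop("positive profiles need delta5 > delta3", call. = FALSE)
  }
  set.seed(seed)
  be <- stats::rnorm(exon_count, baseline_log2, 0.5)
  nv <- 2^(be + stats::rnorm(exon_count, 0, noise_sd))
  delta <- if (status == "positive")
    c(rep(delta5, breakpoint), rep(delta3, exon_count - breakpoint))
  else rep(delta5, exon_count)
  tv <- nv * 2^(delta + stats::rnorm(exon_count, 0, noise_sd))
  vals <- cbind(T = tv, N = nv)
  rownames(vals) <- sprintf("exon_%02d", seq_len(exon_count))
  exon_profile(gene, vals)
}

#' Write a cohort to disk in the pipeline's exchange formats
#'
#' Emits the TSV/GMT files that the readers consume: `mrna.tsv`,
#' `mirna.tsv`, `exon_profile.tsv`, `sample_sheet.tsv`, `annotation.gmt`,
#' `chip_targets.gmt`, `mirna_targets.tsv`, `mutations.tsv`, plus truth
#' tables `truth_genes.tsv`, `truth_fusion.tsv`, `truth_mirna.tsv`.
#'
#' @param cohort an `AccCohort`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "AccCohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(dir, f)
  write_expression_matrix(cohort$mrna, fp("mrna.tsv"))
  write_expression_matrix(cohort$mirna, fp("mirna.tsv"))
  write_exon_profile(cohort$exon, fp("exon_profile.tsv"))
  write_sample_sheet(cohort$sheet, fp("sample_sheet.tsv"))
  wt <- function(df, f) utils::write.table(df, fp(f), sep = "\t",
                                           quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$truth$annotation))
    write_gene_sets(cohort$truth$annotation, fp("annotation.gmt"))
  if (length(cohort$truth$chip_targets))
    write_gene_sets(list(MYB_chip_targets = cohort$truth$chip_targets),
                    fp("chip_targets.gmt"))
  if (!is.null(cohort$truth$target_map))
    wt(cohort$truth$target_map, "mirna_targets.tsv")
  if (!is.null(cohort$truth$mutations))
    wt(cohort$truth$mutations, "mutations.tsv")
  wt(cohort$truth$genes, "truth_genes.tsv")
  wt(cohort$truth$fusion, "truth_fusion.tsv")
  wt(cohort$truth$mirna, "truth_mirna.tsv")
  invisible(dir)
}
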