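#' Merge two cohorts at the VCF (site) level
#'
#' Takes the intersection of sites on the chrom:pos:ref:alt key, realigns
#' the second cohort's dosages to the first cohort's minor allele, and
#' concatenates the genotype matrices without any re-calling or
#' missingness harmonization -- the deliberately naive merge whose
#' artifacts the downstream operations measure.
#'
#' @param a,b `geo_cohort` objects with disjoint sample ids.
#' @return list with `cohort` (the merged `geo_cohort`), `n_shared`,
#'   `n_dropped_a`, `n_dropped_b`.
#' @export
merge_cohorts <- function(a, b) {
  if (length(intersect(a$samples$sample_id, b$samples$sample_id)))
    stop("duplicate sample id(s) across cohorts")
  ka <- variant_key(a$variants)
  kb <- variant_key(b$variants)
  shared <- intersect(ka, kb)
  ia <- match(shared, ka)
  ib <- match(shared, kb)
  ga <- a$genotypes[, ia, drop = FALSE]
  gb <- b$genotypes[, ib, drop = FALSE]
  # realign b to a's minor allele where the two cohorts disagree
  flip <- a$variants$minor_allele[ia] != b$variants$minor_allele[ib]
  if (any(flip)) gb[, flip] <- 2L - gb[, flip, drop = FALSE]
  merged <- geo_cohort(rbind(ga, gb),
                       rbind(a$samples, b$samples),
                       a$variants[ia, , drop = FALSE],
                       validate = FALSE)
  list(cohort = merged, n_shared = length(shared),
       n_dropped_a = length(ka) - length(shared),
       n_dropped_b = length(kb) - length(shared))
}

#' Remove sites highly differentiated between the two merged cohorts
#'
#' Per-cohort frequencies of the first cohort's minor allele are computed
#' from non-missing genotypes; sites with an absolute difference above
#' `max_freq_diff` are removed. Sites where one cohort has no non-missing
#' call are skipped and flagged (kept, but reported).
#'
#' @param merged a merged `geo_cohort` carrying two cohort labels.
#' @param max_freq_diff removal threshold (default 0.05).
#' @return list with `cohort` (filtered), `removed` (variant ids),
#'   `skipped` (variant ids with a zero-call cohort), `freq_diff`.
#' @export
freq_diff_filter <- function(merged, max_freq_diff = 0.05) {
  labs <- unique(merged$samples$cohort)
  if (length(labs) < 2) stop("merged cohort must carry >= 2 cohort labels")
  in_a <- merged$samples$cohort == labs[1]
  pa <- dosage_freq(merged$genotypes[in_a, , drop = FALSE])
  pb <- dosage_freq(merged$genotypes[!in_a, , drop = FALSE])
  skipped <- which(is.nan(pa) | is.nan(pb))
  diff <- abs(pa - pb)
  remove <- which(!is.nan(diff) & diff > max_freq_diff)
  keep <- setdiff(seq_len(ncol(merged$genotypes)), remove)
  list(cohort = subset_variants(merged, keep),
       removed = merged$variants$variant_id[remove],
       skipped = merged$variants$variant_id[skipped],
       freq_diff = diff)
}

#' Batch separation of a merged cohort on PC1
#'
#' GRM + PCA on the merged genotypes; the metric is the absolute
#' point-biserial correlation between PC1 scores and cohort membership,
#' near 1 when the leading axis of variation is the sequencing batch.
#'
#' @param merged a merged `geo_cohort`.
#' @param pc_count number of PCs to compute (PC1 is used for the metric).
#' @param maf_min GRM MAF floor; kept low so rare, batch-sensitive sites
#'   contribute.
#' @return list with `separation` (the |r|), `pca`, `grm`.
#' @export
assess_separation <- function(merged, pc_count = 10, maf_min = 0.001) {
  labs <- unique(merged$samples$cohort)
  if (length(labs) < 2 || min(table(merged$samples$cohort)) < 2)
    stop("need at least two samples per cohort")
  grm <- compute_grm(merged, maf_min = maf_min)
  pc <- pca(grm, k = pc_count)
  ind <- as.numeric(merged$samples$cohort == labs[1])
  r <- suppressWarnings(stats::cor(pc$vectors[, 1], ind))
  if (is.na(r)) stop("degenerate PC1: separation undefined")
  list(separation = abs(r), pca = pc, grm = grm)
}

#' Case versus external-control association scan
#'
#' Restricts the merged cohort to the first cohort's cases and the second
#' cohort's (external) samples, fits an intercept-only null model on the
#' case/external contrast, and reports the genomic inflation factor for
#' the single-variant scan and for a T1 burden scan -- the readout of how
#' much batch structure masquerades as association signal.
#'
#' @param merged a merged `geo_cohort` (optionally frequency-filtered).
#' @param case_cohort label of the internally sequenced cohort (its cases
#'   are used); defaults to the first label.
#' @param maf_min single-variant MAF floor.
#' @param burden_test which burden test's p-values feed the burden lambda.
#' @return list with `lambda_single`, `lambda_burden`, `scan`, `burden`.
#' @export
external_control_scan <- function(merged, case_cohort = NULL,
                                  maf_min = 0.005, burden_test = "T1") {
  labs <- unique(merged$samples$cohort)
  if (is.null(case_cohort)) case_cohort <- labs[1]
  keep <- (merged$samples$cohort == case_cohort &
           merged$samples$status == 1) |
          merged$samples$cohort != case_cohort
  sub <- subset_samples(merged, keep)
  y <- as.integer(sub$samples$cohort == case_cohort)
  nm <- fit_null_logistic(y)
  scan <- gw_scan(sub, nm, maf_min = maf_min)
  # burden groups built on the case/external subset with its own MAFs
  sub$samples$status <- 1L - y              # externals act as controls
  groups <- build_groups(sub)
  burden <- if (length(groups))
    run_burden_scan(sub, nm, groups, tests = burden_test) else NULL
  lambda_burden <- if (!is.null(burden) && any(!is.na(burden$p_value)))
    genomic_lambda(burden$p_value) else NA_real_
  list(lambda_single = genomic_lambda(scan$p_value),
       lambda_burden = lambda_burden,
       scan = scan, burden = burden)
}
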