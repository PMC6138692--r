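#' QC configuration
#'
#' Thresholds follow common WGS case-control practice: 95 percent call rate
#' at both sample and variant level, heterozygosity outliers beyond 3 SD,
#' Hardy-Weinberg tested in controls only at p < 1e-6, and relatedness
#' pruning of pairs whose estimated kinship (GRM off-diagonal / 2) exceeds
#' the 3rd-degree cutoff 0.0884.
#'
#' @param sample_call_rate_min,variant_call_rate_min minimum call rates.
#' @param het_outlier_sd heterozygosity outlier cut in SD units.
#' @param hwe_p_min HWE exact-test threshold (controls only).
#' @param kinship_max maximum tolerated kinship coefficient (0.0884 is the
#'   conventional 3rd-degree cutoff); GRM off-diagonals are approximately
#'   twice the kinship, so a pair is pruned when `GRM/2 > kinship_max`.
#' @param grm_maf_min MAF floor for the relatedness GRM (common variants
#'   only: rare alleles have heavy-tailed standardized contributions).
#' @return an object of class `qc_config`.
#' @export
qc_config <- function(sample_call_rate_min = 0.95,
                      variant_call_rate_min = 0.95,
                      het_outlier_sd = 3,
                      hwe_p_min = 1e-6,
                      kinship_max = 0.0884,
                      grm_maf_min = 0.05) {
  stopifnot(sample_call_rate_min >= 0, sample_call_rate_min <= 1,
            variant_call_rate_min >= 0, variant_call_rate_min <= 1,
            het_outlier_sd > 0, hwe_p_min > 0, hwe_p_min < 1,
            kinship_max > 0)
  structure(list(sample_call_rate_min = sample_call_rate_min,
                 variant_call_rate_min = variant_call_rate_min,
                 het_outlier_sd = het_outlier_sd,
                 hwe_p_min = hwe_p_min,
                 kinship_max = kinship_max,
                 grm_maf_min = grm_maf_min),
            class = "qc_config")
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test by full enumeration of heterozygote counts
#' conditional on the allele counts: the p-value is the sum of the
#' probabilities of all configurations no more probable than the observed
#' one (no mid-p correction).
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts.
#' @return the exact p-value.
#' @export
#' @examples
#' hwe_exact_test(1, 2, 1)
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  cnt <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(cnt < 0)) stop("genotype counts must be >= 0")
  if (all(cnt == 0)) stop("at least one genotype count must be positive")
  n <- sum(cnt)
  nA <- 2 * n_hom_ref + n_het          # ref allele count
  na <- 2 * n_hom_alt + n_het
  r <- min(nA, na)                     # minor allele count
  if (r == 0) return(1)                # monomorphic
  hets <- seq(r %% 2, r, by = 2)       # feasible het counts (parity of r)
  # log P(h | n, r) = log choose terms; constant terms cancel in the ratio
  logp <- lchoose(n, (r - hets) / 2) +
    lchoose(n - (r - hets) / 2, hets) +
    lchoose(n - (r - hets) / 2 - hets, (2 * n - r - hets) / 2) +
    hets * log(2) - (lchoose(2 * n, r))
  # normalize in log space for numerical safety
  logp <- logp - max(logp)
  p <- exp(logp); p <- p / sum(p)
  obs <- p[match(n_het, hets)]
  if (is.na(obs)) stop("observed het count inconsistent with allele counts")
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

#' Sample-level quality control
#'
#' Applies, in order: call-rate filter, heterozygosity-rate outlier filter
#' (mean +- `het_outlier_sd` SD), and relatedness pruning (for each pair
#' with estimated kinship (GRM off-diagonal / 2) above `kinship_max`, the
#' member with the lower call rate is dropped; ties drop the later sample
#' id).
#'
#' @param cohort a `geo_cohort`.
#' @param config a `qc_config`.
#' @return list with `cohort` (filtered) and `report` (a `qc_report`).
#' @export
run_sample_qc <- function(cohort, config = qc_config()) {
  g <- cohort$genotypes
  ids <- cohort$samples$sample_id
  steps <- data.frame(filter = character(0), n_removed = integer(0),
                      n_surviving = integer(0))
  removed <- data.frame(sample_id = character(0), reason = character(0))
  # 1. call rate
  cr <- rowMeans(!is.na(g))
  drop1 <- which(cr < config$sample_call_rate_min)
  removed <- rbind(removed, data.frame(sample_id = ids[drop1],
                                       reason = rep("call_rate", length(drop1))))
  keep <- setdiff(seq_len(nrow(g)), drop1)
  steps <- rbind(steps, data.frame(filter = "call_rate",
                                   n_removed = length(drop1),
                                   n_surviving = length(keep)))
  # 2. heterozygosity outliers
  het <- rowMeans(g[keep, , drop = FALSE] == 1L, na.rm = TRUE)
  mu <- mean(het); sdv <- stats::sd(het)
  out <- if (is.finite(sdv) && sdv > 0)
    which(abs(het - mu) > config$het_outlier_sd * sdv) else integer(0)
  removed <- rbind(removed, data.frame(sample_id = ids[keep][out],
                                       reason = rep("het_outlier", length(out))))
  keep <- if (length(out)) keep[-out] else keep
  steps <- rbind(steps, data.frame(filter = "het_outlier",
                                   n_removed = length(out),
                                   n_surviving = length(keep)))
  # 3. relatedness pruning on a common-variant GRM
  sub <- subset_samples(cohort, keep)
  n_rel <- 0L
  if (length(keep) >= 2 && any(cohort_maf(sub) >= config$grm_maf_min)) {
    A <- compute_grm(sub, maf_min = config$grm_maf_min)$grm
    cr_k <- rowMeans(!is.na(sub$genotypes))
    repeat {
      diag(A) <- 0
      w <- which(A / 2 > config$kinship_max, arr.ind = TRUE)
      if (!nrow(w)) break
      i <- w[1, 1]; j <- w[1, 2]
      drop <- if (cr_k[i] < cr_k[j]) i
              else if (cr_k[j] < cr_k[i]) j
              else max(i, j)                   # tie: later sample id
      removed <- rbind(removed,
                       data.frame(sample_id = sub$samples$sample_id[drop],
                                  reason = "relatedness"))
      A <- A[-drop, -drop, drop = FALSE]
      cr_k <- cr_k[-drop]
      keep_ids <- setdiff(sub$samples$sample_id, removed$sample_id)
      sub <- subset_samples(cohort,
                            match(keep_ids, cohort$samples$sample_id))
      n_rel <- n_rel + 1L
    }
    keep <- match(sub$samples$sample_id, cohort$samples$sample_id)
  }
  steps <- rbind(steps, data.frame(filter = "relatedness",
                                   n_removed = n_rel,
                                   n_surviving = length(keep)))
  if (!length(keep)) stop("sample QC removed every sample")
  list(cohort = subset_samples(cohort, keep),
       report = structure(list(level = "sample", steps = steps,
                               removed = removed), class = "qc_report"))
}

#' Variant-level quality control
#'
#' Removes variants failing, in order: call rate, Hardy-Weinberg exact test
#' in controls (p < `hwe_p_min`), and monomorphism in the full cohort.
#'
#' @param cohort a `geo_cohort`.
#' @param config a `qc_config`.
#' @return list with `cohort` (filtered) and `report` (a `qc_report`).
#' @export
run_variant_qc <- function(cohort, config = qc_config()) {
  g <- cohort$genotypes
  vid <- cohort$variants$variant_id
  steps <- data.frame(filter = character(0), n_removed = integer(0),
                      n_surviving = integer(0))
  removed <- data.frame(variant_id = character(0), reason = character(0))
  keep <- seq_len(ncol(g))
  # 1. call rate
  cr <- colMeans(!is.na(g))
  bad <- keep[cr[keep] < config$variant_call_rate_min]
  removed <- rbind(removed, data.frame(variant_id = vid[bad],
                                       reason = rep("call_rate", length(bad))))
  keep <- setdiff(keep, bad)
  steps <- rbind(steps, data.frame(filter = "call_rate",
                                   n_removed = length(bad),
                                   n_surviving = length(keep)))
  # 2. HWE in controls
  ctrl <- cohort$samples$status == 0
  bad <- integer(0)
  if (any(ctrl)) {
    gc <- g[ctrl, keep, drop = FALSE]
    n0 <- colSums(gc == 0L, na.rm = TRUE)
    n1 <- colSums(gc == 1L, na.rm = TRUE)
    n2 <- colSums(gc == 2L, na.rm = TRUE)
    # only polymorphic-in-controls sites can fail
    cand <- which(n1 + n2 > 0 & n0 + n1 > 0 & (n0 + n1 + n2) > 0)
    pv <- vapply(cand, function(k) hwe_exact_test(n0[k], n1[k], n2[k]),
                 numeric(1))
    bad <- keep[cand[pv < config$hwe_p_min]]
  }
  removed <- rbind(removed, data.frame(variant_id = vid[bad],
                                       reason = rep("hwe", length(bad))))
  keep <- setdiff(keep, bad)
  steps <- rbind(steps, data.frame(filter = "hwe",
                                   n_removed = length(bad),
                                   n_surviving = length(keep)))
  # 3. monomorphic in the full cohort
  maf <- cohort_maf(cohort)
  bad <- keep[is.nan(maf[keep]) | maf[keep] == 0]
  removed <- rbind(removed, data.frame(variant_id = vid[bad],
                                       reason = rep("monomorphic", length(bad))))
  keep <- setdiff(keep, bad)
  steps <- rbind(steps, data.frame(filter = "monomorphic",
                                   n_removed = length(bad),
                                   n_surviving = length(keep)))
  list(cohort = subset_variants(cohort, keep),
       report = structure(list(level = "variant", steps = steps,
                               removed = removed), class = "qc_report"))
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report (", x$level, " level)\n", sep = "")
  print(x$steps, row.names = FALSE)
  invisible(x)
}
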