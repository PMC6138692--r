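#' Cohort container
#'
#' A `geo_cohort` bundles a genotype dosage matrix with per-sample and
#' per-variant metadata, the in-memory analogue of a VCF plus its sample
#' sheet and gene-group file.  Genotypes are coded as minor-allele dosage
#' (0/1/2, `NA` = missing); the `minor_allele` column of the variant table
#' records whether the minor allele is REF or ALT so cohorts can be merged
#' without losing allele orientation.
#'
#' @param genotypes integer matrix, samples in rows, variants in columns;
#'   dimnames are sample ids and variant ids.
#' @param samples data.frame with columns `sample_id`, `sex` ("M"/"F"),
#'   `status` (0 control / 1 case), `lat`, `lon`, `cohort`.
#' @param variants data.frame with columns `variant_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `minor_allele` ("ref"/"alt"), `gene_id` (NA if not in a
#'   gene), `functional_class` ("LOF", "nonsynonymous", "other").
#' @param validate run the invariant checks (default `TRUE`).
#' @return an object of class `geo_cohort`.
#' @export
geo_cohort <- function(genotypes, samples, variants, validate = TRUE) {
  storage.mode(genotypes) <- "integer"
  obj <- structure(list(genotypes = genotypes,
                        samples   = as.data.frame(samples),
                        variants  = as.data.frame(variants)),
                   class = "geo_cohort")
  if (validate) validate_cohort(obj)
  obj
}

#' Check the invariants of a cohort object
#'
#' @param cohort a `geo_cohort`.
#' @return the cohort, invisibly; stops on violation.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "geo_cohort"))
  g <- cohort$genotypes
  s <- cohort$samples
  v <- cohort$variants
  req_s <- c("sample_id", "sex", "status", "lat", "lon", "cohort")
  req_v <- c("variant_id", "chrom", "pos", "ref", "alt", "minor_allele",
             "gene_id", "functional_class")
  missing_s <- setdiff(req_s, names(s))
  if (length(missing_s))
    stop("sample table is missing columns: ", paste(missing_s, collapse = ", "))
  missing_v <- setdiff(req_v, names(v))
  if (length(missing_v))
    stop("variant table is missing columns: ", paste(missing_v, collapse = ", "))
  if (nrow(g) != nrow(s))
    stop("genotype rows (", nrow(g), ") != samples (", nrow(s), ")")
  if (ncol(g) != nrow(v))
    stop("genotype columns (", ncol(g), ") != variants (", nrow(v), ")")
  if (anyDuplicated(s$sample_id)) stop("duplicate sample ids")
  if (anyDuplicated(v$variant_id)) stop("duplicate variant ids")
  if (!all(g[!is.na(g)] %in% 0:2)) stop("genotypes must be 0, 1, 2 or NA")
  if (any(v$ref == v$alt)) stop("ref and alt alleles must differ")
  if (any(v$pos < 1)) stop("positions must be >= 1")
  bad_cls <- setdiff(unique(v$functional_class),
                     c("LOF", "nonsynonymous", "other"))
  if (length(bad_cls))
    stop("unknown functional class: ", paste(bad_cls, collapse = ", "))
  # positions strictly increasing within each chromosome
  for (chr in unique(v$chrom)) {
    p <- v$pos[v$chrom == chr]
    if (length(p) > 1 && any(diff(p) <= 0))
      stop("positions not strictly increasing on chromosome ", chr)
  }
  invisible(cohort)
}

#' @export
print.geo_cohort <- function(x, ...) {
  cat("geo_cohort:", nrow(x$genotypes), "samples x", ncol(x$genotypes),
      "variants\n")
  cat("  cases:", sum(x$samples$status == 1),
      " controls:", sum(x$samples$status == 0),
      " cohorts:", paste(unique(x$samples$cohort), collapse = ", "), "\n")
  ng <- sum(!is.na(x$variants$gene_id))
  cat("  variants in genes:", ng, "(",
      length(unique(stats::na.omit(x$variants$gene_id))), "genes )\n")
  invisible(x)
}

#' Number of samples / variants in a cohort
#' @param cohort a `geo_cohort`.
#' @return integer count.
#' @export
n_samples <- function(cohort) nrow(cohort$genotypes)

#' @rdname n_samples
#' @export
n_variants <- function(cohort) ncol(cohort$genotypes)

#' Subset a cohort by sample or variant index
#'
#' @param cohort a `geo_cohort`.
#' @param idx integer or logical index.
#' @return a new `geo_cohort`.
#' @export
subset_samples <- function(cohort, idx) {
  geo_cohort(cohort$genotypes[idx, , drop = FALSE],
             cohort$samples[idx, , drop = FALSE],
             cohort$variants, validate = FALSE)
}

#' @rdname subset_samples
#' @export
subset_variants <- function(cohort, idx) {
  geo_cohort(cohort$genotypes[, idx, drop = FALSE],
             cohort$samples,
             cohort$variants[idx, , drop = FALSE], validate = FALSE)
}

#' Per-variant minor allele frequency
#'
#' Estimated from non-missing genotypes; the minor allele is re-evaluated on
#' the samples present, so the value is always in `[0, 0.5]`.
#'
#' @param cohort a `geo_cohort`, or a genotype matrix.
#' @return numeric vector of MAFs (NaN for all-missing variants).
#' @export
cohort_maf <- function(cohort) {
  g <- if (inherits(cohort, "geo_cohort")) cohort$genotypes else cohort
  p <- colMeans(g, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' Per-variant frequency of the stored (dosage-counted) allele
#' @param cohort a `geo_cohort` or genotype matrix.
#' @return numeric vector in `[0, 1]`.
#' @export
dosage_freq <- function(cohort) {
  g <- if (inherits(cohort, "geo_cohort")) cohort$genotypes else cohort
  colMeans(g, na.rm = TRUE) / 2
}

#' Canonical site key (chrom:pos:ref:alt) for merge operations
#' @param variants a variant table with chrom, pos, ref, alt columns.
#' @return character vector of keys.
#' @export
variant_key <- function(variants) {
  paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")
}
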