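#' Write a cohort to a minimal VCF v4.2
#'
#' GT-only records with fixed header lines, so identical cohorts always
#' produce byte-identical files. Genotypes are written on the REF/ALT axis
#' (the stored minor-allele dosage is converted back via the
#' `minor_allele` column); missing genotypes become `./.`.
#'
#' @param cohort a `geo_cohort`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(cohort, path) {
  g <- cohort$genotypes
  v <- cohort$variants
  s <- cohort$samples
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=geostrat",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", s$sample_id), collapse = "\t"), con)
  if (ncol(g) > 0) {
    # ALT dosage per site
    alt <- t(g)
    flip <- v$minor_allele == "ref"
    if (any(flip)) alt[flip, ] <- 2L - alt[flip, , drop = FALSE]
    gt <- matrix(c("0/0", "0/1", "1/1")[alt + 1L], nrow = nrow(alt))
    gt[is.na(alt)] <- "./."
    rec <- paste(v$chrom, v$pos, v$variant_id, v$ref, v$alt, ".", "PASS",
                 ".", "GT", apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
    writeLines(rec, con)
  }
  invisible(path)
}

#' Read a minimal GT-only VCF v4.2
#'
#' Accepts biallelic SNV/indel records with a GT field. Genotypes are
#' recoded to minor-allele dosage, with the minor allele defined per site
#' over the loaded samples (ties at frequency 0.5 keep ALT as minor);
#' `./.` becomes missing. Multi-allelic records raise an error naming the
#' site.
#'
#' @param path VCF file path.
#' @return list with `genotypes` (minor-allele dosage matrix), `variants`
#'   (data.frame with `minor_allele` filled in) and `sample_ids`.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "##fileformat=VCF"))
    stop("not a VCF: missing ##fileformat header in ", path)
  hdr_i <- which(startsWith(lines, "#CHROM"))
  if (length(hdr_i) != 1)
    stop("malformed VCF: expected exactly one #CHROM line in ", path)
  hdr <- strsplit(lines[hdr_i], "\t", fixed = TRUE)[[1]]
  if (length(hdr) < 10 || hdr[9] != "FORMAT")
    stop("malformed VCF header at line ", hdr_i, ": need FORMAT + samples")
  sample_ids <- hdr[-(1:9)]
  body <- lines[-seq_len(hdr_i)]
  body <- body[nzchar(body)]
  m <- length(body)
  ns <- length(sample_ids)
  geno <- matrix(NA_integer_, nrow = ns, ncol = m)
  variants <- data.frame(variant_id = character(m), chrom = character(m),
                         pos = integer(m), ref = character(m),
                         alt = character(m), minor_allele = "alt",
                         gene_id = NA_character_, functional_class = "other")
  for (k in seq_len(m)) {
    f <- strsplit(body[k], "\t", fixed = TRUE)[[1]]
    ln <- hdr_i + k
    if (length(f) != 9 + ns)
      stop("malformed VCF record at line ", ln, ": ", length(f), " fields")
    if (grepl(",", f[5], fixed = TRUE))
      stop("unsupported multi-allelic record at ", f[1], ":", f[2],
           " (line ", ln, ")")
    gt <- sub(":.*$", "", f[-(1:9)])
    dos <- match(gt, c("0/0", "0/1", "1/0", "1/1", "0|0", "0|1", "1|0", "1|1"))
    dos <- c(0L, 1L, 1L, 2L, 0L, 1L, 1L, 2L)[dos]
    bad <- is.na(dos) & !(gt %in% c("./.", ".|.", "."))
    if (any(bad))
      stop("unparseable GT '", gt[which(bad)[1]], "' at line ", ln)
    geno[, k] <- dos
    variants$chrom[k] <- f[1]
    variants$pos[k] <- as.integer(f[2])
    variants$variant_id[k] <- if (f[3] == ".")
      paste(f[1], f[2], sep = ":") else f[3]
    variants$ref[k] <- f[4]
    variants$alt[k] <- f[5]
  }
  # recode to minor-allele dosage; ties at 0.5 keep ALT
  p_alt <- colMeans(geno, na.rm = TRUE) / 2
  flip <- !is.na(p_alt) & p_alt > 0.5
  if (any(flip)) {
    geno[, flip] <- 2L - geno[, flip, drop = FALSE]
    variants$minor_allele[flip] <- "ref"
  }
  rownames(geno) <- sample_ids
  colnames(geno) <- variants$variant_id
  list(genotypes = geno, variants = variants, sample_ids = sample_ids)
}

#' Read / write the tab-separated sample sheet
#'
#' Columns: `sample_id sex status lat lon cohort`.
#'
#' @param path file path.
#' @return data.frame of sample metadata.
#' @export
read_samples <- function(path) {
  s <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(sample_id = "character"))
  req <- c("sample_id", "sex", "status", "lat", "lon", "cohort")
  miss <- setdiff(req, names(s))
  if (length(miss))
    stop("sample sheet missing required column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(s$sample_id))
    stop("duplicate sample_id in sample sheet: ",
         s$sample_id[anyDuplicated(s$sample_id)])
  s
}

#' @rdname read_samples
#' @param samples sample metadata data.frame.
#' @export
write_samples <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write the gene-group file
#'
#' Columns: `gene_id variant_id functional_class`; one row per variant.
#'
#' @param path file path.
#' @return data.frame of gene-group assignments.
#' @export
read_groups <- function(path) {
  g <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("gene_id", "variant_id", "functional_class")
  miss <- setdiff(req, names(g))
  if (length(miss))
    stop("group file missing required column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(g$variant_id))
    stop("duplicate variant_id in group file: ",
         g$variant_id[anyDuplicated(g$variant_id)])
  bad <- setdiff(unique(g$functional_class), c("LOF", "nonsynonymous", "other"))
  if (length(bad))
    stop("unknown functional class in group file: ", paste(bad, collapse = ", "))
  g
}

#' @rdname read_groups
#' @param groups gene-group data.frame.
#' @export
write_groups <- function(groups, path) {
  utils::write.table(groups, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write an IBD segment table (`id1 id2 length_cM`)
#' @param path file path.
#' @return data.frame of segments.
#' @export
read_ibd <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("id1", "id2", "length_cM")
  miss <- setdiff(req, names(x))
  if (length(miss))
    stop("IBD table missing column(s): ", paste(miss, collapse = ", "))
  if (any(x$length_cM <= 0)) stop("IBD segment lengths must be > 0")
  x
}

#' @rdname read_ibd
#' @param ibd segment data.frame.
#' @export
write_ibd <- function(ibd, path) {
  utils::write.table(ibd, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble a cohort from VCF + sample sheet + gene groups
#'
#' Joins by `sample_id` and `variant_id`; ids present in the metadata but
#' absent from the VCF (or vice versa) are reported with a warning, and the
#' cohort is restricted to matched samples.
#'
#' @param vcf_path,samples_path paths to the VCF and sample sheet.
#' @param groups_path optional path to the gene-group file.
#' @return a `geo_cohort`.
#' @export
load_cohort <- function(vcf_path, samples_path, groups_path = NULL) {
  vc <- read_vcf(vcf_path)
  s <- read_samples(samples_path)
  unmatched <- setdiff(s$sample_id, vc$sample_ids)
  if (length(unmatched))
    warning(length(unmatched), " sample id(s) in sheet absent from VCF: ",
            paste(utils::head(unmatched, 5), collapse = ", "))
  extra <- setdiff(vc$sample_ids, s$sample_id)
  if (length(extra))
    warning(length(extra), " VCF sample(s) absent from sheet: ",
            paste(utils::head(extra, 5), collapse = ", "))
  keep <- intersect(vc$sample_ids, s$sample_id)
  if (!length(keep)) stop("no samples shared between VCF and sample sheet")
  g <- vc$genotypes[keep, , drop = FALSE]
  s <- s[match(keep, s$sample_id), , drop = FALSE]
  v <- vc$variants
  if (!is.null(groups_path)) {
    gr <- read_groups(groups_path)
    hit <- match(v$variant_id, gr$variant_id)
    v$gene_id <- gr$gene_id[hit]
    v$functional_class <- ifelse(is.na(hit), "other",
                                 gr$functional_class[hit])
    orphan <- setdiff(gr$variant_id, v$variant_id)
    if (length(orphan))
      warning(length(orphan), " group-file variant id(s) absent from VCF")
  }
  geo_cohort(g, s, v)
}
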