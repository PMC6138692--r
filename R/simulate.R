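#' Geographic frame for the simulated cohort
#'
#' A rectangular latitude/longitude box. The default approximates the
#' Netherlands, the sampling frame of the cohorts this package emulates;
#' only the relative geometry (distances in km) matters downstream.
#'
#' @param lat_min,lat_max,lon_min,lon_max box edges in decimal degrees.
#' @return an object of class `spatial_map`.
#' @export
spatial_map <- function(lat_min = 50.7, lat_max = 53.5,
                        lon_min = 3.3, lon_max = 7.2) {
  if (!(lat_min < lat_max) || !(lon_min < lon_max))
    stop("invalid map box: need lat_min < lat_max and lon_min < lon_max")
  structure(list(lat_min = lat_min, lat_max = lat_max,
                 lon_min = lon_min, lon_max = lon_max),
            class = "spatial_map")
}

#' Simulation configuration
#'
#' Collects every knob of the synthetic-cohort generator. Defaults encode the
#' desk-scale study this package is calibrated around: a 2:1 case-control
#' cohort with spatially clustered rare variation, smooth common-variant
#' clines, and an externally sequenced control set re-measured with a
#' platform-specific genotype error model.
#'
#' @param n_cases,n_controls internally sequenced sample counts (2:1 design).
#' @param n_external_controls size of the external control cohort.
#' @param n_common_variants,n_rare_variants variant counts for the two
#'   frequency strata.
#' @param n_genes number of genes the rare variants are partitioned into.
#' @param rare_kernel_scale_km spatial decay scale of rare-variant carrier
#'   clustering (km).
#' @param cline_strength logit-scale slope of common-variant allele-frequency
#'   clines per SD of geographic projection.
#' @param gradient_strength relative excess of case-sampling weight between
#'   the two latitude extremes in the imperfect-matching scenario.
#' @param batch_error_rate per-genotype allele-flip probability at
#'   platform-affected sites in the external cohort.
#' @param batch_site_fraction fraction of sites that are platform-affected.
#' @param ibd_bin_edges_cM segment-length bin edges in centimorgans.
#' @param ibd_params per-bin Poisson intensity parameters, a data.frame with
#'   columns `a` (distance-dependent amplitude), `rho_km` (decay scale) and
#'   `b` (distance-independent floor); rows match the length bins.
#' @param seed master seed; all stages derive named substreams from it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_cases = 400L, n_controls = 200L,
                       n_external_controls = 200L,
                       n_common_variants = 2000L, n_rare_variants = 5000L,
                       n_genes = 200L,
                       rare_kernel_scale_km = 20,
                       cline_strength = 0.1,
                       gradient_strength = 2,
                       batch_error_rate = 0.02,
                       batch_site_fraction = 0.3,
                       ibd_bin_edges_cM = c(1, 2, 7, 15),
                       ibd_params = NULL,
                       seed = 1L) {
  counts <- c(n_cases = n_cases, n_controls = n_controls,
              n_common_variants = n_common_variants,
              n_rare_variants = n_rare_variants, n_genes = n_genes)
  if (any(counts <= 0)) stop("all counts must be > 0")
  if (n_external_controls < 0) stop("n_external_controls must be >= 0")
  probs <- c(batch_error_rate = batch_error_rate,
             batch_site_fraction = batch_site_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (rare_kernel_scale_km <= 0) stop("rare_kernel_scale_km must be > 0")
  if (cline_strength < 0) stop("cline_strength must be >= 0")
  if (gradient_strength < 0) stop("gradient_strength must be >= 0")
  if (any(diff(ibd_bin_edges_cM) <= 0))
    stop("ibd_bin_edges_cM must be strictly increasing")
  if (is.null(ibd_params)) ibd_params <- default_ibd_params(ibd_bin_edges_cM)
  if (nrow(ibd_params) != length(ibd_bin_edges_cM) - 1L)
    stop("ibd_params must have one row per length bin")
  if (any(ibd_params$rho_km <= 0) || any(ibd_params$a < 0) ||
      any(ibd_params$b < 0))
    stop("ibd decay parameters must be positive")
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 n_external_controls = as.integer(n_external_controls),
                 n_common_variants = as.integer(n_common_variants),
                 n_rare_variants = as.integer(n_rare_variants),
                 n_genes = as.integer(n_genes),
                 rare_kernel_scale_km = rare_kernel_scale_km,
                 cline_strength = cline_strength,
                 gradient_strength = gradient_strength,
                 batch_error_rate = batch_error_rate,
                 batch_site_fraction = batch_site_fraction,
                 ibd_bin_edges_cM = ibd_bin_edges_cM,
                 ibd_params = ibd_params,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Segment sharing is ubiquitous and weakly distance-dependent for short
# (old) segments, rare and strongly distance-dependent for long (recent)
# ones; rho shrinks and a/b fall with segment length.
default_ibd_params <- function(edges = c(1, 2, 7, 15)) {
  k <- length(edges) - 1L
  data.frame(a = c(0.6, 0.5, 0.35)[seq_len(k)],
             rho_km = c(400, 150, 60)[seq_len(k)],
             b = c(1.2, 0.15, 0.01)[seq_len(k)])
}

# local planar km coordinates relative to the map box centre
.planar_km <- function(lat, lon, map) {
  lat0 <- (map$lat_min + map$lat_max) / 2
  lon0 <- (map$lon_min + map$lon_max) / 2
  cbind(x = (lon - lon0) * 111.320 * cos(lat0 * pi / 180),
        y = (lat - lat0) * 110.574)
}

#' Sample birthplaces uniformly inside the map box
#'
#' @param config a `sim_config` (only the sample counts are used when `n` is
#'   missing), or `NULL` if `n` is given.
#' @param map a `spatial_map`.
#' @param n optional explicit number of individuals.
#' @param seed optional seed (derived from `config$seed` when omitted).
#' @return data.frame with columns `lat`, `lon`.
#' @export
sample_birthplaces <- function(config = NULL, map = spatial_map(), n = NULL,
                               seed = NULL) {
  if (is.null(n)) {
    stopifnot(inherits(config, "sim_config"))
    n <- config$n_cases + config$n_controls
    if (is.null(seed)) seed <- substream_seed(config$seed, "birthplaces")
  }
  if (n <= 0) stop("n must be > 0")
  with_seed(seed, data.frame(
    lat = stats::runif(n, map$lat_min, map$lat_max),
    lon = stats::runif(n, map$lon_min, map$lon_max)))
}

#' Simulate common variants with smooth allele-frequency clines
#'
#' Each variant draws a baseline frequency p0 ~ U(0.05, 0.5) and a random
#' planar direction; the local allele frequency is
#' inverse-logit(logit(p0) + cline_strength * z) where z is the standardized
#' projection of an individual's birthplace onto that direction. Genotypes
#' are two Bernoulli draws at the local frequency, so a zero cline recovers
#' Hardy-Weinberg sampling at p0 and a strong cline produces the
#' geography-aligned principal components the downstream analyses probe.
#'
#' @param coords data.frame with `lat`, `lon`.
#' @param n number of variants.
#' @param cline_strength non-negative slope on the logit scale.
#' @param map a `spatial_map` used to build planar coordinates.
#' @param seed RNG seed.
#' @return list with `genotypes` (samples x n integer matrix of ALT dosages)
#'   and `p0` (baseline frequencies).
#' @export
simulate_common_variants <- function(coords, n, cline_strength,
                                     map = spatial_map(), seed = NULL) {
  if (nrow(coords) == 0) stop("coords must be non-empty")
  if (cline_strength < 0) stop("cline_strength must be >= 0")
  xy <- .planar_km(coords$lat, coords$lon, map)
  with_seed(seed, {
    m <- nrow(coords)
    p0 <- stats::runif(n, 0.05, 0.5)
    theta <- stats::runif(n, 0, 2 * pi)
    proj <- outer(xy[, "x"], cos(theta)) + outer(xy[, "y"], sin(theta))
    proj <- scale(proj)                       # standardize per variant
    proj[is.nan(proj)] <- 0                   # degenerate (n=1) guard
    pl <- stats::plogis(sweep(proj * cline_strength, 2, stats::qlogis(p0), "+"))
    g <- matrix(stats::rbinom(m * n, 1L, pl) + stats::rbinom(m * n, 1L, pl),
                nrow = m, ncol = n)
    list(genotypes = g, p0 = p0)
  })
}

#' Simulate geographically clustered rare variants
#'
#' Every rare variant originates at the birthplace of a randomly chosen
#' individual. A carrier count is drawn from a truncated geometric on
#' 1..10 (mean about 2, reproducing the observed skew towards fewer than
#' three allele observations) and additionally capped so the cohort MAF
#' stays below 0.5 percent. Carriers are sampled without replacement with
#' probability proportional to exp(-d_km / kernel_scale_km) from the origin,
#' and are heterozygous.
#'
#' @param coords data.frame with `lat`, `lon`.
#' @param n number of rare variants.
#' @param kernel_scale_km spatial decay scale; `Inf` gives unclustered
#'   carriers.
#' @param map a `spatial_map`.
#' @param seed RNG seed.
#' @param maf_cap_n sample count used for the MAF < 0.005 cap; defaults to
#'   the number of rows of `coords`, but [simulate_study()] passes the
#'   internal-cohort size so the cap still holds after the study split.
#' @return integer genotype matrix (samples x n).
#' @export
simulate_rare_variants <- function(coords, n, kernel_scale_km,
                                   map = spatial_map(), seed = NULL,
                                   maf_cap_n = nrow(coords)) {
  if (kernel_scale_km <= 0) stop("kernel_scale_km must be > 0")
  ns <- nrow(coords)
  cmax <- min(10L, max(1L, as.integer(ceiling(0.005 * 2 * maf_cap_n) - 1L)))
  if (cmax > ns) stop("carrier count exceeds number of samples")
  xy <- .planar_km(coords$lat, coords$lon, map)
  with_seed(seed, {
    # truncated geometric on 1..cmax, success prob 0.5
    kk <- seq_len(cmax)
    pk <- 0.5^kk / sum(0.5^kk)
    counts <- sample(kk, n, replace = TRUE, prob = pk)
    origins <- sample.int(ns, n, replace = TRUE)
    g <- matrix(0L, nrow = ns, ncol = n)
    for (j in seq_len(n)) {
      d <- sqrt((xy[, 1] - xy[origins[j], 1])^2 +
                (xy[, 2] - xy[origins[j], 2])^2)
      w <- if (is.infinite(kernel_scale_km)) rep(1, ns)
           else exp(-d / kernel_scale_km)
      carriers <- sample.int(ns, counts[j], prob = w)
      g[carriers, j] <- 1L
    }
    g
  })
}

#' Assign case/control status under a matching scenario
#'
#' `perfect` draws cases uniformly without replacement; `imperfect` weights
#' the case-sampling probability linearly in latitude so that the southern
#' edge of the map carries `1 + gradient_strength` times the weight of the
#' northern edge (the configurable North-to-South enrichment). Both
#' scenarios return exactly `n_cases` cases.
#'
#' @param coords data.frame with `lat`, `lon`.
#' @param n_cases number of cases (< number of rows of `coords`).
#' @param scenario `"perfect"` or `"imperfect"`.
#' @param gradient_strength non-negative gradient amplitude.
#' @param map a `spatial_map` fixing the latitude extremes.
#' @param seed RNG seed.
#' @return integer vector of 0/1 status labels.
#' @export
simulate_phenotype_scenario <- function(coords, n_cases,
                                        scenario = c("perfect", "imperfect"),
                                        gradient_strength = 2,
                                        map = spatial_map(), seed = NULL) {
  scenario <- match.arg(scenario)
  ns <- nrow(coords)
  if (n_cases >= ns) stop("n_cases must be < number of samples")
  if (gradient_strength < 0) stop("gradient_strength must be >= 0")
  with_seed(seed, {
    w <- if (scenario == "perfect") rep(1, ns) else {
      frac_south <- (map$lat_max - coords$lat) / (map$lat_max - map$lat_min)
      1 + gradient_strength * frac_south
    }
    status <- integer(ns)
    status[sample.int(ns, n_cases, prob = w)] <- 1L
    status
  })
}

#' Simulate pairwise IBD segment sharing
#'
#' For every unordered pair of individuals and every segment-length bin the
#' number of shared segments is Poisson with mean
#' `a * exp(-d_km / rho_km) + b`; segment lengths are uniform within the
#' bin. Longer bins use smaller `rho` so recent shared ancestry decays
#' faster with birthplace distance than old, ubiquitous sharing.
#'
#' @param coords data.frame with `lat`, `lon`; row order defines ids 1..n.
#' @param bin_edges_cM length-bin edges (cM).
#' @param params data.frame with per-bin `a`, `rho_km`, `b`.
#' @param map a `spatial_map`.
#' @param seed RNG seed.
#' @return data.frame with columns `id1`, `id2`, `length_cM`, one row per
#'   segment, each unordered pair listed once (id1 < id2).
#' @export
simulate_ibd_segments <- function(coords, bin_edges_cM = c(1, 2, 7, 15),
                                  params = default_ibd_params(bin_edges_cM),
                                  map = spatial_map(), seed = NULL) {
  if (any(params$rho_km <= 0)) stop("per-bin decay parameters must be positive")
  ns <- nrow(coords)
  xy <- .planar_km(coords$lat, coords$lon, map)
  pr <- which(upper.tri(matrix(0, ns, ns)), arr.ind = TRUE)
  i <- pr[, 1]; j <- pr[, 2]
  d <- sqrt((xy[i, 1] - xy[j, 1])^2 + (xy[i, 2] - xy[j, 2])^2)
  nb <- length(bin_edges_cM) - 1L
  with_seed(seed, {
    out <- vector("list", nb)
    for (b in seq_len(nb)) {
      mu <- params$a[b] * exp(-d / params$rho_km[b]) + params$b[b]
      k <- stats::rpois(length(d), mu)
      idx <- rep.int(seq_along(d), k)
      out[[b]] <- data.frame(
        id1 = i[idx], id2 = j[idx],
        length_cM = stats::runif(sum(k), bin_edges_cM[b], bin_edges_cM[b + 1L]))
    }
    do.call(rbind, out)
  })
}

#' Re-measure a cohort with a platform-specific genotype error model
#'
#' Emulates externally sequenced controls merged at the VCF level: a random
#' fraction of sites is "platform-affected"; at those sites each genotype
#' independently flips one allele (hom to het, or het to either hom) with
#' probability `batch_error_rate`, or is set missing with probability
#' `batch_error_rate / 2`. Unaffected sites are copied unchanged.
#'
#' @param cohort a `geo_cohort`.
#' @param batch_error_rate per-genotype flip probability.
#' @param batch_site_fraction fraction of affected sites.
#' @param cohort_label new cohort label for the re-measured copy.
#' @param seed RNG seed.
#' @return list with `cohort` (the perturbed copy) and `affected_sites`
#'   (integer variant indices).
#' @export
simulate_batch_cohort <- function(cohort, batch_error_rate,
                                  batch_site_fraction,
                                  cohort_label = "external", seed = NULL) {
  if (batch_error_rate < 0 || batch_error_rate > 1 ||
      batch_site_fraction < 0 || batch_site_fraction > 1)
    stop("rates must lie in [0, 1]")
  g <- cohort$genotypes
  m <- ncol(g); ns <- nrow(g)
  with_seed(seed, {
    n_aff <- round(batch_site_fraction * m)
    affected <- if (n_aff > 0) sort(sample.int(m, n_aff)) else integer(0)
    if (length(affected) && batch_error_rate > 0) {
      sub <- g[, affected, drop = FALSE]
      u <- matrix(stats::runif(length(sub)), nrow = ns)
      flip <- u < batch_error_rate & !is.na(sub)
      miss <- u >= batch_error_rate &
              u < 1.5 * batch_error_rate & !is.na(sub)
      # flip one allele: 0 -> 1, 2 -> 1, 1 -> 0 or 2 with equal probability
      het_dir <- matrix(sample(c(0L, 2L), length(sub), replace = TRUE),
                        nrow = ns)
      new <- sub
      new[flip & sub == 0L] <- 1L
      new[flip & sub == 2L] <- 1L
      hsel <- flip & sub == 1L
      new[hsel] <- het_dir[hsel]
      new[miss] <- NA_integer_
      g[, affected] <- new
    }
    samples <- cohort$samples
    samples$cohort <- cohort_label
    list(cohort = geo_cohort(g, samples, cohort$variants, validate = FALSE),
         affected_sites = affected)
  })
}

# Partition rare variants into genes and label functional classes.
# Class mix follows typical coding-exome proportions: nonsynonymous
# dominate, LOF are the small minority, the rest are "other" (excluded
# from burden groups).
.assign_genes <- function(n_rare, n_genes, seed) {
  with_seed(seed, {
    gene <- sort(rep_len(seq_len(n_genes), n_rare))
    cls <- sample(c("LOF", "nonsynonymous", "other"), n_rare,
                  replace = TRUE, prob = c(0.15, 0.55, 0.30))
    data.frame(gene_id = sprintf("G%04d", gene), functional_class = cls)
  })
}

#' Simulate a complete case-control cohort
#'
#' Assembles birthplaces, common variants (chromosome "1"), geographically
#' clustered rare variants (chromosome "2", partitioned into genes with
#' functional classes), sex, and perfect-matching case/control labels into a
#' single `geo_cohort`.
#'
#' @param config a `sim_config`.
#' @param map a `spatial_map`.
#' @param n_samples optional override of the total sample count (the
#'   case/control split is taken from `config`; extra samples become
#'   controls of the same cohort and are used by [simulate_study()]).
#' @return a `geo_cohort` with cohort label "internal".
#' @export
simulate_cohort <- function(config = sim_config(), map = spatial_map(),
                            n_samples = NULL) {
  n_int <- config$n_cases + config$n_controls
  n <- if (is.null(n_samples)) n_int else n_samples
  coords <- sample_birthplaces(map = map, n = n,
                               seed = substream_seed(config$seed, "birthplaces"))
  common <- simulate_common_variants(
    coords, config$n_common_variants, config$cline_strength, map,
    seed = substream_seed(config$seed, "common_variants"))
  rare <- simulate_rare_variants(
    coords, config$n_rare_variants, config$rare_kernel_scale_km, map,
    seed = substream_seed(config$seed, "rare_variants"),
    maf_cap_n = min(n, n_int))
  status <- simulate_phenotype_scenario(
    coords[seq_len(n_int), , drop = FALSE], config$n_cases, "perfect",
    map = map, seed = substream_seed(config$seed, "phenotype"))
  if (n > n_int) status <- c(status, integer(n - n_int))
  sex <- with_seed(substream_seed(config$seed, "sex"),
                   sample(c("M", "F"), n, replace = TRUE, prob = c(0.58, 0.42)))
  g <- cbind(common$genotypes, rare)
  mc <- config$n_common_variants
  mr <- config$n_rare_variants
  genes <- .assign_genes(mr, config$n_genes,
                         substream_seed(config$seed, "genes"))
  variants <- data.frame(
    variant_id = c(sprintf("c%05d", seq_len(mc)), sprintf("r%05d", seq_len(mr))),
    chrom = c(rep("1", mc), rep("2", mr)),
    pos = c(seq_len(mc) * 1000L, seq_len(mr) * 1000L),
    ref = "A", alt = "C",
    minor_allele = "alt",
    gene_id = c(rep(NA_character_, mc), genes$gene_id),
    functional_class = c(rep("other", mc), genes$functional_class))
  # store as minor-allele dosage: flip sites where ALT drifted above 0.5
  pf <- colMeans(g, na.rm = TRUE) / 2
  flip <- which(pf > 0.5)
  if (length(flip)) {
    g[, flip] <- 2L - g[, flip]
    variants$minor_allele[flip] <- "ref"
  }
  samples <- data.frame(
    sample_id = sprintf("S%05d", seq_len(n)),
    sex = sex, status = status,
    lat = coords$lat, lon = coords$lon, cohort = "internal")
  rownames(g) <- samples$sample_id
  colnames(g) <- variants$variant_id
  geo_cohort(g, samples, variants)
}

#' Simulate an internal study plus an externally sequenced control cohort
#'
#' Draws one population (shared variant definitions and allele-frequency
#' surfaces), splits it into the internal case/control cohort and an
#' external control-only cohort, and passes the external half through the
#' platform error model. Because both cohorts come from the same spatial
#' process, any separation between them downstream is a batch artifact,
#' exactly the situation the external-control merge experiment probes.
#'
#' @param config a `sim_config`.
#' @param map a `spatial_map`.
#' @return list with `internal` and `external` cohorts and the
#'   `affected_sites` of the batch model.
#' @export
simulate_study <- function(config = sim_config(), map = spatial_map()) {
  n_int <- config$n_cases + config$n_controls
  n_tot <- n_int + config$n_external_controls
  full <- simulate_cohort(config, map, n_samples = n_tot)
  internal <- subset_samples(full, seq_len(n_int))
  ext_raw <- subset_samples(full, (n_int + 1L):n_tot)
  ext_raw$samples$sample_id <- sub("^S", "E", ext_raw$samples$sample_id)
  ext_raw$samples$status <- 0L
  rownames(ext_raw$genotypes) <- ext_raw$samples$sample_id
  batch <- simulate_batch_cohort(
    ext_raw, config$batch_error_rate, config$batch_site_fraction,
    cohort_label = "external",
    seed = substream_seed(config$seed, "batch"))
  list(internal = internal, external = batch$cohort,
       affected_sites = batch$affected_sites)
}
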