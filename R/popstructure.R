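#' Genetic relationship matrix
#'
#' The GCTA-style GRM:
#' \deqn{A_{jk} = \frac{1}{M}\sum_i \frac{(x_{ij}-2p_i)(x_{ik}-2p_i)}
#'   {2p_i(1-p_i)}}
#' over the M variants with MAF at or above `maf_min`. Allele frequencies
#' are estimated from non-missing genotypes and missing genotypes are
#' imputed to `2 p_i` (i.e. contribute zero after centering).
#'
#' @param cohort a `geo_cohort` (or a dosage matrix).
#' @param maf_min minimum minor-allele frequency for inclusion.
#' @return list of class `geo_grm` with `grm`, `m_variants`, `maf_min`.
#' @export
compute_grm <- function(cohort, maf_min = 0.01) {
  g <- if (inherits(cohort, "geo_cohort")) cohort$genotypes else cohort
  if (nrow(g) < 2) stop("need at least two samples")
  p <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  use <- which(!is.nan(maf) & maf >= maf_min & maf > 0)
  if (!length(use)) stop("no variants pass maf_min = ", maf_min)
  gs <- g[, use, drop = FALSE]
  ps <- p[use]
  z <- sweep(gs, 2, 2 * ps, "-")
  z <- sweep(z, 2, sqrt(2 * ps * (1 - ps)), "/")
  z[is.na(z)] <- 0
  A <- tcrossprod(z) / length(use)
  dimnames(A) <- list(rownames(g), rownames(g))
  structure(list(grm = A, m_variants = length(use), maf_min = maf_min),
            class = "geo_grm")
}

#' Principal components of a GRM
#'
#' Top-k eigenpairs with a fixed sign convention (the largest-magnitude
#' loading of each eigenvector is positive), so results are reproducible
#' across platforms.
#'
#' @param grm a `geo_grm` or symmetric matrix.
#' @param k number of components.
#' @return list of class `geo_pca` with `values` (non-increasing),
#'   `vectors` (orthonormal columns), `k`, `maf_threshold`.
#' @export
pca <- function(grm, k = 20) {
  A <- if (inherits(grm, "geo_grm")) grm$grm else grm
  n <- nrow(A)
  if (k > n) stop("k (", k, ") exceeds the number of samples (", n, ")")
  e <- eigen(A, symmetric = TRUE)
  vals <- e$values[seq_len(k)]
  vecs <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  rownames(vecs) <- rownames(A)
  colnames(vecs) <- paste0("PC", seq_len(k))
  structure(list(values = vals, vectors = vecs, k = k,
                 maf_threshold = if (inherits(grm, "geo_grm")) grm$maf_min
                                 else NA_real_),
            class = "geo_pca")
}

#' Great-circle distance in kilometres
#'
#' Haversine formula with Earth radius 6371.0 km; vectorized over points.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees.
#' @return distance(s) in km.
#' @export
#' @examples
#' haversine_km(0, 0, 0, 1)  # one degree of longitude at the equator
haversine_km <- function(lat1, lon1, lat2, lon2) {
  r <- pi / 180
  dlat <- (lat2 - lat1) * r / 2
  dlon <- (lon2 - lon1) * r / 2
  a <- sin(dlat)^2 + cos(lat1 * r) * cos(lat2 * r) * sin(dlon)^2
  2 * 6371.0 * asin(pmin(1, sqrt(a)))
}

#' Leave-one-out birthplace prediction from principal components
#'
#' Regresses latitude and longitude separately on the first `k` PCs (with
#' intercept) by ordinary least squares; for each sample the model is
#' refitted without that sample and used to predict its birthplace. The
#' refit uses the exact leave-one-out identity for linear models
#' (prediction_i = fit_i - h_ii e_i / (1 - h_ii)), which is algebraically
#' identical to an explicit refit. Only the regression is refitted, not the
#' PCA.
#'
#' @param pca_res a `geo_pca`.
#' @param coords data.frame with `lat`, `lon` for the same samples.
#' @param k number of PCs in the model (default 20).
#' @return list of class `birthplace_prediction` with `predicted`
#'   (data.frame lat/lon), `error_km` (per-sample great-circle error) and
#'   `median_error_km`.
#' @export
predict_birthplace_loo <- function(pca_res, coords, k = 20) {
  V <- pca_res$vectors
  if (k > ncol(V)) stop("PCA holds only ", ncol(V), " components")
  n <- nrow(V)
  if (n <= k + 1) stop("underdetermined: need n > k + 1 samples")
  if (nrow(coords) != n) stop("coords must match the PCA samples")
  X <- cbind(1, V[, seq_len(k), drop = FALSE])
  XtX_inv <- chol2inv(chol(crossprod(X)))
  H <- rowSums((X %*% XtX_inv) * X)           # hat diagonal
  loo_predict <- function(y) {
    beta <- XtX_inv %*% crossprod(X, y)
    fit <- drop(X %*% beta)
    fit - H * (y - fit) / (1 - H)
  }
  pred_lat <- loo_predict(coords$lat)
  pred_lon <- loo_predict(coords$lon)
  err <- haversine_km(coords$lat, coords$lon, pred_lat, pred_lon)
  structure(list(predicted = data.frame(lat = pred_lat, lon = pred_lon),
                 error_km = err,
                 median_error_km = stats::median(err),
                 k = k, maf_threshold = pca_res$maf_threshold),
            class = "birthplace_prediction")
}

#' Variance in a coordinate explained by one principal component
#'
#' Squared Pearson correlation from the univariate regression of the
#' coordinate on the PC scores, with the regression p-value.
#'
#' @param pc_scores numeric vector of PC scores.
#' @param coordinate numeric vector (latitude or longitude).
#' @return list with `fraction` (R^2) and `p_value`.
#' @export
variance_explained <- function(pc_scores, coordinate) {
  if (length(pc_scores) != length(coordinate))
    stop("inputs must have the same length")
  if (stats::sd(pc_scores) == 0 || stats::sd(coordinate) == 0)
    stop("zero-variance input: statistic undefined")
  fit <- stats::lm(coordinate ~ pc_scores)
  sm <- summary(fit)
  list(fraction = sm$r.squared,
       p_value = sm$coefficients["pc_scores", "Pr(>|t|)"])
}

#' Mean IBD sharing by segment-length bin and birthplace-distance decile
#'
#' All unordered sample pairs (including pairs sharing nothing) are binned
#' into deciles of great-circle birthplace distance; segments are binned by
#' length. Cell values are mean segment counts per pair.
#'
#' @param ibd segment data.frame (`id1`, `id2`, `length_cM`); ids are row
#'   indices into `coords` or sample ids matching its rownames.
#' @param coords data.frame with `lat`, `lon`.
#' @param bin_edges_cM length-bin edges.
#' @return list with `mean_sharing` (bins x deciles matrix), `n_pairs`
#'   (pairs per decile) and `decile_breaks_km`.
#' @export
ibd_distance_summary <- function(ibd, coords, bin_edges_cM = c(1, 2, 7, 15)) {
  n <- nrow(coords)
  ids <- rownames(coords)
  to_index <- function(x) {
    if (is.numeric(x)) {
      if (any(x < 1 | x > n)) stop("unknown sample index in IBD table")
      as.integer(x)
    } else {
      i <- match(x, ids)
      if (anyNA(i)) stop("unknown sample id in IBD table: ",
                         x[which(is.na(i))[1]])
      i
    }
  }
  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  d <- haversine_km(coords$lat[pr[, 1]], coords$lon[pr[, 1]],
                    coords$lat[pr[, 2]], coords$lon[pr[, 2]])
  breaks <- stats::quantile(d, probs = seq(0, 1, 0.1), names = FALSE)
  breaks[1] <- -Inf; breaks[length(breaks)] <- Inf
  decile <- cut(d, breaks, labels = FALSE)
  pair_id <- (pmin(pr[, 1], pr[, 2]) - 1) * n + pmax(pr[, 1], pr[, 2])
  nb <- length(bin_edges_cM) - 1L
  counts <- matrix(0, nrow = nb, ncol = 10,
                   dimnames = list(paste0(bin_edges_cM[-length(bin_edges_cM)],
                                          "-", bin_edges_cM[-1], "cM"),
                                   paste0("D", 1:10)))
  n_pairs <- tabulate(decile, nbins = 10)
  if (nrow(ibd)) {
    i1 <- to_index(ibd$id1); i2 <- to_index(ibd$id2)
    if (any(i1 == i2)) stop("IBD table contains self pairs")
    sid <- (pmin(i1, i2) - 1) * n + pmax(i1, i2)
    dec_seg <- decile[match(sid, pair_id)]
    lb <- cut(ibd$length_cM, bin_edges_cM, labels = FALSE,
              include.lowest = TRUE)
    ok <- !is.na(lb)
    tab <- table(factor(lb[ok], levels = seq_len(nb)),
                 factor(dec_seg[ok], levels = 1:10))
    counts <- counts + unclass(tab)
  }
  mean_sharing <- sweep(counts, 2, pmax(n_pairs, 1), "/")
  mean_sharing[, n_pairs == 0] <- 0
  list(mean_sharing = mean_sharing, n_pairs = n_pairs,
       decile_breaks_km = stats::quantile(d, probs = seq(0, 1, 0.1),
                                          names = FALSE))
}
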