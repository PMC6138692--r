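#' Build per-gene variant groups for burden testing
#'
#' For every gene with qualifying variants, up to three groups are formed:
#' LOF, nonsynonymous, and combined (their union). Variants with cohort
#' MAF at or above `maf_max` are excluded; empty groups are omitted and
#' counted.
#'
#' @param cohort a `geo_cohort` with gene and functional-class labels.
#' @param maf_max MAF ceiling (default 0.05).
#' @return list of class `gene_groups`: elements are groups with
#'   `gene_id`, `functional_group`, `variant_idx`, `maf`, `control_maf`;
#'   attribute `n_empty` counts omitted groups.
#' @export
build_groups <- function(cohort, maf_max = 0.05) {
  v <- cohort$variants
  maf <- cohort_maf(cohort)
  ctrl <- cohort$samples$status == 0
  control_maf <- if (any(ctrl))
    cohort_maf(cohort$genotypes[ctrl, , drop = FALSE]) else rep(NA_real_, nrow(v))
  qual <- !is.na(v$gene_id) & !is.nan(maf) & maf > 0 & maf < maf_max
  genes <- unique(v$gene_id[qual])
  groups <- list()
  n_empty <- 0L
  for (gene in genes) {
    in_gene <- which(qual & v$gene_id == gene)
    cls <- v$functional_class[in_gene]
    sets <- list(LOF = in_gene[cls == "LOF"],
                 nonsynonymous = in_gene[cls == "nonsynonymous"],
                 combined = in_gene[cls %in% c("LOF", "nonsynonymous")])
    for (fg in names(sets)) {
      idx <- sets[[fg]]
      if (!length(idx)) { n_empty <- n_empty + 1L; next }
      groups[[length(groups) + 1L]] <- list(
        gene_id = gene, functional_group = fg, variant_idx = idx,
        maf = maf[idx], control_maf = control_maf[idx])
    }
  }
  structure(groups, class = "gene_groups", n_empty = n_empty)
}

# group genotype matrix, missing entries mean-imputed per variant
.group_matrix <- function(cohort, idx) {
  G <- cohort$genotypes[, idx, drop = FALSE]
  storage.mode(G) <- "double"
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    na_idx <- which(is.na(G), arr.ind = TRUE)
    G[na_idx] <- mu[na_idx[, 2]]
  }
  G
}

.burden_result <- function(group, test, statistic, p, n_variants,
                           n_permutations = NA_integer_,
                           direction = NA_real_) {
  data.frame(gene_id = group$gene_id,
             functional_group = group$functional_group,
             test = test, statistic = statistic, p_value = p,
             n_variants = n_variants, n_permutations = n_permutations,
             direction = direction)
}

#' Collapse (T1 / T5) burden test
#'
#' Sums dosages over variants with MAF below `maf_threshold` into one
#' burden score per sample and score-tests it against the null model,
#' exactly as a single variant would be tested.
#'
#' @param cohort a `geo_cohort`.
#' @param group a group from [build_groups()].
#' @param null_model a `null_model`.
#' @param maf_threshold 0.01 for T1, 0.05 for T5.
#' @param test label recorded in the result.
#' @return one-row `BurdenResult` data.frame.
#' @export
collapse_score_test <- function(cohort, group, null_model,
                                maf_threshold = 0.05,
                                test = if (maf_threshold <= 0.01) "T1" else "T5") {
  sel <- group$maf < maf_threshold
  if (!any(sel))
    return(.burden_result(group, test, NA_real_, NA_real_, 0L))
  G <- .group_matrix(cohort, group$variant_idx[sel])
  b <- rowSums(G)
  st <- .score_stats(matrix(b, ncol = 1), null_model)
  .burden_result(group, test, st$stat, st$p, sum(sel),
                 direction = sign(st$u))
}

#' Madsen-Browning weighted burden test
#'
#' Weighted burden b_j = sum_i w_i g_ij with
#' w_i = 1 / sqrt(n_ctrl q_i (1 - q_i)),
#' q_i = (control minor-allele count + 1) / (2 n_ctrl + 2),
#' score-tested against the null model. With equal control MAFs the weights
#' are constant and the test reduces to the plain collapse test.
#'
#' @inheritParams collapse_score_test
#' @return one-row `BurdenResult` data.frame.
#' @export
madsen_browning_test <- function(cohort, group, null_model) {
  ctrl <- cohort$samples$status == 0
  n_ctrl <- sum(ctrl)
  if (n_ctrl == 0) stop("Madsen-Browning weights need at least one control")
  if (!length(group$variant_idx))
    return(.burden_result(group, "MB", NA_real_, NA_real_, 0L))
  G <- .group_matrix(cohort, group$variant_idx)
  cnt <- colSums(cohort$genotypes[ctrl, group$variant_idx, drop = FALSE],
                 na.rm = TRUE)
  q <- (cnt + 1) / (2 * n_ctrl + 2)
  w <- 1 / sqrt(n_ctrl * q * (1 - q))
  b <- drop(G %*% w)
  st <- .score_stats(matrix(b, ncol = 1), null_model)
  .burden_result(group, "MB", st$stat, st$p, length(w),
                 direction = sign(st$u))
}

#' Variable-threshold burden test
#'
#' Candidate thresholds are the distinct member MAFs; at each threshold t
#' the burden over variants with MAF <= t is score-tested and standardized
#' (z_t = U_t / sqrt(V_t)). The statistic is max_t |z_t|; its p-value comes
#' from B permutations of the null-model residuals,
#' p = (1 + #\{perm >= observed\}) / (B + 1).
#'
#' @inheritParams collapse_score_test
#' @param B number of permutations (>= 100).
#' @param seed RNG seed for the permutations.
#' @return one-row `BurdenResult` data.frame.
#' @export
variable_threshold_test <- function(cohort, group, null_model, B = 1000,
                                    seed = NULL) {
  if (B < 100) stop("need at least 100 permutations")
  if (!length(group$variant_idx))
    return(.burden_result(group, "VT", NA_real_, NA_real_, 0L, B))
  G <- .group_matrix(cohort, group$variant_idx)
  thr <- sort(unique(group$maf))
  Bt <- vapply(thr, function(t) rowSums(G[, group$maf <= t, drop = FALSE]),
               numeric(nrow(G)))
  st <- .score_stats(Bt, null_model)
  ok <- st$v > 1e-12
  if (!any(ok))
    return(.burden_result(group, "VT", NA_real_, NA_real_,
                          length(group$variant_idx), B))
  sv <- sqrt(st$v[ok])
  obs <- max(abs(st$u[ok]) / sv)
  perm_max <- with_seed(seed, {
    n <- nrow(G)
    P <- vapply(seq_len(B), function(b) null_model$residuals[sample.int(n)],
                numeric(n))
    U <- crossprod(Bt[, ok, drop = FALSE], P)      # thresholds x B
    apply(abs(U) / sv, 2, max)
  })
  p <- (1 + sum(perm_max >= obs)) / (B + 1)
  .burden_result(group, "VT", obs, p, length(group$variant_idx), B)
}

#' Sequence kernel association test (SKAT)
#'
#' Variance-component score statistic Q = (y - yhat)' G W^2 G' (y - yhat)
#' with diagonal weights W (default the Beta(1, 25) density evaluated at
#' each variant's MAF). Under the null Q is distributed as a mixture
#' sum_l lambda_l chi^2_1 where lambda_l are the eigenvalues of
#' W G' P0 G W, P0 the variance-weighted projection orthogonal to the
#' covariates. The tail probability is computed by numerical inversion of
#' the characteristic function, falling back to Liu-type moment matching
#' when the integration is unstable.
#'
#' @inheritParams collapse_score_test
#' @param weight_scheme `"beta"` (Beta(1,25) density), `"mb"`
#'   (Madsen-Browning) or `"flat"` (unit weights).
#' @param p_method `"integration"` or `"liu"`.
#' @return one-row `BurdenResult` data.frame.
#' @export
skat_test <- function(cohort, group, null_model,
                      weight_scheme = c("beta", "mb", "flat"),
                      p_method = c("integration", "liu")) {
  weight_scheme <- match.arg(weight_scheme)
  p_method <- match.arg(p_method)
  if (!length(group$variant_idx))
    return(.burden_result(group, "SKAT", NA_real_, NA_real_, 0L))
  G <- .group_matrix(cohort, group$variant_idx)
  w <- switch(weight_scheme,
              beta = stats::dbeta(group$maf, 1, 25),
              mb = {
                ctrl <- cohort$samples$status == 0
                cnt <- colSums(cohort$genotypes[ctrl, group$variant_idx,
                                                drop = FALSE], na.rm = TRUE)
                q <- (cnt + 1) / (2 * sum(ctrl) + 2)
                1 / sqrt(sum(ctrl) * q * (1 - q))
              },
              flat = rep(1, length(group$variant_idx)))
  GW <- sweep(G, 2, w, "*")
  q_stat <- sum(drop(crossprod(GW, null_model$residuals))^2)
  # eigenvalues of W G' P0 G W without forming the n x n projection
  V <- null_model$weights
  VGW <- GW * V
  XtVGW <- crossprod(null_model$X, VGW)
  M <- crossprod(GW, VGW) - crossprod(XtVGW, null_model$XtWX_inv %*% XtVGW)
  lambda <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  lambda <- lambda[lambda > max(lambda, 0) * 1e-10 & lambda > 0]
  if (!length(lambda))
    return(.burden_result(group, "SKAT", q_stat, NA_real_,
                          length(group$variant_idx)))
  p <- pmixchisq(q_stat, lambda, method = p_method)
  .burden_result(group, "SKAT", q_stat, p, length(group$variant_idx))
}

#' Tail probability of a positive mixture of 1-df chi-squares
#'
#' P(sum_l lambda_l chi^2_1 > q), by Imhof-type numerical inversion of the
#' characteristic function (`"integration"`) or Liu et al. moment matching
#' on a non-central chi-square (`"liu"`). Integration falls back to the
#' moment approximation when the quadrature fails or returns a value
#' outside (0, 1).
#'
#' @param q observed statistic.
#' @param lambda positive mixture weights.
#' @param method `"integration"` or `"liu"`.
#' @return upper-tail probability in (0, 1].
#' @export
pmixchisq <- function(q, lambda, method = c("integration", "liu")) {
  method <- match.arg(method)
  stopifnot(length(lambda) >= 1, all(lambda > 0), q >= 0)
  if (method == "liu") return(.pmix_liu(q, lambda))
  f <- function(u) {
    theta <- 0.5 * colSums(atan(outer(lambda, u))) - 0.5 * q * u
    rho <- exp(0.25 * colSums(log1p(outer(lambda^2, u^2))))
    sin(theta) / (u * rho)
  }
  val <- tryCatch(
    stats::integrate(f, 0, Inf, subdivisions = 5000L,
                     rel.tol = 1e-10, abs.tol = 1e-12,
                     stop.on.error = FALSE)$value,
    error = function(e) NA_real_)
  p <- 0.5 + val / pi
  if (!is.finite(p) || p <= 1e-12 || p > 1) p <- .pmix_liu(q, lambda)
  min(1, max(p, 1e-14))
}

# Liu, Tang & Zhang moment-matching approximation (modified, 2009)
.pmix_liu <- function(q, lambda) {
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5; s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    l <- a^2 - 2 * delta
  } else {
    a <- 1 / sqrt(s2)
    delta <- 0
    l <- 1 / s2
  }
  mu_q <- c1; sigma_q <- sqrt(2 * c2)
  mu_x <- l + delta; sigma_x <- sqrt(2) * a
  t_star <- (q - mu_q) / sigma_q * sigma_x + mu_x
  min(1, max(stats::pchisq(t_star, df = l, ncp = delta, lower.tail = FALSE),
             1e-14))
}

#' Run the full gene x group x test burden scan
#'
#' Deterministic ordering (genes in group order, then functional group,
#' then test); VT permutation seeds are derived from the master seed and
#' the gene id so reruns are bit-identical.
#'
#' @param cohort a `geo_cohort`.
#' @param null_model a `null_model` fitted on the same samples.
#' @param groups a `gene_groups` list (built from the cohort if missing).
#' @param tests subset of `c("T1", "T5", "MB", "VT", "SKAT")`.
#' @param B_vt VT permutation count.
#' @param seed master seed for VT permutations.
#' @return data.frame of `BurdenResult` rows.
#' @export
run_burden_scan <- function(cohort, null_model, groups = NULL,
                            tests = c("T1", "T5", "MB", "VT", "SKAT"),
                            B_vt = 1000, seed = 1L) {
  tests <- match.arg(tests, several.ok = TRUE)
  if (is.null(groups)) groups <- build_groups(cohort)
  out <- vector("list", length(groups) * length(tests))
  k <- 0L
  for (gr in groups) {
    for (tst in tests) {
      k <- k + 1L
      out[[k]] <- switch(tst,
        T1 = collapse_score_test(cohort, gr, null_model, 0.01, "T1"),
        T5 = collapse_score_test(cohort, gr, null_model, 0.05, "T5"),
        MB = madsen_browning_test(cohort, gr, null_model),
        VT = variable_threshold_test(
          cohort, gr, null_model, B = B_vt,
          seed = substream_seed(seed, paste0("vt:", gr$gene_id, ":",
                                             gr$functional_group))),
        SKAT = skat_test(cohort, gr, null_model))
    }
  }
  do.call(rbind, out)
}

#' Bonferroni significance threshold
#'
#' alpha / (n_genes x n_tests); with 20,000 genes and 5 burden tests at
#' alpha = 0.05 this is the exome-wide 5e-7, and with one test over a
#' million independent common variants it is the genome-wide 5e-8.
#'
#' @param n_genes,n_tests positive counts.
#' @param alpha family-wise error budget.
#' @return the per-test significance threshold.
#' @export
#' @examples
#' bonferroni_threshold(20000, 5, 0.05)  # 5e-7
bonferroni_threshold <- function(n_genes, n_tests, alpha = 0.05) {
  if (n_genes <= 0 || n_tests <= 0) stop("counts must be positive")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  alpha / (n_genes * n_tests)
}
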