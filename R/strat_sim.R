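#' Scenario configuration for the type-I-error calibration engine
#'
#' @param scenario `"perfect"` or `"imperfect"` geographic matching.
#' @param n_replicates number of simulated null phenotypes (>= 20).
#' @param gradient_strength North-to-South case-weight gradient used by the
#'   imperfect scenario.
#' @param tests burden tests to run per replicate.
#' @param covariate_mode `"none"` or `"pcs"` (ten common-variant PCs).
#' @param alpha study-wise type-I-error budget.
#' @param pc_maf_min MAF floor for the common-variant PCs (0.001, i.e.
#'   MAF > 0.1 percent).
#' @param B_vt VT permutation count inside the simulation loop (kept small
#'   for cost; VT threshold cells are resolution-limited below 1/(B+1)).
#' @param seed master seed.
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(scenario = c("perfect", "imperfect"),
                            n_replicates = 100L,
                            gradient_strength = 2,
                            tests = "T1",
                            covariate_mode = c("none", "pcs"),
                            alpha = 0.05,
                            pc_maf_min = 0.001,
                            B_vt = 200L,
                            seed = 1L) {
  scenario <- match.arg(scenario)
  covariate_mode <- match.arg(covariate_mode)
  if (n_replicates < 20) stop("n_replicates must be >= 20")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  structure(list(scenario = scenario,
                 n_replicates = as.integer(n_replicates),
                 gradient_strength = gradient_strength,
                 tests = tests, covariate_mode = covariate_mode,
                 alpha = alpha, pc_maf_min = pc_maf_min,
                 B_vt = as.integer(B_vt), seed = as.integer(seed)),
            class = "scenario_config")
}

#' Simulate null phenotype replicates under a matching scenario
#'
#' Each row is one replicate of case/control labels drawn by
#' [simulate_phenotype_scenario()]; case and control totals are identical
#' across replicates.
#'
#' @param cohort a `geo_cohort` with birthplace coordinates.
#' @param config a `scenario_config`.
#' @param map the `spatial_map` fixing the latitude extremes.
#' @return integer matrix (n_replicates x n_samples) of 0/1 labels.
#' @export
simulate_null_replicates <- function(cohort, config, map = spatial_map()) {
  coords <- cohort$samples[, c("lat", "lon")]
  n_cases <- sum(cohort$samples$status == 1)
  t(vapply(seq_len(config$n_replicates), function(r)
    simulate_phenotype_scenario(
      coords, n_cases, config$scenario, config$gradient_strength, map,
      seed = substream_seed(config$seed, paste0("replicate:", r))),
    integer(nrow(coords))))
}

# Precompute per-(gene, group, test) burden score vectors for the
# weighted-collapse family so the replicate loop is a matrix product.
.burden_basis <- function(cohort, groups, tests) {
  cols <- list(); meta <- list()
  ctrl <- cohort$samples$status == 0
  for (gi in seq_along(groups)) {
    gr <- groups[[gi]]
    G <- .group_matrix(cohort, gr$variant_idx)
    for (tst in intersect(tests, c("T1", "T5", "MB"))) {
      b <- switch(tst,
        T1 = { sel <- gr$maf < 0.01
               if (!any(sel)) next
               rowSums(G[, sel, drop = FALSE]) },
        T5 = { sel <- gr$maf < 0.05
               if (!any(sel)) next
               rowSums(G[, sel, drop = FALSE]) },
        MB = { cnt <- colSums(cohort$genotypes[ctrl, gr$variant_idx,
                                               drop = FALSE], na.rm = TRUE)
               q <- (cnt + 1) / (2 * sum(ctrl) + 2)
               drop(G %*% (1 / sqrt(sum(ctrl) * q * (1 - q)))) })
      cols[[length(cols) + 1L]] <- b
      meta[[length(meta) + 1L]] <- data.frame(
        gene_id = gr$gene_id, functional_group = gr$functional_group,
        test = tst)
    }
  }
  list(B = if (length(cols)) do.call(cbind, cols) else NULL,
       meta = if (length(meta)) do.call(rbind, meta) else NULL)
}

#' Minimum burden p-value per null replicate
#'
#' For every replicate the null model is refitted on that replicate's
#' phenotype (with the ten common-variant PCs as covariates when
#' `covariate_mode = "pcs"`), the burden scan is run over the groups, and
#' the smallest p-value across genes is recorded per test. The
#' weighted-collapse tests (T1/T5/MB) share a vectorized path; VT and SKAT
#' are evaluated per gene.
#'
#' @param cohort a `geo_cohort`.
#' @param phenotypes replicate x sample 0/1 matrix from
#'   [simulate_null_replicates()].
#' @param groups a `gene_groups` list; defaults to the LOF and
#'   nonsynonymous groups of the cohort.
#' @param tests tests to run.
#' @param covariate_mode `"none"` or `"pcs"`.
#' @param pc_maf_min MAF floor for the common-variant PCs.
#' @param B_vt VT permutation count.
#' @param seed master seed for VT permutations.
#' @return data.frame with one row per replicate and one column per test.
#' @export
minima_per_replicate <- function(cohort, phenotypes, groups = NULL,
                                 tests = "T1",
                                 covariate_mode = c("none", "pcs"),
                                 pc_maf_min = 0.001, B_vt = 200L,
                                 seed = 1L) {
  covariate_mode <- match.arg(covariate_mode)
  if (is.null(groups)) {
    groups <- build_groups(cohort)
    groups <- structure(
      Filter(function(g) g$functional_group %in% c("LOF", "nonsynonymous"),
             groups),
      class = "gene_groups")
  }
  covs <- NULL
  if (covariate_mode == "pcs") {
    pcs <- pca(compute_grm(cohort, maf_min = pc_maf_min), k = 10)
    covs <- pcs$vectors
  }
  fast <- .burden_basis(cohort, groups, tests)
  slow_tests <- intersect(tests, c("VT", "SKAT"))
  out <- matrix(NA_real_, nrow = nrow(phenotypes), ncol = length(tests),
                dimnames = list(NULL, tests))
  for (r in seq_len(nrow(phenotypes))) {
    nm <- fit_null_logistic(phenotypes[r, ], covs)
    if (!is.null(fast$B)) {
      st <- .score_stats(fast$B, nm)
      for (tst in intersect(tests, unique(fast$meta$test)))
        out[r, tst] <- min(st$p[fast$meta$test == tst], na.rm = TRUE)
    }
    for (tst in slow_tests) {
      pv <- vapply(seq_along(groups), function(gi) {
        gr <- groups[[gi]]
        res <- if (tst == "VT")
          variable_threshold_test(
            cohort, gr, nm, B = B_vt,
            seed = substream_seed(seed, paste0("vt:", r, ":", gr$gene_id,
                                               ":", gr$functional_group)))
        else skat_test(cohort, gr, nm)
        res$p_value
      }, numeric(1))
      out[r, tst] <- min(pv, na.rm = TRUE)
    }
  }
  as.data.frame(out)
}

#' Family-wise error threshold from per-replicate minima
#'
#' The k-th smallest of the per-replicate minimum p-values with
#' k = max(1, floor(alpha * n)); for 100 replicates at alpha = 0.05 this is
#' the fifth-most extreme p-value, the threshold that holds the study-wise
#' type-I error at 5 percent.
#'
#' @param minima vector of per-replicate minimum p-values.
#' @param alpha error budget.
#' @return the threshold.
#' @export
fwer_threshold <- function(minima, alpha = 0.05) {
  minima <- minima[!is.na(minima)]
  if (!length(minima)) stop("no minima supplied")
  if (length(minima) < 1 / alpha)
    warning("fewer than 1/alpha replicates: threshold is coarse")
  k <- max(1L, floor(alpha * length(minima)))
  sort(minima)[k]
}

#' Run one full calibration scenario
#'
#' Simulates the null replicates, extracts per-replicate minima for each
#' configured test, and derives the FWER threshold per test.
#'
#' @param cohort a `geo_cohort`.
#' @param config a `scenario_config`.
#' @param groups optional pre-built `gene_groups`.
#' @param map a `spatial_map`.
#' @return object of class `scenario_report` with `minima` (data.frame),
#'   `thresholds` (named vector), and the configuration.
#' @export
run_scenario <- function(cohort, config, groups = NULL, map = spatial_map()) {
  phen <- simulate_null_replicates(cohort, config, map)
  minima <- minima_per_replicate(cohort, phen, groups,
                                 tests = config$tests,
                                 covariate_mode = config$covariate_mode,
                                 pc_maf_min = config$pc_maf_min,
                                 B_vt = config$B_vt, seed = config$seed)
  thresholds <- vapply(minima, fwer_threshold, numeric(1),
                       alpha = config$alpha)
  structure(list(minima = minima, thresholds = thresholds, config = config),
            class = "scenario_report")
}

#' Compare perfect and imperfect matching scenario reports
#'
#' @param report_perfect,report_imperfect `scenario_report` objects with
#'   identical test sets and covariate modes.
#' @return data.frame with per-test thresholds for both scenarios and their
#'   imperfect/perfect ratio.
#' @export
compare_scenarios <- function(report_perfect, report_imperfect) {
  tp <- report_perfect$thresholds
  ti <- report_imperfect$thresholds
  if (!identical(names(tp), names(ti)) ||
      report_perfect$config$covariate_mode !=
      report_imperfect$config$covariate_mode)
    stop("scenario reports have mismatched test/covariate grids")
  data.frame(test = names(tp),
             covariate_mode = report_perfect$config$covariate_mode,
             threshold_perfect = unname(tp),
             threshold_imperfect = unname(ti),
             ratio = unname(ti / tp))
}

#' Calibrate and evaluate the family-wise error threshold
#'
#' The full calibration experiment in one call: simulate `n_calib` null
#' phenotype replicates under perfect matching, record the minimum burden
#' p-value per replicate over the LOF and nonsynonymous gene groups, take
#' the floor(alpha n)-th smallest as the study-wise threshold, then
#' estimate the achieved family-wise error rate as the fraction of
#' `n_eval` fresh, independently seeded null replicates whose minimum p
#' falls below that threshold.
#'
#' @param cohort a `geo_cohort`.
#' @param groups optional `gene_groups`; defaults to the cohort's LOF and
#'   nonsynonymous groups.
#' @param n_calib calibration replicates (default 100).
#' @param n_eval fresh evaluation replicates (default 500).
#' @param tests burden test(s); the first is used for the threshold.
#' @param alpha error budget.
#' @param covariate_mode `"none"` or `"pcs"`.
#' @param n_rounds number of independent calibration/evaluation rounds;
#'   the reported error rate is their mean.  One round is the literal
#'   procedure; the threshold from 100 replicates is itself a noisy order
#'   statistic (sd of the achieved rate about 2 percentage points), so
#'   averaging a few independent rounds estimates the same operating
#'   characteristic with less noise.
#' @param seed master seed; every round's calibration and evaluation use
#'   disjoint substreams.
#' @param map a `spatial_map`.
#' @return list with `threshold` (first round), `empirical_fwer` (percent,
#'   averaged over rounds), `per_round` (data.frame of per-round thresholds
#'   and rates), `minima_calib`, `minima_eval` (first round).
#' @export
calibrate_fwer <- function(cohort, groups = NULL, n_calib = 100L,
                           n_eval = 500L, tests = "T1", alpha = 0.05,
                           covariate_mode = "none", n_rounds = 1L,
                           seed = 1L, map = spatial_map()) {
  if (is.null(groups)) {
    groups <- build_groups(cohort)
    groups <- structure(
      Filter(function(g) g$functional_group %in% c("LOF", "nonsynonymous"),
             groups),
      class = "gene_groups")
  }
  test1 <- tests[1]
  rounds <- vector("list", n_rounds)
  first <- NULL
  for (i in seq_len(n_rounds)) {
    sr <- substream_seed(seed, paste0("round:", i))
    cfg_cal <- scenario_config("perfect", n_replicates = n_calib,
                               tests = tests, alpha = alpha,
                               seed = substream_seed(sr, "fwer_calibration"))
    cfg_ev <- scenario_config("perfect", n_replicates = n_eval,
                              tests = tests, alpha = alpha,
                              seed = substream_seed(sr, "fwer_evaluation"))
    ph_cal <- simulate_null_replicates(cohort, cfg_cal, map)
    ph_ev <- simulate_null_replicates(cohort, cfg_ev, map)
    m_cal <- minima_per_replicate(cohort, ph_cal, groups, tests = tests,
                                  covariate_mode = covariate_mode,
                                  seed = cfg_cal$seed)[[test1]]
    m_ev <- minima_per_replicate(cohort, ph_ev, groups, tests = tests,
                                 covariate_mode = covariate_mode,
                                 seed = cfg_ev$seed)[[test1]]
    thr <- fwer_threshold(m_cal, alpha)
    rounds[[i]] <- data.frame(round = i, threshold = thr,
                              empirical_fwer = 100 * mean(m_ev < thr))
    if (i == 1L) first <- list(m_cal = m_cal, m_ev = m_ev, thr = thr)
  }
  per_round <- do.call(rbind, rounds)
  list(threshold = first$thr,
       empirical_fwer = mean(per_round$empirical_fwer),
       per_round = per_round,
       minima_calib = first$m_cal, minima_eval = first$m_ev)
}
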