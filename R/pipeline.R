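#' Pipeline configuration
#'
#' Nested configuration for [run_pipeline()]. Unknown keys are rejected so
#' typos fail before any stage runs. All analysis defaults live here: MAF
#' cutoffs 0.005 (single-variant floor), 0.01/0.05 (T1/T5), ten covariate
#' PCs, twenty birthplace PCs, 100 calibration replicates, alpha 0.05 and
#' the 5 percent frequency-difference merge filter.
#'
#' @param sim a `sim_config`.
#' @param qc a `qc_config`.
#' @param grm_maf_thresholds MAF grid for the birthplace-prediction
#'   comparison.
#' @param n_pcs_covariate,n_pcs_birthplace PC counts for adjustment and for
#'   birthplace regression.
#' @param assoc_maf_min single-variant MAF floor.
#' @param n_replicates calibration replicates per scenario.
#' @param alpha FWER budget.
#' @param max_freq_diff merge frequency filter.
#' @param seed master seed (overrides `sim$seed`).
#' @param out_dir output directory.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), qc = qc_config(),
                            grm_maf_thresholds = c(0.1, 0.01, 0.001),
                            n_pcs_covariate = 10L, n_pcs_birthplace = 20L,
                            assoc_maf_min = 0.005, n_replicates = 100L,
                            alpha = 0.05, max_freq_diff = 0.05,
                            seed = 1L, out_dir = "geostrat_out") {
  structure(list(sim = sim, qc = qc,
                 grm_maf_thresholds = grm_maf_thresholds,
                 n_pcs_covariate = as.integer(n_pcs_covariate),
                 n_pcs_birthplace = as.integer(n_pcs_birthplace),
                 assoc_maf_min = assoc_maf_min,
                 n_replicates = as.integer(n_replicates),
                 alpha = alpha, max_freq_diff = max_freq_diff,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' Top-level keys must be arguments of [pipeline_config()]; the `sim` and
#' `qc` sections take the arguments of [sim_config()] and [qc_config()].
#'
#' @param path JSON file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(raw$sim)) {
    bad <- setdiff(names(raw$sim), names(formals(sim_config)))
    if (length(bad)) stop("unknown sim key(s): ", paste(bad, collapse = ", "))
    raw$sim <- do.call(sim_config, raw$sim)
  }
  if (!is.null(raw$qc)) {
    bad <- setdiff(names(raw$qc), names(formals(qc_config)))
    if (length(bad)) stop("unknown qc key(s): ", paste(bad, collapse = ", "))
    raw$qc <- do.call(qc_config, raw$qc)
  }
  do.call(pipeline_config, raw)
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.stage_done <- function(manifest, stage, files) {
  !is.null(manifest$stages[[stage]]) && all(file.exists(files))
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> QC -> PCA/birthplace -> single-variant scan ->
#' burden scan -> stratification calibration -> external-control merge, in
#' order, writing each stage's outputs plus a manifest recording the seed,
#' stage versions and output hashes. Stages whose outputs already exist
#' (per the manifest) are skipped, so the pipeline is resumable after
#' deleting any stage's files.
#'
#' @param config a `pipeline_config` or path to a JSON configuration.
#' @param quiet suppress progress messages.
#' @return the output directory, invisibly; side effect: files + manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  mpath <- file.path(config$out_dir, "manifest.json")
  manifest <- if (file.exists(mpath)) jsonlite::read_json(mpath)
              else list(seed = config$seed, stages = list())
  say <- function(...) if (!quiet) message("[geostrat] ", ...)
  record <- function(stage, files) {
    manifest$stages[[stage]] <<- list(
      files = as.list(files),
      md5 = as.list(unname(tools::md5sum(files))),
      time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
    jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  }
  out <- function(...) file.path(config$out_dir, ...)
  config$sim$seed <- config$seed
  map <- spatial_map()

  ## stage 1: simulate
  f1 <- out(c("cohort.vcf", "samples.tsv", "groups.tsv", "external.vcf",
              "external_samples.tsv", "ibd.tsv"))
  study <- simulate_study(config$sim, map)
  if (!.stage_done(manifest, "simulate", f1)) {
    say("simulate: ", n_samples(study$internal), " internal + ",
        n_samples(study$external), " external samples")
    write_vcf(study$internal, f1[1])
    write_samples(study$internal$samples, f1[2])
    v <- study$internal$variants
    write_groups(v[!is.na(v$gene_id),
                   c("gene_id", "variant_id", "functional_class")], f1[3])
    write_vcf(study$external, f1[4])
    write_samples(study$external$samples, f1[5])
    ibd <- simulate_ibd_segments(
      study$internal$samples[, c("lat", "lon")],
      config$sim$ibd_bin_edges_cM, config$sim$ibd_params, map,
      seed = substream_seed(config$seed, "ibd"))
    write_ibd(ibd, f1[6])
    record("simulate", f1)
  } else say("simulate: up to date, skipping")

  ## stage 2: QC
  f2 <- out(c("qc_samples.tsv", "qc_variants.tsv"))
  sq <- run_sample_qc(study$internal, config$qc)
  vq <- run_variant_qc(sq$cohort, config$qc)
  cohort <- vq$cohort
  if (!.stage_done(manifest, "qc", f2)) {
    say("qc: ", n_samples(cohort), " samples, ", n_variants(cohort),
        " variants pass")
    .write_tsv(sq$report$steps, f2[1])
    .write_tsv(vq$report$steps, f2[2])
    record("qc", f2)
  } else say("qc: up to date, skipping")

  ## stage 3: PCA + birthplace prediction across the MAF grid
  f3 <- out(c("pcs.tsv", "birthplace.tsv", "ibd_summary.tsv"))
  grm <- compute_grm(cohort, maf_min = min(config$grm_maf_thresholds))
  pc <- pca(grm, k = config$n_pcs_birthplace)
  if (!.stage_done(manifest, "popstructure", f3)) {
    coords <- cohort$samples[, c("lat", "lon")]
    bp <- lapply(config$grm_maf_thresholds, function(t) {
      p <- pca(compute_grm(cohort, maf_min = t), k = config$n_pcs_birthplace)
      pred <- predict_birthplace_loo(p, coords, k = config$n_pcs_birthplace)
      data.frame(maf_min = t, median_error_km = pred$median_error_km)
    })
    say("popstructure: median birthplace errors ",
        paste(sprintf("%.1f", vapply(bp, `[[`, numeric(1),
                                     "median_error_km")), collapse = " / "),
        " km across MAF grid")
    .write_tsv(cbind(sample_id = cohort$samples$sample_id,
                     as.data.frame(pc$vectors)), f3[1])
    .write_tsv(do.call(rbind, bp), f3[2])
    ibd <- read_ibd(out("ibd.tsv"))
    # ids are indices into the pre-QC internal cohort
    keep <- match(cohort$samples$sample_id, study$internal$samples$sample_id)
    sel <- ibd$id1 %in% keep & ibd$id2 %in% keep
    remap <- match(seq_len(n_samples(study$internal)), keep)
    ibd_sum <- ibd_distance_summary(
      data.frame(id1 = remap[ibd$id1[sel]], id2 = remap[ibd$id2[sel]],
                 length_cM = ibd$length_cM[sel]),
      cohort$samples[, c("lat", "lon")], config$sim$ibd_bin_edges_cM)
    .write_tsv(as.data.frame(ibd_sum$mean_sharing), f3[3])
    record("popstructure", f3)
  } else say("popstructure: up to date, skipping")

  ## stage 4: single-variant scan
  f4 <- out("assoc.tsv")
  sex01 <- as.numeric(cohort$samples$sex == "F")
  covs <- cbind(sex = sex01, pc$vectors[, seq_len(config$n_pcs_covariate)])
  nm <- fit_null_logistic(cohort$samples$status, covs)
  if (!.stage_done(manifest, "assoc", f4)) {
    scan <- gw_scan(cohort, nm, maf_min = config$assoc_maf_min)
    say("assoc: ", nrow(scan), " variants tested, lambda = ",
        sprintf("%.2f", genomic_lambda(scan$p_value)))
    .write_tsv(scan, f4)
    record("assoc", f4)
  } else say("assoc: up to date, skipping")

  ## stage 5: burden scan
  f5 <- out("burden.tsv")
  groups <- build_groups(cohort)
  if (!.stage_done(manifest, "burden", f5)) {
    burden <- run_burden_scan(cohort, nm, groups, seed = config$seed)
    say("burden: ", nrow(burden), " gene x group x test results")
    .write_tsv(burden, f5)
    record("burden", f5)
  } else say("burden: up to date, skipping")

  ## stage 6: stratification calibration (both scenarios, T1)
  f6 <- out("strat_sim.tsv")
  if (!.stage_done(manifest, "strat_sim", f6)) {
    reps <- lapply(c("perfect", "imperfect"), function(sc)
      run_scenario(cohort,
                   scenario_config(sc, n_replicates = config$n_replicates,
                                   gradient_strength =
                                     config$sim$gradient_strength,
                                   alpha = config$alpha,
                                   seed = substream_seed(config$seed, sc)),
                   map = map))
    cmp <- compare_scenarios(reps[[1]], reps[[2]])
    say("strat-sim: thresholds ",
        paste(sprintf("%.2e", cmp$threshold_perfect), collapse = " "),
        " (perfect) vs ",
        paste(sprintf("%.2e", cmp$threshold_imperfect), collapse = " "),
        " (imperfect)")
    .write_tsv(cmp, f6)
    record("strat_sim", f6)
  } else say("strat-sim: up to date, skipping")

  ## stage 7: external-control merge experiment
  f7 <- out("merge_report.json")
  if (!.stage_done(manifest, "merge_external", f7)) {
    mg <- merge_cohorts(cohort, study$external)
    sep_before <- assess_separation(mg$cohort)$separation
    scan_before <- external_control_scan(mg$cohort)
    filt <- freq_diff_filter(mg$cohort, config$max_freq_diff)
    sep_after <- assess_separation(filt$cohort)$separation
    scan_after <- external_control_scan(filt$cohort)
    report <- list(n_shared = mg$n_shared,
                   n_removed_freq_filter = length(filt$removed),
                   separation_before = sep_before,
                   separation_after = sep_after,
                   lambda_single_before = scan_before$lambda_single,
                   lambda_single_after = scan_after$lambda_single,
                   lambda_burden_before = scan_before$lambda_burden,
                   lambda_burden_after = scan_after$lambda_burden)
    say("merge-external: separation ", sprintf("%.2f", sep_before), " -> ",
        sprintf("%.2f", sep_after), "; lambda single ",
        sprintf("%.2f", report$lambda_single_before), ", burden ",
        sprintf("%.2f", report$lambda_burden_before))
    jsonlite::write_json(report, f7, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    record("merge_external", f7)
  } else say("merge-external: up to date, skipping")

  invisible(config$out_dir)
}

#' Generate the bundled miniature fixture cohort
#'
#' A deterministic 100-sample, 2,000-variant, 20-gene cohort used by the
#' unit tests: small enough to regenerate in seconds, structured enough to
#' exercise every pipeline stage.
#'
#' @param seed master seed.
#' @param dir optional directory; when given, the VCF, sample sheet and
#'   group file are written there.
#' @return the fixture `geo_cohort`.
#' @export
make_fixtures <- function(seed = 42L, dir = NULL) {
  cfg <- sim_config(n_cases = 66L, n_controls = 34L,
                    n_external_controls = 40L,
                    n_common_variants = 1500L, n_rare_variants = 500L,
                    n_genes = 20L, seed = seed)
  cohort <- simulate_cohort(cfg)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_vcf(cohort, file.path(dir, "fixture.vcf"))
    write_samples(cohort$samples, file.path(dir, "fixture_samples.tsv"))
    v <- cohort$variants
    write_groups(v[!is.na(v$gene_id),
                   c("gene_id", "variant_id", "functional_class")],
                 file.path(dir, "fixture_groups.tsv"))
  }
  cohort
}
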