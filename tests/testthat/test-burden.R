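test_that("build_groups partitions by functional class under the MAF ceiling", {
  n <- 60
  g <- matrix(0L, n, 6)
  g[1:2, 1] <- 1L; g[3, 2] <- 1L; g[4:5, 3] <- 1L
  g[6, 4] <- 1L; g[7, 5] <- 1L
  g[, 6] <- rep(c(0L, 1L), n / 2)       # MAF 0.25: above the 5% ceiling
  co <- toy_cohort(g)
  co$variants$gene_id <- c("A", "A", "A", "A", "A", "A")
  co$variants$functional_class <- c("LOF", "LOF", "nonsynonymous",
                                    "nonsynonymous", "nonsynonymous",
                                    "nonsynonymous")
  gr <- build_groups(co, maf_max = 0.05)
  fg <- vapply(gr, `[[`, character(1), "functional_group")
  sizes <- vapply(gr, function(x) length(x$variant_idx), integer(1))
  expect_setequal(fg, c("LOF", "nonsynonymous", "combined"))
  expect_equal(sizes[fg == "LOF"], 2L)
  expect_equal(sizes[fg == "nonsynonymous"], 3L)
  expect_equal(sizes[fg == "combined"], 5L)        # union, variant 6 excluded
  expect_false(6 %in% unlist(lapply(gr, `[[`, "variant_idx")))

  # gene with only "other" variants emits nothing
  co$variants$functional_class <- rep("other", 6)
  gr0 <- build_groups(co)
  expect_length(gr0, 0)
})

test_that("T5 on a single-variant group equals the single-variant score test", {
  co <- default_cohort()
  nm <- default_null()
  groups <- build_groups(co)
  one <- Filter(function(g) length(g$variant_idx) == 1, groups)[[1]]
  t5 <- collapse_score_test(co, one, nm, 0.05)
  sv <- score_test_variant(co$genotypes[, one$variant_idx], nm)
  expect_equal(t5$p_value, sv$p_value, tolerance = 1e-12)
  expect_equal(t5$test, "T5")

  # zero-variance burden: p missing
  z <- one; z$variant_idx <- which(colSums(co$genotypes, na.rm = TRUE) == 0)[1]
  if (!is.na(z$variant_idx)) {
    z$maf <- 0.001
    expect_true(is.na(collapse_score_test(co, z, nm, 0.05)$p_value))
  }
  # no qualifying variants below the threshold
  t1 <- collapse_score_test(co, one, nm, maf_threshold = 1e-9, test = "T1")
  expect_true(is.na(t1$p_value))
  expect_equal(t1$n_variants, 0L)
})

test_that("T1 ignores 1-5% variants; depletion shows a negative direction", {
  n <- 400
  g <- matrix(0L, n, 3)
  g[1:3, 1] <- 1L                      # MAF ~0.004
  g[4:6, 2] <- 1L
  g[seq(1, 24), 3] <- 1L               # MAF 0.03: in [0.01, 0.05)
  co <- toy_cohort(g, status = rep(c(1L, 0L), each = n / 2))
  nm <- fit_null_logistic(co$samples$status)
  gr <- build_groups(co)
  comb <- Filter(function(x) x$functional_group == "combined", gr)[[1]]
  t1_with <- collapse_score_test(co, comb, nm, 0.01, "T1")
  gr2 <- comb; keep <- gr2$maf < 0.01
  gr2$variant_idx <- gr2$variant_idx[keep]; gr2$maf <- gr2$maf[keep]
  t1_without <- collapse_score_test(co, gr2, nm, 0.01, "T1")
  expect_equal(t1_with$p_value, t1_without$p_value, tolerance = 1e-12)
  # T5 is NOT invariant to the 3% variant
  t5_with <- collapse_score_test(co, comb, nm, 0.05)
  t5_without <- collapse_score_test(co, gr2, nm, 0.05)
  expect_false(isTRUE(all.equal(t5_with$p_value, t5_without$p_value)))

  # all carriers controls: negative score direction
  gd <- matrix(0L, n, 1); gd[n/2 + (1:10), 1] <- 1L
  cod <- toy_cohort(gd, status = rep(c(1L, 0L), each = n / 2))
  nmd <- fit_null_logistic(cod$samples$status)
  grd <- list(gene_id = "G1", functional_group = "combined",
              variant_idx = 1L, maf = 10 / (2 * n), control_maf = 10 / n)
  expect_equal(collapse_score_test(cod, grd, nmd, 0.05)$direction, -1)
})

test_that("Madsen-Browning: weight formula and constant-weight equivalence", {
  # toy weight: n_ctrl = 4, control minor count 1 -> q = 2/10
  q <- (1 + 1) / (2 * 4 + 2)
  expect_equal(q, 2 / 10)
  w_expected <- 1 / sqrt(4 * q * (1 - q))

  n <- 8
  g <- matrix(0L, n, 1); g[c(1, 5), 1] <- 1L   # one case + one control carrier
  co <- toy_cohort(g, status = rep(c(1L, 0L), each = 4))
  nm <- fit_null_logistic(co$samples$status)
  gr <- list(gene_id = "G1", functional_group = "combined",
             variant_idx = 1L, maf = cohort_maf(co), control_maf = 1 / 8)
  mb <- madsen_browning_test(co, gr, nm)
  # single variant: weighting cannot change the p-value
  sv <- score_test_variant(g[, 1], nm)
  expect_equal(mb$p_value, sv$p_value, tolerance = 1e-10)

  # constant control MAF across variants: MB == plain collapse
  co2 <- default_cohort()
  nm2 <- default_null()
  ctrl <- co2$samples$status == 0
  cnt <- colSums(co2$genotypes[ctrl, , drop = FALSE], na.rm = TRUE)
  idx <- which(cnt == 2 & cohort_maf(co2) < 0.05 &
               co2$variants$chrom == "2")[1:5]
  gr2 <- list(gene_id = "X", functional_group = "combined",
              variant_idx = idx, maf = cohort_maf(co2)[idx],
              control_maf = cnt[idx] / (2 * sum(ctrl)))
  mb2 <- madsen_browning_test(co2, gr2, nm2)
  cl2 <- collapse_score_test(co2, gr2, nm2, 0.05)
  expect_equal(mb2$p_value, cl2$p_value, tolerance = 1e-10)

  # empty group and zero-control validation
  gr0 <- list(gene_id = "X", functional_group = "LOF",
              variant_idx = integer(0), maf = numeric(0),
              control_maf = numeric(0))
  expect_true(is.na(madsen_browning_test(co2, gr0, nm2)$p_value))
  co3 <- co2; co3$samples$status <- 1L
  expect_error(madsen_browning_test(co3, gr2, nm2), "control")
})

test_that("variable threshold: single-threshold identity and p lower bound", {
  co <- default_cohort()
  nm <- default_null()
  groups <- build_groups(co)
  # group whose members share one distinct MAF
  one <- Filter(function(g) length(unique(g$maf)) == 1, groups)[[1]]
  vt <- variable_threshold_test(co, one, nm, B = 200, seed = 5)
  cl <- collapse_score_test(co, one, nm, max(one$maf) + 1e-9)
  expect_equal(vt$statistic, sqrt(cl$statistic), tolerance = 1e-10)
  expect_gte(vt$p_value, 1 / 201)

  # determinism given seed
  vt2 <- variable_threshold_test(co, one, nm, B = 200, seed = 5)
  expect_identical(vt$p_value, vt2$p_value)
  expect_error(variable_threshold_test(co, one, nm, B = 50), "100")

  # p floor attained when the observed statistic dominates all permutations:
  # plant an extreme burden signal
  n <- 600
  g <- matrix(0L, n, 2)
  g[1:30, 1] <- 1L; g[31:45, 2] <- 1L       # all carriers are cases
  cop <- toy_cohort(g, status = rep(c(1L, 0L), c(300, 300)))
  nmp <- fit_null_logistic(cop$samples$status)
  grp <- list(gene_id = "G1", functional_group = "combined",
              variant_idx = 1:2, maf = cohort_maf(cop), control_maf = c(0, 0))
  vtp <- variable_threshold_test(cop, grp, nmp, B = 100, seed = 9)
  expect_equal(vtp$p_value, 1 / 101, tolerance = 1e-12)
})

test_that("SKAT: single-variant identity and brute-force Q/lambda oracle", {
  co <- default_cohort()
  nm <- default_null()
  groups <- build_groups(co)
  one <- Filter(function(g) length(g$variant_idx) == 1, groups)[[2]]
  sk <- skat_test(co, one, nm, weight_scheme = "flat")
  sv <- score_test_variant(co$genotypes[, one$variant_idx], nm)
  expect_equal(sk$p_value, sv$p_value, tolerance = 5e-3)

  # 5-sample, 2-variant hand-set fixture: Q and lambda by direct matrices
  g <- matrix(c(0L, 1L, 2L, 0L, 1L,
                1L, 0L, 0L, 1L, 0L), ncol = 2)
  cof <- toy_cohort(g, status = c(1L, 0L, 1L, 0L, 0L))
  nmf <- fit_null_logistic(cof$samples$status)
  grf <- list(gene_id = "G1", functional_group = "combined",
              variant_idx = 1:2, maf = cohort_maf(cof),
              control_maf = c(0.1, 0.1))
  skf <- skat_test(cof, grf, nmf, weight_scheme = "beta")
  w <- dbeta(grf$maf, 1, 25)
  GW <- sweep(g, 2, w, "*")
  r <- nmf$residuals
  expect_equal(skf$statistic, drop(crossprod(crossprod(GW, r))),
               tolerance = 1e-10)
  # eigenvalue oracle through the explicit n x n projection
  V <- diag(nmf$weights)
  X <- nmf$X
  P0 <- V - V %*% X %*% solve(t(X) %*% V %*% X) %*% t(X) %*% V
  lam <- eigen(t(GW) %*% P0 %*% GW, symmetric = TRUE)$values
  lam <- lam[lam > 1e-10]
  p_oracle <- pmixchisq(skf$statistic, lam)
  expect_equal(skf$p_value, p_oracle, tolerance = 1e-8)
})

test_that("mixture chi-square tail: integration and Liu agree; chi2_1 limit", {
  # one component: exact chi-square
  expect_equal(pmixchisq(3.84, 1), pchisq(3.84, 1, lower.tail = FALSE),
               tolerance = 5e-3)
  expect_equal(pmixchisq(2 * 3.84, 2), pchisq(3.84, 1, lower.tail = FALSE),
               tolerance = 5e-3)
  # random fixtures: agreement within 10% relative for p > 1e-4
  set.seed(37)
  for (i in 1:20) {
    lam <- rexp(sample(2:15, 1)) + 0.05
    q <- sum(lam) * runif(1, 0.5, 4)
    pi_ <- pmixchisq(q, lam, "integration")
    pl <- pmixchisq(q, lam, "liu")
    if (pi_ > 1e-4)
      expect_lt(abs(pi_ - pl) / pi_, 0.10, label = paste("fixture", i))
  }
})

test_that("burden scan: cardinality, determinism, bonferroni thresholds", {
  co <- subset_samples(default_cohort(), 1:300)
  co <- subset_variants(co, which(co$variants$gene_id %in%
                                  sprintf("G%04d", 1:10)))
  nm <- fit_null_logistic(co$samples$status)
  groups <- build_groups(co)
  res <- run_burden_scan(co, nm, groups, tests = c("T1", "T5", "MB"),
                         seed = 3)
  expect_lte(nrow(res), 10 * 3 * 3)
  expect_true(all(res$p_value > 0 & res$p_value <= 1, na.rm = TRUE))

  res_vt1 <- run_burden_scan(co, nm, groups[1:3], tests = "VT",
                             B_vt = 100, seed = 3)
  res_vt2 <- run_burden_scan(co, nm, groups[1:3], tests = "VT",
                             B_vt = 100, seed = 3)
  expect_identical(res_vt1$p_value, res_vt2$p_value)

  expect_equal(bonferroni_threshold(20000, 5, 0.05), 5e-7)
  expect_equal(bonferroni_threshold(1, 1, 0.05), 0.05)
  expect_equal(bonferroni_threshold(1e6, 1, 0.05), 5e-8)
  expect_error(bonferroni_threshold(0, 5), "positive")
})

test_that("planted burden gene attains the smallest T1 p-value", {
  set.seed(41)
  hits <- vapply(1:25, function(r) {
    n <- 1800
    vpg <- 8                      # 20 genes x 8 rare variants, 2 carriers each
    g <- matrix(0L, n, 20 * vpg)
    for (j in seq_len(ncol(g))) g[sample(n, 2), j] <- 1L
    status <- rep(c(1L, 0L), each = 900)
    # plant 20 excess LOF carriers among cases in gene 4
    extra <- sample(which(status == 1), 20)
    g[cbind(extra, 3L * vpg + sample.int(vpg, 20, replace = TRUE))] <- 1L
    co <- toy_cohort(g, status = status)
    co$variants$gene_id <- rep(sprintf("G%02d", 1:20), each = vpg)
    co$variants$functional_class <- "LOF"
    nm <- fit_null_logistic(status)
    res <- run_burden_scan(co, nm, tests = "T1")
    res <- res[res$functional_group == "combined", ]
    res$gene_id[which.min(res$p_value)] == "G04"
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
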