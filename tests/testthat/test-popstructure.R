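test_that("GRM matches the brute-force formula on a hand-set fixture", {
  g <- matrix(c(0L, 1L, 2L,
                1L, 1L, 0L), nrow = 3)
  A <- compute_grm(g, maf_min = 0)$grm
  # direct evaluation of A_jk = (1/M) sum_i (x_ij-2p_i)(x_ik-2p_i)/(2p_i(1-p_i))
  p <- colMeans(g) / 2
  oracle <- matrix(0, 3, 3)
  for (j in 1:3) for (k in 1:3)
    oracle[j, k] <- mean((g[j, ] - 2 * p) * (g[k, ] - 2 * p) /
                         (2 * p * (1 - p)))
  expect_equal(unname(A), oracle, tolerance = 1e-12)

  # identical samples give identical GRM rows
  g2 <- rbind(g, g[1, ])
  A2 <- compute_grm(g2, maf_min = 0)$grm
  expect_equal(A2[1, ], A2[4, ], tolerance = 1e-12)

  expect_error(compute_grm(g, maf_min = 0.51), "no variants pass")
})

test_that("GRM properties: permutation equivariance, unit diagonal mean", {
  co <- subset_variants(fixture_cohort(), 1:800)
  A <- compute_grm(co, maf_min = 0.05)$grm
  perm <- sample(n_samples(co))
  Ap <- compute_grm(subset_samples(co, perm), maf_min = 0.05)$grm
  expect_equal(unname(Ap), unname(A[perm, perm]), tolerance = 1e-12)
  expect_equal(mean(diag(A)), 1, tolerance = 0.1)
  expect_equal(A, t(A), tolerance = 1e-12)
})

test_that("PCA: spectrum limits, sign convention, dense-solver oracle", {
  # identity GRM: all eigenvalues equal
  p1 <- pca(diag(5), k = 5)
  expect_equal(p1$values, rep(1, 5), tolerance = 1e-12)

  # rank-1: PC1 proportional to v, rest ~ 0
  v <- c(3, -1, 2, 0.5, -2) / sqrt(sum(c(3, -1, 2, 0.5, -2)^2))
  p2 <- pca(tcrossprod(v), k = 5)
  expect_equal(abs(drop(crossprod(p2$vectors[, 1], v))), 1, tolerance = 1e-10)
  expect_equal(p2$values[-1], rep(0, 4), tolerance = 1e-10)
  # sign convention: largest-magnitude loading positive
  expect_gt(p2$vectors[which.max(abs(p2$vectors[, 1])), 1], 0)

  # random PSD oracle via svd (independent dense solver)
  set.seed(17)
  B <- matrix(rnorm(36), 6)
  S <- crossprod(B)
  p3 <- pca(S, k = 6)
  sv <- svd(S)
  expect_equal(p3$values, sv$d, tolerance = 1e-8)
  for (j in 1:6)
    expect_equal(abs(drop(crossprod(p3$vectors[, j], sv$u[, j]))), 1,
                 tolerance = 1e-8)
  # orthonormality
  expect_equal(unname(crossprod(p3$vectors)), diag(6), tolerance = 1e-8)

  expect_error(pca(diag(4), k = 5), "exceeds")
})

test_that("haversine distance: closed form, symmetry, identity", {
  expect_equal(haversine_km(52, 5, 52, 5), 0)
  expect_equal(haversine_km(0, 0, 0, 1), 6371 * pi / 180, tolerance = 1e-10)
  expect_equal(haversine_km(51.2, 4.4, 53.1, 6.6),
               haversine_km(53.1, 6.6, 51.2, 4.4), tolerance = 1e-12)
})

test_that("LOO birthplace prediction equals an explicit refit oracle", {
  set.seed(23)
  n <- 30
  V <- qr.Q(qr(matrix(rnorm(n * 3), n)))   # 3 orthonormal "PCs"
  fake_pca <- structure(list(values = c(3, 2, 1), vectors = V, k = 3,
                             maf_threshold = NA), class = "geo_pca")
  coords <- data.frame(lat = 52 + V[, 1] * 2 + rnorm(n, 0, 0.3),
                       lon = 5 + V[, 2] * 3 + rnorm(n, 0, 0.3))
  pred <- predict_birthplace_loo(fake_pca, coords, k = 3)
  # literal leave-one-out refit
  for (i in c(1, 7, 30)) {
    dtr <- data.frame(lat = coords$lat[-i], lon = coords$lon[-i],
                      V[-i, , drop = FALSE])
    fit_lat <- lm(lat ~ X1 + X2 + X3, dtr)
    fit_lon <- lm(lon ~ X1 + X2 + X3, dtr)
    nd <- setNames(as.data.frame(V[i, , drop = FALSE]), c("X1", "X2", "X3"))
    expect_equal(pred$predicted$lat[i], unname(predict(fit_lat, nd)),
                 tolerance = 1e-10)
    expect_equal(pred$predicted$lon[i], unname(predict(fit_lon, nd)),
                 tolerance = 1e-10)
  }
  expect_equal(pred$median_error_km, median(pred$error_km))

  # noiseless linear recovery
  coords2 <- data.frame(lat = 52 + V[, 1] * 2 + V[, 2],
                        lon = 5 + V[, 2] * 3 - V[, 3])
  pred2 <- predict_birthplace_loo(fake_pca, coords2, k = 3)
  expect_lt(pred2$median_error_km, 1e-6)

  expect_error(predict_birthplace_loo(fake_pca, coords[1:4, ], k = 3),
               "underdetermined|match")
})

test_that("permuted coordinates predict no better than the centroid", {
  set.seed(29)
  n <- 200
  V <- qr.Q(qr(matrix(rnorm(n * 20), n)))
  fake_pca <- structure(list(values = 20:1, vectors = V, k = 20,
                             maf_threshold = NA), class = "geo_pca")
  coords <- data.frame(lat = runif(n, 50.7, 53.5), lon = runif(n, 3.3, 7.2))
  pred <- predict_birthplace_loo(fake_pca, coords, k = 20)
  centroid_err <- haversine_km(coords$lat, coords$lon,
                               mean(coords$lat), mean(coords$lon))
  # independent coords: LOO error not smaller than the centroid baseline
  expect_gt(median(pred$error_km), 0.8 * median(centroid_err))
})

test_that("variance_explained equals squared Pearson correlation", {
  set.seed(31)
  x <- rnorm(12); y <- 2 * x + rnorm(12)
  ve <- variance_explained(x, y)
  expect_equal(ve$fraction, cor(x, y)^2, tolerance = 1e-12)
  expect_equal(ve$p_value, cor.test(x, y)$p.value, tolerance = 1e-10)
  expect_equal(suppressWarnings(variance_explained(x, 3 * x + 1)$fraction), 1,
               tolerance = 1e-12)
  big <- rnorm(10000)
  expect_lt(variance_explained(big, rnorm(10000))$fraction, 0.01)
  expect_error(variance_explained(rep(1, 5), rnorm(5)), "zero-variance")
})

test_that("IBD distance summary bins pairs and segments correctly", {
  coords <- data.frame(lat = seq(51, 53, length.out = 30),
                       lon = seq(4, 6, length.out = 30))
  pr <- combn(30, 2)
  # every pair shares exactly one segment per length bin
  ibd <- do.call(rbind, lapply(c(1.5, 4, 10), function(len)
    data.frame(id1 = pr[1, ], id2 = pr[2, ], length_cM = len)))
  s <- ibd_distance_summary(ibd, coords)
  expect_true(all(abs(s$mean_sharing - 1) < 1e-12))
  expect_equal(sum(s$n_pairs), ncol(pr))

  # empty table: all zeros, counts still reported
  s0 <- ibd_distance_summary(ibd[0, ], coords)
  expect_true(all(s0$mean_sharing == 0))
  expect_equal(sum(s0$n_pairs), ncol(pr))

  expect_error(
    ibd_distance_summary(data.frame(id1 = 1, id2 = 99, length_cM = 3), coords),
    "unknown sample")
})
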