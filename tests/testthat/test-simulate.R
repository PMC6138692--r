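test_that("birthplace sampling respects the box, the seed, and the centroid", {
  # degenerate box widened by epsilon keeps all latitudes within epsilon
  eps <- 1e-6
  m <- spatial_map(52, 52 + eps, 4, 5)
  b <- sample_birthplaces(map = m, n = 50, seed = 1)
  expect_true(all(b$lat >= 52 & b$lat <= 52 + eps))

  # determinism
  expect_identical(sample_birthplaces(map = spatial_map(), n = 20, seed = 9),
                   sample_birthplaces(map = spatial_map(), n = 20, seed = 9))

  # Monte-Carlo centroid oracle: mean of n uniform draws ~ centroid +- 3 SE
  mp <- spatial_map()
  b <- sample_birthplaces(map = mp, n = 10000, seed = 3)
  se_lat <- (mp$lat_max - mp$lat_min) / sqrt(12) / sqrt(10000)
  se_lon <- (mp$lon_max - mp$lon_min) / sqrt(12) / sqrt(10000)
  expect_lt(abs(mean(b$lat) - (mp$lat_min + mp$lat_max) / 2), 3 * se_lat)
  expect_lt(abs(mean(b$lon) - (mp$lon_min + mp$lon_max) / 2), 3 * se_lon)

  expect_error(spatial_map(53, 52, 4, 5), "invalid map box")
})

test_that("common variants: no-structure limit, strong clines, determinism", {
  coords <- sample_birthplaces(map = spatial_map(), n = 2000, seed = 5)

  # cline 0: genotype counts binomial at p0 (chi-square GOF per variant)
  cv <- simulate_common_variants(coords, 80, 0, seed = 11)
  gof <- vapply(seq_len(80), function(j) {
    g <- cv$genotypes[, j]
    p <- cv$p0[j]
    exp_cnt <- 2000 * c((1 - p)^2, 2 * p * (1 - p), p^2)
    obs <- tabulate(g + 1L, nbins = 3)
    sum((obs - exp_cnt)^2 / exp_cnt)
  }, numeric(1))
  # under H0 each GOF stat ~ chi2_2; fraction exceeding the 1% critical
  # value should be small
  expect_lt(mean(gof > qchisq(0.99, df = 2)), 0.10)

  # strong cline (3): north and south halves differ for most variants
  cv3 <- simulate_common_variants(coords, 60, 3, seed = 12)
  north <- coords$lat > median(coords$lat)
  pdiff <- vapply(seq_len(60), function(j) {
    suppressWarnings(prop.test(
      c(sum(cv3$genotypes[north, j]), sum(cv3$genotypes[!north, j])),
      c(2 * sum(north), 2 * sum(!north)))$p.value)
  }, numeric(1))
  expect_gt(mean(pdiff < 0.01), 0.5)

  # determinism and error path
  expect_identical(simulate_common_variants(coords, 5, 1, seed = 2),
                   simulate_common_variants(coords, 5, 1, seed = 2))
  expect_error(simulate_common_variants(coords, 5, -1), "cline_strength")
  expect_error(simulate_common_variants(coords[0, ], 5, 1), "non-empty")
})

test_that("rare variants cluster spatially, stay rare, honour the kernel limit", {
  coords <- sample_birthplaces(map = spatial_map(), n = 600, seed = 6)
  xy_dist <- function(idx) {
    if (length(idx) < 2) return(NA_real_)
    pr <- combn(idx, 2)
    mean(haversine_km(coords$lat[pr[1, ]], coords$lon[pr[1, ]],
                      coords$lat[pr[2, ]], coords$lon[pr[2, ]]))
  }
  pop_pairs <- combn(sample(600, 80), 2)
  pop_mean <- mean(haversine_km(coords$lat[pop_pairs[1, ]],
                                coords$lon[pop_pairs[1, ]],
                                coords$lat[pop_pairs[2, ]],
                                coords$lon[pop_pairs[2, ]]))

  # kernel 20 km: carriers of the same variant are closer than random pairs
  g <- simulate_rare_variants(coords, 500, 20, seed = 13)
  d_carrier <- vapply(seq_len(500), function(j) xy_dist(which(g[, j] > 0)),
                      numeric(1))
  expect_lt(mean(d_carrier, na.rm = TRUE), 0.5 * pop_mean)
  expect_lt(t.test(d_carrier, mu = pop_mean,
                   alternative = "less")$p.value, 0.01)

  # MAF bound and heterozygous carriers
  expect_true(all(colMeans(g) / 2 < 0.005))
  expect_true(all(g %in% 0:1))

  # kernel -> Inf: carrier distances match the population mean
  gi <- simulate_rare_variants(coords, 400, Inf, seed = 14)
  d_inf <- vapply(seq_len(400), function(j) xy_dist(which(gi[, j] > 0)),
                  numeric(1))
  expect_gt(t.test(d_inf, mu = pop_mean)$p.value, 0.01)

  # a variant drawn with carrier count 1 has exactly one heterozygote
  g1 <- simulate_rare_variants(coords[1:250, ], 50, 20, seed = 15)
  cc <- colSums(g1)
  expect_true(all(cc >= 1))
  expect_true(any(cc == 1))       # singletons occur (modal carrier count)
  expect_true(all(g1[, which(cc == 1)] %in% 0:1))

  expect_error(simulate_rare_variants(coords, 10, 0), "kernel_scale_km")
})

test_that("phenotype scenarios keep counts and encode the latitude gradient", {
  coords <- sample_birthplaces(map = spatial_map(), n = 1800, seed = 8)

  # conservation in both scenarios
  s1 <- simulate_phenotype_scenario(coords, 1200, "perfect", seed = 21)
  s2 <- simulate_phenotype_scenario(coords, 1200, "imperfect", 2, seed = 22)
  expect_equal(sum(s1), 1200)
  expect_equal(sum(s2), 1200)

  # gradient 2: cases sit south of controls (t-test)
  tt <- t.test(coords$lat[s2 == 1], coords$lat[s2 == 0])
  expect_lt(tt$p.value, 0.01)
  expect_lt(mean(coords$lat[s2 == 1]), mean(coords$lat[s2 == 0]))

  # gradient 0 imperfect is perfect in law: case-latitude means agree
  diffs <- vapply(1:200, function(r) {
    a <- simulate_phenotype_scenario(coords, 600, "perfect", seed = 100 + r)
    b <- simulate_phenotype_scenario(coords, 600, "imperfect", 0,
                                     seed = 300 + r)
    mean(coords$lat[a == 1]) - mean(coords$lat[b == 1])
  }, numeric(1))
  expect_gt(t.test(diffs, mu = 0)$p.value, 0.01)

  expect_error(simulate_phenotype_scenario(coords, 1800, "perfect"),
               "n_cases")
  expect_error(simulate_phenotype_scenario(coords, 10, "imperfect", -1),
               "gradient_strength")
})

test_that("IBD segment counts follow the distance-decay model", {
  coords <- sample_birthplaces(map = spatial_map(), n = 120, seed = 9)

  # a = 0: sharing is flat at b regardless of distance
  flat <- data.frame(a = c(0, 0, 0), rho_km = c(100, 100, 100),
                     b = c(0.8, 0.4, 0.2))
  seg <- simulate_ibd_segments(coords, params = flat, seed = 31)
  s <- ibd_distance_summary(seg, coords)
  npair <- choose(120, 2)
  # overall mean per bin equals b within Monte-Carlo error
  for (k in 1:3) {
    tot <- sum(s$mean_sharing[k, ] * s$n_pairs) / npair
    expect_lt(abs(tot - flat$b[k]), 4 * sqrt(flat$b[k] / npair))
  }

  # default parameters: 7-15 cM sharing decays from nearest to farthest decile
  seg2 <- simulate_ibd_segments(coords, seed = 32)
  s2 <- ibd_distance_summary(seg2, coords)
  expect_gt(s2$mean_sharing["7-15cM", "D1"], s2$mean_sharing["7-15cM", "D10"])

  # coincident individuals: expected count a + b at d = 0
  co2 <- data.frame(lat = c(52, 52), lon = c(5, 5))
  pars <- data.frame(a = 3, rho_km = 50, b = 1)
  cnt <- vapply(1:400, function(r)
    nrow(simulate_ibd_segments(co2, c(7, 15), pars, seed = 1000 + r)),
    numeric(1))
  expect_lt(abs(mean(cnt) - 4), 4 * sqrt(4 / 400))

  expect_error(sim_config(ibd_params = data.frame(a = 1, rho_km = -1, b = 0),
                          ibd_bin_edges_cM = c(1, 2)),
               "positive")
})

test_that("batch error model perturbs only affected sites", {
  co <- fixture_cohort()

  # identity limits
  same1 <- simulate_batch_cohort(co, 0, 0.3, seed = 41)$cohort
  expect_identical(same1$genotypes, co$genotypes)
  same2 <- simulate_batch_cohort(co, 0.05, 0, seed = 42)$cohort
  expect_identical(same2$genotypes, co$genotypes)
  expect_equal(unique(same2$samples$cohort), "external")

  # rate 0.02 / fraction 0.3: affected sites drift more than unaffected
  bb <- simulate_batch_cohort(co, 0.02, 0.3, seed = 43)
  aff <- bb$affected_sites
  expect_equal(length(aff), round(0.3 * n_variants(co)))
  f0 <- dosage_freq(co)
  f1 <- dosage_freq(bb$cohort)
  expect_gt(mean(abs(f1 - f0)[aff]), mean(abs(f1 - f0)[-aff]))
  # unaffected sites are copied unchanged
  expect_identical(bb$cohort$genotypes[, -aff], co$genotypes[, -aff])
  # missingness appears only at affected sites
  expect_true(all(which(colSums(is.na(bb$cohort$genotypes)) > 0) %in% aff))
})

test_that("generator determinism flows from the master seed via substreams", {
  expect_identical(substream_seed(1L, "a"), substream_seed(1L, "a"))
  expect_false(substream_seed(1L, "a") == substream_seed(1L, "b"))
  c1 <- simulate_cohort(sim_config(n_cases = 40, n_controls = 20,
                                   n_common_variants = 100,
                                   n_rare_variants = 60, n_genes = 5,
                                   seed = 5))
  c2 <- simulate_cohort(sim_config(n_cases = 40, n_controls = 20,
                                   n_common_variants = 100,
                                   n_rare_variants = 60, n_genes = 5,
                                   seed = 5))
  expect_identical(c1$genotypes, c2$genotypes)
  expect_identical(c1$samples, c2$samples)
})
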