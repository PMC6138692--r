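# Shared fixtures, built once per test run and memoized.
.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- force(expr)
  .fixture_env[[name]]
}

# miniature cohort: 100 samples, 1500 common + 500 rare variants, 20 genes
fixture_cohort <- function() memo("fixture", make_fixtures(seed = 42L))

# desk-scale study (400 cases / 200 controls internal + 200 external)
default_study <- function() memo("study", simulate_study(sim_config(seed = 7L)))

default_cohort <- function() default_study()$internal

# intercept-only null model on the default cohort's true labels
default_null <- function() memo("null",
  fit_null_logistic(default_cohort()$samples$status))

# hand-set miniature cohort for formula oracles
toy_cohort <- function(genotypes, status = NULL) {
  n <- nrow(genotypes)
  m <- ncol(genotypes)
  if (is.null(status)) status <- rep(0:1, length.out = n)
  geo_cohort(
    genotypes,
    data.frame(sample_id = sprintf("T%03d", seq_len(n)),
               sex = rep(c("M", "F"), length.out = n),
               status = status,
               lat = seq(51, 53, length.out = n),
               lon = seq(4, 6, length.out = n),
               cohort = "toy"),
    data.frame(variant_id = sprintf("v%03d", seq_len(m)),
               chrom = "1", pos = seq_len(m) * 100L,
               ref = "A", alt = "C", minor_allele = "alt",
               gene_id = "G1", functional_class = "nonsynonymous"))
}
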