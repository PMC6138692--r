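#' Fit the logistic null model
#'
#' Maximum-likelihood logistic regression of the binary phenotype on the
#' covariates (intercept always included), fitted by iteratively reweighted
#' least squares to a score-norm tolerance of 1e-8 with at most 50
#' iterations. Perfect separation is flagged as an explicit error state.
#' The returned object caches the quantities every downstream score test
#' needs (residuals, weights, and the weighted covariate projection).
#'
#' @param phenotype 0/1 vector.
#' @param covariates numeric matrix (or `NULL` for intercept-only); an
#'   intercept column is added automatically.
#' @return object of class `null_model` with elements `coefficients`,
#'   `fitted`, `residuals`, `weights`, `X`, `XtWX_inv`, `converged`.
#' @export
fit_null_logistic <- function(phenotype, covariates = NULL) {
  y <- as.numeric(phenotype)
  if (!all(y %in% c(0, 1))) stop("phenotype must be binary 0/1")
  n <- length(y)
  if (length(unique(y)) < 2)
    stop("perfect separation: phenotype is constant")
  X <- if (is.null(covariates)) matrix(1, n, 1)
       else cbind(1, as.matrix(covariates))
  if (anyNA(X)) stop("covariates must not contain missing values")
  colnames(X) <- c("(Intercept)",
                   if (ncol(X) > 1) {
                     cn <- colnames(X)[-1]
                     if (is.null(cn) || any(!nzchar(cn)))
                       paste0("V", seq_len(ncol(X) - 1)) else cn
                   })
  beta <- numeric(ncol(X))
  beta[1] <- stats::qlogis(mean(y))
  converged <- FALSE
  for (it in seq_len(50)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    score <- crossprod(X, y - mu)
    if (sqrt(sum(score^2)) < 1e-8) { converged <- TRUE; break }
    XtWX <- crossprod(X, X * w)
    step <- tryCatch(solve(XtWX, score), error = function(e) NULL)
    if (is.null(step)) break
    beta <- beta + drop(step)
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  if (!converged)
    stop("null model failed to converge")
  # fitted log-odds beyond +-15 only arise under (quasi-)separation
  if (max(abs(eta)) > 15)
    stop("perfect separation detected: fitted probabilities degenerate")
  w <- mu * (1 - mu)
  XtWX <- crossprod(X, X * w)
  structure(list(coefficients = stats::setNames(beta, colnames(X)),
                 fitted = mu, residuals = y - mu, weights = w,
                 X = X, XtWX_inv = chol2inv(chol(XtWX)),
                 y = y, converged = converged),
            class = "null_model")
}

#' Single-variant score test under the additive model
#'
#' Efficient score test of the logistic model: U = g'(y - yhat),
#' V = g'Wg - g'WX (X'WX)^-1 X'Wg with W = diag(yhat (1 - yhat)).
#' U^2 / V is chi-squared with 1 df under the null. Missing genotypes are
#' mean-imputed.
#'
#' @param genotype dosage vector (0/1/2, NA allowed).
#' @param null_model a fitted `null_model`.
#' @return list with `statistic`, `p_value` (NA when the adjusted variance
#'   is non-positive), `direction` (sign of the score).
#' @export
score_test_variant <- function(genotype, null_model) {
  g <- as.numeric(genotype)
  if (length(g) != length(null_model$fitted))
    stop("genotype length does not match the null model")
  if (anyNA(g)) g[is.na(g)] <- mean(g, na.rm = TRUE)
  st <- .score_stats(matrix(g, ncol = 1), null_model)
  list(statistic = st$stat, p_value = st$p, direction = sign(st$u))
}

# Vectorized score tests for the columns of a burden/genotype matrix.
# Returns u, v, stat, p per column; p is NA where v <= tol.
.score_stats <- function(G, nm, tol = 1e-12) {
  u <- drop(crossprod(G, nm$residuals))
  WG <- G * nm$weights
  XtWG <- crossprod(nm$X, WG)                       # p x m
  v <- colSums(G * WG) - colSums(XtWG * (nm$XtWX_inv %*% XtWG))
  stat <- ifelse(v > tol, u^2 / v, NA_real_)
  p <- ifelse(is.na(stat), NA_real_,
              stats::pchisq(stat, df = 1, lower.tail = FALSE))
  list(u = u, v = v, stat = stat, p = p)
}

#' Genome-wide single-variant scan
#'
#' Score-tests every variant with cohort MAF above `maf_min` against the
#' fitted null model; variants below the floor are excluded and counted.
#'
#' @param cohort a `geo_cohort`.
#' @param null_model a `null_model` fitted on the same samples.
#' @param maf_min MAF floor (default 0.005, i.e. MAF > 0.5 percent).
#' @return object of class `scan_result`: data.frame of results plus the
#'   excluded-variant count as attribute `n_excluded`.
#' @export
gw_scan <- function(cohort, null_model, maf_min = 0.005) {
  maf <- cohort_maf(cohort)
  use <- which(!is.nan(maf) & maf > maf_min)
  G <- cohort$genotypes[, use, drop = FALSE]
  storage.mode(G) <- "double"
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    na_idx <- which(is.na(G), arr.ind = TRUE)
    G[na_idx] <- mu[na_idx[, 2]]
  }
  st <- if (length(use)) .score_stats(G, null_model)
        else list(u = numeric(0), stat = numeric(0), p = numeric(0))
  out <- data.frame(variant_id = cohort$variants$variant_id[use],
                    maf = maf[use],
                    statistic = st$stat,
                    p_value = st$p,
                    direction = sign(st$u))
  attr(out, "n_excluded") <- ncol(cohort$genotypes) - length(use)
  class(out) <- c("scan_result", "data.frame")
  out
}

#' Genomic inflation factor
#'
#' lambda = median of the 1-df chi-square quantiles of the p-values divided
#' by the null median 0.4549364.
#'
#' @param p_values vector of p-values in (0, 1]; NAs are dropped.
#' @return lambda.
#' @export
#' @examples
#' genomic_lambda(runif(1e4))
genomic_lambda <- function(p_values) {
  p <- p_values[!is.na(p_values)]
  if (!length(p)) stop("no p-values supplied")
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  chi <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  stats::median(chi) / stats::qchisq(0.5, df = 1)
}
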