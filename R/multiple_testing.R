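# Li-Ji effective number of independent tests and the composite per-locus
# Bonferroni threshold alpha / (Meff_SNP x Meff_probe).

#' Li-Ji effective number of independent tests
#'
#' Spectral estimator: with eigenvalues `lambda_1..lambda_M` of the
#' correlation matrix, `Meff = sum f(|lambda_i|)` where `f(x) = I(x >= 1) +
#' (x - floor(x))`. Eigenvalues that are numerically below zero (possible
#' when the matrix was assembled from pairwise-complete correlations and is
#' not positive semi-definite) are clipped to zero before applying `f`.
#'
#' @param corr_mat square symmetric correlation matrix with unit diagonal
#'   and entries in \[-1, 1\]; no missing entries.
#' @return the effective number of tests, a positive real in \[1, M\].
#' @export
meff_li_ji <- function(corr_mat) {
  corr_mat <- as.matrix(corr_mat)
  if (nrow(corr_mat) != ncol(corr_mat)) stop("correlation matrix not square")
  if (anyNA(corr_mat)) {
    stop("correlation matrix has missing entries; complete it first")
  }
  if (max(abs(corr_mat - t(corr_mat))) > 1e-8) {
    stop("correlation matrix not symmetric")
  }
  if (max(abs(diag(corr_mat) - 1)) > 1e-8) {
    stop("correlation matrix must have unit diagonal")
  }
  if (max(abs(corr_mat)) > 1 + 1e-8) {
    stop("correlation entries must lie in [-1, 1]")
  }
  lam <- eigen(corr_mat, symmetric = TRUE, only.values = TRUE)$values
  lam <- pmax(lam, 0)
  x <- abs(lam)
  meff <- sum(as.numeric(x >= 1) + (x - floor(x)))
  # mathematically 1 <= Meff <= M; clamp float noise at the boundaries
  min(max(meff, 1), nrow(corr_mat))
}

#' Pairwise dosage correlation matrix for the SNPs of a window
#'
#' Signed Pearson correlations on pairwise-complete observations.
#' Monomorphic SNPs (zero variance on their observed samples) are excluded
#' from the matrix; their count is attached as attribute `n_excluded` and
#' they contribute one independent test each in [meff_snps()].
#'
#' @param genotypes a [genotype_matrix()].
#' @param snp_ids optional subset of SNPs.
#' @return correlation matrix over polymorphic SNPs with attribute
#'   `n_excluded`; a 0x0 matrix (with `n_excluded` = all) if fewer than 2
#'   SNPs are polymorphic.
#' @export
snp_correlation <- function(genotypes, snp_ids = NULL) {
  D <- genotypes$dosages
  if (!is.null(snp_ids)) D <- D[, snp_ids, drop = FALSE]
  v <- apply(D, 2, stats::var, na.rm = TRUE)
  poly <- !is.na(v) & v > 0
  n_ex <- sum(!poly)
  if (sum(poly) < 2) {
    warning("fewer than 2 polymorphic SNPs; Meff falls back to raw count")
    m <- matrix(numeric(0), 0, 0)
    attr(m, "n_excluded") <- ncol(D)
    return(m)
  }
  m <- stats::cor(D[, poly, drop = FALSE], use = "pairwise.complete.obs")
  if (anyNA(m)) {
    stop("correlation undefined for some SNP pair (no overlapping samples)")
  }
  diag(m) <- 1
  m[m > 1] <- 1; m[m < -1] <- -1
  attr(m, "n_excluded") <- n_ex
  m
}

#' Correlation matrix of adjusted expression traits
#'
#' As [snp_correlation()], but over the residual vectors of adjusted
#' probesets on shared samples. Constant traits are excluded and counted as
#' one independent test each.
#'
#' @param adjusted an [adjust_expression()] result.
#' @param probeset_ids optional subset.
#' @return correlation matrix with attribute `n_excluded`.
#' @export
probe_correlation <- function(adjusted, probeset_ids = NULL) {
  R <- adjusted$residuals
  if (!is.null(probeset_ids)) R <- R[, probeset_ids, drop = FALSE]
  v <- apply(R, 2, stats::var, na.rm = TRUE)
  poly <- !is.na(v) & v > 0
  n_ex <- sum(!poly)
  if (sum(poly) < 2) {
    warning("fewer than 2 variable traits; Meff falls back to raw count")
    m <- matrix(numeric(0), 0, 0)
    attr(m, "n_excluded") <- ncol(R)
    return(m)
  }
  m <- stats::cor(R[, poly, drop = FALSE], use = "pairwise.complete.obs")
  if (anyNA(m)) stop("correlation undefined for some trait pair")
  diag(m) <- 1
  m[m > 1] <- 1; m[m < -1] <- -1
  attr(m, "n_excluded") <- n_ex
  m
}

# Meff from a correlation matrix carrying an n_excluded attribute.
meff_with_excluded <- function(m) {
  ex <- attr(m, "n_excluded")
  if (nrow(m) == 0) return(ex)
  meff_li_ji(m) + ex
}

#' Effective number of independent SNPs in a window
#' @param genotypes a [genotype_matrix()].
#' @param snp_ids optional subset.
#' @return Meff for the SNP dimension (monomorphic SNPs add 1 each).
#' @export
meff_snps <- function(genotypes, snp_ids = NULL) {
  meff_with_excluded(snp_correlation(genotypes, snp_ids))
}

#' Effective number of independent expression traits
#' @param adjusted an [adjust_expression()] result.
#' @param probeset_ids optional subset.
#' @return Meff for the probeset dimension.
#' @export
meff_probes <- function(adjusted, probeset_ids = NULL) {
  meff_with_excluded(probe_correlation(adjusted, probeset_ids))
}

#' Composite per-locus Bonferroni threshold
#'
#' `threshold = alpha / (meff_snps * meff_probes)`. Meff values are used at
#' full precision; only the `display` field is rounded (3 significant
#' digits), never the computation.
#'
#' @param meff_snps,meff_probes effective numbers (>= 1).
#' @param alpha family-wise error target in (0, 1).
#' @param locus locus label.
#' @param m_snps,m_probes optional raw counts for the report.
#' @return one-row data.frame of class `locus_threshold`: locus, m_snps,
#'   meff_snps, m_probes, meff_probes, alpha, threshold, display.
#' @export
locus_threshold <- function(meff_snps, meff_probes, alpha = 0.05,
                            locus = "locus", m_snps = NA_integer_,
                            m_probes = NA_integer_) {
  if (meff_snps < 1 || meff_probes < 1) stop("Meff values must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  thr <- alpha / (meff_snps * meff_probes)
  out <- data.frame(locus = locus, m_snps = m_snps, meff_snps = meff_snps,
                    m_probes = m_probes, meff_probes = meff_probes,
                    alpha = alpha, threshold = thr,
                    display = signif(thr, 3), stringsAsFactors = FALSE)
  class(out) <- c("locus_threshold", "data.frame")
  out
}
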