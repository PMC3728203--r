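# Covariate adjustment of expression traits: Huber M-estimation by IRLS,
# followed by a single-pass median +/- 3 SD residual outlier filter.

#' Huber M-estimation by iteratively reweighted least squares
#'
#' Fits `y ~ X` with Huber weights `w(u) = min(1, c/|u|)`, `u =
#' residual/scale`. The scale is re-estimated each iteration as
#' `median(|residual|)/0.6745` (the MAD-about-zero convention used by the
#' classic rlm routine, so results are comparable to it). Iterations stop
#' when the largest coefficient change falls below `tol`.
#'
#' @param X design matrix (with intercept column), full rank.
#' @param y response vector, same length as `nrow(X)`.
#' @param c_tune Huber tuning constant; 1.345 gives 95% efficiency at the
#'   Gaussian.
#' @param tol convergence tolerance on the max absolute coefficient change.
#' @param maxit iteration cap.
#' @return list: `coefficients`, `residuals`, `scale`, `weights`,
#'   `iterations`, `converged`.
#' @export
huber_irls <- function(X, y, c_tune = 1.345, tol = 1e-8, maxit = 50L) {
  X <- as.matrix(X)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    drop <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(drop, collapse = ", "))
  }
  beta <- qr.coef(qrx, y)
  r <- y - drop(X %*% beta)
  converged <- FALSE
  it <- 0L
  w <- rep(1, length(y))
  scale <- median(abs(r)) / 0.6745
  for (it in seq_len(maxit)) {
    scale <- median(abs(r)) / 0.6745
    if (scale <= 0) { converged <- TRUE; break }  # perfect fit
    u <- r / scale
    w <- pmin(1, c_tune / pmax(abs(u), .Machine$double.eps))
    fit <- lm.wfit(X, y, w)
    delta <- max(abs(fit$coefficients - beta))
    beta <- fit$coefficients
    r <- y - drop(X %*% beta)
    if (delta < tol) { converged <- TRUE; break }
  }
  list(coefficients = beta, residuals = r, scale = scale, weights = w,
       iterations = it, converged = converged)
}

# Design matrix for age + sex + smoking; smoking enters as two indicator
# contrasts against "never". Returns NULL rows for incomplete samples via
# the `complete` attribute.
covariate_design <- function(covariates) {
  X <- cbind(`(Intercept)` = 1,
             age = covariates$age,
             sex_male = as.numeric(covariates$sex == "male"),
             smoking_ex = as.numeric(covariates$smoking == "ex"),
             smoking_current = as.numeric(covariates$smoking == "current"))
  rownames(X) <- covariates$sample_id
  X
}

#' Robustly residualize one expression trait on covariates
#'
#' Regresses the trait on age, sex and smoking status (two contrasts vs
#' never-smokers) with Huber M-estimation and returns the residuals.
#' Samples missing the trait or any covariate are dropped for this trait
#' (`NA` residual); no imputation. Requires at least 10 complete samples
#' and a full-rank design on the complete subset.
#'
#' @param y named numeric vector of expression values (names = sample IDs)
#'   or unnamed vector in `covariates` order.
#' @param covariates a [covariate_table()].
#' @param probeset_id label carried into the result.
#' @param c_tune,tol,maxit passed to [huber_irls()].
#' @return list of class `adjusted_trait`: `probeset_id`, `residuals` (full
#'   length, `NA` where dropped), `outlier_mask` (all `FALSE` here; see
#'   [filter_outliers()]), `n_used`, `iterations`, `converged`, `scale`,
#'   `coefficients`.
#' @export
robust_residualize <- function(y, covariates, probeset_id = "trait",
                               c_tune = 1.345, tol = 1e-8, maxit = 50L) {
  if (length(y) != nrow(covariates)) {
    stop("y length does not match covariate rows")
  }
  X <- covariate_design(covariates)
  ok <- stats::complete.cases(X) & !is.na(y)
  if (sum(ok) < 10) {
    stop("fewer than 10 samples with complete covariates and expression (",
         sum(ok), ")")
  }
  fit <- huber_irls(X[ok, , drop = FALSE], y[ok], c_tune = c_tune,
                    tol = tol, maxit = maxit)
  res <- rep(NA_real_, length(y))
  names(res) <- covariates$sample_id
  res[ok] <- fit$residuals
  structure(list(probeset_id = probeset_id, residuals = res,
                 outlier_mask = setNames(rep(FALSE, length(y)),
                                         covariates$sample_id),
                 n_used = sum(ok), iterations = fit$iterations,
                 converged = fit$converged, scale = fit$scale,
                 coefficients = fit$coefficients),
            class = "adjusted_trait")
}

#' Flag residual outliers beyond three SDs of the median
#'
#' A residual is an outlier when it deviates from the median of the
#' non-missing residuals by more than three times their classical sample
#' standard deviation. Single pass: median and SD are computed once on all
#' non-missing residuals, never re-estimated after masking. If all
#' residuals are equal (SD = 0) nothing is flagged.
#'
#' @param residuals numeric vector, `NA` allowed.
#' @param n_sd multiplier (default 3).
#' @return logical vector, `TRUE` where flagged (`FALSE` at `NA` input).
#' @export
filter_outliers <- function(residuals, n_sd = 3) {
  obs <- !is.na(residuals)
  if (sum(obs) < 3) stop("need at least 3 non-missing residuals")
  m <- median(residuals[obs])
  s <- sd(residuals[obs])
  mask <- rep(FALSE, length(residuals))
  if (s > 0) mask[obs] <- abs(residuals[obs] - m) > n_sd * s
  names(mask) <- names(residuals)
  mask
}

#' Adjust all expression traits of a cohort
#'
#' Runs [robust_residualize()] then [filter_outliers()] on every probeset.
#' Masked outliers become `NA` in the residual matrix, so downstream
#' association tests never see them; this is done once per probeset per
#' cohort, before any SNP is involved.
#'
#' @param em an [expression_matrix()].
#' @param covariates a [covariate_table()] covering the same samples (matched
#'   by sample_id).
#' @param filter apply the 3-SD outlier filter (default `TRUE`).
#' @param n_sd outlier multiplier.
#' @return list of class `adjusted_traits`: `residuals` (samples x probesets
#'   matrix, `NA` where dropped or masked), `probesets` (the probe map),
#'   `diagnostics` (per-trait data.frame: probeset_id, n_used, n_outliers,
#'   iterations, converged, scale).
#' @export
adjust_expression <- function(em, covariates, filter = TRUE, n_sd = 3) {
  idx <- match(em$sample_ids, covariates$sample_id)
  if (anyNA(idx)) {
    stop("samples missing from covariate table: ",
         paste(utils::head(em$sample_ids[is.na(idx)], 5), collapse = ", "))
  }
  cv <- covariates[idx, , drop = FALSE]
  P <- ncol(em$values)
  res <- matrix(NA_real_, nrow(em$values), P,
                dimnames = dimnames(em$values))
  diag_list <- vector("list", P)
  for (j in seq_len(P)) {
    at <- robust_residualize(em$values[, j], cv,
                             probeset_id = em$probesets$probeset_id[j])
    r <- at$residuals
    n_out <- 0L
    if (filter) {
      mask <- filter_outliers(r, n_sd = n_sd)
      r[mask] <- NA
      n_out <- sum(mask)
    }
    res[, j] <- r
    diag_list[[j]] <- data.frame(probeset_id = at$probeset_id,
                                 n_used = sum(!is.na(r)),
                                 n_outliers = n_out,
                                 iterations = at$iterations,
                                 converged = at$converged,
                                 scale = at$scale,
                                 stringsAsFactors = FALSE)
  }
  structure(list(residuals = res, probesets = em$probesets,
                 diagnostics = do.call(rbind, diag_list)),
            class = "adjusted_traits")
}
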