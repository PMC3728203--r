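# Per-(SNP, probeset) quantitative association on adjusted residuals:
# simple linear regression of residual on allele dosage, Wald t statistic
# on n - 2 df, and variance explained (squared Pearson correlation).

#' Test one SNP against one adjusted trait
#'
#' Simple linear regression of residual expression on dosage with
#' pairwise-complete deletion. `beta = cov(g, y) / var(g)`, the Wald
#' statistic `beta/se` is referred to a Student-t distribution with `n - 2`
#' degrees of freedom (two-sided), and `r2` is the squared Pearson
#' correlation of dosage and residual. SNPs monomorphic on the complete
#' subset, traits with zero variance, or fewer than 3 complete pairs give
#' status `"untestable"` with `NA` statistics. A perfectly collinear fit
#' (zero residual variance) gives status `"degenerate"` with the smallest
#' representable positive p.
#'
#' @param g dosage vector (0/1/2/NA).
#' @param y adjusted residual vector, same length.
#' @param snp_id,probeset_id,gene,cohort,locus labels carried into the
#'   result row.
#' @return one-row data.frame: snp_id, probeset_id, gene, beta, se, wald,
#'   p, r2, n, direction, status, cohort, locus.
#' @export
fit_single <- function(g, y, snp_id = "snp", probeset_id = "probe",
                       gene = NA_character_, cohort = NA_character_,
                       locus = NA_character_) {
  ok <- !is.na(g) & !is.na(y)
  n <- sum(ok)
  row <- data.frame(snp_id = snp_id, probeset_id = probeset_id, gene = gene,
                    beta = NA_real_, se = NA_real_, wald = NA_real_,
                    p = NA_real_, r2 = NA_real_, n = n,
                    direction = NA_integer_, status = "untestable",
                    cohort = cohort, locus = locus, stringsAsFactors = FALSE)
  if (n < 3) return(row)
  g <- g[ok]; y <- y[ok]
  sxx <- sum((g - mean(g))^2)
  syy <- sum((y - mean(y))^2)
  if (sxx <= 0 || syy <= 0) return(row)
  sxy <- sum((g - mean(g)) * (y - mean(y)))
  beta <- sxy / sxx
  sse <- syy - beta * sxy
  r2 <- sxy^2 / (sxx * syy)
  row$beta <- beta
  row$r2 <- min(max(r2, 0), 1)
  row$direction <- as.integer(sign(beta))
  if (sse <= .Machine$double.eps * syy) {
    row$se <- 0
    row$wald <- Inf * sign(beta)
    row$p <- .Machine$double.xmin
    row$status <- "degenerate"
    return(row)
  }
  se <- sqrt(sse / (n - 2) / sxx)
  tstat <- beta / se
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  row$se <- se
  row$wald <- tstat
  row$p <- max(p, .Machine$double.xmin)
  row$status <- "ok"
  row
}

#' Scan a locus: every SNP against every probeset
#'
#' Vectorized over SNPs with pairwise-complete deletion per test. When a
#' `locus` is given, SNPs are restricted to its window and probesets to its
#' gene list; otherwise the full panel is scanned. Output rows are in
#' deterministic (probeset-major, SNP order) order and include untestable
#' pairs with flagged status, so the row count is always
#' `n_snps_in_window * n_probesets_in_locus`.
#'
#' @param genotypes a [genotype_matrix()].
#' @param adjusted an [adjust_expression()] result (or any list with a
#'   samples x probesets `residuals` matrix and `probesets` map).
#' @param locus optional [locus_definition()].
#' @param cohort cohort label for the result rows.
#' @return data.frame of results, one row per (SNP, probeset) pair.
#' @export
scan_locus <- function(genotypes, adjusted, locus = NULL,
                       cohort = NA_character_) {
  snps <- genotypes$snps
  keep_snp <- rep(TRUE, nrow(snps))
  locus_name <- NA_character_
  probes <- adjusted$probesets
  keep_probe <- rep(TRUE, nrow(probes))
  if (!is.null(locus)) {
    locus_name <- locus$name
    keep_snp <- snps$chrom == locus$chrom & snps$pos >= locus$start &
      snps$pos <= locus$end
    if (length(locus$genes) > 0) {
      keep_probe <- probes$gene %in% locus$genes
    }
  }
  if (!any(keep_snp) || !any(keep_probe)) {
    warning("empty scan: ", sum(keep_snp), " SNPs x ", sum(keep_probe),
            " probesets in window")
    return(empty_results())
  }
  ids <- intersect(genotypes$sample_ids, rownames(adjusted$residuals))
  G <- genotypes$dosages[ids, keep_snp, drop = FALSE]
  Y <- adjusted$residuals[ids, keep_probe, drop = FALSE]
  snps <- snps[keep_snp, , drop = FALSE]
  probes <- probes[keep_probe, , drop = FALSE]

  Gm <- !is.na(G)
  G0 <- ifelse(Gm, G, 0)
  G0sq <- G0^2
  out <- vector("list", ncol(Y))
  for (p in seq_len(ncol(Y))) {
    y <- Y[, p]
    w <- as.numeric(!is.na(y))
    y0 <- ifelse(is.na(y), 0, y)
    nv <- drop(crossprod(Gm, w))
    sg <- drop(crossprod(G0, w))
    sgg <- drop(crossprod(G0sq, w))
    sy <- drop(crossprod(Gm, y0 * w))
    syy <- drop(crossprod(Gm, y0^2 * w))
    sgy <- drop(crossprod(G0, y0 * w))
    sxx <- sgg - sg^2 / nv
    syy_c <- syy - sy^2 / nv
    sxy <- sgy - sg * sy / nv
    beta <- sxy / sxx
    sse <- syy_c - beta * sxy
    r2 <- sxy^2 / (sxx * syy_c)
    se <- sqrt(pmax(sse, 0) / (nv - 2) / sxx)
    tstat <- beta / se
    pval <- 2 * stats::pt(abs(tstat), df = nv - 2, lower.tail = FALSE)
    status <- rep("ok", length(nv))
    eps <- .Machine$double.eps
    untest <- nv < 3 | sxx <= eps * pmax(sgg, 1) | syy_c <= eps * pmax(syy, 1)
    degen <- !untest & sse <= eps * syy_c
    status[degen] <- "degenerate"
    pval[degen] <- .Machine$double.xmin
    se[degen] <- 0
    tstat[degen] <- Inf * sign(beta[degen])
    status[untest] <- "untestable"
    beta[untest] <- se[untest] <- tstat[untest] <- pval[untest] <-
      r2[untest] <- NA_real_
    out[[p]] <- data.frame(
      snp_id = snps$snp_id, probeset_id = probes$probeset_id[p],
      gene = probes$gene[p], beta = beta, se = se, wald = tstat,
      p = pmax(pval, .Machine$double.xmin),
      r2 = pmin(pmax(r2, 0), 1), n = as.integer(nv),
      direction = as.integer(sign(beta)), status = status,
      cohort = cohort, locus = locus_name, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

empty_results <- function() {
  data.frame(snp_id = character(0), probeset_id = character(0),
             gene = character(0), beta = numeric(0), se = numeric(0),
             wald = numeric(0), p = numeric(0), r2 = numeric(0),
             n = integer(0), direction = integer(0), status = character(0),
             cohort = character(0), locus = character(0),
             stringsAsFactors = FALSE)
}

#' Export per-eQTL boxplot data (genotype group -> expression values)
#'
#' Mirrors the genotype-group boxplots used to display single eQTLs: for one
#' SNP and one trait, returns the adjusted expression values grouped by
#' dosage.
#'
#' @param genotypes a [genotype_matrix()].
#' @param adjusted an [adjust_expression()] result.
#' @param snp_id,probeset_id the pair to export.
#' @return data.frame with columns sample_id, dosage, residual (complete
#'   pairs only).
#' @export
boxplot_data <- function(genotypes, adjusted, snp_id, probeset_id) {
  ids <- intersect(genotypes$sample_ids, rownames(adjusted$residuals))
  g <- genotypes$dosages[ids, snp_id]
  y <- adjusted$residuals[ids, probeset_id]
  ok <- !is.na(g) & !is.na(y)
  data.frame(sample_id = ids[ok], dosage = g[ok], residual = y[ok],
             stringsAsFactors = FALSE)
}
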