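# Linkage disequilibrium from unphased dosages (composite r^2) and the
# r^2 > 0.5 rule linking eQTL-SNPs to GWAS SNPs.

#' Pairwise r-squared between two dosage vectors
#'
#' Composite-LD approximation for unphased data: the squared Pearson
#' correlation of the two dosage vectors on pairwise-complete samples.
#' Undefined (monomorphic on the complete subset, or fewer than 3 complete
#' pairs) returns `NA` with attribute `reason` rather than 0.
#'
#' @param g1,g2 dosage vectors of equal length.
#' @return r-squared in \[0, 1\], with attribute `n` (samples used); `NA`
#'   when undefined.
#' @export
r2_dosage <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  n <- sum(ok)
  if (n < 3) {
    return(structure(NA_real_, n = n, reason = "fewer than 3 complete pairs"))
  }
  a <- g1[ok]; b <- g2[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    return(structure(NA_real_, n = n, reason = "monomorphic on complete subset"))
  }
  r <- stats::cor(a, b)
  structure(min(r^2, 1), n = n)
}

#' Pairwise LD matrix for a set of SNPs
#'
#' @param genotypes a [genotype_matrix()].
#' @param snp_ids optional subset of SNP IDs.
#' @return symmetric matrix of r-squared values (`NA` where undefined).
#' @export
ld_matrix <- function(genotypes, snp_ids = NULL) {
  D <- genotypes$dosages
  if (!is.null(snp_ids)) D <- D[, snp_ids, drop = FALSE]
  r <- suppressWarnings(stats::cor(D, use = "pairwise.complete.obs"))
  m <- r^2
  m[m > 1] <- 1
  diag(m) <- ifelse(apply(D, 2, function(x) {
    stats::var(x, na.rm = TRUE) > 0
  }), 1, NA)
  m
}

#' Link significant eQTL-SNPs to GWAS SNPs by LD
#'
#' For each distinct SNP among the significant eQTLs, computes r-squared to
#' every GWAS SNP present in the genotype panel and reports the best one;
#' `linked` is `TRUE` when that maximum exceeds `r2_threshold`. GWAS SNPs
#' absent from the panel are reported separately with status
#' `"not_genotyped"` (no r-squared is invented for them).
#'
#' @param eqtl_results data.frame of significant results (needs `snp_id`).
#' @param gwas_snps data.frame with `snp_id` (and optionally `pos`) of GWAS
#'   SNPs; must be non-empty.
#' @param genotypes a [genotype_matrix()] containing the eQTL-SNPs.
#' @param r2_threshold linkage rule threshold (default 0.5).
#' @return list: `links` (data.frame eqtl_snp, best_gwas_snp, r2, n,
#'   linked) and `not_genotyped` (character vector of absent GWAS SNPs).
#' @export
link_to_gwas <- function(eqtl_results, gwas_snps, genotypes,
                         r2_threshold = 0.5) {
  if (is.null(gwas_snps) || nrow(gwas_snps) == 0) {
    stop("empty GWAS SNP list")
  }
  panel <- genotypes$snps$snp_id
  present <- gwas_snps$snp_id[gwas_snps$snp_id %in% panel]
  absent <- setdiff(gwas_snps$snp_id, panel)
  esnps <- sort(unique(eqtl_results$snp_id))
  if (length(esnps) == 0 || length(present) == 0) {
    links <- data.frame(eqtl_snp = esnps, best_gwas_snp = NA_character_,
                        r2 = NA_real_, n = NA_integer_, linked = NA,
                        stringsAsFactors = FALSE)
    return(list(links = links, not_genotyped = absent))
  }
  links <- do.call(rbind, lapply(esnps, function(s) {
    g <- genotypes$dosages[, s]
    r2s <- vapply(present, function(w) {
      as.numeric(r2_dosage(g, genotypes$dosages[, w]))
    }, numeric(1))
    if (all(is.na(r2s))) {
      return(data.frame(eqtl_snp = s, best_gwas_snp = NA_character_,
                        r2 = NA_real_, n = NA_integer_, linked = NA,
                        stringsAsFactors = FALSE))
    }
    best <- which.max(r2s)
    n_used <- attr(r2_dosage(g, genotypes$dosages[, present[best]]), "n")
    data.frame(eqtl_snp = s, best_gwas_snp = present[best],
               r2 = r2s[best], n = n_used,
               linked = r2s[best] > r2_threshold, stringsAsFactors = FALSE)
  }))
  rownames(links) <- NULL
  list(links = links, not_genotyped = absent)
}
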