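# Multi-cohort simulator: haplotype-pool LD blocks, Table-1-like covariates,
# expression with additive covariate effects, planted cis-eQTLs and gross
# outliers. Everything is deterministic under the config seed.

#' Simulation configuration
#'
#' Defaults emulate the three-cohort lung eQTL study the pipeline was built
#' for: cohorts of 409/339/363 samples, a ~2 Mb locus of 700 SNPs in 10
#' independent LD blocks drawn from small haplotype pools, 50 probesets over
#' 14 genes, and planted cis-eQTLs whose variance explained spans roughly
#' 0.05 to 0.57 (the range of the study's headline signals). Covariate
#' distributions follow the discovery cohort: age about 63 +/- 10 years, 56%
#' male, smoking status mostly ex-smokers.
#'
#' @param seed integer seed; every downstream draw derives from it.
#' @param n_samples integer vector, one entry per cohort.
#' @param cohort_names labels, first is the discovery cohort.
#' @param n_blocks number of independent LD blocks.
#' @param snps_per_block SNPs per block (total SNPs = n_blocks x
#'   snps_per_block).
#' @param haplotypes_per_block size of the haplotype pool each individual's
#'   two block haplotypes are drawn from; small pools give strong blocky LD.
#' @param maf_range target allele-frequency range used when building pools.
#' @param chrom,locus_start chromosome label and window start for SNP
#'   positions, which are evenly spaced over `locus_span_bp`.
#' @param locus_span_bp physical span of the simulated locus.
#' @param n_probesets,n_genes probesets and genes on the simulated array.
#' @param planted_eqtls data.frame with columns `snp`, `probeset` (1-based
#'   indices), `h2` (variance explained on the covariate-adjusted scale,
#'   in \[0,1)) and `direction` (+1/-1). `NULL` plants a default ladder of
#'   six eQTLs with h2 from 0.05 to 0.57.
#' @param age_mean,age_sd,male_fraction,smoking_probs,smoking_missing
#'   per-cohort covariate parameters (recycled across cohorts);
#'   `smoking_probs` are c(never, ex, current) proportions among non-missing.
#' @param beta_age,beta_sex,beta_smoking_ex,beta_smoking_current covariate
#'   effects on expression (log-intensity units; per year for age).
#' @param noise_sd residual SD of expression noise.
#' @param outlier_fraction,outlier_sd fraction of samples per probeset that
#'   receive extra noise of SD `outlier_sd` (gross outliers for the 3-SD
#'   filter).
#' @param dosage_missing_rate fraction of genotype calls set missing.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_samples = c(409L, 339L, 363L),
                       cohort_names = c("discovery", "rep1", "rep2"),
                       n_blocks = 10L,
                       snps_per_block = 70L,
                       haplotypes_per_block = 8L,
                       maf_range = c(0.05, 0.5),
                       chrom = "4",
                       locus_start = 88875909,
                       locus_span_bp = 2010388,
                       n_probesets = 50L,
                       n_genes = 14L,
                       planted_eqtls = NULL,
                       age_mean = c(63.3, 60.2, 51.5),
                       age_sd = c(9.9, 14.3, 15.5),
                       male_fraction = c(0.559, 0.537, 0.532),
                       smoking_probs = c(never = 0.088, ex = 0.692,
                                         current = 0.220),
                       smoking_missing = c(0, 0.153, 0.058),
                       beta_age = 0.02,
                       beta_sex = 0.25,
                       beta_smoking_ex = 0.15,
                       beta_smoking_current = 0.30,
                       noise_sd = 1,
                       outlier_fraction = 0.01,
                       outlier_sd = 5,
                       dosage_missing_rate = 0.01) {
  if (haplotypes_per_block < 1) stop("haplotypes_per_block must be >= 1")
  if (any(maf_range <= 0) || any(maf_range > 0.5)) {
    stop("maf_range must lie in (0, 0.5]")
  }
  if (outlier_fraction < 0 || outlier_fraction >= 1) {
    stop("outlier_fraction must be in [0, 1)")
  }
  n_snps <- n_blocks * snps_per_block
  if (is.null(planted_eqtls)) {
    # one eQTL per block for the first six blocks, h2 ladder spanning the
    # observed range; alternating direction
    h2 <- c(0.57, 0.50, 0.30, 0.125, 0.076, 0.05)
    h2 <- h2[seq_len(min(length(h2), n_blocks, n_probesets))]
    planted_eqtls <- data.frame(
      snp = as.integer((seq_along(h2) - 1L) * snps_per_block +
                         snps_per_block %/% 2L),
      probeset = seq_along(h2),
      h2 = h2,
      direction = rep(c(1, -1), length.out = length(h2)))
  }
  if (any(planted_eqtls$h2 < 0 | planted_eqtls$h2 >= 1)) {
    stop("planted h2 must be in [0, 1)")
  }
  if (any(planted_eqtls$snp < 1 | planted_eqtls$snp > n_snps) ||
      any(planted_eqtls$probeset < 1 | planted_eqtls$probeset > n_probesets)) {
    stop("planted eQTL indices out of range")
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate haplotype pools shared across cohorts
#'
#' Each block gets a pool of `haplotypes_per_block` binary haplotypes whose
#' per-SNP allele probabilities are drawn uniformly from `maf_range`. The
#' same pools are reused for every cohort so cross-cohort LD is consistent.
#'
#' @param config a [sim_config()].
#' @return list of 0/1 matrices (pool haplotypes x SNPs in block).
#' @export
simulate_haplotype_pools <- function(config) {
  H <- config$haplotypes_per_block
  lapply(seq_len(config$n_blocks), function(b) {
    f <- runif(config$snps_per_block, config$maf_range[1], config$maf_range[2])
    pool <- matrix(rbinom(H * config$snps_per_block, 1, rep(f, each = H)),
                   nrow = H)
    if (H >= 2) {
      # genotyping panels target polymorphic SNPs: keep every pool column
      # segregating by flipping one haplotype where a draw came out fixed
      for (j in seq_len(ncol(pool))) {
        s <- sum(pool[, j])
        if (s == 0L) pool[sample.int(H, 1), j] <- 1L
        if (s == H) pool[sample.int(H, 1), j] <- 0L
      }
    }
    pool
  })
}

#' Simulate a cohort's genotypes from shared haplotype pools
#'
#' Every individual draws two haplotypes (with replacement) from each
#' block's pool; the dosage is the allele sum. Blocks are independent, so
#' between-block LD is nil by construction while small pools give strong
#' within-block LD. SNP positions are evenly spaced over the locus span.
#'
#' @param config a [sim_config()].
#' @param n number of individuals.
#' @param pools haplotype pools from [simulate_haplotype_pools()]; generated
#'   fresh if `NULL`.
#' @param sample_prefix prefix for generated sample IDs.
#' @return a [genotype_matrix()].
#' @export
simulate_genotypes <- function(config, n, pools = NULL,
                               sample_prefix = "S") {
  if (is.null(pools)) pools <- simulate_haplotype_pools(config)
  blocks <- lapply(pools, function(pool) {
    h1 <- pool[sample.int(nrow(pool), n, replace = TRUE), , drop = FALSE]
    h2 <- pool[sample.int(nrow(pool), n, replace = TRUE), , drop = FALSE]
    h1 + h2
  })
  dos <- do.call(cbind, blocks)
  if (config$dosage_missing_rate > 0) {
    miss <- runif(length(dos)) < config$dosage_missing_rate
    dos[miss] <- NA
  }
  n_snps <- config$n_blocks * config$snps_per_block
  pos <- config$locus_start +
    round(seq(0, config$locus_span_bp, length.out = n_snps))
  snps <- snp_table(sprintf("snp_%04d", seq_len(n_snps)),
                    chrom = config$chrom, pos = pos,
                    ref_allele = "A", alt_allele = "G")
  rownames(dos) <- sprintf("%s%04d", sample_prefix, seq_len(n))
  genotype_matrix(dos, snps)
}

#' Simulate covariates for one cohort
#'
#' Age is normal truncated to (18, 95); sex is Bernoulli on the male
#' fraction; smoking is multinomial over never/ex/current with an optional
#' missing fraction.
#'
#' @param n cohort size.
#' @param age_mean,age_sd,male_fraction,smoking_probs,smoking_missing
#'   distribution parameters (defaults mimic the discovery cohort).
#' @param sample_prefix prefix for generated sample IDs.
#' @return a [covariate_table()].
#' @export
simulate_covariates <- function(n, age_mean = 63.3, age_sd = 9.9,
                                male_fraction = 0.559,
                                smoking_probs = c(never = 0.088, ex = 0.692,
                                                  current = 0.220),
                                smoking_missing = 0,
                                sample_prefix = "S") {
  age <- rnorm(n, age_mean, age_sd)
  # truncated by redraw; plausible adult surgical-cohort ages
  while (any(bad <- age <= 18 | age >= 95)) {
    age[bad] <- rnorm(sum(bad), age_mean, age_sd)
  }
  sex <- ifelse(runif(n) < male_fraction, "male", "female")
  sp <- smoking_probs / sum(smoking_probs)
  smoking <- sample(c("never", "ex", "current"), n, replace = TRUE, prob = sp)
  if (smoking_missing > 0) {
    smoking[runif(n) < smoking_missing] <- NA
  }
  covariate_table(sprintf("%s%04d", sample_prefix, seq_len(n)),
                  age, sex, smoking)
}

#' Simulate expression traits with planted cis-eQTLs
#'
#' Each probeset is `intercept + covariate effects + beta_g * dosage +
#' noise`. For a planted eQTL the genetic effect is scaled to the realized
#' genotype variance so that `Var(beta_g * g) / (Var(beta_g * g) +
#' noise_sd^2) = h2`; h2 is therefore the variance explained after covariate
#' adjustment, matching what the downstream scan estimates. Probesets
#' without a planted eQTL carry covariate effects and noise only. A random
#' `outlier_fraction` of samples per probeset receives extra noise of SD
#' `outlier_sd`.
#'
#' @param genotypes a [genotype_matrix()] for the cohort.
#' @param covariates a [covariate_table()] (same samples, same order).
#' @param config a [sim_config()].
#' @return list with `expression` (an [expression_matrix()]) and `truth`
#'   (data.frame: snp_id, probeset_id, true_beta, true_h2, direction).
#' @export
simulate_expression <- function(genotypes, covariates, config) {
  n <- length(genotypes$sample_ids)
  P <- config$n_probesets
  genes <- sprintf("GENE%02d", rep(seq_len(config$n_genes), length.out = P))
  probes <- data.frame(probeset_id = sprintf("ps_%03d", seq_len(P)),
                       gene = genes, stringsAsFactors = FALSE)

  sexn <- as.numeric(covariates$sex == "male")
  smk_ex <- as.numeric(covariates$smoking == "ex")
  smk_cur <- as.numeric(covariates$smoking == "current")
  # missing covariates contribute no effect here; they are dropped later by
  # the adjustment stage anyway
  base <- config$beta_age * ifelse(is.na(covariates$age), 0, covariates$age) +
    config$beta_sex * ifelse(is.na(sexn), 0, sexn) +
    config$beta_smoking_ex * ifelse(is.na(smk_ex), 0, smk_ex) +
    config$beta_smoking_current * ifelse(is.na(smk_cur), 0, smk_cur)

  vals <- matrix(rnorm(n * P, sd = config$noise_sd), n, P)
  vals <- vals + base + 8  # array log-intensity baseline
  truth <- config$planted_eqtls
  truth$snp_id <- genotypes$snps$snp_id[truth$snp]
  truth$probeset_id <- probes$probeset_id[truth$probeset]
  truth$true_beta <- NA_real_
  for (k in seq_len(nrow(truth))) {
    g <- genotypes$dosages[, truth$snp[k]]
    vg <- stats::var(g, na.rm = TRUE)
    if (!is.finite(vg) || vg == 0) {
      stop("planted eQTL on monomorphic SNP: ", truth$snp_id[k])
    }
    h2 <- truth$h2[k]
    beta <- truth$direction[k] * config$noise_sd * sqrt(h2 / (1 - h2)) /
      sqrt(vg)
    truth$true_beta[k] <- beta
    gc <- ifelse(is.na(g), mean(g, na.rm = TRUE), g)  # mean-impute for signal
    vals[, truth$probeset[k]] <- vals[, truth$probeset[k]] + beta * gc
  }
  if (config$outlier_fraction > 0 && config$outlier_sd > 0) {
    out <- matrix(runif(n * P) < config$outlier_fraction, n, P)
    vals[out] <- vals[out] + rnorm(sum(out), sd = config$outlier_sd)
  }
  rownames(vals) <- genotypes$sample_ids
  list(expression = expression_matrix(vals, probes),
       truth = truth[, c("snp_id", "probeset_id", "snp", "probeset",
                         "true_beta", "h2", "direction")])
}

#' Simulate a full multi-cohort study
#'
#' Generates shared haplotype pools, then per-cohort genotypes, covariates
#' and expression with the same SNP panel and planted truth everywhere.
#' Fully deterministic under `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list of class `simulated_study`: `cohorts` (named list with
#'   `genotypes`, `expression`, `covariates` per cohort), `truth`, `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  set.seed(config$seed)
  pools <- simulate_haplotype_pools(config)
  k <- length(config$n_samples)
  cn <- rep(config$cohort_names, length.out = k)
  rec <- function(x, i) x[[((i - 1L) %% length(x)) + 1L]]
  cohorts <- list()
  truth <- NULL
  for (i in seq_len(k)) {
    n <- config$n_samples[i]
    prefix <- sprintf("%s_", cn[i])
    gm <- simulate_genotypes(config, n, pools, sample_prefix = prefix)
    cv <- simulate_covariates(n,
                              age_mean = rec(config$age_mean, i),
                              age_sd = rec(config$age_sd, i),
                              male_fraction = rec(config$male_fraction, i),
                              smoking_probs = config$smoking_probs,
                              smoking_missing = rec(config$smoking_missing, i),
                              sample_prefix = prefix)
    ex <- simulate_expression(gm, cv, config)
    truth <- ex$truth  # identical panel and plan in every cohort
    cohorts[[cn[i]]] <- list(genotypes = gm, expression = ex$expression,
                             covariates = cv)
  }
  structure(list(cohorts = cohorts, truth = truth, config = config),
            class = "simulated_study")
}

#' Write a simulated study to disk in the pipeline's input formats
#'
#' Per cohort: `<name>_dosages.tsv`, `<name>_snps.tsv`, `<name>_expr.tsv`,
#' `<name>_probes.tsv`, `<name>_covariates.tsv`; plus `truth.tsv`.
#'
#' @param study a [simulate_study()] result.
#' @param dir output directory (created if absent).
#' @param vcf also write per-cohort VCF genotype files.
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir, vcf = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(study$cohorts)) {
    co <- study$cohorts[[nm]]
    write_genotypes_tsv(co$genotypes,
                        file.path(dir, paste0(nm, "_dosages.tsv")),
                        file.path(dir, paste0(nm, "_snps.tsv")))
    write_expression_tsv(co$expression,
                         file.path(dir, paste0(nm, "_expr.tsv")),
                         file.path(dir, paste0(nm, "_probes.tsv")))
    write_covariates_tsv(co$covariates,
                         file.path(dir, paste0(nm, "_covariates.tsv")))
    if (vcf) write_vcf(co$genotypes, file.path(dir, paste0(nm, ".vcf")))
  }
  data.table::fwrite(study$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE)
  invisible(dir)
}
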