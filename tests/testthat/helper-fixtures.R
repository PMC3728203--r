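# Fixtures are built in code; nothing is read from disk except what a test
# writes itself.

# 3-sample, 2-SNP toy VCF covering all genotype codes incl. missing.
write_toy_vcf <- function(path, alt1 = "T") {
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "NA1", "NA2", "NA3", sep = "\t"),
    paste("4", "89875909", "rs0001", "A", alt1, ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", sep = "\t"),
    paste("4", "89883979", "rs0002", "G", "C", ".", "PASS", ".", "GT",
          "0|1", "./.", "1/1", sep = "\t")), path)
  path
}

# deterministic covariate table without randomness
fixed_covariates <- function(n = 20) {
  covariate_table(sprintf("S%02d", seq_len(n)),
                  age = 40 + seq_len(n),
                  sex = rep(c("male", "female"), length.out = n),
                  smoking = rep(c("never", "ex", "current"),
                                length.out = n))
}

# tiny two-block genotype matrix with perfect within-block LD
two_block_genotypes <- function(n = 40, seed = 11) {
  set.seed(seed)
  h1 <- rbinom(n, 1, 0.4); h2 <- rbinom(n, 1, 0.4)
  b1 <- h1 + h2                      # block 1: 3 identical SNPs
  g1 <- rbinom(n, 1, 0.5); g2 <- rbinom(n, 1, 0.5)
  b2 <- g1 + g2                      # block 2: independent of block 1
  dos <- cbind(b1, b1, b1, b2, b2)
  snps <- snp_table(paste0("s", 1:5), "1", c(100, 200, 300, 5e5, 5e5 + 100),
                    "A", "G")
  genotype_matrix(dos, snps, sprintf("S%03d", seq_len(n)))
}

# small simulated study for pipeline-level tests
small_study_config <- function(seed = 5) {
  sim_config(seed = seed, n_samples = c(200L, 160L, 160L),
             n_blocks = 4L, snps_per_block = 15L, n_probesets = 8L,
             n_genes = 4L,
             planted_eqtls = data.frame(snp = c(8L, 23L), probeset = c(1L, 2L),
                                        h2 = c(0.5, 0.3), direction = c(1, -1)))
}
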