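test_that("read_vcf encodes additive dosages and metadata from a toy VCF", {
  path <- write_toy_vcf(withr::local_tempfile(fileext = ".vcf"))
  gm <- read_vcf(path)
  expect_s3_class(gm, "genotype_matrix")
  # hand-encoded expectations, cell by cell
  expect_identical(unname(gm$dosages[, "rs0001"]), c(0, 1, 2))
  expect_identical(unname(gm$dosages[, "rs0002"]), c(1, NA, 2))
  expect_identical(gm$sample_ids, c("NA1", "NA2", "NA3"))
  expect_identical(gm$snps$pos, c(89875909L, 89883979L))
  expect_identical(gm$snps$counted_allele, gm$snps$alt_allele)
})

test_that("read_vcf rejects multi-allelic records", {
  path <- write_toy_vcf(withr::local_tempfile(fileext = ".vcf"),
                        alt1 = "T,C")
  expect_error(read_vcf(path), "multi-allelic")
})

test_that("VCF round-trip preserves dosages", {
  path <- write_toy_vcf(withr::local_tempfile(fileext = ".vcf"))
  gm <- read_vcf(path)
  out <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(gm, out)
  gm2 <- read_vcf(out)
  expect_equal(gm2$dosages, gm$dosages)
  expect_equal(gm2$snps, gm$snps)
})

test_that("matrix TSV handles missing cells, transposition and round-trips", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tc1\tc2", "r1\t1.5\t", "r2\t0\t2"), path)
  m <- read_matrix_tsv(path)
  expect_equal(dim(m), c(2L, 2L))
  expect_true(is.na(m["r1", "c2"]))
  expect_equal(m["r2", "c2"], 2)
  # transposed orientation: same data, axes swapped
  mt <- read_matrix_tsv(path, orientation = "samples_in_columns")
  expect_equal(mt, t(m))
  # round-trip identity
  out <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(m, out)
  expect_equal(read_matrix_tsv(out), m)
})

test_that("ragged TSV rows are rejected with the row number", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tc1\tc2", "r1\t1\t2", "r2\t3"), path)
  expect_error(read_matrix_tsv(path), "row 3")
})

test_that("containers validate their invariants", {
  expect_error(snp_table(c("a", "a"), "1", c(1, 2), "A", "G"), "duplicate")
  expect_error(snp_table("a", "1", 0, "A", "G"), "1-based")
  expect_error(snp_table("a", "1", 5, "A", "G", counted_allele = "T"),
               "counted_allele")
  expect_error(genotype_matrix(matrix(3, 1, 1),
                               snp_table("a", "1", 5, "A", "G"), "S1"),
               "0, 1, 2")
  expect_error(covariate_table("S1", -5, "male", "never"), "age")
  expect_error(covariate_table("S1", 50, "male", "sometimes"), "smoking")
  # unknown smoking maps to NA
  cv <- covariate_table(c("S1", "S2"), c(50, 60), c("male", "female"),
                        c("unknown", "ex"))
  expect_true(is.na(cv$smoking[1]))
  expect_error(locus_definition("x", "1", 10, 5), "start")
})

test_that("write_results orders deterministically and round-trips", {
  res <- data.frame(snp_id = c("b", "a", "c"), probeset_id = "p1",
                    gene = "G", beta = c(1, 2, 3), se = 0.1,
                    wald = c(10, 20, 30), p = c(0.01, 0.01, 0.5),
                    r2 = c(0.1, 0.2, 0.3), n = 10L, direction = 1L,
                    status = "ok", cohort = "d", locus = "L",
                    stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_results(res, path)
  back <- read_results(path)
  # equal p ordered by snp_id tie-break
  expect_identical(back$snp_id, c("a", "b", "c"))
  expect_equal(back$beta, c(2, 1, 3))
  # empty result: header only
  write_results(res[0, ], path)
  expect_equal(nrow(read_results(path)), 0L)
  expect_match(readLines(path)[1], "snp_id\tprobeset_id")
})

test_that("genotype, expression and covariate TSVs round-trip", {
  gm <- two_block_genotypes()
  d <- withr::local_tempfile(fileext = ".tsv")
  s <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes_tsv(gm, d, s)
  gm2 <- read_genotypes_tsv(d, s)
  expect_equal(gm2$dosages, gm$dosages)
  expect_equal(gm2$snps, gm$snps)

  cv <- fixed_covariates()
  cv$age[3] <- NA
  p <- withr::local_tempfile(fileext = ".tsv")
  write_covariates_tsv(cv, p)
  cv2 <- read_covariates_tsv(p)
  expect_equal(cv2$age, cv$age)
  expect_equal(as.character(cv2$smoking), as.character(cv$smoking))

  em <- expression_matrix(matrix(rnorm(40), 10, 4,
                                 dimnames = list(sprintf("S%02d", 1:10),
                                                 paste0("ps", 1:4))),
                          data.frame(probeset_id = paste0("ps", 1:4),
                                     gene = c("g1", "g1", "g2", "g2")))
  v <- withr::local_tempfile(fileext = ".tsv")
  pm <- withr::local_tempfile(fileext = ".tsv")
  write_expression_tsv(em, v, pm)
  em2 <- read_expression_tsv(v, pm)
  expect_equal(em2$values, em$values)
  expect_equal(em2$probesets, em$probesets)
})
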