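mk_res <- function(p, dir = 1L, snp = "s1", probe = "p1") {
  data.frame(snp_id = snp, probeset_id = probe, gene = "g", beta = dir * 0.5,
             se = 0.1, wald = dir * 5, p = p, r2 = 0.1, n = 100L,
             direction = as.integer(dir), status = "ok", cohort = "x",
             locus = "L", stringsAsFactors = FALSE)
}

test_that("replication rule application", {
  disc <- mk_res(1e-8)
  reps <- list(rep1 = mk_res(0.01), rep2 = mk_res(0.2))
  rec <- classify_replication(disc, reps, threshold = 5.1e-6)
  expect_equal(as.character(rec$status), "replicated_one")
  expect_true(rec$direction_consistent)
  # discovery p above threshold: not_significant regardless of replication
  rec2 <- classify_replication(mk_res(1e-4), reps, threshold = 5.1e-6)
  expect_equal(as.character(rec2$status), "not_significant")
  # both replications significant
  rec3 <- classify_replication(disc, list(a = mk_res(0.01), b = mk_res(0.001)),
                               threshold = 5.1e-6)
  expect_equal(as.character(rec3$status), "replicated_both")
  # untestable replication counts as non-replicating
  unt <- mk_res(NA); unt$status <- "untestable"
  rec4 <- classify_replication(disc, list(a = mk_res(0.01), b = unt),
                               threshold = 5.1e-6)
  expect_equal(as.character(rec4$status), "replicated_one")
})

test_that("direction handling: recorded always, required only in strict mode", {
  disc <- mk_res(1e-8, dir = 1L)
  flip <- mk_res(0.01, dir = -1L)
  nonsig <- mk_res(0.5, dir = 1L)
  rec <- classify_replication(disc, list(a = flip, b = nonsig),
                              threshold = 5.1e-6)
  expect_equal(as.character(rec$status), "replicated_one")
  expect_false(rec$direction_consistent)
  strict <- classify_replication(disc, list(a = flip, b = nonsig),
                                 threshold = 5.1e-6,
                                 require_direction = TRUE)
  expect_equal(as.character(strict$status), "discovery_only")
  # a single replication cohort that replicates counts as replicated_both
  one <- classify_replication(disc, list(a = mk_res(0.01)),
                              threshold = 5.1e-6)
  expect_equal(as.character(one$status), "replicated_both")
})

test_that("key mismatches across cohorts are rejected", {
  disc <- rbind(mk_res(1e-8, snp = "s1"), mk_res(1e-8, snp = "s2"))
  expect_error(classify_replication(disc, list(a = mk_res(0.01, snp = "s1")),
                                    threshold = 5.1e-6),
               "missing key")
})

test_that("identical cohorts replicate everything; alpha_rep is monotone", {
  study <- simulate_study(small_study_config(seed = 73))
  co <- study$cohorts$discovery
  adj <- adjust_expression(co$expression, co$covariates)
  disc <- scan_locus(co$genotypes, adj, cohort = "d")
  thr <- 1e-4
  same <- classify_replication(disc, list(a = disc, b = disc), thr)
  sig <- same$status != "not_significant"
  expect_true(any(sig))
  expect_true(all(same$status[sig] == "replicated_both"))
  expect_true(all(same$direction_consistent[sig]))
  # lowering alpha_rep never raises a status
  loose <- classify_replication(disc, list(a = disc, b = disc), thr,
                                alpha_rep = 0.05)
  tight <- classify_replication(disc, list(a = disc, b = disc), thr,
                                alpha_rep = 1e-30)
  expect_true(all(as.integer(tight$status) <= as.integer(loose$status)))
})

test_that("planted eQTLs replicate across simulated cohorts", {
  # 10 planted eQTLs at h2 = 0.3 shared by 3 cohorts of n = 350: power at
  # p < 0.05 is essentially 1, so nearly all should be replicated_both
  cfg <- sim_config(seed = 79, n_samples = c(350L, 350L, 350L),
                    n_blocks = 10L, snps_per_block = 5L, n_probesets = 10L,
                    n_genes = 5L,
                    planted_eqtls = data.frame(snp = seq(3, 48, by = 5),
                                               probeset = 1:10, h2 = 0.3,
                                               direction = rep(c(1, -1), 5)))
  study <- simulate_study(cfg)
  adj <- lapply(study$cohorts, function(co) {
    adjust_expression(co$expression, co$covariates)
  })
  scans <- mapply(function(co, a, nm) scan_locus(co$genotypes, a, cohort = nm),
                  study$cohorts, adj, names(study$cohorts), SIMPLIFY = FALSE)
  rec <- classify_replication(scans$discovery,
                              scans[c("rep1", "rep2")], threshold = 1e-4)
  key <- paste(rec$snp_id, rec$probeset_id)
  tkey <- paste(study$truth$snp_id, study$truth$probeset_id)
  planted <- rec[key %in% tkey, ]
  expect_gte(sum(planted$status == "replicated_both"), 9)
  expect_true(all(planted$direction_consistent))
})
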