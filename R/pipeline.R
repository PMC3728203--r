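# End-to-end orchestration: locus windows, per-cohort adjustment, scans,
# Li-Ji thresholds, replication, LD linkage and TSV report bundle.

#' Build a locus window around GWAS SNPs
#'
#' The window spans from `min(pos) - flank_bp` (floored at 1) to
#' `max(pos) + flank_bp`, i.e. a flank on each side of the most distant
#' associated SNPs. All SNPs must lie on one chromosome.
#'
#' @param gwas_snps data.frame with columns `snp_id`, `chrom`, `pos`
#'   (1-based).
#' @param flank_bp flank size in bp (default 1 Mb).
#' @param name locus label.
#' @param genes gene symbols tested as cis targets at this locus.
#' @return a [locus_definition()].
#' @export
build_locus_window <- function(gwas_snps, flank_bp = 1e6, name = "locus",
                               genes = character(0)) {
  if (nrow(gwas_snps) < 1) stop("need at least one GWAS SNP")
  if (flank_bp < 0) stop("flank_bp must be >= 0")
  chroms <- unique(gwas_snps$chrom)
  if (length(chroms) > 1) {
    stop("GWAS SNPs span multiple chromosomes: ",
         paste(chroms, collapse = ", "))
  }
  start <- max(1, min(gwas_snps$pos) - flank_bp)
  end <- max(gwas_snps$pos) + flank_bp
  locus_definition(name, chroms, start, end, gwas_snps = gwas_snps,
                   genes = genes)
}

#' Run the full cis-eQTL pipeline on in-memory cohorts
#'
#' For each locus: adjust expression per cohort, scan the discovery cohort,
#' compute the Li-Ji composite threshold, scan the replication cohorts on
#' the significant pairs' full key space, classify replication, and link
#' significant eQTL-SNPs to GWAS SNPs by LD. Reports are written as TSV
#' under `out_dir` and are byte-identical across reruns of the same inputs.
#'
#' @param cohorts named list; each element is a list with `genotypes`,
#'   `expression`, `covariates`.
#' @param loci list of [locus_definition()] objects.
#' @param discovery name of the discovery cohort (default: first).
#' @param alpha family-wise error target for the locus threshold.
#' @param alpha_rep nominal replication level.
#' @param r2_link_threshold LD linkage rule threshold.
#' @param out_dir output directory, created if needed; `NULL` skips writing.
#' @return list of class `eqtl_run`: per locus `threshold`, `scan`
#'   (discovery results), `significant`, `replication`, `ld_links`,
#'   `counts`; plus `log` (character vector of per-stage counts).
#' @export
run_pipeline <- function(cohorts, loci, discovery = names(cohorts)[1],
                         alpha = 0.05, alpha_rep = 0.05,
                         r2_link_threshold = 0.5, out_dir = NULL) {
  if (!discovery %in% names(cohorts)) {
    stop("discovery cohort '", discovery, "' not among cohorts")
  }
  rep_names <- setdiff(names(cohorts), discovery)
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
    invisible(NULL)
  }
  note("cohorts: ", paste(names(cohorts), collapse = ", "),
       " (discovery: ", discovery, ")")

  adjusted <- lapply(cohorts, function(co) {
    adjust_expression(co$expression, co$covariates)
  })

  results <- list()
  for (locus in loci) {
    nm <- locus$name
    note("locus ", nm, ": window ", locus$chrom, ":",
         format(locus$start, scientific = FALSE), "-",
         format(locus$end, scientific = FALSE))
    gm <- cohorts[[discovery]]$genotypes
    in_win <- gm$snps$chrom == locus$chrom & gm$snps$pos >= locus$start &
      gm$snps$pos <= locus$end
    probe_in <- if (length(locus$genes) > 0) {
      adjusted[[discovery]]$probesets$gene %in% locus$genes
    } else rep(TRUE, nrow(adjusted[[discovery]]$probesets))
    note("locus ", nm, ": ", sum(in_win), " SNPs, ", sum(probe_in),
         " probesets in window")
    if (!any(in_win) || !any(probe_in)) {
      warning("locus ", nm, ": empty window, writing empty reports")
      results[[nm]] <- list(threshold = NULL, scan = empty_results(),
                            significant = empty_results(),
                            replication = NULL, ld_links = NULL,
                            counts = c(snps = sum(in_win),
                                       probes = sum(probe_in), tests = 0,
                                       significant = 0, replicated = 0))
      next
    }
    win_ids <- gm$snps$snp_id[in_win]
    ms <- meff_snps(gm, win_ids)
    probe_ids <- adjusted[[discovery]]$probesets$probeset_id[probe_in]
    mp <- meff_probes(adjusted[[discovery]], probe_ids)
    thr <- locus_threshold(ms, mp, alpha = alpha, locus = nm,
                           m_snps = sum(in_win), m_probes = sum(probe_in))
    note("locus ", nm, ": Meff_snps = ", format(ms), ", Meff_probes = ",
         format(mp), ", threshold = ", format(thr$display))

    disc <- scan_locus(gm, adjusted[[discovery]], locus, cohort = discovery)
    tested <- disc[disc$status != "untestable", , drop = FALSE]
    sig <- tested[tested$p < thr$threshold, , drop = FALSE]
    note("locus ", nm, ": ", nrow(disc), " tests (", nrow(tested),
         " testable), ", nrow(sig), " significant")

    reps <- lapply(rep_names, function(rn) {
      scan_locus(cohorts[[rn]]$genotypes, adjusted[[rn]], locus, cohort = rn)
    })
    names(reps) <- rep_names
    repl <- if (length(reps) > 0) {
      classify_replication(disc, reps, thr, alpha_rep = alpha_rep)
    } else NULL
    n_repl <- if (!is.null(repl)) {
      sum(repl$status == "replicated_both", na.rm = TRUE)
    } else NA_integer_
    note("locus ", nm, ": ", n_repl, " replicated in all replication cohorts")

    ldl <- if (!is.null(locus$gwas_snps) && nrow(sig) > 0) {
      link_to_gwas(sig, locus$gwas_snps, gm,
                   r2_threshold = r2_link_threshold)
    } else NULL
    if (!is.null(ldl) && length(ldl$not_genotyped) > 0) {
      note("locus ", nm, ": GWAS SNP(s) not genotyped: ",
           paste(ldl$not_genotyped, collapse = ", "))
    }
    results[[nm]] <- list(threshold = thr, scan = disc, significant = sig,
                          replication = repl, ld_links = ldl,
                          counts = c(snps = sum(in_win),
                                     probes = sum(probe_in),
                                     tests = nrow(disc),
                                     significant = nrow(sig),
                                     replicated = n_repl))
  }
  run <- structure(list(loci = results, log = log_lines,
                        discovery = discovery),
                   class = "eqtl_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' Write an `eqtl_run` report bundle to a directory
#'
#' Files: `thresholds.tsv`, per locus `<name>_eqtls.tsv` (full discovery
#' scan), `<name>_significant.tsv`, `<name>_replication.tsv`,
#' `<name>_ld_links.tsv`, and `run_log.txt`. Output is deterministic (no
#' timestamps), so identical runs produce byte-identical bundles.
#'
#' @param run a [run_pipeline()] result.
#' @param out_dir output directory.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  thr <- do.call(rbind, lapply(run$loci, `[[`, "threshold"))
  if (!is.null(thr)) {
    data.table::fwrite(thr, file.path(out_dir, "thresholds.tsv"),
                       sep = "\t", quote = FALSE)
  }
  for (nm in names(run$loci)) {
    res <- run$loci[[nm]]
    write_results(res$scan, file.path(out_dir, paste0(nm, "_eqtls.tsv")))
    write_results(res$significant,
                  file.path(out_dir, paste0(nm, "_significant.tsv")))
    if (!is.null(res$replication)) {
      rp <- res$replication
      rp$status <- as.character(rp$status)
      o <- order(rp$discovery_p, rp$snp_id, rp$probeset_id, method = "radix")
      data.table::fwrite(rp[o, , drop = FALSE],
                         file.path(out_dir, paste0(nm, "_replication.tsv")),
                         sep = "\t", na = "NA", quote = FALSE)
    }
    if (!is.null(res$ld_links)) {
      data.table::fwrite(res$ld_links$links,
                         file.path(out_dir, paste0(nm, "_ld_links.tsv")),
                         sep = "\t", na = "NA", quote = FALSE)
      writeLines(res$ld_links$not_genotyped,
                 file.path(out_dir, paste0(nm, "_gwas_not_genotyped.txt")))
    }
  }
  writeLines(run$log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' @export
print.eqtl_run <- function(x, ...) {
  cat("eqtl_run (discovery:", x$discovery, ")\n")
  for (nm in names(x$loci)) {
    cnt <- x$loci[[nm]]$counts
    cat(sprintf("  %s: %d SNPs x %d probes, %d tests, %d significant, %s replicated\n",
                nm, cnt[["snps"]], cnt[["probes"]], cnt[["tests"]],
                cnt[["significant"]], format(cnt[["replicated"]])))
  }
  invisible(x)
}

#' Simulate a study and run the pipeline on it
#'
#' Convenience wrapper used by tests and the command line: simulates a
#' study under `config`, builds one locus covering the simulated window
#' with all simulated genes as cis targets (GWAS SNPs default to the first
#' planted eQTL-SNP so LD linkage has a target), then runs [run_pipeline()].
#'
#' @param config a [sim_config()].
#' @param out_dir optional report directory.
#' @param ... passed to [run_pipeline()].
#' @return list: `study`, `run`.
#' @export
run_simulated <- function(config = sim_config(), out_dir = NULL, ...) {
  study <- simulate_study(config)
  gm <- study$cohorts[[1]]$genotypes
  gwas <- data.frame(snp_id = study$truth$snp_id[1],
                     chrom = config$chrom,
                     pos = gm$snps$pos[match(study$truth$snp_id[1],
                                             gm$snps$snp_id)],
                     stringsAsFactors = FALSE)
  locus <- locus_definition("sim_locus", config$chrom,
                            min(gm$snps$pos), max(gm$snps$pos),
                            gwas_snps = gwas,
                            genes = unique(study$cohorts[[1]]$expression$probesets$gene))
  run <- run_pipeline(lapply(study$cohorts, identity), list(locus),
                      out_dir = out_dir, ...)
  list(study = study, run = run)
}
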