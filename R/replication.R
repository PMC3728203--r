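# Discovery/replication classification: eQTLs significant in the discovery
# cohort at the locus threshold are confirmed at nominal p < alpha_rep in
# each replication cohort.

rep_status_levels <- c("not_significant", "discovery_only", "replicated_one",
                       "replicated_both")

#' Classify discovery eQTLs by replication status
#'
#' A pair is discovery-significant when its discovery p-value is below the
#' locus threshold. Among those, the status counts the replication cohorts
#' with p below `alpha_rep` (`"replicated_both"` means every replication
#' cohort, `"replicated_one"` means some but not all). Untestable
#' pairs in a replication cohort count as non-replicating there.
#' `direction_consistent` is `TRUE` when every cohort in which the pair is
#' significant shares the discovery sign; with `require_direction = TRUE`,
#' an opposite-sign replication does not count as replicating.
#'
#' @param discovery data.frame of discovery results ([scan_locus()] output).
#' @param replications named list of result data.frames, one per
#'   replication cohort, covering the same (snp_id, probeset_id) keys.
#' @param threshold the locus significance threshold for discovery (a
#'   number or a [locus_threshold()] row).
#' @param alpha_rep nominal replication significance level.
#' @param require_direction demand matching sign for replication.
#' @return data.frame with one row per discovery-tested pair: snp_id,
#'   probeset_id, gene, discovery_p, threshold, per-cohort `p_<name>` and
#'   `dir_<name>` columns, n_replicated, status (ordered factor),
#'   direction_consistent. A `summary` attribute gives counts per status.
#' @export
classify_replication <- function(discovery, replications, threshold,
                                 alpha_rep = 0.05,
                                 require_direction = FALSE) {
  if (is.data.frame(threshold)) threshold <- threshold$threshold
  key <- function(d) paste(d$snp_id, d$probeset_id, sep = ":")
  dk <- key(discovery)
  if (anyDuplicated(dk)) stop("duplicate (snp, probeset) keys in discovery")
  for (nm in names(replications)) {
    rk <- key(replications[[nm]])
    missing_keys <- setdiff(dk, rk)
    if (length(missing_keys) > 0) {
      stop("replication cohort '", nm, "' is missing key(s): ",
           paste(utils::head(missing_keys, 5), collapse = ", "))
    }
  }
  out <- data.frame(snp_id = discovery$snp_id,
                    probeset_id = discovery$probeset_id,
                    gene = discovery$gene,
                    discovery_p = discovery$p,
                    discovery_dir = discovery$direction,
                    threshold = threshold,
                    stringsAsFactors = FALSE)
  disc_sig <- !is.na(out$discovery_p) & out$discovery_p < threshold
  n_rep <- length(replications)
  rep_ok <- matrix(FALSE, nrow(out), n_rep)
  sig_dirs <- lapply(seq_len(nrow(out)), function(i) {
    if (disc_sig[i]) out$discovery_dir[i] else integer(0)
  })
  for (j in seq_len(n_rep)) {
    nm <- names(replications)[j]
    r <- replications[[j]]
    idx <- match(dk, key(r))
    p_r <- r$p[idx]
    d_r <- r$direction[idx]
    ok <- !is.na(p_r) & p_r < alpha_rep
    if (require_direction) {
      ok <- ok & !is.na(d_r) & d_r == out$discovery_dir
    }
    rep_ok[, j] <- ok
    out[[paste0("p_", nm)]] <- p_r
    out[[paste0("dir_", nm)]] <- d_r
    for (i in which(ok)) sig_dirs[[i]] <- c(sig_dirs[[i]], d_r[i])
  }
  nrep_sig <- rowSums(rep_ok)
  status <- ifelse(!disc_sig, "not_significant",
                   ifelse(nrep_sig == 0, "discovery_only",
                          ifelse(nrep_sig < n_rep, "replicated_one",
                                 "replicated_both")))
  out$n_replicated <- ifelse(disc_sig, nrep_sig, NA_integer_)
  out$status <- factor(status, levels = rep_status_levels, ordered = TRUE)
  out$direction_consistent <- vapply(sig_dirs, function(d) {
    length(unique(d[!is.na(d)])) <= 1
  }, logical(1))
  attr(out, "summary") <- table(out$status)
  out
}
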