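# Containers and file I/O. One internal coordinate convention: all positions
# are 1-based inclusive base pairs; 0-based half-open (BED-style) inputs are
# converted at the read boundary and never internally. Missing data use NA.

#' SNP metadata table
#'
#' Builds and validates the SNP metadata used throughout the package.
#'
#' @param snp_id character vector of unique SNP identifiers (rsIDs or
#'   synthetic IDs).
#' @param chrom chromosome labels.
#' @param pos 1-based base-pair positions (integers >= 1).
#' @param ref_allele,alt_allele single-character nucleotide codes.
#' @param counted_allele the allele counted by the dosage; must equal
#'   `ref_allele` or `alt_allele` row-wise. Defaults to the alt allele.
#' @return a `data.frame` with one row per SNP.
#' @export
snp_table <- function(snp_id, chrom, pos, ref_allele, alt_allele,
                      counted_allele = alt_allele) {
  snp_id <- as.character(snp_id)
  if (anyDuplicated(snp_id)) {
    stop("duplicate snp_id: ", paste(unique(snp_id[duplicated(snp_id)]),
                                     collapse = ", "))
  }
  pos <- as.integer(pos)
  if (any(is.na(pos)) || any(pos < 1L)) {
    stop("SNP positions must be 1-based integers >= 1")
  }
  ok <- counted_allele == ref_allele | counted_allele == alt_allele
  if (!all(ok)) {
    stop("counted_allele must be ref or alt for SNP(s): ",
         paste(snp_id[!ok], collapse = ", "))
  }
  data.frame(snp_id = snp_id, chrom = as.character(chrom), pos = pos,
             ref_allele = as.character(ref_allele),
             alt_allele = as.character(alt_allele),
             counted_allele = as.character(counted_allele),
             stringsAsFactors = FALSE)
}

#' Genotype matrix of additive allele dosages
#'
#' @param dosages numeric matrix, samples in rows and SNPs in columns; every
#'   entry must be 0, 1, 2 or `NA`.
#' @param snps SNP metadata as returned by [snp_table()]; one row per column
#'   of `dosages`.
#' @param sample_ids character vector of unique sample identifiers.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, snps, sample_ids = rownames(dosages)) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample IDs: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (length(sample_ids) != nrow(dosages)) {
    stop("sample_ids length does not match dosage rows")
  }
  if (nrow(snps) != ncol(dosages)) {
    stop("snps rows do not match dosage columns")
  }
  bad <- !(is.na(dosages) | dosages %in% c(0, 1, 2))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  dimnames(dosages) <- list(sample_ids, snps$snp_id)
  structure(list(dosages = dosages, snps = snps, sample_ids = sample_ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs (%s:%s-%s)\n",
              length(x$sample_ids), nrow(x$snps), x$snps$chrom[1],
              format(min(x$snps$pos), big.mark = ","),
              format(max(x$snps$pos), big.mark = ",")))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Expression matrix of log-scale intensities
#'
#' @param values numeric matrix, samples in rows and probesets in columns;
#'   finite where not `NA`.
#' @param probesets data.frame with columns `probeset_id` and `gene`.
#' @param sample_ids character vector of unique sample identifiers.
#' @return an object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, probesets, sample_ids = rownames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("duplicate sample IDs")
  if (length(sample_ids) != nrow(values)) {
    stop("sample_ids length does not match value rows")
  }
  if (!all(c("probeset_id", "gene") %in% names(probesets))) {
    stop("probesets needs columns probeset_id, gene")
  }
  probesets <- data.frame(probeset_id = as.character(probesets$probeset_id),
                          gene = as.character(probesets$gene),
                          stringsAsFactors = FALSE)
  if (anyDuplicated(probesets$probeset_id)) stop("duplicate probeset_id")
  if (nrow(probesets) != ncol(values)) {
    stop("probesets rows do not match value columns")
  }
  if (any(is.infinite(values))) stop("expression values must be finite or NA")
  dimnames(values) <- list(sample_ids, probesets$probeset_id)
  structure(list(values = values, probesets = probesets,
                 sample_ids = sample_ids),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d samples x %d probesets (%d genes)\n",
              length(x$sample_ids), nrow(x$probesets),
              length(unique(x$probesets$gene))))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Per-sample covariate table
#'
#' @param sample_id unique sample identifiers.
#' @param age age in years, positive where present (`NA` allowed).
#' @param sex `"male"` or `"female"` (`NA` allowed).
#' @param smoking `"current"`, `"ex"` or `"never"`; unknown status is `NA`.
#' @return a `data.frame` of class `covariate_table`. `sex` and `smoking`
#'   are factors; smoking uses `never` as the reference level so the model
#'   contrasts are ex-vs-never and current-vs-never.
#' @export
covariate_table <- function(sample_id, age, sex, smoking) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) stop("duplicate sample IDs")
  age <- as.numeric(age)
  if (any(!is.na(age) & age <= 0)) stop("age must be > 0 where present")
  sex <- as.character(sex)
  if (!all(is.na(sex) | sex %in% c("male", "female"))) {
    stop("sex must be male/female or NA")
  }
  smoking <- as.character(smoking)
  smoking[smoking %in% "unknown"] <- NA
  if (!all(is.na(smoking) | smoking %in% c("current", "ex", "never"))) {
    stop("smoking must be current/ex/never or NA")
  }
  out <- data.frame(sample_id = sample_id, age = age,
                    sex = factor(sex, levels = c("female", "male")),
                    smoking = factor(smoking,
                                     levels = c("never", "ex", "current")),
                    stringsAsFactors = FALSE)
  class(out) <- c("covariate_table", "data.frame")
  out
}

#' Locus definition
#'
#' @param name locus label, e.g. `"4q31"`.
#' @param chrom chromosome.
#' @param start,end 1-based inclusive window bounds.
#' @param gwas_snps data.frame with at least `snp_id` and `pos` for the GWAS
#'   SNPs defining the locus; all positions must fall inside the window.
#' @param genes character vector of gene symbols whose probesets are tested
#'   as cis targets at this locus.
#' @return an object of class `locus_definition`.
#' @export
locus_definition <- function(name, chrom, start, end, gwas_snps = NULL,
                             genes = character(0)) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (start > end) stop("locus start must be <= end")
  if (start < 1) stop("locus start must be >= 1")
  if (!is.null(gwas_snps) && nrow(gwas_snps) > 0) {
    if (any(gwas_snps$pos < start | gwas_snps$pos > end)) {
      stop("all GWAS SNPs must lie within [start, end]")
    }
  }
  structure(list(name = as.character(name), chrom = as.character(chrom),
                 start = start, end = end, gwas_snps = gwas_snps,
                 genes = as.character(genes)),
            class = "locus_definition")
}

# ---- VCF ----

#' Read a VCF file into a genotype matrix
#'
#' Parses genotype calls (GT) from a VCF 4.x file into additive dosages
#' counting the alternate allele. Only biallelic records are accepted; a
#' multi-allelic ALT aborts with an error. Missing genotypes (`./.`) become
#' `NA`. Phased separators (`|`) are accepted.
#'
#' @param path path to an uncompressed or bgzipped VCF file.
#' @return a [genotype_matrix()] with `counted_allele` = alt.
#' @export
read_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("read_vcf requires the VariantAnnotation package")
  }
  hdr <- VariantAnnotation::scanVcfHeader(path)
  smp <- VariantAnnotation::samples(hdr)
  if (anyDuplicated(smp)) {
    stop("duplicate sample IDs in VCF header: ",
         paste(unique(smp[duplicated(smp)]), collapse = ", "))
  }
  vcf <- VariantAnnotation::readVcf(path)
  alt <- VariantAnnotation::alt(vcf)
  nalt <- S4Vectors::elementNROWS(alt)
  if (any(nalt != 1L)) {
    stop("multi-allelic record(s) not supported: ",
         paste(names(vcf)[nalt != 1L], collapse = ", "))
  }
  gt <- VariantAnnotation::geno(vcf)$GT  # variants x samples, character
  if (is.null(gt)) stop("VCF has no GT field")
  dos <- gt_to_dosage(gt)
  rr <- SummarizedExperiment::rowRanges(vcf)
  snps <- snp_table(
    snp_id = names(vcf),
    chrom = as.character(GenomeInfoDb::seqnames(rr)),
    pos = BiocGenerics::start(rr),
    ref_allele = as.character(VariantAnnotation::ref(vcf)),
    alt_allele = as.character(unlist(alt)))
  genotype_matrix(t(dos), snps, sample_ids = colnames(gt))
}

# GT strings -> alt-allele counts; rejects allele indices > 1.
gt_to_dosage <- function(gt) {
  u <- unique(as.vector(gt))
  map <- vapply(u, function(g) {
    if (g %in% c(".", "./.", ".|.")) return(NA_real_)
    al <- strsplit(g, "[/|]")[[1]]
    if (any(al == ".")) return(NA_real_)
    ai <- suppressWarnings(as.integer(al))
    if (any(is.na(ai)) || any(ai > 1L) || length(ai) != 2L) {
      stop("unsupported genotype call: ", g)
    }
    sum(ai)
  }, numeric(1))
  out <- matrix(map[match(as.vector(gt), u)], nrow = nrow(gt),
                dimnames = dimnames(gt))
  out
}

#' Write a genotype matrix as VCF 4.2
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @export
write_vcf <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", gm$sample_ids), collapse = "\t"), con)
  gt_codes <- c("0/0", "0/1", "1/1")
  for (j in seq_len(nrow(gm$snps))) {
    d <- gm$dosages[, j]
    # dosage counts the counted allele; VCF GT counts alt
    if (gm$snps$counted_allele[j] == gm$snps$ref_allele[j]) d <- 2 - d
    gt <- ifelse(is.na(d), "./.", gt_codes[d + 1])
    writeLines(paste(c(gm$snps$chrom[j], gm$snps$pos[j], gm$snps$snp_id[j],
                       gm$snps$ref_allele[j], gm$snps$alt_allele[j],
                       ".", "PASS", ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

# ---- TSV matrices ----

#' Read a rectangular TSV into a numeric matrix
#'
#' First column holds row IDs, header holds column IDs. Empty cells and `NA`
#' become missing values. Ragged rows abort with the offending row number.
#'
#' @param path TSV path.
#' @param orientation `"samples_in_rows"` (default) returns the matrix as
#'   stored; `"samples_in_columns"` transposes so samples always end up in
#'   rows.
#' @return a numeric matrix with dimnames, samples in rows.
#' @export
read_matrix_tsv <- function(path,
                            orientation = c("samples_in_rows",
                                            "samples_in_columns")) {
  orientation <- match.arg(orientation)
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty file: ", path)
  # sentinel keeps trailing empty cells that strsplit would drop
  fields <- strsplit(paste0(lines, "\r"), "\t", fixed = TRUE)
  fields <- lapply(fields, function(f) {
    f[length(f)] <- sub("\r$", "", f[length(f)])
    f
  })
  ncol_exp <- length(fields[[1]])
  nf <- lengths(fields)
  if (any(nf != ncol_exp)) {
    stop("ragged TSV: row ", which(nf != ncol_exp)[1], " has ",
         nf[nf != ncol_exp][1], " fields, expected ", ncol_exp)
  }
  header <- fields[[1]][-1]
  body <- fields[-1]
  ids <- vapply(body, `[[`, character(1), 1)
  vals <- vapply(body, function(f) {
    x <- f[-1]
    x[x == ""] <- NA
    suppressWarnings(as.numeric(x))
  }, numeric(ncol_exp - 1))
  m <- if (is.matrix(vals)) t(vals) else matrix(vals, ncol = ncol_exp - 1)
  dimnames(m) <- list(ids, header)
  if (orientation == "samples_in_columns") m <- t(m)
  m
}

#' Write a numeric matrix as TSV
#'
#' Inverse of [read_matrix_tsv()]: row IDs in the first column, column IDs in
#' the header, `NA` written as empty cells.
#'
#' @param m numeric matrix with dimnames.
#' @param path output path.
#' @param id_header label for the ID column (cosmetic).
#' @export
write_matrix_tsv <- function(m, path, id_header = "id") {
  dt <- data.table::as.data.table(m, keep.rownames = id_header)
  data.table::fwrite(dt, path, sep = "\t", na = "", quote = FALSE)
  invisible(path)
}

#' Read covariates from TSV
#'
#' Expects columns `sample_id`, `age`, `sex`, `smoking` (extra columns
#' ignored). Empty strings become `NA`.
#'
#' @param path TSV path.
#' @return a [covariate_table()].
#' @export
read_covariates_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", na.strings = c("", "NA"),
                          colClasses = list(character = "sample_id"))
  need <- c("sample_id", "age", "sex", "smoking")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("covariate TSV missing column(s): ",
                         paste(miss, collapse = ", "))
  covariate_table(dt$sample_id, dt$age, dt$sex, dt$smoking)
}

#' Write covariates to TSV
#' @param covars a [covariate_table()].
#' @param path output path.
#' @export
write_covariates_tsv <- function(covars, path) {
  dt <- data.table::as.data.table(covars)
  dt$sex <- as.character(dt$sex)
  dt$smoking <- as.character(dt$smoking)
  data.table::fwrite(dt, path, sep = "\t", na = "", quote = FALSE)
  invisible(path)
}

#' Read genotype dosages + SNP metadata from TSV
#'
#' @param dosage_path samples x SNPs dosage TSV (see [read_matrix_tsv()]).
#' @param snp_path SNP metadata TSV with columns snp_id, chrom, pos,
#'   ref_allele, alt_allele, counted_allele.
#' @return a [genotype_matrix()].
#' @export
read_genotypes_tsv <- function(dosage_path, snp_path) {
  d <- read_matrix_tsv(dosage_path)
  s <- data.table::fread(snp_path, sep = "\t", data.table = FALSE,
                         colClasses = list(character = c("snp_id", "chrom")))
  snps <- snp_table(s$snp_id, s$chrom, s$pos, s$ref_allele, s$alt_allele,
                    s$counted_allele)
  if (!identical(colnames(d), snps$snp_id)) {
    d <- d[, snps$snp_id, drop = FALSE]
  }
  genotype_matrix(d, snps)
}

#' Write a genotype matrix to a dosage TSV plus SNP metadata TSV
#' @param gm a [genotype_matrix()].
#' @param dosage_path,snp_path output paths.
#' @export
write_genotypes_tsv <- function(gm, dosage_path, snp_path) {
  write_matrix_tsv(gm$dosages, dosage_path, id_header = "sample_id")
  data.table::fwrite(gm$snps, snp_path, sep = "\t", quote = FALSE)
  invisible(dosage_path)
}

#' Read an expression matrix from TSV
#' @param value_path samples x probesets TSV.
#' @param probe_path probeset map TSV with columns probeset_id, gene.
#' @param orientation passed to [read_matrix_tsv()].
#' @return an [expression_matrix()].
#' @export
read_expression_tsv <- function(value_path, probe_path,
                                orientation = "samples_in_rows") {
  v <- read_matrix_tsv(value_path, orientation)
  p <- data.table::fread(probe_path, sep = "\t", data.table = FALSE,
                         colClasses = "character")
  if (!identical(colnames(v), p$probeset_id)) {
    v <- v[, p$probeset_id, drop = FALSE]
  }
  expression_matrix(v, p)
}

#' Write an expression matrix to TSV
#' @param em an [expression_matrix()].
#' @param value_path,probe_path output paths.
#' @export
write_expression_tsv <- function(em, value_path, probe_path) {
  write_matrix_tsv(em$values, value_path, id_header = "sample_id")
  data.table::fwrite(em$probesets, probe_path, sep = "\t", quote = FALSE)
  invisible(value_path)
}

# ---- result tables ----

result_columns <- c("snp_id", "probeset_id", "gene", "beta", "se", "wald",
                    "p", "r2", "n", "direction", "status", "cohort", "locus")

#' Write eQTL results to TSV
#'
#' Rows are ordered deterministically by locus, then p ascending, then
#' `snp_id` and `probeset_id` as tie-breaks. An empty result writes a
#' header-only file.
#'
#' @param results data.frame of eQTL test results as produced by
#'   [scan_locus()].
#' @param path output path.
#' @export
write_results <- function(results, path) {
  if (nrow(results) > 0) {
    o <- order(results$locus, results$p, results$snp_id, results$probeset_id,
               method = "radix")
    results <- results[o, , drop = FALSE]
  }
  keep <- intersect(result_columns, names(results))
  data.table::fwrite(results[, keep, drop = FALSE], path, sep = "\t",
                     na = "NA", quote = FALSE)
  invisible(path)
}

#' Read an eQTL result TSV written by [write_results()]
#' @param path TSV path.
#' @return a data.frame.
#' @export
read_results <- function(path) {
  data.table::fread(path, sep = "\t", data.table = FALSE, na.strings = "NA",
                    colClasses = list(character = c("snp_id", "probeset_id",
                                                    "gene", "status",
                                                    "cohort", "locus")))
}

#' Read locus definitions from a JSON config
#'
#' The config is a JSON array of objects with fields `name`, `chrom`,
#' `gwas_snps` (objects with `snp_id`, `pos`) and `genes`; window bounds are
#' derived with [build_locus_window()] using `flank_bp` (default 1 Mb).
#' Positions in the config are 1-based.
#'
#' @param path JSON path.
#' @param flank_bp window flank in bp applied on each side.
#' @return list of [locus_definition()] objects.
#' @export
read_locus_config <- function(path, flank_bp = 1e6) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("read_locus_config requires jsonlite")
  }
  cfg <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (is.data.frame(cfg)) cfg <- split(cfg, seq_len(nrow(cfg)))
  lapply(cfg, function(x) {
    gs <- as.data.frame(if (is.data.frame(x$gwas_snps)) x$gwas_snps
                        else x$gwas_snps[[1]])
    build_locus_window(data.frame(snp_id = gs$snp_id, chrom = x$chrom,
                                  pos = as.numeric(gs$pos)),
                       flank_bp = flank_bp, name = x$name,
                       genes = unlist(x$genes))
  })
}
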