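# Shared TSV readers/writers. Every table written by the package starts with
# a dialect header comment ("# mgwas_dialect: <name> v1"); readers validate it
# when present so stage outputs cannot be fed to the wrong stage silently.

.dialect_header <- function(dialect) sprintf("# mgwas_dialect: %s v1", dialect)

write_dialect_tsv <- function(df, path, dialect) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.dialect_header(dialect), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_dialect_tsv <- function(path, dialect = NULL) {
  first <- readLines(path, n = 1)
  has_header <- startsWith(first, "# mgwas_dialect:")
  if (!is.null(dialect) && has_header && first != .dialect_header(dialect))
    stop(sprintf("dialect mismatch in %s: found %s, expected %s", path,
                 sub("^# mgwas_dialect: ", "", first), dialect))
  read.delim(path, skip = as.integer(has_header), stringsAsFactors = FALSE,
             check.names = FALSE)
}

.sumstats_cols <- c("SNP", "CHR", "POS", "EA", "OA", "EAF", "BETA", "SE",
                    "P", "N")

#' Read a GWAS summary-statistics table
#'
#' Tab-separated with required columns SNP, CHR, POS, EA, OA, EAF, BETA, SE,
#' P, N. Rows with non-positive SE, p outside [0, 1] or missing essentials are
#' rejected; their line numbers are reported in attribute `"rejected"`.
#'
#' @param path file path.
#' @return validated data.frame.
#' @export
read_summary_stats <- function(path) {
  x <- read_dialect_tsv(path, "summary_stats")
  missing <- setdiff(.sumstats_cols, names(x))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  bad <- !is.finite(x$SE) | x$SE <= 0 | !is.finite(x$P) | x$P < 0 | x$P > 1 |
    is.na(x$SNP) | !is.finite(x$POS)
  out <- x[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- which(bad)
  out
}

#' Write a GWAS summary-statistics table
#'
#' @param stats data.frame with the required summary-statistics columns.
#' @param path output path.
#' @export
write_summary_stats <- function(stats, path) {
  missing <- setdiff(.sumstats_cols, names(stats))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  write_dialect_tsv(stats, path, "summary_stats")
}

#' Write a genotype matrix as a dosage TSV (variants as rows)
#' @param G a `genotype_matrix`.
#' @param path output path.
#' @export
write_dosage_tsv <- function(G, path) {
  df <- cbind(G$variants[, c("snp", "chr", "pos", "ea", "oa", "eaf")],
              as.data.frame(t(G$dosage), check.names = FALSE))
  write_dialect_tsv(df, path, "dosage")
}

#' Read a dosage TSV written by [write_dosage_tsv()]
#' @param path file path.
#' @param cohort cohort label to assign to the samples.
#' @return a `genotype_matrix`.
#' @export
read_dosage_tsv <- function(path, cohort = "cohort1") {
  df <- read_dialect_tsv(path, "dosage")
  meta_cols <- c("snp", "chr", "pos", "ea", "oa", "eaf")
  variants <- df[, meta_cols]
  d <- t(as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE]))
  samples <- data.frame(sample_id = rownames(d), cohort = cohort,
                        stringsAsFactors = FALSE)
  genotype_matrix(d, variants, samples)
}

#' Write a genotype matrix as minimal VCF v4.2 (GT only)
#' @param G a `genotype_matrix`.
#' @param path output path (plain text).
#' @export
write_vcf <- function(G, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", G$samples$sample_id),
                     collapse = "\t")), con)
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  for (j in seq_len(ncol(G$dosage))) {
    d <- G$dosage[, j]
    gt <- ifelse(is.na(d), "./.", gt_code[as.character(d)])
    v <- G$variants[j, ]
    writeLines(paste(c(v$chr, v$pos, v$snp, v$oa, v$ea, ".", "PASS", ".",
                       "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a minimal GT-only VCF into a genotype matrix
#' @param path file path.
#' @param cohort cohort label.
#' @return a `genotype_matrix` (ALT is the effect allele).
#' @export
read_vcf <- function(path, cohort = "cohort1") {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (length(hdr) != 1) stop("no #CHROM header line found")
  cols <- strsplit(lines[hdr], "\t")[[1]]
  ids <- cols[-(1:9)]
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body)]
  parse_gt <- function(g) {
    a <- strsplit(sub(":.*", "", g), "[/|]")
    vapply(a, function(v) {
      if (any(v == ".")) return(NA_real_)
      sum(as.numeric(v))
    }, numeric(1))
  }
  fields <- strsplit(body, "\t")
  variants <- data.frame(
    snp = vapply(fields, `[`, "", 3),
    chr = as.integer(vapply(fields, `[`, "", 1)),
    pos = as.integer(vapply(fields, `[`, "", 2)),
    ea = vapply(fields, `[`, "", 5),
    oa = vapply(fields, `[`, "", 4), stringsAsFactors = FALSE)
  d <- vapply(fields, function(f) parse_gt(f[-(1:9)]), numeric(length(ids)))
  if (is.null(dim(d))) d <- matrix(d, nrow = length(ids))
  rownames(d) <- ids
  genotype_matrix(d, variants,
                  data.frame(sample_id = ids, cohort = cohort,
                             stringsAsFactors = FALSE))
}

#' Write an abundance table as counts + taxonomy TSVs
#' @param table an `abundance_table`.
#' @param counts_path,taxonomy_path output paths.
#' @export
write_abundance <- function(table, counts_path, taxonomy_path) {
  cdf <- cbind(table$samples, as.data.frame(table$counts, check.names = FALSE))
  write_dialect_tsv(cdf, counts_path, "counts")
  write_dialect_tsv(table$taxonomy, taxonomy_path, "taxonomy")
  invisible(counts_path)
}

#' Read an abundance table from counts + taxonomy TSVs
#' @param counts_path,taxonomy_path input paths.
#' @return an `abundance_table`.
#' @export
read_abundance <- function(counts_path, taxonomy_path) {
  cdf <- read_dialect_tsv(counts_path, "counts")
  tax <- read_dialect_tsv(taxonomy_path, "taxonomy")
  tax[tax == "NA"] <- NA
  sample_cols <- intersect(c("sample_id", "cohort", "site"), names(cdf))
  counts <- as.matrix(cdf[, setdiff(names(cdf), sample_cols), drop = FALSE])
  abundance_table(counts, tax, cdf[, sample_cols, drop = FALSE])
}

#' Write a covariate table
#' @param covariates data.frame with sample_id plus covariate columns.
#' @param path output path.
#' @export
write_covariates <- function(covariates, path) {
  write_dialect_tsv(covariates, path, "covariates")
}

#' Read a covariate table
#' @param path input path.
#' @return data.frame.
#' @export
read_covariates <- function(path) read_dialect_tsv(path, "covariates")
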