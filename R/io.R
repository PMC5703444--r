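#' @name cortwin-io
#' @title Plain-text readers and writers for the pipeline's interchange files
#' @description Pedigree and phenotype tables travel as TSV, GWAS summary
#'   statistics as TSV with the conventional SNP/CHR/BP/A1/A2/FREQ/BETA/SE/P
#'   columns, genotypes as uncompressed VCF v4.2 with a GT field, and
#'   generating parameters as JSON.
NULL

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' @rdname cortwin-io
#' @param cohort a `twin_cohort`.
#' @param path output file path.
#' @export
write_pedigree <- function(cohort, path) {
  write_tsv(cohort$persons[c("family_id", "person_id", "zygosity", "role",
                             "sex", "age_t1", "age_t2")], path)
}

#' @rdname cortwin-io
#' @export
read_pedigree <- function(path) read_tsv(path)

#' @rdname cortwin-io
#' @param phenotypes long phenotype table (one row per person x time point),
#'   e.g. `prepare_phenotypes()$prepared` or an [emit_hcc_raw()] table.
#' @export
write_phenotypes <- function(phenotypes, path) write_tsv(phenotypes, path)

#' @rdname cortwin-io
#' @export
read_phenotypes <- function(path) read_tsv(path)

#' @rdname cortwin-io
#' @param stats summary-statistics data.frame.
#' @export
write_sumstats <- function(stats, path) write_tsv(stats, path)

#' @rdname cortwin-io
#' @export
read_sumstats <- function(path) read_tsv(path)

#' @rdname cortwin-io
#' @param G persons x variants dosage matrix.
#' @param variants variant table (`id`, `chrom`, `pos`, `ref`, `alt`).
#' @export
write_vcf <- function(G, variants, path) {
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(G)), collapse = "\t")), con)
  gt <- matrix(gt_code[as.character(round(t(G)))], nrow = ncol(G))
  gt[is.na(gt)] <- "./."
  lines <- paste(variants$chrom, variants$pos, variants$id, variants$ref,
                 variants$alt, ".", "PASS", ".", "GT",
                 apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' @rdname cortwin-io
#' @return for `read_vcf_dosages()`, a list with the ALT-dosage matrix `G`
#'   and the `variants` table.
#' @export
read_vcf_dosages <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(NA_real_, nrow = nrow(gt), ncol = ncol(gt))
  dos[gt %in% c("0/0", "0|0")] <- 0
  dos[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1
  dos[gt %in% c("1/1", "1|1")] <- 2
  fix <- vcfR::getFIX(v)
  variants <- data.frame(id = fix[, "ID"],
                         chrom = as.integer(fix[, "CHROM"]),
                         pos = as.integer(fix[, "POS"]),
                         ref = fix[, "REF"], alt = fix[, "ALT"],
                         stringsAsFactors = FALSE)
  G <- t(dos)
  rownames(G) <- colnames(gt)
  colnames(G) <- variants$id
  list(G = G, variants = variants)
}

#' @rdname cortwin-io
#' @param x list of generating parameters.
#' @export
write_truth_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

# small deterministic polynomial hash for provenance stamps
prov_hash <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}
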