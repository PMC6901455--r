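#' Genotype matrix container
#'
#' Bundles an individuals-by-SNPs allele-dosage matrix with per-SNP allele
#' metadata. Dosages count copies of the coded allele (0, 1, 2) with `NA`
#' for missing calls. The coded allele defaults to the minor allele
#' (`allele1`) but may be either allele per SNP; recoding a SNP to the other
#' allele maps every non-missing dosage d to 2 - d.
#'
#' @param dosage integer matrix, samples in rows, SNPs in columns; values in
#'   \{0, 1, 2, NA\}.
#' @param snps data.frame with columns `snp_id`, `chrom`, `pos`, `allele1`
#'   (minor), `allele2` (major), `coded_allele`; one row per dosage column.
#' @param samples character vector of unique sample IDs, one per dosage row.
#' @return An object of class `geno_matrix`: a list with elements `dosage`,
#'   `snps`, `samples`.
#' @examples
#' g <- geno_matrix(matrix(c(0L, 1L, 2L, NA), 2, 2),
#'                  data.frame(snp_id = c("rs1", "rs2"), chrom = "1",
#'                             pos = c(100L, 200L), allele1 = "A",
#'                             allele2 = "G", coded_allele = "A"),
#'                  c("s1", "s2"))
#' dim(g$dosage)
#' @export
geno_matrix <- function(dosage, snps, samples) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  stopifnot(is.data.frame(snps))
  required <- c("snp_id", "chrom", "pos", "allele1", "allele2", "coded_allele")
  missing_cols <- setdiff(required, names(snps))
  if (length(missing_cols))
    stop("snps is missing columns: ", paste(missing_cols, collapse = ", "))
  samples <- as.character(samples)
  if (nrow(dosage) != length(samples))
    stop("dosage has ", nrow(dosage), " rows but ", length(samples), " sample IDs")
  if (ncol(dosage) != nrow(snps))
    stop("dosage has ", ncol(dosage), " columns but ", nrow(snps), " SNP records")
  if (anyDuplicated(samples))
    stop("duplicate sample IDs")
  if (anyDuplicated(snps$snp_id))
    stop("duplicate SNP IDs")
  bad <- !is.na(dosage) & !(dosage %in% 0:2)
  if (any(bad))
    stop("dosage values must be 0, 1, 2 or NA")
  if (any(snps$allele1 == snps$allele2))
    stop("allele1 and allele2 must differ for every SNP")
  if (any(snps$coded_allele != snps$allele1 & snps$coded_allele != snps$allele2))
    stop("coded_allele must equal allele1 or allele2")
  if (any(snps$pos <= 0))
    stop("positions must be positive")
  rownames(dosage) <- samples
  colnames(dosage) <- snps$snp_id
  snps$chrom <- as.character(snps$chrom)
  structure(list(dosage = dosage, snps = snps, samples = samples),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", length(x$samples), "samples x", nrow(x$snps), "SNPs\n")
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missingness: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

#' Flip the coded allele of selected SNPs
#'
#' Switches `coded_allele` to the other allele and replaces each non-missing
#' dosage d by 2 - d. Applying the recode twice restores the input.
#'
#' @param g a [geno_matrix()].
#' @param snp_ids SNP identifiers to recode.
#' @return The recoded `geno_matrix`.
#' @export
recode_allele <- function(g, snp_ids) {
  stopifnot(inherits(g, "geno_matrix"))
  idx <- match(snp_ids, g$snps$snp_id)
  if (anyNA(idx))
    stop("unknown SNP IDs: ", paste(snp_ids[is.na(idx)], collapse = ", "))
  g$dosage[, idx] <- 2L - g$dosage[, idx]
  flip <- g$snps$coded_allele[idx] == g$snps$allele1[idx]
  g$snps$coded_allele[idx] <- ifelse(flip, g$snps$allele2[idx], g$snps$allele1[idx])
  g
}

# PLINK 1 binary genotype code table (SNP-major, mode 1):
#   2-bit value 00 = homozygous allele1, 01 = missing, 10 = heterozygous,
#   11 = homozygous allele2; samples packed 4 per byte, lowest bits first.
# Dosage below counts allele1 copies (the default coded allele).
plink_code_to_dosage <- c(`0` = 2L, `1` = NA_integer_, `2` = 1L, `3` = 0L)

#' Read a PLINK BED/BIM/FAM file set
#'
#' Decodes the PLINK 1 binary format (magic bytes 0x6C 0x1B, SNP-major mode
#' 0x01). The coded allele is BIM allele 1 (conventionally the minor allele),
#' so dosages count A1 copies.
#'
#' @param bed_path path to the .bed file.
#' @param bim_path,fam_path paths to the .bim and .fam files; default to
#'   `bed_path` with the extension swapped.
#' @return A [geno_matrix()].
#' @export
read_plink <- function(bed_path,
                       bim_path = sub("\\.bed$", ".bim", bed_path),
                       fam_path = sub("\\.bed$", ".fam", bed_path)) {
  for (p in c(bed_path, bim_path, fam_path))
    if (!file.exists(p)) stop("file not found: ", p)
  bim <- utils::read.table(bim_path, header = FALSE, sep = "\t",
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  names(bim) <- c("chrom", "snp_id", "cm", "pos", "allele1", "allele2")
  fam <- utils::read.table(fam_path, header = FALSE,
                           colClasses = c("character", "character", "character",
                                          "character", "character", "character"))
  n_snp <- nrow(bim)
  n_sam <- nrow(fam)
  raw <- readBin(bed_path, "raw", n = file.size(bed_path))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK BED file (bad magic bytes)")
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major BED files (mode 1) are supported")
  bytes_per_snp <- ceiling(n_sam / 4)
  if (length(raw) - 3L != bytes_per_snp * n_snp)
    stop("BED file is truncated or inconsistent with BIM/FAM dimensions")
  body <- as.integer(raw[-(1:3)])
  # unpack 4 samples per byte, low bits first
  codes <- matrix(0L, nrow = bytes_per_snp * 4L, ncol = n_snp)
  byte_mat <- matrix(body, nrow = bytes_per_snp, ncol = n_snp)
  for (k in 0:3) {
    codes[seq_len(bytes_per_snp) * 4L - 3L + k, ] <-
      byte_mat %/% (4L^k) %% 4L
  }
  codes <- codes[seq_len(n_sam), , drop = FALSE]
  dosage <- matrix(plink_code_to_dosage[codes + 1L],
                   nrow = n_sam, ncol = n_snp)
  snps <- data.frame(snp_id = bim$snp_id, chrom = bim$chrom, pos = bim$pos,
                     allele1 = bim$allele1, allele2 = bim$allele2,
                     coded_allele = bim$allele1, stringsAsFactors = FALSE)
  geno_matrix(dosage, snps, fam[[2]])
}

#' Write a PLINK BED/BIM/FAM file set
#'
#' Inverse of [read_plink()]. Dosages are interpreted as allele-1 copies:
#' SNPs whose coded allele is allele 2 are recoded to allele 1 before
#' encoding, so a read-back returns allele-1 dosages.
#'
#' @param g a [geno_matrix()].
#' @param prefix output path prefix; `<prefix>.bed/.bim/.fam` are written.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(g, prefix) {
  stopifnot(inherits(g, "geno_matrix"))
  flip <- g$snps$coded_allele == g$snps$allele2
  if (any(flip)) g <- recode_allele(g, g$snps$snp_id[flip])
  n_sam <- length(g$samples)
  n_snp <- nrow(g$snps)
  bim <- data.frame(g$snps$chrom, g$snps$snp_id, 0, g$snps$pos,
                    g$snps$allele1, g$snps$allele2)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  fam <- data.frame(g$samples, g$samples, 0, 0, 0, -9)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  dosage_to_code <- function(d) ifelse(is.na(d), 1L, c(3L, 2L, 0L)[d + 1L])
  bytes_per_snp <- ceiling(n_sam / 4)
  pad <- bytes_per_snp * 4L - n_sam
  codes <- rbind(matrix(dosage_to_code(as.vector(g$dosage)), nrow = n_sam),
                 matrix(0L, nrow = pad, ncol = n_snp))
  dim(codes) <- c(4L, bytes_per_snp * n_snp)
  bytes <- as.integer(codes[1, ] + 4L * codes[2, ] + 16L * codes[3, ] +
                        64L * codes[4, ])
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(bytes), con)
  invisible(prefix)
}

#' Read/write the plain-TSV genotype dialect
#'
#' A human-readable alternative to BED: a TSV with a `sample_id` column then
#' one column per SNP holding dosages 0/1/2/NA. SNP metadata (chromosome,
#' position, alleles) travels in a sidecar TSV `<path>.snps`; when absent on
#' read, placeholder metadata is synthesized (chrom "1", positions 1..p,
#' alleles A/B).
#'
#' @param path TSV path.
#' @return `read_geno_tsv` returns a [geno_matrix()]; `write_geno_tsv`
#'   returns `path` invisibly.
#' @export
read_geno_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = NA,
                           na.strings = "NA")
  if (names(tab)[1] != "sample_id")
    stop("first column must be sample_id")
  dosage <- as.matrix(tab[, -1, drop = FALSE])
  sidecar <- paste0(path, ".snps")
  if (file.exists(sidecar)) {
    snps <- utils::read.table(sidecar, header = TRUE, sep = "\t",
                              colClasses = "character")
    snps$pos <- as.numeric(snps$pos)
    snps <- snps[match(colnames(dosage), snps$snp_id), ]
  } else {
    snps <- data.frame(snp_id = colnames(dosage), chrom = "1",
                       pos = seq_len(ncol(dosage)), allele1 = "A",
                       allele2 = "B", coded_allele = "A",
                       stringsAsFactors = FALSE)
  }
  geno_matrix(dosage, snps, tab$sample_id)
}

#' @rdname read_geno_tsv
#' @param g a [geno_matrix()].
#' @export
write_geno_tsv <- function(g, path) {
  stopifnot(inherits(g, "geno_matrix"))
  tab <- data.frame(sample_id = g$samples, g$dosage, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(g$snps, paste0(path, ".snps"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Restrict genotypes and cohort to their shared samples
#'
#' Both objects are subset to the intersection of sample IDs and put in the
#' genotype ordering, so row i of the dosage matrix and row i of the cohort
#' describe the same individual. Counts of dropped IDs are reported via
#' `message()`.
#'
#' @param g a [geno_matrix()].
#' @param cohort a cohort data.frame with a `sample_id` column
#'   (see [read_cohort()]).
#' @return `list(genotypes = , cohort = )`.
#' @export
align_cohort_genotypes <- function(g, cohort) {
  stopifnot(inherits(g, "geno_matrix"), is.data.frame(cohort))
  shared <- intersect(g$samples, cohort$sample_id)
  if (!length(shared))
    stop("no shared sample IDs between genotypes and cohort")
  drop_g <- length(g$samples) - length(shared)
  drop_c <- nrow(cohort) - length(shared)
  if (drop_g || drop_c)
    message("align_cohort_genotypes: dropped ", drop_g,
            " genotype-only and ", drop_c, " cohort-only samples")
  keep <- g$samples[g$samples %in% shared]
  g$dosage <- g$dosage[keep, , drop = FALSE]
  g$samples <- keep
  cohort <- cohort[match(keep, cohort$sample_id), , drop = FALSE]
  rownames(cohort) <- NULL
  list(genotypes = g, cohort = cohort)
}
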