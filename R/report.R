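fmt_or_ci <- function(est, lo, hi) sprintf("%.2f (%.2f, %.2f)", est, lo, hi)

#' Write scan results in the summary-table layout
#'
#' One row per SNP with odds ratios rendered as `"x.xx (lo, hi)"`, the AP
#' with its 95% CI in the same style, and p-value/FDR in scientific
#' notation — the conventional published layout for combination-group
#' interaction scans.
#'
#' @param results an `interaction_scan` data.frame from [run_scan()];
#'   must be non-empty.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(results, path) {
  stopifnot(is.data.frame(results))
  if (!nrow(results)) stop("results is empty")
  tab <- data.frame(
    marker_name = results$snp_id,
    chr = results$chrom,
    position = results$pos,
    a1_a2 = paste0(results$allele1, "/", results$allele2),
    ca = results$coded_allele,
    or_snp = fmt_or_ci(results$or10, results$or10_lo, results$or10_hi),
    or_smok = fmt_or_ci(results$or01, results$or01_lo, results$or01_hi),
    or_snp_smok = fmt_or_ci(results$or11, results$or11_lo, results$or11_hi),
    ap_95ci = fmt_or_ci(results$ap, results$ap_lo, results$ap_hi),
    ap_pval = sprintf("%.2E", results$ap_p),
    fdr = sprintf("%.2E", results$fdr),
    significant = results$significant,
    converged = results$converged,
    reason = ifelse(is.na(results$reason), "", results$reason),
    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-locus summary of scan results
#'
#' Aggregates significant SNPs by locus: for each locus the best
#' (minimum AP p-value) SNP, its p-value, and the count of significant
#' SNPs. Loci come from an annotation table; significant SNPs without an
#' annotation are kept in a trailing `"(unassigned)"` row rather than
#' dropped. A SNP falling in two overlapping loci is counted in both (with
#' a warning).
#'
#' @param results an `interaction_scan` data.frame.
#' @param annotations either a SNP map data.frame (`snp_id`, `locus`) or a
#'   BED-like data.frame (`chrom`, `start`, `stop`, `locus`) matched against
#'   SNP positions.
#' @return data.frame: `locus`, `chrom`, `n_significant`, `best_snp`,
#'   `best_ap_p`.
#' @export
summarize_loci <- function(results, annotations) {
  stopifnot(is.data.frame(results), is.data.frame(annotations))
  sig <- results[results$significant %in% TRUE, , drop = FALSE]
  if (!nrow(sig))
    return(data.frame(locus = character(0), chrom = character(0),
                      n_significant = integer(0), best_snp = character(0),
                      best_ap_p = numeric(0), stringsAsFactors = FALSE))
  if (all(c("snp_id", "locus") %in% names(annotations))) {
    hits <- merge(sig, annotations[, c("snp_id", "locus")], by = "snp_id")
  } else if (all(c("chrom", "start", "stop", "locus") %in%
                 names(annotations))) {
    rows <- lapply(seq_len(nrow(annotations)), function(i) {
      a <- annotations[i, ]
      m <- sig[sig$chrom == a$chrom & sig$pos >= a$start &
                 sig$pos <= a$stop, , drop = FALSE]
      if (nrow(m)) cbind(m, locus = a$locus) else NULL
    })
    hits <- do.call(rbind, rows)
    if (is.null(hits))
      hits <- cbind(sig[0, , drop = FALSE], locus = character(0))
  } else {
    stop("annotations need columns snp_id+locus or chrom+start+stop+locus")
  }
  if (nrow(hits) && anyDuplicated(hits$snp_id))
    warning("SNPs assigned to more than one locus: ",
            paste(unique(hits$snp_id[duplicated(hits$snp_id)]),
                  collapse = ", "))
  per_locus <- lapply(split(hits, hits$locus), function(h) {
    best <- h[which.min(h$ap_p), ]
    data.frame(locus = best$locus, chrom = best$chrom,
               n_significant = nrow(h), best_snp = best$snp_id,
               best_ap_p = best$ap_p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_locus)
  out <- out[order(out$best_ap_p), , drop = FALSE]
  un <- sig[!(sig$snp_id %in% hits$snp_id), , drop = FALSE]
  if (nrow(un)) {
    best <- un[which.min(un$ap_p), ]
    out <- rbind(out, data.frame(locus = "(unassigned)", chrom = best$chrom,
                                 n_significant = nrow(un),
                                 best_snp = best$snp_id,
                                 best_ap_p = best$ap_p,
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Validate a pipeline run configuration
#'
#' @param config named list; recognized entries: `genotypes` (BED or TSV
#'   path), `cohort` (TSV path), `phenotype`, `covariates`, `adjust_hla`,
#'   `n_pcs`, `prune_r2`, `tag_r2`, `ap_p_threshold`, `fdr_threshold`,
#'   `min_cell`, `out_dir`, `annotations` (optional SNP->locus TSV).
#' @return The config with defaults filled in; errors on invalid thresholds
#'   before any computation.
#' @export
validate_config <- function(config) {
  defaults <- list(phenotype = "LS", covariates = c("sex", "age"),
                   adjust_hla = FALSE, n_pcs = 2, prune_r2 = 0.25,
                   tag_r2 = 0.80, ap_p_threshold = 0.05,
                   fdr_threshold = 0.05, min_cell = 5,
                   annotations = NULL)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  for (nm in c("prune_r2", "tag_r2", "ap_p_threshold", "fdr_threshold")) {
    v <- config[[nm]]
    if (!is.numeric(v) || length(v) != 1 || v <= 0 || v >= 1)
      stop(nm, " must be a number in (0, 1), got ", format(config[[nm]]))
  }
  if (config$min_cell < 1) stop("min_cell must be >= 1")
  if (config$n_pcs < 0) stop("n_pcs must be >= 0")
  if (!config$phenotype %in% c("LS", "non-LS"))
    stop("phenotype must be LS or non-LS")
  for (nm in c("genotypes", "cohort"))
    if (is.null(config[[nm]]) || !file.exists(config[[nm]]))
      stop("config$", nm, " must name an existing file")
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  config
}

#' Run the full interaction-scan pipeline
#'
#' LD-prunes the genotypes, computes ancestry PCs, runs the per-SNP
#' combination-model scan with FDR control, priority-prunes significant
#' signals into tags, and writes `results.tsv`, `tags.tsv`, an
#' excluded-SNP ledger, the retained (pruned) SNP list, the PC matrix, an
#' optional per-locus summary, and a run log into `config$out_dir`.
#'
#' @param config list, see [validate_config()]; may also be a YAML file
#'   path if the `yaml` package is installed.
#' @return The scan results data.frame, invisibly.
#' @export
cmd_scan <- function(config) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs needs the yaml package")
    config <- yaml::read_yaml(config)
  }
  config <- validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  g <- if (grepl("\\.bed$", config$genotypes))
    read_plink(config$genotypes) else read_geno_tsv(config$genotypes)
  cohort <- read_cohort(config$cohort)
  aligned <- align_cohort_genotypes(g, cohort)
  g <- aligned$genotypes
  cohort <- aligned$cohort

  pruned <- ld_prune(g, r2_threshold = config$prune_r2)
  writeLines(pruned, file.path(config$out_dir, "pruned_snps.txt"))
  covariates <- config$covariates
  if (config$n_pcs > 0) {
    pcs <- compute_pcs(g, pruned, k = config$n_pcs)
    cohort <- cbind(cohort, as.data.frame(pcs))
    utils::write.table(
      data.frame(sample_id = rownames(pcs), pcs, check.names = FALSE),
      file.path(config$out_dir, "pcs.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    covariates <- c(covariates, colnames(pcs))
  }
  results <- run_scan(g, cohort, phenotype = config$phenotype,
                      covariate_names = covariates,
                      adjust_hla = config$adjust_hla,
                      min_cell = config$min_cell,
                      ap_p_threshold = config$ap_p_threshold,
                      fdr_threshold = config$fdr_threshold)
  write_results_tsv(results, file.path(config$out_dir, "results.tsv"))
  excluded <- results[!results$converged,
                      c("snp_id", "chrom", "pos", "reason")]
  utils::write.table(excluded, file.path(config$out_dir, "excluded_snps.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tags <- priority_prune(results, g, r2_threshold = config$tag_r2)
  utils::write.table(tags, file.path(config$out_dir, "tags.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(config$annotations)) {
    ann <- utils::read.table(config$annotations, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    utils::write.table(summarize_loci(results, ann),
                       file.path(config$out_dir, "loci.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  log_lines <- c(
    paste0("geiscan ", as.character(utils::packageVersion("geiscan"))),
    paste0("R ", R.version.string),
    paste0("phenotype: ", config$phenotype),
    paste0("covariates: ", paste(covariates, collapse = ", ")),
    paste0("adjust_hla: ", config$adjust_hla),
    paste0("samples: ", length(g$samples), "  SNPs: ", nrow(g$snps)),
    paste0("pruned SNPs retained: ", length(pruned)),
    paste0("FDR family size (converged SNPs): ",
           attr(results, "fdr_family_size")),
    paste0("significant SNPs: ", sum(results$significant)),
    paste0("thresholds: ap_p < ", config$ap_p_threshold,
           ", fdr < ", config$fdr_threshold,
           ", min_cell = ", config$min_cell,
           ", prune_r2 = ", config$prune_r2,
           ", tag_r2 = ", config$tag_r2))
  writeLines(log_lines, file.path(config$out_dir, "run.log"))
  invisible(results)
}

#' Write a simulated cohort to disk
#'
#' Materializes [simulate_cohort()] output as files readable by
#' [cmd_scan()]: genotypes (TSV dialect or PLINK BED), the cohort table,
#' and the per-SNP truth table.
#'
#' @param spec a [simulation_spec()].
#' @param out_dir output directory.
#' @param format `"tsv"` or `"plink"`.
#' @param phenotype status label for the simulated cases.
#' @return Named character vector of written paths, invisibly.
#' @export
cmd_simulate <- function(spec, out_dir, format = c("tsv", "plink"),
                         phenotype = "LS") {
  format <- match.arg(format)
  validate_simulation_spec(spec)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_cohort(spec, phenotype = phenotype)
  if (format == "tsv") {
    geno_path <- file.path(out_dir, "genotypes.tsv")
    write_geno_tsv(sim$genotypes, geno_path)
  } else {
    geno_path <- file.path(out_dir, "genotypes.bed")
    write_plink(sim$genotypes, file.path(out_dir, "genotypes"))
  }
  cohort_path <- file.path(out_dir, "cohort.tsv")
  write_cohort(sim$cohort, cohort_path)
  truth_path <- file.path(out_dir, "truth.tsv")
  utils::write.table(sim$truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(genotypes = geno_path, cohort = cohort_path,
              truth = truth_path))
}
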