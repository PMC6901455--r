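#' Priority pruning of significant interaction signals into tag SNPs
#'
#' Greedy selection of independent lead signals among significant SNPs:
#' repeatedly the unassigned SNP with the smallest AP p-value becomes a tag
#' (ties broken by ascending genomic position), and every unassigned SNP
#' with squared dosage correlation above `r2_threshold` to the tag — and the
#' same locus label, when labels are supplied — is assigned to it.
#' Deterministic; no SNP is lost (tags plus tagged partition the input) and
#' no two tags exceed the LD threshold with each other.
#'
#' @param results an `interaction_scan` data.frame (or any data.frame with
#'   `snp_id`, `pos`, `ap_p`); rows flagged `significant` are pruned when
#'   that column is present, otherwise all rows.
#' @param g a [geno_matrix()] holding genotypes for every result SNP.
#' @param r2_threshold LD threshold above which a SNP is tagged
#'   (default 0.80, the conventional high-LD cutoff).
#' @param locus optional named character vector mapping `snp_id` to a locus
#'   (gene) label; tagging then only acts within a locus.
#' @return data.frame, one row per tag: `tag_snp`, `ap_p_tag`, `n_tagged`,
#'   `tagged` (comma-separated ids, `""` if none), `r2` (comma-separated,
#'   aligned with `tagged`).
#' @export
priority_prune <- function(results, g, r2_threshold = 0.80, locus = NULL) {
  stopifnot(is.data.frame(results), inherits(g, "geno_matrix"))
  if ("significant" %in% names(results))
    results <- results[results$significant, , drop = FALSE]
  if (!nrow(results))
    return(data.frame(tag_snp = character(0), ap_p_tag = numeric(0),
                      n_tagged = integer(0), tagged = character(0),
                      r2 = character(0), stringsAsFactors = FALSE))
  missing_snp <- setdiff(results$snp_id, g$snps$snp_id)
  if (length(missing_snp))
    stop("result SNPs missing from genotypes: ",
         paste(missing_snp, collapse = ", "))
  ids <- results$snp_id
  pval <- results$ap_p
  pos <- results$pos
  loc <- if (is.null(locus)) NULL else unname(locus[ids])
  unassigned <- rep(TRUE, length(ids))
  rows <- list()
  while (any(unassigned)) {
    cand <- which(unassigned)
    best <- cand[order(pval[cand], pos[cand])][1]
    unassigned[best] <- FALSE
    others <- which(unassigned)
    tagged_idx <- integer(0)
    r2s <- numeric(0)
    for (o in others) {
      if (!is.null(loc) &&
          (is.na(loc[best]) || is.na(loc[o]) || loc[best] != loc[o]))
        next
      r2 <- ld_r2(g, ids[best], ids[o])
      if (!is.na(r2) && r2 > r2_threshold) {
        tagged_idx <- c(tagged_idx, o)
        r2s <- c(r2s, r2)
      }
    }
    unassigned[tagged_idx] <- FALSE
    rows[[length(rows) + 1]] <- data.frame(
      tag_snp = ids[best], ap_p_tag = pval[best],
      n_tagged = length(tagged_idx),
      tagged = paste(ids[tagged_idx], collapse = ","),
      r2 = paste(sprintf("%.3f", r2s), collapse = ","),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
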