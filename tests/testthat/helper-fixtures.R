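# Shared fixtures and independent oracles used across test files.

# Small genotype matrix with explicit dosages (samples x snps).
make_geno <- function(dosage, ids = NULL, pos = NULL) {
  dosage <- as.matrix(dosage)
  p <- ncol(dosage)
  if (is.null(ids)) ids <- sprintf("rs%d", seq_len(p))
  if (is.null(pos)) pos <- seq_len(p) * 100
  geno_matrix(dosage,
              data.frame(snp_id = ids, chrom = "1", pos = pos,
                         allele1 = "A", allele2 = "G", coded_allele = "A",
                         stringsAsFactors = FALSE),
              sprintf("s%d", seq_len(nrow(dosage))))
}

# Independent Benjamini-Hochberg step-up oracle (straight from the
# definition: sort, multiply by m/rank, enforce monotone from the top).
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- pmin(rev(cummin(rev(ranked))), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Crude combination-group odds ratios straight from a 2x4 contingency
# table: counts is a 2 x 4 matrix (rows control/case, cols g00..g11).
crude_group_ors <- function(counts) {
  ref <- counts[2, 1] / counts[1, 1]
  (counts[2, 2:4] / counts[1, 2:4]) / ref
}

# Expand a 2x4 table of combination-group counts into individual-level
# group labels and outcomes.
expand_2x4 <- function(counts) {
  grp <- factor(rep(rep(c("g00", "g01", "g10", "g11"), 2),
                    c(counts[1, ], counts[2, ])),
                levels = c("g00", "g01", "g10", "g11"))
  y <- rep(c(0L, 1L), c(sum(counts[1, ]), sum(counts[2, ])))
  list(groups = grp, outcome = y)
}

# Cohort expanded from 2x2 smoking-by-status counts.
cohort_from_counts <- function(case_ever, case_never, ctrl_ever, ctrl_never,
                               phenotype = "LS") {
  n <- case_ever + case_never + ctrl_ever + ctrl_never
  data.frame(
    sample_id = sprintf("c%d", seq_len(n)),
    status = rep(c(phenotype, "control"),
                 c(case_ever + case_never, ctrl_ever + ctrl_never)),
    sex = 0L, age = 50,
    smoking_ever = c(rep(1L, case_ever), rep(0L, case_never),
                     rep(1L, ctrl_ever), rep(0L, ctrl_never)),
    stringsAsFactors = FALSE)
}

# Independent priority-pruning oracle: literal restatement of the rule
# (smallest p becomes a tag, position breaks ties, everything above the LD
# threshold and unassigned joins it), written over plain vectors.
priority_prune_oracle <- function(ids, pval, pos, r2mat, r2_threshold) {
  state <- rep("un", length(ids))
  tags <- list()
  while (any(state == "un")) {
    cand <- which(state == "un")
    cand <- cand[order(pval[cand], pos[cand])]
    t <- cand[1]
    state[t] <- "tag"
    members <- which(state == "un" & !is.na(r2mat[t, ]) &
                       r2mat[t, ] > r2_threshold)
    state[members] <- "tagged"
    tags[[length(tags) + 1]] <- list(tag = ids[t], tagged = ids[members])
  }
  tags
}

# Table 2 printed combination odds ratios (OR11, OR01, OR10) and the
# printed AP for the worked examples.
table2_rows <- data.frame(
  snp = c("rs12132140", "rs61780312", "rs115265657", "rs79460410",
          "rs34093877", "rs1060242", "rs62198467"),
  or11 = c(2.92, 3.23, 3.35, 2.81, 4.27, 2.06, 2.41),
  or01 = c(1.18, 1.18, 1.21, 1.01, 1.70, 1.03, 1.11),
  or10 = c(1.09, 1.05, 1.12, 1.06, 1.10, 1.00, 1.05),
  ap_printed = c(0.56, 0.62, 0.60, 0.62, 0.58, 0.50, 0.52),
  stringsAsFactors = FALSE)
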