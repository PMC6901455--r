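#' Double-exposure odds ratio implied by a target attributable proportion
#'
#' Inverts the attributable-proportion formula
#' AP = (OR11 - OR01 - OR10 + 1) / OR11 for OR11, the odds ratio of the
#' doubly exposed group versus the unexposed reference. Used by the cohort
#' generator to plant interactions of a chosen strength.
#'
#' @param or01 odds ratio of the exposure-only group (> 0).
#' @param or10 odds ratio of the carrier-only group (> 0).
#' @param ap target attributable proportion (< 1).
#' @return OR11 = (or01 + or10 - 1) / (1 - ap).
#' @examples
#' or11_from_ap(1.18, 1.09, 0.565)  # ~2.92
#' or11_from_ap(1.0, 1.0, 0.5)      # 2
#' @export
or11_from_ap <- function(or01, or10, ap) {
  if (any(ap >= 1)) stop("ap must be < 1")
  if (any(or01 <= 0) || any(or10 <= 0)) stop("odds ratios must be positive")
  excess <- or01 + or10 - 1
  if (any(excess <= 0))
    stop("or01 + or10 - 1 must be positive for a positive OR11")
  excess / (1 - ap)
}

#' Specification for a synthetic case-control cohort
#'
#' Defaults mirror the study design the package targets: a sarcoidosis-style
#' case-control cohort (292 cases, 2,966 controls), ever-smoking prevalence
#' 0.5 independent of genotype, biallelic SNPs in Hardy-Weinberg equilibrium,
#' a mostly-female control pool (73.8% female) with male sex raising disease
#' odds, and age drawn around 50 years with younger cases induced by a
#' protective per-year odds ratio.
#'
#' Disease status is drawn from a prospective logistic model. For each SNP
#' listed in `causal`, dominant carrier status contributes log(or10) and the
#' carrier-by-exposure product contributes log(or11) - log(or01) - log(or10),
#' so the four combination-group odds ratios are exactly
#' (1, or01, or10, or11) with or11 = [or11_from_ap()]`(or01, or10, ap_true)`.
#' Non-causal SNPs are pure noise.
#'
#' @param n_cases,n_controls retained case and control counts.
#' @param n_snps number of SNPs.
#' @param maf per-SNP minor-allele frequency in (0, 0.5]; recycled.
#' @param exposure_prev probability of ever-smoking.
#' @param or01 odds ratio of exposure without the risk allele.
#' @param or10 odds ratio of dominant carriage without exposure (causal SNPs).
#' @param ap_true attributable proportion planted at causal SNPs.
#' @param causal integer indices of SNPs carrying the interaction.
#' @param baseline_risk disease probability of an unexposed non-carrier
#'   female of mean age.
#' @param sex_or per-unit odds ratio for male sex.
#' @param age_or per-year odds ratio for age.
#' @param p_female probability of female sex.
#' @param age_mean,age_sd population age distribution (years).
#' @param hla_prev carrier prevalence of the HLA flag (simulated independent
#'   of disease).
#' @param seed integer RNG seed; identical specs give identical cohorts.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(n_cases = 292, n_controls = 2966, n_snps = 100,
                            maf = 0.3, exposure_prev = 0.5,
                            or01 = 1.0, or10 = 1.0, ap_true = 0,
                            causal = integer(0), baseline_risk = 0.05,
                            sex_or = 3.0, age_or = 0.985, p_female = 0.738,
                            age_mean = 50, age_sd = 15, hla_prev = 0.3,
                            seed = 1L) {
  spec <- list(n_cases = n_cases, n_controls = n_controls, n_snps = n_snps,
               maf = rep_len(maf, n_snps), exposure_prev = exposure_prev,
               or01 = or01, or10 = or10, ap_true = ap_true,
               causal = as.integer(causal), baseline_risk = baseline_risk,
               sex_or = sex_or, age_or = age_or, p_female = p_female,
               age_mean = age_mean, age_sd = age_sd, hla_prev = hla_prev,
               seed = as.integer(seed))
  validate_simulation_spec(spec)
  structure(spec, class = "simulation_spec")
}

validate_simulation_spec <- function(spec) {
  stopifnot(spec$n_cases >= 1, spec$n_controls >= 1, spec$n_snps >= 1)
  if (any(spec$maf <= 0) || any(spec$maf > 0.5))
    stop("maf must lie in (0, 0.5]")
  if (spec$exposure_prev <= 0 || spec$exposure_prev >= 1)
    stop("exposure_prev must lie in (0, 1)")
  if (spec$or01 <= 0 || spec$or10 <= 0) stop("odds ratios must be positive")
  if (spec$ap_true >= 1) stop("ap_true must be < 1")
  if (length(spec$causal) &&
      (min(spec$causal) < 1 || max(spec$causal) > spec$n_snps))
    stop("causal indices out of range")
  if (spec$baseline_risk <= 0 || spec$baseline_risk >= 1)
    stop("baseline_risk must lie in (0, 1)")
  # planted OR11 must exist
  if (length(spec$causal)) or11_from_ap(spec$or01, spec$or10, spec$ap_true)
  invisible(spec)
}

#' Simulate a case-control cohort with known interaction structure
#'
#' Draws a source population (genotypes under HWE, exposure and covariates
#' independent of genotype, disease from the logistic model described in
#' [simulation_spec()]) and rejection-samples it until exactly `n_cases`
#' cases and `n_controls` controls are retained, so the case-control
#' ascertainment matches the fitted logistic design and group odds ratios
#' stay at their planted values.
#'
#' @param spec a [simulation_spec()].
#' @param phenotype status label given to cases (`"LS"` or `"non-LS"`).
#' @return `list(genotypes = geno_matrix, cohort = data.frame,
#'   truth = data.frame)` where `truth` has one row per SNP with the
#'   generative `or01`, `or10`, `or11`, `ap_true`.
#' @export
simulate_cohort <- function(spec, phenotype = "LS") {
  validate_simulation_spec(spec)
  stopifnot(phenotype %in% c("LS", "non-LS"))
  set.seed(spec$seed)
  n_snps <- spec$n_snps
  is_causal <- seq_len(n_snps) %in% spec$causal
  or11 <- if (any(is_causal))
    or11_from_ap(spec$or01, spec$or10, spec$ap_true) else NA_real_
  b_exp <- log(spec$or01)
  b_snp <- log(spec$or10)
  b_int <- if (any(is_causal)) log(or11) - b_exp - b_snp else 0

  need_cases <- spec$n_cases
  need_controls <- spec$n_controls
  base_lp <- stats::qlogis(spec$baseline_risk)
  caseG <- list(); caseX <- list(); ctrlG <- list(); ctrlX <- list()
  got_cases <- 0L; got_controls <- 0L
  batch <- max(5000L, 2L * (need_cases + need_controls))
  for (iter in seq_len(60L)) {
    male <- stats::rbinom(batch, 1L, 1 - spec$p_female)
    age <- stats::rnorm(batch, spec$age_mean, spec$age_sd)
    expo <- stats::rbinom(batch, 1L, spec$exposure_prev)
    G <- vapply(seq_len(n_snps),
                function(j) stats::rbinom(batch, 2L, spec$maf[j]),
                integer(batch))
    lp <- base_lp + log(spec$sex_or) * male +
      log(spec$age_or) * (age - spec$age_mean) + b_exp * expo
    if (any(is_causal)) {
      carrier <- (G[, is_causal, drop = FALSE] >= 1L) + 0L
      lp <- lp + b_snp * rowSums(carrier) + b_int * rowSums(carrier * expo)
    }
    y <- stats::rbinom(batch, 1L, stats::plogis(lp))
    hla <- stats::rbinom(batch, 1L, spec$hla_prev)
    X <- data.frame(sex = male, age = age, smoking_ever = expo,
                    hla_drb1_03 = hla, y = y)
    take_case <- which(y == 1L)[seq_len(min(sum(y == 1L),
                                            need_cases - got_cases))]
    take_ctrl <- which(y == 0L)[seq_len(min(sum(y == 0L),
                                            need_controls - got_controls))]
    if (length(take_case)) {
      caseG[[iter]] <- G[take_case, , drop = FALSE]
      caseX[[iter]] <- X[take_case, , drop = FALSE]
      got_cases <- got_cases + length(take_case)
    }
    if (length(take_ctrl)) {
      ctrlG[[iter]] <- G[take_ctrl, , drop = FALSE]
      ctrlX[[iter]] <- X[take_ctrl, , drop = FALSE]
      got_controls <- got_controls + length(take_ctrl)
    }
    if (got_cases >= need_cases && got_controls >= need_controls) break
  }
  if (got_cases < need_cases || got_controls < need_controls)
    stop("could not accrue ", need_cases, " cases and ", need_controls,
         " controls within the iteration cap; increase baseline_risk")
  G <- rbind(do.call(rbind, caseG), do.call(rbind, ctrlG))
  X <- rbind(do.call(rbind, caseX), do.call(rbind, ctrlX))
  n <- nrow(X)
  ids <- sprintf("S%06d", seq_len(n))
  snps <- data.frame(snp_id = sprintf("snp%04d", seq_len(n_snps)),
                     chrom = "1", pos = seq_len(n_snps) * 1000,
                     allele1 = "A", allele2 = "G", coded_allele = "A",
                     stringsAsFactors = FALSE)
  g <- geno_matrix(G, snps, ids)
  cohort <- data.frame(sample_id = ids,
                       status = ifelse(X$y == 1L, phenotype, "control"),
                       sex = X$sex, age = X$age,
                       smoking_ever = X$smoking_ever,
                       hla_drb1_03 = X$hla_drb1_03,
                       stringsAsFactors = FALSE)
  truth <- data.frame(snp_id = snps$snp_id,
                      or01 = spec$or01,
                      or10 = ifelse(is_causal, spec$or10, 1),
                      or11 = ifelse(is_causal, or11, spec$or01),
                      ap_true = ifelse(is_causal, spec$ap_true, 0),
                      stringsAsFactors = FALSE)
  list(genotypes = g, cohort = as_cohort(cohort), truth = truth)
}

#' Append SNPs in linkage disequilibrium with an existing SNP
#'
#' Each appended copy keeps the source genotype with probability
#' sqrt(r2_target) per sample and otherwise redraws a fresh HWE genotype at
#' the source allele frequency, giving an expected genotype correlation of
#' sqrt(r2_target), i.e. squared correlation near `r2_target`.
#' `r2_target = 1` duplicates the column exactly.
#'
#' @param g a [geno_matrix()].
#' @param snp source SNP id or column index.
#' @param n_copies number of correlated SNPs to append.
#' @param r2_target target squared correlation in (0, 1].
#' @param seed optional RNG seed.
#' @return The augmented `geno_matrix`; copies are named
#'   `<snp_id>_ld1`, `<snp_id>_ld2`, ... and placed at consecutive positions
#'   after the source SNP.
#' @export
inject_ld_block <- function(g, snp, n_copies, r2_target, seed = NULL) {
  stopifnot(inherits(g, "geno_matrix"))
  if (r2_target <= 0 || r2_target > 1)
    stop("r2_target must lie in (0, 1]")
  if (n_copies == 0) return(g)
  if (!is.null(seed)) set.seed(seed)
  j <- if (is.character(snp)) match(snp, g$snps$snp_id) else as.integer(snp)
  if (is.na(j) || j < 1 || j > nrow(g$snps)) stop("unknown source SNP")
  src <- g$dosage[, j]
  p_hat <- mean(src, na.rm = TRUE) / 2
  n <- length(src)
  keep_prob <- sqrt(r2_target)
  new_cols <- vapply(seq_len(n_copies), function(k) {
    if (r2_target == 1) return(src)
    keep <- stats::rbinom(n, 1L, keep_prob) == 1L
    out <- src
    out[!keep] <- stats::rbinom(sum(!keep), 2L, p_hat)
    out
  }, integer(n))
  info <- g$snps[rep(j, n_copies), ]
  info$snp_id <- paste0(g$snps$snp_id[j], "_ld", seq_len(n_copies))
  info$pos <- g$snps$pos[j] + seq_len(n_copies)
  geno_matrix(cbind(g$dosage, new_cols),
              rbind(g$snps, info), g$samples)
}
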