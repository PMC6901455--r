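#' Dominant-model carrier coding
#'
#' Collapses allele dosage to carrier status: 1 for one or two copies of the
#' coded allele, 0 for none. Missing dosages propagate.
#'
#' @param dosage integer vector of dosages in \{0, 1, 2, NA\}.
#' @return Integer 0/1 carrier indicator with `NA` preserved.
#' @examples
#' code_dominant(c(0L, 1L, 2L, NA))
#' @export
code_dominant <- function(dosage) {
  if (any(!is.na(dosage) & !(dosage %in% 0:2)))
    stop("dosages must be 0, 1, 2 or NA")
  as.integer(dosage >= 1L)
}

#' Combination-group labels for one SNP
#'
#' Partitions complete-case individuals into the four joint-exposure strata:
#' `g00` (neither), `g01` (exposed only), `g10` (carrier only), `g11`
#' (both), with `g00` the reference.
#'
#' @param carrier 0/1 dominant carrier indicator ([code_dominant()]).
#' @param exposure 0/1 exposure indicator.
#' @return Factor with levels `g00`, `g01`, `g10`, `g11`; `NA` where either
#'   input is missing.
#' @export
combination_groups <- function(carrier, exposure) {
  stopifnot(length(carrier) == length(exposure))
  lab <- paste0("g", carrier, exposure)
  lab[is.na(carrier) | is.na(exposure)] <- NA
  factor(lab, levels = c("g00", "g01", "g10", "g11"))
}

# Logistic ML fit on a prebuilt model matrix via IRLS (stats::glm.fit),
# returning coefficients and the observed-information covariance.
# Separation is flagged by huge Wald SEs rather than error.
logit_fit <- function(X, y, epsilon = 1e-10, maxit = 100) {
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = epsilon,
                                                maxit = maxit)))
  R <- qr.R(fit$qr)
  piv <- fit$qr$pivot
  cov_piv <- tryCatch(chol2inv(R), error = function(e) NULL)
  if (is.null(cov_piv) || any(!is.finite(cov_piv))) {
    return(list(coef = fit$coefficients, vcov = NULL, converged = FALSE,
                fitted = fit$fitted.values))
  }
  vc <- matrix(NA_real_, ncol(X), ncol(X),
               dimnames = list(colnames(X), colnames(X)))
  vc[piv, piv] <- cov_piv
  se <- sqrt(diag(vc))
  ok <- fit$converged && all(is.finite(fit$coefficients)) &&
    all(is.finite(se)) && all(se < 10)
  list(coef = fit$coefficients, vcov = vc, converged = ok,
       fitted = fit$fitted.values)
}

#' Fit the combination-group logistic model for one SNP
#'
#' Maximum-likelihood logistic regression of case status on indicator
#' variables for the `g01`, `g10`, `g11` combination groups (reference
#' `g00`) plus covariates. Exponentiated group coefficients are the
#' combination odds ratios OR01, OR10, OR11 against the doubly unexposed
#' reference (OR00 = 1).
#'
#' Fits with fewer than `min_cell` individuals in any combination group, or
#' showing separation (non-finite or huge standard errors), are flagged
#' `converged = FALSE` so the caller can exclude them from FDR rather than
#' crash.
#'
#' @param groups factor from [combination_groups()].
#' @param outcome 0/1 case indicator.
#' @param covars optional numeric covariate matrix (columns named).
#' @param min_cell minimum individuals per combination group (default 5).
#' @return List with `coef` (named, the three group log-ORs among them),
#'   `vcov` (full covariance), `n_by_group` (4 counts), `converged`,
#'   `reason` (NULL or why the fit is unusable), `fitted`.
#' @export
fit_combination_model <- function(groups, outcome, covars = NULL,
                                  min_cell = 5) {
  ok <- !is.na(groups) & !is.na(outcome)
  if (!is.null(covars)) {
    covars <- as.matrix(covars)
    ok <- ok & stats::complete.cases(covars)
  }
  groups <- groups[ok]; outcome <- outcome[ok]
  if (!is.null(covars)) covars <- covars[ok, , drop = FALSE]
  n_by_group <- table(groups)
  res <- list(coef = NULL, vcov = NULL,
              n_by_group = as.integer(n_by_group), converged = FALSE,
              reason = NULL, fitted = NULL)
  names(res$n_by_group) <- names(n_by_group)
  if (sum(outcome) == 0 || sum(outcome) == length(outcome)) {
    res$reason <- "no cases or no controls"
    return(res)
  }
  if (any(n_by_group < min_cell)) {
    res$reason <- sprintf("sparse combination cell (min %d < %d)",
                          min(n_by_group), min_cell)
    return(res)
  }
  X <- cbind(`(Intercept)` = 1,
             g01 = as.numeric(groups == "g01"),
             g10 = as.numeric(groups == "g10"),
             g11 = as.numeric(groups == "g11"))
  if (!is.null(covars)) X <- cbind(X, covars)
  if (qr(X)$rank < ncol(X)) {
    res$reason <- "rank-deficient design"
    return(res)
  }
  fit <- logit_fit(X, outcome)
  res$coef <- fit$coef
  res$vcov <- fit$vcov
  res$fitted <- fit$fitted
  res$converged <- fit$converged
  if (!fit$converged) res$reason <- "non-convergence or separation"
  res
}

#' Attributable proportion due to interaction
#'
#' AP = (OR11 - OR01 - OR10 + 1) / OR11, the share of disease odds in the
#' doubly exposed group attributable to departure from additivity of the two
#' exposures' excess odds ratios (the reference group has OR00 = 1).
#' AP = 0 at the additive null OR11 = OR01 + OR10 - 1; AP <= 1 always.
#' Symmetric in (or01, or10).
#'
#' @param or11 odds ratio of the doubly exposed group (> 0).
#' @param or01 odds ratio of the exposure-only group.
#' @param or10 odds ratio of the carrier-only group.
#' @return The attributable proportion.
#' @examples
#' compute_ap(2.92, 1.18, 1.09)  # ~0.57 from the rounded inputs
#' compute_ap(2.06, 1.03, 1.00)  # 0.50
#' @export
compute_ap <- function(or11, or01, or10) {
  if (any(or11 <= 0)) stop("or11 must be positive")
  (or11 - or01 - or10 + 1) / or11
}

#' Delta-method inference for the attributable proportion
#'
#' Transforms the combination-group log-OR estimates and their covariance
#' into an AP estimate with a first-order delta-method standard error,
#' 95% Wald interval and two-sided normal p-value. The gradient of AP with
#' respect to (b01, b10, b11) is (-e^(b01-b11), -e^(b10-b11), 1 - AP).
#'
#' @param coef named coefficient vector containing `g01`, `g10`, `g11`
#'   (log odds ratios versus the `g00` reference).
#' @param vcov covariance matrix with matching row/column names.
#' @return List with `ap`, `se`, `ci` (length-2), `p`, and `ok` (FALSE when
#'   the covariance block is not positive definite).
#' @export
ap_inference <- function(coef, vcov) {
  need <- c("g01", "g10", "g11")
  if (!all(need %in% names(coef)) ||
      !all(need %in% rownames(vcov)))
    stop("coef/vcov must contain g01, g10, g11")
  b <- coef[need]
  V <- vcov[need, need]
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (any(!is.finite(ev)) || any(ev <= 0))
    return(list(ap = NA_real_, se = NA_real_, ci = c(NA_real_, NA_real_),
                p = NA_real_, ok = FALSE))
  ap <- compute_ap(exp(b["g11"]), exp(b["g01"]), exp(b["g10"]))
  grad <- c(-exp(b["g01"] - b["g11"]),
            -exp(b["g10"] - b["g11"]),
            1 - ap)
  se <- sqrt(drop(grad %*% V %*% grad))
  z <- ap / se
  list(ap = unname(ap), se = unname(se),
       ci = unname(ap + c(-1, 1) * 1.96 * se),
       p = unname(2 * stats::pnorm(-abs(z))), ok = TRUE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment of the AP p-values (via `stats::p.adjust`),
#' order-preserving with the input and capped at 1.
#'
#' @param p numeric p-values in [0, 1]; `NA` allowed and propagated.
#' @return Adjusted p-values in input order.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Genome scan for SNP-exposure additive interaction
#'
#' For each polymorphic SNP: codes dominant carrier status, partitions the
#' phenotype's cases plus all controls into the four combination groups,
#' fits the covariate-adjusted logistic model ([fit_combination_model()]),
#' and derives the attributable proportion with delta-method CI and p-value
#' ([ap_inference()]). FDR is controlled by Benjamini-Hochberg across all
#' converged SNPs of the scan, and a SNP is flagged significant when
#' AP > 0, AP p < `ap_p_threshold` and FDR < `fdr_threshold`.
#' Analysis is per-SNP complete-case and fully deterministic.
#'
#' @param g a [geno_matrix()], sample-aligned with `cohort`
#'   (see [align_cohort_genotypes()]).
#' @param cohort cohort data.frame; rows with `status` equal to `phenotype`
#'   are cases, `"control"` rows are controls, others are dropped.
#' @param phenotype `"LS"` or `"non-LS"`.
#' @param covariate_names cohort columns entered as covariates
#'   (default sex, age; add `"PC1"`, `"PC2"` after [compute_pcs()]).
#' @param adjust_hla also adjust for the `hla_drb1_03` carrier flag.
#' @param min_cell sparse-cell minimum per combination group.
#' @param ap_p_threshold,fdr_threshold significance thresholds.
#' @return data.frame of class `interaction_scan`, one row per SNP:
#'   SNP metadata, group counts `n00..n11`, `or01/or10/or11` with
#'   `_lo`/`_hi` 95% limits, `ap`, `ap_lo`, `ap_hi`, `ap_p`, `fdr`,
#'   `converged`, `significant`, `reason`.
#' @export
run_scan <- function(g, cohort, phenotype = c("LS", "non-LS"),
                     covariate_names = c("sex", "age"),
                     adjust_hla = FALSE, min_cell = 5,
                     ap_p_threshold = 0.05, fdr_threshold = 0.05) {
  stopifnot(inherits(g, "geno_matrix"))
  phenotype <- match.arg(phenotype)
  cohort <- as_cohort(cohort)
  if (!any(cohort$status == phenotype))
    stop("phenotype ", phenotype, " absent from cohort")
  if (!identical(g$samples, cohort$sample_id))
    stop("genotypes and cohort are not sample-aligned; ",
         "use align_cohort_genotypes() first")
  if (adjust_hla) covariate_names <- union(covariate_names, "hla_drb1_03")
  missing_cov <- setdiff(covariate_names, names(cohort))
  if (length(missing_cov))
    stop("covariates not in cohort: ", paste(missing_cov, collapse = ", "))
  sel <- cohort$status %in% c(phenotype, "control")
  y <- as.integer(cohort$status[sel] == phenotype)
  expo <- cohort$smoking_ever[sel]
  covars <- if (length(covariate_names))
    as.matrix(cohort[sel, covariate_names, drop = FALSE]) else NULL
  D <- g$dosage[sel, , drop = FALSE]

  p <- nrow(g$snps)
  out <- g$snps[, c("snp_id", "chrom", "pos", "allele1", "allele2",
                    "coded_allele")]
  num <- function() rep(NA_real_, p)
  out$n00 <- NA_integer_; out$n01 <- NA_integer_
  out$n10 <- NA_integer_; out$n11 <- NA_integer_
  for (nm in c("or01", "or01_lo", "or01_hi", "or10", "or10_lo", "or10_hi",
               "or11", "or11_lo", "or11_hi", "ap", "ap_lo", "ap_hi",
               "ap_p", "fdr"))
    out[[nm]] <- num()
  out$converged <- FALSE
  out$significant <- FALSE
  out$reason <- NA_character_

  for (j in seq_len(p)) {
    d <- D[, j]
    if (length(unique(d[!is.na(d)])) < 2) {
      out$reason[j] <- "monomorphic"
      next
    }
    grp <- combination_groups(code_dominant(d), expo)
    fit <- fit_combination_model(grp, y, covars, min_cell = min_cell)
    if (length(fit$n_by_group) == 4)
      out[j, c("n00", "n01", "n10", "n11")] <- fit$n_by_group
    if (!fit$converged) {
      out$reason[j] <- fit$reason
      next
    }
    inf <- ap_inference(fit$coef, fit$vcov)
    if (!inf$ok) {
      out$reason[j] <- "AP inference failed (covariance not PD)"
      next
    }
    se <- sqrt(diag(fit$vcov)[c("g01", "g10", "g11")])
    ors <- exp(fit$coef[c("g01", "g10", "g11")])
    out[j, c("or01", "or10", "or11")] <- ors
    out[j, c("or01_lo", "or10_lo", "or11_lo")] <- exp(log(ors) - 1.96 * se)
    out[j, c("or01_hi", "or10_hi", "or11_hi")] <- exp(log(ors) + 1.96 * se)
    out$ap[j] <- inf$ap
    out$ap_lo[j] <- inf$ci[1]
    out$ap_hi[j] <- inf$ci[2]
    out$ap_p[j] <- inf$p
    out$converged[j] <- TRUE
  }
  if (!any(out$converged))
    stop("no SNP produced a converged combination-model fit")
  out$fdr[out$converged] <- bh_fdr(out$ap_p[out$converged])
  out$significant <- out$converged & !is.na(out$ap) &
    out$ap > 0 & out$ap_p < ap_p_threshold & out$fdr < fdr_threshold
  attr(out, "phenotype") <- phenotype
  attr(out, "covariates") <- covariate_names
  attr(out, "fdr_family_size") <- sum(out$converged)
  class(out) <- c("interaction_scan", "data.frame")
  out
}
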