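#' Smoking-disease association without genetic data
#'
#' The no-genetics baseline: logistic regression of case status (one
#' phenotype versus controls) on the ever/never smoking exposure, adjusted
#' for covariates. Reports the Wald odds ratio, 95% CI and p-value for the
#' smoking coefficient. Optionally restricted to one HLA-DRB1*03 carrier
#' stratum.
#'
#' @param cohort cohort data.frame (see [as_cohort()]).
#' @param phenotype `"LS"` or `"non-LS"`.
#' @param covariate_names cohort columns to adjust for (default sex and
#'   age; use `character(0)` for the crude 2x2 odds ratio).
#' @param stratum `"all"`, `"HLA+"` or `"HLA-"`; the HLA strata need a
#'   `hla_drb1_03` column.
#' @return One-row data.frame: `phenotype`, `stratum`, `or`, `or_lo`,
#'   `or_hi`, `p`, `n_cases`, `n_controls`.
#' @examples
#' # crude OR from a 2x2 of counts (cases 137 ever / 155 never;
#' # controls 1617 ever / 1349 never) equals the cross-product ratio
#' co <- data.frame(
#'   sample_id = sprintf("s%d", 1:3258),
#'   status = rep(c("LS", "control"), c(292, 2966)),
#'   sex = 0, age = 50,
#'   smoking_ever = c(rep(1, 137), rep(0, 155), rep(1, 1617), rep(0, 1349)))
#' smoking_or(co, "LS", covariate_names = character(0))$or
#' @export
smoking_or <- function(cohort, phenotype = c("LS", "non-LS"),
                       covariate_names = c("sex", "age"),
                       stratum = c("all", "HLA+", "HLA-")) {
  phenotype <- match.arg(phenotype)
  stratum <- match.arg(stratum)
  cohort <- as_cohort(cohort)
  if (stratum != "all") {
    if (!"hla_drb1_03" %in% names(cohort))
      stop("stratified analysis needs an hla_drb1_03 column")
    want <- if (stratum == "HLA+") 1 else 0
    cohort <- cohort[!is.na(cohort$hla_drb1_03) &
                       cohort$hla_drb1_03 == want, , drop = FALSE]
  }
  sel <- cohort$status %in% c(phenotype, "control")
  cohort <- cohort[sel, , drop = FALSE]
  y <- as.integer(cohort$status == phenotype)
  keep <- !is.na(cohort$smoking_ever)
  covars <- NULL
  if (length(covariate_names)) {
    missing_cov <- setdiff(covariate_names, names(cohort))
    if (length(missing_cov))
      stop("covariates not in cohort: ", paste(missing_cov, collapse = ", "))
    covars <- as.matrix(cohort[, covariate_names, drop = FALSE])
    keep <- keep & stats::complete.cases(covars)
  }
  y <- y[keep]
  expo <- cohort$smoking_ever[keep]
  if (!is.null(covars)) covars <- covars[keep, , drop = FALSE]
  cells <- table(factor(y, levels = 0:1), factor(expo, levels = 0:1))
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("empty cell in %s stratum '%s': %s / %s-smokers",
                 phenotype, stratum,
                 c("controls", "cases")[empty[1]],
                 c("never", "ever")[empty[2]]))
  }
  X <- cbind(`(Intercept)` = 1, smoking_ever = expo)
  if (!is.null(covars)) X <- cbind(X, covars)
  fit <- logit_fit(X, y)
  if (!fit$converged)
    stop("smoking association fit did not converge in stratum ", stratum)
  b <- fit$coef["smoking_ever"]
  se <- sqrt(fit$vcov["smoking_ever", "smoking_ever"])
  data.frame(phenotype = phenotype, stratum = stratum,
             or = unname(exp(b)),
             or_lo = unname(exp(b - 1.96 * se)),
             or_hi = unname(exp(b + 1.96 * se)),
             p = unname(2 * stats::pnorm(-abs(b / se))),
             n_cases = sum(y == 1L), n_controls = sum(y == 0L),
             stringsAsFactors = FALSE)
}

#' Smoking association within HLA-DRB1*03 strata
#'
#' Runs [smoking_or()] separately in carriers (`HLA+`) and non-carriers
#' (`HLA-`) of the HLA-DRB1*03 allele.
#'
#' @inheritParams smoking_or
#' @return data.frame with one row per stratum.
#' @export
stratified_smoking_or <- function(cohort, phenotype = c("LS", "non-LS"),
                                  covariate_names = c("sex", "age")) {
  phenotype <- match.arg(phenotype)
  if (!"hla_drb1_03" %in% names(cohort))
    stop("stratified analysis needs an hla_drb1_03 column")
  rbind(smoking_or(cohort, phenotype, covariate_names, "HLA+"),
        smoking_or(cohort, phenotype, covariate_names, "HLA-"))
}
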