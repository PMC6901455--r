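#' Smoking exposure harmonization rule
#'
#' Raw questionnaire smoking categories are collapsed into the binary
#' ever/never exposure used throughout the scan: current, ex- and
#' non-regular smokers are ever-smokers; never-smokers are the reference.
#'
#' @param smoking_raw character vector of raw categories; allowed values are
#'   `"current"`, `"ex"`, `"non-regular"`, `"never"`.
#' @return Integer vector, 1 for ever-smokers and 0 for never-smokers.
#' @examples
#' harmonize_smoking(c("never", "ex", "non-regular", "current"))
#' @export
harmonize_smoking <- function(smoking_raw) {
  ever <- c("current", "ex", "non-regular")
  known <- c(ever, "never")
  bad <- !(smoking_raw %in% known)
  if (any(bad))
    stop("unknown smoking categories at rows ",
         paste(utils::head(which(bad), 10), collapse = ", "), ": ",
         paste(unique(smoking_raw[bad]), collapse = ", "))
  as.integer(smoking_raw %in% ever)
}

cohort_statuses <- c("control", "LS", "non-LS")

#' Validate and finalize a cohort table
#'
#' Checks the per-individual phenotype/covariate table used by the scan:
#' unique sample IDs, recognized case status, binary sex, numeric age, and a
#' valid smoking exposure. If `smoking_ever` is absent it is derived from
#' `smoking_raw` via [harmonize_smoking()].
#'
#' @param cohort data.frame with columns `sample_id`, `status` (one of
#'   `"control"`, `"LS"`, `"non-LS"`), `sex` (0/1, 1 = male), `age` (years),
#'   and `smoking_raw` and/or `smoking_ever`; optionally `hla_drb1_03`
#'   (0/1 carrier flag) and principal-component columns `PC1`, `PC2`, ...
#' @return The validated data.frame with `smoking_ever` populated.
#' @export
as_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  needed <- c("sample_id", "status", "sex", "age")
  missing_cols <- setdiff(needed, names(cohort))
  if (length(missing_cols))
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(cohort$sample_id))
    stop("duplicate sample IDs: ",
         paste(unique(cohort$sample_id[duplicated(cohort$sample_id)]),
               collapse = ", "))
  bad_status <- !(cohort$status %in% cohort_statuses)
  if (any(bad_status))
    stop("unknown status values: ",
         paste(unique(cohort$status[bad_status]), collapse = ", "))
  if (!all(cohort$sex %in% c(0, 1, NA)))
    stop("sex must be binary 0/1")
  if (!is.numeric(cohort$age))
    stop("age must be numeric (years)")
  if (!"smoking_ever" %in% names(cohort)) {
    if (!"smoking_raw" %in% names(cohort))
      stop("cohort needs smoking_raw or smoking_ever")
    cohort$smoking_ever <- harmonize_smoking(cohort$smoking_raw)
  } else if (!all(cohort$smoking_ever %in% c(0, 1, NA))) {
    stop("smoking_ever must be binary 0/1")
  }
  if ("hla_drb1_03" %in% names(cohort) &&
      !all(cohort$hla_drb1_03 %in% c(0, 1, NA)))
    stop("hla_drb1_03 must be binary 0/1")
  cohort$sample_id <- as.character(cohort$sample_id)
  cohort
}

#' Read a cohort phenotype/covariate TSV
#'
#' Expects a header row with at least `sample_id`, `status`, `sex`, `age`
#' and a smoking column. The raw smoking categories are harmonized into the
#' binary ever/never exposure (see [harmonize_smoking()]); files that
#' already carry a 0/1 `smoking_ever` column are accepted as-is.
#'
#' @param path TSV path.
#' @return A validated cohort data.frame (see [as_cohort()]).
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, na.strings = "NA")
  as_cohort(tab)
}

#' @rdname read_cohort
#' @param cohort a cohort data.frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
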