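#' Validate a per-patient clinical cohort table
#'
#' The cohort table carries one row per patient: recurrence group, RFS and
#' OS times (days) with event indicators, and the clinical covariates used
#' as comparators (age, sex, disease type, stage, differentiation, lymph
#' metastasis, CEA in ng/mL, CA19-9 in U/mL). Invariants enforced:
#' unique patient ids; strictly positive times; \code{rfs_days <= os_days};
#' \code{group == "recurrence"} exactly when \code{rfs_event} is TRUE.
#'
#' @param cohort a data.frame.
#' @return the validated cohort, classed \code{"cohort_table"}.
#' @export
validate_cohort <- function(cohort) {
  need <- c("patient_id", "group", "rfs_days", "rfs_event",
            "os_days", "os_event")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("cohort table missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(cohort$patient_id))
    stop("cohort table has duplicated patient_id")
  if (!all(cohort$group %in% c("recurrence", "nonrecurrence")))
    stop("cohort group must be 'recurrence' or 'nonrecurrence'")
  if (any(cohort$rfs_days <= 0) || any(cohort$os_days <= 0))
    stop("survival times must be strictly positive")
  if (any(cohort$rfs_days > cohort$os_days))
    stop("rfs_days must not exceed os_days")
  if (!identical(cohort$group == "recurrence", as.logical(cohort$rfs_event)))
    stop("group == 'recurrence' must coincide with rfs_event == TRUE")
  if (!inherits(cohort, "cohort_table"))
    class(cohort) <- c("cohort_table", class(cohort))
  cohort
}

#' Read / write the cohort table and the sample sheet as CSV
#'
#' The sample sheet maps arrays to patients and time points and has
#' columns \code{sample_id}, \code{patient_id}, \code{time_point} with
#' \code{time_point} one of \code{"pre"}, \code{"post"}, \code{"final"}
#' (\code{final} = recurrence time point for relapsers, last observation
#' otherwise). Each (patient, time point) pair must be unique and every
#' patient must have a \code{pre} sample.
#'
#' @param path file path.
#' @param cohort,samples the tables to write.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("rfs_event", "os_event", "lymph_metastasis"))
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  validate_cohort(df)
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_cohort
#' @export
read_samples <- function(path) {
  validate_samples(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_cohort
#' @export
write_samples <- function(samples, path) {
  utils::write.csv(samples, path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_cohort
#' @export
validate_samples <- function(samples) {
  need <- c("sample_id", "patient_id", "time_point")
  miss <- setdiff(need, names(samples))
  if (length(miss))
    stop("sample sheet missing columns: ", paste(miss, collapse = ", "))
  ok <- samples$time_point %in% c("pre", "post", "final") |
    is.na(samples$time_point)
  if (!all(ok))
    stop("time_point must be 'pre', 'post' or 'final'")
  key <- paste(samples$patient_id, samples$time_point)
  if (anyDuplicated(key[!is.na(samples$time_point)]))
    stop("duplicated (patient_id, time_point) pair in sample sheet")
  pre <- samples$patient_id[samples$time_point %in% "pre"]
  nopre <- setdiff(unique(samples$patient_id), pre)
  if (length(nopre))
    warning("patients without a pre-operative sample: ",
            paste(nopre, collapse = ", "))
  samples
}

# sample ids for one time point, in sample-sheet order
samples_at <- function(samples, tp) {
  samples$sample_id[samples$time_point %in% tp]
}
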