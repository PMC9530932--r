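#' Inclusion/exclusion rules for the analysis universe
#'
#' Captures the study-style inclusion rules applied to a reporting database
#' before disproportionality screening: an ATC prefix selecting the drug
#' class (e.g. `"J01"`, antibacterials for systemic use), an inclusive
#' calendar window, and exclusion of medication-error notifications.
#'
#' @param atc_prefix Non-empty uppercase alphanumeric ATC prefix; a report
#'   qualifies if at least one of its drug codes starts with it.
#' @param date_start,date_end Inclusive window bounds (`Date` or ISO-8601
#'   strings), `date_start <= date_end`.
#' @param exclude_med_errors Drop reports flagged as medication errors?
#' @return A list of class `pv_filter_spec`.
#' @export
#' @examples
#' filter_spec("J01", "2018-12-01", "2021-12-31")
filter_spec <- function(atc_prefix, date_start, date_end,
                        exclude_med_errors = TRUE) {
  atc_prefix <- toupper(stringr::str_trim(atc_prefix))
  if (!nzchar(atc_prefix) || grepl("[^A-Z0-9]", atc_prefix)) {
    abort("atc_prefix must be non-empty uppercase alphanumeric")
  }
  date_start <- as.Date(date_start)
  date_end <- as.Date(date_end)
  if (is.na(date_start) || is.na(date_end) || date_start > date_end) {
    abort("need parseable dates with date_start <= date_end")
  }
  structure(
    list(atc_prefix = atc_prefix, date_start = date_start,
         date_end = date_end,
         exclude_med_errors = isTRUE(exclude_med_errors)),
    class = "pv_filter_spec"
  )
}

#' Apply inclusion rules to a report collection
#'
#' Retains reports whose date lies in the inclusive window, that mention at
#' least one drug matching the ATC prefix, and (if requested) that are not
#' medication-error notifications.
#'
#' By default drug mentions not matching the prefix are dropped from the
#' retained reports, so the screening universe is the drug-class subset
#' itself and "other drugs" in the 2x2 denominator means other drugs of the
#' class — mirroring an extract pulled by drug class. Set
#' `keep_nonmatching_drugs = TRUE` to keep class-external co-medications as
#' comparators for sensitivity analyses.
#'
#' @param reports An ICSR collection.
#' @param spec A [filter_spec()].
#' @param keep_nonmatching_drugs Keep drug mentions outside `atc_prefix`
#'   within retained reports?
#' @return The filtered ICSR collection. The operation is idempotent and
#'   never increases the report count.
#' @export
apply_filters <- function(reports, spec, keep_nonmatching_drugs = FALSE) {
  assert_icsr(reports)
  stopifnot(inherits(spec, "pv_filter_spec"))
  in_window <- reports$date >= spec$date_start & reports$date <= spec$date_end
  has_class_drug <- vapply(
    reports$drugs,
    function(d) any(startsWith(d, spec$atc_prefix)),
    logical(1)
  )
  keep <- in_window & has_class_drug
  if (spec$exclude_med_errors) keep <- keep & !reports$med_error
  out <- reports[keep, , drop = FALSE]
  if (!keep_nonmatching_drugs) {
    out$drugs <- lapply(out$drugs, function(d)
      d[startsWith(d, spec$atc_prefix)])
  }
  out
}
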