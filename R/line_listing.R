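#' Write an ICSR collection as a delimited line listing
#'
#' Two UTF-8 CSV dialects are supported. `"long"` writes one row per
#' report-drug-event combination (columns `report_id`, `date`, `drug_code`,
#' `event_term`, `med_error`); a report with no drug or no event mention
#' keeps a row with the missing side empty so the report survives a round
#' trip. `"wide"` writes one row per report with semicolon-delimited
#' `drug_codes` and `event_terms` lists. Dates are ISO-8601.
#'
#' @param reports An ICSR collection (see [icsr_reports()]).
#' @param path Output file path.
#' @param dialect `"long"` or `"wide"`.
#' @return `path`, invisibly.
#' @seealso [read_line_listing()]
#' @export
write_line_listing <- function(reports, path, dialect = c("long", "wide")) {
  assert_icsr(reports)
  dialect <- match.arg(dialect)
  if (dialect == "long") {
    rows <- lapply(seq_len(nrow(reports)), function(i) {
      d <- reports$drugs[[i]]
      e <- reports$events[[i]]
      if (length(d) == 0) d <- NA_character_
      if (length(e) == 0) e <- NA_character_
      grid <- expand.grid(drug_code = d, event_term = e,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      tibble::tibble(
        report_id = reports$report_id[i],
        date = reports$date[i],
        drug_code = grid$drug_code,
        event_term = grid$event_term,
        med_error = reports$med_error[i]
      )
    })
    out <- if (length(rows)) dplyr::bind_rows(rows) else
      tibble::tibble(report_id = character(), date = as.Date(character()),
                     drug_code = character(), event_term = character(),
                     med_error = logical())
  } else {
    out <- tibble::tibble(
      report_id = reports$report_id,
      date = reports$date,
      med_error = reports$med_error,
      drug_codes = vapply(reports$drugs, paste, character(1), collapse = ";"),
      event_terms = vapply(reports$events, paste, character(1), collapse = ";")
    )
  }
  tryCatch(
    readr::write_csv(out, path, na = ""),
    error = function(e) abort(sprintf("cannot write '%s': %s",
                                      path, conditionMessage(e)))
  )
  invisible(path)
}

#' Read an ICSR line listing
#'
#' Parses one of the two CSV dialects written by [write_line_listing()]
#' (also the expected shape of exports from VigiFlow-like systems once
#' drug codes are ATC-coded). Rows sharing a `report_id` are merged into a
#' single report; drug codes and event terms are normalized (upper-cased
#' codes, case-folded and whitespace-collapsed terms) and deduplicated.
#'
#' @param path Path to the CSV file.
#' @param dialect `"long"` or `"wide"`.
#' @return An ICSR collection sorted by `report_id`.
#' @details Rows that fail to parse raise an error naming the line; rows
#'   sharing a `report_id` but disagreeing on `date` or `med_error` raise an
#'   integrity error rather than silently keeping one of the values.
#' @export
read_line_listing <- function(path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  cols <- if (dialect == "long") {
    readr::cols(report_id = readr::col_character(),
                date = readr::col_date(),
                drug_code = readr::col_character(),
                event_term = readr::col_character(),
                med_error = readr::col_logical())
  } else {
    readr::cols(report_id = readr::col_character(),
                date = readr::col_date(),
                med_error = readr::col_logical(),
                drug_codes = readr::col_character(),
                event_terms = readr::col_character())
  }
  # parsing problems are promoted to errors below; silence readr's advisory
  df <- suppressWarnings(
    readr::read_csv(path, col_types = cols, na = c("", "NA"),
                    progress = FALSE)
  )
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    abort(sprintf("unparseable row at line %d of '%s': %s",
                  probs$row[1] + 1L, path, probs$expected[1]))
  }
  miss <- setdiff(names(cols$cols), names(df))
  if (length(miss)) {
    abort(sprintf("'%s' lacks required column(s): %s",
                  path, paste(miss, collapse = ", ")))
  }
  if (nrow(df) == 0) return(empty_icsr())
  if (anyNA(df$report_id)) abort(sprintf("missing report_id in '%s'", path))

  if (dialect == "wide") {
    if (anyDuplicated(df$report_id)) {
      abort(sprintf("duplicate report_id '%s' in wide listing",
                    df$report_id[duplicated(df$report_id)][1]))
    }
    split_list <- function(x) {
      lapply(x, function(s) {
        if (is.na(s) || !nzchar(s)) character(0)
        else strsplit(s, ";", fixed = TRUE)[[1]]
      })
    }
    return(icsr_reports(df$report_id, df$date,
                        split_list(df$drug_codes),
                        split_list(df$event_terms),
                        df$med_error))
  }

  key <- df$report_id
  first <- !duplicated(key)
  idx <- match(key, key[first])
  conflict_date <- tapply(as.integer(df$date), idx,
                          function(x) length(unique(x)) > 1)
  conflict_err <- tapply(df$med_error, idx,
                         function(x) length(unique(x)) > 1)
  if (any(conflict_date) || any(conflict_err)) {
    bad <- key[first][which(conflict_date | conflict_err)[1]]
    abort(sprintf(
      "report '%s' has conflicting date or med_error values across rows", bad))
  }
  drugs <- lapply(split(df$drug_code, idx), function(x) x[!is.na(x)])
  events <- lapply(split(df$event_term, idx), function(x) x[!is.na(x)])
  ord <- as.character(seq_len(sum(first)))
  icsr_reports(
    report_id = key[first],
    date = df$date[first],
    drugs = drugs[ord],
    events = events[ord],
    med_error = df$med_error[first]
  )
}
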