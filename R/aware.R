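#' Is a string a syntactically valid ATC level-5 code?
#'
#' Level 5 of the Anatomical Therapeutic Chemical classification identifies
#' a single substance and has the lexical shape letter, two digits, two
#' letters, two digits (e.g. `J01DD52`, ceftazidime/avibactam). Input is
#' canonicalized to upper case before matching.
#'
#' @param code Character vector of candidate codes.
#' @return Logical vector, `TRUE` where the code matches the level-5 shape.
#' @export
#' @examples
#' validate_atc5(c("J01DD52", "J01", "j01fa10"))
validate_atc5 <- function(code) {
  code <- toupper(stringr::str_trim(as.character(code)))
  !is.na(code) & grepl("^[A-Z][0-9]{2}[A-Z]{2}[0-9]{2}$", code)
}

#' Load an AWaRe classification table
#'
#' Reads a two-column CSV (`atc_code,group`) mapping ATC level-5 codes to
#' the WHO AWaRe stewardship groups Access, Watch and Reserve. With no
#' `path` the table packaged with pvsignal is returned; it covers the
#' systemic antibacterials (ATC J01) commonly screened in national
#' spontaneous-report databases and can be replaced or extended by the user
#' as WHO revises the AWaRe list.
#'
#' @param path Optional path to a user CSV; `NULL` loads the packaged table.
#' @return A tibble with columns `atc_code`, `group`.
#' @details Malformed codes or group labels outside the closed set
#'   \{Access, Watch, Reserve\} raise an error naming the offending row.
#' @export
#' @examples
#' aware <- load_aware_table()
#' head(aware)
load_aware_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "aware_classification.csv",
                        package = "pvsignal", mustWork = TRUE)
  }
  if (!file.exists(path)) abort(sprintf("AWaRe table not found: %s", path))
  df <- readr::read_csv(
    path,
    col_types = readr::cols(atc_code = readr::col_character(),
                            group = readr::col_character()),
    progress = FALSE
  )
  if (!all(c("atc_code", "group") %in% names(df))) {
    abort("AWaRe table needs columns atc_code, group")
  }
  df$atc_code <- toupper(stringr::str_trim(df$atc_code))
  df$group <- stringr::str_trim(df$group)
  bad <- which(!validate_atc5(df$atc_code))
  if (length(bad)) {
    abort(sprintf("row %d: '%s' is not an ATC level-5 code",
                  bad[1], df$atc_code[bad[1]]))
  }
  bad <- which(!df$group %in% c("Access", "Watch", "Reserve"))
  if (length(bad)) {
    abort(sprintf("row %d: unknown AWaRe group '%s'",
                  bad[1], df$group[bad[1]]))
  }
  if (anyDuplicated(df$atc_code)) {
    abort(sprintf("duplicate atc_code '%s' in AWaRe table",
                  df$atc_code[duplicated(df$atc_code)][1]))
  }
  tibble::as_tibble(df)
}

#' AWaRe group of ATC codes
#'
#' Total, deterministic lookup: codes absent from the table yield
#' `"unclassified"` rather than an error, so screening never halts on
#' vocabulary gaps — the group is an annotation, not a gate.
#'
#' @param code Character vector of ATC codes (canonicalized to upper case).
#' @param table An AWaRe table from [load_aware_table()]; the packaged
#'   default if omitted.
#' @return Character vector over \{`"Access"`, `"Watch"`, `"Reserve"`,
#'   `"unclassified"`\}.
#' @export
#' @examples
#' aware_group(c("J01DD52", "J01FA10", "J01CA04", "X00XX00"))
aware_group <- function(code, table = load_aware_table()) {
  code <- toupper(stringr::str_trim(as.character(code)))
  out <- table$group[match(code, table$atc_code)]
  out[is.na(out)] <- "unclassified"
  out
}
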