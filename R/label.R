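#' Load a label-knowledge table
#'
#' A label-knowledge table records, per drug, the event terms already
#' described in the drug's summary of product characteristics (SPC). It is
#' user-curated data — the manual label lookup of a screening exercise
#' captured as a CSV — never scraped from regulator websites. Event terms
#' are normalized exactly like the ingest step so that membership tests
#' match.
#'
#' @param path CSV with columns `atc_code`, `event_term` (one row per
#'   labelled drug-event pair).
#' @return A tibble with normalized `atc_code`, `event_term` columns.
#' @export
load_label_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("label table not found: %s", path))
  df <- readr::read_csv(
    path,
    col_types = readr::cols(atc_code = readr::col_character(),
                            event_term = readr::col_character()),
    progress = FALSE
  )
  if (!all(c("atc_code", "event_term") %in% names(df))) {
    abort("label table needs columns atc_code, event_term")
  }
  tibble::tibble(
    atc_code = toupper(stringr::str_trim(df$atc_code)),
    event_term = tolower(stringr::str_squish(df$event_term))
  )
}

#' Annotate signals with label-knowledge status
#'
#' Adds a tri-state `labelled` column: `TRUE` when the drug-event pair is in
#' the knowledge table (the event is on the drug's label), `FALSE` when the
#' drug is curated but the event is not listed (a candidate new signal), and
#' `NA` when the drug is absent from the table entirely — unknown is kept
#' distinct from "not on label" so incomplete curation can never manufacture
#' new-signal claims.
#'
#' @param signals Signal tibble from [screen_all()].
#' @param table Label-knowledge tibble from [load_label_table()] (or any
#'   data frame with `atc_code`, `event_term`).
#' @return `signals` with a `labelled` logical column appended; no other
#'   column, row or ordering changes.
#' @export
#' @examples
#' sig <- tibble::tibble(drug_code = c("J01FA10", "J01FA10"),
#'                       event_term = c("rash", "tremor"))
#' known <- tibble::tibble(atc_code = "J01FA10", event_term = "rash")
#' annotate_labelled(sig, known)$labelled # TRUE FALSE
annotate_labelled <- function(signals, table) {
  stopifnot(all(c("drug_code", "event_term") %in% names(signals)),
            all(c("atc_code", "event_term") %in% names(table)))
  curated <- unique(table$atc_code)
  key <- paste(table$atc_code, table$event_term, sep = "\r")
  sig_key <- paste(signals$drug_code, signals$event_term, sep = "\r")
  labelled <- sig_key %in% key
  labelled[!signals$drug_code %in% curated] <- NA
  signals$labelled <- labelled
  signals
}
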