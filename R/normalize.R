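# Term canonicalization shared by ingest, simulation and annotation.
# Drug codes: trimmed, upper case. Event terms: case-folded to lower case,
# internal whitespace collapsed to single spaces. No fuzzy matching.

normalize_drug_code <- function(x, drop = TRUE) {
  x <- toupper(stringr::str_trim(as.character(x)))
  if (drop) x[!is.na(x) & nzchar(x)] else x
}

normalize_event_term <- function(x, drop = TRUE) {
  x <- tolower(stringr::str_squish(as.character(x)))
  if (drop) x[!is.na(x) & nzchar(x)] else x
}
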