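#' Construct a collection of individual case safety reports
#'
#' An ICSR collection is a tibble with one row per report and list-columns
#' holding the deduplicated sets of drug codes and event terms mentioned on
#' the report. All pvsignal analysis functions operate on this container.
#'
#' @param report_id Character vector of unique report identifiers.
#' @param date Report dates (`Date` or ISO-8601 strings).
#' @param drugs List of character vectors: ATC-like drug codes per report.
#' @param events List of character vectors: event terms per report
#'   (MedDRA-Preferred-Term-like strings).
#' @param med_error Logical vector: is the report a medication-error
#'   notification?
#'
#' @details Drug codes are canonicalized to trimmed upper case; event terms
#'   are case-folded to lower case with internal whitespace collapsed.
#'   Mentions within a report are deduplicated and sorted so that two
#'   collections with the same content compare identical regardless of
#'   input order.
#'
#' @return A tibble of class `pv_icsr` with columns `report_id`, `date`,
#'   `drugs`, `events`, `med_error`, sorted by `report_id`.
#' @export
#' @examples
#' icsr_reports(
#'   report_id = c("R1", "R2"),
#'   date = c("2020-01-01", "2020-06-30"),
#'   drugs = list("J01FA10", c("J01CA04", "J01DD04")),
#'   events = list(c("rash", "pyrexia"), "vomiting"),
#'   med_error = c(FALSE, FALSE)
#' )
icsr_reports <- function(report_id, date, drugs, events,
                         med_error = FALSE) {
  report_id <- as.character(report_id)
  if (anyDuplicated(report_id)) {
    dup <- report_id[duplicated(report_id)][1]
    abort(sprintf("duplicate report_id '%s' in collection", dup))
  }
  date <- as.Date(date)
  if (anyNA(date) && length(date) > 0) {
    abort("unparseable report date(s)")
  }
  n <- length(report_id)
  med_error <- rep_len(as.logical(med_error), n)
  stopifnot(length(date) == n, length(drugs) == n, length(events) == n)
  out <- new_icsr(report_id, date,
                  normalize_mention_sets(drugs, normalize_drug_code),
                  normalize_mention_sets(events, normalize_event_term),
                  med_error)
  out[order(out$report_id, method = "radix"), ]
}

# vectorized set normalization: flatten, normalize once, re-split, dedupe
normalize_mention_sets <- function(x, fn) {
  n <- length(x)
  lens <- lengths(x)
  flat <- as.character(unlist(x, use.names = FALSE))
  idx <- rep.int(seq_len(n), lens)
  flat <- fn(flat, drop = FALSE)
  keep <- !is.na(flat) & nzchar(flat)
  out <- rep(list(character(0)), n)
  if (any(keep)) {
    spl <- lapply(split(flat[keep], idx[keep]),
                  function(v) sort(unique(v), method = "radix"))
    out[as.integer(names(spl))] <- spl
  }
  out
}

# trusted constructor: fields already canonical, deduplicated and sorted
new_icsr <- function(report_id, date, drugs, events, med_error) {
  out <- tibble::tibble(
    report_id = report_id, date = date,
    drugs = drugs, events = events, med_error = med_error
  )
  class(out) <- c("pv_icsr", class(tibble::tibble()))
  out
}

empty_icsr <- function() {
  icsr_reports(character(), as.Date(character()), list(), list(), logical())
}

assert_icsr <- function(reports) {
  need <- c("report_id", "date", "drugs", "events", "med_error")
  if (!is.data.frame(reports) || !all(need %in% names(reports))) {
    abort(paste(
      "expected an ICSR collection with columns",
      paste(need, collapse = ", ")
    ))
  }
  invisible(reports)
}

#' Vocabulary of a report collection
#'
#' @param reports An ICSR collection (see [icsr_reports()]).
#' @return A list with sorted character vectors `drugs` and `events`: the
#'   exact unions of the per-report mention sets.
#' @export
#' @examples
#' r <- icsr_reports("R1", "2020-01-01", list(c("J01FA10", "J01CA04")),
#'                   list("rash"), FALSE)
#' vocabulary(r)
vocabulary <- function(reports) {
  assert_icsr(reports)
  union_of <- function(x) {
    u <- unlist(x, use.names = FALSE)
    if (is.null(u)) character(0) else sort(unique(u), method = "radix")
  }
  list(drugs = union_of(reports$drugs), events = union_of(reports$events))
}

# report x term logical membership matrix over a fixed vocabulary
mention_matrix <- function(mentions, vocab) {
  n <- length(mentions)
  m <- matrix(FALSE, nrow = n, ncol = length(vocab),
              dimnames = list(NULL, vocab))
  if (n == 0 || length(vocab) == 0) return(m)
  lens <- lengths(mentions)
  flat <- unlist(mentions, use.names = FALSE)
  row <- rep.int(seq_len(n), lens)
  col <- match(flat, vocab)
  keep <- !is.na(col)
  m[cbind(row[keep], col[keep])] <- TRUE
  m
}
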