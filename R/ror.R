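#' 2x2 contingency table for a drug-event pair
#'
#' The case/non-case cross-classification of a report universe for a target
#' drug P and target event R: `a` reports list both P and R, `b` list P but
#' not R, `c` list R but not P, and `d` list neither. The counting unit is
#' the report, never the individual mention.
#'
#' @param a,b,c,d Cell counts (non-negative; non-integers are allowed for
#'   expected-value tables when `integer_counts = FALSE`).
#' @param drug_code,event_term Optional pair labels carried for reporting.
#' @param integer_counts Require integer cells (the default for observed
#'   tables)?
#' @return A list of class `pv_contingency` with fields `a`, `b`, `c`, `d`,
#'   `n` and the labels.
#' @export
#' @examples
#' contingency_table(5, 10, 20, 1000)
contingency_table <- function(a, b, c, d, drug_code = NA_character_,
                              event_term = NA_character_,
                              integer_counts = TRUE) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (anyNA(counts) || any(counts < 0)) {
    abort("contingency counts must be non-negative")
  }
  if (integer_counts && any(counts != round(counts))) {
    abort("observed contingency counts must be integers")
  }
  structure(
    list(a = unname(a), b = unname(b), c = unname(c), d = unname(d),
         n = unname(a + b + c + d),
         drug_code = drug_code, event_term = event_term),
    class = "pv_contingency"
  )
}

#' @export
print.pv_contingency <- function(x, ...) {
  lab <- if (!is.na(x$drug_code)) sprintf(" [%s / %s]", x$drug_code,
                                          x$event_term) else ""
  cat(sprintf("2x2 report-level contingency table%s\n", lab))
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("drug+", "drug-"), c("event+", "event-")))
  print(m)
  cat(sprintf("n = %s reports\n", format(x$n)))
  invisible(x)
}

#' Build the contingency table for one drug-event pair
#'
#' Each report in the universe contributes exactly once to exactly one
#' cell, by set membership of the target drug code in its drug set and the
#' target event term in its event set. An unknown pair is legitimate and
#' yields `a = 0`.
#'
#' @param reports The filtered ICSR universe.
#' @param drug_code Target drug (canonicalized like the ingest step).
#' @param event_term Target event (canonicalized like the ingest step).
#' @return A `pv_contingency`.
#' @export
#' @examples
#' r <- icsr_reports(
#'   c("R1", "R2", "R3"), rep("2020-01-01", 3),
#'   drugs = list("J01FA10", "J01FA10", "J01CA04"),
#'   events = list("rash", "vomiting", "rash")
#' )
#' build_contingency(r, "J01FA10", "rash")
build_contingency <- function(reports, drug_code, event_term) {
  assert_icsr(reports)
  drug_code <- normalize_drug_code(drug_code)
  event_term <- normalize_event_term(event_term)
  stopifnot(length(drug_code) == 1, length(event_term) == 1)
  has_d <- vapply(reports$drugs, function(x) drug_code %in% x, logical(1))
  has_e <- vapply(reports$events, function(x) event_term %in% x, logical(1))
  contingency_table(
    a = sum(has_d & has_e), b = sum(has_d & !has_e),
    c = sum(!has_d & has_e), d = sum(!has_d & !has_e),
    drug_code = drug_code, event_term = event_term
  )
}

#' Reporting odds ratio with Woolf confidence interval
#'
#' Computes ROR = (a.d)/(c.b) for a 2x2 report-level table, with the Woolf
#' (log-normal) confidence interval
#' `exp(ln ROR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`.
#'
#' Zero cells follow the conventions of ROR-based screening systems:
#' when `c = 0` (every report with the event also lists the drug) the ratio
#' is undefined by division and the ROR is arbitrarily set to the sentinel
#' value 99.9 with status `"sentinel_c_zero"`, marking a possible signal;
#' the sentinel is a marker, not an estimate, and carries no interval.
#' When `a = 0` there is no information on the pair, and when `b = 0` or
#' `d = 0` (with `c > 0`) the interval is uncomputable: both give status
#' `"undefined"`. No continuity correction is applied by default;
#' `correction = "haldane"` adds 0.5 to every cell and always returns a
#' finite estimate.
#'
#' @param table A `pv_contingency` with integer counts.
#' @param z Normal quantile for the interval (1.96 for 95%).
#' @param correction `"none"` (default) or `"haldane"`.
#' @return A list of class `pv_ror`: `ror`, `ci_low`, `ci_high`,
#'   `status` in \{`"ok"`, `"sentinel_c_zero"`, `"undefined"`\}, `z`, and
#'   the input `table`.
#' @export
#' @examples
#' compute_ror(contingency_table(5, 10, 20, 1000))
#' compute_ror(contingency_table(5, 100, 0, 1000)) # sentinel 99.9
compute_ror <- function(table, z = 1.96, correction = c("none", "haldane")) {
  stopifnot(inherits(table, "pv_contingency"))
  correction <- match.arg(correction)
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  if (any(c(a, b, c, d) < 0)) abort("negative contingency counts")

  make <- function(ror, lo, hi, status) {
    structure(list(ror = ror, ci_low = lo, ci_high = hi, status = status,
                   z = z, table = table), class = "pv_ror")
  }
  if (correction == "haldane") {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  } else {
    if (a == 0) return(make(NA_real_, NA_real_, NA_real_, "undefined"))
    if (c == 0) return(make(99.9, NA_real_, NA_real_, "sentinel_c_zero"))
    if (b == 0 || d == 0) {
      return(make(NA_real_, NA_real_, NA_real_, "undefined"))
    }
  }
  ror <- (a * d) / (c * b)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  make(ror, exp(log(ror) - z * se), exp(log(ror) + z * se), "ok")
}

#' @export
print.pv_ror <- function(x, ...) {
  cat(sprintf("ROR = %s [status: %s]\n",
              format(x$ror, digits = 4), x$status))
  if (x$status == "ok") {
    cat(sprintf("%.1f%% CI (Woolf): %.4g - %.4g\n",
                100 * (2 * stats::pnorm(x$z) - 1), x$ci_low, x$ci_high))
  }
  invisible(x)
}

#' Signal-of-disproportionate-reporting decision and intensity stratum
#'
#' A pair is an SDR when the lower bound of the ROR confidence interval
#' exceeds 1 and the pair has at least `min_a` case reports; sentinel
#' (`c = 0`) pairs with enough cases are flagged as possible SDRs in their
#' own stratum. Intensity strata separate pairs with `3 <= a < 5` from
#' those with `a >= 5`.
#'
#' @param result A `pv_ror`.
#' @param min_a Minimum case count for eligibility (default 3 notifications).
#' @return A list with `is_sdr` (logical) and `intensity`, one of
#'   `"excluded_a<3"`, `"3<=a<5"`, `"a>=5"`, `"a>=3_c=0"` (the exclusion
#'   label follows `min_a` if it is changed from its default).
#' @export
#' @examples
#' classify_sdr(compute_ror(contingency_table(5, 10, 20, 1000)))
classify_sdr <- function(result, min_a = 3) {
  stopifnot(inherits(result, "pv_ror"))
  a <- result$table$a
  if (a < min_a) {
    return(list(is_sdr = FALSE,
                intensity = sprintf("excluded_a<%g", min_a)))
  }
  if (result$status == "sentinel_c_zero") {
    return(list(is_sdr = TRUE, intensity = "a>=3_c=0"))
  }
  intensity <- if (a < 5) "3<=a<5" else "a>=5"
  if (result$status != "ok") {
    return(list(is_sdr = FALSE, intensity = intensity))
  }
  list(is_sdr = isTRUE(result$ci_low > 1), intensity = intensity)
}
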