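#' Per-drug report and signal counts
#'
#' Summarizes a screening run by drug: how many reports of the universe
#' mention the drug (a report mentioning several drugs counts once for each
#' of them; the distinct-report total is recorded as an attribute) and how
#' many SDR-flagged pairs the drug has.
#'
#' @param reports The ICSR universe the signals were computed from.
#' @param signals Signal tibble from [screen_all()] on that same universe.
#' @return A tibble with columns `drug_code`, `n_reports`, `n_signals`,
#'   `aware_group`, sorted by `n_reports` descending then code, covering
#'   every drug in the universe vocabulary. Attribute `n_reports_distinct`
#'   holds `nrow(reports)`.
#' @details The pairing of `reports` and `signals` is cross-checked: for
#'   every drug appearing in `signals`, `a + b` of any of its rows must
#'   equal the drug's report count in `reports`; a mismatch raises an
#'   integrity error (the signals were computed on a different universe).
#' @export
summarize_by_drug <- function(reports, signals) {
  assert_icsr(reports)
  voc <- vocabulary(reports)
  dm <- mention_matrix(reports$drugs, voc$drugs)
  n_rep <- colSums(dm)

  if (nrow(signals) > 0) {
    per_drug_exposed <- signals$a + signals$b
    expected <- n_rep[match(signals$drug_code, voc$drugs)]
    bad <- which(is.na(expected) | per_drug_exposed != expected)
    if (length(bad)) {
      abort(sprintf(
        "signals do not match this universe: drug '%s' has a+b = %d but %s reports mention it",
        signals$drug_code[bad[1]], per_drug_exposed[bad[1]],
        ifelse(is.na(expected[bad[1]]), "no", expected[bad[1]])
      ))
    }
  }
  sdr_by_drug <- if (nrow(signals)) {
    tapply(signals$is_sdr, signals$drug_code, sum)
  } else {
    integer(0)
  }
  n_sig <- as.integer(sdr_by_drug[match(voc$drugs, names(sdr_by_drug))])
  n_sig[is.na(n_sig)] <- 0L
  grp <- if ("aware_group" %in% names(signals)) {
    signals$aware_group[match(voc$drugs, signals$drug_code)]
  } else {
    rep(NA_character_, length(voc$drugs))
  }
  grp[is.na(grp)] <- aware_group(voc$drugs[is.na(grp)])
  out <- tibble::tibble(
    drug_code = voc$drugs,
    n_reports = as.integer(n_rep),
    n_signals = n_sig,
    aware_group = grp
  )
  out <- out[order(-out$n_reports, out$drug_code, method = "radix"), ]
  attr(out, "n_reports_distinct") <- nrow(reports)
  out
}
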