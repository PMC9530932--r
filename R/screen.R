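#' Screen every eligible drug-event pair of a report universe
#'
#' Runs the full disproportionality screen: for each (drug, event) pair of
#' the universe vocabulary with at least `min_a` case reports, computes the
#' 2x2 table, the ROR with its confidence interval, the SDR decision and
#' intensity stratum, and the AWaRe group of the drug. Pairs with `a = 0`
#' carry no information and are never emitted.
#'
#' @param reports The filtered ICSR universe.
#' @param aware An AWaRe table ([load_aware_table()]); the packaged default
#'   if omitted.
#' @param min_a Minimum case count (default 3 notifications).
#' @param z Normal quantile for the confidence interval (1.96 for 95%).
#' @param correction Zero-cell handling passed to [compute_ror()].
#' @return A tibble with one row per screened pair, ordered by drug code
#'   then event term (lexicographic, locale-independent), with columns
#'   `drug_code`, `event_term`, `a`, `b`, `c`, `d`, `ror`, `ci_low`,
#'   `ci_high`, `status`, `is_sdr`, `intensity`, `aware_group`. Attributes
#'   `n_pairs_a_pos` (pairs with `a >= 1`) and `n_excluded_min_a` (pairs
#'   with `1 <= a < min_a`) record the screening funnel.
#' @export
#' @examples
#' cfg <- synth_config(
#'   2000, c(J01FA10 = 0.2, J01CA04 = 0.2), c(rash = 0.1, cough = 0.1),
#'   injected_signals = data.frame(drug_code = "J01FA10",
#'                                 event_term = "rash", odds_multiplier = 8),
#'   seed = 11
#' )
#' screen_all(generate_reports(cfg))
screen_all <- function(reports, aware = load_aware_table(), min_a = 3,
                       z = 1.96, correction = "none") {
  assert_icsr(reports)
  voc <- vocabulary(reports)
  n <- nrow(reports)

  empty <- tibble::tibble(
    drug_code = character(), event_term = character(),
    a = integer(), b = integer(), c = integer(), d = integer(),
    ror = numeric(), ci_low = numeric(), ci_high = numeric(),
    status = character(), is_sdr = logical(), intensity = character(),
    aware_group = character()
  )
  if (n == 0 || length(voc$drugs) == 0 || length(voc$events) == 0) {
    attr(empty, "n_pairs_a_pos") <- 0L
    attr(empty, "n_excluded_min_a") <- 0L
    return(empty)
  }

  dm <- mention_matrix(reports$drugs, voc$drugs)
  em <- mention_matrix(reports$events, voc$events)
  a_mat <- crossprod(dm, em) # pairwise co-mention report counts
  drug_tot <- colSums(dm)
  event_tot <- colSums(em)

  n_pairs_a_pos <- sum(a_mat >= 1)
  n_excluded <- sum(a_mat >= 1 & a_mat < min_a)

  hit <- which(a_mat >= max(min_a, 1), arr.ind = TRUE)
  if (nrow(hit) == 0) {
    attr(empty, "n_pairs_a_pos") <- as.integer(n_pairs_a_pos)
    attr(empty, "n_excluded_min_a") <- as.integer(n_excluded)
    return(empty)
  }
  m <- nrow(hit)
  ror <- ci_low <- ci_high <- numeric(m)
  status <- intensity <- character(m)
  is_sdr <- logical(m)
  for (k in seq_len(m)) {
    i <- hit[k, 1]; j <- hit[k, 2]
    a <- a_mat[i, j]
    tab <- contingency_table(
      a = a, b = drug_tot[i] - a, c = event_tot[j] - a,
      d = n - drug_tot[i] - event_tot[j] + a,
      drug_code = voc$drugs[i], event_term = voc$events[j]
    )
    res <- compute_ror(tab, z = z, correction = correction)
    cls <- classify_sdr(res, min_a = min_a)
    ror[k] <- res$ror; ci_low[k] <- res$ci_low; ci_high[k] <- res$ci_high
    status[k] <- res$status; is_sdr[k] <- cls$is_sdr
    intensity[k] <- cls$intensity
  }
  a_hit <- a_mat[hit]
  out <- tibble::tibble(
    drug_code = voc$drugs[hit[, 1]], event_term = voc$events[hit[, 2]],
    a = as.integer(a_hit),
    b = as.integer(drug_tot[hit[, 1]] - a_hit),
    c = as.integer(event_tot[hit[, 2]] - a_hit),
    d = as.integer(n - drug_tot[hit[, 1]] - event_tot[hit[, 2]] + a_hit),
    ror = ror, ci_low = ci_low, ci_high = ci_high, status = status,
    is_sdr = is_sdr, intensity = intensity,
    aware_group = aware_group(voc$drugs[hit[, 1]], aware)
  )
  out <- out[order(out$drug_code, out$event_term, method = "radix"), ]
  attr(out, "n_pairs_a_pos") <- as.integer(n_pairs_a_pos)
  attr(out, "n_excluded_min_a") <- as.integer(n_excluded)
  out
}
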