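#' Configuration for the synthetic ICSR generator
#'
#' Defines a generative model for a spontaneous-reporting database with
#' known ground truth. Each report mentions each drug independently with its
#' marginal probability; each event is mentioned with its baseline marginal
#' probability, modified on the odds scale when an injected signal's drug is
#' present on the report. Because the modification acts on the odds, the
#' `odds_multiplier` of an injected signal is exactly the true odds ratio
#' targeted by recovery tests.
#'
#' @param n_reports Number of reports to generate (non-negative integer).
#' @param drugs Named numeric vector: names are ATC-like drug codes, values
#'   the marginal probability that a report mentions the drug.
#' @param events Named numeric vector: names are event terms, values the
#'   baseline marginal probability that a report mentions the event.
#' @param injected_signals Optional data frame with columns `drug_code`,
#'   `event_term`, `odds_multiplier` (each >= 0). When the drug is present
#'   on a report, the event's mention odds are multiplied by
#'   `odds_multiplier`. Several signals hitting the same event multiply.
#' @param med_error_prob Probability in \[0, 1\] that a report is flagged as
#'   a medication-error notification (flag is report-level, mirroring the
#'   exclusion of whole notifications).
#' @param date_range Length-2 vector of inclusive start/end dates.
#' @param seed Integer seed driving one global pseudo-random stream.
#'
#' @return A validated list of class `pv_synth_config`.
#' @seealso [generate_reports()], [expected_contingency()]
#' @export
#' @examples
#' synth_config(
#'   n_reports = 1000,
#'   drugs = c(J01FA10 = 0.1, J01CA04 = 0.15),
#'   events = c("rash" = 0.05, "vomiting" = 0.08),
#'   injected_signals = data.frame(
#'     drug_code = "J01FA10", event_term = "rash", odds_multiplier = 5
#'   ),
#'   seed = 42
#' )
synth_config <- function(n_reports, drugs, events, injected_signals = NULL,
                         med_error_prob = 0,
                         date_range = as.Date(c("2018-12-01", "2021-12-31")),
                         seed = 1L) {
  n_reports <- as.integer(n_reports)
  if (is.na(n_reports) || n_reports < 0) {
    abort("n_reports must be a non-negative integer")
  }
  check_probs <- function(p, what) {
    if (is.null(names(p)) || any(!nzchar(names(p)))) {
      abort(sprintf("%s must be a named probability vector", what))
    }
    bad <- which(is.na(p) | p < 0 | p > 1)
    if (length(bad)) {
      abort(sprintf("%s probability out of [0,1] for '%s'",
                    what, names(p)[bad[1]]))
    }
    p
  }
  drug_p <- check_probs(drugs, "drugs")
  names(drug_p) <- vapply(names(drug_p), function(x)
    normalize_drug_code(x), character(1))
  event_p <- check_probs(events, "events")
  names(event_p) <- vapply(names(event_p), function(x)
    normalize_event_term(x), character(1))
  if (anyDuplicated(names(drug_p))) abort("duplicate drug code in vocabulary")
  if (anyDuplicated(names(event_p))) abort("duplicate event term in vocabulary")

  if (is.null(injected_signals)) {
    injected_signals <- tibble::tibble(
      drug_code = character(), event_term = character(),
      odds_multiplier = numeric()
    )
  } else {
    injected_signals <- tibble::as_tibble(injected_signals)
    need <- c("drug_code", "event_term", "odds_multiplier")
    if (!all(need %in% names(injected_signals))) {
      abort("injected_signals needs columns drug_code, event_term, odds_multiplier")
    }
    injected_signals$drug_code <-
      vapply(injected_signals$drug_code, function(x)
        normalize_drug_code(x), character(1))
    injected_signals$event_term <-
      vapply(injected_signals$event_term, function(x)
        normalize_event_term(x), character(1))
    bad <- setdiff(injected_signals$drug_code, names(drug_p))
    if (length(bad)) {
      abort(sprintf("injected signal names unknown drug '%s'", bad[1]))
    }
    bad <- setdiff(injected_signals$event_term, names(event_p))
    if (length(bad)) {
      abort(sprintf("injected signal names unknown event '%s'", bad[1]))
    }
    if (any(is.na(injected_signals$odds_multiplier) |
              injected_signals$odds_multiplier < 0)) {
      abort("odds_multiplier must be >= 0")
    }
  }
  if (is.na(med_error_prob) || med_error_prob < 0 || med_error_prob > 1) {
    abort("med_error_prob must be in [0,1]")
  }
  date_range <- as.Date(date_range)
  if (length(date_range) != 2 || anyNA(date_range) ||
        date_range[1] > date_range[2]) {
    abort("date_range must be two parseable dates with start <= end")
  }
  structure(
    list(
      n_reports = n_reports, drugs = drug_p, events = event_p,
      injected_signals = injected_signals,
      med_error_prob = med_error_prob, date_range = date_range,
      seed = as.integer(seed)
    ),
    class = "pv_synth_config"
  )
}

#' Read a synthetic-data configuration from YAML or JSON
#'
#' The file mirrors the [synth_config()] fields: `n_reports`, `drugs` and
#' `events` as lists of `{drug_code|event_term, marginal_prob}` records,
#' `injected_signals` as `{drug_code, event_term, odds_multiplier}` records,
#' `med_error_prob`, `date_range` as `{start, end}`, and `seed`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `pv_synth_config` object.
#' @export
read_synth_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  pull_vocab <- function(entries, key) {
    p <- vapply(entries, function(e) as.numeric(e$marginal_prob), numeric(1))
    names(p) <- vapply(entries, function(e) as.character(e[[key]]),
                       character(1))
    p
  }
  inj <- NULL
  if (length(raw$injected_signals)) {
    inj <- do.call(rbind, lapply(raw$injected_signals, function(s) {
      data.frame(drug_code = as.character(s$drug_code),
                 event_term = as.character(s$event_term),
                 odds_multiplier = as.numeric(s$odds_multiplier))
    }))
  }
  synth_config(
    n_reports = raw$n_reports,
    drugs = pull_vocab(raw$drugs, "drug_code"),
    events = pull_vocab(raw$events, "event_term"),
    injected_signals = inj,
    med_error_prob = raw$med_error_prob %||% 0,
    date_range = as.Date(c(raw$date_range$start, raw$date_range$end)),
    seed = raw$seed %||% 1L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic spontaneous-report database
#'
#' Draws `n_reports` ICSRs from the generative model in a
#' [synth_config()]. A single global stream seeded by `config$seed` drives
#' all draws in a fixed order (drug mentions, then event mentions, then
#' dates, then the medication-error flag), so an identical configuration
#' reproduces an identical collection bit-for-bit. The caller's random
#' number generator state is left untouched.
#'
#' @param config A `pv_synth_config`.
#' @return An ICSR collection (see [icsr_reports()]) with report identifiers
#'   `R000001`, `R000002`, ...
#' @export
#' @examples
#' cfg <- synth_config(50, c(J01FA10 = 0.3), c("rash" = 0.2), seed = 7)
#' reports <- generate_reports(cfg)
#' nrow(reports)
generate_reports <- function(config) {
  stopifnot(inherits(config, "pv_synth_config"))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)

  n <- config$n_reports
  drug_codes <- names(config$drugs)
  event_terms <- names(config$events)
  nd <- length(drug_codes)
  nv <- length(event_terms)

  present <- matrix(runif(n * nd), nrow = n, ncol = nd) <
    matrix(config$drugs, nrow = n, ncol = nd, byrow = TRUE)

  # per-report event odds: baseline odds times the multiplier of every
  # injected signal whose drug is present on the report
  base_odds <- config$events / (1 - config$events)
  base_odds[config$events == 1] <- Inf
  odds <- matrix(base_odds, nrow = n, ncol = nv, byrow = TRUE)
  sig <- config$injected_signals
  if (nrow(sig) > 0 && n > 0) {
    for (i in seq_len(nrow(sig))) {
      j <- match(sig$drug_code[i], drug_codes)
      k <- match(sig$event_term[i], event_terms)
      odds[present[, j], k] <- odds[present[, j], k] * sig$odds_multiplier[i]
    }
  }
  pmat <- odds / (1 + odds)
  pmat[is.infinite(odds)] <- 1
  pmat[is.nan(pmat)] <- 0 # Inf odds hit by a zero multiplier
  has_event <- matrix(runif(n * nv), nrow = n, ncol = nv) < pmat

  ndays <- as.integer(config$date_range[2] - config$date_range[1]) + 1L
  dates <- config$date_range[1] + floor(runif(n) * ndays)
  med_error <- runif(n) < config$med_error_prob

  to_sets <- function(m, vocab) {
    # scan columns in sorted vocabulary order so each report's set comes
    # out sorted without a per-report sort
    ord <- order(vocab, method = "radix")
    out <- rep(list(character(0)), n)
    hit <- which(m[, ord, drop = FALSE], arr.ind = TRUE)
    if (nrow(hit)) {
      spl <- split(vocab[ord][hit[, 2]], hit[, 1])
      out[as.integer(names(spl))] <- spl
    }
    out
  }
  # vocabulary codes are canonical already and report ids are pre-sorted,
  # so the trusted constructor can skip re-normalization
  new_icsr(
    report_id = sprintf("R%06d", seq_len(n)),
    date = dates,
    drugs = to_sets(present, drug_codes),
    events = to_sets(has_event, event_terms),
    med_error = med_error
  )
}

#' Expected contingency table under the generative model
#'
#' Analytic (non-integer) expected values of the report-level a/b/c/d counts
#' for one drug-event pair, obtained by exact enumeration of the joint
#' presence patterns of the drugs that carry injected signals into the
#' event. Used as the oracle in parameter-recovery and consistency tests.
#'
#' @param config A `pv_synth_config`.
#' @param drug_code Target drug code (must be in the config vocabulary).
#' @param event_term Target event term (must be in the config vocabulary).
#' @return A `pv_contingency` with non-integer expected counts summing
#'   exactly to `n_reports`.
#' @export
#' @examples
#' cfg <- synth_config(1000, c(D1 = 0.5), c(e1 = 0.5), seed = 1)
#' expected_contingency(cfg, "D1", "e1") # 250 in every cell
expected_contingency <- function(config, drug_code, event_term) {
  stopifnot(inherits(config, "pv_synth_config"))
  drug_code <- normalize_drug_code(drug_code)
  event_term <- normalize_event_term(event_term)
  if (!drug_code %in% names(config$drugs)) {
    abort(sprintf("unknown drug code '%s'", drug_code))
  }
  if (!event_term %in% names(config$events)) {
    abort(sprintf("unknown event term '%s'", event_term))
  }
  p_d <- unname(config$drugs[drug_code])
  p_e <- unname(config$events[event_term])
  sig <- config$injected_signals[
    config$injected_signals$event_term == event_term, , drop = FALSE]
  sdrugs <- sig$drug_code
  mult <- sig$odds_multiplier
  k <- length(sdrugs)
  if (k > 20) abort("too many injected signals on one event to enumerate")

  base_odds <- if (p_e == 1) Inf else p_e / (1 - p_e)
  # enumerate presence patterns of the signal-bearing drugs
  patterns <- if (k == 0) {
    matrix(logical(0), nrow = 1, ncol = 0)
  } else {
    as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), k)))
  }
  p_sd <- unname(config$drugs[sdrugs])
  p_e_joint <- 0 # P(E)
  p_de <- 0     # P(D and E)
  target_in <- match(drug_code, sdrugs)
  for (r in seq_len(nrow(patterns))) {
    pat <- patterns[r, ]
    w <- prod(ifelse(pat, p_sd, 1 - p_sd))
    o <- base_odds * prod(mult[pat])
    pe <- if (is.infinite(o)) 1 else if (is.nan(o)) 0 else o / (1 + o)
    p_e_joint <- p_e_joint + w * pe
    if (!is.na(target_in)) {
      if (pat[target_in]) p_de <- p_de + w * pe
    }
  }
  if (is.na(target_in)) p_de <- p_d * p_e_joint

  n <- config$n_reports
  a <- n * p_de
  b <- n * (p_d - p_de)
  c <- n * (p_e_joint - p_de)
  d <- n - a - b - c # d absorbs rounding so the cells sum to n
  tab <- contingency_table(a, b, c, d, drug_code = drug_code,
                           event_term = event_term, integer_counts = FALSE)
  tab$n <- as.numeric(n)
  tab
}
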