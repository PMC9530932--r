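# Independent oracles used across the suite. They deliberately avoid the
# package's table/ROR code paths: counts are accumulated by looping over raw
# report sets and the odds ratio is formed as a ratio of odds, not as
# (a*d)/(c*b).

brute_force_counts <- function(reports, drug, event) {
  a <- b <- cc <- d <- 0L
  for (i in seq_len(nrow(reports))) {
    has_d <- drug %in% reports$drugs[[i]]
    has_e <- event %in% reports$events[[i]]
    if (has_d && has_e) a <- a + 1L
    else if (has_d) b <- b + 1L
    else if (has_e) cc <- cc + 1L
    else d <- d + 1L
  }
  list(a = a, b = b, c = cc, d = d)
}

brute_force_or <- function(reports, drug, event) {
  k <- brute_force_counts(reports, drug, event)
  odds_exposed <- k$a / k$b
  odds_unexposed <- k$c / k$d
  odds_exposed / odds_unexposed
}

# small random universe with ATC-like drug codes and lowercase event terms
random_universe <- function(n, n_drugs = 3, n_events = 3, seed = 1) {
  set.seed(seed)
  drugs <- sprintf("J01AA%02d", seq_len(n_drugs))
  events <- sprintf("event %d", seq_len(n_events))
  cfg <- synth_config(
    n_reports = n,
    drugs = stats::setNames(runif(n_drugs, 0.2, 0.7), drugs),
    events = stats::setNames(runif(n_events, 0.2, 0.7), events),
    seed = seed
  )
  generate_reports(cfg)
}

fixture_reports <- function() {
  # 6 reports: 2 with (P,R), 1 with P only, 2 with R only, 1 with neither
  icsr_reports(
    report_id = paste0("F", 1:6),
    date = rep("2020-06-15", 6),
    drugs = list("J01FA10", "J01FA10", "J01FA10",
                 "J01CA04", "J01CA04", "J01CA04"),
    events = list("rash", "rash", "cough", "rash", "rash", "cough"),
    med_error = rep(FALSE, 6)
  )
}
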