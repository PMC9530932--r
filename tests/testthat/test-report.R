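test_that("label annotation is tri-state and leaves signals untouched", {
  sig <- tibble::tibble(
    drug_code = c("J01FA10", "J01FA10", "J01CA04"),
    event_term = c("rash", "tremor", "rash"),
    is_sdr = c(TRUE, TRUE, FALSE), ror = c(5, 7, 1.2)
  )
  known <- tibble::tibble(atc_code = "J01FA10", event_term = "rash")
  out <- annotate_labelled(sig, known)
  expect_equal(out$labelled, c(TRUE, FALSE, NA))
  expect_equal(out[names(sig)], sig) # nothing else changed
})

test_that("per-drug summaries match hand enumeration", {
  fix <- fixture_reports()
  sig <- screen_all(fix, min_a = 1)
  s <- summarize_by_drug(fix, sig)
  expect_equal(s$n_reports[s$drug_code == "J01FA10"], 3L)
  expect_equal(s$n_reports[s$drug_code == "J01CA04"], 3L)
  expect_equal(sum(s$n_signals), sum(sig$is_sdr))
  expect_equal(attr(s, "n_reports_distinct"), 6L)
  # sorted by report count descending, then code
  expect_identical(s$drug_code,
                   s$drug_code[order(-s$n_reports, s$drug_code)])
})

test_that("a report mentioning two class drugs counts once for each", {
  r <- icsr_reports(
    c("R1", "R2"), c("2020-01-01", "2020-01-02"),
    drugs = list(c("J01FA10", "J01CA04"), "J01FA10"),
    events = list("rash", "rash")
  )
  s <- summarize_by_drug(r, screen_all(r, min_a = 1))
  expect_equal(s$n_reports[s$drug_code == "J01FA10"], 2L)
  expect_equal(s$n_reports[s$drug_code == "J01CA04"], 1L)
  expect_equal(attr(s, "n_reports_distinct"), 2L)
})

test_that("summaries reject signals computed on a different universe", {
  fix <- fixture_reports()
  sig <- screen_all(fix, min_a = 1)
  other <- fix[1:4, ]
  expect_error(summarize_by_drug(other, sig), "universe")
})

test_that("run_pipeline is deterministic and its run log matches enumeration", {
  listing <- withr::local_tempfile(fileext = ".csv")
  cfg_synth <- synth_config(
    800,
    c(J01FA10 = 0.3, J01CA04 = 0.25, J01DD04 = 0.2),
    c(rash = 0.1, cough = 0.12, vomiting = 0.05),
    injected_signals = data.frame(drug_code = "J01FA10",
                                  event_term = "rash",
                                  odds_multiplier = 8),
    med_error_prob = 0.05,
    seed = 55
  )
  reports <- generate_reports(cfg_synth)
  write_line_listing(reports, listing, "long")

  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  config <- list(
    input = listing, dialect = "long",
    filters = list(atc_prefix = "J01", date_start = "2018-12-01",
                   date_end = "2021-12-31", exclude_med_errors = TRUE),
    out_dir = out1
  )
  res <- run_pipeline(config)
  config$out_dir <- out2
  run_pipeline(config)
  for (f in c("signals.csv", "drug_summary.csv")) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  }

  # run-log counts against independent enumeration of the raw reports
  log <- res$run_log$counts
  expect_equal(log$reports_read, 800L)
  expect_equal(log$reports_in_date_window, 800L)
  # reports that mention no drug at all never enter the class universe
  universe <- reports[!reports$med_error & lengths(reports$drugs) > 0, ]
  expect_equal(log$reports_in_universe, nrow(universe))
  voc <- vocabulary(universe)
  a_all <- unlist(lapply(voc$drugs, function(d)
    vapply(voc$events, function(e)
      brute_force_counts(universe, d, e)$a, numeric(1))))
  expect_equal(log$pairs_a_positive, sum(a_all >= 1))
  expect_equal(log$pairs_excluded_min_a, sum(a_all >= 1 & a_all < 3))
  expect_equal(log$pairs_screened, sum(a_all >= 3))
  expect_equal(log$sdrs_found, sum(res$signals$is_sdr))
  # filter funnel is monotone non-increasing
  funnel <- c(log$reports_read, log$reports_in_date_window,
              log$reports_with_class_drug, log$reports_in_universe)
  expect_true(all(diff(funnel) <= 0))
})

test_that("a universe emptied by filtering yields empty outputs and a warning", {
  listing <- withr::local_tempfile(fileext = ".csv")
  cfg <- synth_config(50, c(J01FA10 = 0.5), c(rash = 0.3),
                      med_error_prob = 1, seed = 3)
  write_line_listing(generate_reports(cfg), listing, "long")
  out <- withr::local_tempdir()
  config <- list(
    input = listing, dialect = "long",
    filters = list(atc_prefix = "J01", date_start = "2018-12-01",
                   date_end = "2021-12-31", exclude_med_errors = TRUE),
    out_dir = out
  )
  expect_warning(res <- run_pipeline(config), "no reports")
  expect_equal(nrow(res$signals), 0)
  expect_equal(res$run_log$counts$sdrs_found, 0L)
  expect_true(file.exists(file.path(out, "signals.csv")))
})

test_that("pipeline errors name the failing stage", {
  expect_error(
    run_pipeline(list(input = file.path(tempdir(), "absent.csv"),
                      dialect = "long",
                      filters = list(atc_prefix = "J01",
                                     date_start = "2018-12-01",
                                     date_end = "2021-12-31",
                                     exclude_med_errors = TRUE),
                      out_dir = withr::local_tempdir())),
    "stage 'read'"
  )
  expect_error(run_pipeline(list(dialect = "long")), "lacks")
})

test_that("label annotation integrates into the pipeline outputs", {
  listing <- withr::local_tempfile(fileext = ".csv")
  cfg <- synth_config(
    600, c(J01FA10 = 0.4), c(rash = 0.1, tremor = 0.08),
    injected_signals = data.frame(
      drug_code = c("J01FA10", "J01FA10"),
      event_term = c("rash", "tremor"),
      odds_multiplier = c(10, 10)
    ),
    seed = 12
  )
  write_line_listing(generate_reports(cfg), listing, "long")
  labels <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("atc_code,event_term", "J01FA10,rash"), labels)
  out <- withr::local_tempdir()
  res <- run_pipeline(list(
    input = listing, dialect = "long",
    filters = list(atc_prefix = "J01", date_start = "2018-12-01",
                   date_end = "2021-12-31", exclude_med_errors = TRUE),
    label_table = labels,
    out_dir = out
  ))
  sig <- res$signals
  expect_true(isTRUE(sig$labelled[sig$event_term == "rash"]))
  expect_false(isTRUE(sig$labelled[sig$event_term == "tremor"]))
})
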