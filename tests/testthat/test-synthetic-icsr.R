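test_that("generator is reproducible and honours n_reports", {
  cfg <- synth_config(
    200, c(J01FA10 = 0.3, J01CA04 = 0.2), c(rash = 0.1, cough = 0.2),
    med_error_prob = 0.1, seed = 42
  )
  r1 <- generate_reports(cfg)
  r2 <- generate_reports(cfg)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 200)

  empty <- generate_reports(synth_config(0, c(D = 0.5), c(e = 0.5), seed = 1))
  expect_equal(nrow(empty), 0)

  # the caller's RNG stream is not consumed
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(generate_reports(cfg)); after <- runif(1)
  expect_identical(before, after)
})

test_that("joint mention frequency matches independence at null", {
  n <- 20000
  cfg <- synth_config(n, c(D1 = 0.5), c(e1 = 0.5), seed = 7)
  r <- generate_reports(cfg)
  joint <- mean(vapply(seq_len(n), function(i) {
    "D1" %in% r$drugs[[i]] && "e1" %in% r$events[[i]]
  }, logical(1)))
  se <- sqrt(0.25 * 0.75 / n) # binomial standard error at p = 0.25
  expect_lt(abs(joint - 0.25), 3 * se)
})

test_that("injected odds multiplier is recovered as the empirical odds ratio", {
  cfg <- synth_config(
    20000, c(D1 = 0.3), c(e1 = 0.1),
    injected_signals = data.frame(drug_code = "D1", event_term = "e1",
                                  odds_multiplier = 5),
    seed = 11
  )
  r <- generate_reports(cfg)
  k <- brute_force_counts(r, "D1", "e1")
  or_hat <- (k$a / k$b) / (k$c / k$d)
  woolf_se <- sqrt(1 / k$a + 1 / k$b + 1 / k$c + 1 / k$d)
  expect_lt(abs(log(or_hat) - log(5)), 3 * woolf_se)
})

test_that("expected contingency matches direct probability arithmetic", {
  cfg <- synth_config(1000, c(D1 = 0.5), c(e1 = 0.5), seed = 1)
  tab <- expected_contingency(cfg, "D1", "e1")
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(250, 250, 250, 250))

  # multiplier of exactly 1 is a no-op
  cfg1 <- synth_config(
    1000, c(D1 = 0.5), c(e1 = 0.5),
    injected_signals = data.frame(drug_code = "D1", event_term = "e1",
                                  odds_multiplier = 1),
    seed = 1
  )
  tab1 <- expected_contingency(cfg1, "D1", "e1")
  expect_equal(c(tab1$a, tab1$b, tab1$c, tab1$d),
               c(tab$a, tab$b, tab$c, tab$d))

  # injected pair: four joint probabilities written out longhand
  cfg2 <- synth_config(
    10000, c(D1 = 0.2), c(e1 = 0.1),
    injected_signals = data.frame(drug_code = "D1", event_term = "e1",
                                  odds_multiplier = 5),
    seed = 1
  )
  p_d <- 0.2
  odds_base <- 0.1 / 0.9
  p_e_given_d <- (odds_base * 5) / (1 + odds_base * 5)
  p_e_given_nd <- 0.1
  exp_a <- 10000 * p_d * p_e_given_d
  exp_b <- 10000 * p_d * (1 - p_e_given_d)
  exp_c <- 10000 * (1 - p_d) * p_e_given_nd
  exp_d <- 10000 * (1 - p_d) * (1 - p_e_given_nd)
  tab2 <- expected_contingency(cfg2, "D1", "e1")
  expect_equal(c(tab2$a, tab2$b, tab2$c, tab2$d),
               c(exp_a, exp_b, exp_c, exp_d))
  expect_identical(tab2$n, 10000) # cells sum to n_reports exactly

  # the expected table is also exact for a drug without any injection
  cfg3 <- synth_config(
    5000, c(D1 = 0.2, D2 = 0.4), c(e1 = 0.1),
    injected_signals = data.frame(drug_code = "D1", event_term = "e1",
                                  odds_multiplier = 5),
    seed = 1
  )
  tab3 <- expected_contingency(cfg3, "D2", "e1")
  p_e_marg <- p_d * p_e_given_d + (1 - p_d) * p_e_given_nd
  expect_equal(tab3$a, 5000 * 0.4 * p_e_marg)
  expect_equal(tab3$a + tab3$b + tab3$c + tab3$d, 5000)
})

test_that("realized counts converge to expected counts", {
  cfg <- synth_config(
    20000, c(D1 = 0.2), c(e1 = 0.1),
    injected_signals = data.frame(drug_code = "D1", event_term = "e1",
                                  odds_multiplier = 5),
    seed = 23
  )
  expd <- expected_contingency(cfg, "D1", "e1")
  obs <- brute_force_counts(generate_reports(cfg), "D1", "e1")
  for (cell in c("a", "b", "c", "d")) {
    p <- expd[[cell]] / expd$n
    se <- sqrt(expd$n * p * (1 - p)) # multinomial cell standard error
    expect_lt(abs(obs[[cell]] - expd[[cell]]), 3 * se)
  }
})

test_that("invalid configurations are rejected with a pointer at the entry", {
  expect_error(synth_config(10, c(D1 = 1.2), c(e1 = 0.5)), "D1")
  expect_error(synth_config(10, c(D1 = 0.5), c(e1 = -0.1)), "e1")
  expect_error(synth_config(-1, c(D1 = 0.5), c(e1 = 0.5)), "n_reports")
  expect_error(
    synth_config(10, c(D1 = 0.5), c(e1 = 0.5),
                 injected_signals = data.frame(drug_code = "NOPE",
                                               event_term = "e1",
                                               odds_multiplier = 2)),
    "NOPE"
  )
  expect_error(
    synth_config(10, c(D1 = 0.5), c(e1 = 0.5),
                 injected_signals = data.frame(drug_code = "D1",
                                               event_term = "e1",
                                               odds_multiplier = -2)),
    "odds_multiplier"
  )
  expect_error(
    synth_config(10, c(D1 = 0.5), c(e1 = 0.5),
                 date_range = c("2021-01-01", "2020-01-01")),
    "date_range"
  )
  expect_error(expected_contingency(
    synth_config(10, c(D1 = 0.5), c(e1 = 0.5)), "D9", "e1"), "D9")
})

test_that("synthetic configs round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "n_reports: 500",
    "drugs:",
    "  - {drug_code: J01FA10, marginal_prob: 0.25}",
    "  - {drug_code: J01CA04, marginal_prob: 0.10}",
    "events:",
    "  - {event_term: rash, marginal_prob: 0.05}",
    "injected_signals:",
    "  - {drug_code: J01FA10, event_term: rash, odds_multiplier: 4}",
    "med_error_prob: 0.02",
    "date_range: {start: 2018-12-01, end: 2021-12-31}",
    "seed: 77"
  ), path)
  cfg <- read_synth_config(path)
  expect_s3_class(cfg, "pv_synth_config")
  expect_equal(cfg$n_reports, 500L)
  expect_equal(unname(cfg$drugs["J01FA10"]), 0.25)
  expect_equal(cfg$injected_signals$odds_multiplier, 4)
  expect_equal(cfg$seed, 77L)
  expect_identical(generate_reports(cfg), generate_reports(cfg))
})
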