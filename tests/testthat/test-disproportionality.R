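## Independent closed-form oracle for the four statistics, written out
## directly from the 2x2 definitions (kept free of package internals).
oracle_metrics <- function(a, b, c, d) {
  N <- a + b + c + d
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  ror <- (a / b) / (c / d)
  list(
    ror = ror,
    ror_lo = exp(log(ror) - 1.96 * se), ror_hi = exp(log(ror) + 1.96 * se),
    prr = (a / (a + c)) / (b / (b + d)),
    ic = log2(a * N / ((a + c) * (a + b))),
    ic025 = log2(a * N / ((a + c) * (a + b))) * exp(-1.96 * se),
    ebgm = a * N / ((a + c) * (a + b)),
    ebgm05 = (a * N / ((a + c) * (a + b))) * exp(-1.64 * se),
    se = se)
}

test_that("worked table reproduces the closed-form values and bounds", {
  m <- signal_metrics(worked_table())
  o <- oracle_metrics(20, 180, 80, 9720)
  expect_equal(m$ror, 13.5, tolerance = 1e-12)
  expect_equal(m$prr, 11.0, tolerance = 1e-12)
  expect_equal(m$ic, log2(10), tolerance = 1e-12)
  expect_equal(m$ebgm, 10, tolerance = 1e-12)
  for (f in names(o)) expect_equal(m[[f]], o[[f]], tolerance = 1e-12)
  ## chi2 against stats::chisq.test as an independent implementation
  tab <- matrix(c(20, 180, 80, 9720), 2, byrow = TRUE)
  expect_equal(m$chi2,
               unname(suppressWarnings(chisq.test(tab, correct = FALSE))$statistic),
               tolerance = 1e-9)
  expect_true(m$chi2 > 166.9 && m$chi2 < 167.1)
  expect_true(m$ror_signal && m$prr_signal && m$ic_signal && m$ebgm_signal)
})

test_that("identity table gives unit ratios, zero chi2, no flags", {
  m <- signal_metrics(contingency_table(5, 5, 5, 5))
  expect_equal(m$ror, 1); expect_equal(m$prr, 1)
  expect_equal(m$chi2, 0); expect_equal(m$ic, 0); expect_equal(m$ebgm, 1)
  ## CI symmetric about 1 in log space
  expect_equal(log(m$ror_hi), -log(m$ror_lo))
  expect_false(any(m$ror_signal, m$prr_signal, m$ic_signal, m$ebgm_signal))
})

test_that("chi-squared matches the independent Pearson computation on random tables", {
  tabs <- random_tables(250, seed = 3)
  m <- signal_metrics(tabs)
  for (i in sample(nrow(tabs), 25)) {
    mt <- matrix(c(tabs$a[i], tabs$c[i], tabs$b[i], tabs$d[i]), 2, byrow = TRUE)
    expect_equal(m$chi2[i],
                 unname(suppressWarnings(chisq.test(mt, correct = FALSE))$statistic),
                 tolerance = 1e-9)
  }
  ## doubling all cells doubles chi2, leaves prr and ror unchanged
  m2 <- signal_metrics(contingency_table(2 * tabs$a, 2 * tabs$b,
                                         2 * tabs$c, 2 * tabs$d))
  expect_equal(m2$chi2, 2 * m$chi2, tolerance = 1e-9)
  expect_equal(m2$prr, m$prr, tolerance = 1e-12)
  expect_equal(m2$ror, m$ror, tolerance = 1e-12)
})

test_that("single-cell and Yates chi-squared options work as defined", {
  t1 <- worked_table()
  m1 <- signal_metrics(t1, chi2_cells = "single-cell")
  Ea <- (20 + 180) * (20 + 80) / 10000
  expect_equal(m1$chi2, (20 - Ea)^2 / Ea, tolerance = 1e-12)
  my <- signal_metrics(t1, yates = TRUE)
  tab <- matrix(c(20, 180, 80, 9720), 2, byrow = TRUE)
  expect_equal(my$chi2,
               unname(suppressWarnings(chisq.test(tab, correct = TRUE))$statistic),
               tolerance = 1e-9)
})

test_that("zero cells give undefined metrics (no flags, no errors) by default", {
  m <- signal_metrics(contingency_table(0, 180, 80, 9720))
  expect_true(is.na(m$ror) && is.na(m$ic) && is.na(m$ebgm))
  expect_false(any(m$ror_signal, m$ic_signal, m$ebgm_signal))
  ## batch runs keep going: mixture of defined and undefined rows
  mm <- signal_metrics(contingency_table(c(0, 20), c(180, 180),
                                         c(80, 80), c(9720, 9720)))
  expect_true(is.na(mm$ror[1]) && !is.na(mm$ror[2]))
})

test_that("Haldane-Anscombe policy adds 0.5 to all cells of zero-containing tables", {
  m <- signal_metrics(contingency_table(0, 180, 80, 9720),
                      zero_policy = "haldane")
  o <- oracle_metrics(0.5, 180.5, 80.5, 9720.5)
  expect_equal(m$ror, o$ror, tolerance = 1e-12)
  expect_equal(m$ebgm, o$ebgm, tolerance = 1e-12)
  ## n gate still uses the raw count: a = 0 can never satisfy n >= 2
  expect_false(m$ror_signal)
  ## tables without zeros are untouched
  m2 <- signal_metrics(worked_table(), zero_policy = "haldane")
  expect_equal(m2$ror, 13.5, tolerance = 1e-12)
})

test_that("literature mode uses the additive log2-scale IC bound", {
  m <- signal_metrics(worked_table(), mode = "literature")
  o <- oracle_metrics(20, 180, 80, 9720)
  expect_equal(m$ic025, o$ic - 1.96 * o$se / log(2), tolerance = 1e-12)
  ## defined even for negative IC, unlike the printed multiplicative bound
  neg <- contingency_table(5, 500, 400, 5000)
  expect_true(signal_metrics(neg)$ic < 0)
  expect_true(is.na(signal_metrics(neg)$ic025))
  expect_false(is.na(signal_metrics(neg, mode = "literature")$ic025))
})

test_that("criteria gates: counts can veto strong ratios", {
  ## a = 1 with an extreme ratio: ROR flag blocked by n >= 2,
  ## PRR flag blocked by n >= 3
  m <- signal_metrics(contingency_table(1, 10, 1, 10000))
  expect_true(m$ror > 100)
  expect_false(m$ror_signal)
  expect_false(m$prr_signal)
  m2 <- signal_metrics(contingency_table(2, 10, 1, 10000))
  expect_true(m2$ror_signal)
  expect_false(m2$prr_signal)  # n = 2 < 3
})

test_that("build_contingency satisfies the margin identities", {
  rs <- tiny_report_set()
  sel <- select_cohort(rs)
  tab <- build_contingency(rs, drug_ids = sel$exposure$primaryid,
                           evt_ids = sel$event_ids)
  expect_equal(tab$a, 1); expect_equal(tab$b, 1)
  expect_equal(tab$c, 1); expect_equal(tab$d, 1)
  ## drug absent from the set
  tab0 <- build_contingency(rs, character(), sel$event_ids)
  expect_equal(tab0$a, 0); expect_equal(tab0$c, 0)
  ## generated set: a equals ground-truth exposed-event count
  g <- generate_reports(synthetic_config(n_reports = 20000, seed = 21,
                                         true_rr = c(caspofungin = 6)))
  rs2 <- deduplicate(g$reports)
  sel2 <- select_cohort(rs2)
  tab2 <- build_contingency(
    rs2, sel2$exposure[drug == "caspofungin"]$primaryid, sel2$event_ids)
  gt <- g$truth$per_drug[drug == "caspofungin"]
  expect_equal(tab2$a, as.numeric(gt$n_event))
  expect_equal(tab2$a + tab2$c, as.numeric(gt$n_exposed))
  expect_equal(tab2$a + tab2$b, length(sel2$event_ids))
  expect_equal(tab2$a + tab2$b + tab2$c + tab2$d, n_reports(rs2))
})

test_that("analyze_all emits a formatted publication-style row per drug", {
  g <- generate_reports(synthetic_config(n_reports = 30000, seed = 2,
                                         true_rr = c(voriconazole = 8)))
  rs <- deduplicate(g$reports)
  sel <- select_cohort(rs)
  m <- analyze_all(rs, sel)
  expect_equal(nrow(m), 11L)
  expect_setequal(m$drug, names(sel$per_drug))
  v <- m[drug == "voriconazole"]
  expect_match(v$ror_ci, "^\\d+\\.\\d{2} \\(\\d+\\.\\d{2}, \\d+\\.\\d{2}\\)\\*?$")
  ## zero-case drugs get a row with n = 0 and no stars
  zero <- m[n == 0]
  if (nrow(zero)) {
    expect_false(any(zero$ror_signal))
    expect_false(any(grepl("\\*", zero$ror_ci)))
  }
  ## undefined bounds render as empty parentheses, as published tables do
  mm <- signal_metrics(contingency_table(5, 500, 400, 5000))
  expect_true(mm$ic < 0 && is.na(mm$ic025))
})

test_that("monotonicity: moving mass onto the diagonal raises every ratio", {
  base <- c(a = 20, b = 180, c = 80, d = 9720)
  m1 <- signal_metrics(do.call(contingency_table, as.list(base)))
  shifted <- contingency_table(base["a"] + 5, base["b"] - 5,
                               base["c"] - 5, base["d"] + 5)
  m2 <- signal_metrics(shifted)
  expect_gt(m2$ror, m1$ror); expect_gt(m2$prr, m1$prr)
  expect_gt(m2$ic, m1$ic); expect_gt(m2$ebgm, m1$ebgm)
})

test_that("ROR >= PRR >= 1 whenever the drug's event proportion dominates", {
  tabs <- random_tables(2000, seed = 14)
  m <- signal_metrics(tabs)
  dom <- with(tabs, a / (a + c) >= b / (b + d))
  expect_true(all(m$ror[dom] >= m$prr[dom] - 1e-12))
  expect_true(all(m$prr[dom] >= 1 - 1e-12))
})
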