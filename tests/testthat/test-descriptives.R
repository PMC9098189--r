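## Brute-force type-7 quantile oracle: sort, index h = (n-1)p + 1,
## interpolate between the flanking order statistics.
oracle_q7 <- function(x, p) {
  x <- sort(x); n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

test_that("quantile rule agrees with the brute-force oracle on all small samples", {
  set.seed(8)
  for (n in 1:8) {
    for (rep in 1:20) {
      x <- sample(0:60, n, replace = TRUE)
      q <- dilisignal:::onset_quantiles(x)
      expect_equal(q$q1, oracle_q7(x, 0.25))
      expect_equal(q$median, oracle_q7(x, 0.50))
      expect_equal(q$q3, oracle_q7(x, 0.75))
    }
  }
  ## the worked three-point example: median 8, IQR (2, 20) ... with
  ## interpolation the type-7 quartiles of {2,8,20} are 5 and 14
  q <- dilisignal:::onset_quantiles(c(2, 8, 20))
  expect_equal(q$median, 8)
  expect_equal(q$q1, oracle_q7(c(2, 8, 20), 0.25))
  expect_equal(q$q3, oracle_q7(c(2, 8, 20), 0.75))
})

test_that("onset_days implements the first-start-to-event rule", {
  expect_equal(onset_days(as.Date("2020-01-09"), as.Date("2020-01-01")), 8L)
  expect_equal(onset_days(as.Date("2020-01-01"), as.Date("2020-01-01")), 0L)
  ## event before start and missing dates are excluded, not negative
  expect_true(is.na(onset_days(as.Date("2019-12-31"), as.Date("2020-01-01"))))
  expect_true(is.na(onset_days(as.Date(NA), as.Date("2020-01-01"))))
  expect_true(is.na(onset_days(as.Date("2020-01-09"), as.Date(NA))))
})

test_that("demographic summary partitions the cohort within each dimension", {
  rs <- reference_cohort()
  sel <- select_cohort(rs)
  coh <- cohort_table(rs, sel)
  ds <- summarize_demographics(coh)
  n <- sel$flow$n_case
  for (dim in c("age_band", "sex", "reporter", "year", "area")) {
    expect_equal(sum(ds[dimension == dim]$count), n, info = dim)
  }
  ## single attribution here, so drug counts also partition the cohort
  expect_equal(sum(ds[dimension == "drug"]$count), n)
  expect_true(all(ds$percent >= 0 & ds$percent <= 100))
})

test_that("single-report cohort puts every category at 100.00", {
  rs <- tiny_report_set()
  sel <- select_cohort(rs)
  coh <- cohort_table(rs, sel)
  ds <- summarize_demographics(coh)
  expect_true(all(ds[count > 0]$percent == 100))
})

test_that("empty cohort summarises to an empty table, not an error", {
  coh <- cohort_table(tiny_report_set(),
                      select_cohort(subset_reports(tiny_report_set(),
                                                   character())))
  expect_equal(nrow(summarize_demographics(coh[0])), 0L)
})

test_that("onset summary computes per-drug medians and group tests", {
  coh <- data.table::data.table(
    primaryid = sprintf("P%03d", 1:9),
    drug = rep(c("voriconazole", "caspofungin", "fluconazole"), each = 3),
    onset_days_ = c(2L, 8L, 20L, 1L, 5L, 11L, NA, 3L, 17L))
  os <- summarize_onset(coh)
  v <- os$by_drug[drug == "voriconazole"]
  expect_equal(v$median, 8); expect_equal(v$n_with_onset, 3L)
  f <- os$by_drug[drug == "fluconazole"]
  expect_equal(f$n_with_onset, 2L)
  expect_true(os$overall_p > 0 && os$overall_p <= 1)
  expect_true(all(os$by_drug[, !is.na(median) | n_with_onset == 0]))
  ## q1 <= median <= q3
  ok <- os$by_drug[n_with_onset > 0]
  expect_true(all(ok$q1 <= ok$median & ok$median <= ok$q3))
})

test_that("well-separated onset distributions are detected", {
  ## short-onset echinocandin vs long-onset azole: pairwise Wilcoxon
  ## p < 0.05 in >= 90% of seeds at n = 150 per drug
  hits <- logical(10)
  for (s in 1:10) {
    set.seed(s)
    coh <- data.table::data.table(
      primaryid = sprintf("P%04d", 1:300),
      drug = rep(c("caspofungin", "ketoconazole"), each = 150),
      onset_days_ = as.integer(round(c(exp(rnorm(150, log(5), 1.1)),
                                       exp(rnorm(150, log(21), 1.1))))))
    os <- summarize_onset(coh)
    p <- os$pairwise["ketoconazole", "caspofungin"]
    hits[s] <- !is.na(p) && p < 0.05
  }
  expect_gte(mean(hits), 0.9)
})

test_that("null onset comparison does not over-reject", {
  ps <- numeric(20)
  for (s in 1:20) {
    set.seed(100 + s)
    coh <- data.table::data.table(
      primaryid = sprintf("P%04d", 1:1000),
      drug = rep(c("A", "B"), each = 500),
      onset_days_ = as.integer(round(exp(rnorm(1000, log(10), 1)))))
    ps[s] <- summarize_onset(coh)$overall_p
  }
  expect_lte(sum(ps < 0.05), 4)  # ~1 expected at the 5% level
  expect_gt(mean(ps), 0.2)       # roughly uniform, not degenerate
})

test_that("outcome summary counts multi-outcome reports once per category", {
  rs <- tiny_report_set()  # A1 carries DE + HO
  sel <- select_cohort(rs)
  coh <- cohort_table(rs, sel)
  os <- summarize_outcomes(coh, rs)
  x <- os$by_drug_category[drug == "voriconazole"]
  expect_equal(x[outc_cod == "DE"]$count, 1L)
  expect_equal(x[outc_cod == "HO"]$count, 1L)
  expect_equal(x[outc_cod == "DE"]$percent, 100)  # 1 of 1 with outcomes
  expect_equal(os$mortality[drug == "voriconazole"]$mortality_pct, 100)
})

test_that("mortality uses reports-with-any-outcome as denominator", {
  ## 4 case reports: outcomes {DE}, {DE}, {HO}, {OT}; a 5th with none
  demo <- data.frame(
    primaryid = paste0("M", 1:5, "1"), caseid = paste0("M", 1:5),
    caseversion = "1", fda_dt = as.Date("2020-06-01"), age_yrs = 50,
    sex = "F", reporter = "Physician", country = "US",
    event_dt = as.Date("2020-05-01"))
  drug <- data.frame(primaryid = demo$primaryid, drug_seq = 1L,
                     drugname = "anidulafungin", role_cod = "PS",
                     start_dt = as.Date("2020-04-01"))
  reac <- data.frame(primaryid = demo$primaryid, pt = "Hepatic failure")
  outc <- data.frame(primaryid = paste0("M", 1:4, "1"),
                     outc_cod = c("DE", "DE", "HO", "OT"))
  rs <- report_set(demo, drug, reac, outc)
  sel <- select_cohort(rs)
  os <- summarize_outcomes(cohort_table(rs, sel), rs)
  m <- os$mortality[drug == "anidulafungin"]
  expect_equal(m$n_outcome, 4L)   # the no-outcome report is excluded
  expect_equal(m$deaths, 2L)
  expect_equal(m$mortality_pct, 50)
})

test_that("generated mortality matches the configured death probability", {
  ## single-drug lexicon: every report is a primary-suspect micafungin
  ## report, so its configured death probability drives the whole cohort
  lex <- data.frame(drug = "micafungin", weight = 1)
  op <- list(micafungin = dilisignal:::default_outcome_probs(p_death = 0.475),
             ".default" = dilisignal:::default_outcome_probs(p_death = 0.1))
  g <- generate_reports(synthetic_config(
    n_reports = 20000, seed = 12, drug_lexicon = lex,
    true_rr = c(micafungin = 4.5), outcome_probs = op))
  rs <- deduplicate(g$reports)
  sel <- select_cohort(rs)
  os <- summarize_outcomes(cohort_table(rs, sel), rs)
  m <- os$mortality[drug == "micafungin"]
  se <- sqrt(0.475 * 0.525 / m$n_outcome)
  expect_lt(abs(m$mortality_pct / 100 - 0.475), 3 * se)
  expect_true(m$mortality_pct >= 0 && m$mortality_pct <= 100)
})
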