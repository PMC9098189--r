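AGE_BANDS <- c("<18", "18-44", "45-64", "65-74", "75-84", ">=85", "Unknown")
AREAS <- c("Africa", "Asia", "Europe", "North America", "Oceania",
           "South America", "Unknown")
OUTCOME_LABELS <- c(
  CA = "Congenital Anomaly", DE = "Death", DS = "Disability",
  HO = "Hospitalization - Initial or Prolonged", LT = "Life-Threatening",
  OT = "Other Serious",
  RI = "Required Intervention to Prevent Permanent Impairment/Damage")

#' Age band classification
#' @param age_yrs numeric age in years (`NA` = unknown).
#' @return factor over `<18, 18-44, 45-64, 65-74, 75-84, >=85, Unknown`.
#' @export
age_band <- function(age_yrs) {
  out <- cut(age_yrs, breaks = c(-Inf, 18, 45, 65, 75, 85, Inf),
             labels = AGE_BANDS[1:6], right = FALSE)
  out <- as.character(out)
  out[is.na(out)] <- "Unknown"
  factor(out, levels = AGE_BANDS)
}

## ISO-2 country code (or already-labelled continent) -> reporting area
COUNTRY_AREA <- c(
  US = "North America", CA = "North America", MX = "North America",
  PR = "North America", BR = "South America", AR = "South America",
  CO = "South America", CL = "South America", PE = "South America",
  VE = "South America", GB = "Europe", DE = "Europe", FR = "Europe",
  IT = "Europe", ES = "Europe", NL = "Europe", BE = "Europe",
  CH = "Europe", AT = "Europe", SE = "Europe", DK = "Europe",
  NO = "Europe", FI = "Europe", PL = "Europe", PT = "Europe",
  IE = "Europe", GR = "Europe", CZ = "Europe", HU = "Europe",
  RU = "Europe", TR = "Europe", UA = "Europe", JP = "Asia", CN = "Asia",
  KR = "Asia", IN = "Asia", TH = "Asia", TW = "Asia", SG = "Asia",
  MY = "Asia", PH = "Asia", ID = "Asia", VN = "Asia", IL = "Asia",
  SA = "Asia", AE = "Asia", HK = "Asia", AU = "Oceania", NZ = "Oceania",
  ZA = "Africa", NG = "Africa", EG = "Africa", KE = "Africa",
  MA = "Africa", TN = "Africa")

#' Reporting area from country
#' @param country ISO-2 country codes or continent labels.
#' @return factor over the six continents plus `Unknown`.
#' @export
reporting_area <- function(country) {
  x <- trimws(as.character(country))
  out <- unname(COUNTRY_AREA[toupper(x)])
  keep <- x %in% AREAS
  out[keep] <- x[keep]
  out[is.na(out) | out == ""] <- "Unknown"
  factor(out, levels = AREAS)
}

#' Per-case analysis table for a selected cohort
#'
#' Joins case demographics onto the per-drug case attribution from
#' [select_cohort()] — one row per (report, attributed study drug) — and
#' derives age band, reporting area, receipt year and time to onset
#' (event date minus that drug's earliest therapy start).
#'
#' @param rs the deduplicated `report_set`.
#' @param selection a [select_cohort()] result.
#' @return data.table with columns `primaryid`, `drug`, `age_yrs`,
#'   `age_band`, `sex`, `reporter`, `area`, `year`, `onset_days_`.
#' @export
cohort_table <- function(rs, selection) {
  cases <- selection$cases
  x <- rs$demo[cases, on = "primaryid"]
  x[, `:=`(
    age_band = age_band(age_yrs),
    area = reporting_area(country),
    year = fifelse(is.na(fda_dt), "Unknown", format(fda_dt, "%Y")),
    onset_days_ = onset_days(event_dt, start_dt)
  )]
  x[, .(primaryid, drug, age_yrs, age_band, sex, reporter, area, year,
        onset_days_)]
}

#' Time to onset in days
#'
#' Whole days from therapy start to the adverse-event date. Missing when
#' either date is absent or the difference is negative (events recorded
#' before therapy start are excluded from onset analyses).
#'
#' @param event_dt,start_dt Date vectors.
#' @return integer vector of non-negative day counts (`NA` when
#'   undefined).
#' @export
onset_days <- function(event_dt, start_dt) {
  d <- as.integer(as.Date(event_dt) - as.Date(start_dt))
  d[!is.na(d) & d < 0] <- NA_integer_
  d
}

#' Demographic summary of a cohort
#'
#' Category counts and percentages per dimension (age band, sex,
#' reporter, area, year, drug). Within each report-level dimension every
#' report is counted exactly once (unknowns are first-class categories);
#' percentages use the full cohort size as denominator and are rounded
#' half-up to two decimals. For the `drug` dimension a report naming two
#' study drugs counts under each, so drug percentages can sum above 100.
#'
#' @param cohort a [cohort_table()].
#' @return data.table `dimension` / `category` / `count` / `percent`.
#' @export
summarize_demographics <- function(cohort) {
  n_cohort <- uniqueN(cohort$primaryid)
  if (n_cohort == 0L)
    return(data.table(dimension = character(), category = character(),
                      count = integer(), percent = numeric()))
  per_report <- unique(cohort, by = "primaryid")
  one <- function(dim, values, levels = NULL) {
    v <- as.character(values)
    if (is.null(levels)) levels <- sort(unique(v))
    cnt <- table(factor(v, levels = levels))
    data.table(dimension = dim, category = names(cnt),
               count = as.integer(cnt))
  }
  out <- rbind(
    one("age_band", per_report$age_band, AGE_BANDS),
    one("sex", fifelse(per_report$sex %in% c("F", "M"),
                       per_report$sex, "Unknown"),
        c("F", "M", "Unknown")),
    one("reporter", per_report$reporter, REPORTER_LEVELS),
    one("year", per_report$year,
        c(sort(setdiff(unique(per_report$year), "Unknown")), "Unknown")),
    one("area", per_report$area, AREAS),
    one("drug", cohort$drug, unique(cohort$drug))
  )
  out[, percent := round_half_up(100 * count / n_cohort, 2)]
  out[]
}

## Type-7 (linear interpolation) quantiles; Table-5-style fractional IQR
## bounds such as 2.5-45.75 arise from this rule.
onset_quantiles <- function(x) {
  q <- unname(quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE))
  list(q1 = q[1], median = q[2], q3 = q[3])
}

#' Time-to-onset summary with nonparametric comparisons
#'
#' Median and IQR of onset days per drug (type-7 quantiles), a
#' Kruskal-Wallis test across drugs and unadjusted pairwise two-sided
#' Wilcoxon rank-sum (Mann-Whitney U) comparisons.
#'
#' @param cohort a [cohort_table()].
#' @return list: `by_drug` (drug, n_with_onset, median, q1, q3),
#'   `overall_p` (Kruskal-Wallis; `NA` if fewer than two drugs have onset
#'   data) and `pairwise` (lower-triangular p-value matrix or `NULL`).
#' @export
summarize_onset <- function(cohort) {
  x <- cohort[!is.na(onset_days_)]
  by_drug <- cohort[, {
    v <- onset_days_[!is.na(onset_days_)]
    if (length(v) == 0L) {
      list(n_with_onset = 0L, median = NA_real_, q1 = NA_real_,
           q3 = NA_real_)
    } else {
      q <- onset_quantiles(v)
      list(n_with_onset = length(v), median = q$median, q1 = q$q1,
           q3 = q$q3)
    }
  }, by = drug]
  overall_p <- NA_real_; pairwise <- NULL
  if (uniqueN(x$drug) >= 2L) {
    overall_p <- kruskal.test(onset_days_ ~ factor(drug), data = x)$p.value
    pw <- suppressWarnings(
      pairwise.wilcox.test(x$onset_days_, factor(x$drug),
                           p.adjust.method = "none", exact = FALSE))
    pairwise <- pw$p.value
  }
  list(by_drug = by_drug[], overall_p = overall_p, pairwise = pairwise)
}

#' Outcome and mortality summary
#'
#' Per drug and outcome category, the count and percentage of case
#' reports carrying that outcome. The denominator is the number of the
#' drug's case reports with at least one recorded outcome code; a report
#' with several codes counts once in each category, so column percentages
#' may exceed 100. Mortality is the Death percentage on that same
#' denominator; a chi-squared test compares death proportions across
#' drugs.
#'
#' @param cohort a [cohort_table()].
#' @param rs the `report_set` supplying outcome codes.
#' @return list: `by_drug_category` (drug, category, count, percent),
#'   `mortality` (drug, n_outcome, deaths, mortality_pct),
#'   `mortality_p` (chi-squared p across drugs, `NA` when degenerate).
#' @export
summarize_outcomes <- function(cohort, rs) {
  cases <- unique(cohort[, .(primaryid, drug)])
  oc <- unique(rs$outc[cases, on = "primaryid", allow.cartesian = TRUE,
                       nomatch = NULL])
  denom <- oc[, .(n_outcome = uniqueN(primaryid)), by = drug]
  drugs <- unique(cases$drug)
  grid <- CJ(drug = drugs, outc_cod = names(OUTCOME_LABELS))
  cnt <- oc[, .(count = uniqueN(primaryid)), by = .(drug, outc_cod)]
  cnt <- cnt[grid, on = c("drug", "outc_cod")]
  cnt[is.na(count), count := 0L]
  cnt <- denom[cnt, on = "drug"]
  cnt[is.na(n_outcome), n_outcome := 0L]
  cnt[, `:=`(category = unname(OUTCOME_LABELS[outc_cod]),
             percent = ifelse(n_outcome > 0,
                              round_half_up(100 * count / n_outcome, 2), NA))]
  mort <- cnt[outc_cod == "DE",
              .(drug, n_outcome, deaths = count, mortality_pct = percent)]
  mortality_p <- NA_real_
  ok <- mort[n_outcome > 0]
  if (nrow(ok) >= 2L && sum(ok$deaths) > 0L) {
    m <- rbind(ok$deaths, ok$n_outcome - ok$deaths)
    mortality_p <- suppressWarnings(chisq.test(m)$p.value)
  }
  list(by_drug_category = cnt[, .(drug, category, outc_cod, count,
                                  n_outcome, percent)],
       mortality = mort[], mortality_p = mortality_p)
}

#' Fixture cohort matching a published antifungal-DILI case series
#'
#' Builds a synthetic 2943-report cohort whose marginal counts per
#' dimension (age band, sex, reporter, year, area, attributed drug)
#' exactly equal those of the published FAERS antifungal-DILI cohort
#' shipped in `extdata/antifungal_dili_cohort_counts.tsv`. Dimensions are
#' assigned independently (the joint distribution is not reconstructable
#' from marginals); each report carries one primary-suspect study drug
#' and one liver-event PT, so the full selection pipeline can run on it.
#'
#' @return a deduplicated-ready `report_set` of 2943 reports.
#' @export
reference_cohort <- function() {
  cc <- reference_cohort_counts()
  n <- sum(cc[dimension == "drug"]$count)
  ## the published year column totals 2942, one short of the cohort size;
  ## the missing report is assigned to the Unknown year category
  pull <- function(dim) {
    x <- cc[dimension == dim]
    out <- rep(x$category, x$count)
    if (length(out) < n) out <- c(out, rep("Unknown", n - length(out)))
    out
  }
  band_age <- c("<18" = 10, "18-44" = 30, "45-64" = 50, "65-74" = 70,
                "75-84" = 80, ">=85" = 90, "Unknown" = NA)
  yr <- pull("year")
  fda <- as.Date(ifelse(yr == "Unknown", NA, paste0(yr, "-07-01")))
  demo <- data.table(
    primaryid = sprintf("R%05d1", seq_len(n)),
    caseid = sprintf("R%05d", seq_len(n)),
    caseversion = "1",
    fda_dt = fda,
    age_yrs = unname(band_age[pull("age_band")]),
    sex = pull("sex"),
    reporter = pull("reporter"),
    country = pull("area"),
    event_dt = fda
  )
  drug <- data.table(primaryid = demo$primaryid, drug_seq = 1L,
                     drugname = pull("drug"), role_cod = "PS",
                     start_dt = as.Date(NA))
  reac <- data.table(primaryid = demo$primaryid, pt = "Hepatotoxicity")
  report_set(demo, drug, reac,
             provenance = "synthetic fixture from published cohort marginals")
}

#' Marginal counts of the published antifungal-DILI cohort
#' @return data.table `dimension` / `category` / `count`.
#' @export
reference_cohort_counts <- function() {
  fread(pkg_extdata("antifungal_dili_cohort_counts.tsv"),
        sep = "\t", header = TRUE, quote = "", skip = 4)
}
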