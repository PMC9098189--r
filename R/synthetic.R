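## Background (decoy) drug names and non-liver decoy PTs used by the
## default generator lexicons. Chosen to be common, clearly non-study
## drugs / non-hepatic events.
BACKGROUND_DRUGS <- c(
  "ASPIRIN", "PARACETAMOL", "IBUPROFEN", "METFORMIN", "LISINOPRIL",
  "AMLODIPINE", "ATORVASTATIN", "SIMVASTATIN", "OMEPRAZOLE",
  "PANTOPRAZOLE", "LEVOTHYROXINE", "METOPROLOL", "LOSARTAN",
  "HYDROCHLOROTHIAZIDE", "FUROSEMIDE", "PREDNISONE", "WARFARIN",
  "CLOPIDOGREL", "APIXABAN", "RIVAROXABAN", "INSULIN GLARGINE",
  "GABAPENTIN", "PREGABALIN", "SERTRALINE", "FLUOXETINE", "ESCITALOPRAM",
  "DULOXETINE", "VENLAFAXINE", "QUETIAPINE", "RISPERIDONE",
  "OLANZAPINE", "ARIPIPRAZOLE", "LAMOTRIGINE", "LEVETIRACETAM",
  "CARBAMAZEPINE", "AMOXICILLIN", "AZITHROMYCIN", "CEFTRIAXONE",
  "CIPROFLOXACIN", "LEVOFLOXACIN", "VANCOMYCIN", "MEROPENEM",
  "PIPERACILLIN", "TRIMETHOPRIM", "DOXYCYCLINE", "METHOTREXATE",
  "ADALIMUMAB", "ETANERCEPT", "INFLIXIMAB", "RITUXIMAB", "TACROLIMUS",
  "CYCLOSPORINE", "MYCOPHENOLATE", "AZATHIOPRINE", "ALLOPURINOL",
  "COLCHICINE", "MORPHINE", "OXYCODONE", "TRAMADOL", "ONDANSETRON")

DECOY_PTS <- c(
  "Headache", "Nausea", "Vomiting", "Diarrhoea", "Constipation",
  "Dizziness", "Fatigue", "Pyrexia", "Rash", "Pruritus", "Urticaria",
  "Arthralgia", "Myalgia", "Back pain", "Abdominal pain", "Dyspnoea",
  "Cough", "Insomnia", "Somnolence", "Anxiety", "Depression", "Tremor",
  "Paraesthesia", "Hypotension", "Hypertension", "Tachycardia",
  "Bradycardia", "Palpitations", "Syncope", "Oedema peripheral",
  "Weight decreased", "Weight increased", "Decreased appetite",
  "Dysgeusia", "Dry mouth", "Alopecia", "Hyperhidrosis", "Night sweats",
  "Chills", "Asthenia", "Malaise", "Chest pain", "Anaemia",
  "Thrombocytopenia", "Neutropenia", "Leukopenia", "Renal impairment",
  "Acute kidney injury", "Blood creatinine increased", "Hypokalaemia",
  "Hyponatraemia", "Hyperkalaemia", "Hyperglycaemia", "Hypoglycaemia",
  "Visual impairment", "Tinnitus", "Vertigo", "Epistaxis", "Dyspepsia",
  "Gastrooesophageal reflux disease")

ANTIFUNGALS <- c("ketoconazole", "miconazole", "clotrimazole",
                 "fluconazole", "voriconazole", "itraconazole",
                 "isavuconazole", "posaconazole", "caspofungin",
                 "micafungin", "anidulafungin")

default_demographics <- function() {
  list(
    age_band = c("<18" = 0.08, "18-44" = 0.22, "45-64" = 0.28,
                 "65-74" = 0.14, "75-84" = 0.08, ">=85" = 0.02,
                 "Unknown" = 0.18),
    sex = c(F = 0.45, M = 0.42, Unknown = 0.13),
    reporter = c("Consumer" = 0.25, "Lawyer" = 0.01,
                 "Other health-professional" = 0.22, "Pharmacist" = 0.10,
                 "Physician" = 0.32, "Unknown" = 0.10),
    area = c("Africa" = 0.01, "Asia" = 0.20, "Europe" = 0.35,
             "North America" = 0.35, "Oceania" = 0.02,
             "South America" = 0.02, "Unknown" = 0.05),
    year = c(setNames(rep(1 / 18.2, 18), as.character(2004:2021)),
             "Unknown" = 0.2 / 18.2)
  )
}

default_outcome_probs <- function(p_any = 0.6, p_death = 0.15) {
  list(p_any = p_any, p_death = p_death, p_second = 0.4,
       other = c(LT = 0.10, HO = 0.45, DS = 0.03, CA = 0.005, RI = 0.015,
                 OT = 0.40))
}

#' Synthetic spontaneous-report generator configuration
#'
#' Defines a FAERS-like population with known ground truth. Each report
#' draws `1 + Poisson(1.5)` distinct drugs from the lexicon
#' (first = primary suspect, the rest secondary suspect or concomitant);
#' the probability that a report is a liver-event report is
#' `min(1, baseline_event_prob * max(true_rr over its suspect drugs))`,
#' so `true_rr` is a per-drug reporting-rate ratio and 1 means no
#' signal. Liver-event reports carry 1-3 PTs from the liver dictionary,
#' others 1-3 decoy PTs. Onset days are `round(exp(N(mu, sigma)))` per
#' the primary-suspect drug; the event date is therapy start plus onset
#' and the receipt date follows within 60 days inside the sampled
#' reporting year. A `duplicate_rate` fraction of cases is emitted twice
#' with a bumped case version and later receipt date.
#'
#' @param n_reports number of distinct cases (>= 1).
#' @param drug_lexicon data.frame `drug`/`weight`: relative sampling
#'   weights. Default: the 11 study antifungals at weight 0.03 each plus
#'   60 background drugs at weight 1 — study-drug exposure around 0.1%
#'   of reports, a realistic prevalence for a niche systemic antifungal.
#' @param event_lexicon list with `liver` and `decoy` PT character
#'   vectors; defaults to the packaged liver dictionary plus 60 decoys.
#' @param true_rr named numeric, reporting-rate ratio per drug (drugs
#'   not named have ratio 1).
#' @param baseline_event_prob liver-event probability absent any signal
#'   drug.
#' @param demographics named list of categorical distributions
#'   (`age_band`, `sex`, `reporter`, `area`, `year`), each a named
#'   probability vector summing to 1.
#' @param onset_lognormal named list drug -> `c(mu, sigma)` of log-days;
#'   entry `".default"` applies to unnamed drugs.
#' @param outcome_probs named list drug -> list(`p_any`, `p_death`,
#'   `p_second`, `other`); `p_death` is the death probability among
#'   reports with any recorded outcome (i.e. the mortality rate), entry
#'   `".default"` applies to unnamed drugs.
#' @param duplicate_rate fraction of cases duplicated as a second
#'   version.
#' @param seed integer RNG seed.
#' @return validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_reports = 50000,
                             drug_lexicon = NULL,
                             event_lexicon = NULL,
                             true_rr = numeric(),
                             baseline_event_prob = 0.02,
                             demographics = default_demographics(),
                             onset_lognormal = list(".default" = c(mu = log(10), sigma = 1)),
                             outcome_probs = list(".default" = default_outcome_probs()),
                             duplicate_rate = 0.07,
                             seed = 1L) {
  if (is.null(drug_lexicon)) {
    drug_lexicon <- data.table(
      drug = c(ANTIFUNGALS, BACKGROUND_DRUGS),
      weight = c(rep(0.03, length(ANTIFUNGALS)),
                 rep(1, length(BACKGROUND_DRUGS))))
  }
  drug_lexicon <- as.data.table(drug_lexicon)
  if (is.null(event_lexicon)) {
    event_lexicon <- list(
      liver = readLines(pkg_extdata("liver_event_pts.txt"), warn = FALSE),
      decoy = DECOY_PTS)
    event_lexicon$liver <- trimws(event_lexicon$liver)
    event_lexicon$liver <- event_lexicon$liver[
      event_lexicon$liver != "" & !startsWith(event_lexicon$liver, "#")]
  }
  cfg <- structure(list(
    n_reports = n_reports, drug_lexicon = drug_lexicon,
    event_lexicon = event_lexicon, true_rr = true_rr,
    baseline_event_prob = baseline_event_prob,
    demographics = demographics, onset_lognormal = onset_lognormal,
    outcome_probs = outcome_probs, duplicate_rate = duplicate_rate,
    seed = as.integer(seed)), class = "synthetic_config")
  validate_synthetic_config(cfg)
}

validate_synthetic_config <- function(cfg) {
  fail <- function(field, why) stop("synthetic_config$", field, ": ", why,
                                    call. = FALSE)
  if (!is.numeric(cfg$n_reports) || cfg$n_reports < 1)
    fail("n_reports", "must be >= 1")
  lx <- cfg$drug_lexicon
  if (!all(c("drug", "weight") %in% names(lx)) || nrow(lx) < 1)
    fail("drug_lexicon", "needs columns drug, weight")
  if (any(lx$weight < 0) || sum(lx$weight) <= 0)
    fail("drug_lexicon", "weights must be non-negative, not all zero")
  if (anyDuplicated(lx$drug)) fail("drug_lexicon", "duplicated drug names")
  if (length(cfg$true_rr) && (is.null(names(cfg$true_rr)) ||
                              any(cfg$true_rr <= 0)))
    fail("true_rr", "must be a named vector of ratios > 0")
  p <- cfg$baseline_event_prob
  if (!is.numeric(p) || p < 0 || p > 1)
    fail("baseline_event_prob", "must be in [0, 1]")
  for (dim in c("age_band", "sex", "reporter", "area", "year")) {
    pr <- cfg$demographics[[dim]]
    if (is.null(pr)) fail(paste0("demographics$", dim), "missing")
    if (any(pr < 0) || abs(sum(pr) - 1) > 1e-6)
      fail(paste0("demographics$", dim),
           "probabilities must be >= 0 and sum to 1")
  }
  if (cfg$duplicate_rate < 0 || cfg$duplicate_rate > 1)
    fail("duplicate_rate", "must be in [0, 1]")
  if (length(cfg$event_lexicon$liver) < 1 ||
      length(cfg$event_lexicon$decoy) < 1)
    fail("event_lexicon", "needs non-empty liver and decoy term sets")
  cfg
}

#' Read a generator configuration from YAML or JSON
#'
#' Scalar fields and the demographic distributions map directly onto
#' [synthetic_config()] arguments; omitted fields keep their defaults.
#'
#' @param path YAML (or JSON; YAML is a superset) config file.
#' @return a `synthetic_config`.
#' @export
read_synthetic_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- list()
  for (f in c("n_reports", "baseline_event_prob", "duplicate_rate", "seed"))
    if (!is.null(raw[[f]])) args[[f]] <- raw[[f]]
  if (!is.null(raw$true_rr)) args$true_rr <- unlist(raw$true_rr)
  if (!is.null(raw$demographics))
    args$demographics <- lapply(raw$demographics, unlist)
  if (!is.null(raw$drug_lexicon))
    args$drug_lexicon <- rbindlist(lapply(raw$drug_lexicon, as.data.table))
  do.call(synthetic_config, args)
}

lookup_onset <- function(cfg, drugs) {
  def <- cfg$onset_lognormal[[".default"]] %||% c(mu = log(10), sigma = 1)
  mu <- rep(def[["mu"]], length(drugs))
  sg <- rep(def[["sigma"]], length(drugs))
  named <- setdiff(names(cfg$onset_lognormal), ".default")
  for (dg in named) {
    i <- drugs == dg
    mu[i] <- cfg$onset_lognormal[[dg]][["mu"]]
    sg[i] <- cfg$onset_lognormal[[dg]][["sigma"]]
  }
  list(mu = mu, sigma = sg)
}

#' Generate a synthetic report set with ground truth
#'
#' Deterministic given `cfg$seed`. The returned ground truth records,
#' per lexicon drug, the suspect-exposed report count and liver-event
#' count among them (computed by direct tabulation of the generated
#' records, independent of the case-selection code path), the injected
#' duplicate count and each report's true onset days.
#'
#' @param cfg a [synthetic_config()].
#' @return list with elements `reports` (a `report_set`, duplicates
#'   included) and `truth` (list: `per_drug` data.table of
#'   drug/n_exposed/n_event/true_rr, `n_duplicates`, `onsets`
#'   data.table of primaryid/drug/onset, `event_ids`).
#' @export
generate_reports <- function(cfg) {
  validate_synthetic_config(cfg)
  set.seed(cfg$seed)
  n <- as.integer(cfg$n_reports)
  lex <- cfg$drug_lexicon

  ## ---- drugs: 1 + Poisson(1.5) draws, distinct within report ----
  k <- pmin(1L + rpois(n, 1.5), nrow(lex))
  rid <- rep.int(seq_len(n), k)
  dn <- sample(lex$drug, length(rid), replace = TRUE,
               prob = lex$weight / sum(lex$weight))
  dd <- unique(data.table(rid = rid, drugname = dn))
  role <- sample(c("SS", "C"), nrow(dd), replace = TRUE, prob = c(0.6, 0.4))
  dd[, seq_ := seq_len(.N), by = rid]
  role[dd$seq_ == 1L] <- "PS"
  dd[, role_cod := role]

  ## ---- liver event indicator from suspect drugs' rate ratios ----
  rrmap <- setNames(rep(1, nrow(lex)), lex$drug)
  if (length(cfg$true_rr)) rrmap[names(cfg$true_rr)] <- cfg$true_rr
  dd[, rr := rrmap[drugname]]
  sus <- dd[role_cod %chin% c("PS", "SS"), .(rrmax = max(rr)), by = rid]
  p_event <- rep(cfg$baseline_event_prob, n)
  p_event[sus$rid] <- pmin(1, cfg$baseline_event_prob * sus$rrmax)
  is_event <- runif(n) < p_event

  ## ---- demographics ----
  dg <- cfg$demographics
  draw <- function(pr) sample(names(pr), n, replace = TRUE, prob = pr)
  band <- draw(dg$age_band)
  band_lo <- c("<18" = 0, "18-44" = 18, "45-64" = 45, "65-74" = 65,
               "75-84" = 75, ">=85" = 85, "Unknown" = 0)
  band_hi <- c("<18" = 18, "18-44" = 45, "45-64" = 65, "65-74" = 75,
               "75-84" = 85, ">=85" = 101, "Unknown" = 1)
  age <- floor(runif(n, band_lo[band], band_hi[band]))
  age[band == "Unknown"] <- NA_real_
  yr <- draw(dg$year)

  ## ---- onset & dates (receipt year anchors the calendar) ----
  ps_drug <- dd[role_cod == "PS"][order(rid)]$drugname
  on_par <- lookup_onset(cfg, ps_drug)
  onset <- as.integer(round(exp(rnorm(n, on_par$mu, on_par$sigma))))
  yr_num <- suppressWarnings(as.integer(yr))
  ## year -> Jan 1 lookup avoids per-report date-string parsing
  yr_all <- sort(unique(yr_num[!is.na(yr_num)]))
  jan1 <- setNames(as.Date(paste0(c(yr_all, 2015L), "-01-01")),
                   c(yr_all, "U"))
  fda <- jan1[fifelse(is.na(yr_num), "U", as.character(yr_num))] +
    sample(0:364, n, replace = TRUE)
  delay <- sample(0:60, n, replace = TRUE)
  event_dt <- fda - delay
  start_dt <- event_dt - onset
  fda[is.na(yr_num)] <- NA

  caseid <- sprintf("C%08d", seq_len(n))
  pid <- paste0(caseid, "1")
  demo <- data.table(
    primaryid = pid, caseid = caseid, caseversion = "1",
    fda_dt = fda, age_yrs = age, sex = draw(dg$sex),
    reporter = draw(dg$reporter), country = draw(dg$area),
    event_dt = event_dt)

  drug <- dd[, .(primaryid = pid[rid], drug_seq = seq_,
                 drugname, role_cod)]
  drug[, start_dt := start_dt[dd$rid]]

  ## ---- reactions: 1-3 PTs, liver terms iff event report ----
  kpt <- sample(1:3, n, replace = TRUE)
  rid2 <- rep.int(seq_len(n), kpt)
  ev2 <- is_event[rid2]
  pts <- character(length(rid2))
  pts[ev2] <- sample(cfg$event_lexicon$liver, sum(ev2), replace = TRUE)
  pts[!ev2] <- sample(cfg$event_lexicon$decoy, sum(!ev2), replace = TRUE)
  reac <- unique(data.table(primaryid = pid[rid2], pt = pts))

  ## ---- outcomes ----
  getp <- function(field) {
    def <- (cfg$outcome_probs[[".default"]] %||% default_outcome_probs())[[field]]
    out <- rep(def, n)
    for (dg_ in setdiff(names(cfg$outcome_probs), ".default"))
      out[ps_drug == dg_] <- cfg$outcome_probs[[dg_]][[field]]
    out
  }
  p_any <- getp("p_any"); p_death <- getp("p_death")
  p_second <- getp("p_second")
  has_out <- runif(n) < p_any
  dies <- has_out & (runif(n) < p_death)
  other_codes <- function(idx) {
    ## sample one non-death code per selected report, honouring per-drug dists
    out <- character(length(idx))
    def <- (cfg$outcome_probs[[".default"]] %||% default_outcome_probs())$other
    grp <- rep("__default__", length(idx))
    named <- setdiff(names(cfg$outcome_probs), ".default")
    grp[ps_drug[idx] %in% named] <- ps_drug[idx][ps_drug[idx] %in% named]
    for (g in unique(grp)) {
      pr <- if (g == "__default__") def else cfg$outcome_probs[[g]]$other
      sel <- grp == g
      out[sel] <- sample(names(pr), sum(sel), replace = TRUE, prob = pr)
    }
    out
  }
  ## non-death code: always for surviving outcome reports (so every
  ## outcome report has >= 1 code); with prob p_second also for deaths
  need_other <- which(has_out & (!dies | runif(n) < p_second))
  oc1 <- data.table(primaryid = pid[need_other],
                    outc_cod = other_codes(need_other))
  ocd <- data.table(primaryid = pid[which(dies)],
                    outc_cod = "DE")
  outc <- unique(rbind(ocd, oc1))

  ## ---- ground truth (direct tabulation, pre-duplication) ----
  sus_dd <- dd[role_cod %chin% c("PS", "SS")]
  gt <- sus_dd[, .(n_exposed = uniqueN(rid),
                   n_event = uniqueN(rid[is_event[rid]])), by = .(drug = drugname)]
  gt <- gt[data.table(drug = lex$drug), on = "drug"]
  gt[is.na(n_exposed), `:=`(n_exposed = 0L, n_event = 0L)]
  gt[, rr := rrmap[drug]]
  setnames(gt, "rr", "true_rr")
  truth <- list(
    per_drug = gt[],
    n_events_total = sum(is_event),
    onsets = data.table(primaryid = pid, drug = ps_drug,
                        onset = onset),
    event_ids = pid[is_event],
    n_duplicates = 0L)

  ## ---- case-version duplicates ----
  ndup <- as.integer(round(cfg$duplicate_rate * n))
  if (ndup > 0L) {
    pick <- sort(sample.int(n, ndup))
    old_id <- pid[pick]
    new_id <- paste0(caseid[pick], "2")
    remap <- function(x) {
      y <- x[primaryid %chin% old_id]
      y[, primaryid := paste0(substr(primaryid, 1, nchar(primaryid) - 1), "2")]
      y
    }
    demo2 <- demo[primaryid %chin% old_id]
    demo2[, `:=`(primaryid = new_id, caseversion = "2",
                 fda_dt = fda_dt + 30)]
    demo <- rbind(demo, demo2)
    drug <- rbind(drug, remap(drug))
    reac <- rbind(reac, remap(reac))
    outc <- rbind(outc, remap(outc))
    truth$n_duplicates <- ndup
  }

  rs <- report_set(demo, drug, reac, outc,
                   provenance = sprintf("synthetic(seed=%d)", cfg$seed))
  list(reports = rs, truth = truth)
}

#' Cohort-like generator configuration
#'
#' A [synthetic_config()] whose demographic marginals equal the
#' published antifungal-DILI cohort proportions (so generated cohorts
#' reproduce them within binomial error), whose per-antifungal
#' reporting-rate ratios sit at the published ROR point estimates, and
#' whose onset log-normals and mortality probabilities are centred near
#' the published per-drug onset medians and mortality rates. These
#' defaults emulate the published study conditions; they are an
#' emulation, not a reconstruction of the real FAERS joint distribution.
#'
#' @param n_reports cohort size.
#' @param seed RNG seed.
#' @return a `synthetic_config`.
#' @export
make_paper_like_config <- function(n_reports = 100000, seed = 1L) {
  cc <- reference_cohort_counts()
  marg <- function(dim) {
    x <- cc[dimension == dim]
    setNames(x$count / sum(x$count), x$category)
  }
  true_rr <- c(ketoconazole = 2.28, miconazole = 0.30, clotrimazole = 0.16,
               fluconazole = 3.19, voriconazole = 4.58, itraconazole = 5.06,
               isavuconazole = 1.22, posaconazole = 3.99, caspofungin = 6.12,
               micafungin = 4.53, anidulafungin = 5.15)
  onset_med <- c(ketoconazole = 21, miconazole = 22, clotrimazole = 10,
                 fluconazole = 8, voriconazole = 8, itraconazole = 11,
                 isavuconazole = 7, posaconazole = 6, caspofungin = 5,
                 micafungin = 5, anidulafungin = 4)
  onset <- c(lapply(onset_med, function(m) c(mu = log(m), sigma = 1.1)),
             list(".default" = c(mu = log(10), sigma = 1)))
  mortality <- c(ketoconazole = 0.096, miconazole = 0.133,
                 clotrimazole = 0.05, fluconazole = 0.183,
                 voriconazole = 0.222, itraconazole = 0.180,
                 isavuconazole = 0.209, posaconazole = 0.203,
                 caspofungin = 0.364, micafungin = 0.475,
                 anidulafungin = 0.500)
  outc <- c(lapply(mortality, function(p) default_outcome_probs(p_death = p)),
            list(".default" = default_outcome_probs()))
  synthetic_config(
    n_reports = n_reports,
    true_rr = true_rr,
    demographics = list(age_band = marg("age_band"), sex = marg("sex"),
                        reporter = marg("reporter"), area = marg("area"),
                        year = marg("year")),
    onset_lognormal = onset,
    outcome_probs = outc,
    seed = seed)
}
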