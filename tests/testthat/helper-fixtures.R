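## Hand-built four-report set: one report per 2x2 cell for
## voriconazole x liver event.
tiny_report_set <- function() {
  d <- function(i) as.Date("2020-01-01") + i
  demo <- data.frame(
    primaryid = c("A1", "B1", "C1", "D1"),
    caseid = c("A", "B", "C", "D"),
    caseversion = "1",
    fda_dt = d(1:4),
    age_yrs = c(50, 30, NA, 70),
    sex = c("F", "M", "Unknown", "M"),
    reporter = c("Physician", "Consumer", "Unknown", "Pharmacist"),
    country = c("US", "JP", "DE", "Unknown"),
    event_dt = d(1:4)
  )
  drug <- data.frame(
    primaryid = c("A1", "B1", "C1", "D1"),
    drug_seq = 1L,
    drugname = c("VFEND", "ASPIRIN", "voriconazole 200mg", "IBUPROFEN"),
    role_cod = "PS",
    start_dt = d(0)
  )
  reac <- data.frame(
    primaryid = c("A1", "B1", "C1", "D1"),
    pt = c("Hepatotoxicity", "Liver injury", "Headache", "Nausea")
  )
  outc <- data.frame(primaryid = c("A1", "A1", "B1"),
                     outc_cod = c("DE", "HO", "OT"))
  report_set(demo, drug, reac, outc, provenance = "tiny fixture")
}

## Canonical worked 2x2 table used across the metric tests.
worked_table <- function() contingency_table(a = 20, b = 180, c = 80, d = 9720)

## Random strictly-positive 2x2 tables for property tests.
random_tables <- function(n, seed = 42) {
  set.seed(seed)
  contingency_table(a = sample(1:200, n, TRUE), b = sample(1:2000, n, TRUE),
                    c = sample(1:2000, n, TRUE), d = sample(100:50000, n, TRUE))
}

## Exact-independence tables: a = x*y, b = x*(M-y), c = (K-x)*y,
## d = (K-x)*(M-y) gives a*N = (a+b)(a+c) ... with margins (xK rows).
independence_tables <- function(n, seed = 7) {
  set.seed(seed)
  x <- sample(2:50, n, TRUE); K <- x + sample(2:50, n, TRUE)
  y <- sample(2:50, n, TRUE); M <- y + sample(2:50, n, TRUE)
  contingency_table(a = x * y, b = (K - x) * y, c = x * (M - y),
                    d = (K - x) * (M - y))
}
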