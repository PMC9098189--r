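#' FAERS file dialect descriptor
#'
#' Describes the on-disk layout of a quarterly-extract style report set:
#' five delimited ASCII tables (demographics, drugs, reactions, outcomes,
#' therapy dates) joined on `primaryid` (= case id + case version).
#'
#' @param delim single-character field delimiter; FAERS quarterly files
#'   use `"$"`.
#' @param ext file extension including the dot.
#' @return a list of class `faers_dialect` with the per-table file names
#'   and column layouts.
#' @export
faers_dialect <- function(delim = "$", ext = ".txt") {
  stopifnot(is.character(delim), nchar(delim) == 1L)
  structure(list(
    delim = delim,
    files = c(demo = paste0("DEMO", ext), drug = paste0("DRUG", ext),
              reac = paste0("REAC", ext), outc = paste0("OUTC", ext),
              ther = paste0("THER", ext)),
    columns = list(
      demo = c("primaryid", "caseid", "caseversion", "fda_dt", "age",
               "age_cod", "sex", "occp_cod", "occr_country", "event_dt"),
      drug = c("primaryid", "drug_seq", "drugname", "role_cod"),
      reac = c("primaryid", "pt"),
      outc = c("primaryid", "outc_cod"),
      ther = c("primaryid", "dsg_drug_seq", "start_dt")
    )
  ), class = "faers_dialect")
}

ROLE_CODES <- c("PS", "SS", "C", "I")
OUTCOME_CODES <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")
REPORTER_LEVELS <- c("Consumer", "Lawyer", "Other health-professional",
                     "Pharmacist", "Physician", "Unknown")

#' Construct a spontaneous-report set
#'
#' The in-memory data model is relational, mirroring the source tables:
#' one demographics row per report plus drug, reaction and outcome child
#' tables keyed by `primaryid`. Every report must carry at least one drug
#' record and one reaction preferred term.
#'
#' @param demo data.frame with columns `primaryid`, `caseid`,
#'   `caseversion`, `fda_dt` (Date), `age_yrs`, `sex` (`F`/`M`/`Unknown`),
#'   `reporter`, `country`, `event_dt` (Date).
#' @param drug data.frame with `primaryid`, `drug_seq`, `drugname`,
#'   `role_cod` (`PS`/`SS`/`C`/`I`), `start_dt` (Date).
#' @param reac data.frame with `primaryid`, `pt`.
#' @param outc data.frame with `primaryid`, `outc_cod` (subset of
#'   `DE,LT,HO,DS,CA,RI,OT`).
#' @param provenance character vector of source labels.
#' @return an object of class `report_set`.
#' @export
report_set <- function(demo, drug, reac,
                       outc = data.frame(primaryid = character(),
                                         outc_cod = character()),
                       provenance = character()) {
  demo <- as.data.table(demo); drug <- as.data.table(drug)
  reac <- as.data.table(reac); outc <- as.data.table(outc)
  rs <- structure(list(demo = demo, drug = drug, reac = reac, outc = outc,
                       provenance = provenance),
                  class = "report_set")
  validate_report_set(rs)
}

validate_report_set <- function(rs) {
  demo <- rs$demo
  if (anyDuplicated(demo$primaryid))
    stop("report_set: duplicated primaryid in demographics table")
  bad_role <- setdiff(unique(rs$drug$role_cod), ROLE_CODES)
  if (length(bad_role))
    stop("report_set: invalid role code(s): ", paste(bad_role, collapse = ", "))
  bad_outc <- setdiff(unique(rs$outc$outc_cod), OUTCOME_CODES)
  if (length(bad_outc))
    stop("report_set: invalid outcome code(s): ", paste(bad_outc, collapse = ", "))
  no_drug <- setdiff(demo$primaryid, rs$drug$primaryid)
  if (length(no_drug))
    stop("report_set: ", length(no_drug),
         " report(s) without any drug record (first: ", no_drug[1], ")")
  no_reac <- setdiff(demo$primaryid, rs$reac$primaryid)
  if (length(no_reac))
    stop("report_set: ", length(no_reac),
         " report(s) without any reaction PT (first: ", no_reac[1], ")")
  rs
}

#' @export
print.report_set <- function(x, ...) {
  cat("<report_set> ", nrow(x$demo), " reports, ",
      nrow(x$drug), " drug records, ", nrow(x$reac), " reaction records, ",
      nrow(x$outc), " outcome records\n", sep = "")
  if (length(x$provenance))
    cat("  provenance: ", paste(x$provenance, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Number of reports in a report set
#' @param rs a `report_set`.
#' @return integer count of reports.
#' @export
n_reports <- function(rs) nrow(rs$demo)

#' Subset a report set by report identifier
#' @param rs a `report_set`.
#' @param primaryids character vector of report identifiers to keep.
#' @return a `report_set` restricted to those reports.
#' @export
subset_reports <- function(rs, primaryids) {
  keep <- unique(primaryids)
  report_set(rs$demo[primaryid %in% keep],
             rs$drug[primaryid %in% keep],
             rs$reac[primaryid %in% keep],
             rs$outc[primaryid %in% keep],
             provenance = rs$provenance)
}

## Age normalisation: value + unit code -> years. Implausible ages (>120)
## are set to missing rather than propagated into age-band summaries.
normalize_age <- function(age, age_cod) {
  age <- suppressWarnings(as.numeric(age))
  cod <- toupper(trimws(as.character(age_cod)))
  fac <- rep(1, length(age))
  fac[cod == "DEC"] <- 10
  fac[cod == "MON"] <- 1 / 12
  fac[cod == "WK"]  <- 1 / 52.1775
  fac[cod == "DY"]  <- 1 / 365.25
  fac[cod == "HR"]  <- 1 / 8766
  yrs <- age * fac
  yrs[!is.na(yrs) & (yrs < 0 | yrs > 120)] <- NA_real_
  yrs
}

#' Read a FAERS-dialect report set
#'
#' Reads the five delimited tables, joins the children onto the
#' demographics table by `primaryid`, normalises ages to years
#' (MON/12, DY/365.25, ...; >120 set missing), parses `yyyymmdd` dates
#' (partial dates resolve to mid-period) and attaches therapy start dates
#' to drug records via the drug sequence number. Reports violating the
#' data model (no drug or no reaction record) and orphan child rows are
#' counted, reported via a warning, and skipped — never silently dropped.
#'
#' @param dir directory containing the dialect's five files, or a named
#'   character vector of paths with names `demo`, `drug`, `reac`, `outc`,
#'   `ther`.
#' @param dialect a [faers_dialect()].
#' @return a `report_set` with attribute `skipped`, a named integer
#'   vector of skipped-record counts.
#' @export
read_reports <- function(dir, dialect = faers_dialect()) {
  if (is.null(names(dir))) {
    paths <- file.path(dir, dialect$files)
    names(paths) <- names(dialect$files)
  } else paths <- dir[names(dialect$files)]
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("input file(s) not found: ", paste(missing, collapse = ", "))

  rd <- function(key) {
    out <- fread(paths[[key]], sep = dialect$delim, header = TRUE,
                 colClasses = "character", quote = "", fill = TRUE,
                 na.strings = NULL, showProgress = FALSE)
    need <- dialect$columns[[key]]
    miss <- setdiff(need, names(out))
    if (length(miss))
      stop(basename(paths[[key]]), ": missing column(s) ",
           paste(miss, collapse = ", "))
    out[, need, with = FALSE]
  }
  demo_raw <- rd("demo"); drug_raw <- rd("drug"); reac_raw <- rd("reac")
  outc_raw <- rd("outc"); ther_raw <- rd("ther")

  skipped <- c(malformed = 0L, orphan = 0L, no_drug = 0L, no_reaction = 0L)

  bad <- demo_raw$primaryid == "" | is.na(demo_raw$primaryid)
  skipped["malformed"] <- skipped["malformed"] + sum(bad)
  demo_raw <- demo_raw[!bad]

  demo <- data.table(
    primaryid = demo_raw$primaryid,
    caseid = demo_raw$caseid,
    caseversion = demo_raw$caseversion,
    fda_dt = parse_faers_date(demo_raw$fda_dt),
    age_yrs = normalize_age(demo_raw$age, demo_raw$age_cod),
    sex = fifelse(demo_raw$sex %in% c("F", "M"), demo_raw$sex, "Unknown"),
    reporter = decode_reporter(demo_raw$occp_cod),
    country = fifelse(trimws(demo_raw$occr_country) == "", "Unknown",
                      trimws(demo_raw$occr_country)),
    event_dt = parse_faers_date(demo_raw$event_dt)
  )

  ids <- demo$primaryid
  orphan <- function(x) {
    n <- sum(!(x$primaryid %in% ids))
    if (n > 0L) skipped["orphan"] <<- skipped["orphan"] + n
    x[primaryid %in% ids]
  }
  drug_raw <- orphan(drug_raw); reac_raw <- orphan(reac_raw)
  outc_raw <- orphan(outc_raw); ther_raw <- orphan(ther_raw)

  drug <- data.table(
    primaryid = drug_raw$primaryid,
    drug_seq = suppressWarnings(as.integer(drug_raw$drug_seq)),
    drugname = drug_raw$drugname,
    role_cod = drug_raw$role_cod
  )
  drug <- drug[drugname != "" & role_cod %in% ROLE_CODES]
  ther <- data.table(primaryid = ther_raw$primaryid,
                     drug_seq = suppressWarnings(as.integer(ther_raw$dsg_drug_seq)),
                     start_dt = parse_faers_date(ther_raw$start_dt))
  drug <- ther[drug, on = c("primaryid", "drug_seq")]
  setcolorder(drug, c("primaryid", "drug_seq", "drugname", "role_cod", "start_dt"))

  reac <- data.table(primaryid = reac_raw$primaryid, pt = reac_raw$pt)[pt != ""]
  outc <- data.table(primaryid = outc_raw$primaryid,
                     outc_cod = outc_raw$outc_cod)[outc_cod %in% OUTCOME_CODES]

  keep <- ids
  no_drug <- setdiff(keep, drug$primaryid)
  skipped["no_drug"] <- length(no_drug)
  keep <- setdiff(keep, no_drug)
  no_reac <- setdiff(keep, reac$primaryid)
  skipped["no_reaction"] <- length(no_reac)
  keep <- setdiff(keep, no_reac)

  if (sum(skipped) > 0L)
    warning("read_reports: skipped records — ",
            paste(names(skipped), skipped, sep = "=", collapse = ", "),
            call. = FALSE)

  rs <- report_set(demo[primaryid %in% keep], drug[primaryid %in% keep],
                   reac[primaryid %in% keep], outc[primaryid %in% keep],
                   provenance = basename(unname(paths)))
  attr(rs, "skipped") <- skipped
  rs
}

decode_reporter <- function(x) {
  x <- trimws(as.character(x))
  map <- c(CN = "Consumer", LW = "Lawyer", HP = "Other health-professional",
           OT = "Other health-professional", PH = "Pharmacist",
           MD = "Physician")
  out <- unname(map[x])
  out[x %in% REPORTER_LEVELS] <- x[x %in% REPORTER_LEVELS]
  out[is.na(out) | out == ""] <- "Unknown"
  out
}

encode_reporter <- function(x) {
  map <- c("Consumer" = "CN", "Lawyer" = "LW",
           "Other health-professional" = "HP", "Pharmacist" = "PH",
           "Physician" = "MD", "Unknown" = "")
  out <- unname(map[x])
  out[is.na(out)] <- ""
  out
}

#' Write a report set as FAERS-dialect files
#'
#' Inverse of [read_reports()]: the round trip is lossless for every
#' modeled field (ages are written in years with unit code `YR`).
#'
#' @param rs a `report_set`.
#' @param dir output directory, created if needed.
#' @param dialect a [faers_dialect()].
#' @return invisibly, the named vector of written file paths.
#' @export
write_reports <- function(rs, dir, dialect = faers_dialect()) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir)
  paths <- file.path(dir, dialect$files)
  names(paths) <- names(dialect$files)

  demo_out <- data.table(
    primaryid = rs$demo$primaryid, caseid = rs$demo$caseid,
    caseversion = rs$demo$caseversion,
    fda_dt = format_faers_date(rs$demo$fda_dt),
    age = fifelse(is.na(rs$demo$age_yrs), "",
                  format(rs$demo$age_yrs, trim = TRUE, scientific = FALSE)),
    age_cod = fifelse(is.na(rs$demo$age_yrs), "", "YR"),
    sex = fifelse(rs$demo$sex %in% c("F", "M"), rs$demo$sex, ""),
    occp_cod = encode_reporter(rs$demo$reporter),
    occr_country = fifelse(rs$demo$country == "Unknown", "", rs$demo$country),
    event_dt = format_faers_date(rs$demo$event_dt)
  )
  drug_out <- data.table(primaryid = rs$drug$primaryid,
                         drug_seq = rs$drug$drug_seq,
                         drugname = rs$drug$drugname,
                         role_cod = rs$drug$role_cod)
  ther_out <- rs$drug[!is.na(start_dt),
                      .(primaryid, dsg_drug_seq = drug_seq,
                        start_dt = format_faers_date(start_dt))]
  wr <- function(x, p) fwrite(x, p, sep = dialect$delim, quote = FALSE)
  wr(demo_out, paths["demo"]); wr(drug_out, paths["drug"])
  wr(rs$reac, paths["reac"]); wr(rs$outc, paths["outc"])
  wr(ther_out, paths["ther"])
  invisible(paths)
}

#' Deduplicate case versions
#'
#' FAERS cases are re-submitted as new versions; a case must contribute a
#' single report to any disproportionality analysis. For each `caseid`
#' the version with the greatest `(fda_dt, caseversion)` under
#' lexicographic comparison is retained (missing receipt dates sort
#' earliest).
#'
#' @param rs a `report_set`.
#' @return a deduplicated `report_set` with attribute `n_removed`.
#' @export
deduplicate <- function(rs) {
  demo <- copy(rs$demo)
  ord <- order(demo$caseid, !is.na(demo$fda_dt), demo$fda_dt,
               demo$caseversion, method = "radix")
  demo <- demo[ord]
  keep_ids <- demo[, primaryid[.N], by = caseid]$V1
  out <- subset_reports(rs, keep_ids)
  ## preserve input report order among the retained versions
  out$demo <- out$demo[match(intersect(rs$demo$primaryid, keep_ids), primaryid)]
  attr(out, "n_removed") <- nrow(rs$demo) - length(keep_ids)
  out
}
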