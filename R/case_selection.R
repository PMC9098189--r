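#' Liver-event preferred-term dictionary
#'
#' Loads the MedDRA preferred-term (PT) list defining the drug-induced
#' liver injury event set. Terms are normalised (uppercased, whitespace
#' collapsed) and matching anywhere in the package is against this
#' normalised form, so source-data casing and spacing do not matter.
#'
#' @param path optional path to a one-term-per-line text file; defaults
#'   to the packaged liver-event list (52 PTs).
#' @return character vector of normalised PTs, class `pt_dictionary`.
#' @export
pt_dictionary <- function(path = NULL) {
  path <- path %||% pkg_extdata("liver_event_pts.txt")
  if (!file.exists(path)) stop("PT dictionary file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  terms <- unique(normalize_term(lines))
  structure(terms, class = c("pt_dictionary", "character"))
}

#' Study-drug lexicon
#'
#' Maps each canonical study drug (the eight triazoles and three
#' echinocandins) to its synonym set: generic name, major brand names and
#' salt variants. Free-text drug names are matched by token-level
#' case-insensitive containment of a synonym; no fuzzy matching is done.
#'
#' @param path optional path to a tab-separated `canonical<TAB>synonym`
#'   file; defaults to the packaged antifungal lexicon.
#' @return named list canonical name -> character vector of normalised
#'   synonyms, class `drug_lexicon`.
#' @export
drug_lexicon <- function(path = NULL) {
  path <- path %||% pkg_extdata("antifungal_lexicon.tsv")
  if (!file.exists(path)) stop("drug lexicon file not found: ", path)
  x <- fread(path, sep = "\t", header = FALSE,
             col.names = c("canonical", "synonym"), quote = "")
  x <- x[!startsWith(canonical, "#")]
  lex <- lapply(split(normalize_term(x$synonym), x$canonical), unique)
  ## keep file order of canonical names, not alphabetical split() order
  structure(lex[unique(x$canonical)], class = "drug_lexicon")
}

#' Is a report a DILI case?
#'
#' A report is a case when any of its reaction PTs, after normalisation,
#' is in the event dictionary. Invariant to PT order and duplication.
#'
#' @param pts character vector of reaction PTs for one report.
#' @param dict a [pt_dictionary()].
#' @return logical scalar.
#' @export
is_dili_case <- function(pts, dict = pt_dictionary()) {
  any(normalize_term(pts) %in% dict)
}

## Map unique free-text drug names to canonical lexicon names by
## token-boundary containment. Returns data.table(drugname, canonical),
## possibly several canonicals per name.
match_drug_names <- function(drugnames, lex) {
  un <- unique(drugnames)
  norm <- normalize_term(un)
  hits <- vector("list", length(lex))
  for (i in seq_along(lex)) {
    pat <- paste0("(^|[^A-Z0-9])(",
                  paste(gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", lex[[i]]),
                        collapse = "|"),
                  ")($|[^A-Z0-9])")
    m <- grepl(pat, norm)
    if (any(m)) hits[[i]] <- data.table(drugname = un[m],
                                        canonical = names(lex)[i])
  }
  rbindlist(hits[!vapply(hits, is.null, logical(1))])
}

#' Canonical study drugs named by one report
#'
#' @param drugs data.frame with columns `drugname` and `role_cod` — the
#'   drug records of a single report.
#' @param lex a [drug_lexicon()].
#' @param roles role codes that count as exposure; the default restricts
#'   to suspect drugs (primary + secondary suspect).
#' @return character vector of canonical drug names (possibly empty).
#' @export
exposed_drugs <- function(drugs, lex = drug_lexicon(), roles = c("PS", "SS")) {
  drugs <- as.data.table(drugs)[role_cod %in% roles]
  if (nrow(drugs) == 0L) return(character())
  sort(unique(match_drug_names(drugs$drugname, lex)$canonical))
}

## Exposure map for a whole report set: data.table(primaryid, drug,
## start_dt = earliest therapy start among records matching that drug).
exposure_map <- function(rs, lex, roles) {
  d <- rs$drug[role_cod %in% roles]
  if (nrow(d) == 0L)
    return(data.table(primaryid = character(), drug = character(),
                      start_dt = as.Date(character())))
  mm <- match_drug_names(d$drugname, lex)
  if (nrow(mm) == 0L)
    return(data.table(primaryid = character(), drug = character(),
                      start_dt = as.Date(character())))
  hit <- mm[d, on = "drugname", allow.cartesian = TRUE, nomatch = NULL]
  hit[, .(start_dt = if (all(is.na(start_dt))) as.Date(NA) else
            min(start_dt, na.rm = TRUE)),
      by = .(primaryid, drug = canonical)]
}

## primaryids of reports whose reaction list hits the event dictionary
event_ids <- function(rs, dict) {
  unique(rs$reac[normalize_term(pt) %chin% as.character(dict)]$primaryid)
}

#' Select the drug-event study cohort
#'
#' Implements the case-selection flow: identify event (DILI) reports via
#' the PT dictionary, identify study-drug-exposed reports via the drug
#' lexicon (suspect roles by default), and intersect. A report naming k
#' study drugs contributes a case to each drug's list; such multi-drug
#' reports are counted in `flow$n_multi_drug` so attribution inflation is
#' visible.
#'
#' @param rs a deduplicated `report_set`.
#' @param dict a [pt_dictionary()].
#' @param lex a [drug_lexicon()].
#' @param roles exposure role codes, default `c("PS","SS")`.
#' @return list of class `cohort_selection`:
#'   `cases` (data.table primaryid/drug/start_dt for drug-and-event
#'   reports), `exposure` (same for all exposed reports), `event_ids`,
#'   `per_drug` (named case counts for every lexicon drug) and `flow`
#'   (n_total, n_drug, n_event, n_case, n_multi_drug).
#' @export
select_cohort <- function(rs, dict = pt_dictionary(), lex = drug_lexicon(),
                          roles = c("PS", "SS")) {
  ev <- event_ids(rs, dict)
  exp_map <- exposure_map(rs, lex, roles)
  cases <- exp_map[primaryid %in% ev]
  per_drug <- setNames(integer(length(lex)), names(lex))
  if (nrow(cases)) {
    tab <- cases[, .N, by = drug]
    per_drug[tab$drug] <- tab$N
  }
  n_case <- uniqueN(cases$primaryid)
  flow <- list(
    n_total = n_reports(rs),
    n_drug = uniqueN(exp_map$primaryid),
    n_event = length(ev),
    n_case = n_case,
    n_multi_drug = if (nrow(cases)) sum(cases[, .N, by = primaryid]$N > 1L) else 0L
  )
  structure(list(cases = cases, exposure = exp_map, event_ids = ev,
                 per_drug = per_drug, flow = flow, roles = roles),
            class = "cohort_selection")
}

#' @export
print.cohort_selection <- function(x, ...) {
  f <- x$flow
  cat("<cohort_selection>\n",
      "  total reports:   ", f$n_total, "\n",
      "  drug-exposed:    ", f$n_drug, " (roles ",
      paste(x$roles, collapse = ","), ")\n",
      "  event reports:   ", f$n_event, "\n",
      "  drug-and-event:  ", f$n_case,
      " (", f$n_multi_drug, " naming >1 study drug)\n", sep = "")
  print(x$per_drug)
  invisible(x)
}
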