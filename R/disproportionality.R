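#' Two-by-two contingency table(s) for disproportionality analysis
#'
#' Orientation: rows are drug exposure, columns are the event —
#' `a` = target drug & event, `b` = all other drugs & event,
#' `c` = target drug & other reactions, `d` = all other drugs & other
#' reactions. Vectorised: each row of the result is one drug-event table.
#'
#' @param a,b,c,d non-negative counts (equal-length vectors).
#' @param drug optional drug labels.
#' @return data.table of class `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d, drug = NULL) {
  x <- data.table(a = as.numeric(a), b = as.numeric(b),
                  c = as.numeric(c), d = as.numeric(d))
  if (!is.null(drug)) x[, drug := drug]
  if (any(x$a < 0 | x$b < 0 | x$c < 0 | x$d < 0, na.rm = TRUE))
    stop("contingency_table: negative cell count")
  if (any(x$a + x$b + x$c + x$d <= 0, na.rm = TRUE))
    stop("contingency_table: empty table (N = 0)")
  setcolorder(x, c(intersect("drug", names(x)), "a", "b", "c", "d"))
  setattr(x, "class", c("contingency_table", class(x)))
  x[]
}

#' Build the 2x2 table for one drug from a report set
#'
#' @param rs the deduplicated `report_set` providing the full background
#'   (N = all reports).
#' @param drug_ids primaryids of reports exposed to the target drug.
#' @param evt_ids primaryids of event (DILI) reports.
#' @param drug optional drug label.
#' @return a one-row [contingency_table()] satisfying
#'   `a+b = |event|`, `a+c = |exposed|`, `a+b+c+d = |rs|`.
#' @export
build_contingency <- function(rs, drug_ids, evt_ids, drug = NULL) {
  drug_ids <- unique(drug_ids); evt_ids <- unique(evt_ids)
  N <- n_reports(rs)
  a <- length(intersect(drug_ids, evt_ids))
  b <- length(evt_ids) - a
  c <- length(drug_ids) - a
  contingency_table(a, b, c, d = N - a - b - c, drug = drug)
}

.abcd <- function(tab, b, c, d) {
  if (inherits(tab, "contingency_table") ||
      (is.data.frame(tab) && all(c("a", "b", "c", "d") %in% names(tab)))) {
    list(a = as.numeric(tab$a), b = as.numeric(tab$b),
         c = as.numeric(tab$c), d = as.numeric(tab$d))
  } else list(a = as.numeric(tab), b = as.numeric(b),
              c = as.numeric(c), d = as.numeric(d))
}

## shared log-scale standard error term sqrt(1/a+1/b+1/c+1/d)
se_term <- function(a, b, c, d) sqrt(1 / a + 1 / b + 1 / c + 1 / d)

#' Reporting odds ratio with 95% confidence interval
#'
#' `ROR = (a/b)/(c/d)`; `95% CI = exp(ln ROR +/- 1.96 * se)` with
#' `se = sqrt(1/a + 1/b + 1/c + 1/d)`. Cells left at zero by the active
#' zero-cell policy make the metric undefined (`NA`), never an error.
#'
#' @param tab a [contingency_table()] (or the `a` counts).
#' @param b,c,d remaining counts when `tab` is given as `a`.
#' @return data.table with columns `ror`, `ror_lo`, `ror_hi`, `se`.
#' @export
compute_ror <- function(tab, b = NULL, c = NULL, d = NULL) {
  x <- .abcd(tab, b, c, d)
  ok <- x$a > 0 & x$b > 0 & x$c > 0 & x$d > 0
  se <- ifelse(ok, se_term(x$a, x$b, x$c, x$d), NA_real_)
  ror <- ifelse(ok, (x$a / x$b) / (x$c / x$d), NA_real_)
  data.table(ror = ror,
             ror_lo = ror * exp(-1.96 * se),
             ror_hi = ror * exp(1.96 * se),
             se = se)
}

#' Proportional reporting ratio and chi-squared statistic
#'
#' `PRR = (a/(a+c)) / (b/(b+d))`. The chi-squared statistic is the
#' Pearson sum over the four cells with expected counts from the margins
#' (`chi2_cells = "four-cell"`, the field-standard form) or, optionally,
#' the single-cell term `(a - E_a)^2 / E_a`.
#'
#' @inheritParams compute_ror
#' @param chi2_cells `"four-cell"` (default) or `"single-cell"`.
#' @param yates apply the Yates continuity correction (default off).
#' @return data.table with columns `prr`, `chi2`.
#' @export
compute_prr <- function(tab, b = NULL, c = NULL, d = NULL,
                        chi2_cells = c("four-cell", "single-cell"),
                        yates = FALSE) {
  chi2_cells <- match.arg(chi2_cells)
  x <- .abcd(tab, b, c, d)
  N <- x$a + x$b + x$c + x$d
  ok_prr <- (x$a + x$c) > 0 & (x$b + x$d) > 0 & x$b > 0
  prr <- ifelse(ok_prr, (x$a / (x$a + x$c)) / (x$b / (x$b + x$d)), NA_real_)
  Ea <- (x$a + x$b) * (x$a + x$c) / N
  Eb <- (x$a + x$b) * (x$b + x$d) / N
  Ec <- (x$c + x$d) * (x$a + x$c) / N
  Ed <- (x$c + x$d) * (x$b + x$d) / N
  ok_chi <- Ea > 0 & Eb > 0 & Ec > 0 & Ed > 0
  dev <- function(o, e) (pmax(abs(o - e) - if (yates) 0.5 else 0, 0))^2 / e
  chi2 <- if (chi2_cells == "four-cell") {
    dev(x$a, Ea) + dev(x$b, Eb) + dev(x$c, Ec) + dev(x$d, Ed)
  } else dev(x$a, Ea)
  data.table(prr = prr, chi2 = ifelse(ok_chi, chi2, NA_real_))
}

#' Information component with lower bound
#'
#' `IC = log2( a * N / ((a+c)(a+b)) )`, the log2
#' observed-to-expected reporting ratio. The default (`mode =
#' "printed"`) lower bound is the multiplicative form
#' `IC025 = IC * exp(-1.96 * se)` — undefined for `IC <= 0` (its
#' logarithm does not exist), in which case `ic025` is `NA` and the IC
#' criterion cannot fire. `mode = "literature"` gives the conventional
#' additive bound on the log2 scale, `IC - 1.96 * se / ln 2`.
#'
#' @inheritParams compute_ror
#' @param mode `"printed"` (default) or `"literature"`.
#' @return data.table with columns `ic`, `ic025`.
#' @export
compute_ic <- function(tab, b = NULL, c = NULL, d = NULL,
                       mode = c("printed", "literature")) {
  mode <- match.arg(mode)
  x <- .abcd(tab, b, c, d)
  N <- x$a + x$b + x$c + x$d
  ok <- x$a > 0 & (x$a + x$c) > 0 & (x$a + x$b) > 0
  ic <- ifelse(ok, log2(x$a * N / ((x$a + x$c) * (x$a + x$b))), NA_real_)
  ok_se <- x$a > 0 & x$b > 0 & x$c > 0 & x$d > 0
  se <- ifelse(ok_se, se_term(x$a, x$b, x$c, x$d), NA_real_)
  ic025 <- if (mode == "printed") {
    ifelse(!is.na(ic) & ic > 0, ic * exp(-1.96 * se), NA_real_)
  } else ic - 1.96 * se / log(2)
  data.table(ic = ic, ic025 = ic025)
}

#' Empirical Bayesian geometric mean with lower bound
#'
#' `EBGM = a * N / ((a+c)(a+b))` — the observed-to-expected reporting
#' ratio (so `EBGM = 2^IC` identically) — with the one-sided 90% lower
#' bound `EBGM05 = EBGM * exp(-1.64 * se)`.
#'
#' @inheritParams compute_ror
#' @return data.table with columns `ebgm`, `ebgm05`.
#' @export
compute_ebgm <- function(tab, b = NULL, c = NULL, d = NULL) {
  x <- .abcd(tab, b, c, d)
  N <- x$a + x$b + x$c + x$d
  ok <- x$a > 0 & (x$a + x$c) > 0 & (x$a + x$b) > 0
  ebgm <- ifelse(ok, x$a * N / ((x$a + x$c) * (x$a + x$b)), NA_real_)
  ok_se <- x$a > 0 & x$b > 0 & x$c > 0 & x$d > 0
  se <- ifelse(ok_se, se_term(x$a, x$b, x$c, x$d), NA_real_)
  data.table(ebgm = ebgm, ebgm05 = ebgm * exp(-1.64 * se))
}

#' Signal criteria flags
#'
#' Applies the four algorithms' signal thresholds:
#' ROR — CI lower bound > 1 and n >= 2; PRR — PRR >= 2, chi2 >= 4 and
#' n >= 3; IC — IC025 > 0; EBGM — EBGM05 >= 2 and n > 0. Undefined
#' metrics never fire.
#'
#' @param m data.table of metrics as returned by [signal_metrics()]
#'   (needs `n`, `ror_lo`, `prr`, `chi2`, `ic025`, `ebgm05`).
#' @return `m` with logical columns `ror_signal`, `prr_signal`,
#'   `ic_signal`, `ebgm_signal` added.
#' @export
evaluate_criteria <- function(m) {
  m <- as.data.table(m)
  flag <- function(x) !is.na(x) & x
  m[, ror_signal  := flag(ror_lo > 1 & n >= 2)]
  m[, prr_signal  := flag(prr >= 2 & chi2 >= 4 & n >= 3)]
  m[, ic_signal   := flag(ic025 > 0)]
  m[, ebgm_signal := flag(ebgm05 >= 2 & n > 0)]
  m[]
}

#' All four disproportionality statistics for 2x2 table(s)
#'
#' One call computing ROR (95% CI), PRR (chi2), IC (IC025), EBGM
#' (EBGM05), the shared log-scale standard error and the four signal
#' flags. Vectorised over the rows of `tab`.
#'
#' @param tab a [contingency_table()] (one row per drug).
#' @param mode IC lower-bound mode, see [compute_ic()].
#' @param chi2_cells see [compute_prr()].
#' @param zero_policy `"undefined"` (default): metrics whose cells are
#'   zero are `NA` and flag false; `"haldane"`: add 0.5 to all four cells
#'   of any table containing a zero before computing.
#' @param yates see [compute_prr()].
#' @return data.table with one row per table: `drug` (if present), `n`
#'   (= a), a/b/c/d, all metrics, bounds, `se` and flags.
#' @export
signal_metrics <- function(tab, mode = c("printed", "literature"),
                           chi2_cells = c("four-cell", "single-cell"),
                           zero_policy = c("undefined", "haldane"),
                           yates = FALSE) {
  mode <- match.arg(mode); chi2_cells <- match.arg(chi2_cells)
  zero_policy <- match.arg(zero_policy)
  x <- .abcd(tab, NULL, NULL, NULL)
  n <- x$a  # co-occurrence count gates use the raw count, not corrected
  if (zero_policy == "haldane") {
    z <- x$a == 0 | x$b == 0 | x$c == 0 | x$d == 0
    for (cell in c("a", "b", "c", "d")) x[[cell]] <- x[[cell]] + 0.5 * z
  }
  ct <- data.table(a = x$a, b = x$b, c = x$c, d = x$d)
  out <- data.table(n = n)
  if (is.data.frame(tab) && "drug" %in% names(tab)) out[, drug := tab$drug]
  out <- cbind(out, ct,
               compute_ror(ct),
               compute_prr(ct, chi2_cells = chi2_cells, yates = yates),
               compute_ic(ct, mode = mode),
               compute_ebgm(ct))
  setcolorder(out, c(intersect("drug", names(out)), "n", "a", "b", "c", "d",
                     "ror", "ror_lo", "ror_hi", "prr", "chi2",
                     "ic", "ic025", "ebgm", "ebgm05", "se"))
  evaluate_criteria(out)
}

#' Per-drug signal table for a selected cohort
#'
#' Builds each study drug's 2x2 table against the full deduplicated
#' background and computes all metrics, flags and publication-style
#' formatted columns (`"4.58 (4.29, 4.90)*"`; a star marks a drug meeting
#' that algorithm's signal criteria; an empty-parenthesis bound means the
#' bound is undefined).
#'
#' @param rs the deduplicated `report_set`.
#' @param selection a [select_cohort()] result.
#' @param sort_by `"lexicon"` (lexicon order, default), `"ror"` or `"n"`
#'   (both descending).
#' @param ... passed to [signal_metrics()] (`mode`, `chi2_cells`,
#'   `zero_policy`, `yates`).
#' @return data.table: one row per lexicon drug with raw metrics, flags
#'   and formatted display columns `ror_ci`, `prr_chi2`, `ic_ic025`,
#'   `ebgm_ebgm05`.
#' @export
analyze_all <- function(rs, selection, sort_by = c("lexicon", "ror", "n"),
                        ...) {
  sort_by <- match.arg(sort_by)
  drugs <- names(selection$per_drug)
  n_ev <- selection$flow$n_event
  N <- selection$flow$n_total
  expo <- selection$exposure[, .(n_drug = uniqueN(primaryid)), by = drug]
  a <- selection$per_drug
  n_drug <- setNames(integer(length(drugs)), drugs)
  n_drug[expo$drug] <- expo$n_drug
  tab <- contingency_table(a = a[drugs],
                           b = n_ev - a[drugs],
                           c = n_drug[drugs] - a[drugs],
                           d = N - n_ev - n_drug[drugs] + a[drugs],
                           drug = drugs)
  m <- signal_metrics(tab, ...)
  fmt <- function(v, lo, hi = NULL, star) {
    num <- function(z) ifelse(is.na(z), "", formatC(round_half_up(z, 2),
                                                    format = "f", digits = 2))
    inner <- if (is.null(hi)) num(lo) else
      ifelse(is.na(lo) & is.na(hi), "", paste0(num(lo), ", ", num(hi)))
    paste0(num(v), " (", inner, ")", ifelse(star, "*", ""))
  }
  m[, `:=`(ror_ci   = fmt(ror, ror_lo, ror_hi, ror_signal),
           prr_chi2 = fmt(prr, chi2, star = prr_signal),
           ic_ic025 = fmt(ic, ic025, star = ic_signal),
           ebgm_ebgm05 = fmt(ebgm, ebgm05, star = ebgm_signal))]
  if (sort_by == "ror") setorder(m, -ror, na.last = TRUE)
  if (sort_by == "n") setorder(m, -n)
  m[]
}

#' Screen every drug name in a report set for the event
#'
#' Exploratory counterpart of [analyze_all()]: exposure is exact
#' normalised-name matching for every distinct drug name (no lexicon),
#' the event is the PT dictionary. Used for calibration studies where
#' background drugs carry known null signals.
#'
#' @param rs a deduplicated `report_set`.
#' @param dict a [pt_dictionary()].
#' @param roles exposure role codes.
#' @param min_exposed drop drugs with fewer exposed reports (default 1).
#' @param ... passed to [signal_metrics()].
#' @return data.table of metrics, one row per distinct drug name.
#' @export
all_drug_signals <- function(rs, dict = pt_dictionary(),
                             roles = c("PS", "SS"), min_exposed = 1L, ...) {
  ev <- event_ids(rs, dict)
  d <- unique(rs$drug[role_cod %in% roles, .(primaryid, drugname)])
  cnt <- d[, .(n_exposed = .N), by = drugname]
  d[, is_event := primaryid %chin% ev]
  aa <- d[, .(a = sum(is_event)), by = drugname]
  cnt <- aa[cnt, on = "drugname"][n_exposed >= min_exposed]
  N <- n_reports(rs); n_ev <- length(ev)
  tab <- contingency_table(a = cnt$a, b = n_ev - cnt$a,
                           c = cnt$n_exposed - cnt$a,
                           d = N - n_ev - cnt$n_exposed + cnt$a,
                           drug = cnt$drugname)
  signal_metrics(tab, ...)
}
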