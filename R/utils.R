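`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero
#'
#' Commercial ("half-up") rounding, used for all reported percentages so
#' that printed tables are reproducible independent of the IEEE
#' round-half-even behaviour of [base::round()].
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @examples
#' round_half_up(c(0.125, 0.135), 2)  # 0.13 0.14
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # small eps absorbs representation error so e.g. 34.5 never lands below .5
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

## Parse FAERS-style dates: yyyymmdd; partial dates yyyymm resolve to the
## 15th and yyyy to July 1 (needed for onset arithmetic). Returns Date.
parse_faers_date <- function(x, quiet = TRUE) {
  x <- trimws(as.character(x))
  x[!is.na(x) & (x == "" | x == "NA")] <- NA_character_
  nc <- nchar(x)
  out <- rep(as.Date(NA), length(x))
  full <- !is.na(x) & nc == 8L
  ym   <- !is.na(x) & nc == 6L
  yo   <- !is.na(x) & nc == 4L
  out[full] <- as.Date(x[full], format = "%Y%m%d")
  out[ym]   <- as.Date(paste0(x[ym], "15"), format = "%Y%m%d")
  out[yo]   <- as.Date(paste0(x[yo], "0701"), format = "%Y%m%d")
  n_partial <- sum(ym) + sum(yo)
  if (n_partial > 0L && !quiet) {
    message(n_partial, " partial date(s) resolved (yyyymm -> 15th, yyyy -> Jul 1)")
  }
  bad <- !is.na(x) & !(full | ym | yo)
  if (any(bad) && !quiet) message(sum(bad), " unparseable date(s) set to missing")
  out
}

format_faers_date <- function(d) {
  out <- rep("", length(d))
  ok <- !is.na(d)
  out[ok] <- format(d[ok], "%Y%m%d")
  out
}

## Normalize free text for matching: uppercase, collapse whitespace, trim.
normalize_term <- function(x) {
  x <- toupper(trimws(x))
  gsub("[[:space:]]+", " ", x)
}

pkg_extdata <- function(file) {
  path <- system.file("extdata", file, package = "dilisignal")
  if (path == "") stop("packaged resource not found: ", file)
  path
}
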