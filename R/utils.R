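# internal helpers shared across modules

#' Parse FAERS-style dates, keeping partial dates flagged rather than dropped
#'
#' FAERS date fields are 8-digit `YYYYMMDD` strings, but partial dates
#' (`YYYYMM`, `YYYY`) are common. Only complete 8-digit dates parse to a
#' calendar [Date]; partials keep their raw string and a precision flag so
#' downstream modules can decide whether to use them (time-to-onset requires
#' day precision, yearly counts only need the year).
#'
#' @param x character (or numeric) vector of raw date strings.
#' @return data.frame with columns `raw`, `date` (Date, `NA` unless day
#'   precision), `precision` (`"day"`, `"month"`, `"year"`, `"none"`) and
#'   `year` (integer, `NA` when no year is recoverable).
#' @keywords internal
parse_partial_date <- function(x) {
  raw <- trimws(as.character(x))
  raw[is.na(raw)] <- ""
  digits <- grepl("^[0-9]+$", raw)
  nch <- nchar(raw)
  precision <- rep("none", length(raw))
  precision[digits & nch == 4L] <- "year"
  precision[digits & nch == 6L] <- "month"
  precision[digits & nch == 8L] <- "day"
  date <- as.Date(rep(NA_character_, length(raw)))
  full <- precision == "day"
  if (any(full)) {
    parsed <- as.Date(raw[full], format = "%Y%m%d")
    # impossible dates like 20231340 fail to parse -> downgrade to none
    precision[full][is.na(parsed)] <- "none"
    date[full] <- parsed
  }
  year <- rep(NA_integer_, length(raw))
  has_year <- precision != "none"
  year[has_year] <- as.integer(substr(raw[has_year], 1L, 4L))
  data.frame(raw = raw, date = date, precision = precision, year = year,
             stringsAsFactors = FALSE)
}

# numeric coercion that maps unparseable strings to NA without warnings
as_num <- function(x) suppressWarnings(as.numeric(x))
as_int <- function(x) suppressWarnings(as.integer(x))

# age unit codes -> years (FAERS AGE_COD vocabulary)
age_to_years <- function(age, unit) {
  age <- as_num(age)
  unit <- toupper(trimws(ifelse(is.na(unit), "YR", unit)))
  unit[unit == ""] <- "YR"
  factor_tbl <- c(YR = 1, DEC = 10, MON = 1 / 12, WK = 1 / 52.18,
                  DY = 1 / 365.25, HR = 1 / 8766)
  f <- factor_tbl[unit]
  f[is.na(f)] <- 1
  age * unname(f)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
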