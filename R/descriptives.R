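#' @title Descriptive report-characteristics summaries
#' @description Frequency/percentage tables over demographics, reporters,
#'   countries, outcomes, indications and report years, matching the layout
#'   of a clinical-characteristics table, plus the serious-outcome fraction
#'   and yearly report counts.
#' @name descriptives
NULL

.outcome_labels <- c(DE = "death", LT = "life-threatening",
                     HO = "hospitalization", DS = "disability",
                     CA = "congenital anomaly",
                     RI = "required-intervention", OT = "other")
.serious_outcomes <- c("death", "life-threatening", "hospitalization",
                       "disability")

#' Build a categorical summary from labels and counts
#'
#' Percentages are `100 * count / denominator` rounded to 2 decimals, with
#' the denominator equal to the sum of the emitted counts — so percentages
#' always sum to 100 up to rounding.
#'
#' @param labels character vector of category labels.
#' @param counts integer vector of counts (same length).
#' @param field name of the summarized field.
#' @return data.frame of class `categorical_summary` with columns `label`,
#'   `count`, `percent` and attributes `field`, `denominator`.
#' @export
categorical_summary <- function(labels, counts, field = "") {
  stopifnot(length(labels) == length(counts), all(counts >= 0))
  denom <- sum(counts)
  out <- data.frame(label = as.character(labels), count = as.integer(counts),
                    percent = round(100 * counts / max(1L, denom), 2),
                    stringsAsFactors = FALSE)
  attr(out, "field") <- field
  attr(out, "denominator") <- denom
  class(out) <- c("categorical_summary", "data.frame")
  out
}

.age_breaks <- c(-Inf, 18, 45, 65, 75, Inf)
.age_labels <- c("<18", "18-44", "45-64", "65-75", ">75")
.weight_breaks <- c(-Inf, 50, 100, Inf)
.weight_labels <- c("<50 kg", "50-100 kg", ">100 kg")

bin_numeric <- function(x, breaks, labels) {
  f <- cut(x, breaks = breaks, labels = labels, right = FALSE)
  lv <- as.character(f)
  lv[is.na(lv)] <- "unknown"
  factor(lv, levels = c(labels, "unknown"))
}

#' Summarize one report characteristic as counts and percentages
#'
#' Continuous fields (age in years, weight in kg) are binned left-closed on
#' the conventional intervals — `"65-75"` means `[65, 75)`, `">75"` means
#' `[75, Inf)` — with an explicit `unknown` bin; categorical fields are
#' tabulated directly. Outcomes are counted per *mention*: a case carrying
#' several outcome codes contributes one count to each, so the outcome
#' denominator can exceed the case count. Indications come from
#' primary-suspect drug rows and omit missing values from the denominator.
#'
#' @param store a deduplicated `faers_store`.
#' @param field one of `"sex"`, `"age"`, `"weight"`, `"reporter"`,
#'   `"country"`, `"outcome"`, `"indication"`, `"year"`.
#' @param breaks,labels optional custom binning for `age`/`weight`.
#' @return a [categorical_summary()].
#' @export
summarize_categorical <- function(store, field, breaks = NULL,
                                  labels = NULL) {
  stopifnot(inherits(store, "faers_store"))
  field <- match.arg(field, c("sex", "age", "weight", "reporter", "country",
                              "outcome", "indication", "year"))
  demo <- store$demo
  vals <- switch(field,
    sex = factor(demo$sex, levels = c("male", "female", "unknown")),
    age = bin_numeric(demo$age_years, breaks %||% .age_breaks,
                      labels %||% .age_labels),
    weight = bin_numeric(demo$weight_kg, breaks %||% .weight_breaks,
                         labels %||% .weight_labels),
    reporter = factor(demo$reporter,
                      levels = c("consumer", "physician", "pharmacist",
                                 "other", "unknown")),
    country = {
      x <- demo$country
      lv <- c(sort(setdiff(unique(x), "unknown")), "unknown")
      factor(x, levels = lv)
    },
    outcome = {
      codes <- strsplit(demo$outcomes, ";", fixed = TRUE)
      codes <- lapply(codes, function(cs) {
        cs <- cs[nzchar(cs)]
        if (length(cs) == 0L) "unknown" else
          unname(.outcome_labels[cs])
      })
      x <- unlist(codes)
      x[is.na(x)] <- "unknown"
      factor(x, levels = c(unname(.outcome_labels), "unknown"))
    },
    indication = {
      ps <- store$drug[store$drug$role == "PS" &
                         !is.na(store$drug$indication_pt), , drop = FALSE]
      pairs <- unique(ps[, c("case_id", "indication_pt")])
      factor(pairs$indication_pt)
    },
    year = {
      y <- demo$report_year
      lv <- c(as.character(sort(unique(y[!is.na(y)]))), "unknown")
      x <- ifelse(is.na(y), "unknown", as.character(y))
      factor(x, levels = lv)
    })
  counts <- table(vals)
  if (field == "indication") {
    counts <- sort(counts, decreasing = TRUE)
  }
  categorical_summary(names(counts), as.integer(counts), field = field)
}

#' Fraction of reports with a serious outcome
#'
#' Serious outcomes are death, life-threatening events, hospitalization and
#' disability. The fraction is computed on outcome *mentions*:
#' `100 * serious mentions / all outcome-category mentions` (including
#' `unknown`, `other`, congenital anomaly and required-intervention).
#'
#' @param x a `faers_store`, or a named numeric vector of outcome-category
#'   counts using the labels of the outcome [summarize_categorical()].
#' @return percentage (numeric scalar).
#' @export
serious_outcome_fraction <- function(x) {
  if (inherits(x, "faers_store")) {
    if (nrow(x$demo) == 0L) stop("empty store", call. = FALSE)
    s <- summarize_categorical(x, "outcome")
    counts <- stats::setNames(s$count, s$label)
  } else {
    counts <- x
    stopifnot(is.numeric(counts), !is.null(names(counts)))
  }
  100 * sum(counts[names(counts) %in% .serious_outcomes]) / sum(counts)
}

#' Reports per calendar year, with gap years filled as zero
#'
#' @param store a `faers_store`.
#' @return data.frame `year`, `count`; empty when no report year is known.
#' @export
yearly_counts <- function(store) {
  stopifnot(inherits(store, "faers_store"))
  y <- store$demo$report_year
  y <- y[!is.na(y)]
  if (length(y) == 0L) {
    return(data.frame(year = integer(), count = integer()))
  }
  span <- seq(min(y), max(y))
  data.frame(year = span,
             count = as.integer(table(factor(y, levels = span))))
}

#' @export
print.categorical_summary <- function(x, ...) {
  cat(sprintf("Summary of '%s' (denominator %d)\n", attr(x, "field"),
              attr(x, "denominator")))
  print(as.data.frame(x), row.names = FALSE, ...)
  invisible(x)
}
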