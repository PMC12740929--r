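#' @title Disproportionality statistics and signal criteria
#' @description The four classical pharmacovigilance algorithms on a 2x2
#'   table — reporting odds ratio (ROR), proportional reporting ratio (PRR)
#'   with its chi-square, the Bayesian confidence propagation neural network
#'   information component (IC), and the unshrunk empirical Bayes geometric
#'   mean (EBGM, the observed/expected relative reporting ratio) — plus the
#'   conjunction signal rule and signal ranking.
#'
#'   All four lower bounds share one log-normal standard error,
#'   `SE = sqrt(1/a + 1/b + 1/c + 1/d)`:
#'   `ROR` CI `= exp(log ROR +/- z SE)`, `EBGM05 = exp(log EBGM - z SE)`,
#'   and `IC025 = IC - z SE / log(2)` (the IC is a base-2 logarithm, so its
#'   normal-approximation bound subtracts on the log2 scale). In this
#'   simplified form `IC = log2(EBGM)` identically.
#' @name dispro
NULL

# Haldane-Anscombe correction: +0.5 on all four cells when any cell is zero.
# Keeps every ratio and CI defined; flagged in the output.
haldane_correct <- function(a, b, c, d) {
  a <- as.double(a); b <- as.double(b); c <- as.double(c); d <- as.double(d)
  if (any(a + b + c + d == 0)) stop("empty table", call. = FALSE)
  zero <- a == 0 | b == 0 | c == 0 | d == 0
  k <- ifelse(zero, 0.5, 0)
  list(a = a + k, b = b + k, c = c + k, d = d + k, corrected = zero)
}

ln_se <- function(a, b, c, d) sqrt(1 / a + 1 / b + 1 / c + 1 / d)

#' Reporting odds ratio with 95% confidence interval
#'
#' `ROR = ad / (bc)`; `CI = exp(log ROR +/- z * SE)` with
#' `SE = sqrt(1/a + 1/b + 1/c + 1/d)`. Cells are Haldane-corrected (+0.5 on
#' all four) when any cell is zero.
#'
#' @param a,b,c,d contingency-table cells (vectorized): `a` target drug with
#'   the term, `b` target drug other terms, `c` other drugs with the term,
#'   `d` other drugs other terms.
#' @param z normal quantile for the interval (1.96 for 95%).
#' @return data.frame with `ror`, `ror_low`, `ror_high`.
#' @examples
#' ror_estimate(20, 80, 10, 890)  # ROR 22.25, CI (10.07, 49.17)
#' @export
ror_estimate <- function(a, b, c, d, z = 1.96) {
  h <- haldane_correct(a, b, c, d)
  ror <- h$a * h$d / (h$b * h$c)
  se <- ln_se(h$a, h$b, h$c, h$d)
  data.frame(ror = ror, ror_low = exp(log(ror) - z * se),
             ror_high = exp(log(ror) + z * se))
}

#' Proportional reporting ratio and chi-square statistic
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]`;
#' `chi2 = (ad - bc)^2 (a+b+c+d) / [(a+b)(c+d)(a+c)(b+d)]`
#' (Pearson's statistic without continuity correction).
#'
#' @inheritParams ror_estimate
#' @return data.frame with `prr`, `chi2`.
#' @examples
#' prr_estimate(20, 80, 10, 890)  # PRR 18, chi2 110.3
#' @export
prr_estimate <- function(a, b, c, d) {
  h <- haldane_correct(a, b, c, d)
  a <- h$a; b <- h$b; c <- h$c; d <- h$d
  n <- a + b + c + d
  prr <- (a / (a + b)) / (c / (c + d))
  chi2 <- (a * d - b * c)^2 * n / ((a + b) * (c + d) * (a + c) * (b + d))
  data.frame(prr = prr, chi2 = chi2)
}

#' Information component (BCPNN) with lower 95% bound
#'
#' `IC = log2[a N / ((a+c)(a+b))]` and `IC025 = IC - z * SE / log(2)`, the
#' normal-approximation lower bound on the base-2 log scale (printed
#' SOC-level values can be negative, which an exponentiated bound could not
#' produce).
#'
#' @inheritParams ror_estimate
#' @return data.frame with `ic`, `ic025`.
#' @examples
#' bcpnn_ic(20, 80, 10, 890)  # IC 2.737, IC025 1.593
#' @export
bcpnn_ic <- function(a, b, c, d, z = 1.96) {
  h <- haldane_correct(a, b, c, d)
  n <- h$a + h$b + h$c + h$d
  ic <- log2(h$a * n / ((h$a + h$c) * (h$a + h$b)))
  se <- ln_se(h$a, h$b, h$c, h$d)
  data.frame(ic = ic, ic025 = ic - z * se / log(2))
}

#' Empirical Bayes geometric mean (unshrunk) with lower bound
#'
#' `EBGM = a N / ((a+c)(a+b))`, the observed-over-expected relative
#' reporting ratio (the gamma-Poisson shrinkage of the full MGPS is not
#' applied), and `EBGM05 = exp(log EBGM - z * SE)`. With `z = 1.96` this is
#' a two-sided-95% lower limit, the convention the SOC- and PT-level
#' reference values follow; set `z = qnorm(0.95)` for a strict 5th
#' percentile.
#'
#' @inheritParams ror_estimate
#' @return data.frame with `ebgm`, `ebgm05`.
#' @examples
#' mgps_ebgm(20, 80, 10, 890)  # EBGM 6.667, EBGM05 3.02
#' @export
mgps_ebgm <- function(a, b, c, d, z = 1.96) {
  h <- haldane_correct(a, b, c, d)
  n <- h$a + h$b + h$c + h$d
  ebgm <- h$a * n / ((h$a + h$c) * (h$a + h$b))
  se <- ln_se(h$a, h$b, h$c, h$d)
  data.frame(ebgm = ebgm, ebgm05 = exp(log(ebgm) - z * se))
}

#' Signal criteria thresholds
#'
#' The conjunction rule: a term is a signal when *all* of `n >= min_n`,
#' `ROR lower CI > 1`, `PRR >= 2`, `chi2 >= 4`, `IC025 > 0` and
#' `EBGM05 > 2` hold.
#'
#' @param min_n minimum report count (`a` cell), default 3.
#' @param ror_low_gt,prr_ge,chi2_ge,ic025_gt,ebgm05_gt the remaining
#'   thresholds.
#' @return list of class `signal_criteria`.
#' @export
signal_criteria <- function(min_n = 3, ror_low_gt = 1, prr_ge = 2,
                            chi2_ge = 4, ic025_gt = 0, ebgm05_gt = 2) {
  crit <- list(min_n = min_n, ror_low_gt = ror_low_gt, prr_ge = prr_ge,
               chi2_ge = chi2_ge, ic025_gt = ic025_gt, ebgm05_gt = ebgm05_gt)
  stopifnot(all(vapply(crit, is.finite, TRUE)))
  structure(crit, class = "signal_criteria")
}

#' Evaluate the conjunction signal rule
#'
#' @param metrics data.frame with columns `n`, `ror_low`, `prr`, `chi2`,
#'   `ic025`, `ebgm05` (one row per term), e.g. from [signal_metrics()].
#' @param criteria a [signal_criteria()] object.
#' @return data.frame with logical `is_signal` and `failed_criteria`
#'   (comma-separated names of every violated clause, `""` when none).
#' @export
evaluate_signal <- function(metrics, criteria = signal_criteria()) {
  checks <- cbind(
    min_n = metrics$n >= criteria$min_n,
    ror_low = metrics$ror_low > criteria$ror_low_gt,
    prr = metrics$prr >= criteria$prr_ge,
    chi2 = metrics$chi2 >= criteria$chi2_ge,
    ic025 = metrics$ic025 > criteria$ic025_gt,
    ebgm05 = metrics$ebgm05 > criteria$ebgm05_gt)
  failed <- apply(checks, 1L, function(row) {
    paste(colnames(checks)[!row], collapse = ",")
  })
  data.frame(is_signal = rowSums(!checks) == 0L,
             failed_criteria = failed, stringsAsFactors = FALSE)
}

#' Compute all four disproportionality statistics for a set of tables
#'
#' @param tables `contingency_tables` data.frame ([build_pt_tables()] or
#'   [aggregate_soc()]).
#' @param criteria a [signal_criteria()] object.
#' @param z normal quantile for every lower/upper bound.
#' @return data.frame of class `signal_table`: `term`, `level`, `n` (= `a`),
#'   `ror`, `ror_low`, `ror_high`, `prr`, `chi2`, `ic`, `ic025`, `ebgm`,
#'   `ebgm05`, `haldane` (zero-cell correction applied), `is_signal`,
#'   `failed_criteria`.
#' @export
signal_metrics <- function(tables, criteria = signal_criteria(), z = 1.96) {
  stopifnot(all(c("term", "a", "b", "c", "d") %in% names(tables)))
  a <- tables$a; b <- tables$b; c <- tables$c; d <- tables$d
  out <- data.frame(term = tables$term,
                    level = tables$level %||% "PT",
                    n = a, stringsAsFactors = FALSE)
  out <- cbind(out, ror_estimate(a, b, c, d, z), prr_estimate(a, b, c, d),
               bcpnn_ic(a, b, c, d, z), mgps_ebgm(a, b, c, d, z))
  out$haldane <- haldane_correct(a, b, c, d)$corrected
  out <- cbind(out, evaluate_signal(out, criteria))
  class(out) <- c("signal_table", "data.frame")
  out
}

#' Rank signal metrics by frequency or signal strength
#'
#' `"frequency"` sorts by descending report count `n`; `"strength"` by
#' descending `EBGM05` (the lower-bound ranking under which strong rare
#' terms surface). Ties are broken alphabetically by term.
#'
#' @param metrics a `signal_table` from [signal_metrics()].
#' @param key `"frequency"` or `"strength"`.
#' @param signals_only keep only rows with `is_signal` (default).
#' @param top optional number of rows to keep after ranking.
#' @return reordered `signal_table`.
#' @export
rank_signals <- function(metrics, key = c("frequency", "strength"),
                         signals_only = TRUE, top = NULL) {
  key <- match.arg(key)
  out <- if (signals_only) metrics[metrics$is_signal, , drop = FALSE]
         else metrics
  sort_col <- if (key == "frequency") out$n else out$ebgm05
  out <- out[order(-sort_col, out$term), , drop = FALSE]
  if (!is.null(top)) out <- utils::head(out, top)
  rownames(out) <- NULL
  out
}

#' @export
print.signal_table <- function(x, digits = 3, ...) {
  cat(sprintf("<signal_table> %d terms (%s level), %d signals\n",
              nrow(x), paste(unique(x$level), collapse = "/"),
              sum(x$is_signal)))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], signif, digits = digits)
  print(utils::head(df[, setdiff(names(df), "failed_criteria")], 20), ...)
  if (nrow(df) > 20) cat("... (", nrow(df) - 20, " more rows)\n", sep = "")
  invisible(x)
}
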