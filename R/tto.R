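#' @title Time-to-onset analysis and Weibull hazard-pattern modelling
#' @description Time-to-onset (TTO) is the number of days between therapy
#'   start (START_DT) and adverse-event onset (EVENT_DT). Records with
#'   partial dates or onset preceding treatment are excluded with per-reason
#'   accounting. The TTO distribution is summarized by median/IQR and the
#'   five conventional latency bins, and modelled with a two-parameter
#'   Weibull distribution whose shape classifies the hazard pattern:
#'   shape < 1 early failure (declining hazard), shape ~ 1 random (constant),
#'   shape > 1 wear-out (increasing).
#' @name tto_weibull
NULL

#' Compute time-to-onset records for the target cases
#'
#' One record per target case with a complete (day-precision) event date and
#' a complete therapy start date for the target drug, with onset on or after
#' start. When several target-drug rows carry start dates, the earliest is
#' used (earliest exposure as onset origin). Exclusions are counted by
#' reason in the `exclusions` attribute.
#'
#' @param store a deduplicated `faers_store`.
#' @param target_case_ids cases from [select_primary_suspect()].
#' @param target canonical drug name whose therapy rows define the start.
#' @return data.frame (`case_id`, `days`) with attribute `exclusions`, a
#'   named count vector over reasons `missing_event_date`,
#'   `missing_start_date`, `negative_interval`.
#' @export
compute_tto <- function(store, target_case_ids, target = "roflumilast") {
  stopifnot(inherits(store, "faers_store"))
  ids <- unique(target_case_ids)
  demo <- store$demo[match(ids, store$demo$case_id), , drop = FALSE]
  event_ok <- !is.na(demo$event_date)

  dr <- store$drug[store$drug$case_id %in% ids &
                     store$drug$canonical_name == target &
                     !is.na(store$drug$start_date), , drop = FALSE]
  start <- tapply(as.numeric(dr$start_date), dr$case_id, min)
  start_date <- as.Date(as.numeric(start[ids]))
  start_ok <- !is.na(start_date)

  days <- as.integer(demo$event_date - start_date)
  keep <- event_ok & start_ok & !is.na(days) & days >= 0
  exclusions <- c(
    missing_event_date = sum(!event_ok),
    missing_start_date = sum(event_ok & !start_ok),
    negative_interval = sum(event_ok & start_ok & days < 0, na.rm = TRUE))
  out <- data.frame(case_id = ids[keep], days = days[keep],
                    stringsAsFactors = FALSE)
  attr(out, "exclusions") <- exclusions
  out
}

.tto_breaks <- c(0, 30, 180, 360, 720, Inf)
.tto_labels <- c("<30", "30-180", "180-360", "360-720", ">720")

#' Bin time-to-onset into the five conventional latency intervals
#'
#' Half-open bins `[0,30)`, `[30,180)`, `[180,360)`, `[360,720)`,
#' `[720,Inf)`; a 30-day onset falls in `30-180`. Percentages are relative
#' to the number of records, rounded to 2 decimals.
#'
#' @param records data.frame with a `days` column (or a numeric vector).
#' @return data.frame `bin`, `count`, `percent`.
#' @export
bin_tto <- function(records) {
  days <- if (is.data.frame(records)) records$days else records
  f <- cut(days, breaks = .tto_breaks, labels = .tto_labels, right = FALSE)
  count <- as.integer(table(f))
  data.frame(bin = .tto_labels, count = count,
             percent = round(100 * count / max(1L, length(days)), 2),
             stringsAsFactors = FALSE)
}

#' Median and interquartile range of time-to-onset
#'
#' Uses the inverted-ECDF quantile convention with averaging at
#' discontinuities (`quantile(type = 2)`), under which quartiles are always
#' observed values or midpoints of two — e.g. days `(0, 4, 34)` give median
#' 4 with IQR 0 to 34.
#'
#' @param records data.frame with a `days` column (or a numeric vector).
#' @return named numeric `c(median, q1, q3)`.
#' @export
summarize_tto <- function(records) {
  days <- if (is.data.frame(records)) records$days else records
  if (length(days) == 0L) stop("no time-to-onset records", call. = FALSE)
  q <- stats::quantile(days, probs = c(0.5, 0.25, 0.75), type = 2,
                       names = FALSE)
  c(median = q[1], q1 = q[2], q3 = q[3])
}

#' Fit a Weibull model to time-to-onset data
#'
#' Maximum-likelihood fit of the two-parameter Weibull distribution
#' (shape `beta`, scale `alpha` in days). Zero-day onsets are replaced by
#' 0.5 day for the likelihood only (the Weibull support is strictly
#' positive); they stay at 0 in medians and bins. Confidence intervals are
#' Wald intervals on the log-parameters from the observed information, so
#' they are always positive and bracket the estimates.
#'
#' @param records data.frame with a `days` column, or a numeric vector of
#'   onset times in days.
#' @param conf_level confidence level for the intervals.
#' @return object of class `weibull_tto`: list with `shape`, `scale`,
#'   `shape_ci`, `scale_ci`, `n`, `n_zero_replaced`, `loglik`, `vcov_log`
#'   (covariance of `log(shape)`, `log(scale)`), `conf_level` and
#'   `classification` (see [classify_failure()]).
#' @examples
#' set.seed(7)
#' fit <- fit_weibull(rweibull(500, shape = 0.6, scale = 40))
#' fit
#' @export
fit_weibull <- function(records, conf_level = 0.95) {
  x <- if (is.data.frame(records)) records$days else records
  x <- as.numeric(x[!is.na(x)])
  n_zero <- sum(x == 0)
  x[x == 0] <- 0.5
  if (length(x) < 10L) {
    stop("need at least 10 time-to-onset records to fit a Weibull model",
         call. = FALSE)
  }
  if (stats::sd(x) == 0) {
    stop("degenerate time-to-onset data: all values identical", call. = FALSE)
  }
  lx <- log(x)
  # moment-based init on the log scale (extreme-value regression heuristic)
  shape0 <- 1.2 / stats::sd(lx)
  scale0 <- exp(mean(lx) + 0.5772157 / shape0)
  nll <- function(par) {
    ll <- suppressWarnings(
      sum(stats::dweibull(x, shape = exp(par[1]), scale = exp(par[2]),
                          log = TRUE)))
    if (!is.finite(ll)) return(1e10)  # keep BFGS away from overflow regions
    -ll
  }
  opt <- stats::optim(c(log(shape0), log(scale0)), nll, method = "BFGS",
                      hessian = TRUE)
  vc <- solve(opt$hessian)
  se <- sqrt(diag(vc))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  est <- exp(opt$par)
  ci <- rbind(exp(opt$par[1] + c(-1, 1) * z * se[1]),
              exp(opt$par[2] + c(-1, 1) * z * se[2]))
  fit <- structure(list(
    shape = est[1], scale = est[2],
    shape_ci = ci[1, ], scale_ci = ci[2, ],
    n = length(x), n_zero_replaced = n_zero,
    loglik = -opt$value, vcov_log = vc, conf_level = conf_level),
    class = "weibull_tto")
  fit$classification <- classify_failure(fit)
  fit
}

#' Classify the hazard pattern of a Weibull time-to-onset fit
#'
#' Decided on the shape-parameter confidence interval: `early-failure` when
#' the upper bound is below 1, `wear-out` when the lower bound is above 1,
#' `random` otherwise (interval spans 1, i.e. compatible with a constant
#' hazard).
#'
#' @param fit a `weibull_tto` object.
#' @return one of `"early-failure"`, `"random"`, `"wear-out"`.
#' @export
classify_failure <- function(fit) {
  stopifnot(inherits(fit, "weibull_tto"))
  if (fit$shape_ci[2] < 1) "early-failure"
  else if (fit$shape_ci[1] > 1) "wear-out"
  else "random"
}

#' @export
print.weibull_tto <- function(x, digits = 3, ...) {
  cat("Weibull time-to-onset fit (n = ", x$n, ")\n", sep = "")
  cat(sprintf("  shape beta:  %.*g  (%g%% CI %.*g-%.*g)\n", digits, x$shape,
              100 * x$conf_level, digits, x$shape_ci[1], digits,
              x$shape_ci[2]))
  cat(sprintf("  scale alpha: %.*g days (%g%% CI %.*g-%.*g)\n", digits,
              x$scale, 100 * x$conf_level, digits, x$scale_ci[1], digits,
              x$scale_ci[2]))
  cat("  hazard pattern:", x$classification, "\n")
  invisible(x)
}

#' @export
summary.weibull_tto <- function(object, ...) {
  out <- data.frame(
    n = object$n,
    shape = object$shape, shape_low = object$shape_ci[1],
    shape_high = object$shape_ci[2],
    scale = object$scale, scale_low = object$scale_ci[1],
    scale_high = object$scale_ci[2],
    median_model = object$scale * log(2)^(1 / object$shape),
    classification = object$classification,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' @export
coef.weibull_tto <- function(object, ...) {
  c(shape = object$shape, scale = object$scale)
}

#' @export
confint.weibull_tto <- function(object, parm = c("shape", "scale"),
                                level = NULL, ...) {
  ci <- rbind(shape = object$shape_ci, scale = object$scale_ci)
  colnames(ci) <- c("low", "high")
  ci[match.arg(parm, several.ok = TRUE), , drop = FALSE]
}

#' @export
plot.weibull_tto <- function(x, data = NULL, max_days = NULL, ...) {
  max_days <- max_days %||% stats::qweibull(0.99, x$shape, x$scale)
  t <- seq(0.01, max_days, length.out = 300)
  if (!is.null(data)) {
    days <- if (is.data.frame(data)) data$days else data
    graphics::hist(days, breaks = 30, freq = FALSE,
                   main = "Time to onset", xlab = "days", border = "grey60")
    graphics::lines(t, stats::dweibull(t, x$shape, x$scale), lwd = 2)
  } else {
    plot(t, stats::dweibull(t, x$shape, x$scale), type = "l", lwd = 2,
         xlab = "days", ylab = "density",
         main = sprintf("Weibull(shape %.2f, scale %.1f d): %s",
                        x$shape, x$scale, x$classification), ...)
  }
  invisible(x)
}
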