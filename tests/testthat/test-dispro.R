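# Frozen oracle values for the running example a=20, b=80, c=10, d=890,
# computed by direct arithmetic on the printed formulas:
#   ROR = 20*890/(80*10) = 22.25, SE = sqrt(1/20+1/80+1/10+1/890) = 0.4045041
#   CI  = exp(log(22.25) -/+ 1.96*SE) = (10.0695287, 49.1644162)
#   PRR = (20/100)/(10/900) = 18,  chi2 = 17000^2*1000/(100*900*30*970)
#   IC  = log2(20*1000/(30*100)) = 2.7369656, IC025 = IC - 1.96*SE/log(2)
#   EBGM = 20*1000/(30*100) = 6.6666667, EBGM05 = exp(log(EBGM) - 1.96*SE)

test_that("the four statistics reproduce the hand-computed example", {
  ror <- ror_estimate(20, 80, 10, 890)
  expect_equal(ror$ror, 22.25)
  expect_equal(ror$ror_low, 10.0695287, tolerance = 1e-7)
  expect_equal(ror$ror_high, 49.1644162, tolerance = 1e-7)

  prr <- prr_estimate(20, 80, 10, 890)
  expect_equal(prr$prr, 18)
  expect_equal(prr$chi2, 110.3474634, tolerance = 1e-7)

  ic <- bcpnn_ic(20, 80, 10, 890)
  expect_equal(ic$ic, 2.7369656, tolerance = 1e-7)
  expect_equal(ic$ic025, 1.5931564, tolerance = 1e-7)

  eb <- mgps_ebgm(20, 80, 10, 890)
  expect_equal(eb$ebgm, 20 / 3)
  expect_equal(eb$ebgm05, 3.0170873, tolerance = 1e-7)
})

test_that("the null table gives ROR = PRR = EBGM = 1, IC = chi2 = 0", {
  expect_equal(ror_estimate(5, 5, 5, 5)$ror, 1)
  ci <- ror_estimate(5, 5, 5, 5)
  expect_equal(ci$ror_low * ci$ror_high, 1)  # symmetric about 1 on log scale
  prr <- prr_estimate(5, 5, 5, 5)
  expect_equal(prr$prr, 1)
  expect_equal(prr$chi2, 0)
  ic <- bcpnn_ic(5, 5, 5, 5)
  expect_equal(ic$ic, 0)
  expect_lt(ic$ic025, 0)
  expect_equal(mgps_ebgm(5, 5, 5, 5)$ebgm, 1)
})

test_that("chi-square is invariant to swapping rows and columns", {
  expect_equal(prr_estimate(20, 80, 10, 890)$chi2,
               prr_estimate(10, 890, 20, 80)$chi2)   # swap rows
  expect_equal(prr_estimate(20, 80, 10, 890)$chi2,
               prr_estimate(20, 10, 80, 890)$chi2)   # swap columns
})

test_that("chi-square matches Pearson's uncorrected test", {
  chi <- prr_estimate(20, 80, 10, 890)$chi2
  ref <- suppressWarnings(
    stats::chisq.test(matrix(c(20, 10, 80, 890), 2), correct = FALSE))
  expect_equal(chi, unname(ref$statistic))
})

test_that("zero cells are Haldane-corrected on all four cells", {
  got <- ror_estimate(0, 10, 10, 10)
  want <- (0.5 * 10.5) / (10.5 * 10.5)
  expect_equal(got$ror, want)
  se <- sqrt(1 / 0.5 + 3 / 10.5)
  expect_equal(got$ror_low, exp(log(want) - 1.96 * se))
  # all-zero table is an error
  expect_error(ror_estimate(0, 0, 0, 0), "empty table")
  expect_error(prr_estimate(0, 0, 0, 0), "empty table")
})

test_that("metrics agree with a naive reimplementation on 1000 random tables",
{
  set.seed(1203)
  n <- 1000
  a <- rpois(n, 5); b <- rpois(n, 60); c <- rpois(n, 40); d <- rpois(n, 800)
  keep <- a + b + c + d > 0 & a + c > 0 & a + b > 0
  a <- a[keep]; b <- b[keep]; c <- c[keep]; d <- d[keep]
  tables <- data.frame(term = sprintf("t%04d", seq_along(a)), level = "PT",
                       a = a, b = b, c = c, d = d)
  got <- signal_metrics(tables)
  cols <- c("ror", "ror_low", "ror_high", "prr", "chi2", "ic", "ic025",
            "ebgm", "ebgm05")
  for (i in seq_along(a)) {
    want <- naive_metrics(a[i], b[i], c[i], d[i])
    for (cl in cols) {
      expect_equal(got[[cl]][i], want[[cl]], tolerance = 1e-12,
                   label = sprintf("%s on table %d", cl, i))
    }
  }
})

test_that("IC equals log2(EBGM) exactly and metrics are concordant", {
  set.seed(77)
  for (rep in 1:200) {
    a <- sample(1:50, 1); b <- sample(1:200, 1)
    c <- sample(1:100, 1); d <- sample(1:2000, 1)
    m <- signal_metrics(data.frame(term = "x", level = "PT",
                                   a = a, b = b, c = c, d = d))
    expect_equal(m$ic, log2(m$ebgm), tolerance = 1e-14)
    # all-positive cells: ROR>1 <=> PRR>1 <=> IC>0 <=> EBGM>1
    s <- sign(m$ror - 1)
    if (s != 0) {
      expect_equal(sign(m$prr - 1), s)
      expect_equal(sign(m$ic), s)
      expect_equal(sign(m$ebgm - 1), s)
    }
  }
})

test_that("signal rule is the conjunction of all six criteria", {
  # the running example passes every clause
  m <- signal_metrics(data.frame(term = "x", level = "PT",
                                 a = 20, b = 80, c = 10, d = 890))
  expect_true(m$is_signal)
  expect_equal(m$failed_criteria, "")
  # n = 2 with arbitrarily strong metrics fails only min_n
  m2 <- signal_metrics(data.frame(term = "x", level = "PT",
                                  a = 2, b = 8, c = 1, d = 889))
  expect_false(m2$is_signal)
  expect_equal(m2$failed_criteria, "min_n")
  # a null table fails every distributional clause
  m3 <- signal_metrics(data.frame(term = "x", level = "PT",
                                  a = 5, b = 5, c = 5, d = 5))
  expect_false(m3$is_signal)
  expect_setequal(strsplit(m3$failed_criteria, ",")[[1]],
                  c("ror_low", "prr", "chi2", "ic025", "ebgm05"))
  # thresholds are configurable
  strict <- signal_metrics(data.frame(term = "x", level = "PT",
                                      a = 20, b = 80, c = 10, d = 890),
                           criteria = signal_criteria(min_n = 50))
  expect_false(strict$is_signal)
})

test_that("null-calibrated data yield few signals, fewer as min_n rises", {
  set.seed(99)
  # independent drug/event: expected cell counts satisfy ad = bc
  n_terms <- 400
  p <- runif(n_terms, 0.001, 0.05)
  a <- rbinom(n_terms, 1000, p)
  c <- rbinom(n_terms, 20000, p)
  tables <- data.frame(term = sprintf("t%03d", 1:n_terms), level = "PT",
                       a = a, b = 1000 - a, c = c, d = 20000 - c)
  frac <- function(min_n) {
    mean(signal_metrics(tables,
                        criteria = signal_criteria(min_n = min_n))$is_signal)
  }
  expect_lt(frac(3), 0.05)
  expect_lte(frac(10), frac(3))   # monotone in the report-count threshold
  expect_lte(frac(30), frac(10))
})

test_that("ranking orders by n or EBGM05 with alphabetical ties", {
  m <- signal_metrics(data.frame(
    term = c("Diarrhoea", "Death", "Zeta", "Alpha"), level = "PT",
    a = c(461, 497, 10, 10), b = c(2679, 2643, 3130, 3130),
    c = c(20000, 30000, 500, 500), d = c(8e5, 79e4, 819500, 819500)))
  by_n <- rank_signals(m, "frequency", signals_only = FALSE)
  expect_equal(by_n$term[1:2], c("Death", "Diarrhoea"))
  expect_equal(by_n$term[3:4], c("Alpha", "Zeta"))  # equal n -> alphabetical
  by_s <- rank_signals(m, "strength", signals_only = FALSE)
  expect_equal(by_s$term, by_s$term[order(-by_s$ebgm05, by_s$term)])
  expect_error(rank_signals(m, "magnitude"))
  # empty input stays empty
  expect_equal(nrow(rank_signals(m[0, ], "frequency")), 0)
})
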