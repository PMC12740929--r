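# Build small in-memory stores and on-disk quarters for unit tests.

# store_from(): compact construction of a faers_store; missing columns get
# neutral defaults so tests only state what they care about.
store_from <- function(cases, drugs = NULL, reacs = NULL) {
  n <- nrow(cases)
  defaults <- data.frame(
    case_id = cases$case_id,
    version = cases$version %||% rep(1L, n),
    fda_dt_raw = cases$fda %||% rep("20240101", n),
    event_dt_raw = cases$event %||% rep("", n),
    sex = cases$sex %||% rep("unknown", n),
    age_years = cases$age_years %||% rep(NA_real_, n),
    weight_kg = cases$weight_kg %||% rep(NA_real_, n),
    reporter = cases$reporter %||% rep("unknown", n),
    country = cases$country %||% rep("US", n),
    outcomes = cases$outcomes %||% rep("", n),
    stringsAsFactors = FALSE)
  fda <- faersignal:::parse_partial_date(defaults$fda_dt_raw)
  evt <- faersignal:::parse_partial_date(defaults$event_dt_raw)
  defaults$fda_date <- fda$date
  defaults$event_date <- evt$date
  defaults$event_precision <- evt$precision
  defaults$report_year <- ifelse(is.na(fda$year), evt$year, fda$year)
  drugs <- drugs %||% data.frame(case_id = character(), drug_seq = integer(),
                                 role = character(),
                                 verbatim_name = character(),
                                 canonical_name = character(),
                                 indication_pt = character(),
                                 start_dt_raw = character(),
                                 stringsAsFactors = FALSE)
  if (is.null(drugs$canonical_name)) {
    drugs$canonical_name <- normalize_drug_name(drugs$verbatim_name)
  }
  if (is.null(drugs$indication_pt)) drugs$indication_pt <- NA_character_
  if (is.null(drugs$drug_seq)) drugs$drug_seq <- seq_len(nrow(drugs))
  st <- faersignal:::parse_partial_date(drugs$start_dt_raw %||%
                                          rep("", nrow(drugs)))
  drugs$start_dt_raw <- st$raw
  drugs$start_date <- st$date
  drugs$start_precision <- st$precision
  reacs <- reacs %||% data.frame(case_id = character(), pt = character(),
                                 stringsAsFactors = FALSE)
  faersignal:::new_faers_store(defaults, drugs, reacs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# drug-row shorthand
drug_row <- function(case_id, name, role = "PS", start = "", seq = 1L,
                     indication = NA_character_) {
  data.frame(case_id = case_id, drug_seq = seq, role = role,
             verbatim_name = name, start_dt_raw = start,
             indication_pt = indication, stringsAsFactors = FALSE)
}

reac_rows <- function(case_id, pts) {
  data.frame(case_id = rep(case_id, length(pts)), pt = pts,
             stringsAsFactors = FALSE)
}

# Write a tiny quarter to disk in either dialect; returns named file paths.
write_quarter_files <- function(demo, drug, reac, ther = NULL,
                                dialect = "simple-csv",
                                dir = withr::local_tempdir(
                                  .local_envir = parent.frame())) {
  sep <- if (dialect == "faers-ascii") "$" else ","
  files <- c(demo = file.path(dir, "DEMO.txt"),
             drug = file.path(dir, "DRUG.txt"),
             reac = file.path(dir, "REAC.txt"),
             ther = file.path(dir, "THER.txt"))
  utils::write.table(demo, files["demo"], sep = sep, row.names = FALSE,
                     quote = FALSE)
  utils::write.table(drug, files["drug"], sep = sep, row.names = FALSE,
                     quote = FALSE)
  utils::write.table(reac, files["reac"], sep = sep, row.names = FALSE,
                     quote = FALSE)
  if (!is.null(ther)) {
    utils::write.table(ther, files["ther"], sep = sep, row.names = FALSE,
                       quote = FALSE)
  } else {
    files <- files[c("demo", "drug", "reac")]
  }
  files
}

# naive re-implementations of the four statistics, used as the independent
# oracle: transliterated straight from the printed formulas, one value at a
# time, no sharing with the package internals.
naive_metrics <- function(a, b, c, d) {
  a <- as.double(a); b <- as.double(b); c <- as.double(c); d <- as.double(d)
  if (a == 0 || b == 0 || c == 0 || d == 0) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  N <- a + b + c + d
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  ror <- (a * d) / (b * c)
  prr <- (a / (a + b)) / (c / (c + d))
  chi2 <- (a * d - b * c)^2 * N / ((a + b) * (c + d) * (a + c) * (b + d))
  ic <- log2(a * N / ((a + c) * (a + b)))
  ebgm <- a * N / ((a + c) * (a + b))
  list(ror = ror, ror_low = exp(log(ror) - 1.96 * se),
       ror_high = exp(log(ror) + 1.96 * se),
       prr = prr, chi2 = chi2,
       ic = ic, ic025 = ic - 1.96 * se / log(2),
       ebgm = ebgm, ebgm05 = exp(log(ebgm) - 1.96 * se))
}

# Materialize a generate_reports() result as a deduplicated store via the
# normal file round trip.
store_from_generated <- function(gen, dir = withr::local_tempdir(
                                   .local_envir = parent.frame())) {
  files <- write_quarter_files(gen$demo, gen$drug, gen$reac, gen$ther,
                               dir = dir)
  deduplicate(read_quarter(files["demo"], files["drug"], files["reac"],
                           files["ther"]))
}
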