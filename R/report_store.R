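#' @title Spontaneous-report store: ingestion, deduplication, case selection
#' @description Functions that read FAERS-style quarterly files (DEMO, DRUG,
#'   REAC, THER), deduplicate case versions, normalize drug names through a
#'   synonym table and select reports with a target drug as primary suspect.
#' @name report_store
NULL

# column vocabularies for the two supported dialects (identical names; only
# the delimiter differs: "$" for faers-ascii, "," for simple-csv)
.demo_cols <- c("caseid", "caseversion", "fda_dt", "event_dt", "sex", "age",
                "age_cod", "wt", "occp_cod", "occr_country", "outc_cod")
.drug_cols <- c("caseid", "drug_seq", "role_cod", "drugname", "indi_pt")
.reac_cols <- c("caseid", "pt")
.ther_cols <- c("caseid", "dsg_drug_seq", "start_dt")

new_faers_store <- function(demo, drug, reac, log = NULL) {
  structure(list(demo = demo, drug = drug, reac = reac,
                 log = log %||% empty_log()),
            class = "faers_store")
}

empty_log <- function() {
  data.frame(stage = character(), metric = character(), value = numeric(),
             stringsAsFactors = FALSE)
}

log_add <- function(log, stage, metric, value) {
  rbind(log, data.frame(stage = stage, metric = metric,
                        value = as.numeric(value), stringsAsFactors = FALSE))
}

# Delimited reader with malformed-row accounting. Fields must not contain the
# delimiter (FAERS ASCII guarantees this; the simple-csv dialect assumes it).
# Returns list(data = data.frame of character columns, n_malformed).
read_delim_logged <- function(path, sep) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) {
    stop("file has no header row: ", path, call. = FALSE)
  }
  split_fields <- function(line) {
    # sentinel keeps trailing empty fields; blank line -> single empty field
    out <- strsplit(paste0(line, sep, "\x01"), sep, fixed = TRUE)[[1]]
    out[-length(out)]
  }
  header <- tolower(trimws(split_fields(lines[1L])))
  body <- lines[-1L]  # blank rows stay and are counted as malformed
  fields <- lapply(body, split_fields)
  ok <- vapply(fields, length, 1L) == length(header)
  n_malformed <- sum(!ok)
  if (any(ok)) {
    mat <- do.call(rbind, fields[ok])
    data <- as.data.frame(mat, stringsAsFactors = FALSE)
    names(data) <- header
  } else {
    data <- as.data.frame(matrix(character(), ncol = length(header),
                                 dimnames = list(NULL, header)),
                          stringsAsFactors = FALSE)
  }
  list(data = data, n_malformed = n_malformed)
}

# ensure expected columns exist (missing optional columns become NA)
with_cols <- function(df, cols) {
  for (cl in setdiff(cols, names(df))) df[[cl]] <- NA_character_
  df[, cols, drop = FALSE]
}

#' Read one FAERS-style quarter into a report store
#'
#' Loads the DEMO, DRUG, REAC and (optionally) THER tables of a quarterly
#' extract, parses dates and demographics, normalizes drug names and links
#' therapy start dates onto drug rows by `(caseid, drug_seq)`. Rows whose
#' field count does not match the header are counted in the provenance log
#' and skipped, never fatal. No deduplication is performed here; see
#' [deduplicate()].
#'
#' @param demo_path,drug_path,reac_path paths to the DEMO/DRUG/REAC tables.
#' @param ther_path optional path to the THER table with therapy start dates.
#' @param dialect `"simple-csv"` (comma-separated, header row) or
#'   `"faers-ascii"` (the FDA's `"$"`-delimited quarterly format).
#' @param synonyms drug-synonym table used by [normalize_drug_name()].
#' @return A `faers_store`: list with `demo`, `drug`, `reac` data frames and
#'   a provenance `log` of row counts in/out of every step.
#' @examples
#' dir <- tempfile(); cfg <- synth_config(n_target_cases = 20,
#'                                        n_background_cases = 50, seed = 1)
#' gen <- generate_reports(cfg, dir = dir)
#' store <- read_quarter(gen$files["demo"], gen$files["drug"],
#'                       gen$files["reac"], gen$files["ther"])
#' store
#' @export
read_quarter <- function(demo_path, drug_path, reac_path, ther_path = NULL,
                         dialect = c("simple-csv", "faers-ascii"),
                         synonyms = default_drug_synonyms()) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "faers-ascii") "$" else ","
  paths <- c(DEMO = demo_path, DRUG = drug_path, REAC = reac_path)
  if (!is.null(ther_path)) paths <- c(paths, THER = ther_path)
  for (nm in names(paths)) {
    if (!file.exists(paths[[nm]])) {
      stop(nm, " file not found: ", paths[[nm]], call. = FALSE)
    }
  }
  log <- empty_log()

  raw_demo <- read_delim_logged(demo_path, sep)
  raw_drug <- read_delim_logged(drug_path, sep)
  raw_reac <- read_delim_logged(reac_path, sep)
  log <- log_add(log, "read", "demo_rows", nrow(raw_demo$data))
  log <- log_add(log, "read", "drug_rows", nrow(raw_drug$data))
  log <- log_add(log, "read", "reac_rows", nrow(raw_reac$data))
  log <- log_add(log, "read", "demo_malformed", raw_demo$n_malformed)
  log <- log_add(log, "read", "drug_malformed", raw_drug$n_malformed)
  log <- log_add(log, "read", "reac_malformed", raw_reac$n_malformed)

  d <- with_cols(raw_demo$data, .demo_cols)
  fda <- parse_partial_date(d$fda_dt)
  evt <- parse_partial_date(d$event_dt)
  sex <- tolower(trimws(d$sex))
  sex <- ifelse(sex %in% c("m", "male"), "male",
                ifelse(sex %in% c("f", "female"), "female", "unknown"))
  occp <- toupper(trimws(ifelse(is.na(d$occp_cod), "", d$occp_cod)))
  reporter <- c(CN = "consumer", MD = "physician", PH = "pharmacist",
                OT = "other", LW = "other", HP = "physician")[occp]
  reporter[is.na(reporter)] <- "unknown"
  country <- toupper(trimws(ifelse(is.na(d$occr_country), "", d$occr_country)))
  country[country == ""] <- "unknown"
  demo <- data.frame(
    case_id = trimws(d$caseid),
    version = as_int(d$caseversion),
    fda_dt_raw = fda$raw, fda_date = fda$date,
    event_dt_raw = evt$raw, event_date = evt$date,
    event_precision = evt$precision,
    sex = sex,
    age_years = age_to_years(d$age, d$age_cod),
    weight_kg = as_num(d$wt),
    reporter = unname(reporter),
    country = country,
    outcomes = toupper(trimws(ifelse(is.na(d$outc_cod), "", d$outc_cod))),
    report_year = ifelse(is.na(fda$year), evt$year, fda$year),
    stringsAsFactors = FALSE)
  demo$version[is.na(demo$version)] <- 0L
  demo <- demo[nzchar(demo$case_id), , drop = FALSE]

  dr <- with_cols(raw_drug$data, .drug_cols)
  drug <- data.frame(
    case_id = trimws(dr$caseid),
    drug_seq = as_int(dr$drug_seq),
    role = toupper(trimws(ifelse(is.na(dr$role_cod), "", dr$role_cod))),
    verbatim_name = ifelse(is.na(dr$drugname), "", dr$drugname),
    canonical_name = normalize_drug_name(dr$drugname, synonyms),
    indication_pt = ifelse(is.na(dr$indi_pt) | !nzchar(trimws(dr$indi_pt)),
                           NA_character_, trimws(dr$indi_pt)),
    stringsAsFactors = FALSE)
  drug <- drug[nzchar(drug$case_id), , drop = FALSE]

  rc <- with_cols(raw_reac$data, .reac_cols)
  reac <- data.frame(case_id = trimws(rc$caseid), pt = trimws(rc$pt),
                     stringsAsFactors = FALSE)
  reac <- reac[nzchar(reac$case_id) & nzchar(reac$pt), , drop = FALSE]

  drug$start_dt_raw <- ""
  drug$start_date <- as.Date(NA)
  drug$start_precision <- "none"
  if (!is.null(ther_path)) {
    raw_ther <- read_delim_logged(ther_path, sep)
    log <- log_add(log, "read", "ther_rows", nrow(raw_ther$data))
    log <- log_add(log, "read", "ther_malformed", raw_ther$n_malformed)
    th <- with_cols(raw_ther$data, .ther_cols)
    st <- parse_partial_date(th$start_dt)
    key_th <- paste(trimws(th$caseid), as_int(th$dsg_drug_seq))
    key_dr <- paste(drug$case_id, drug$drug_seq)
    idx <- match(key_dr, key_th)
    hit <- !is.na(idx)
    drug$start_dt_raw[hit] <- st$raw[idx[hit]]
    drug$start_date[hit] <- st$date[idx[hit]]
    drug$start_precision[hit] <- st$precision[idx[hit]]
  }

  log <- log_add(log, "parse", "cases_loaded", length(unique(demo$case_id)))
  new_faers_store(demo, drug, reac, log)
}

#' Deduplicate case versions in a report store
#'
#' Spontaneous-report databases carry multiple versions of the same case.
#' For each unique case identifier the version with the most recent FDA
#' receipt date is retained; ties are broken by the highest report version,
#' remaining ties by last-seen input order (stable). Absent dates sort
#' lowest. Drug and reaction rows of cases that disappear entirely are
#' dropped with the discarded versions.
#'
#' @param store a `faers_store` from [read_quarter()].
#' @return A deduplicated `faers_store` (one demo row per `case_id`).
#' @export
deduplicate <- function(store) {
  stopifnot(inherits(store, "faers_store"))
  demo <- store$demo
  n_in <- nrow(demo)
  if (n_in > 0L) {
    fda_key <- as.numeric(demo$fda_date)
    fda_key[is.na(fda_key)] <- -Inf
    ver_key <- demo$version
    ver_key[is.na(ver_key)] <- -Inf
    o <- order(fda_key, ver_key, seq_len(n_in))
    sorted <- demo[o, , drop = FALSE]
    keep_sorted <- !duplicated(sorted$case_id, fromLast = TRUE)
    keep_rows <- sort(o[keep_sorted])
    demo <- demo[keep_rows, , drop = FALSE]
    rownames(demo) <- NULL
  }
  ids <- demo$case_id
  drug <- unique(store$drug[store$drug$case_id %in% ids, , drop = FALSE])
  reac <- unique(store$reac[store$reac$case_id %in% ids, , drop = FALSE])
  rownames(drug) <- rownames(reac) <- NULL
  log <- log_add(store$log, "deduplicate", "versions_in", n_in)
  log <- log_add(log, "deduplicate", "cases_out", nrow(demo))
  new_faers_store(demo, drug, reac, log)
}

#' Built-in drug-synonym table
#'
#' Maps brand names and synonymous designations to an ingredient name; ships
#' with the roflumilast brand names (Daliresp, Daxas) and is extended by
#' passing additional rows or a user table to [read_drug_synonyms()].
#'
#' @return data.frame with columns `verbatim`, `canonical`.
#' @export
default_drug_synonyms <- function() {
  path <- system.file("extdata", "drug_synonyms.csv", package = "faersignal")
  read_drug_synonyms(path)
}

#' Read a two-column drug-synonym table
#'
#' @param path CSV with columns `verbatim`, `canonical`.
#' @return data.frame with normalized `verbatim` and lower-case `canonical`.
#' @export
read_drug_synonyms <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("verbatim", "canonical") %in% names(tab))) {
    stop("synonym table needs columns 'verbatim' and 'canonical'",
         call. = FALSE)
  }
  tab$verbatim <- normalize_drug_name(tab$verbatim, synonyms = NULL)
  tab$canonical <- tolower(trimws(tab$canonical))
  tab
}

#' Normalize a verbatim drug name
#'
#' Lower-cases, trims, collapses punctuation and repeated whitespace, then
#' maps through the synonym table (brand name to ingredient). Unmapped names
#' pass through in normalized form.
#'
#' @param verbatim character vector of raw drug names.
#' @param synonyms synonym data.frame (`verbatim`, `canonical`) or `NULL`
#'   for normalization without mapping.
#' @return character vector of canonical names.
#' @examples
#' normalize_drug_name("DALIRESP")        # "roflumilast"
#' normalize_drug_name("  Roflumilast ")  # "roflumilast"
#' @export
normalize_drug_name <- function(verbatim, synonyms = default_drug_synonyms()) {
  x <- tolower(trimws(as.character(verbatim)))
  x[is.na(x)] <- ""
  x <- gsub("[[:punct:]]+", " ", x)
  x <- gsub("\\s+", " ", x)
  x <- trimws(x)
  if (!is.null(synonyms) && nrow(synonyms) > 0L) {
    idx <- match(x, synonyms$verbatim)
    hit <- !is.na(idx)
    x[hit] <- synonyms$canonical[idx[hit]]
  }
  x
}

#' Select cases reporting the target drug as primary suspect
#'
#' Returns the case identifiers whose drug entries list the target canonical
#' name with role code `PS`. Cases carrying the drug only as secondary
#' suspect (`SS`), concomitant (`C`) or interacting (`I`) are excluded.
#'
#' @param store a deduplicated `faers_store`.
#' @param target canonical drug name (already normalized).
#' @return character vector of case identifiers (possibly empty).
#' @export
select_primary_suspect <- function(store, target = "roflumilast") {
  stopifnot(inherits(store, "faers_store"))
  hit <- store$drug$role == "PS" & store$drug$canonical_name == target
  sort(unique(store$drug$case_id[hit]))
}

#' Remove cases with incomplete critical fields
#'
#' Drops cases lacking any drug entry or any reaction entry; removal counts
#' go to the provenance log. Event-date completeness is *not* enforced here:
#' partial or missing event dates only exclude a case from time-to-onset
#' analysis (see [compute_tto()]), not from signal detection.
#'
#' @param store a deduplicated `faers_store`.
#' @return filtered `faers_store`.
#' @export
apply_completeness_filter <- function(store) {
  stopifnot(inherits(store, "faers_store"))
  has_drug <- store$demo$case_id %in% store$drug$case_id
  has_reac <- store$demo$case_id %in% store$reac$case_id
  keep <- has_drug & has_reac
  demo <- store$demo[keep, , drop = FALSE]
  ids <- demo$case_id
  log <- log_add(store$log, "completeness", "removed_no_drug", sum(!has_drug))
  log <- log_add(log, "completeness", "removed_no_reaction",
                 sum(has_drug & !has_reac))
  log <- log_add(log, "completeness", "cases_out", nrow(demo))
  new_faers_store(demo,
                  store$drug[store$drug$case_id %in% ids, , drop = FALSE],
                  store$reac[store$reac$case_id %in% ids, , drop = FALSE],
                  log)
}

#' Serialize a report store to per-table CSV files plus a provenance log
#'
#' @param store a `faers_store`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_store <- function(store, dir) {
  stopifnot(inherits(store, "faers_store"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("demo.csv", "drug.csv", "reac.csv",
                            "provenance.txt"))
  utils::write.csv(store$demo, paths[1], row.names = FALSE)
  utils::write.csv(store$drug, paths[2], row.names = FALSE)
  utils::write.csv(store$reac, paths[3], row.names = FALSE)
  writeLines(sprintf("%-14s %-22s %g", store$log$stage, store$log$metric,
                     store$log$value), paths[4])
  invisible(paths)
}

#' @export
print.faers_store <- function(x, ...) {
  cat("<faers_store>\n")
  cat(sprintf("  cases:     %d (%d demo rows)\n",
              length(unique(x$demo$case_id)), nrow(x$demo)))
  cat(sprintf("  drug rows: %d\n", nrow(x$drug)))
  cat(sprintf("  reactions: %d (%d distinct PTs)\n",
              nrow(x$reac), length(unique(x$reac$pt))))
  invisible(x)
}
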