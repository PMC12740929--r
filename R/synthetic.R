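#' @title Seeded FAERS-like synthetic data with a ground-truth answer key
#' @description Generates quarterly-style DEMO/DRUG/REAC/THER tables whose
#'   structure mirrors a spontaneous-report database: case identifiers with
#'   multiple report versions, PS/SS/C/I drug roles, one-to-many case-to-PT
#'   reactions, partially missing demographics and dates, Weibull-distributed
#'   onset latencies, and drug-event associations injected at configurable
#'   relative risk. Every draw comes from the single seed in the config, so
#'   identical configs produce byte-identical files, and the returned ground
#'   truth records what was planted for recovery tests.
#' @name synthetic_data
NULL

.default_pt_vocab <- function() {
  data.frame(
    pt = c("Diarrhoea", "Nausea", "Vomiting", "Abdominal pain",
           "Insomnia", "Anxiety", "Depression", "Suicidal ideation",
           "Headache", "Dizziness", "Tremor",
           "Fatigue", "Drug ineffective", "Malaise",
           "Dyspnoea", "Cough", "Chronic obstructive pulmonary disease",
           "Weight decreased", "Heart rate increased",
           "Decreased appetite", "Back pain", "Arthralgia",
           "Fall", "Overdose"),
    soc = c(rep("Gastrointestinal disorders", 4),
            rep("Psychiatric disorders", 4),
            rep("Nervous system disorders", 3),
            rep("General disorders and administration site conditions", 3),
            rep("Respiratory, thoracic and mediastinal disorders", 3),
            rep("Investigations", 2),
            "Metabolism and nutrition disorders",
            rep("Musculoskeletal and connective tissue disorders", 2),
            rep("Injury, poisoning and procedural complications", 2)),
    p_background = c(0.06, 0.05, 0.04, 0.03,
                     0.04, 0.04, 0.03, 0.01,
                     0.06, 0.05, 0.02,
                     0.06, 0.08, 0.04,
                     0.06, 0.05, 0.01,
                     0.03, 0.02,
                     0.03, 0.04, 0.03,
                     0.04, 0.02),
    stringsAsFactors = FALSE)
}

.default_injected <- function() {
  data.frame(pt = c("Insomnia", "Weight decreased", "Decreased appetite",
                    "Tremor", "Suicidal ideation"),
             rr = c(8, 8, 8, 8, 12),
             stringsAsFactors = FALSE)
}

#' Configuration for the synthetic report generator
#'
#' Defaults emulate the study conditions of a primary-suspect
#' pharmacovigilance analysis at tractable scale: 500 target cases against a
#' 20,000-case background (a 40:1 case/non-case asymmetry standing in for
#' the full database), onset latencies drawn from Weibull(shape 0.573,
#' scale 38.653 days) — an early-failure pattern — demographics dominated by
#' older patients with heavy missingness, and five adverse events injected
#' at relative risk 8-12 against baseline reporting probabilities of
#' 0.01-0.04.
#'
#' @param seed integer seed driving every draw.
#' @param n_target_cases,n_background_cases case counts.
#' @param target_drug canonical target drug name.
#' @param target_variants verbatim spellings emitted for the target
#'   (brand-name synonyms, mixed case, stray whitespace).
#' @param background_drugs verbatim names for the background vocabulary.
#' @param pt_vocab data.frame `pt`, `soc`, `p_background`: the PT
#'   vocabulary, its toy PT-to-SOC map, and baseline per-case reporting
#'   probabilities.
#' @param injected_signals data.frame `pt`, `rr`: multiplies the baseline
#'   probability for target cases (the planted signals).
#' @param reaction_intensity scalar multiplying all baseline probabilities
#'   (reaction multiplicity dial; each case is conditioned on reporting at
#'   least one PT).
#' @param duplicate_rate fraction of cases emitted as two report versions
#'   (the earlier version differs only in FDA receipt date and version).
#' @param missing_date_rate fraction of target cases whose event or start
#'   date is missing or partial.
#' @param inconsistent_date_rate fraction of target cases with onset before
#'   therapy start (must be excluded from TTO downstream).
#' @param target_concomitant_rate fraction of background cases carrying the
#'   target drug in a concomitant (non-PS) role.
#' @param tto_shape_beta,tto_scale_alpha_days Weibull onset parameters.
#' @param demographics list of sampling parameters (see defaults in the
#'   function definition).
#' @return list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_target_cases = 500L,
                         n_background_cases = 20000L,
                         target_drug = "roflumilast",
                         target_variants = c("Roflumilast", "DALIRESP",
                                             "Daxas", " roflumilast "),
                         background_drugs = c("Metformin", "Lisinopril",
                                              "Atorvastatin", "Salbutamol",
                                              "Tiotropium", "Prednisone",
                                              "Omeprazole", "Amoxicillin"),
                         pt_vocab = .default_pt_vocab(),
                         injected_signals = .default_injected(),
                         reaction_intensity = 1,
                         duplicate_rate = 0.10,
                         missing_date_rate = 0.15,
                         inconsistent_date_rate = 0.02,
                         target_concomitant_rate = 0.02,
                         tto_shape_beta = 0.573,
                         tto_scale_alpha_days = 38.653,
                         demographics = list()) {
  if (nrow(pt_vocab) == 0L) stop("empty PT vocabulary", call. = FALSE)
  if (length(background_drugs) == 0L) {
    stop("empty drug vocabulary", call. = FALSE)
  }
  if (!all(injected_signals$pt %in% pt_vocab$pt)) {
    stop("injected signal PTs must be in the PT vocabulary", call. = FALSE)
  }
  if (any(injected_signals$rr <= 0)) {
    stop("relative-risk multipliers must be positive", call. = FALSE)
  }
  probs <- pt_vocab$p_background * reaction_intensity
  if (any(probs < 0 | probs > 1)) {
    stop("baseline probabilities must lie in [0, 1]", call. = FALSE)
  }
  dem <- utils::modifyList(list(
    sex_probs = c(male = 0.45, female = 0.41, unknown = 0.14),
    age_unknown = 0.43, age_mean = 68, age_sd = 12,
    weight_unknown = 0.72, weight_mean = 75, weight_sd = 16,
    reporter_probs = c(CN = 0.35, MD = 0.24, PH = 0.03, OT = 0.29,
                       unknown = 0.09),
    country_probs = c(US = 0.78, DE = 0.17, CA = 0.02, KR = 0.01,
                      DK = 0.005, GB = 0.015),
    outcome_none = 0.31,
    outcome_probs = c(OT = 0.325, HO = 0.295, DE = 0.25, RI = 0.082,
                      LT = 0.037, DS = 0.0145, CA = 0.0005),
    outcome_second_rate = 0.16), demographics)
  structure(list(
    seed = as.integer(seed),
    n_target_cases = as.integer(n_target_cases),
    n_background_cases = as.integer(n_background_cases),
    target_drug = target_drug, target_variants = target_variants,
    background_drugs = background_drugs,
    pt_vocab = pt_vocab, injected_signals = injected_signals,
    reaction_intensity = reaction_intensity,
    duplicate_rate = duplicate_rate,
    missing_date_rate = missing_date_rate,
    inconsistent_date_rate = inconsistent_date_rate,
    target_concomitant_rate = target_concomitant_rate,
    tto_shape_beta = tto_shape_beta,
    tto_scale_alpha_days = tto_scale_alpha_days,
    demographics = dem), class = "synth_config")
}

# Per-case PT indicator matrix: independent Bernoulli per PT with the
# target-case probabilities multiplied by injected RR, conditioned on at
# least one reaction by redrawing empty rows. Under this conditioning the
# expected count for PT j is n * p_j / P(>=1 reaction), which the ground
# truth reports exactly.
draw_reactions <- function(n, probs) {
  p <- matrix(probs, nrow = n, ncol = length(probs), byrow = TRUE)
  hit <- matrix(stats::runif(n * length(probs)), n) < p
  empty <- which(rowSums(hit) == 0L)
  while (length(empty) > 0L) {
    redraw <- matrix(stats::runif(length(empty) * length(probs)),
                     length(empty)) < p[empty, , drop = FALSE]
    hit[empty, ] <- redraw
    empty <- empty[rowSums(redraw) == 0L]
  }
  hit
}

fmt_date <- function(d) format(d, "%Y%m%d")

#' Generate a seeded synthetic report dataset
#'
#' Target cases receive the target drug as primary suspect (under a random
#' verbatim variant) and Weibull-latency onset dates; background cases get
#' background drugs, with a small fraction carrying the target in a
#' concomitant role. A `duplicate_rate` fraction of cases is emitted twice
#' (an extra earlier report version). Reactions are drawn per PT with
#' injected relative risks applied to target cases.
#'
#' @param config a [synth_config()].
#' @param dir if non-`NULL`, write `demo/drug/reac/ther` files there.
#' @param dialect output file dialect (see [read_quarter()]).
#' @return list with `demo`, `drug`, `reac`, `ther` data frames (raw file
#'   columns), `files` (named paths, when `dir` given) and `truth`, the
#'   ground-truth key: `expected_target_count`/`expected_background_count`
#'   per PT, the injected-signal table, the generating Weibull parameters,
#'   the emitted duplicate map and the emitted row counts.
#' @export
generate_reports <- function(config = synth_config(), dir = NULL,
                             dialect = c("simple-csv", "faers-ascii")) {
  stopifnot(inherits(config, "synth_config"))
  dialect <- match.arg(dialect)
  set.seed(config$seed)
  dem <- config$demographics
  n_t <- config$n_target_cases
  n_b <- config$n_background_cases
  n <- n_t + n_b
  case_id <- sprintf("%07d", seq_len(n) + 1000000L)
  is_target <- c(rep(TRUE, n_t), rep(FALSE, n_b))

  # reaction draws --------------------------------------------------------
  p_bg <- config$pt_vocab$p_background * config$reaction_intensity
  rr <- rep(1, nrow(config$pt_vocab))
  idx <- match(config$injected_signals$pt, config$pt_vocab$pt)
  rr[idx] <- config$injected_signals$rr
  p_tg <- pmin(p_bg * rr, 0.95)
  hits <- matrix(FALSE, n, nrow(config$pt_vocab))
  if (n_t > 0) hits[is_target, ] <- draw_reactions(n_t, p_tg)
  if (n_b > 0) hits[!is_target, ] <- draw_reactions(n_b, p_bg)
  hit_idx <- which(hits, arr.ind = TRUE)
  reac <- data.frame(caseid = case_id[hit_idx[, 1]],
                     pt = config$pt_vocab$pt[hit_idx[, 2]],
                     stringsAsFactors = FALSE)
  reac <- reac[order(match(reac$caseid, case_id), reac$pt), , drop = FALSE]

  # drugs ----------------------------------------------------------------
  ps_name <- character(n)
  ps_name[is_target] <- sample(config$target_variants, n_t, replace = TRUE)
  ps_name[!is_target] <- sample(config$background_drugs, n_b, replace = TRUE)
  n_extra <- sample(0:2, n, replace = TRUE, prob = c(0.5, 0.35, 0.15))
  extra_rows <- data.frame()
  if (sum(n_extra) > 0) {
    owner <- rep(seq_len(n), n_extra)
    extra_rows <- data.frame(
      caseid = case_id[owner],
      drug_seq = unlist(lapply(n_extra[n_extra > 0], function(k) 1 + seq_len(k))),
      role_cod = sample(c("SS", "C", "I"), sum(n_extra), replace = TRUE,
                        prob = c(0.3, 0.6, 0.1)),
      drugname = sample(config$background_drugs, sum(n_extra),
                        replace = TRUE),
      indi_pt = "", stringsAsFactors = FALSE)
  }
  # some background cases carry the target drug concomitantly (never PS)
  conc <- !is_target & stats::runif(n) < config$target_concomitant_rate
  if (any(conc)) {
    extra_rows <- rbind(extra_rows, data.frame(
      caseid = case_id[conc], drug_seq = 9L, role_cod = "C",
      drugname = sample(config$target_variants, sum(conc), replace = TRUE),
      indi_pt = "", stringsAsFactors = FALSE))
  }
  indication <- ifelse(is_target,
                       sample(c("Chronic obstructive pulmonary disease",
                                "Psoriasis", "Asthma", ""),
                              n, replace = TRUE,
                              prob = c(0.72, 0.08, 0.05, 0.15)),
                       "")
  drug <- rbind(data.frame(caseid = case_id, drug_seq = 1L, role_cod = "PS",
                           drugname = ps_name, indi_pt = indication,
                           stringsAsFactors = FALSE),
                extra_rows)
  drug <- drug[order(match(drug$caseid, case_id), drug$drug_seq), ,
               drop = FALSE]

  # dates and time-to-onset ----------------------------------------------
  fda_date <- as.Date("2011-01-01") +
    sample.int(5200L, n, replace = TRUE)          # receipts 2011-2025
  start_date <- fda_date - sample.int(540L, n, replace = TRUE)
  # calendar-date truncation: an event T days after start falls on the date
  # start + floor(T), so same-day onsets yield a 0-day interval
  latency <- floor(stats::rweibull(n, shape = config$tto_shape_beta,
                                   scale = config$tto_scale_alpha_days))
  event_date <- start_date + latency
  u <- stats::runif(n)
  miss <- u < config$missing_date_rate
  incons <- !miss & u < config$missing_date_rate + config$inconsistent_date_rate
  event_dt <- fmt_date(event_date)
  # half the "missing" events are absent, half only month-precision
  half <- miss & stats::runif(n) < 0.5
  event_dt[miss & !half] <- ""
  event_dt[half] <- substr(fmt_date(event_date[half]), 1, 6)
  event_dt[incons] <- fmt_date(start_date[incons] -
                                 sample.int(60L, sum(incons), replace = TRUE))
  start_dt <- fmt_date(start_date)
  start_dt[stats::runif(n) < config$missing_date_rate / 2] <- ""

  # demographics ----------------------------------------------------------
  sex <- sample(c("M", "F", ""), n, replace = TRUE, prob = dem$sex_probs)
  age <- round(stats::rnorm(n, dem$age_mean, dem$age_sd))
  age <- pmin(pmax(age, 18), 97)
  age[stats::runif(n) < dem$age_unknown] <- NA
  wt <- round(stats::rnorm(n, dem$weight_mean, dem$weight_sd), 1)
  wt[stats::runif(n) < dem$weight_unknown] <- NA
  occp <- sample(c("CN", "MD", "PH", "OT", ""), n, replace = TRUE,
                 prob = dem$reporter_probs)
  country <- sample(names(dem$country_probs), n, replace = TRUE,
                    prob = dem$country_probs)
  oc <- names(dem$outcome_probs)
  first <- sample(oc, n, replace = TRUE, prob = dem$outcome_probs)
  second <- sample(oc, n, replace = TRUE, prob = dem$outcome_probs)
  outc <- ifelse(stats::runif(n) < dem$outcome_none, "",
                 ifelse(stats::runif(n) < dem$outcome_second_rate &
                          second != first,
                        paste(first, second, sep = ";"), first))

  demo <- data.frame(
    caseid = case_id, caseversion = 2L, fda_dt = fmt_date(fda_date),
    event_dt = event_dt, sex = sex,
    age = ifelse(is.na(age), "", age), age_cod = ifelse(is.na(age), "", "YR"),
    wt = ifelse(is.na(wt), "", wt),
    occp_cod = occp, occr_country = country, outc_cod = outc,
    stringsAsFactors = FALSE)

  # duplicate versions: same case, earlier receipt, lower version number
  dup <- stats::runif(n) < config$duplicate_rate
  if (any(dup)) {
    first_version <- demo[dup, , drop = FALSE]
    first_version$caseversion <- 1L
    first_version$fda_dt <- fmt_date(fda_date[dup] -
                                       sample.int(90L, sum(dup),
                                                  replace = TRUE))
    demo <- rbind(first_version, demo)   # earlier versions listed first
    demo <- demo[order(match(demo$caseid, case_id), demo$caseversion), ,
                 drop = FALSE]
  }

  ther <- data.frame(caseid = case_id, dsg_drug_seq = 1L,
                     start_dt = start_dt, stringsAsFactors = FALSE)
  ther <- ther[nzchar(ther$start_dt), , drop = FALSE]
  rownames(demo) <- rownames(drug) <- rownames(reac) <- rownames(ther) <- NULL

  p_any_t <- 1 - prod(1 - p_tg)
  p_any_b <- 1 - prod(1 - p_bg)
  truth <- list(
    target_case_ids = case_id[is_target],
    expected_pt_counts = data.frame(
      pt = config$pt_vocab$pt,
      expected_target_count = n_t * p_tg / p_any_t,
      expected_background_count = n_b * p_bg / p_any_b,
      stringsAsFactors = FALSE),
    injected_signals = config$injected_signals,
    tto_shape_beta = config$tto_shape_beta,
    tto_scale_alpha_days = config$tto_scale_alpha_days,
    duplicate_map = stats::setNames(ifelse(dup, 2L, 1L), case_id),
    emitted = c(demo_rows = nrow(demo), drug_rows = nrow(drug),
                reac_rows = nrow(reac), ther_rows = nrow(ther),
                cases = n))

  out <- list(demo = demo, drug = drug, reac = reac, ther = ther,
              truth = truth, config = config)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    sep <- if (dialect == "faers-ascii") "$" else ","
    ext <- if (dialect == "faers-ascii") "txt" else "csv"
    files <- c(demo = file.path(dir, paste0("DEMO.", ext)),
               drug = file.path(dir, paste0("DRUG.", ext)),
               reac = file.path(dir, paste0("REAC.", ext)),
               ther = file.path(dir, paste0("THER.", ext)))
    for (nm in names(files)) {
      utils::write.table(out[[nm]], files[[nm]], sep = sep, row.names = FALSE,
                         quote = FALSE)
    }
    truth_path <- file.path(dir, "ground_truth.json")
    jsonlite::write_json(truth[c("injected_signals", "tto_shape_beta",
                                 "tto_scale_alpha_days", "emitted")],
                         truth_path, auto_unbox = TRUE, digits = NA)
    out$files <- files
    out$truth_file <- truth_path
  }
  invisible(out)
}

#' Toy PT-to-SOC map matching the default synthetic vocabulary
#'
#' @param config a [synth_config()].
#' @return data.frame `pt`, `soc`.
#' @export
synth_pt_soc_map <- function(config = synth_config()) {
  config$pt_vocab[, c("pt", "soc")]
}
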