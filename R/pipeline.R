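#' @title Pipeline commands: ingest, signals, tto, describe, simulate, report
#' @description Thin orchestration over the analysis modules, mirroring the
#'   end-to-end workflow: read and deduplicate a quarter, select
#'   primary-suspect cases, run disproportionality at PT and SOC level,
#'   summarize time-to-onset with the Weibull fit, and write descriptive
#'   tables — every command writing CSV outputs plus a machine-readable run
#'   manifest. The `faerspv` script under `inst/scripts/` exposes the same
#'   commands from a shell.
#' @name cli_pipeline
NULL

write_manifest <- function(out_dir, command, params, counts) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(command = command, params = params, counts = as.list(counts)),
    file.path(out_dir, paste0(command, "_manifest.json")),
    auto_unbox = TRUE, digits = NA, null = "null")
}

#' Simulate a synthetic quarter to disk
#'
#' @param out_dir output directory for the DEMO/DRUG/REAC/THER files, the
#'   ground-truth sidecar and the manifest.
#' @param seed integer seed (overrides the config's).
#' @param config a [synth_config()].
#' @param dialect output dialect.
#' @return invisibly, the [generate_reports()] result.
#' @export
pv_simulate <- function(out_dir, seed = NULL, config = synth_config(),
                        dialect = "simple-csv") {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  gen <- generate_reports(config, dir = out_dir, dialect = dialect)
  write_manifest(out_dir, "simulate",
                 list(seed = config$seed, dialect = dialect,
                      n_target_cases = config$n_target_cases,
                      n_background_cases = config$n_background_cases),
                 gen$truth$emitted)
  invisible(gen)
}

#' Ingest a quarter: read, deduplicate, completeness-filter
#'
#' @param demo_path,drug_path,reac_path,ther_path input tables.
#' @param dialect input dialect (see [read_quarter()]).
#' @param synonyms_path optional drug-synonym CSV; defaults to the built-in
#'   table.
#' @param out_dir optional directory for the serialized store and manifest.
#' @return the filtered `faers_store`.
#' @export
pv_ingest <- function(demo_path, drug_path, reac_path, ther_path = NULL,
                      dialect = "simple-csv", synonyms_path = NULL,
                      out_dir = NULL) {
  synonyms <- if (is.null(synonyms_path)) default_drug_synonyms()
              else read_drug_synonyms(synonyms_path)
  store <- read_quarter(demo_path, drug_path, reac_path, ther_path,
                        dialect = dialect, synonyms = synonyms)
  store <- apply_completeness_filter(deduplicate(store))
  if (!is.null(out_dir)) {
    write_store(store, out_dir)
    write_manifest(out_dir, "ingest",
                   list(dialect = dialect, demo = demo_path,
                        drug = drug_path, reac = reac_path),
                   c(cases = nrow(store$demo), drug_rows = nrow(store$drug),
                     reac_rows = nrow(store$reac)))
  }
  store
}

#' Run disproportionality signal detection at PT and SOC level
#'
#' @param store a deduplicated `faers_store` (e.g. from [pv_ingest()]).
#' @param drug canonical target drug name.
#' @param pt_soc_map data.frame or CSV path mapping PT to SOC.
#' @param criteria a [signal_criteria()].
#' @param out_dir optional directory for `signals_pt.csv`,
#'   `signals_soc.csv`, ranked tables and the manifest.
#' @return list with `pt` and `soc` signal tables and the ranked views
#'   `by_frequency`, `by_strength`.
#' @export
pv_signals <- function(store, drug = "roflumilast", pt_soc_map = NULL,
                       criteria = signal_criteria(), out_dir = NULL) {
  target <- select_primary_suspect(store, drug)
  pt_tables <- build_pt_tables(store, target)
  pt <- signal_metrics(pt_tables, criteria)
  soc <- NULL
  if (!is.null(pt_soc_map)) {
    if (is.character(pt_soc_map)) pt_soc_map <- read_pt_soc_map(pt_soc_map)
    soc <- signal_metrics(aggregate_soc(pt_tables, pt_soc_map), criteria)
  }
  out <- list(pt = pt, soc = soc,
              by_frequency = rank_signals(pt, "frequency"),
              by_strength = rank_signals(pt, "strength"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(pt, file.path(out_dir, "signals_pt.csv"),
                     row.names = FALSE)
    if (!is.null(soc)) {
      utils::write.csv(soc, file.path(out_dir, "signals_soc.csv"),
                       row.names = FALSE)
    }
    utils::write.csv(out$by_frequency,
                     file.path(out_dir, "signals_ranked_frequency.csv"),
                     row.names = FALSE)
    utils::write.csv(out$by_strength,
                     file.path(out_dir, "signals_ranked_strength.csv"),
                     row.names = FALSE)
    write_manifest(out_dir, "signals",
                   list(drug = drug, criteria = unclass(criteria)),
                   c(target_cases = length(target), pt_terms = nrow(pt),
                     pt_signals = sum(pt$is_signal)))
  }
  out
}

#' Time-to-onset summary and Weibull fit for the target drug
#'
#' @inheritParams pv_signals
#' @param out_dir optional output directory (`tto_bins.csv`,
#'   `tto_weibull.csv`, manifest).
#' @return list with `records`, `bins`, `quartiles` and `fit` (`NULL` when
#'   fewer than 10 usable records).
#' @export
pv_tto <- function(store, drug = "roflumilast", out_dir = NULL) {
  target <- select_primary_suspect(store, drug)
  records <- compute_tto(store, target, target = drug)
  bins <- bin_tto(records)
  quartiles <- if (nrow(records)) summarize_tto(records) else NULL
  fit <- if (nrow(records) >= 10L) fit_weibull(records) else NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(bins, file.path(out_dir, "tto_bins.csv"),
                     row.names = FALSE)
    if (!is.null(fit)) {
      utils::write.csv(summary(fit), file.path(out_dir, "tto_weibull.csv"),
                       row.names = FALSE)
    }
    write_manifest(out_dir, "tto", list(drug = drug),
                   c(records = nrow(records), attr(records, "exclusions")))
  }
  c(list(records = records, bins = bins, quartiles = quartiles, fit = fit))
}

#' Descriptive report-characteristics tables
#'
#' @inheritParams pv_signals
#' @param fields which characteristics to summarize.
#' @param out_dir optional output directory (one CSV per field plus
#'   `yearly_counts.csv` and the manifest).
#' @return named list of [categorical_summary()] tables plus `yearly` and
#'   `serious_outcome_pct`.
#' @export
pv_describe <- function(store, fields = c("sex", "age", "weight", "reporter",
                                          "country", "outcome", "indication",
                                          "year"),
                        out_dir = NULL) {
  tabs <- lapply(fields, function(f) summarize_categorical(store, f))
  names(tabs) <- fields
  yearly <- yearly_counts(store)
  serious <- if (nrow(store$demo)) serious_outcome_fraction(store) else NA
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (f in fields) {
      utils::write.csv(tabs[[f]],
                       file.path(out_dir, paste0("describe_", f, ".csv")),
                       row.names = FALSE)
    }
    utils::write.csv(yearly, file.path(out_dir, "yearly_counts.csv"),
                     row.names = FALSE)
    write_manifest(out_dir, "describe", list(fields = fields),
                   c(cases = nrow(store$demo),
                     serious_outcome_pct = serious))
  }
  c(tabs, list(yearly = yearly, serious_outcome_pct = serious))
}

#' Run the full workflow and collect all outputs in one directory
#'
#' @inheritParams pv_signals
#' @param out_dir directory receiving every module's CSV outputs and a
#'   combined manifest.
#' @return invisibly, list with `signals`, `tto`, `describe`.
#' @export
pv_report <- function(store, drug = "roflumilast", pt_soc_map = NULL,
                      criteria = signal_criteria(), out_dir) {
  signals <- pv_signals(store, drug, pt_soc_map, criteria, out_dir = out_dir)
  tto <- pv_tto(store, drug, out_dir = out_dir)
  desc <- pv_describe(store, out_dir = out_dir)
  write_manifest(out_dir, "report", list(drug = drug),
                 c(cases = nrow(store$demo),
                   pt_signals = sum(signals$pt$is_signal),
                   tto_records = nrow(tto$records)))
  invisible(list(signals = signals, tto = tto, describe = desc))
}

#' Read an INI-style key: value pipeline configuration file
#'
#' Lines of the form `key: value` (or `key = value`); `#` starts a comment.
#' Values are returned as strings; numeric-looking values are converted.
#'
#' @param path configuration file.
#' @return named list.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- lines[grepl("[:=]", lines)]
  keys <- trimws(sub("[:=].*$", "", lines))
  vals <- trimws(sub("^[^:=]*[:=]", "", lines))
  num <- suppressWarnings(as.numeric(vals))
  out <- lapply(seq_along(vals),
                function(i) if (is.na(num[i])) vals[i] else num[i])
  names(out) <- keys
  out
}
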