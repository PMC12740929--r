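test_that("read_quarter loads both dialects and counts malformed rows", {
  demo <- data.frame(caseid = c("101", "102", "103"), caseversion = 1,
                     fda_dt = "20240215", event_dt = c("20240110", "202401", ""),
                     sex = c("M", "F", ""), age = c(70, "", 55),
                     age_cod = "YR", wt = c("", 80, ""), occp_cod = "MD",
                     occr_country = "US", outc_cod = c("DE;HO", "", "OT"))
  drug <- data.frame(caseid = c("101", "102", "103"), drug_seq = 1,
                     role_cod = "PS",
                     drugname = c("DALIRESP", "Metformin", "Roflumilast"),
                     indi_pt = c("COPD", "", ""))
  reac <- data.frame(caseid = c("101", "101", "102", "103"),
                     pt = c("Nausea", "Insomnia", "Headache", "Diarrhoea"))
  ther <- data.frame(caseid = "101", dsg_drug_seq = 1, start_dt = "20240101")

  for (dialect in c("simple-csv", "faers-ascii")) {
    files <- write_quarter_files(demo, drug, reac, ther, dialect = dialect)
    store <- read_quarter(files["demo"], files["drug"], files["reac"],
                          files["ther"], dialect = dialect)
    expect_s3_class(store, "faers_store")
    expect_equal(nrow(store$demo), 3)
    expect_equal(sort(unique(store$demo$case_id)), c("101", "102", "103"))
    # date parsing: full, month-partial, absent
    expect_equal(store$demo$event_precision,
                 c("day", "month", "none"))
    expect_equal(store$demo$event_date[1], as.Date("2024-01-10"))
    expect_true(all(is.na(store$demo$event_date[2:3])))
    # demographics normalization
    expect_equal(store$demo$sex, c("male", "female", "unknown"))
    expect_equal(store$demo$outcomes[1], "DE;HO")
    # drug-name canonicalization incl. brand synonym
    expect_equal(store$drug$canonical_name,
                 c("roflumilast", "metformin", "roflumilast"))
    # therapy start linked by (caseid, drug_seq)
    expect_equal(store$drug$start_date[1], as.Date("2024-01-01"))
    expect_true(is.na(store$drug$start_date[2]))
  }
})

test_that("empty REAC file yields a store with zero reactions, no errors", {
  demo <- data.frame(caseid = "1", caseversion = 1, fda_dt = "20240101",
                     event_dt = "", sex = "M", age = "", age_cod = "",
                     wt = "", occp_cod = "", occr_country = "",
                     outc_cod = "")
  drug <- data.frame(caseid = "1", drug_seq = 1, role_cod = "PS",
                     drugname = "x", indi_pt = "")
  reac <- data.frame(caseid = character(), pt = character())
  files <- write_quarter_files(demo, drug, reac)
  store <- read_quarter(files["demo"], files["drug"], files["reac"])
  expect_equal(nrow(store$reac), 0)
  log <- store$log
  expect_equal(log$value[log$metric == "reac_malformed"], 0)
})

test_that("malformed rows are logged and skipped, not fatal", {
  dir <- withr::local_tempdir()
  demo_path <- file.path(dir, "DEMO.csv")
  writeLines(c("caseid,caseversion,fda_dt,event_dt,sex,age,age_cod,wt,occp_cod,occr_country,outc_cod",
               "7,1,20240101,,M,70,YR,,MD,US,",
               "",                      # zero-field row
               "8,1,too,few"), demo_path)
  drug_path <- file.path(dir, "DRUG.csv")
  reac_path <- file.path(dir, "REAC.csv")
  writeLines(c("caseid,drug_seq,role_cod,drugname,indi_pt",
               "7,1,PS,x,"), drug_path)
  writeLines(c("caseid,pt", "7,Nausea"), reac_path)
  store <- read_quarter(demo_path, drug_path, reac_path)
  expect_equal(nrow(store$demo), 1)
  expect_equal(store$log$value[store$log$metric == "demo_malformed"], 2)
})

test_that("missing files and unknown dialects are fatal with named errors", {
  drug <- data.frame(caseid = "1", drug_seq = 1, role_cod = "PS",
                     drugname = "x", indi_pt = "")
  reac <- data.frame(caseid = "1", pt = "Nausea")
  demo <- data.frame(caseid = "1", caseversion = 1, fda_dt = "20240101",
                     event_dt = "", sex = "", age = "", age_cod = "",
                     wt = "", occp_cod = "", occr_country = "", outc_cod = "")
  files <- write_quarter_files(demo, drug, reac)
  expect_error(read_quarter("/nonexistent/DEMO.txt", files["drug"],
                            files["reac"]),
               "DEMO.*nonexistent")
  expect_error(read_quarter(files["demo"], files["drug"], files["reac"],
                            dialect = "parquet"))
})

test_that("deduplicate keeps max fda date, then max version, stably", {
  cases <- data.frame(
    case_id = c("123", "123", "77", "55", "55", "55"),
    version = c(1L, 2L, 1L, 1L, 3L, 2L),
    fda = c("20240101", "20240301", "20230615",
            "20240501", "20240501", "20240501"))
  store <- store_from(cases)
  dd <- deduplicate(store)
  expect_equal(sort(dd$demo$case_id), c("123", "55", "77"))
  expect_equal(dd$demo$version[dd$demo$case_id == "123"], 2L)  # later fda
  expect_equal(dd$demo$version[dd$demo$case_id == "55"], 3L)   # fda tie -> max version
  # idempotence
  dd2 <- deduplicate(dd)
  expect_equal(dd2$demo[names(dd2$demo) != "row.names"],
               dd$demo[names(dd$demo) != "row.names"])
  # size never grows; survivors existed in input
  expect_lte(nrow(dd$demo), nrow(store$demo))
  expect_true(all(dd$demo$case_id %in% store$demo$case_id))
})

test_that("absent fda dates sort below any real date", {
  cases <- data.frame(case_id = c("9", "9"), version = c(5L, 1L),
                      fda = c("", "20200101"))
  dd <- deduplicate(store_from(cases))
  expect_equal(dd$demo$version, 1L)  # dated version wins despite lower number
})

test_that("equal fda date and version fall back to last-seen input order", {
  cases <- data.frame(case_id = c("4", "4"), version = c(1L, 1L),
                      fda = c("20240101", "20240101"),
                      sex = c("male", "female"))
  dd <- deduplicate(store_from(cases))
  expect_equal(dd$demo$sex, "female")
})

test_that("drug name normalization maps synonyms and passes others through", {
  expect_equal(normalize_drug_name("DALIRESP"), "roflumilast")
  expect_equal(normalize_drug_name("  Roflumilast "), "roflumilast")
  expect_equal(normalize_drug_name("Daxas."), "roflumilast")
  expect_equal(normalize_drug_name("aspirin"), "aspirin")
  expect_equal(normalize_drug_name("ASPIRIN  (extra-strength)"),
               "aspirin extra strength")
})

test_that("primary-suspect selection excludes non-PS roles", {
  cases <- data.frame(case_id = c("1", "2", "3"))
  drugs <- rbind(drug_row("1", "Daliresp", role = "PS"),
                 drug_row("2", "roflumilast", role = "C"),
                 drug_row("3", "metformin", role = "PS"))
  store <- store_from(cases, drugs)
  expect_equal(select_primary_suspect(store, "roflumilast"), "1")
  # empty store -> empty set
  empty <- store_from(data.frame(case_id = character()))
  expect_length(select_primary_suspect(empty, "roflumilast"), 0)
})

test_that("completeness filter drops cases without drugs or reactions", {
  cases <- data.frame(case_id = c("a", "b", "c"))
  drugs <- rbind(drug_row("a", "x"), drug_row("b", "y"))
  reacs <- reac_rows("a", "Nausea")
  store <- apply_completeness_filter(store_from(cases, drugs, reacs))
  expect_equal(store$demo$case_id, "a")     # b: no reaction; c: no drug
  log <- store$log
  expect_equal(log$value[log$metric == "removed_no_drug"], 1)
  expect_equal(log$value[log$metric == "removed_no_reaction"], 1)
  # a store of only incomplete cases empties out
  all_bad <- apply_completeness_filter(
    store_from(data.frame(case_id = c("q", "r"))))
  expect_equal(nrow(all_bad$demo), 0)
})

test_that("generator round-trip preserves record counts", {
  cfg <- synth_config(seed = 11, n_target_cases = 30,
                      n_background_cases = 120, duplicate_rate = 0.2)
  dir <- withr::local_tempdir()
  gen <- generate_reports(cfg, dir = dir)
  store <- read_quarter(gen$files["demo"], gen$files["drug"],
                        gen$files["reac"], gen$files["ther"])
  expect_equal(nrow(store$demo), unname(gen$truth$emitted["demo_rows"]))
  expect_equal(nrow(store$drug), unname(gen$truth$emitted["drug_rows"]))
  expect_equal(nrow(store$reac), unname(gen$truth$emitted["reac_rows"]))
  dd <- deduplicate(store)
  expect_equal(nrow(dd$demo), unname(gen$truth$emitted["cases"]))
  # every case_id resolves after dedup
  expect_true(all(dd$drug$case_id %in% dd$demo$case_id))
  expect_true(all(dd$reac$case_id %in% dd$demo$case_id))
})
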