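test_that("reading generated tables round-trips row counts", {
  ds <- small_dataset()
  for (tb in c("demo", "drug", "reac", "hist")) {
    n_lines <- length(readLines(ds$paths[[tb]])) - 1L
    expect_identical(nrow(ds$bundle[[tb]]), n_lines, label = tb)
  }
})

test_that("dose strings with unit suffixes are coerced and logged", {
  dir <- file.path(tempdir(), "io-dose")
  dir.create(dir, showWarnings = FALSE)
  writeLines(c("case_id,sex,age,reporting_year", "X1,male,60s,2020"),
             file.path(dir, "demo.csv"))
  writeLines(c("case_id,drug_name,role_code,daily_dose_g,start_date",
               "X1,Shosaikoto,suspected,2.5g,2020-01-01",
               "X1,Yokukansan,concomitant,abc,2020-01"),
             file.path(dir, "drug.csv"))
  writeLines("case_id,pt_code,pt_name,onset_date", file.path(dir, "reac.csv"))
  writeLines("case_id,disease_name", file.path(dir, "hist.csv"))
  b <- read_tables(file.path(dir, "demo.csv"), file.path(dir, "drug.csv"),
                   file.path(dir, "reac.csv"), file.path(dir, "hist.csv"))
  expect_identical(b$drug$daily_dose_g, c(2.5, NA_real_))
  expect_identical(b$parse_log$dose_unit_stripped, 1L)
  expect_identical(b$parse_log$dose_unparseable, 1L)
  # partial date becomes missing but is counted, not dropped
  expect_identical(b$parse_log$start_date_partial, 1L)
  expect_identical(nrow(b$drug), 2L)
  # header-only reaction table is fine
  expect_identical(nrow(b$reac), 0L)
})

test_that("a missing required column names the file and column", {
  dir <- file.path(tempdir(), "io-col")
  dir.create(dir, showWarnings = FALSE)
  writeLines(c("case_id,sex,age", "X1,male,60s"), file.path(dir, "demo.csv"))
  writeLines("case_id,drug_name,role_code,daily_dose_g,start_date", file.path(dir, "drug.csv"))
  writeLines("case_id,pt_code,pt_name,onset_date", file.path(dir, "reac.csv"))
  writeLines("case_id,disease_name", file.path(dir, "hist.csv"))
  expect_error(read_tables(file.path(dir, "demo.csv"), file.path(dir, "drug.csv"),
                           file.path(dir, "reac.csv"), file.path(dir, "hist.csv")),
               "demo.*reporting_year")
})

write_tiny_tables <- function(dir, demo_rows, drug_rows = character(),
                              reac_rows = character(), hist_rows = character()) {
  dir.create(dir, showWarnings = FALSE)
  writeLines(c("case_id,sex,age,reporting_year", demo_rows), file.path(dir, "demo.csv"))
  writeLines(c("case_id,drug_name,role_code,daily_dose_g,start_date", drug_rows),
             file.path(dir, "drug.csv"))
  writeLines(c("case_id,pt_code,pt_name,onset_date", reac_rows), file.path(dir, "reac.csv"))
  writeLines(c("case_id,disease_name", hist_rows), file.path(dir, "hist.csv"))
  read_tables(file.path(dir, "demo.csv"), file.path(dir, "drug.csv"),
              file.path(dir, "reac.csv"), file.path(dir, "hist.csv"))
}

test_that("duplicate case ids collapse with the last version winning", {
  b <- write_tiny_tables(file.path(tempdir(), "io-lastwins"),
                         demo_rows = c("X1,female,50s,2019", "X1,male,60s,2020"))
  r <- integrate_reports(b)
  expect_identical(nrow(r), 1L)
  expect_identical(r$sex, "male")
  expect_identical(r$age_decade, "60s")
  expect_identical(attr(r, "log")$n_duplicate_demo, 1L)
})

test_that("orphan child rows are dropped with a logged count", {
  b <- write_tiny_tables(file.path(tempdir(), "io-orphan"),
                         demo_rows = "X1,male,60s,2020",
                         drug_rows = c("X1,Shosaikoto,suspected,7.5,2020-01-01",
                                       "GHOST,Shosaikoto,suspected,7.5,2020-01-01"),
                         reac_rows = "GHOST,10022611,Interstitial lung disease,2020-02-01")
  r <- integrate_reports(b)
  expect_identical(nrow(r), 1L)
  expect_identical(nrow(r$drugs[[1]]), 1L)
  lg <- attr(r, "log")
  expect_identical(unname(lg$n_orphan_rows["drug"]), 1L)
  expect_identical(unname(lg$n_orphan_rows["reac"]), 1L)
})

test_that("integration is stable: re-integrating the same bundle changes nothing", {
  ds <- small_dataset()
  r1 <- integrate_reports(ds$bundle)
  r2 <- integrate_reports(ds$bundle)
  attr(r1, "log") <- attr(r2, "log") <- NULL
  expect_identical(r1, r2)
})

test_that("sex/age sentinels map to missing and suspected filter keeps all reports", {
  b <- write_tiny_tables(file.path(tempdir(), "io-sent"),
                         demo_rows = c("X1,unknown,aged,2020", "X2,male,unknown,2021",
                                       "X3,female,70s,2022"),
                         drug_rows = c("X3,Shosaikoto,suspected,7.5,2020-01-01",
                                       "X3,Yokukansan,concomitant,5,2020-01-01",
                                       "X3,Rikkunshito,interacting,5,2020-01-01",
                                       "X2,Yokukansan,concomitant,5,2020-01-01"))
  r <- filter_suspected(integrate_reports(b))
  expect_identical(nrow(r), 3L)
  expect_true(is.na(r$sex[r$case_id == "X1"]))
  expect_true(is.na(r$age_decade[r$case_id == "X1"]))
  expect_true(is.na(r$age_decade[r$case_id == "X2"]))
  # only the suspected drug remains; X2 keeps an empty drug list but stays
  expect_identical(nrow(r$drugs[[which(r$case_id == "X3")]]), 1L)
  expect_identical(nrow(r$drugs[[which(r$case_id == "X2")]]), 0L)
})

test_that("demographic_subset excludes the missing share and shrinks monotonically", {
  ds <- small_dataset()
  r <- integrate_reports(ds$bundle)
  sub_sex <- demographic_subset(r, "sex")
  sub_both <- demographic_subset(r, c("sex", "age"))
  # identity when nothing is required of an already-complete frame
  expect_identical(nrow(demographic_subset(sub_both, "sex")), nrow(sub_both))
  expect_lte(nrow(sub_both), nrow(sub_sex))
  expect_lte(nrow(sub_sex), nrow(r))
  # about missing_sex_rate excluded, within 3 binomial SE
  p <- ds$config$missing_sex_rate
  excl <- attr(sub_sex, "exclusions")
  expect_identical(excl$n_input - excl$n_excluded, nrow(sub_sex))
  expect_lt(abs(excl$n_excluded / nrow(r) - p), 3 * sqrt(p * (1 - p) / nrow(r)))
})

test_that("case flagging matches the preferred-term code with any-event semantics", {
  r <- dplyr::bind_rows(
    make_report("A", events = ild_event()),
    make_report("B"),
    make_report("C", events = dplyr::bind_rows(ild_event(), other_event(),
                                               other_event(), other_event())),
    make_report("D", events = other_event()),
    make_report("E", events = tibble::tibble(pt_code = NA_character_,
                                             pt_name = "INTERSTITIAL LUNG DISEASE",
                                             onset_date = as.Date("2020-02-01"))))
  expect_identical(flag_diild(r), c(TRUE, FALSE, TRUE, FALSE, TRUE))
})
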