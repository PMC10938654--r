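# Shared fixtures, all built in code at test time.

example_formulary_path <- function() {
  system.file("extdata", "kampo_formulary_synthetic.csv", package = "kampovig")
}

example_formulary <- function() load_formulary(example_formulary_path())

# Hand-build an integrated-reports tibble without going through CSV files.
make_report <- function(case_id, sex = "male", age = "60s", year = 2020L,
                        drugs = NULL, events = NULL, history = character()) {
  if (is.null(drugs)) {
    drugs <- tibble::tibble(name = character(), role = character(),
                            daily_dose_g = numeric(),
                            start_date = as.Date(character()))
  }
  if (is.null(events)) {
    events <- tibble::tibble(pt_code = character(), pt_name = character(),
                             onset_date = as.Date(character()))
  }
  tibble::tibble(case_id = case_id, sex = sex, age_decade = age,
                 reporting_year = year, drugs = list(drugs),
                 events = list(events), history = list(history))
}

drug_row <- function(name, role = "suspected", dose = 7.5, start = "2020-01-01") {
  tibble::tibble(name = name, role = role, daily_dose_g = dose,
                 start_date = as.Date(start))
}

ild_event <- function(onset = "2020-02-05") {
  tibble::tibble(pt_code = "10022611", pt_name = "Interstitial lung disease",
                 onset_date = as.Date(onset))
}

other_event <- function(onset = "2020-02-05") {
  tibble::tibble(pt_code = "10028813", pt_name = "Nausea",
                 onset_date = as.Date(onset))
}

# A small generated dataset reused across IO tests.
small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(1500, drug_catalog = list(
        drug_spec("Shosaikoto", 0.05, 6, onset_alpha = 40, onset_beta = 1.36),
        drug_spec("Yokukansan", 0.05, 1.5)),
        duplicate_rate = 0.1, seed = 42)
      dir <- file.path(tempdir(), "kampovig-small")
      paths <- generate_tables(cfg, dir)
      cache <<- list(config = cfg, paths = paths,
                     bundle = read_tables(paths$demo, paths$drug,
                                          paths$reac, paths$hist))
    }
    cache
  }
})

# Reference counts shipped with the package, split into margins and rows.
reference_rows <- function() {
  ref <- diild_reference_counts()
  list(margins = ref[ref$stratum == "margin", ],
       rows = ref[ref$stratum != "margin", ])
}
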