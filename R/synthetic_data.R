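#' Describe one drug for the synthetic report generator
#'
#' A catalog entry gives a drug's marginal exposure probability among reports,
#' its multiplicative effect on the odds of the target event, a discrete daily
#' dose distribution (grams of formulation product per day), and the Weibull
#' time-to-onset distribution used when the drug is picked as the causal agent.
#'
#' @param name Drug (product) name as it will appear in the drug table.
#' @param exposure_prob Marginal probability that a report lists the drug.
#' @param odds_multiplier Multiplier on the odds of the target event when the
#'   drug is present; 1 means no association.
#' @param dose_support Numeric vector of possible daily doses in grams.
#' @param dose_probs Probabilities over `dose_support`; uniform when `NULL`.
#' @param onset_alpha,onset_beta Weibull scale (days) and shape of the
#'   administration-to-onset delay.
#' @return A list suitable for `sim_config(drug_catalog = list(...))`.
#' @export
drug_spec <- function(name, exposure_prob, odds_multiplier = 1,
                      dose_support = c(2.5, 5, 7.5), dose_probs = NULL,
                      onset_alpha = 60, onset_beta = 1.2) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    abort("drug_spec: `name` must be a non-empty string")
  }
  if (is.null(dose_probs)) dose_probs <- rep(1 / length(dose_support), length(dose_support))
  spec <- list(name = name, exposure_prob = exposure_prob,
               odds_multiplier = odds_multiplier,
               dose_support = dose_support, dose_probs = dose_probs,
               onset_alpha = onset_alpha, onset_beta = onset_beta)
  check_prob(exposure_prob, "exposure_prob")
  if (!is.numeric(odds_multiplier) || odds_multiplier <= 0) {
    abort("drug_spec: `odds_multiplier` must be positive")
  }
  if (length(dose_support) != length(dose_probs) || any(dose_support < 0) ||
      any(dose_probs < 0) || sum(dose_probs) <= 0) {
    abort("drug_spec: `dose_support`/`dose_probs` must be nonnegative and matched in length")
  }
  if (onset_alpha <= 0 || onset_beta <= 0) {
    abort("drug_spec: `onset_alpha` and `onset_beta` must be positive")
  }
  spec
}

check_prob <- function(x, field, open_upper = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 &&
    (if (open_upper) x < 1 else x <= 1)
  if (!ok) abort(sprintf("sim_config: `%s` must be a probability in [0, 1)", field))
  invisible(x)
}

DECADE_LEVELS <- c("10s", "20s", "30s", "40s", "50s", "60s", "70s", "80s or older")

#' Configuration for the synthetic JADER-like generator
#'
#' Defines the study conditions a generated dataset emulates: report volume,
#' background event rate, the drug catalog with per-drug association strength
#' and dose/onset distributions, the demographic mix, missingness rates for
#' sex, age and dates, and the rate of duplicate case-id submissions.
#'
#' Event assignment follows a logistic model:
#' `log-odds = logit(background_event_rate) + sum(log(odds_multiplier) * exposed)`,
#' so realized reporting odds ratios converge to the configured multipliers as
#' the number of reports grows.
#'
#' @param n_reports Number of distinct reports (cases) to generate.
#' @param background_event_rate Event probability for a report with no catalog
#'   drug; default 0.044, the target event's share of the full background
#'   database (36,745 / 830,079).
#' @param drug_catalog List of [drug_spec()] entries.
#' @param sex_mix Probability that a report's patient is male.
#' @param age_decade_weights Named nonnegative weights over the decade strings
#'   `"10s"` .. `"80s or older"`; defaults approximate the elderly-skewed age
#'   distribution of herbal-medicine reports.
#' @param missing_sex_rate,missing_age_rate Probability that the field is
#'   replaced by a sentinel ("unknown", or "aged" for age).
#' @param missing_date_rate Probability that a date is emitted partially
#'   (year or year-month only), exercising the time-to-onset exclusion rule.
#' @param duplicate_rate Probability that a report's demographic row is
#'   emitted twice with the same case id (a resubmission).
#' @param year_range Inclusive reporting-year span.
#' @param seed Integer seed; identical config + seed reproduces byte-identical
#'   output files.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_reports,
                       background_event_rate = 0.044,
                       drug_catalog = list(),
                       sex_mix = 0.45,
                       age_decade_weights = c("10s" = 1, "20s" = 2, "30s" = 4,
                                              "40s" = 7, "50s" = 12, "60s" = 20,
                                              "70s" = 28, "80s or older" = 26),
                       missing_sex_rate = 0.05,
                       missing_age_rate = 0.05,
                       missing_date_rate = 0.10,
                       duplicate_rate = 0,
                       year_range = c(2004L, 2023L),
                       seed = 1L) {
  if (!is.numeric(n_reports) || length(n_reports) != 1L || n_reports < 1 ||
      n_reports != round(n_reports)) {
    abort("sim_config: `n_reports` must be a positive integer")
  }
  if (!is.numeric(background_event_rate) || background_event_rate <= 0 ||
      background_event_rate >= 1) {
    abort("sim_config: `background_event_rate` must lie in (0, 1)")
  }
  check_prob(sex_mix, "sex_mix", open_upper = FALSE)
  check_prob(missing_sex_rate, "missing_sex_rate")
  check_prob(missing_age_rate, "missing_age_rate")
  check_prob(missing_date_rate, "missing_date_rate")
  check_prob(duplicate_rate, "duplicate_rate")
  if (is.null(names(age_decade_weights)) ||
      !all(names(age_decade_weights) %in% DECADE_LEVELS)) {
    abort(sprintf("sim_config: `age_decade_weights` names must be among: %s",
                  paste(DECADE_LEVELS, collapse = ", ")))
  }
  if (any(age_decade_weights < 0) || sum(age_decade_weights) <= 0) {
    abort("sim_config: `age_decade_weights` must be nonnegative and not all zero")
  }
  for (d in drug_catalog) {
    if (!all(c("name", "exposure_prob", "odds_multiplier") %in% names(d))) {
      abort("sim_config: every `drug_catalog` entry must come from drug_spec()")
    }
  }
  if (anyDuplicated(vapply(drug_catalog, `[[`, "", "name"))) {
    abort("sim_config: `drug_catalog` drug names must be unique")
  }
  structure(list(n_reports = as.integer(n_reports),
                 background_event_rate = background_event_rate,
                 drug_catalog = drug_catalog, sex_mix = sex_mix,
                 age_decade_weights = age_decade_weights,
                 missing_sex_rate = missing_sex_rate,
                 missing_age_rate = missing_age_rate,
                 missing_date_rate = missing_date_rate,
                 duplicate_rate = duplicate_rate,
                 year_range = as.integer(year_range),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Other adverse events assigned to non-case reports so every report carries at
# least one reaction row, as in a real spontaneous-reporting extract.
OTHER_PTS <- data.frame(
  pt_code = c("10028813", "10019670", "10037844", "10012735", "10047700"),
  pt_name = c("Nausea", "Hepatic function abnormal", "Rash", "Diarrhoea", "Vomiting"),
  stringsAsFactors = FALSE
)

HISTORY_POOL <- c("Hypertension" = 0.25, "Diabetes" = 0.12, "Constipation" = 0.10,
                  "Insomnia" = 0.10, "Hyperlipidaemia" = 0.09, "Dementia" = 0.07,
                  "Asthma" = 0.07, "Depression" = 0.06,
                  "Gastrooesophageal reflux disease" = 0.06,
                  "Atrial fibrillation" = 0.04, "Haemorrhoids" = 0.04)

truncate_date <- function(iso, level) {
  # level 1 -> year-month, level 2 -> year only (JADER partial-date dialect)
  ifelse(level >= 2L, substr(iso, 1L, 4L),
         ifelse(level == 1L, substr(iso, 1L, 7L), iso))
}

#' Generate a four-table JADER-dialect dataset
#'
#' Writes `demo.csv`, `drug.csv`, `reac.csv` and `hist.csv` to `out_dir`:
#' one demographic row per report version (duplicate submissions share a case
#' id), one drug row per (report, drug) with role code, daily dose string and
#' administration start date, one reaction row per (report, event) with
#' MedDRA-like preferred-term code/name and onset date, and one history row
#' per (report, underlying disease).
#'
#' Four independent RNG streams, all derived from `config$seed`, drive the
#' demographic, drug, reaction and history stages, so enlarging one stage does
#' not perturb the others within a stage ordering.
#'
#' @param config A [sim_config()].
#' @param out_dir Writable output directory (created if absent).
#' @param dialect Column-name map, see [jader_dialect()].
#' @return Invisibly, a named list of the four file paths.
#' @export
generate_tables <- function(config, out_dir, dialect = jader_dialect()) {
  stopifnot(inherits(config, "sim_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  n <- config$n_reports
  case_id <- sprintf("C%07d", seq_len(n))
  k <- length(config$drug_catalog)

  # --- stage 1: demographics ------------------------------------------------
  withr::with_seed(config$seed + 11L, {
    sex <- ifelse(runif(n) < config$sex_mix, "male", "female")
    sex[runif(n) < config$missing_sex_rate] <- "unknown"
    w <- config$age_decade_weights
    age <- sample(names(w), n, replace = TRUE, prob = w / sum(w))
    age_missing <- runif(n) < config$missing_age_rate
    age[age_missing] <- sample(c("unknown", "aged"), sum(age_missing), replace = TRUE)
    year <- sample(seq(config$year_range[1], config$year_range[2]), n, replace = TRUE)
    dup <- runif(n) < config$duplicate_rate
  })

  # --- stage 2: drug exposure, doses, start dates ---------------------------
  withr::with_seed(config$seed + 23L, {
    exposed <- matrix(FALSE, n, max(k, 1L))
    dose <- matrix(NA_real_, n, max(k, 1L))
    for (j in seq_len(k)) {
      d <- config$drug_catalog[[j]]
      exposed[, j] <- runif(n) < d$exposure_prob
      nj <- sum(exposed[, j])
      if (nj > 0) {
        dose[exposed[, j], j] <- sample(d$dose_support, nj, replace = TRUE,
                                        prob = d$dose_probs / sum(d$dose_probs))
      }
    }
    start <- as.Date(paste0(year, "-01-01")) + sample(0:330, n, replace = TRUE)
    n_drug_rows <- sum(exposed)
    dose_has_unit <- runif(n_drug_rows) < 0.3
    start_trunc <- ifelse(runif(n_drug_rows) < config$missing_date_rate,
                          sample(1:2, n_drug_rows, replace = TRUE), 0L)
  })

  # --- stage 3: events and onsets -------------------------------------------
  withr::with_seed(config$seed + 37L, {
    logodds <- rep(qlogis(config$background_event_rate), n)
    if (k > 0) {
      mult <- log(vapply(config$drug_catalog, `[[`, 0, "odds_multiplier"))
      logodds <- logodds + as.numeric(exposed %*% mult)
    }
    event <- runif(n) < plogis(logodds)
    # causal drug: first exposed catalog drug, else background onset profile
    causal <- if (k > 0) apply(exposed, 1L, function(e) which(e)[1L]) else rep(NA_integer_, n)
    delay <- numeric(n)
    for (j in seq_len(k)) {
      idx <- which(!is.na(causal) & causal == j)
      d <- config$drug_catalog[[j]]
      delay[idx] <- rweibull(length(idx), shape = d$onset_beta, scale = d$onset_alpha)
    }
    idx_bg <- which(is.na(causal))
    delay[idx_bg] <- rweibull(length(idx_bg), shape = 1.2, scale = 60)
    delay <- pmax(1, round(delay))
    other <- sample(nrow(OTHER_PTS), n, replace = TRUE)
    onset_trunc <- ifelse(runif(n) < config$missing_date_rate,
                          sample(1:2, n, replace = TRUE), 0L)
  })

  # --- stage 4: underlying diseases -----------------------------------------
  withr::with_seed(config$seed + 53L, {
    n_hist <- rbinom(n, size = 3L, prob = 0.35)
    hist_disease <- sample(names(HISTORY_POOL), sum(n_hist), replace = TRUE,
                           prob = HISTORY_POOL / sum(HISTORY_POOL))
  })

  d <- dialect
  demo <- tibble::tibble(!!d$demo[["case_id"]] := case_id,
                         !!d$demo[["sex"]] := sex,
                         !!d$demo[["age"]] := age,
                         !!d$demo[["reporting_year"]] := year)
  demo <- dplyr::bind_rows(demo, demo[dup, , drop = FALSE])

  if (k > 0) {
    drug_rows <- which(exposed, arr.ind = TRUE)
    drug_rows <- drug_rows[order(drug_rows[, "row"], drug_rows[, "col"]), , drop = FALSE]
    i <- drug_rows[, "row"]; j <- drug_rows[, "col"]
    dose_str <- sprintf("%g", dose[drug_rows])
    dose_str[dose_has_unit] <- paste0(dose_str[dose_has_unit], "g")
    drug <- tibble::tibble(
      !!d$drug[["case_id"]] := case_id[i],
      !!d$drug[["drug_name"]] := vapply(config$drug_catalog, `[[`, "", "name")[j],
      !!d$drug[["role_code"]] := "suspected",
      !!d$drug[["daily_dose_g"]] := dose_str,
      !!d$drug[["start_date"]] := truncate_date(format(start[i], "%Y-%m-%d"), start_trunc))
  } else {
    drug <- tibble::tibble(!!d$drug[["case_id"]] := character(),
                           !!d$drug[["drug_name"]] := character(),
                           !!d$drug[["role_code"]] := character(),
                           !!d$drug[["daily_dose_g"]] := character(),
                           !!d$drug[["start_date"]] := character())
  }

  onset <- format(start + delay, "%Y-%m-%d")
  reac <- tibble::tibble(
    !!d$reac[["case_id"]] := case_id,
    !!d$reac[["pt_code"]] := ifelse(event, DIILD_PT_CODE, OTHER_PTS$pt_code[other]),
    !!d$reac[["pt_name"]] := ifelse(event, "Interstitial lung disease", OTHER_PTS$pt_name[other]),
    !!d$reac[["onset_date"]] := truncate_date(onset, onset_trunc))

  hist <- tibble::tibble(!!d$hist[["case_id"]] := rep(case_id, n_hist),
                         !!d$hist[["disease_name"]] := hist_disease)

  paths <- list(demo = file.path(out_dir, "demo.csv"),
                drug = file.path(out_dir, "drug.csv"),
                reac = file.path(out_dir, "reac.csv"),
                hist = file.path(out_dir, "hist.csv"))
  readr::write_csv(demo, paths$demo)
  readr::write_csv(drug, paths$drug)
  readr::write_csv(reac, paths$reac)
  readr::write_csv(hist, paths$hist)
  invisible(paths)
}

#' Simulate covariates and outcomes from a known logistic model
#'
#' Draws reporting year, daily crude-drug intakes (`d1` = Scutellariae radix,
#' `d2` = Pinelliae tuber, both grams/day with a point mass at zero), sex and
#' age indicators, and an outcome generated from the logistic model with the
#' supplied coefficients (including the `d1:a` and `d1:d2` interactions).
#' Used for parameter-recovery checks of the multivariate model.
#'
#' @param n Number of observations.
#' @param beta Named coefficients: `intercept`, `year`, `d1`, `d2`, `s`, `a`,
#'   `d1_a`, `d1_d2` (missing names default to 0).
#' @param seed Integer seed.
#' @return Tibble with columns `year, d1, d2, s, a, event`.
#' @export
simulate_covariate_outcomes <- function(n, beta, seed = 1L) {
  full <- c(intercept = 0, year = 0, d1 = 0, d2 = 0, s = 0, a = 0, d1_a = 0, d1_d2 = 0)
  full[names(beta)] <- beta
  withr::with_seed(seed, {
    year <- sample(2004:2023, n, replace = TRUE)
    d1 <- ifelse(runif(n) < 0.6, 0, round(rweibull(n, 1.5, 1.8), 2))
    d2 <- ifelse(runif(n) < 0.6, 0, round(rweibull(n, 1.5, 2.2), 2))
    s <- as.integer(runif(n) < 0.4)
    a <- as.integer(runif(n) < 0.6)
    lo <- full["intercept"] + full["year"] * year + full["d1"] * d1 +
      full["d2"] * d2 + full["s"] * s + full["a"] * a +
      full["d1_a"] * d1 * a + full["d1_d2"] * d1 * d2
    event <- runif(n) < plogis(lo)
  })
  tibble::tibble(year = year, d1 = d1, d2 = d2, s = s, a = a, event = event)
}

#' Simulate a confounded exposure cohort
#'
#' Generates a cohort in which exposure to a crude drug depends on age, sex
#' and the intakes of the other two crude drugs (the confounders), while the
#' event depends on the same confounders plus an optional direct exposure
#' effect. This is the test bed for propensity-score matching: with
#' `direct_log_or = 0` the crude reporting odds ratio is biased away from 1 by
#' confounding, and matching should recover a null.
#'
#' @param n Cohort size.
#' @param direct_log_or Log odds ratio of the direct exposure effect on the
#'   event (0 = no direct effect).
#' @param conf_age,conf_sex,conf_dose Confounder strengths (log-odds scale) on
#'   the exposure model; the same age/sex/dose effects also enter the event
#'   model at fixed moderate values.
#' @param seed Integer seed.
#' @return Tibble with columns `s, a, br_g, pt_g, exposed, event`.
#' @export
simulate_confounded_cohort <- function(n, direct_log_or = 0, conf_age = 1.0,
                                       conf_sex = 0.5, conf_dose = 0.3, seed = 1L) {
  withr::with_seed(seed, {
    a <- as.integer(runif(n) < 0.5)
    s <- as.integer(runif(n) < 0.4)
    br_g <- ifelse(runif(n) < 0.5, 0, round(rweibull(n, 1.5, 2.5), 2))
    pt_g <- ifelse(runif(n) < 0.5, 0, round(rweibull(n, 1.5, 2.0), 2))
    # exposure intercept set so that marginal exposure prevalence is ~28%,
    # the regime of real matched-cohort analyses (exposed well below controls)
    lo_exp <- -2.5 + conf_age * a + conf_sex * s + conf_dose * (br_g + pt_g)
    exposed <- runif(n) < plogis(lo_exp)
    lo_ev <- qlogis(0.20) + 0.8 * a + 0.4 * s + 0.12 * br_g + 0.10 * pt_g +
      direct_log_or * exposed
    event <- runif(n) < plogis(lo_ev)
  })
  tibble::tibble(s = s, a = a, br_g = br_g, pt_g = pt_g,
                 exposed = exposed, event = event)
}
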