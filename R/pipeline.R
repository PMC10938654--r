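#' Pipeline configuration
#'
#' Bundles the file paths, thresholds and switches that drive
#' [run_pipeline()]. Can also be read from a JSON file holding the same
#' fields via `pipeline_config_from_json()`.
#'
#' @param demo,drug,reac,hist Paths to the four tables.
#' @param formulary Path to the formulation registry CSV.
#' @param out_dir Output directory for the result CSVs.
#' @param pt_code Target preferred-term code.
#' @param min_cases Signal criterion minimum case count.
#' @param caliper_mult Caliper width multiplier for matching.
#' @param window Time-to-onset analysis window in days.
#' @param alpha Stepwise selection significance level.
#' @param run_signals,run_model,run_match,run_dose,run_tto,run_history
#'   Stage switches.
#' @param seed Integer seed (used only for matching tie-breaks).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(demo, drug, reac, hist, formulary, out_dir,
                            pt_code = DIILD_PT_CODE, min_cases = 3L,
                            caliper_mult = 0.2, window = 365, alpha = 0.05,
                            run_signals = TRUE, run_model = TRUE,
                            run_match = TRUE, run_dose = TRUE,
                            run_tto = TRUE, run_history = TRUE, seed = 1L) {
  for (p in c(demo, drug, reac, hist, formulary)) {
    if (!file.exists(p)) abort(sprintf("pipeline_config: file not found: %s", p))
  }
  if (min_cases < 1 || caliper_mult <= 0 || window <= 0 || alpha <= 0 || alpha >= 1) {
    abort("pipeline_config: thresholds must be positive (alpha in (0,1))")
  }
  structure(list(demo = demo, drug = drug, reac = reac, hist = hist,
                 formulary = formulary, out_dir = out_dir, pt_code = pt_code,
                 min_cases = as.integer(min_cases), caliper_mult = caliper_mult,
                 window = window, alpha = alpha, run_signals = run_signals,
                 run_model = run_model, run_match = run_match,
                 run_dose = run_dose, run_tto = run_tto,
                 run_history = run_history, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path JSON file with the `pipeline_config()` fields.
#' @export
pipeline_config_from_json <- function(path) {
  do.call(pipeline_config, jsonlite::read_json(path, simplifyVector = TRUE))
}

stage_log <- function(stage, fmt, ...) {
  inform(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: table ingestion and integration, restriction to
#' suspected drugs, exposure-group classification and intake reconstruction,
#' the per-product/per-group and sex/age-stratified signal tables, the
#' multivariate logistic model with stepwise selection and adjusted RORs,
#' propensity-score matching per crude drug, dose-response and ROC analysis
#' per crude drug, time-to-onset profiling, and the underlying-disease
#' table. Every exclusion step logs its counts; the input files are never
#' modified; the output CSVs are deterministic given config + seed.
#'
#' Within this run the contingency background is the analysis set itself
#' (its own margins play the role of the whole-database background).
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a named list of the computed tables (also written as
#'   CSVs under `config$out_dir`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  out <- list()
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage `%s` failed: %s", stage, conditionMessage(e)))
    })
  }

  reports <- run_stage("io", {
    bundle <- read_tables(config$demo, config$drug, config$reac, config$hist)
    r <- integrate_reports(bundle)
    lg <- attr(r, "log")
    stage_log("io", "%d demo rows -> %d reports (%d duplicate resubmissions, %s orphan child rows)",
              lg$n_demo_rows, lg$n_reports, lg$n_duplicate_demo,
              paste(lg$n_orphan_rows, collapse = "/"))
    filter_suspected(r)
  })
  event <- flag_diild(reports, pt_code = config$pt_code)
  form <- run_stage("formulary", load_formulary(config$formulary))
  intake <- run_stage("formulary", report_daily_intake(reports, form))
  n_case <- sum(event)
  n_total <- nrow(reports)
  stage_log("formulary", "%d reports, %d cases; groups: %s", n_total, n_case,
            paste(names(table(intake$group)), table(intake$group),
                  sep = "=", collapse = ", "))

  if (config$run_signals) {
    out$signals <- run_stage("signals", signal_table(
      reports, form, event, n_case_total = n_case,
      n_noncase_total = n_total - n_case, min_cases = config$min_cases))
    sex_sub <- demographic_subset(reports, "sex")
    stage_log("signals", "sex-complete subset: %d of %d reports",
              nrow(sex_sub), n_total)
    herb <- classify_group(sex_sub, form) != "NONE"
    out$signals_sex <- run_stage("signals", stratified_signals(
      sex_sub, "sex", exposed = herb, event = event[match(sex_sub$case_id, reports$case_id)],
      n_case_total = n_case, n_noncase_total = n_total - n_case,
      min_cases = config$min_cases))
    age_sub <- demographic_subset(reports, "age")
    herb_a <- classify_group(age_sub, form) != "NONE"
    out$signals_age <- run_stage("signals", stratified_signals(
      age_sub, "age_decade", exposed = herb_a,
      event = event[match(age_sub$case_id, reports$case_id)],
      n_case_total = n_case, n_noncase_total = n_total - n_case,
      min_cases = config$min_cases))
  }

  # dose-complete demographically complete subset for model-based stages
  complete <- demographic_subset(reports, c("sex", "age"))
  dat <- intake[match(complete$case_id, intake$case_id), ]
  keep <- !dat$dose_missing & dat$group != "NONE"
  stage_log("model", "analysis subset: %d dose-complete herbal reports of %d",
            sum(keep), n_total)
  dat <- tibble::tibble(
    year = complete$reporting_year[keep],
    d1 = dat$sr_g[keep], d2 = dat$pt_g[keep], br = dat$br_g[keep],
    s = as.integer(complete$sex[keep] == "male"),
    a = as.integer(complete$age_decade[keep] %in% c("60s", "70s", "80s+")),
    event = event[match(complete$case_id[keep], reports$case_id)])

  if (config$run_model && sum(keep) > 50 && sum(dat$event) > 5) {
    out$model <- run_stage("model", {
      fit <- stepwise_select(dat, "event",
                             candidates = c("year", "d1", "d2", "s", "a", "d1:a", "d1:d2"),
                             alpha = config$alpha)
      sel <- attr(fit, "selected")
      stage_log("model", "stepwise selected: %s",
                if (length(sel)) paste(sel, collapse = ", ") else "(intercept only)")
      tt <- term_table(fit)
      tt$adjusted_ror <- exp(tt$estimate)
      tt
    })
  }

  crude <- c(SR = "d1", BR = "br", PT = "d2")
  if (config$run_dose) {
    out$dose_response <- run_stage("dose_response", dplyr::bind_rows(lapply(
      names(crude), function(cd) {
        x <- dat[[crude[[cd]]]]
        if (length(unique(x)) < 2L || length(unique(dat$event)) < 2L) return(NULL)
        fit <- fit_dose_response(x, dat$event)
        roc <- roc_analysis(x, dat$event)
        tibble::tibble(crude_drug = cd, intercept = fit$intercept,
                       slope = fit$slope, ror_per_gram = fit$ror_per_gram$or,
                       ror_low = fit$ror_per_gram$ci_low,
                       ror_high = fit$ror_per_gram$ci_high,
                       auc = roc$auc, cutoff_g = roc$cutoff)
      })))
  }

  if (config$run_match) {
    out$matching <- run_stage("ps_matching", dplyr::bind_rows(lapply(
      names(crude), function(cd) {
        dat$exposed <- dat[[crude[[cd]]]] > 0
        covs <- c("s", "a", setdiff(unname(crude), crude[[cd]]))
        if (sum(dat$exposed) < 20 || sum(!dat$exposed) < 20) return(NULL)
        ps <- estimate_ps(dat, "exposed", covs)
        cohort <- match_caliper(ps$scores, dat$exposed,
                                caliper_mult = config$caliper_mult,
                                seed = config$seed)
        stage_log("ps_matching", "%s: %d/%d exposed matched (AUC %.3f)",
                  cd, nrow(cohort$pairs), cohort$n_exposed_input, ps$auc)
        bal <- balance_table(dat, "exposed", covs, cohort)
        before <- compute_ror(build_contingency(dat, dat$exposed, dat$event))
        after <- matched_ror(cohort, dat$event)
        tibble::tibble(crude_drug = cd, ps_auc = ps$auc,
                       n_pairs = nrow(cohort$pairs),
                       max_smd_before = max(bal$smd_before),
                       max_smd_after = max(bal$smd_after),
                       ror_before = before$ror, ror_before_low = before$ci_low,
                       ror_before_high = before$ci_high,
                       ror_after = after$ror, ror_after_low = after$ci_low,
                       ror_after_high = after$ci_high)
      })))
  }

  if (config$run_tto) {
    groups <- c("SR", "BR", "PT", "SR_BR", "SR_PT", "SR_BR_PT")
    out$tto_groups <- run_stage("time_to_onset", tto_table(
      reports, groups, level = "group", formulary = form, event = event,
      window = config$window))
    counts <- table(unlist(lapply(which(event), function(i) {
      unique(reports$drugs[[i]]$name[!is.na(lookup_products(reports$drugs[[i]]$name, form))])
    })))
    drugs <- names(counts[counts > 10])
    if (length(drugs)) {
      out$tto_drugs <- run_stage("time_to_onset", tto_table(
        reports, drugs, level = "drug", event = event, window = config$window))
    }
  }

  if (config$run_history) {
    grp <- classify_group(reports, form)
    out$history <- run_stage("history", tabulate_history(
      reports[event, , drop = FALSE], grp[event]))
  }

  for (nm in names(out)) {
    if (is.data.frame(out[[nm]])) {
      readr::write_csv(out[[nm]], file.path(config$out_dir, paste0(nm, ".csv")))
    }
  }
  invisible(out)
}

#' Underlying-disease frequency table per exposure group
#'
#' Tabulates the history entries of case reports within each exposure group:
#' disease name, count, and percentage of the group's history entries,
#' sorted descending, with diseases below `min_share` of the group's entries
#' collapsed into an "Others" row. Percentages sum to 100 up to rounding.
#'
#' @param reports Reports (typically the case subset), with `history`
#'   list-column.
#' @param groups Character vector of group labels aligned with `reports`.
#' @param min_share Collapse threshold as a share of the group's entries
#'   (default 0.01).
#' @return Tibble: `group`, `disease`, `n`, `pct`.
#' @export
tabulate_history <- function(reports, groups, min_share = 0.01) {
  stopifnot(length(groups) == nrow(reports))
  rows <- lapply(unique(groups[!groups %in% c("NONE", "MIXED")]), function(g) {
    entries <- unlist(reports$history[groups == g])
    if (length(entries) == 0L) return(NULL)
    tab <- sort(table(entries), decreasing = TRUE)
    share <- as.numeric(tab) / sum(tab)
    small <- share < min_share
    top <- tibble::tibble(group = g, disease = names(tab)[!small],
                          n = as.integer(tab[!small]),
                          pct = round(100 * share[!small], 2))
    if (any(small)) {
      top <- dplyr::bind_rows(top, tibble::tibble(
        group = g, disease = "Others", n = as.integer(sum(tab[small])),
        pct = round(100 * sum(share[small]), 2)))
    }
    top
  })
  dplyr::bind_rows(rows)
}
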