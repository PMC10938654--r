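#' Estimate propensity scores for crude-drug exposure
#'
#' Fits a logistic model of exposure on the stated covariates (sex, the
#' age >= 60 indicator, and the daily intakes of the other two crude drugs)
#' and returns the fitted exposure probabilities together with the model's
#' discrimination (ROC AUC). Separated models abort: matching on a
#' degenerate score is meaningless.
#'
#' @param data Data frame on the dose-complete analysis subset.
#' @param exposure Name of the logical/0-1 exposure column.
#' @param covariates Character vector of covariate column names.
#' @return Object of class `ps_fit`: `scores` in (0,1), `auc`, `fit`.
#' @export
estimate_ps <- function(data, exposure, covariates) {
  stopifnot(exposure %in% names(data), all(covariates %in% names(data)))
  fit <- fit_logistic(build_formula(exposure, covariates), data)
  if (fit$separation) {
    abort("estimate_ps: separation in the propensity model; matching aborted")
  }
  scores <- unname(predict(fit$model, type = "response"))
  auc <- roc_analysis(scores, as.logical(data[[exposure]]))$auc
  structure(list(scores = scores, auc = auc, fit = fit), class = "ps_fit")
}

#' 1:1 greedy nearest-neighbor caliper matching on the logit propensity score
#'
#' The caliper is `caliper_mult` times the standard deviation of the logit
#' propensity score over all subjects. Exposed subjects are processed in
#' descending logit-score order; each is matched without replacement to the
#' nearest still-unmatched control within the caliper, and dropped if none
#' is available. The only randomness is the resolution of exact distance
#' ties, controlled by `seed`.
#'
#' @param scores Propensity scores in (0,1) for all subjects.
#' @param exposed Logical exposure flags, same length.
#' @param caliper_mult Caliper width as a multiple of sd(logit PS); default
#'   0.2.
#' @param seed Integer seed for tie-breaking.
#' @return Object of class `matched_cohort`: `pairs` tibble
#'   `(exposed, control)` of subject indices, `caliper`, `logit_sd`,
#'   `n_exposed_input`, `n_control_input`.
#' @export
match_caliper <- function(scores, exposed, caliper_mult = 0.2, seed = 1L) {
  stopifnot(length(scores) == length(exposed))
  exposed <- as.logical(exposed)
  if (!any(exposed) || all(exposed)) {
    abort("match_caliper: both exposed and control subjects are required")
  }
  lg <- qlogis(pmin(pmax(scores, 1e-12), 1 - 1e-12))
  sdl <- sd(lg)
  if (!is.finite(sdl) || sdl == 0) {
    abort("match_caliper: zero variance of logit propensity scores")
  }
  caliper <- caliper_mult * sdl
  e_idx <- which(exposed)
  e_idx <- e_idx[order(lg[e_idx], decreasing = TRUE)]
  c_idx <- which(!exposed)
  c_lg <- lg[c_idx]
  available <- rep(TRUE, length(c_idx))
  pairs_e <- integer(0); pairs_c <- integer(0)
  withr::with_seed(seed, {
    for (i in e_idx) {
      d <- abs(c_lg - lg[i])
      d[!available] <- Inf
      dmin <- min(d)
      if (is.finite(dmin) && dmin <= caliper) {
        cand <- which(d <= dmin + 1e-15)
        j <- if (length(cand) > 1L) cand[sample.int(length(cand), 1L)] else cand
        available[j] <- FALSE
        pairs_e <- c(pairs_e, i)
        pairs_c <- c(pairs_c, c_idx[j])
      }
    }
  })
  structure(list(pairs = tibble::tibble(exposed = pairs_e, control = pairs_c),
                 caliper = caliper, logit_sd = sdl,
                 n_exposed_input = sum(exposed),
                 n_control_input = sum(!exposed)),
            class = "matched_cohort")
}

#' Standardized mean difference between two groups
#'
#' Continuous: `|m1 - m2| / sqrt((s1^2 + s2^2) / 2)` with sample variances.
#' Binary: `|p1 - p2| / sqrt((p1 (1 - p1) + p2 (1 - p2)) / 2)`. Returns 0
#' when numerator and denominator are both 0.
#'
#' @param x Covariate values.
#' @param g Logical group flags (TRUE = group 1).
#' @param type `"auto"` detects binary (two distinct values or logical).
#' @return Nonnegative number.
#' @export
compute_smd <- function(x, g, type = c("auto", "continuous", "binary")) {
  type <- match.arg(type)
  g <- as.logical(g)
  x1 <- x[g]; x2 <- x[!g]
  if (type == "auto") {
    type <- if (is.logical(x) || length(unique(x[!is.na(x)])) <= 2L) "binary" else "continuous"
  }
  if (type == "binary") {
    p1 <- mean(as.numeric(x1)); p2 <- mean(as.numeric(x2))
    num <- abs(p1 - p2)
    den <- sqrt((p1 * (1 - p1) + p2 * (1 - p2)) / 2)
  } else {
    num <- abs(mean(x1) - mean(x2))
    den <- sqrt((var(x1) + var(x2)) / 2)
  }
  if (num == 0 && (is.na(den) || den == 0)) return(0)
  num / den
}

#' Covariate balance before and after matching
#'
#' One row per covariate with the standardized mean difference and a
#' two-group p-value (chi-squared for binary covariates, two-sample t-test
#' for continuous ones) computed on the full sample and on the matched
#' sample.
#'
#' @param data Data frame.
#' @param exposure Exposure column name.
#' @param covariates Covariate column names.
#' @param cohort A [match_caliper()] result.
#' @return Tibble: `covariate`, `smd_before`, `p_before`, `smd_after`,
#'   `p_after`.
#' @export
balance_table <- function(data, exposure, covariates, cohort) {
  stopifnot(inherits(cohort, "matched_cohort"))
  e <- as.logical(data[[exposure]])
  idx_m <- c(cohort$pairs$exposed, cohort$pairs$control)
  e_m <- e[idx_m]
  one <- function(v) {
    x <- data[[v]]
    binary <- is.logical(x) || length(unique(x[!is.na(x)])) <= 2L
    pval <- function(x, g) {
      tryCatch({
        if (binary) chisq.test(table(factor(as.numeric(x)), g))$p.value
        else t.test(x[g], x[!g])$p.value
      }, error = function(e) NA_real_)
    }
    tibble::tibble(covariate = v,
                   smd_before = compute_smd(x, e),
                   p_before = pval(x, e),
                   smd_after = compute_smd(x[idx_m], e_m),
                   p_after = pval(x[idx_m], e_m))
  }
  dplyr::bind_rows(lapply(covariates, one))
}

#' Reporting odds ratio on a matched cohort
#'
#' Tabulates the unpaired 2x2 table over the matched subjects (exposed vs
#' matched controls, event vs not) and completes it with the subtracted-
#' formula ROR and Woolf interval. A zero cell yields an undefined ROR, not
#' an error.
#'
#' @param cohort A [match_caliper()] result.
#' @param event Logical event flags over the original subjects, indexed by
#'   the cohort's pair indices.
#' @return A completed `contingency_signal`.
#' @export
matched_ror <- function(cohort, event) {
  stopifnot(inherits(cohort, "matched_cohort"))
  if (nrow(cohort$pairs) == 0L) abort("matched_ror: no matched pairs")
  a <- sum(event[cohort$pairs$exposed])
  b <- nrow(cohort$pairs) - a
  cc <- sum(event[cohort$pairs$control])
  d <- nrow(cohort$pairs) - cc
  compute_ror(contingency(a, b, cc, d))
}
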