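#' Extract times from drug start to event onset
#'
#' For each case report containing the target drug (or classified into the
#' target exposure group) and flagged with the target event, the duration is
#' onset date minus administration start date in whole days. Within a
#' report, duplicate (drug, start date) rows are collapsed to one; when a
#' drug has several distinct start dates the earliest is used. Rows with a
#' partial or missing date on either side are excluded and counted, as are
#' nonpositive durations (onset on or before the start, treated as
#' inconsistent) and durations beyond the analysis window.
#'
#' @param reports Integrated reports (suspected drugs only).
#' @param drug Target drug (product) name; exactly one of `drug`/`group`.
#' @param group Target exposure group label (requires `formulary`).
#' @param formulary A [load_formulary()] registry, needed for `group`.
#' @param event Logical case flags; defaults to [flag_diild()] on `reports`.
#' @param window Analysis window in days after the start of administration
#'   (default 365).
#' @return Object of class `onset_sample`: `label`, `durations` (days), and
#'   the exclusion counters `n_excluded_duplicates`,
#'   `n_excluded_incomplete_dates`, `n_excluded_inconsistent`,
#'   `n_excluded_beyond_window`.
#' @export
extract_durations <- function(reports, drug = NULL, group = NULL,
                              formulary = NULL, event = NULL, window = 365) {
  if (is.null(drug) == is.null(group)) {
    abort("extract_durations: supply exactly one of `drug` or `group`")
  }
  if (is.null(event)) event <- flag_diild(reports)
  if (!is.null(group)) {
    if (is.null(formulary)) abort("extract_durations: `group` requires `formulary`")
    in_target <- classify_group(reports, formulary) == group
    label <- group
  } else {
    in_target <- vapply(reports$drugs, function(d) {
      any(tolower(trimws(d$name)) == tolower(drug))
    }, logical(1))
    label <- drug
  }
  idx <- which(in_target & event)
  n_dup <- 0L; n_incomplete <- 0L; n_inconsistent <- 0L; n_beyond <- 0L
  durations <- integer(0)
  for (i in idx) {
    d <- reports$drugs[[i]]
    rows <- if (!is.null(drug)) {
      d[tolower(trimws(d$name)) == tolower(drug), , drop = FALSE]
    } else {
      keep <- !is.na(lookup_products(d$name, formulary))
      d[keep, , drop = FALSE]
    }
    dup <- duplicated(rows[, c("name", "start_date")])
    n_dup <- n_dup + sum(dup)
    rows <- rows[!dup, , drop = FALSE]
    start <- suppressWarnings(min(rows$start_date, na.rm = TRUE))
    ev <- reports$events[[i]]
    ild <- ev[(!is.na(ev$pt_code) & ev$pt_code == DIILD_PT_CODE) |
                (!is.na(ev$pt_name) & tolower(ev$pt_name) == DIILD_PT_NAME), ,
              drop = FALSE]
    onset <- suppressWarnings(min(ild$onset_date, na.rm = TRUE))
    if (!is.finite(start) || !is.finite(onset)) { n_incomplete <- n_incomplete + 1L; next }
    dt <- as.integer(onset - start)
    if (dt <= 0L) { n_inconsistent <- n_inconsistent + 1L; next }
    if (dt > window) { n_beyond <- n_beyond + 1L; next }
    durations <- c(durations, dt)
  }
  structure(list(label = label, durations = durations, window = window,
                 n_cases = length(idx),
                 n_excluded_duplicates = n_dup,
                 n_excluded_incomplete_dates = n_incomplete,
                 n_excluded_inconsistent = n_inconsistent,
                 n_excluded_beyond_window = n_beyond),
            class = "onset_sample")
}

as_durations <- function(sample) {
  if (inherits(sample, "onset_sample")) sample$durations else as.numeric(sample)
}

#' Median and interquartile range of onset times
#'
#' Percentiles use linear interpolation between closest ranks
#' ([stats::quantile()] type 7). The `formatted` element follows the
#' "36.0 (27.0–63.0)" convention of time-to-onset report tables.
#'
#' @param sample An `onset_sample` or numeric vector of durations.
#' @return List: `n`, `median`, `q1`, `q3`, `formatted`.
#' @export
summarize_durations <- function(sample) {
  x <- as_durations(sample)
  if (length(x) == 0L) abort("summarize_durations: empty sample")
  q <- unname(quantile(x, c(0.25, 0.5, 0.75), type = 7))
  list(n = length(x), median = q[2], q1 = q[1], q3 = q[3],
       formatted = sprintf("%.1f (%.1f–%.1f)", q[2], q[1], q[3]))
}

weibull_nll <- function(par, x) {
  # par = (log alpha, log beta)
  alpha <- exp(par[1]); beta <- exp(par[2])
  -sum(stats::dweibull(x, shape = beta, scale = alpha, log = TRUE))
}

#' Weibull maximum-likelihood fit of time-to-onset data
#'
#' Fits the two-parameter Weibull (scale `alpha` in days, shape `beta`) to
#' uncensored durations. The shape is found by Newton iteration on the
#' profile-likelihood score equation (tolerance 1e-10, at most 100
#' iterations) and the scale follows in closed form; 95% confidence
#' intervals are Wald intervals on the log-parameter scale using the
#' observed information. All observations are treated as events: reports
#' exist because the event occurred, so the analysis window acts as
#' truncation, not censoring.
#'
#' @param sample An `onset_sample` or numeric vector of positive durations;
#'   at least 10 observations are required (below that the interval is
#'   meaningless).
#' @param conf_level Confidence level.
#' @return Object of class `weibull_fit`: `alpha`, `beta`, `alpha_ci`,
#'   `beta_ci`, `classification`, `converged`, `n`, `log_likelihood`.
#' @export
fit_weibull <- function(sample, conf_level = 0.95) {
  x <- as_durations(sample)
  label <- if (inherits(sample, "onset_sample")) sample$label else NA_character_
  if (length(x) < 10L) {
    abort("fit_weibull: at least 10 uncensored durations are required")
  }
  if (any(x <= 0)) abort("fit_weibull: durations must be positive")
  out <- structure(list(label = label, alpha = NA_real_, beta = NA_real_,
                        alpha_ci = c(NA_real_, NA_real_),
                        beta_ci = c(NA_real_, NA_real_),
                        classification = NA_character_, converged = FALSE,
                        n = length(x), log_likelihood = NA_real_),
                   class = "weibull_fit")
  lx <- log(x)
  if (sd(lx) < 1e-12) return(out)  # degenerate: beta diverges
  # profile score for beta: sum(x^b log x)/sum(x^b) - 1/b - mean(log x) = 0
  g <- function(b) {
    xb <- x^b
    sum(xb * lx) / sum(xb) - 1 / b - mean(lx)
  }
  gprime <- function(b) {
    xb <- x^b
    s0 <- sum(xb); s1 <- sum(xb * lx); s2 <- sum(xb * lx^2)
    (s2 * s0 - s1^2) / s0^2 + 1 / b^2
  }
  b <- 1.2 / sd(lx)  # moment-style start
  converged <- FALSE
  for (it in seq_len(100L)) {
    step <- g(b) / gprime(b)
    b_new <- b - step
    if (!is.finite(b_new) || b_new <= 0) b_new <- b / 2
    if (abs(b_new - b) < 1e-10 * max(1, b)) { b <- b_new; converged <- TRUE; break }
    b <- b_new
  }
  if (!converged || b > 1e3) return(out)
  a <- mean(x^b)^(1 / b)
  par <- c(log(a), log(b))
  hess <- stats::optimHess(par, weibull_nll, x = x)
  vc <- tryCatch(solve(hess), error = function(e) NULL)
  if (is.null(vc) || any(diag(vc) <= 0)) return(out)
  z <- qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(diag(vc))
  out$alpha <- a; out$beta <- b
  out$alpha_ci <- exp(par[1] + c(-1, 1) * z * se[1])
  out$beta_ci <- exp(par[2] + c(-1, 1) * z * se[2])
  out$converged <- TRUE
  out$log_likelihood <- -weibull_nll(par, x)
  out$classification <- classify_hazard(out)
  out
}

#' Hazard-type classification from the Weibull shape parameter
#'
#' The shape parameter describes how the hazard of the event evolves after
#' the start of administration: `beta > 1` with a confidence interval
#' excluding 1 means an increasing hazard (wear-out failure), `beta < 1`
#' with the interval excluding 1 a decreasing hazard (initial failure), and
#' anything else is compatible with a constant hazard (random failure).
#'
#' @param fit A converged `weibull_fit`.
#' @return `"wear_out"`, `"initial_failure"`, or `"random_failure"`.
#' @export
classify_hazard <- function(fit) {
  stopifnot(inherits(fit, "weibull_fit"))
  if (!is.na(fit$classification)) return(fit$classification)
  if (is.na(fit$beta) || anyNA(fit$beta_ci)) {
    abort("classify_hazard: fit did not converge")
  }
  if (fit$beta > 1 && fit$beta_ci[1] > 1) "wear_out"
  else if (fit$beta < 1 && fit$beta_ci[2] < 1) "initial_failure"
  else "random_failure"
}

#' @export
print.weibull_fit <- function(x, ...) {
  if (!x$converged) {
    cat(sprintf("Weibull fit (n = %d): NOT CONVERGED\n", x$n))
  } else {
    cat(sprintf(
      "Weibull fit (n = %d): alpha = %.2f (%.2f–%.2f) days, beta = %.2f (%.2f–%.2f) [%s]\n",
      x$n, x$alpha, x$alpha_ci[1], x$alpha_ci[2],
      x$beta, x$beta_ci[1], x$beta_ci[2], x$classification))
  }
  invisible(x)
}

#' Kaplan-Meier curve of onset times
#'
#' Product-limit estimate treating every extracted duration as an event (no
#' censoring within the window), computed with [survival::survfit()]. With
#' no censoring this equals the empirical survival function.
#'
#' @param sample An `onset_sample` or numeric vector of durations.
#' @return Tibble `(time, surv)` of right-continuous steps, starting at
#'   `time = 0`, `surv = 1`.
#' @export
km_curve <- function(sample) {
  x <- as_durations(sample)
  if (length(x) == 0L) abort("km_curve: empty sample")
  sf <- survival::survfit(survival::Surv(x, rep(1L, length(x))) ~ 1)
  tibble::tibble(time = c(0, sf$time), surv = c(1, sf$surv))
}

#' Time-to-onset summary table over drugs or groups
#'
#' One row per target: case and duration counts, median (IQR) string,
#' Weibull scale and shape with confidence intervals, and hazard
#' classification. Targets with 10 or fewer usable durations get summary
#' statistics but no Weibull fit. The published convention of analyzing
#' drugs with more than 10 reported onset cases is applied through
#' `min_durations`.
#'
#' @param reports Integrated reports (suspected drugs only).
#' @param targets Character vector of drug names (`level = "drug"`) or group
#'   labels (`level = "group"`).
#' @param level `"drug"` or `"group"`.
#' @param formulary Registry, required for `level = "group"`.
#' @param event Logical case flags; defaults to [flag_diild()].
#' @param window Analysis window in days.
#' @param min_durations Minimum usable durations for a Weibull fit
#'   (default 10; targets at or below it keep `NA` fits).
#' @return Tibble, one row per target.
#' @export
tto_table <- function(reports, targets, level = c("drug", "group"),
                      formulary = NULL, event = NULL, window = 365,
                      min_durations = 10L) {
  level <- match.arg(level)
  if (is.null(event)) event <- flag_diild(reports)
  rows <- lapply(targets, function(tg) {
    s <- if (level == "drug") {
      extract_durations(reports, drug = tg, event = event, window = window)
    } else {
      extract_durations(reports, group = tg, formulary = formulary,
                        event = event, window = window)
    }
    n <- length(s$durations)
    med <- if (n > 0) summarize_durations(s) else NULL
    fit <- if (n > min_durations) fit_weibull(s) else NULL
    tibble::tibble(
      label = tg, n_cases = s$n_cases, n_durations = n,
      median_iqr = if (is.null(med)) NA_character_ else med$formatted,
      alpha = if (is.null(fit) || !fit$converged) NA_real_ else fit$alpha,
      alpha_low = if (is.null(fit) || !fit$converged) NA_real_ else fit$alpha_ci[1],
      alpha_high = if (is.null(fit) || !fit$converged) NA_real_ else fit$alpha_ci[2],
      beta = if (is.null(fit) || !fit$converged) NA_real_ else fit$beta,
      beta_low = if (is.null(fit) || !fit$converged) NA_real_ else fit$beta_ci[1],
      beta_high = if (is.null(fit) || !fit$converged) NA_real_ else fit$beta_ci[2],
      classification = if (is.null(fit) || !fit$converged) NA_character_ else fit$classification)
  })
  dplyr::bind_rows(rows)
}
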