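#' Fit a logistic regression by maximum likelihood
#'
#' Thin wrapper around iteratively reweighted least squares
#' ([stats::glm()] with a binomial family) returning a `logistic_fit`
#' object: term names, coefficients, covariance (inverse observed
#' information), log-likelihood, sample size and a convergence flag.
#' Convergence tolerance is a relative deviance change below 1e-10 within
#' 100 iterations. Perfect separation is flagged (`converged = FALSE`, with
#' a warning) rather than silently returning diverging estimates.
#'
#' @param formula Model formula with a logical/0-1 response.
#' @param data Data frame.
#' @return Object of class `logistic_fit`.
#' @export
fit_logistic <- function(formula, data) {
  response <- stats::model.response(stats::model.frame(formula, data))
  if (length(unique(response)) < 2L) {
    abort("fit_logistic: outcome is constant")
  }
  separated <- FALSE
  fit <- withCallingHandlers(
    glm(formula, family = binomial(), data = data,
        control = glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (length(coef(fit)) >= fit$df.null + 1) {
    abort("fit_logistic: more terms than observations")
  }
  if (separated) {
    warn("fit_logistic: possible complete separation; estimates unreliable")
  }
  structure(list(terms = names(coef(fit)),
                 coefficients = coef(fit),
                 covariance = vcov(fit),
                 log_likelihood = as.numeric(logLik(fit)),
                 n_obs = stats::nobs(fit),
                 converged = fit$converged && !separated,
                 separation = separated,
                 model = fit),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("logistic fit: %d terms, n = %d, logLik = %.3f%s\n",
              length(x$terms), x$n_obs, x$log_likelihood,
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(term_table(x))
  invisible(x)
}

#' Coefficient table with Wald confidence intervals
#'
#' @param fit A `logistic_fit`.
#' @param conf_level Confidence level.
#' @return Tibble: `term`, `estimate`, `se`, `ci_low`, `ci_high`, `p` (Wald).
#' @export
term_table <- function(fit, conf_level = 0.95) {
  z <- qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(diag(fit$covariance))
  est <- fit$coefficients
  tibble::tibble(term = fit$terms, estimate = unname(est), se = unname(se),
                 ci_low = unname(est - z * se), ci_high = unname(est + z * se),
                 p = unname(2 * stats::pnorm(-abs(est / se))))
}

#' Likelihood-ratio test between nested logistic fits
#'
#' @param full,reduced `logistic_fit` objects on the same observations, with
#'   the reduced model's terms a subset of the full model's.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
lrt <- function(full, reduced) {
  stopifnot(inherits(full, "logistic_fit"), inherits(reduced, "logistic_fit"))
  if (!all(reduced$terms %in% full$terms)) {
    abort("lrt: models are not nested (reduced terms must be a subset of full terms)")
  }
  if (full$n_obs != reduced$n_obs) {
    abort("lrt: models were fit on different numbers of observations")
  }
  df <- length(full$terms) - length(reduced$terms)
  stat <- max(0, 2 * (full$log_likelihood - reduced$log_likelihood))
  p <- if (df == 0L) {
    if (stat < 1e-8) 1 else 0
  } else {
    pchisq(stat, df = df, lower.tail = FALSE)
  }
  list(statistic = stat, df = df, p_value = p)
}

term_components <- function(term) strsplit(term, ":", fixed = TRUE)[[1]]

build_formula <- function(response, terms) {
  rhs <- if (length(terms) == 0L) "1" else paste(terms, collapse = " + ")
  stats::as.formula(paste(response, "~", rhs))
}

#' Forward-backward stepwise selection by likelihood-ratio tests
#'
#' Starting from the intercept (plus any forced `include` terms), alternates
#' forward entry and backward elimination using likelihood-ratio p-values
#' with the same threshold `alpha` for entry and stay. Model hierarchy is
#' enforced: an interaction (`"d1:a"`) may enter only while all its
#' components are in the model, and a main effect cannot leave while an
#' interaction containing it remains. Selection is deterministic given the
#' candidate order (ties by smaller p, then candidate order).
#'
#' @param data Data frame.
#' @param response Response column name (logical/0-1).
#' @param candidates Character vector of candidate terms; interactions as
#'   `"x:y"`.
#' @param alpha Entry and stay significance level (default 0.05).
#' @param include Terms forced into the model.
#' @return The final `logistic_fit`; `attr(, "selected")` holds the selected
#'   terms and `attr(, "steps")` the step log.
#' @export
stepwise_select <- function(data, response, candidates, alpha = 0.05,
                            include = character()) {
  current <- unique(include)
  steps <- list()
  refit <- function(terms) fit_logistic(build_formula(response, terms), data)
  fit_cur <- refit(current)
  repeat {
    changed <- FALSE
    # forward
    eligible <- setdiff(candidates, current)
    eligible <- eligible[vapply(eligible, function(t) {
      comp <- term_components(t)
      length(comp) == 1L || all(comp %in% current)
    }, logical(1))]
    if (length(eligible)) {
      ps <- vapply(eligible, function(t) {
        lrt(refit(c(current, t)), fit_cur)$p_value
      }, numeric(1))
      if (min(ps) < alpha) {
        add <- eligible[which.min(ps)]
        current <- c(current, add)
        fit_cur <- refit(current)
        steps[[length(steps) + 1L]] <- list(action = "add", term = add, p = min(ps))
        changed <- TRUE
      }
    }
    # backward
    removable <- setdiff(current, include)
    removable <- removable[vapply(removable, function(t) {
      !any(vapply(setdiff(current, t), function(u) {
        comp <- term_components(u)
        length(comp) > 1L && t %in% comp
      }, logical(1)))
    }, logical(1))]
    if (length(removable)) {
      ps <- vapply(removable, function(t) {
        lrt(fit_cur, refit(setdiff(current, t)))$p_value
      }, numeric(1))
      if (max(ps) >= alpha) {
        drop <- removable[which.max(ps)]
        current <- setdiff(current, drop)
        fit_cur <- refit(current)
        steps[[length(steps) + 1L]] <- list(action = "drop", term = drop, p = max(ps))
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  attr(fit_cur, "selected") <- current
  attr(fit_cur, "steps") <- steps
  fit_cur
}

#' Adjusted reporting odds ratio for a term or term combination
#'
#' For a single main effect this is `exp(coefficient)` with its Wald
#' interval. For an interaction row the combined effect is reported:
#' `exp(sum of the named coefficients)` — e.g. main effect + moderator +
#' interaction for the "exposure at moderator = 1" odds ratio — with the
#' interval from the delta method on the summed linear combination
#' (`var = 1' Sigma 1` over the named terms).
#'
#' @param fit A `logistic_fit`.
#' @param terms Term name(s) whose coefficients are summed at unit values.
#' @param conf_level Confidence level.
#' @return List with `or`, `ci_low`, `ci_high`, `log_or`, `se`.
#' @export
adjusted_or <- function(fit, terms, conf_level = 0.95) {
  stopifnot(inherits(fit, "logistic_fit"))
  missing <- setdiff(terms, fit$terms)
  if (length(missing)) {
    abort(sprintf("adjusted_or: term(s) not in fit: %s", paste(missing, collapse = ", ")))
  }
  est <- sum(fit$coefficients[terms])
  se <- sqrt(sum(fit$covariance[terms, terms]))
  z <- qnorm(1 - (1 - conf_level) / 2)
  list(or = exp(est), ci_low = exp(est - z * se), ci_high = exp(est + z * se),
       log_or = est, se = se)
}

#' Dose-response logistic fit for one crude drug
#'
#' Fits `log(odds) = b0 + b1 * intake` for a single crude drug's daily
#' intake; `exp(b1)` is the crude reporting odds ratio per gram per day.
#'
#' @param intake Daily intake in grams/day (nonnegative; `NA` rows dropped).
#' @param outcome Logical case flags.
#' @return A `logistic_fit` with extra elements `intercept`, `slope`,
#'   `ror_per_gram` (with `ci_low`/`ci_high`).
#' @export
fit_dose_response <- function(intake, outcome) {
  keep <- !is.na(intake) & !is.na(outcome)
  intake <- intake[keep]; outcome <- outcome[keep]
  if (any(intake < 0)) abort("fit_dose_response: intakes must be nonnegative")
  if (length(unique(intake)) < 2L) abort("fit_dose_response: intake is constant")
  fit <- fit_logistic(event ~ intake, tibble::tibble(event = outcome, intake = intake))
  or <- adjusted_or(fit, "intake")
  fit$intercept <- unname(fit$coefficients[1])
  fit$slope <- unname(fit$coefficients["intake"])
  fit$ror_per_gram <- or
  fit
}

#' Predicted dose-response curve
#'
#' @param fit A [fit_dose_response()] result.
#' @param grid Intake grid; defaults to 200 points over the observed range.
#' @return Tibble `(intake, prob)` of predicted event probabilities.
#' @export
dose_response_curve <- function(fit, grid = NULL) {
  stopifnot(inherits(fit, "logistic_fit"), !is.null(fit$slope))
  if (is.null(grid)) {
    r <- range(fit$model$model$intake)
    grid <- seq(r[1], r[2], length.out = 200)
  }
  tibble::tibble(intake = grid, prob = plogis(fit$intercept + fit$slope * grid))
}

#' Empirical ROC curve, AUC and intake cutoff
#'
#' Computes the empirical ROC over all distinct score thresholds
#' (classification rule: positive when `score >= threshold`), the area under
#' the curve by the trapezoid rule (equal to the Mann-Whitney concordance
#' probability), and an operating cutoff. The default cutoff maximizes
#' Youden's J = sensitivity + specificity - 1, operationalizing "highest
#' sensitivity while maintaining high specificity"; ties go to the smaller
#' threshold. `cutoff_method = "closest01"` instead minimizes the distance
#' to the (0, 1) corner.
#'
#' @param scores Numeric scores (e.g. daily intake in g/day).
#' @param labels Logical outcome flags; both classes must be present.
#' @param cutoff_method `"youden"` or `"closest01"`.
#' @return Object of class `roc_result`: `points` tibble
#'   `(threshold, fpr, tpr)`, `auc`, `cutoff`.
#' @export
roc_analysis <- function(scores, labels, cutoff_method = c("youden", "closest01")) {
  cutoff_method <- match.arg(cutoff_method)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- as.logical(labels[keep])
  if (!any(labels) || all(labels)) {
    abort("roc_analysis: both outcome classes must be present")
  }
  thr_fin <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  idx <- match(scores, thr_fin)
  k <- length(thr_fin)
  tpr <- c(0, cumsum(tabulate(idx[labels], nbins = k))) / n_pos
  fpr <- c(0, cumsum(tabulate(idx[!labels], nbins = k))) / n_neg
  thr <- c(Inf, thr_fin)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  finite <- is.finite(thr)
  crit <- switch(cutoff_method,
                 youden = (tpr - fpr)[finite],
                 closest01 = -sqrt((1 - tpr[finite])^2 + fpr[finite]^2))
  best <- which(crit >= max(crit) - 1e-12)
  cutoff <- min(thr[finite][best])
  structure(list(points = tibble::tibble(threshold = thr, fpr = fpr, tpr = tpr),
                 auc = auc, cutoff = cutoff, cutoff_method = cutoff_method),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.5f, cutoff (%s) = %g over %d thresholds\n",
              x$auc, x$cutoff_method, x$cutoff, nrow(x$points) - 1L))
  invisible(x)
}
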