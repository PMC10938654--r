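test_that("the intercept-only fit recovers logit of the prevalence exactly", {
  d <- tibble::tibble(event = rep(c(TRUE, FALSE), c(30, 70)))
  f <- fit_logistic(event ~ 1, d)
  expect_equal(unname(f$coefficients), qlogis(0.3), tolerance = 1e-8)
  expect_true(f$converged)
  expect_error(fit_logistic(event ~ 1, tibble::tibble(event = rep(TRUE, 10))),
               "constant")
})

test_that("known coefficients are recovered within 3 SE at large n", {
  truth <- c(intercept = -3, d1 = 0.4, d2 = 0.05, s = 0.37, a = 0.65,
             d1_a = 0.17, d1_d2 = -0.04)
  d <- simulate_covariate_outcomes(50000, truth, seed = 17)
  f <- fit_logistic(event ~ d1 + d2 + s + a + d1:a + d1:d2, d)
  tt <- term_table(f)
  key <- c("(Intercept)" = "intercept", d1 = "d1", d2 = "d2", s = "s", a = "a",
           "d1:a" = "d1_a", "d1:d2" = "d1_d2")
  for (term in tt$term) {
    row <- tt[tt$term == term, ]
    expect_lt(abs(row$estimate - truth[[key[[term]]]]), 3 * row$se, label = term)
  }
})

test_that("perfect separation is flagged, not silently returned", {
  d <- tibble::tibble(x = c(1:10, 21:30), event = rep(c(FALSE, TRUE), each = 10))
  expect_warning(f <- fit_logistic(event ~ x, d), "separation")
  expect_false(f$converged)
  expect_true(f$separation)
})

test_that("likelihood-ratio tests behave at the identity, under strong effects, and on non-nested models", {
  d <- simulate_covariate_outcomes(20000, c(intercept = -2, d1 = 0.5), seed = 23)
  full <- fit_logistic(event ~ d1 + s, d)
  same <- fit_logistic(event ~ d1 + s, d)
  res <- lrt(full, same)
  expect_equal(res$statistic, 0, tolerance = 1e-6)
  expect_identical(res$p_value, 1)
  reduced <- fit_logistic(event ~ s, d)
  expect_lt(lrt(full, reduced)$p_value, 1e-6)
  other <- fit_logistic(event ~ a, d)
  expect_error(lrt(full, other), "nested")
  short <- fit_logistic(event ~ d1, d[1:1000, ])
  expect_error(lrt(full, short), "observations")
})

test_that("stepwise selection keeps a true interaction with its components and drops null terms", {
  hits <- 0L
  n_reps <- 10L
  for (rep in seq_len(n_reps)) {
    d <- simulate_covariate_outcomes(30000, c(intercept = -2.8, d1 = 0.35,
                                              a = 0.6, d1_a = 0.25), seed = 100 + rep)
    f <- stepwise_select(d, "event", c("d1", "d2", "s", "a", "d1:a", "d1:d2"))
    sel <- attr(f, "selected")
    if (all(c("d1", "a", "d1:a") %in% sel) && !"d2" %in% sel) hits <- hits + 1L
  }
  # the null term enters with ~alpha probability per replicate, so allow the
  # binomial slack of a 95%-per-replicate success rate at 10 replicates
  expect_gte(hits, 8L)
})

test_that("stepwise on pure noise usually returns the intercept-only model", {
  empty <- 0L
  for (rep in 1:10) {
    d <- simulate_covariate_outcomes(2000, c(intercept = -1.5), seed = 200 + rep)
    f <- stepwise_select(d, "event", c("d1", "d2", "s", "a"))
    if (length(attr(f, "selected")) == 0L) empty <- empty + 1L
  }
  expect_gte(empty, 6L)
})

test_that("with selection disabled (all terms forced) stepwise equals a direct fit", {
  d <- simulate_covariate_outcomes(5000, c(intercept = -2, d1 = 0.3, a = 0.5), seed = 31)
  terms <- c("d1", "d2", "s", "a")
  f1 <- stepwise_select(d, "event", candidates = character(), include = terms)
  f2 <- fit_logistic(event ~ d1 + d2 + s + a, d)
  expect_equal(f1$coefficients, f2$coefficients)
  expect_equal(f1$log_likelihood, f2$log_likelihood)
})

test_that("adjusted odds ratios exponentiate coefficients and combine with the delta method", {
  d <- simulate_covariate_outcomes(20000, c(intercept = -2.5, d1 = 0.4, a = 0.6,
                                            d1_a = 0.2), seed = 37)
  f <- fit_logistic(event ~ d1 + a + d1:a, d)
  single <- adjusted_or(f, "d1")
  expect_equal(single$or, exp(unname(f$coefficients["d1"])))
  combo <- adjusted_or(f, c("d1", "a", "d1:a"))
  expect_equal(combo$or, exp(sum(f$coefficients[c("d1", "a", "d1:a")])))
  v <- sum(f$covariance[c("d1", "a", "d1:a"), c("d1", "a", "d1:a")])
  expect_equal(combo$se, sqrt(v))
  expect_error(adjusted_or(f, "d9"), "d9")
  # published-scale arithmetic: the combined exposure-at-age>=60 effect
  expect_equal(round(exp(0.38 + 0.65 + 0.17), 2), 3.32)
  expect_equal(round(exp(0.38), 2), 1.46)
})

test_that("dose-response fits expose the per-gram odds ratio and predicted curve", {
  d <- simulate_covariate_outcomes(20000, c(intercept = -2, d1 = 0.4), seed = 41)
  f <- fit_dose_response(d$d1, d$event)
  expect_lt(abs(f$slope - 0.4), 3 * term_table(f)$se[2])
  expect_equal(f$ror_per_gram$or, exp(f$slope))
  curve <- dose_response_curve(f, grid = c(0, 1, 2))
  expect_equal(curve$prob, plogis(f$intercept + f$slope * c(0, 1, 2)))
  # outcome independent of intake: slope compatible with zero
  f0 <- fit_dose_response(d$d1, sample(d$event))
  expect_lt(abs(f0$slope), 3 * term_table(f0)$se[2])
  expect_error(fit_dose_response(rep(2, 100), rbinom(100, 1, 0.5) == 1), "constant")
})

test_that("ROC analysis handles separation, null scores, and Youden ties", {
  sep <- roc_analysis(c(1, 2, 3, 11, 12, 13), c(F, F, F, T, T, T))
  expect_equal(sep$auc, 1)
  expect_gt(sep$cutoff, 3)
  expect_lte(sep$cutoff, 11)
  withr::with_seed(43, {
    null <- roc_analysis(runif(4000), runif(4000) < 0.3)
    expect_lt(abs(null$auc - 0.5), 0.03)
  })
  # all thresholds tie at J = 0 for constant-quality scores: smallest wins
  tie <- roc_analysis(c(1, 2, 3, 4), c(T, F, T, F))
  expect_identical(tie$cutoff, 1)
  expect_error(roc_analysis(1:5, rep(TRUE, 5)), "both")
})

test_that("trapezoid AUC equals the exhaustive pairwise concordance count", {
  mw_auc <- function(s, l) {
    pos <- s[l]; neg <- s[!l]
    tot <- 0
    for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
    tot / (length(pos) * length(neg))
  }
  withr::with_seed(47, {
    for (i in 1:10) {
      n <- sample(20:200, 1)
      s <- round(rweibull(n, 1.5, 2), sample(0:2, 1))  # ties likely
      l <- runif(n) < plogis(-0.5 + 0.4 * s)
      if (!any(l) || all(l)) next
      expect_equal(roc_analysis(s, l)$auc, mw_auc(s, l), tolerance = 1e-12)
    }
  })
})

test_that("AUC is invariant under strictly monotone transforms of the scores", {
  withr::with_seed(53, {
    s <- rexp(300); l <- runif(300) < plogis(-1 + s)
    a1 <- roc_analysis(s, l)$auc
    expect_equal(roc_analysis(log(s + 1), l)$auc, a1)
    expect_equal(roc_analysis(s^3, l)$auc, a1)
  })
})

test_that("independent ROC implementation agrees with pROC", {
  skip_if_not_installed("pROC")
  withr::with_seed(59, {
    s <- round(rweibull(500, 1.4, 2), 1)
    l <- runif(500) < plogis(-1 + 0.5 * s)
    ours <- roc_analysis(s, l)
    theirs <- pROC::roc(response = l, predictor = s, quiet = TRUE,
                        direction = "<")
    expect_equal(ours$auc, as.numeric(pROC::auc(theirs)), tolerance = 1e-10)
  })
})
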