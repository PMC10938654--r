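test_that("durations are whole-day differences with the stated exclusion rules", {
  form <- example_formulary()
  r <- dplyr::bind_rows(
    make_report("A", drugs = drug_row("Shosaikoto", start = "2020-01-01"),
                events = ild_event("2020-02-05")),                      # 35 days
    make_report("B", drugs = drug_row("Shosaikoto", start = "2020-03-01"),
                events = ild_event("2020-02-01")),                      # onset before start
    make_report("C", drugs = drug_row("Shosaikoto", start = NA),
                events = ild_event("2020-02-01")),                      # incomplete date
    make_report("D", drugs = drug_row("Shosaikoto", start = "2019-01-01"),
                events = ild_event("2020-06-01")),                      # beyond 365 days
    make_report("E", drugs = dplyr::bind_rows(drug_row("Shosaikoto", start = "2020-01-01"),
                                              drug_row("Shosaikoto", start = "2020-01-01")),
                events = ild_event("2020-01-11")),                      # duplicate rows
    make_report("F", drugs = drug_row("Shosaikoto", start = "2020-01-01"),
                events = other_event()))                                # not a case
  s <- extract_durations(r, drug = "Shosaikoto")
  expect_identical(sort(s$durations), c(10L, 35L))
  expect_identical(s$n_excluded_inconsistent, 1L)
  expect_identical(s$n_excluded_incomplete_dates, 1L)
  expect_identical(s$n_excluded_beyond_window, 1L)
  expect_identical(s$n_excluded_duplicates, 1L)
  # group-level extraction via the formulary
  sg <- extract_durations(r, group = "SR_BR_PT", formulary = form)
  expect_identical(sort(sg$durations), c(10L, 35L))
  expect_error(extract_durations(r), "exactly one")
})

test_that("median and IQR use linear rank interpolation and the report format", {
  s <- summarize_durations(c(1, 2, 3, 4, 5))
  expect_identical(c(s$median, s$q1, s$q3), c(3, 2, 4))
  one <- summarize_durations(7)
  expect_identical(c(one$median, one$q1, one$q3), c(7, 7, 7))
  expect_identical(one$formatted, "7.0 (7.0–7.0)")
  expect_error(summarize_durations(numeric(0)), "empty")
})

test_that("empirical medians of generated onsets match the Weibull closed form", {
  alpha <- 45; beta <- 1.4  # median ~ alpha * log(2)^(1/beta)
  withr::with_seed(83, x <- pmax(1, round(rweibull(4000, beta, alpha))))
  med_true <- alpha * log(2)^(1 / beta)
  expect_lt(abs(summarize_durations(x)$median - med_true), 2.5)
})

test_that("the Weibull MLE recovers parameters and flags degenerate inputs", {
  withr::with_seed(89, x <- rweibull(1000, shape = 1.36, scale = 40))
  f <- fit_weibull(x)
  expect_true(f$converged)
  expect_true(f$beta_ci[1] < 1.36 && 1.36 < f$beta_ci[2])
  expect_true(f$alpha_ci[1] < 40 && 40 < f$alpha_ci[2])
  expect_identical(f$classification, "wear_out")
  # exponential data: shape compatible with 1
  withr::with_seed(97, e <- rexp(1000, 1 / 50))
  fe <- fit_weibull(e)
  expect_identical(fe$classification, "random_failure")
  # degenerate: all durations equal
  fd <- fit_weibull(rep(30, 50))
  expect_false(fd$converged)
  expect_error(fit_weibull(1:5), "at least 10")
  expect_error(fit_weibull(c(rep(1, 9), 0, 3)), "positive")
})

test_that("the Weibull MLE agrees with an independent fitter", {
  skip_if_not_installed("fitdistrplus")
  withr::with_seed(101, x <- rweibull(500, shape = 1.2, scale = 55))
  ours <- fit_weibull(x)
  ref <- fitdistrplus::fitdist(x, "weibull")
  expect_equal(ours$beta, unname(ref$estimate["shape"]), tolerance = 1e-3)
  expect_equal(ours$alpha, unname(ref$estimate["scale"]), tolerance = 1e-3)
})

test_that("rescaling durations rescales the scale and preserves the shape", {
  withr::with_seed(103, x <- rweibull(800, shape = 1.5, scale = 30))
  f1 <- fit_weibull(x)
  f2 <- fit_weibull(3 * x)
  expect_equal(f2$beta, f1$beta, tolerance = 1e-6)
  expect_equal(f2$alpha, 3 * f1$alpha, tolerance = 1e-6)
})

test_that("hazard classification follows the shape-parameter rules", {
  mk <- function(beta, lo, hi) {
    structure(list(beta = beta, beta_ci = c(lo, hi), classification = NA_character_),
              class = "weibull_fit")
  }
  expect_identical(classify_hazard(mk(1.36, 1.20, 1.52)), "wear_out")
  expect_identical(classify_hazard(mk(1.31, 0.98, 1.68)), "random_failure")
  expect_identical(classify_hazard(mk(0.70, 0.50, 0.90)), "initial_failure")
  expect_error(classify_hazard(mk(NA, NA, NA)), "converge")
})

test_that("the Kaplan-Meier curve equals the empirical survival function without censoring", {
  k <- km_curve(10)
  expect_equal(k$time, c(0, 10))
  expect_equal(k$surv, c(1, 0))
  withr::with_seed(107, x <- sample(1:1000, 40))  # no ties
  k <- km_curve(x)
  expect_equal(k$surv, 1 - (0:40) / 40)
  withr::with_seed(109, xt <- sample(1:20, 60, replace = TRUE))  # heavy ties
  kt <- km_curve(xt)
  emp <- vapply(kt$time, function(t) mean(xt > t), numeric(1))
  expect_equal(kt$surv, emp)
})

test_that("the onset summary table fits only targets with enough durations", {
  cfg <- sim_config(4000, drug_catalog = list(
    drug_spec("Shosaikoto", 0.15, 12, onset_alpha = 40, onset_beta = 1.36),
    drug_spec("Kakkonto", 0.004, 4)),
    missing_date_rate = 0, seed = 113)
  paths <- generate_tables(cfg, file.path(tempdir(), "tto-tab"))
  b <- read_tables(paths$demo, paths$drug, paths$reac, paths$hist)
  r <- filter_suspected(integrate_reports(b))
  tab <- tto_table(r, c("Shosaikoto", "Kakkonto"), level = "drug")
  sho <- tab[tab$label == "Shosaikoto", ]
  expect_gt(sho$n_durations, 10L)
  expect_false(is.na(sho$beta))
  expect_true(is.na(tab$beta[tab$label == "Kakkonto"]))
})
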