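#' Build a 2x2 contingency table from explicit cell counts
#'
#' Cells follow the reporting-odds-ratio convention: `a` exposed cases,
#' `b` exposed non-cases, `c` unexposed cases, `d` unexposed non-cases.
#'
#' @param a,b,c,d Nonnegative integer counts.
#' @return Object of class `contingency_signal` (counts only; see
#'   [compute_ror()] to complete it).
#' @export
contingency <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0)) {
    abort("contingency: cell counts must be nonnegative")
  }
  structure(list(a = a, b = b, c = c, d = d, n_case = a,
                 ror = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                 formula = NA_character_),
            class = "contingency_signal")
}

#' Build a 2x2 table from exposed counts and whole-database margins
#'
#' The unexposed cells are obtained by subtraction from the database margins,
#' the convention used when a drug's reports are tabulated against the full
#' spontaneous-report background.
#'
#' @param case_exposed,noncase_exposed Exposed cell counts (`a`, `b`).
#' @param n_case_total,n_noncase_total Database margins: all case reports and
#'   all non-case reports (defaults: the April 2004 - April 2023 JADER
#'   extract margins, 36,745 and 793,334).
#' @return A `contingency_signal`.
#' @export
contingency_from_margins <- function(case_exposed, noncase_exposed,
                                     n_case_total = JADER_DIILD_CASES,
                                     n_noncase_total = JADER_DIILD_NONCASES) {
  contingency(case_exposed, noncase_exposed,
              n_case_total - case_exposed, n_noncase_total - noncase_exposed)
}

#' Count a 2x2 contingency table over a report set
#'
#' `a` and `b` are counted directly over the exposed reports; the unexposed
#' cells are computed by subtraction from the analysis-set margins, so that
#' the background is "all other reports in the database".
#'
#' @param reports Integrated reports (the full analysis set).
#' @param exposed,event Logical vectors over `reports`, or predicate
#'   functions applied to each report row.
#' @return A `contingency_signal` with counts only.
#' @export
build_contingency <- function(reports, exposed, event) {
  if (nrow(reports) == 0L) abort("build_contingency: empty report set")
  as_flags <- function(p) {
    if (is.function(p)) {
      vapply(seq_len(nrow(reports)), function(i) isTRUE(p(reports[i, ])), logical(1))
    } else {
      stopifnot(is.logical(p), length(p) == nrow(reports))
      p & !is.na(p)
    }
  }
  e <- as_flags(exposed)
  v <- as_flags(event)
  a <- sum(e & v)
  b <- sum(e & !v)
  contingency(a, b, sum(v) - a, sum(!v) - b)
}

#' Reporting odds ratio with Woolf confidence interval
#'
#' Completes a contingency table with the ROR point estimate and a Woolf
#' (log-scale normal) 95% confidence interval,
#' `exp(ln ROR +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`.
#'
#' Two cell conventions are supported. `"subtracted"` (default) uses the
#' unexposed cells `c`, `d`: `ROR = (a/c) / (b/d)`. `"marginal"` reproduces
#' the arithmetic of the worked example in which the denominators are the
#' database margins including the exposed reports: `ROR = (a/(a+c)) /
#' (b/(b+d))`. The two agree to table-rounding precision for rare exposures
#' but are not identical; the subtracted form is the one that reproduces the
#' published tables.
#'
#' The ROR is undefined (`NA`) when any cell of the chosen formula is zero,
#' and reported as such rather than as infinity; setting `continuity = TRUE`
#' applies a Haldane 0.5 correction to all cells instead (off by default).
#'
#' @param x A `contingency_signal`.
#' @param formula `"subtracted"` or `"marginal"`.
#' @param conf_level Confidence level (normal multiplier 1.96 at the default
#'   0.95).
#' @param continuity Apply the 0.5 continuity correction when a cell is zero.
#' @return The `contingency_signal` with `ror`, `ci_low`, `ci_high` filled.
#' @export
compute_ror <- function(x, formula = c("subtracted", "marginal"),
                        conf_level = 0.95, continuity = FALSE) {
  stopifnot(inherits(x, "contingency_signal"))
  formula <- match.arg(formula)
  cells <- switch(formula,
                  subtracted = c(x$a, x$b, x$c, x$d),
                  marginal = c(x$a, x$b, x$a + x$c, x$b + x$d))
  if (any(cells < 0)) abort("compute_ror: negative cell counts")
  if (any(cells == 0)) {
    if (!continuity) {
      x$ror <- NA_real_; x$ci_low <- NA_real_; x$ci_high <- NA_real_
      x$formula <- formula
      return(x)
    }
    cells <- cells + 0.5
  }
  z <- qnorm(1 - (1 - conf_level) / 2)
  ror <- (cells[1] / cells[3]) / (cells[2] / cells[4])
  se <- sqrt(sum(1 / cells))
  x$ror <- ror
  x$ci_low <- exp(log(ror) - z * se)
  x$ci_high <- exp(log(ror) + z * se)
  x$formula <- formula
  x
}

#' Signal criterion on a completed contingency table
#'
#' A drug-event pair is a signal when the lower bound of the ROR confidence
#' interval exceeds 1 and the case count reaches `min_cases`. With fewer than
#' two cases the signal is not evaluated (`NA`), matching the dashes of
#' published report tables.
#'
#' @param x A `contingency_signal` completed by [compute_ror()].
#' @param min_cases Minimum number of cases for a signal (default 3).
#' @return `TRUE`, `FALSE`, or `NA` (not evaluated, case count below 2).
#' @export
detect_signal <- function(x, min_cases = 3L) {
  stopifnot(inherits(x, "contingency_signal"))
  if (x$n_case < 2L) return(NA)
  if (is.na(x$ror) || is.na(x$ci_low)) return(NA)
  isTRUE(x$ci_low > 1) && x$n_case >= min_cases
}

#' @export
print.contingency_signal <- function(x, ...) {
  cat(sprintf("2x2 table: a=%d b=%d c=%d d=%d\n", x$a, x$b, x$c, x$d))
  if (!is.na(x$ror)) {
    cat(sprintf("ROR (%s): %s\n", x$formula, format_ror(x$ror, x$ci_low, x$ci_high)))
  } else if (!is.na(x$formula)) {
    cat("ROR: undefined (zero cell)\n")
  }
  invisible(x)
}

#' Format "ROR (low - high)" at one decimal, or a dash
#' @param ror,ci_low,ci_high Numbers (any `NA` yields a dash).
#' @export
format_ror <- function(ror, ci_low, ci_high) {
  ifelse(is.na(ror), "—",
         sprintf("%.1f (%.1f − %.1f)", ror, ci_low, ci_high))
}

#' Stratified signals against the whole-database background
#'
#' One contingency table per stratum level: exposed = reports in the stratum
#' (among the exposure-flagged, stratum-complete reports), with the unexposed
#' cells by subtraction from the database margins.
#'
#' @param reports Integrated reports after [demographic_subset()] for the
#'   stratifying variable.
#' @param by Column name to stratify on (`"sex"` or `"age_decade"`).
#' @param exposed,event Logical vectors over `reports`.
#' @param n_case_total,n_noncase_total Database margins for subtraction.
#' @param min_cases Passed to [detect_signal()].
#' @return A tibble with one row per stratum: counts, ROR, CI, signal flag.
#' @export
stratified_signals <- function(reports, by, exposed, event,
                               n_case_total = JADER_DIILD_CASES,
                               n_noncase_total = JADER_DIILD_NONCASES,
                               min_cases = 3L) {
  stopifnot(by %in% names(reports))
  strata <- reports[[by]]
  levels <- unique(strata[exposed & !is.na(strata)])
  levels <- levels[order(match(levels, c("male", "female", "<20", "20s", "30s",
                                         "40s", "50s", "60s", "70s", "80s+")))]
  rows <- lapply(levels, function(L) {
    in_stratum <- exposed & !is.na(strata) & strata == L
    a <- sum(in_stratum & event)
    b <- sum(in_stratum & !event)
    sig <- compute_ror(contingency(a, b, n_case_total - a, n_noncase_total - b))
    tibble::tibble(stratum = L, total = a + b, case = a, noncase = b,
                   ror = sig$ror, ci_low = sig$ci_low, ci_high = sig$ci_high,
                   signal = detect_signal(sig, min_cases))
  })
  dplyr::bind_rows(rows)
}

#' Per-product / per-group signal table
#'
#' Builds the report-count and ROR table for a set of exposure definitions:
#' one row per product (membership = the product is among the report's
#' suspected drugs) or per exposure group (reports classified into that
#' group; MIXED reports are excluded from every group's counts).
#'
#' @param reports Integrated reports (suspected drugs only).
#' @param formulary A [load_formulary()] registry.
#' @param event Logical case flags over `reports` (see [flag_diild()]).
#' @param level `"product"`, `"group"`, or `"both"`.
#' @param n_case_total,n_noncase_total Database margins.
#' @param min_cases Passed to [detect_signal()].
#' @return Tibble: `level`, `label`, `total`, `case`, `noncase`, `ror`,
#'   `ci_low`, `ci_high`, `signal`, and the formatted `ror_ci` string.
#' @export
signal_table <- function(reports, formulary, event,
                         level = c("both", "product", "group"),
                         n_case_total = JADER_DIILD_CASES,
                         n_noncase_total = JADER_DIILD_NONCASES,
                         min_cases = 3L) {
  level <- match.arg(level)
  group <- classify_group(reports, formulary)
  one_row <- function(lvl, label, flags) {
    a <- sum(flags & event)
    b <- sum(flags & !event)
    sig <- compute_ror(contingency(a, b, n_case_total - a, n_noncase_total - b))
    tibble::tibble(level = lvl, label = label, total = a + b, case = a,
                   noncase = b, ror = sig$ror, ci_low = sig$ci_low,
                   ci_high = sig$ci_high, signal = detect_signal(sig, min_cases),
                   ror_ci = format_ror(sig$ror, sig$ci_low, sig$ci_high))
  }
  out <- list()
  if (level %in% c("both", "group")) {
    groups <- c("SR", "BR", "PT", "SR_BR", "SR_PT", "BR_PT", "SR_BR_PT")
    out <- c(out, lapply(groups, function(g) one_row("group", g, group == g)))
  }
  if (level %in% c("both", "product")) {
    products <- formulary$product_name[formulary$group != "NONE"]
    has_product <- function(p) {
      vapply(reports$drugs, function(d) {
        any(tolower(trimws(d$name)) == tolower(p))
      }, logical(1))
    }
    out <- c(out, lapply(products, function(p) one_row("product", p, has_product(p))))
  }
  dplyr::bind_rows(out)
}

#' Published DIILD report counts from the JADER background
#'
#' Reference counts (and published ROR values) of interstitial-lung-disease
#' reports for SR/BR/PT-containing herbal medicines, exposure groups, and
#' sex/age strata, tabulated against the 830,079-report public JADER extract
#' (April 2004 - April 2023). Shipped as plain CSV; the `margin` row carries
#' the database totals used for subtraction.
#'
#' @return Tibble with columns `stratum`, `label`, `group`, `total`, `case`,
#'   `noncase`, `ror`, `ci_low`, `ci_high` (`NA` where the source prints a
#'   dash).
#' @export
diild_reference_counts <- function() {
  path <- system.file("extdata", "diild_reference_counts.csv", package = "kampovig")
  readr::read_csv(path, col_types = "ccciiinnn", progress = FALSE)
}
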