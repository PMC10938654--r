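#' @section Crude drugs of interest:
#' The three crude drugs tracked by the exposure analysis are Scutellariae
#' radix ("ogon", SR), Bupleuri radix ("saiko", BR) and Pinelliae tuber
#' ("hange", PT). A formulation's exposure group is the subset of these it
#' contains, written "SR", "SR_BR", "SR_BR_PT", ... or "NONE".
#' @name formulary
#' @keywords internal
NULL

CRUDE_COLS <- c(SR = "scutellariae_radix", BR = "bupleuri_radix", PT = "pinelliae_tuber")

group_label <- function(sr, br, pt) {
  parts <- c("SR", "BR", "PT")[c(sr, br, pt)]
  if (length(parts) == 0L) "NONE" else paste(parts, collapse = "_")
}

#' Load a Kampo formulation registry
#'
#' The registry is a CSV with columns `product_name`, `full_daily_dose_g`
#' (grams of granule product per full daily dose) and one column per crude
#' drug holding grams of that crude drug per full daily dose (0 or empty =
#' absent). The columns `scutellariae_radix`, `bupleuri_radix` and
#' `pinelliae_tuber` determine each product's exposure group.
#'
#' Crude contents vary across manufacturers, so the registry is data, never
#' code; the registry shipped with the package
#' (`system.file("extdata", "kampo_formulary_synthetic.csv", package =
#' "kampovig")`) carries synthetic placeholder compositions.
#'
#' @param path Registry CSV path.
#' @return A tibble of class `formulary` with one row per product, the crude
#'   content columns, and derived columns `contains` (list of crude-drug
#'   abbreviations) and `group`.
#' @export
load_formulary <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    product_name = readr::col_character(), .default = readr::col_double()),
    progress = FALSE)
  if (!all(c("product_name", "full_daily_dose_g") %in% names(df))) {
    abort("load_formulary: registry needs columns `product_name` and `full_daily_dose_g`")
  }
  dups <- unique(df$product_name[duplicated(df$product_name)])
  if (length(dups)) {
    abort(sprintf("load_formulary: duplicated product name(s): %s",
                  paste(dups, collapse = ", ")))
  }
  crude_cols <- setdiff(names(df), c("product_name", "full_daily_dose_g"))
  df[crude_cols] <- lapply(df[crude_cols], function(x) ifelse(is.na(x), 0, x))
  bad <- df$product_name[is.na(df$full_daily_dose_g) | df$full_daily_dose_g <= 0]
  if (length(bad)) {
    abort(sprintf("load_formulary: nonpositive full_daily_dose_g for: %s",
                  paste(bad, collapse = ", ")))
  }
  neg <- df$product_name[apply(as.matrix(df[crude_cols]) < 0, 1L, any)]
  if (length(neg)) {
    abort(sprintf("load_formulary: negative crude content for: %s",
                  paste(neg, collapse = ", ")))
  }
  for (ab in names(CRUDE_COLS)) {
    if (!CRUDE_COLS[[ab]] %in% names(df)) df[[CRUDE_COLS[[ab]]]] <- 0
  }
  has <- lapply(names(CRUDE_COLS), function(ab) df[[CRUDE_COLS[[ab]]]] > 0)
  names(has) <- names(CRUDE_COLS)
  df$contains <- Map(function(sr, br, pt) c("SR", "BR", "PT")[c(sr, br, pt)],
                     has$SR, has$BR, has$PT)
  df$group <- mapply(group_label, has$SR, has$BR, has$PT)
  attr(df, "crude_cols") <- crude_cols
  class(df) <- c("formulary", class(df))
  df
}

lookup_products <- function(names, formulary) {
  match(tolower(trimws(names)), tolower(formulary$product_name))
}

#' Classify a report into a crude-drug exposure group
#'
#' Each suspected Kampo product belongs to one of the 2^3 = 8 groups defined
#' by which of SR, BR, PT it contains. A report whose suspected Kampo all
#' share one group gets that group; products spanning different groups yield
#' `"MIXED"` (excluded from group-level signal counts); a report with no
#' resolvable Kampo is `"NONE"`. Drug names not present in the formulary are
#' treated as non-Kampo. The result does not depend on drug order.
#'
#' @param reports Integrated reports (after [filter_suspected()]).
#' @param formulary A [load_formulary()] registry.
#' @return Character vector of group labels, one per report.
#' @export
classify_group <- function(reports, formulary) {
  vapply(reports$drugs, function(d) {
    if (nrow(d) == 0L) return("NONE")
    idx <- lookup_products(d$name, formulary)
    idx <- idx[!is.na(idx)]
    if (length(idx) == 0L) return("NONE")
    groups <- unique(formulary$group[idx])
    if (length(groups) == 1L) groups else "MIXED"
  }, character(1))
}

#' Compute per-report daily crude-drug intake in grams
#'
#' For each suspected Kampo product, the daily intake of each crude drug is
#' the product's crude content per full daily dose scaled by the reported
#' product dose: `crude_g_per_day = crude_content * daily_dose_g /
#' full_daily_dose_g`, summed over the report's Kampo products. Reports whose
#' Kampo all lack a parseable dose — or any report where a Kampo dose is
#' missing — get missing intakes and are excluded from dose-based analyses.
#'
#' @param reports Integrated reports (after [filter_suspected()]).
#' @param formulary A [load_formulary()] registry.
#' @return Tibble with one row per report: `case_id`, `group`, `n_kampo`,
#'   `dose_missing`, and `sr_g`, `br_g`, `pt_g` daily intakes.
#' @export
report_daily_intake <- function(reports, formulary) {
  res <- lapply(reports$drugs, function(d) {
    if (nrow(d) == 0L) return(c(0, 0, 0, 0, 0))
    idx <- lookup_products(d$name, formulary)
    kampo <- !is.na(idx)
    if (!any(kampo)) return(c(0, 0, 0, 0, 0))
    dose <- d$daily_dose_g[kampo]
    if (anyNA(dose)) return(c(NA_real_, NA_real_, NA_real_, sum(kampo), 1))
    rows <- idx[kampo]
    scale <- dose / formulary$full_daily_dose_g[rows]
    c(sum(formulary[[CRUDE_COLS[["SR"]]]][rows] * scale),
      sum(formulary[[CRUDE_COLS[["BR"]]]][rows] * scale),
      sum(formulary[[CRUDE_COLS[["PT"]]]][rows] * scale),
      sum(kampo), 0)
  })
  m <- do.call(rbind, res)
  tibble::tibble(case_id = reports$case_id,
                 group = classify_group(reports, formulary),
                 n_kampo = as.integer(m[, 4]),
                 dose_missing = m[, 5] == 1,
                 sr_g = m[, 1], br_g = m[, 2], pt_g = m[, 3])
}
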