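#' @export
print.vasari_report <- function(x, ...) {
  f <- x$features
  cat("<vasari_report>\n")
  for (nm in names(f)) cat(sprintf("  %-4s %s\n", nm, as.character(f[[nm]])))
  v <- x$raw$volume_mm3
  cat(sprintf("  volumes (mm^3): ET %.0f | necrosis %.0f | NET %.0f | PS %.0f\n",
              v$et, v$necrosis, v$net_residual, v$ps))
  if (!is.na(x$raw$thickness_mm) && x$raw$thickness_mm > 0)
    cat(sprintf("  enhancing margin %.2f mm\n", x$raw$thickness_mm))
  invisible(x)
}

# 0-based ordinal code of a feature value under the declared level sets
feature_code <- function(feature, value) {
  levs <- vasari_feature_levels()[[feature]]
  m <- match(as.character(value), levs)
  if (is.na(m)) NA_integer_ else m - 1L
}

#' Flatten one or more VASARI reports to a tibble
#'
#' One row per report: the 15 feature codes as character/logical columns,
#' plus raw measurement columns prefixed `raw_`.
#'
#' @param x a `vasari_report`.
#' @param ... unused.
#' @return a tibble with one row.
#' @export
as_tibble.vasari_report <- function(x, ...) {
  f <- x$features
  v <- x$raw$volume_mm3
  tibble(
    f1 = f$f1, f2 = f$f2, f4 = f$f4, f5 = f$f5, f6 = f$f6, f7 = f$f7,
    f9 = f$f9, f11 = f$f11, f14 = f$f14,
    f19 = f$f19, f20 = f$f20, f21 = f$f21, f22 = f$f22, f23 = f$f23,
    f24 = f$f24,
    raw_lesion_mm3 = v$lesion, raw_et_mm3 = v$et,
    raw_necrosis_mm3 = v$necrosis, raw_net_mm3 = v$net_residual,
    raw_ps_mm3 = v$ps,
    raw_thickness_mm = x$raw$thickness_mm,
    raw_n_core_components = x$raw$n_core_components,
    raw_n_et_components = x$raw$n_et_components,
    raw_epicentre_region = x$raw$epicentre_region %||% NA_character_
  )
}

#' Bind a list of VASARI reports into a cohort table
#'
#' @param reports list of `vasari_report` objects (optionally named; names
#'   become `case_id`).
#' @return tibble with one row per case.
#' @export
vasari_table <- function(reports) {
  stopifnot(length(reports) > 0)
  ids <- names(reports) %||% sprintf("case_%03d", seq_along(reports))
  if (is.null(names(reports))) names(reports) <- ids
  dplyr::bind_rows(lapply(reports, as_tibble), .id = "case_id")
}

#' Serialise a VASARI report to JSON
#'
#' Feature codes are emitted both as human-readable strings and as ordinal
#' integers under the declared category sets; raw measurements are
#' included so the binning can be audited.
#'
#' @param report a `vasari_report`.
#' @param path output file; `NULL` returns the JSON string.
#' @return `path` (or the JSON string), invisibly.
#' @export
write_report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "vasari_report"))
  f <- report$features
  payload <- list(
    features = lapply(setNames(names(f), names(f)), function(nm) {
      list(label = as.character(f[[nm]]), code = feature_code(nm, f[[nm]]))
    }),
    raw = report$raw,
    params = report$params
  )
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null", pretty = TRUE)
  if (is.null(path)) return(invisible(as.character(js)))
  writeLines(js, path)
  invisible(path)
}

#' Serialise VASARI reports to a flat CSV
#'
#' @param reports a single `vasari_report` or a list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(reports, path) {
  if (inherits(reports, "vasari_report")) reports <- list(case_001 = reports)
  readr::write_csv(vasari_table(reports), path)
  invisible(path)
}

#' Encode VASARI reports as a rater table for agreement analysis
#'
#' Converts report feature labels into the ordinal integer codes of the
#' declared category sets (see [vasari_feature_levels()]), producing the
#' long-format rater table the agreement metrics consume.
#'
#' @param reports list of `vasari_report` objects, optionally named by case.
#' @param rater_id identifier recorded in the `rater_id` column.
#' @param covariates optional tibble with `case_id`, `age`, `sex` columns
#'   to join on.
#' @return tibble with columns `case_id`, `rater_id`, `feature_id`, `code`
#'   (plus any covariates).
#' @export
as_rater_table <- function(reports, rater_id = "engine", covariates = NULL) {
  tab <- vasari_table(reports)
  long <- tab |>
    select("case_id", dplyr::all_of(names(vasari_feature_levels()))) |>
    mutate(across(-"case_id", as.character)) |>
    tidyr::pivot_longer(-"case_id", names_to = "feature_id",
                        values_to = "label") |>
    mutate(
      code = purrr::map2_int(.data$feature_id, .data$label, feature_code),
      rater_id = rater_id
    ) |>
    select("case_id", "rater_id", "feature_id", "code")
  if (!is.null(covariates)) long <- left_join(long, covariates, by = "case_id")
  long
}
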