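#' Dice-Sørensen overlap between two binary masks
#'
#' `2|A∩B| / (|A|+|B|)`. When both masks are empty the score is defined as
#' 1 (agreement on absence), avoiding an undefined 0/0 when a compartment
#' is lesion-free in both segmentations.
#'
#' @param a,b logical arrays/vectors of identical shape.
#' @return numeric in \[0, 1\].
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b)) || length(a) != length(b))
    stop_data("dice: mask shapes differ")
  a <- as.logical(a); b <- as.logical(b)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Cohen's kappa, optionally linearly weighted for ordinal scales
#'
#' Computed in the disagreement form `1 - sum(w * O) / sum(w * E)` where O
#' is the observed confusion matrix (proportions), E the expected matrix
#' from the marginal products, and `w_ij = |i - j| / (k - 1)` for linear
#' weighting over k ordered categories (0/1 disagreement weights when
#' unweighted). The weight matrix is built over the declared category list
#' when given, so unobserved categories still shape the weights.
#'
#' Degenerate margins: identical constant ratings give kappa = 1, flagged
#' via `attr(, "flag") = "degenerate-identical"`; non-identical ratings
#' with zero expected disagreement give `NA` flagged `"undefined"`.
#'
#' @param x,y paired rating vectors (coercible to a common category set).
#' @param weighting `"none"` or `"linear"`.
#' @param categories optional ordered vector of all categories; default is
#'   the sorted union of the observed values.
#' @return numeric in \[-1, 1\] (possibly with a `flag` attribute).
#' @export
cohen_kappa <- function(x, y, weighting = c("none", "linear"),
                        categories = NULL) {
  weighting <- match.arg(weighting)
  if (length(x) != length(y)) stop_data("kappa: rating vectors differ in length")
  if (length(x) < 2) stop_data("kappa: need at least 2 paired ratings")
  if (is.null(categories)) categories <- sort(unique(c(x, y)))
  xi <- match(x, categories); yi <- match(y, categories)
  if (anyNA(xi) || anyNA(yi))
    stop_data("kappa: ratings outside the declared category set")
  k <- length(categories)
  n <- length(x)
  O <- matrix(0, k, k)
  for (i in seq_len(n)) O[xi[i], yi[i]] <- O[xi[i], yi[i]] + 1
  O <- O / n
  E <- rowSums(O) %o% colSums(O)
  W <- if (k == 1L) {
    matrix(0, 1, 1)
  } else if (weighting == "linear") {
    abs(outer(seq_len(k), seq_len(k), `-`)) / (k - 1)
  } else {
    1 - diag(k)
  }
  ew <- sum(W * E)
  if (ew == 0) {
    if (all(xi == yi)) return(structure(1, flag = "degenerate-identical"))
    return(structure(NA_real_, flag = "undefined"))
  }
  1 - sum(W * O) / ew
}

#' Balanced accuracy (mean per-class recall)
#'
#' Classes are those present in `truth`; each class contributes its recall
#' and the result is their unweighted mean, making the score robust to
#' class imbalance.
#'
#' @param truth,pred paired rating vectors; `truth` defines the class set.
#' @return numeric in \[0, 1\].
#' @export
balanced_accuracy <- function(truth, pred) {
  if (length(truth) != length(pred))
    stop_data("balanced_accuracy: vectors differ in length")
  if (length(truth) == 0) stop_data("balanced_accuracy: empty input")
  classes <- unique(truth)
  mean(vapply(classes, function(cl) {
    mean(pred[truth == cl] == cl)
  }, numeric(1)))
}

# [20,30), ..., [80,90) age-decade label, NA outside the cohort range
age_decade <- function(age) {
  d <- floor(age / 10) * 10
  ifelse(!is.na(age) & d >= 20 & d <= 80, sprintf("%d-%d", d, d + 9),
         NA_character_)
}

#' Agreement metrics stratified by sex and age decade
#'
#' Joins two rater tables by case and feature, forms sex-by-decade strata
#' (decades are closed-open intervals \[20,30) ... \[80,90)), and computes
#' the chosen metric per feature within each stratum. Strata with fewer
#' than `min_cases` paired cases are reported as insufficient rather than
#' as a number.
#'
#' @param table_a,table_b rater tables (columns `case_id`, `feature_id`,
#'   `code`; `table_a` must also carry `age` and `sex`).
#' @param metric `"kappa"` or `"balanced_accuracy"`; for kappa, ordinal
#'   features (more than two declared categories) are linearly weighted,
#'   matching the convention that only non-Boolean features are weighted.
#' @param min_cases minimum paired cases for a stratum to be scored.
#' @return tidy tibble: `feature_id`, `sex`, `decade`, `metric`, `value`,
#'   `n`, `flag`.
#' @export
equity_stratification <- function(table_a, table_b,
                                  metric = c("kappa", "balanced_accuracy"),
                                  min_cases = 2L) {
  metric <- match.arg(metric)
  need <- c("case_id", "feature_id", "code")
  for (tb in list(table_a, table_b))
    if (!all(need %in% names(tb)))
      stop_data("rater tables need columns: %s", paste(need, collapse = ", "))
  if (!all(c("age", "sex") %in% names(table_a)))
    stop_data("equity stratification requires age and sex covariates")

  paired <- inner_join(
    table_a |> select("case_id", "feature_id", a = "code", "age", "sex"),
    table_b |> select("case_id", "feature_id", b = "code"),
    by = c("case_id", "feature_id")
  ) |>
    mutate(decade = age_decade(.data$age)) |>
    filter(!is.na(.data$decade), !is.na(.data$sex))

  levels_map <- vasari_feature_levels()
  paired |>
    group_by(.data$feature_id, .data$sex, .data$decade) |>
    summarise(
      n = dplyr::n(),
      value = {
        if (dplyr::n() < min_cases) NA_real_
        else {
          feat <- .data$feature_id[1]
          levs <- levels_map[[feat]]
          cats <- if (!is.null(levs)) seq_along(levs) - 1L
                  else sort(unique(c(.data$a, .data$b)))
          if (metric == "kappa") {
            w <- if (length(cats) > 2) "linear" else "none"
            as.numeric(cohen_kappa(.data$a, .data$b, weighting = w,
                                   categories = cats))
          } else {
            balanced_accuracy(.data$a, .data$b)
          }
        }
      },
      .groups = "drop"
    ) |>
    mutate(metric = metric,
           flag = ifelse(.data$n < min_cases, "insufficient", "ok")) |>
    select("feature_id", "sex", "decade", "metric", "value", "n", "flag")
}

#' Per-feature agreement between two rater tables
#'
#' Unstratified companion to [equity_stratification()]: one kappa (or
#' balanced accuracy) per feature over all paired cases, plus an
#' unweighted mean across features (labelled as such — whether a mean
#' kappa should weight features differently is a reporting choice).
#'
#' @inheritParams equity_stratification
#' @return list with `per_feature` tibble and `mean_value`.
#' @export
agreement_summary <- function(table_a, table_b,
                              metric = c("kappa", "balanced_accuracy")) {
  metric <- match.arg(metric)
  paired <- inner_join(
    table_a |> select("case_id", "feature_id", a = "code"),
    table_b |> select("case_id", "feature_id", b = "code"),
    by = c("case_id", "feature_id")
  )
  if (!nrow(paired)) stop_data("no paired cases between the rater tables")
  levels_map <- vasari_feature_levels()
  per <- paired |>
    group_by(.data$feature_id) |>
    summarise(
      n = dplyr::n(),
      value = {
        feat <- .data$feature_id[1]
        levs <- levels_map[[feat]]
        cats <- if (!is.null(levs)) seq_along(levs) - 1L
                else sort(unique(c(.data$a, .data$b)))
        if (metric == "kappa") {
          w <- if (length(cats) > 2) "linear" else "none"
          as.numeric(cohen_kappa(.data$a, .data$b, weighting = w,
                                 categories = cats))
        } else balanced_accuracy(.data$a, .data$b)
      },
      .groups = "drop"
    ) |>
    mutate(metric = metric)
  list(per_feature = per,
       mean_value = mean(per$value, na.rm = TRUE))
}
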