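#' Encode a VASARI cohort table as a numeric design matrix
#'
#' Ordinal features (proportion bins, enhancement quality, margin
#' thickness, focality, epicentre side) enter as integer scores under the
#' declared category order; booleans as 0/1; the categorical location (F1)
#' is one-hot encoded with the most frequent location as the reference
#' level.
#'
#' @param tbl cohort tibble from [vasari_table()] (feature columns f1 ...
#'   f24).
#' @return tibble of numeric predictors (no intercept column).
#' @export
encode_vasari_design <- function(tbl) {
  levs <- vasari_feature_levels()
  ordinal <- c("f2", "f4", "f5", "f6", "f7", "f9", "f11", "f14")
  boolean <- c("f19", "f20", "f21", "f22", "f23", "f24")
  out <- tibble(.rows = nrow(tbl))
  for (nm in ordinal) {
    out[[nm]] <- match(as.character(tbl[[nm]]), levs[[nm]]) - 1L
  }
  for (nm in boolean) out[[nm]] <- as.integer(as.logical(tbl[[nm]]))
  locs <- as.character(tbl$f1)
  ref <- names(sort(table(locs), decreasing = TRUE))[1]
  for (lv in setdiff(unique(locs), ref)) {
    safe <- gsub("[^a-z0-9]+", "_", tolower(lv))
    out[[paste0("f1_", safe)]] <- as.integer(locs == lv)
  }
  out
}

# VIFs of every column of a numeric design (1/(1 - R^2_j) of column j
# regressed on the others); intercept included in the auxiliary fits
design_vifs <- function(X) {
  X <- as.matrix(X)
  p <- ncol(X)
  vapply(seq_len(p), function(j) {
    y <- X[, j]
    if (stats::var(y) == 0) return(Inf)      # constant column
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), y)
    r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' Variance-inflation-factor pre-filter for a regression design
#'
#' Iteratively removes the column with the highest VIF while any VIF
#' exceeds the threshold (10, the conventional multicollinearity cut-off).
#' VIF_j = 1 / (1 - R^2_j) from regressing column j on the remaining
#' columns. Ties (including perfectly collinear pairs, whose VIFs are
#' infinite) are broken by retaining the earlier column and removing the
#' later one.
#'
#' @param design numeric matrix or data frame of predictors (no intercept
#'   column); at least 2 columns and more rows than columns.
#' @param threshold VIF above which a column is dropped (default 10).
#' @return list with `retained`/`removed` column names and `vifs`, the
#'   final VIFs of the retained columns.
#' @export
vif_filter <- function(design, threshold = 10) {
  X <- as.matrix(design)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (ncol(X) < 2) stop_data("vif_filter needs at least 2 columns")
  if (nrow(X) <= ncol(X))
    stop_data("vif_filter needs more rows than columns")
  removed <- character()
  repeat {
    v <- design_vifs(X)
    if (all(v <= threshold, na.rm = TRUE) || ncol(X) == 1L) break
    worst <- max(which(v == max(v)))    # ties: drop the later column
    removed <- c(removed, colnames(X)[worst])
    X <- X[, -worst, drop = FALSE]
  }
  list(retained = colnames(X), removed = removed,
       vifs = setNames(design_vifs(X), colnames(X)))
}

#' Ordinary least-squares model of overall survival on VASARI features
#'
#' Fits `OS ~ 1 + f1 + f2 + ... + fn` by least squares after
#' variance-inflation-factor pre-filtering of the encoded feature design.
#' Deliberately linear and unpartitioned: at cohort sizes of order 100 a
#' nonlinear or train/test-split model would be the more fragile choice.
#'
#' @param data tibble holding the outcome column and numeric predictors
#'   (e.g. [encode_vasari_design()] output bound to an `os_days` column).
#' @param outcome name of the outcome column (default `"os_days"`).
#' @param vif_threshold VIF cut-off passed to [vif_filter()] (`Inf`
#'   disables filtering beyond rank-deficiency protection).
#' @return an `os_fit`: the underlying `lm`, the retained/removed
#'   predictors and their VIFs, and `r_squared`. Supports
#'   [generics::tidy()] and [generics::glance()].
#' @export
fit_os_model <- function(data, outcome = "os_days", vif_threshold = 10) {
  if (!outcome %in% names(data))
    stop_data("outcome column '%s' not found", outcome)
  y <- data[[outcome]]
  if (any(y < 0)) stop_data("overall survival must be non-negative")
  X <- data[setdiff(names(data), outcome)]
  keep <- vapply(X, function(col) stats::var(col) > 0, logical(1))
  dropped_const <- names(X)[!keep]
  X <- X[keep]
  flt <- if (ncol(X) >= 2) {
    vif_filter(X, threshold = vif_threshold)
  } else {
    list(retained = names(X), removed = character(),
         vifs = setNames(rep(1, ncol(X)), names(X)))
  }
  Xr <- X[flt$retained]
  df <- data.frame(.os = y, Xr, check.names = FALSE)
  fit <- if (ncol(df) == 1L) lm(.os ~ 1, data = df)
         else lm(.os ~ ., data = df)
  if (any(is.na(coef(fit))))
    stop_data("design is rank deficient after filtering; lower vif_threshold")
  structure(
    list(lm = fit, retained = flt$retained,
         removed = c(dropped_const, flt$removed), vifs = flt$vifs,
         r_squared = summary(fit)$r.squared, n = nrow(df)),
    class = "os_fit"
  )
}

#' @export
print.os_fit <- function(x, ...) {
  cat(sprintf("<os_fit> n = %d, %d predictors retained (%d removed), R^2 = %.3f\n",
              x$n, length(x$retained), length(x$removed), x$r_squared))
  invisible(x)
}

#' @rdname fit_os_model
#' @param x an `os_fit`.
#' @param ... unused.
#' @export
tidy.os_fit <- function(x, ...) {
  s <- summary(x$lm)$coefficients
  tibble(term = rownames(s), estimate = s[, 1], std_error = s[, 2],
         statistic = s[, 3], p_value = s[, 4])
}

#' @rdname fit_os_model
#' @export
glance.os_fit <- function(x, ...) {
  s <- summary(x$lm)
  tibble(r_squared = s$r.squared, adj_r_squared = s$adj.r.squared,
         sigma = s$sigma, n = x$n,
         n_retained = length(x$retained), n_removed = length(x$removed))
}

#' Per-case predictions of an OS fit
#'
#' @param object an `os_fit`.
#' @param ... unused.
#' @return numeric vector of fitted survival (days).
#' @export
predict.os_fit <- function(object, ...) unname(fitted(object$lm))
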