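#' Natural-log transform of LFQ intensities
#'
#' Label-free-quantification intensities enter all fits as Ln(LFQ).
#' Non-positive intensities are the standard missing-value code in LFQ
#' output; they propagate as `NA` (the unit is excluded from fits using
#' that protein) and are counted in a warning rather than log-imputed.
#'
#' @param lfq Numeric vector of raw intensities.
#' @return `log(lfq)`, with `NA` where `lfq <= 0` or missing.
#' @export
log_transform <- function(lfq) {
  lfq <- as.numeric(lfq)
  bad <- !is.na(lfq) & lfq <= 0
  if (any(bad))
    warning(sprintf("%d non-positive LFQ intensities treated as missing",
                    sum(bad)))
  out <- rep(NA_real_, length(lfq))
  ok <- !is.na(lfq) & lfq > 0
  out[ok] <- log(lfq[ok])
  out
}

.check_columns <- function(table, cols) {
  miss <- setdiff(cols, names(table))
  if (length(miss))
    stop("missing column(s) in proteomics table: ",
         paste(miss, collapse = ", "))
}

#' Fit a linear deformability predictor from membrane proteomics
#'
#' Least-squares fit of a unit-level deformability response (median or
#' average elongation ratio) on the Ln(LFQ) level of one membrane protein,
#' optionally combined with the membrane-bound hemoglobin beta-subunit
#' (HBB):
#' `response = a * [protein] + b * [HBB] + intercept`.
#'
#' The reported `R` is the (multiple) correlation coefficient
#' `sqrt(R-squared)`; for a single predictor it equals the absolute Pearson
#' correlation. The p-value is the regression's overall F-test, which for a
#' single predictor coincides with the two-sided Pearson correlation test.
#' An intercept is included by default; the no-intercept variant
#' (`intercept = FALSE`) mirrors the bare two-coefficient equation, but note
#' that without centering `R` loses its Pearson interpretation (it is then
#' reported as the correlation between fitted and observed values).
#'
#' @param table Proteomics data frame: one row per unit, Ln(LFQ) columns
#'   per protein, and the response column.
#' @param protein Column name of the membrane protein predictor.
#' @param hbb Column name of the membrane-bound HBB predictor, or `NULL`
#'   for a single-protein fit.
#' @param response Response column name (default `"mer"`; `"aer"` is the
#'   common alternative).
#' @param intercept Include an intercept (default `TRUE`).
#' @return An object of class `biomarker_fit` with `print`, `summary`,
#'   `coef`, `confint`, `predict`, `residuals` and `plot` methods.
#' @examples
#' tab <- simulate_proteomics(proteomics_sim_params(), seed = 1)
#' fit <- fit_biomarker(tab, "flotillin_1", hbb = "HBB")
#' fit$R
#' @export
fit_biomarker <- function(table, protein, hbb = NULL, response = "mer",
                          intercept = TRUE) {
  stopifnot(is.data.frame(table), length(protein) == 1L)
  predictors <- c(protein, hbb)
  .check_columns(table, c(predictors, response))
  cols <- c(response, predictors)
  dat <- table[, cols, drop = FALSE]
  for (cl in cols) dat[[cl]] <- as.numeric(dat[[cl]])
  complete <- stats::complete.cases(dat)
  n_excluded <- sum(!complete)
  dat <- dat[complete, , drop = FALSE]
  n <- nrow(dat)
  min_n <- if (is.null(hbb)) 3L else 4L
  if (n < min_n)
    stop(sprintf("insufficient data: need >= %d complete units, have %d",
                 min_n, n))
  for (p in predictors)
    if (stats::sd(dat[[p]]) == 0)
      stop("degenerate fit: predictor '", p, "' has zero variance")
  rhs <- paste(sprintf("`%s`", predictors), collapse = " + ")
  if (!intercept) rhs <- paste(rhs, "- 1")
  fml <- stats::as.formula(sprintf("`%s` ~ %s", response, rhs))
  fit <- stats::lm(fml, data = dat)
  if (length(predictors) > 1L) {
    kappa_x <- kappa(stats::model.matrix(fit), exact = TRUE)
    if (kappa_x > 1e8)
      warning(sprintf("near-collinear predictors (condition number %.3g)",
                      kappa_x))
  }
  sm <- summary(fit)
  if (intercept) {
    R <- sqrt(sm$r.squared)
    fstat <- sm$fstatistic
    p_value <- if (is.null(fstat)) NA_real_ else
      unname(stats::pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE))
  } else {
    # uncentered R^2 is not a Pearson quantity; report the fitted-observed
    # correlation and the overall F against the zero model
    R <- if (stats::sd(stats::fitted(fit)) > 0)
      abs(stats::cor(stats::fitted(fit), dat[[response]])) else NA_real_
    fstat <- sm$fstatistic
    p_value <- if (is.null(fstat)) NA_real_ else
      unname(stats::pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE))
  }
  cf <- stats::coef(fit)
  structure(
    list(lm = fit, predictors = predictors,
         coefficients = cf[predictors],
         intercept = if (intercept) unname(cf["(Intercept)"]) else 0,
         has_intercept = intercept,
         R = R, p_value = p_value, n = n, n_excluded = n_excluded,
         response_name = response),
    class = "biomarker_fit")
}

#' @rdname fit_biomarker
#' @export
fit_single <- function(table, protein, response = "mer", intercept = TRUE) {
  fit_biomarker(table, protein, hbb = NULL, response = response,
                intercept = intercept)
}

#' @rdname fit_biomarker
#' @export
fit_combined <- function(table, protein, hbb = "HBB", response = "mer",
                         intercept = TRUE) {
  fit_biomarker(table, protein, hbb = hbb, response = response,
                intercept = intercept)
}

#' @export
print.biomarker_fit <- function(x, ...) {
  eq <- paste(sprintf("%.4g x [%s]", x$coefficients, x$predictors),
              collapse = " + ")
  if (x$has_intercept) eq <- sprintf("%s + %.4g", eq, x$intercept)
  cat(sprintf("Deformability biomarker fit (n = %d units%s)\n", x$n,
              if (x$n_excluded) sprintf(", %d excluded", x$n_excluded) else ""))
  cat(sprintf("  %s = %s\n", toupper(x$response_name), eq))
  cat(sprintf("  R = %.3f, p = %.3g\n", x$R, x$p_value))
  invisible(x)
}

#' @export
summary.biomarker_fit <- function(object, ...) {
  print(object)
  cat("\nUnderlying least-squares fit:\n")
  print(summary(object$lm))
  invisible(object)
}

#' @export
coef.biomarker_fit <- function(object, ...) stats::coef(object$lm)

#' @export
confint.biomarker_fit <- function(object, parm, level = 0.95, ...) {
  stats::confint(object$lm, level = level, ...)
}

#' @export
residuals.biomarker_fit <- function(object, ...) stats::residuals(object$lm)

#' @export
predict.biomarker_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::fitted(object$lm))
  .check_columns(newdata, object$predictors)
  stats::predict(object$lm, newdata = newdata, ...)
}

#' @export
plot.biomarker_fit <- function(x, ...) {
  obs <- x$lm$model[[1L]]
  graphics::plot(stats::fitted(x$lm), obs,
                 xlab = sprintf("Predicted %s", toupper(x$response_name)),
                 ylab = sprintf("Measured %s", toupper(x$response_name)),
                 main = sprintf("Biomarker fit: %s (R = %.2f)",
                                paste(x$predictors, collapse = " + "), x$R),
                 ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Single-protein and HBB-combined correlation panel
#'
#' Reproduces the standard correlation-table structure for a protein panel:
#' one single-predictor fit per protein (including HBB itself), then one
#' combined HBB + protein fit per non-HBB protein.
#'
#' @param table Proteomics data frame.
#' @param proteins Panel of Ln(LFQ) column names; must include `hbb` for
#'   the combined rows to be built.
#' @param hbb HBB column name (default `"HBB"`).
#' @param response Response column.
#' @param sort_by_r Sort rows by descending R instead of panel order.
#' @return Data frame with columns `predictors`, `R`, `p_value`, `n`.
#' @export
evaluate_panel <- function(table,
                           proteins = c("HBB", "ezrin", "stomatin",
                                        "band_4.1", "flotillin_2",
                                        "flotillin_1"),
                           hbb = "HBB", response = "mer",
                           sort_by_r = FALSE) {
  if (length(proteins) == 0L) stop("missing input: empty protein panel")
  .check_columns(table, unique(c(proteins, if (hbb %in% proteins) hbb)))
  singles <- lapply(proteins, function(p)
    fit_single(table, p, response = response))
  fits <- singles
  labels <- proteins
  if (hbb %in% proteins) {
    others <- setdiff(proteins, hbb)
    combos <- lapply(others, function(p)
      fit_combined(table, p, hbb = hbb, response = response))
    fits <- c(fits, combos)
    labels <- c(labels, sprintf("%s and %s", hbb, others))
  }
  out <- data.frame(
    predictors = labels,
    R = vapply(fits, function(f) f$R, numeric(1)),
    p_value = vapply(fits, function(f) f$p_value, numeric(1)),
    n = vapply(fits, function(f) f$n, numeric(1)),
    stringsAsFactors = FALSE)
  if (sort_by_r) out <- out[order(-out$R), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Predict candidate-unit deformability and rank against a recipient
#'
#' Applies a trained biomarker fit to candidate units' proteomics rows and
#' feeds the predicted response into the unit-ranking semantics of
#' [rank_units()]. Units missing a predictor are flagged `unrankable` and
#' excluded from selection.
#'
#' @param fit A [fit_biomarker()] result.
#' @param candidate_units Proteomics data frame with the fit's predictor
#'   columns and a `unit_id` column.
#' @param recipient_response The recipient's measured (or predicted)
#'   deformability on the same response scale.
#' @param tolerance Equality tolerance on the response (default 0.01).
#' @return A `unit_ranking` whose rankings table carries the predicted
#'   response in `unit_mer`; unrankable units appear with verdict
#'   `"unrankable"`.
#' @export
predict_and_select <- function(fit, candidate_units, recipient_response,
                               tolerance = 0.01) {
  stopifnot(inherits(fit, "biomarker_fit"), is.data.frame(candidate_units))
  .check_columns(candidate_units, c("unit_id", fit$predictors))
  ok <- stats::complete.cases(candidate_units[, fit$predictors,
                                              drop = FALSE])
  pred <- rep(NA_real_, nrow(candidate_units))
  if (any(ok))
    pred[ok] <- predict(fit, candidate_units[ok, , drop = FALSE])
  if (!any(ok)) stop("no rankable candidate units")
  pv <- pred[ok]
  names(pv) <- candidate_units$unit_id[ok]
  ranking <- rank_units(pv, recipient_response, tolerance = tolerance)
  if (any(!ok)) {
    extra <- data.frame(unit_id = candidate_units$unit_id[!ok],
                        unit_mer = NA_real_, pct_udfc = NA_real_,
                        recipient_mer = recipient_response, diff = NA_real_,
                        verdict = "unrankable", stringsAsFactors = FALSE)
    ranking$rankings <- rbind(ranking$rankings, extra)
    warning(sprintf("%d unit(s) missing predictors flagged unrankable",
                    sum(!ok)))
  }
  ranking
}
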