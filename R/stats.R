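#' Shapiro-Wilk normality screen
#'
#' Thin wrapper around the Shapiro-Wilk test with the conventions used
#' throughout the package: at least 3 observations, an explicit error for
#' constant samples (where the statistic is undefined), and a `nonnormal`
#' flag at p < 0.05.
#'
#' @param values Numeric vector, 3 <= n <= 5000.
#' @return List with `W`, `p`, `n` and `nonnormal`.
#' @export
normality_check <- function(values) {
  values <- as.numeric(values)
  values <- values[is.finite(values)]
  if (length(values) < 3L)
    stop("insufficient data: Shapiro-Wilk needs at least 3 values")
  if (length(values) > 5000L)
    stop("Shapiro-Wilk implementation limit is 5000 values")
  if (stats::sd(values) == 0)
    stop("insufficient variation: all values are identical")
  ht <- stats::shapiro.test(values)
  list(W = unname(ht$statistic), p = ht$p.value, n = length(values),
       nonnormal = ht$p.value < 0.05)
}

.profile_param <- function(profiles, parameter) {
  if (is.numeric(profiles)) return(as.numeric(profiles))
  if (inherits(profiles, "deformability_profile")) profiles <- list(profiles)
  vapply(profiles, function(p) {
    stopifnot(inherits(p, "deformability_profile"))
    p[[parameter]]
  }, numeric(1))
}

#' Two-group comparison of a deformability parameter
#'
#' Compares one deformability parameter (unit-level MER, AER or a band
#' percentage) between two groups of units by a two-sample t-test: pooled
#' variance Student by default, Welch when `welch = TRUE`. Each group is
#' also screened for normality (Shapiro-Wilk); a warning is emitted when a
#' group looks non-normal and has fewer than 30 units, the regime where the
#' t-test's normality robustness argument does not apply.
#'
#' @param profiles_a,profiles_b Lists of `deformability_profile`s (or bare
#'   numeric vectors of the parameter values).
#' @param parameter One of `"mer"`, `"aer"`, `"pct_hdfc"`, `"pct_ldfc"`,
#'   `"pct_udfc"`.
#' @param welch Use the Welch (unequal variance) variant.
#' @param labels Length-2 character vector naming the groups.
#' @return An object of class `group_comparison`.
#' @export
compare_groups <- function(profiles_a, profiles_b,
                           parameter = c("mer", "aer", "pct_hdfc",
                                         "pct_ldfc", "pct_udfc"),
                           welch = FALSE, labels = c("A", "B")) {
  parameter <- match.arg(parameter)
  a <- .profile_param(profiles_a, parameter)
  b <- .profile_param(profiles_b, parameter)
  if (length(a) < 2L || length(b) < 2L)
    stop("insufficient data: each group needs at least 2 units")
  ht <- stats::t.test(a, b, var.equal = !welch)
  norm_p <- function(x) {
    if (length(x) >= 3L && stats::sd(x) > 0)
      stats::shapiro.test(x)$p.value else NA_real_
  }
  pa <- norm_p(a); pb <- norm_p(b)
  for (i in 1:2) {
    p <- c(pa, pb)[i]; n <- c(length(a), length(b))[i]
    if (!is.na(p) && p < 0.05 && n < 30)
      warning(sprintf(
        "group %s looks non-normal (Shapiro-Wilk p = %.3g) with only n = %d units",
        labels[i], p, n))
  }
  structure(
    list(parameter = parameter, labels = labels,
         mean_a = mean(a), sd_a = stats::sd(a), n_a = length(a),
         mean_b = mean(b), sd_b = stats::sd(b), n_b = length(b),
         min_a = min(a), max_a = max(a), min_b = min(b), max_b = max(b),
         t_stat = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value, welch = welch,
         normality_p_a = pa, normality_p_b = pb),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Comparison of %s (%s t-test)\n", x$parameter,
              if (x$welch) "Welch" else "Student"))
  cat(sprintf("  %s: %.3f +/- %.3f (n = %d, range %.3f-%.3f)\n",
              x$labels[1], x$mean_a, x$sd_a, x$n_a, x$min_a, x$max_a))
  cat(sprintf("  %s: %.3f +/- %.3f (n = %d, range %.3f-%.3f)\n",
              x$labels[2], x$mean_b, x$sd_b, x$n_b, x$min_b, x$max_b))
  cat(sprintf("  t = %.3f (df = %.1f), p = %.3g\n", x$t_stat, x$df,
              x$p_value))
  invisible(x)
}

#' @export
as.data.frame.group_comparison <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  data.frame(parameter = x$parameter,
             mean_a = x$mean_a, sd_a = x$sd_a, n_a = x$n_a,
             mean_b = x$mean_b, sd_b = x$sd_b, n_b = x$n_b,
             max_a = x$max_a, min_a = x$min_a,
             max_b = x$max_b, min_b = x$min_b,
             t_stat = x$t_stat, p_value = x$p_value,
             stringsAsFactors = FALSE, row.names = row.names)
}

#' Compare all deformability parameters between two groups
#'
#' Applies [compare_groups()] to MER, AER and the three band percentages,
#' returning one summary table. Raw per-parameter p-values are reported;
#' a Bonferroni-adjusted column can be added with `bonferroni = TRUE`.
#'
#' @inheritParams compare_groups
#' @param bonferroni Add a `p_adjusted` column (Bonferroni over the five
#'   parameters).
#' @return Data frame, one row per parameter.
#' @export
compare_all_parameters <- function(profiles_a, profiles_b, welch = FALSE,
                                   labels = c("A", "B"),
                                   bonferroni = FALSE) {
  params <- c("mer", "aer", "pct_hdfc", "pct_ldfc", "pct_udfc")
  rows <- lapply(params, function(p)
    as.data.frame(compare_groups(profiles_a, profiles_b, p, welch = welch,
                                 labels = labels)))
  out <- do.call(rbind, rows)
  if (bonferroni)
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "bonferroni")
  out
}

.verdicts <- function(diff, tolerance) {
  ifelse(diff > tolerance, "higher",
         ifelse(diff < -tolerance, "lower", "equal_within_tol"))
}

#' Rank transfusion units against a recipient's deformability
#'
#' Classifies each candidate unit's median ER against the recipient's as
#' `higher`, `equal_within_tol` or `lower` (difference compared to a
#' tolerance), and selects the units suitable for transfusion: all `higher`
#' units if any, otherwise all `equal_within_tol` units, otherwise the
#' maximal-MER unit with a warning that no unit matches the recipient.
#'
#' @param units Named list of `deformability_profile`s (or a named numeric
#'   vector of unit MERs).
#' @param recipient The recipient's `deformability_profile` (or its MER).
#' @param tolerance MER difference treated as "equal" (default 0.01).
#' @param secondary_udfc Break ties among selected units by lower %UDFC
#'   (requires profile input).
#' @return An object of class `unit_ranking`: a list with `rankings` (data
#'   frame: `unit_id`, `unit_mer`, `recipient_mer`, `diff`, `verdict`,
#'   ordered by descending MER) and `selected` (character vector of unit
#'   ids).
#' @export
rank_units <- function(units, recipient, tolerance = 0.01,
                       secondary_udfc = FALSE) {
  if (length(units) < 1L) stop("need at least one unit")
  if (is.numeric(units)) {
    mers <- as.numeric(units)
    ids <- names(units) %||% sprintf("unit%02d", seq_along(units))
    udfc <- rep(NA_real_, length(units))
  } else {
    mers <- .profile_param(units, "mer")
    udfc <- .profile_param(units, "pct_udfc")
    ids <- names(units) %||%
      vapply(units, function(p) p$sample_id, character(1))
  }
  rec_mer <- if (inherits(recipient, "deformability_profile"))
    recipient$mer else as.numeric(recipient)[1L]
  if (!is.finite(tolerance) || tolerance < 0)
    stop("tolerance must be a non-negative number")
  diff <- mers - rec_mer
  verdict <- .verdicts(diff, tolerance)
  rk <- data.frame(unit_id = ids, unit_mer = mers, pct_udfc = udfc,
                   recipient_mer = rec_mer, diff = diff, verdict = verdict,
                   stringsAsFactors = FALSE)
  ord <- order(-rk$unit_mer, if (secondary_udfc) rk$pct_udfc else seq_along(ids))
  rk <- rk[ord, , drop = FALSE]
  rownames(rk) <- NULL
  selected <- if (any(verdict == "higher")) {
    rk$unit_id[rk$verdict == "higher"]
  } else if (any(verdict == "equal_within_tol")) {
    rk$unit_id[rk$verdict == "equal_within_tol"]
  } else {
    warning("no unit has deformability at least equal to the recipient's; ",
            "falling back to the maximal-MER unit")
    rk$unit_id[which.max(rk$unit_mer)]
  }
  structure(list(rankings = rk, selected = selected, tolerance = tolerance),
            class = "unit_ranking")
}

#' @export
print.unit_ranking <- function(x, ...) {
  cat(sprintf("Unit ranking vs recipient MER %.3f (tolerance %.3g)\n",
              x$rankings$recipient_mer[1L], x$tolerance))
  print(x$rankings[, c("unit_id", "unit_mer", "diff", "verdict")],
        row.names = FALSE)
  cat("Selected:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}
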