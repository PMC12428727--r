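# Seed hygiene: run expr under a temporary RNG state so generators are
# reproducible without clobbering the caller's stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

.halfnorm_cdf <- function(x, spread) {
  if (spread <= 0) return(as.numeric(x >= 0))
  2 * stats::pnorm(x / spread) - 1
}

#' Parametric model of a within-sample ER population
#'
#' ER values are modelled as `1 + excess`, where the excess is a two-part
#' mixture: with probability `rigid_fraction` a half-normal "rigid spike"
#' of scale `rigid_spread` (cells that barely deform), otherwise a lognormal
#' "deformable" component with log-sd `tail_shape` and median `tail_scale`.
#' The support is ER >= 1 by construction; the lognormal gives the
#' right-skewed body-plus-tail shape typical of measured ER distributions,
#' and its two parameters plus the rigid fraction map one-to-one onto a
#' target (MER, %UDFC, %HDFC) triple — see [calibrate_population()].
#'
#' @param rigid_fraction Mixture weight of the rigid spike, in `[0, 1]`.
#' @param rigid_spread Half-normal scale of the rigid spike (ER units).
#' @param tail_shape Log-sd of the deformable (lognormal) component.
#' @param tail_scale Median of the deformable excess (so the deformable
#'   component's median ER is `1 + tail_scale`).
#' @param description Free-text provenance note.
#' @return An object of class `population_model`.
#' @export
population_model <- function(rigid_fraction = 0.02, rigid_spread = 0.03,
                             tail_shape = 0.65, tail_scale = 0.55,
                             description = "") {
  if (!is.finite(rigid_fraction) || rigid_fraction < 0 || rigid_fraction > 1)
    stop("rigid_fraction must be in [0, 1]")
  if (!is.finite(rigid_spread) || rigid_spread < 0)
    stop("rigid_spread must be >= 0")
  if (!is.finite(tail_shape) || tail_shape <= 0)
    stop("tail_shape must be > 0")
  if (!is.finite(tail_scale) || tail_scale <= 0)
    stop("tail_scale must be > 0")
  structure(
    list(rigid_fraction = rigid_fraction, rigid_spread = rigid_spread,
         tail_shape = tail_shape, tail_scale = tail_scale,
         description = description),
    class = "population_model")
}

#' @export
print.population_model <- function(x, ...) {
  cat(sprintf(
    "ER population model: %.3g%% rigid (spread %.3g) + lognormal tail (median %.3g, log-sd %.3g)\n",
    100 * x$rigid_fraction, x$rigid_spread, x$tail_scale, x$tail_shape))
  cat(sprintf("  analytic MER %.4f, %%UDFC %.3f, %%HDFC %.3f\n",
              population_quantile(x, 0.5),
              100 * population_cdf(x, 1.1),
              100 * (1 - population_cdf(x, 2.5))))
  if (nzchar(x$description)) cat(" ", x$description, "\n")
  invisible(x)
}

#' Analytic CDF and quantiles of a population model
#'
#' `population_cdf()` gives `P(ER < er)` (the left-open mass used by the
#' disjoint band convention); `population_quantile()` inverts it
#' numerically.
#'
#' @param model A [population_model].
#' @param er Elongation-ratio value(s).
#' @export
population_cdf <- function(model, er) {
  t <- er - 1
  p <- model$rigid_fraction
  out <- p * .halfnorm_cdf(t, model$rigid_spread) +
    (1 - p) * stats::plnorm(t, meanlog = log(model$tail_scale),
                            sdlog = model$tail_shape)
  out[t < 0] <- 0
  out
}

#' @rdname population_cdf
#' @param q Probability level(s) in (0, 1).
#' @export
population_quantile <- function(model, q) {
  vapply(q, function(qi) {
    stopifnot(qi > 0, qi < 1)
    upper <- 1 + max(model$rigid_spread * 10,
                     stats::qlnorm(qi, log(model$tail_scale),
                                   model$tail_shape) * 2, 1)
    while (population_cdf(model, upper) < qi) upper <- upper * 2
    stats::uniroot(function(e) population_cdf(model, e) - qi,
                   lower = 1, upper = upper, tol = 1e-10)$root
  }, numeric(1))
}

#' Draw a synthetic ER sample from a population model
#'
#' Reproducible for a fixed seed; all values are >= 1 by construction.
#'
#' @param model A [population_model].
#' @param n Number of cells to draw (>= 1).
#' @param seed Integer seed; `NULL` uses (and advances) the current RNG
#'   stream.
#' @param sample_id Label for the resulting sample.
#' @return An [er_sample].
#' @export
simulate_er_population <- function(model, n, seed = NULL,
                                   sample_id = "simulated") {
  stopifnot(inherits(model, "population_model"))
  if (!is.numeric(n) || n < 1)
    stop("invalid size: n must be >= 1")
  n <- as.integer(n)
  values <- with_seed(seed, {
    rigid <- stats::runif(n) < model$rigid_fraction
    t <- numeric(n)
    if (any(rigid))
      t[rigid] <- abs(stats::rnorm(sum(rigid), 0, model$rigid_spread))
    if (any(!rigid))
      t[!rigid] <- stats::rlnorm(sum(!rigid), log(model$tail_scale),
                                 model$tail_shape)
    1 + t
  })
  er_sample(values, sample_id = sample_id)
}

#' @export
simulate.population_model <- function(object, nsim = 1, seed = NULL, ...) {
  simulate_er_population(object, n = nsim, seed = seed, ...)
}

#' Calibrate a population model to target deformability parameters
#'
#' Solves for the mixture parameters such that the model's analytic median
#' equals `target_mer` and the analytic band masses below `udfc_upper` and
#' at/above `hdfc_lower` equal the target percentages. With all three
#' targets given, the rigid fraction, the lognormal log-sd and its median
#' are all determined (a damped fixed-point with closed-form updates);
#' with `target_hdfc_pct = NULL` the log-sd is held at `default_shape` and
#' only the rigid fraction and lognormal median are solved. Deterministic:
#' the same targets always return identical parameters.
#'
#' When the %UDFC target lies below the floor contributed by the deformable
#' component alone, the rigid fraction clamps at zero and the achieved
#' %UDFC is the floor; this is reported with a warning rather than an error.
#' Structurally impossible targets (percentages outside `[0, 100)`, their
#' sum >= 100, or `target_mer` outside `(1, hdfc_lower)`) raise a
#' calibration-infeasible error.
#'
#' @param target_mer Target median ER, in `(1, hdfc_lower)`.
#' @param target_udfc_pct Target %UDFC (mass with ER < `udfc_upper`).
#' @param target_hdfc_pct Target %HDFC (mass with ER >= `hdfc_lower`), or
#'   `NULL` to leave the tail shape at its default.
#' @param udfc_upper,hdfc_lower Band thresholds (defaults 1.1 and 2.5).
#' @param rigid_spread Half-normal scale of the rigid spike (default 0.03,
#'   which keeps >99.9% of the spike below ER 1.1).
#' @param default_shape Lognormal log-sd used when %HDFC is not targeted.
#' @param tol Residual tolerance on the three constraints (probability
#'   scale).
#' @return A calibrated [population_model].
#' @export
calibrate_population <- function(target_mer, target_udfc_pct,
                                 target_hdfc_pct = NULL,
                                 udfc_upper = 1.1, hdfc_lower = 2.5,
                                 rigid_spread = 0.03, default_shape = 0.65,
                                 tol = 1e-3) {
  u <- target_udfc_pct / 100
  h <- if (is.null(target_hdfc_pct)) NULL else target_hdfc_pct / 100
  if (!is.finite(target_mer) || target_mer <= 1 || target_mer >= hdfc_lower)
    stop("calibration infeasible: target_mer must lie in (1, hdfc_lower)")
  if (!is.finite(u) || u < 0 || u >= 1)
    stop("calibration infeasible: target_udfc_pct must be in [0, 100)")
  if (!is.null(h)) {
    if (!is.finite(h) || h < 0 || h >= 0.5)
      stop("calibration infeasible: target_hdfc_pct must be in [0, 50)")
    if (u + h >= 1)
      stop("calibration infeasible: %UDFC + %HDFC must be < 100")
  }
  m <- target_mer - 1
  tu <- udfc_upper - 1
  th <- hdfc_lower - 1

  if (u > 0.5) {
    # Rigid-dominated population: the spike carries the median. Solve the
    # spike scale so the overall median lands on target; deformable part
    # keeps default shape with its median at the HDFC-feasible default.
    shape <- default_shape
    scale <- max(m, tu)
    p <- u
    s <- rigid_spread
    for (i in 1:200) {
      Lu <- stats::plnorm(tu, log(scale), shape)
      p_new <- min(max((u - Lu) / max(.halfnorm_cdf(tu, s) - Lu, 1e-12), 0),
                   0.9999)
      # median: p * Fh(m; s) + (1-p) * L(m) = 0.5
      Lm <- stats::plnorm(m, log(scale), shape)
      target_fh <- (0.5 - (1 - p_new) * Lm) / p_new
      if (target_fh <= 0 || target_fh >= 1)
        stop("calibration infeasible: median target incompatible with %UDFC")
      s_new <- m / stats::qnorm((target_fh + 1) / 2)
      if (abs(s_new - s) < 1e-12 && abs(p_new - p) < 1e-12) {
        p <- p_new; s <- s_new; break
      }
      p <- p_new; s <- s_new
    }
    model <- population_model(p, s, shape, scale,
                              description = "calibrated (rigid-dominated)")
  } else {
    shape <- default_shape
    p <- 0
    meanlog <- log(m)
    clamped <- FALSE
    for (i in 1:500) {
      Lu <- stats::plnorm(tu, meanlog, shape)
      Rh <- .halfnorm_cdf(tu, rigid_spread)
      p_raw <- (u - Lu) / max(Rh - Lu, 1e-12)
      p_new <- min(max(p_raw, 0), 0.98)
      clamped <- p_raw < 0
      qn <- (0.5 - p_new * .halfnorm_cdf(m, rigid_spread)) / (1 - p_new)
      if (qn <= 0 || qn >= 1)
        stop("calibration infeasible: rigid mass implied by %UDFC exceeds the median")
      zq <- stats::qnorm(qn)
      if (!is.null(h)) {
        hp <- h / (1 - p_new)
        if (hp >= 0.5)
          stop("calibration infeasible: %HDFC too large for the deformable mass")
        zh <- stats::qnorm(1 - hp)
        if (zh - zq < 1e-6)
          stop("calibration infeasible: %HDFC incompatible with target MER")
        shape_new <- (log(th) - log(m)) / (zh - zq)
        if (!is.finite(shape_new) || shape_new <= 0)
          stop("calibration infeasible: %HDFC incompatible with target MER")
      } else {
        shape_new <- shape
      }
      meanlog_new <- log(m) - shape_new * zq
      done <- abs(shape_new - shape) < 1e-13 &&
        abs(meanlog_new - meanlog) < 1e-13 && abs(p_new - p) < 1e-13
      shape <- shape_new; meanlog <- meanlog_new; p <- p_new
      if (done) break
    }
    model <- population_model(p, rigid_spread, shape, exp(meanlog),
                              description = "calibrated")
    if (clamped) {
      achieved <- 100 * population_cdf(model, udfc_upper)
      warning(sprintf(
        "%%UDFC target %.3g below the deformable component's floor; achieved %.3g",
        target_udfc_pct, achieved))
    }
  }
  # verify residuals on the constraints that were actually solvable
  res_med <- abs(population_cdf(model, target_mer) - 0.5)
  res_h <- if (is.null(h)) 0 else
    abs((1 - population_cdf(model, hdfc_lower)) - h)
  if (res_med > tol || res_h > tol)
    stop(sprintf(
      "calibration infeasible: residuals (median %.2g, hdfc %.2g) exceed tolerance",
      res_med, res_h))
  model
}

#' Cohort presets for unit-level deformability variability
#'
#' Named presets encode the group-level MER and %UDFC means/SDs and group
#' sizes used for simulated cohorts of transfusion units: `"PRBC"` (packed
#' red-blood-cell units: MER 1.52 +/- 0.11, %UDFC 3.18 +/- 3.83, n = 156)
#' and `"CRBC"` (cord-blood RBCs: MER 1.61 +/- 0.07, %UDFC 2.21 +/- 1.06,
#' n = 78).
#'
#' @param name `"PRBC"`, `"CRBC"`, or `"custom"` with the remaining
#'   arguments supplied.
#' @param mer_mean,mer_sd Between-unit mean and SD of the unit median ER.
#' @param udfc_mean,udfc_sd Between-unit mean and SD of %UDFC.
#' @param n_units Number of units in the cohort.
#' @return An object of class `cohort_preset`.
#' @export
cohort_preset <- function(name = c("PRBC", "CRBC", "custom"),
                          mer_mean = NULL, mer_sd = NULL,
                          udfc_mean = NULL, udfc_sd = NULL, n_units = NULL) {
  name <- match.arg(name)
  defaults <- switch(name,
    PRBC = list(mer_mean = 1.52, mer_sd = 0.11, udfc_mean = 3.18,
                udfc_sd = 3.83, n_units = 156L),
    CRBC = list(mer_mean = 1.61, mer_sd = 0.07, udfc_mean = 2.21,
                udfc_sd = 1.06, n_units = 78L),
    custom = list(mer_mean = mer_mean, mer_sd = mer_sd,
                  udfc_mean = udfc_mean, udfc_sd = udfc_sd,
                  n_units = n_units))
  vals <- list(mer_mean = mer_mean %||% defaults$mer_mean,
               mer_sd = mer_sd %||% defaults$mer_sd,
               udfc_mean = udfc_mean %||% defaults$udfc_mean,
               udfc_sd = udfc_sd %||% defaults$udfc_sd,
               n_units = as.integer(n_units %||% defaults$n_units))
  if (any(vapply(vals, is.null, logical(1))))
    stop("custom presets need mer_mean, mer_sd, udfc_mean, udfc_sd, n_units")
  if (vals$mer_mean < 1) stop("mer_mean must be >= 1")
  if (vals$mer_sd < 0 || vals$udfc_sd < 0) stop("SDs must be >= 0")
  structure(c(list(name = name), vals), class = "cohort_preset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.rtruncnorm1 <- function(mean, sd, lower, upper = Inf) {
  if (sd == 0) return(min(max(mean, lower), upper))
  repeat {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lower && x <= upper) return(x)
  }
}

#' Simulate a cohort of transfusion units
#'
#' Draws each unit's target median ER from
#' `Normal(mer_mean, mer_sd)` truncated at 1.05 and its target %UDFC from
#' `Normal(udfc_mean, udfc_sd)` truncated at 0, calibrates a
#' [population_model] per unit and samples `cells_per_unit` ER values from
#' it. %UDFC targets below the deformable component's floor are raised to
#' the floor (the truncation is part of the generator's semantics).
#'
#' @param preset A [cohort_preset].
#' @param seed Integer seed.
#' @param cells_per_unit ER draws per unit (default 10000, the low end of
#'   the per-specimen cell-count protocol).
#' @return An object of class `rbc_cohort`: a list with `units` (named list
#'   of [er_sample]s), `targets` (data frame of the drawn per-unit targets)
#'   and `preset`.
#' @export
simulate_cohort <- function(preset, seed = NULL, cells_per_unit = 10000L) {
  stopifnot(inherits(preset, "cohort_preset"))
  with_seed(seed, {
    units <- vector("list", preset$n_units)
    ids <- sprintf("%s_U%03d", preset$name, seq_len(preset$n_units))
    targets <- data.frame(unit_id = ids, target_mer = NA_real_,
                          target_udfc = NA_real_, stringsAsFactors = FALSE)
    for (i in seq_len(preset$n_units)) {
      tm <- .rtruncnorm1(preset$mer_mean, preset$mer_sd, lower = 1.05,
                         upper = 2.4)
      tu <- .rtruncnorm1(preset$udfc_mean, preset$udfc_sd, lower = 0,
                         upper = 49)
      model <- suppressWarnings(calibrate_population(tm, tu))
      units[[i]] <- simulate_er_population(model, cells_per_unit,
                                           sample_id = ids[i])
      targets$target_mer[i] <- tm
      targets$target_udfc[i] <- tu
    }
    names(units) <- ids
    structure(list(units = units, targets = targets, preset = preset),
              class = "rbc_cohort")
  })
}

#' @export
print.rbc_cohort <- function(x, ...) {
  mers <- vapply(x$units, function(u) stats::median(u$values), numeric(1))
  cat(sprintf("Simulated %s cohort: %d units, %d cells each\n",
              x$preset$name, length(x$units), length(x$units[[1]]$values)))
  cat(sprintf("  unit MER mean %.3f, sd %.3f\n", mean(mers), stats::sd(mers)))
  invisible(x)
}

#' Per-unit deformability profiles of a simulated cohort
#'
#' @param cohort An [simulate_cohort()] result.
#' @param scheme A [threshold_scheme].
#' @return Named list of `deformability_profile`s.
#' @export
cohort_profiles <- function(cohort, scheme = threshold_scheme()) {
  stopifnot(inherits(cohort, "rbc_cohort"))
  lapply(cohort$units, compute_profile, scheme = scheme)
}

#' Simulation parameters for a proteomics table
#'
#' Configures a synthetic label-free-quantification table: `n_units` rows
#' with independent Normal Ln(LFQ) levels per membrane protein, and a
#' response (unit deformability) generated as
#' `coef_protein * [driver protein] + coef_hbb * [HBB] + intercept + noise`.
#' Default coefficients and noise are set so the combined two-predictor
#' model has a population multiple correlation of about 0.77 at the default
#' Ln(LFQ) spread.
#'
#' @param n_units Units (rows), >= 3. Default 15 (one proteomics batch of
#'   PRBC units).
#' @param coef_protein,coef_hbb,intercept Linear-model truth.
#' @param noise_sd Residual SD of the response.
#' @param lnlfq_mean,lnlfq_sd Mean and SD of the Ln(LFQ) predictors.
#' @param proteins Membrane-protein column names (besides `HBB`).
#' @param driver_protein Which protein carries the `coef_protein` signal.
#' @param response Name of the response column, `"mer"` or `"aer"`.
#' @return An object of class `proteomics_sim_params`.
#' @export
proteomics_sim_params <- function(n_units = 15L, coef_protein = 0.02,
                                  coef_hbb = 0.03, intercept = 0.3,
                                  noise_sd = 0.045,
                                  lnlfq_mean = 25, lnlfq_sd = 1.5,
                                  proteins = c("ezrin", "stomatin",
                                               "band_4.1", "flotillin_1",
                                               "flotillin_2"),
                                  driver_protein = "flotillin_1",
                                  response = c("mer", "aer")) {
  response <- match.arg(response)
  if (!is.numeric(n_units) || n_units < 3)
    stop("n_units must be >= 3")
  if (!is.finite(noise_sd) || noise_sd < 0)
    stop("invalid parameter: noise_sd must be >= 0")
  if (!driver_protein %in% proteins)
    stop("driver_protein must be one of the proteins")
  structure(
    list(n_units = as.integer(n_units), coef_protein = coef_protein,
         coef_hbb = coef_hbb, intercept = intercept, noise_sd = noise_sd,
         lnlfq_mean = lnlfq_mean, lnlfq_sd = lnlfq_sd, proteins = proteins,
         driver_protein = driver_protein, response = response),
    class = "proteomics_sim_params")
}

#' Simulate a membrane-proteomics table with a known deformability signal
#'
#' @param params A [proteomics_sim_params].
#' @param seed Integer seed.
#' @return A data frame with columns `unit_id`, `HBB`, one Ln(LFQ) column
#'   per protein, the response column (noisy) and `true_response` (the
#'   noiseless linear predictor).
#' @export
simulate_proteomics <- function(params = proteomics_sim_params(),
                                seed = NULL) {
  stopifnot(inherits(params, "proteomics_sim_params"))
  with_seed(seed, {
    n <- params$n_units
    cols <- c("HBB", params$proteins)
    mat <- matrix(stats::rnorm(n * length(cols), params$lnlfq_mean,
                               params$lnlfq_sd),
                  nrow = n, dimnames = list(NULL, cols))
    truth <- params$coef_protein * mat[, params$driver_protein] +
      params$coef_hbb * mat[, "HBB"] + params$intercept
    resp <- truth + stats::rnorm(n, 0, params$noise_sd)
    out <- data.frame(unit_id = sprintf("U%03d", seq_len(n)),
                      mat, check.names = FALSE, stringsAsFactors = FALSE)
    out[[params$response]] <- resp
    out$true_response <- truth
    attr(out, "sim_params") <- params
    out
  })
}
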