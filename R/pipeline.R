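#' Configuration for a reproducible end-to-end pipeline run
#'
#' Bundles every tunable of the synthetic end-to-end analysis: band
#' thresholds, detection QC, imaging geometry, the recipient's target
#' deformability, the candidate-unit cohort, comparison/ranking options and
#' the proteomics simulation. All validation happens here, before any
#' compute. The resolved configuration (including the seed) is written
#' beside every run's outputs and can be reloaded losslessly with
#' [load_pipeline_config()].
#'
#' @param seed Integer seed; mandatory, covers every stage.
#' @param output_dir Directory for reports (created if needed).
#' @param thresholds A [threshold_scheme].
#' @param qc A [qc_params].
#' @param imaging An [imaging_params].
#' @param recipient_targets Named vector `c(mer=, udfc=, hdfc=)` for the
#'   recipient population (defaults: the worked recipient example,
#'   MER 1.55, %UDFC 1.12, %HDFC 6.14).
#' @param recipient_fields Number of fields imaged for the recipient.
#' @param unit_preset,n_units Candidate-unit cohort preset name and size.
#' @param comparison_presets Two preset names compared group-wise, or
#'   `NULL` to skip the comparison stage.
#' @param comparison_n_units Units per group in the comparison stage.
#' @param cells_per_unit ER draws per simulated unit.
#' @param rank_tolerance MER difference treated as equal when ranking.
#' @param welch Use the Welch t-test variant in comparisons.
#' @param proteomics A [proteomics_sim_params].
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed,
                            output_dir = tempfile("rbcdeform_run_"),
                            thresholds = threshold_scheme(),
                            qc = qc_params(),
                            imaging = imaging_params(cells_per_field = 120L),
                            recipient_targets = c(mer = 1.55, udfc = 1.12,
                                                  hdfc = 6.14),
                            recipient_fields = 5L,
                            unit_preset = "PRBC", n_units = 5L,
                            comparison_presets = c("PRBC", "CRBC"),
                            comparison_n_units = 8L,
                            cells_per_unit = 2000L,
                            rank_tolerance = 0.01,
                            welch = FALSE,
                            proteomics = proteomics_sim_params()) {
  if (missing(seed) || !is.numeric(seed) || !is.finite(seed))
    stop("validation error: an integer seed is mandatory")
  stopifnot(inherits(thresholds, "threshold_scheme"),
            inherits(qc, "qc_params"),
            inherits(imaging, "imaging_params"),
            inherits(proteomics, "proteomics_sim_params"))
  if (!all(c("mer", "udfc", "hdfc") %in% names(recipient_targets)))
    stop("validation error: recipient_targets needs mer, udfc, hdfc")
  if (!is.null(comparison_presets) && length(comparison_presets) != 2L)
    stop("validation error: comparison_presets must name two presets")
  if (rank_tolerance < 0)
    stop("validation error: rank_tolerance must be >= 0")
  structure(
    list(seed = as.integer(seed), output_dir = output_dir,
         thresholds = thresholds, qc = qc, imaging = imaging,
         recipient_targets = recipient_targets,
         recipient_fields = as.integer(recipient_fields),
         unit_preset = unit_preset, n_units = as.integer(n_units),
         comparison_presets = comparison_presets,
         comparison_n_units = as.integer(comparison_n_units),
         cells_per_unit = as.integer(cells_per_unit),
         rank_tolerance = rank_tolerance, welch = isTRUE(welch),
         proteomics = proteomics),
    class = "pipeline_config")
}

.config_as_list <- function(config) {
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  lst <- strip(config)
  # named vectors would serialize as bare arrays and lose their names
  lst$recipient_targets <- as.list(config$recipient_targets)
  lst
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path JSON file path.
#' @export
save_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  jsonlite::write_json(.config_as_list(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname pipeline_config
#' @export
load_pipeline_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pipeline_config(
    seed = obj$seed, output_dir = obj$output_dir,
    thresholds = do.call(threshold_scheme, obj$thresholds),
    qc = do.call(qc_params, c(obj$qc[setdiff(names(obj$qc),
                                             "fixed_threshold")],
                              list(fixed_threshold = obj$qc$fixed_threshold))),
    imaging = do.call(imaging_params, obj$imaging),
    recipient_targets = unlist(obj$recipient_targets),
    recipient_fields = obj$recipient_fields,
    unit_preset = obj$unit_preset, n_units = obj$n_units,
    comparison_presets = obj$comparison_presets,
    comparison_n_units = obj$comparison_n_units,
    cells_per_unit = obj$cells_per_unit,
    rank_tolerance = obj$rank_tolerance, welch = obj$welch,
    proteomics = do.call(proteomics_sim_params, obj$proteomics))
}

# Hash of the scientific configuration (the output location is not part of
# the science, so two runs into different directories hash identically).
config_hash <- function(config) {
  lst <- .config_as_list(config)
  lst$output_dir <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(lst, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  unname(tools::md5sum(tmp))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the synthetic end-to-end deformability pipeline
#'
#' Executes simulate -> render -> segment -> profile -> compare -> rank ->
#' biomarker with the given configuration and writes all reports (CSV/JSON
#' plus a run log naming the seed, package version and configuration hash)
#' into `config$output_dir`. Every stage is deterministic given the seed;
#' rerunning with the same configuration reproduces the reports exactly.
#' A stage failure aborts with a stage-named diagnostic; reports already
#' written are retained.
#'
#' @param config A [pipeline_config].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the recipient profile, unit profiles,
#'   comparison table, ranking, biomarker panel and fit, and the output
#'   paths.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  hash <- config_hash(config)
  paths <- list(config = file.path(config$output_dir, "config.json"))
  save_pipeline_config(config, paths$config)
  seed <- config$seed

  recipient <- .stage("recipient imaging", {
    model <- calibrate_population(config$recipient_targets[["mer"]],
                                  config$recipient_targets[["udfc"]],
                                  config$recipient_targets[["hdfc"]])
    spec <- render_specimen(model, n_fields = config$recipient_fields,
                            params = config$imaging, seed = seed + 1L)
    res <- suppressWarnings(
      analyze_specimen(spec$images, config$qc, config$thresholds,
                       sample_id = "recipient"))
    paths$recipient_cells <- file.path(config$output_dir,
                                        "recipient_cells.csv")
    write_cell_table(res$cells, paths$recipient_cells)
    paths$recipient_profile <- file.path(config$output_dir,
                                          "recipient_profile.json")
    write_profile_json(res$profile, paths$recipient_profile)
    say("recipient: %d cells over %d fields, MER %.3f",
        res$profile$n_cells, config$recipient_fields, res$profile$mer)
    res
  })

  units <- .stage("unit cohort", {
    cohort <- simulate_cohort(cohort_preset(config$unit_preset,
                                            n_units = config$n_units),
                              seed = seed + 2L,
                              cells_per_unit = config$cells_per_unit)
    profiles <- cohort_profiles(cohort, config$thresholds)
    tab <- do.call(rbind, lapply(profiles, as.data.frame))
    paths$unit_profiles <- file.path(config$output_dir, "unit_profiles.csv")
    utils::write.csv(tab, paths$unit_profiles, row.names = FALSE)
    say("units: %d simulated from preset %s", length(profiles),
        config$unit_preset)
    profiles
  })

  comparison <- if (!is.null(config$comparison_presets)) .stage("comparison", {
    ga <- cohort_profiles(simulate_cohort(
      cohort_preset(config$comparison_presets[1L],
                    n_units = config$comparison_n_units),
      seed = seed + 3L, cells_per_unit = config$cells_per_unit),
      config$thresholds)
    gb <- cohort_profiles(simulate_cohort(
      cohort_preset(config$comparison_presets[2L],
                    n_units = config$comparison_n_units),
      seed = seed + 4L, cells_per_unit = config$cells_per_unit),
      config$thresholds)
    cmp <- suppressWarnings(
      compare_all_parameters(ga, gb, welch = config$welch,
                             labels = config$comparison_presets))
    paths$comparison <- file.path(config$output_dir, "comparison.csv")
    utils::write.csv(cmp, paths$comparison, row.names = FALSE)
    say("comparison: %s vs %s, MER p = %.3g",
        config$comparison_presets[1L], config$comparison_presets[2L],
        cmp$p_value[cmp$parameter == "mer"])
    cmp
  }) else NULL

  ranking <- .stage("ranking", {
    rk <- withCallingHandlers(
      rank_units(units, recipient$profile, tolerance = config$rank_tolerance),
      warning = function(w) {
        say("ranking note: %s", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    paths$ranking <- file.path(config$output_dir, "ranking.csv")
    utils::write.csv(rk$rankings, paths$ranking, row.names = FALSE)
    say("ranking: selected %s", paste(rk$selected, collapse = ", "))
    rk
  })

  biomarker <- .stage("biomarker", {
    tab <- simulate_proteomics(config$proteomics, seed = seed + 5L)
    panel <- evaluate_panel(tab, response = config$proteomics$response)
    paths$biomarker_panel <- file.path(config$output_dir,
                                        "biomarker_panel.csv")
    utils::write.csv(panel, paths$biomarker_panel, row.names = FALSE)
    fit <- fit_combined(tab, config$proteomics$driver_protein,
                        response = config$proteomics$response)
    paths$biomarker_fit <- file.path(config$output_dir, "biomarker_fit.json")
    jsonlite::write_json(
      list(predictors = fit$predictors,
           coefficients = as.list(fit$coefficients),
           intercept = fit$intercept, R = fit$R, p_value = fit$p_value,
           n = fit$n, response_name = fit$response_name),
      paths$biomarker_fit, auto_unbox = TRUE, digits = NA)
    say("biomarker: combined %s + HBB, R = %.3f",
        config$proteomics$driver_protein, fit$R)
    list(table = tab, panel = panel, fit = fit)
  })

  paths$run_log <- file.path(config$output_dir, "run_log.txt")
  writeLines(c(
    sprintf("rbcdeform %s",
            as.character(utils::packageVersion("rbcdeform"))),
    sprintf("seed: %d", config$seed),
    sprintf("config_hash: %s", hash),
    sprintf("stages: recipient imaging, unit cohort%s, ranking, biomarker",
            if (is.null(comparison)) "" else ", comparison"),
    sprintf("outputs: %s",
            paste(basename(unlist(paths)), collapse = ", "))),
    paths$run_log)
  say("run complete: %s", config$output_dir)
  invisible(list(recipient = recipient, units = units,
                 comparison = comparison, ranking = ranking,
                 biomarker = biomarker, paths = paths, config_hash = hash))
}
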