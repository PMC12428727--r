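#' Read and write per-cell measurement tables
#'
#' The on-disk dialect is a plain CSV with columns `sample_id`, `field_id`,
#' `cell_id`, `major_um`, `minor_um`, `er`, `qc_pass` (and optionally
#' `qc_reason`, `centroid_x`, `centroid_y`, `area_um2`, `orientation`).
#'
#' @param path CSV file path.
#' @return `read_cell_table()`: a data frame; `write_cell_table()`: the path,
#'   invisibly.
#' @export
read_cell_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "field_id", "cell_id", "major_um", "minor_um",
            "er", "qc_pass")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("cell table missing columns: ", paste(miss, collapse = ", "))
  tab$qc_pass <- as.logical(tab$qc_pass)
  tab
}

#' @rdname read_cell_table
#' @param table Cell-measurement data frame.
#' @export
write_cell_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Serialise a deformability profile to JSON
#'
#' Writes (or renders) the standard profile report: MER, AER, band
#' percentages, cell/field counts, thresholds and boundary convention.
#'
#' @param profile A [compute_profile()] result.
#' @param path Output file; `NULL` returns the JSON string.
#' @export
write_profile_json <- function(profile, path = NULL) {
  stopifnot(inherits(profile, "deformability_profile"))
  obj <- list(
    sample_id = profile$sample_id,
    mer = profile$mer, aer = profile$aer,
    pct_hdfc = profile$pct_hdfc, pct_ldfc = profile$pct_ldfc,
    pct_udfc = profile$pct_udfc, pct_mid = profile$pct_mid,
    n_cells = profile$n_cells, n_fields = profile$n_fields,
    thresholds = list(udfc_upper = profile$thresholds$udfc_upper,
                      ldfc_upper = profile$thresholds$ldfc_upper,
                      hdfc_lower = profile$thresholds$hdfc_lower),
    boundary_convention = profile$thresholds$boundary_convention)
  if (is.null(path))
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null",
                            na = "null"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_profile_json
#' @export
read_profile_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  scheme <- threshold_scheme(obj$thresholds$udfc_upper,
                             obj$thresholds$ldfc_upper,
                             obj$thresholds$hdfc_lower,
                             obj$boundary_convention)
  structure(
    list(mer = obj$mer, aer = obj$aer,
         pct_udfc = obj$pct_udfc, pct_ldfc = obj$pct_ldfc,
         pct_mid = obj$pct_mid, pct_hdfc = obj$pct_hdfc,
         n_cells = as.integer(obj$n_cells),
         n_fields = if (is.null(obj$n_fields)) NA_integer_ else as.integer(obj$n_fields),
         sample_id = obj$sample_id, thresholds = scheme),
    class = "deformability_profile")
}

#' Read an ER table as a pooled specimen sample
#'
#' Convenience wrapper: reads a cell-measurement CSV and pools its
#' QC-passing ER values with [aggregate_fields()].
#'
#' @inheritParams read_cell_table
#' @param sample_id Label; defaults to the table's own `sample_id`.
#' @param quiet Suppress protocol-coverage warnings (useful for partial
#'   tables).
#' @return An [er_sample].
#' @export
read_er_sample <- function(path, sample_id = NULL, quiet = FALSE) {
  tab <- read_cell_table(path)
  if (is.null(sample_id))
    sample_id <- if (nrow(tab)) as.character(tab$sample_id[1L]) else "sample"
  if (quiet)
    suppressWarnings(aggregate_fields(tab, sample_id = sample_id))
  else
    aggregate_fields(tab, sample_id = sample_id)
}
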