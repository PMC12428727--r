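#' Deformability profile of an ER population
#'
#' Reduces a sample of per-cell elongation ratios to the standard population
#' deformability parameters: MER (median ER), AER (mean ER) and the
#' subpopulation percentages %UDFC (undeformable), %LDFC (low-deformable),
#' %MID (the unnamed intermediate band) and %HDFC (highly deformable).
#'
#' Under the default `disjoint_bins` convention the four bands are the
#' half-open partition `[1, udfc_upper)`, `[udfc_upper, ldfc_upper)`,
#' `[ldfc_upper, hdfc_lower)`, `[hdfc_lower, Inf)`, so the percentages sum
#' to exactly 100. Under `cumulative`, %UDFC and %LDFC are read off the
#' cumulative distribution (ER <= threshold) and %MID is reported as the
#' remainder between %LDFC and %HDFC bounds.
#'
#' @param sample An [er_sample] (or a bare numeric vector of ER values).
#' @param scheme A [threshold_scheme].
#' @return An object of class `deformability_profile` with fields `mer`,
#'   `aer`, `pct_udfc`, `pct_ldfc`, `pct_mid`, `pct_hdfc`, `n_cells`,
#'   `n_fields`, `sample_id` and `thresholds`.
#' @examples
#' p <- compute_profile(er_sample(c(1.05, 1.2, 1.5, 2.6)))
#' p$mer        # 1.35
#' p$pct_hdfc   # 25
#' @export
compute_profile <- function(sample, scheme = threshold_scheme()) {
  sample <- as_er_sample(sample)
  stopifnot(inherits(scheme, "threshold_scheme"))
  v <- sample$values
  n <- length(v)
  if (scheme$boundary_convention == "disjoint_bins") {
    udfc <- sum(v < scheme$udfc_upper)
    ldfc <- sum(v >= scheme$udfc_upper & v < scheme$ldfc_upper)
    mid  <- sum(v >= scheme$ldfc_upper & v < scheme$hdfc_lower)
    hdfc <- sum(v >= scheme$hdfc_lower)
  } else {
    udfc <- sum(v <= scheme$udfc_upper)
    ldfc <- sum(v <= scheme$ldfc_upper)
    hdfc <- sum(v >= scheme$hdfc_lower)
    mid  <- n - ldfc - hdfc
  }
  structure(
    list(mer = stats::median(v),
         aer = mean(v),
         pct_udfc = 100 * udfc / n,
         pct_ldfc = 100 * ldfc / n,
         pct_mid  = 100 * mid / n,
         pct_hdfc = 100 * hdfc / n,
         n_cells = n,
         n_fields = sample$n_fields,
         sample_id = sample$sample_id,
         thresholds = scheme),
    class = "deformability_profile")
}

#' @export
print.deformability_profile <- function(x, ...) {
  cat(sprintf("Deformability profile '%s' (n = %d cells%s)\n", x$sample_id,
              x$n_cells,
              if (is.na(x$n_fields)) "" else sprintf(", %d fields", x$n_fields)))
  cat(sprintf("  MER %.3f   AER %.3f\n", x$mer, x$aer))
  cat(sprintf("  %%UDFC %.2f   %%LDFC %.2f   %%MID %.2f   %%HDFC %.2f   (%s)\n",
              x$pct_udfc, x$pct_ldfc, x$pct_mid, x$pct_hdfc,
              x$thresholds$boundary_convention))
  invisible(x)
}

#' @export
as.data.frame.deformability_profile <- function(x, row.names = NULL,
                                                optional = FALSE, ...) {
  data.frame(sample_id = x$sample_id, mer = x$mer, aer = x$aer,
             pct_udfc = x$pct_udfc, pct_ldfc = x$pct_ldfc,
             pct_mid = x$pct_mid, pct_hdfc = x$pct_hdfc,
             n_cells = x$n_cells, n_fields = x$n_fields,
             stringsAsFactors = FALSE, row.names = row.names)
}

#' ER histogram and cumulative distribution curve
#'
#' Builds the ER distribution curve of a sample: a normalised histogram over
#' `[1, max(ER)]` with the given bin width plus the cumulative fraction of
#' cells per bin, from which MER and the band percentages can be read.
#'
#' @param sample An [er_sample] or numeric vector.
#' @param bin_width Histogram bin width on the ER axis (default 0.05, which
#'   resolves the 1.1 and 1.3 thresholds).
#' @return An object of class `er_distribution` with `bin_edges` (length
#'   nbins + 1), `density` (fraction of cells per bin, sums to 1) and
#'   `cumulative` (non-decreasing, ends at 1).
#' @export
distribution_curve <- function(sample, bin_width = 0.05) {
  sample <- as_er_sample(sample)
  if (!is.finite(bin_width) || bin_width <= 0)
    stop("bin_width must be a positive number")
  v <- sample$values
  upper <- max(v, 1 + bin_width)
  nbins <- ceiling((upper - 1) / bin_width + 1e-9)
  edges <- 1 + bin_width * seq(0L, nbins)
  # right-open bins [e_i, e_{i+1}); top edge closed so max(v) is counted
  idx <- pmin(floor((v - 1) / bin_width) + 1L, nbins)
  counts <- tabulate(idx, nbins)
  dens <- counts / length(v)
  structure(
    list(bin_edges = edges, density = dens, cumulative = cumsum(dens),
         bin_width = bin_width, n_cells = length(v),
         sample_id = sample$sample_id),
    class = "er_distribution")
}

#' Median ER read from a cumulative distribution curve
#'
#' The cumulative-curve counterpart of the raw-sample MER: the ER at which
#' the cumulative fraction first reaches 0.5, linearly interpolated inside
#' that bin. Agrees with the raw-sample median to within one bin width; the
#' raw-sample value is the canonical one.
#'
#' @param curve An [distribution_curve()] result.
#' @return The interpolated median ER.
#' @export
curve_median <- function(curve) {
  stopifnot(inherits(curve, "er_distribution"))
  cum <- curve$cumulative
  i <- which(cum >= 0.5)[1L]
  lo <- if (i == 1L) 0 else cum[i - 1L]
  frac <- if (cum[i] > lo) (0.5 - lo) / (cum[i] - lo) else 0.5
  curve$bin_edges[i] + frac * curve$bin_width
}

#' @export
print.er_distribution <- function(x, ...) {
  cat(sprintf("ER distribution '%s': %d bins of width %.3g over [%.3g, %.3g], n = %d\n",
              x$sample_id, length(x$density), x$bin_width,
              x$bin_edges[1L], x$bin_edges[length(x$bin_edges)], x$n_cells))
  invisible(x)
}

#' @export
plot.er_distribution <- function(x, which = c("both", "density", "cumulative"),
                                 ...) {
  which <- match.arg(which)
  mids <- x$bin_edges[-length(x$bin_edges)] + x$bin_width / 2
  if (which == "both") {
    op <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(op))
  }
  if (which %in% c("both", "density"))
    graphics::plot(mids, x$density, type = "h", lwd = 3,
                   xlab = "Elongation ratio", ylab = "Fraction of cells",
                   main = sprintf("ER distribution (%s)", x$sample_id), ...)
  if (which %in% c("both", "cumulative"))
    graphics::plot(mids, x$cumulative, type = "s",
                   xlab = "Elongation ratio", ylab = "Cumulative fraction",
                   main = "Cumulative distribution", ylim = c(0, 1), ...)
  invisible(x)
}

#' Pool per-field cell measurements into one specimen-level ER sample
#'
#' Concatenates the ER values of QC-passing cells across field-level
#' measurement tables (as produced by [segment_field()] or read with
#' [read_cell_table()]). The measurement protocol targets 25-35 fields and
#' 10,000-15,000 cells per specimen; totals outside those ranges trigger a
#' warning, not an error.
#'
#' @param per_field_tables A list of cell-measurement data frames (columns
#'   including `er` and `qc_pass`), or one combined data frame with a
#'   `field_id` column.
#' @param sample_id Specimen label for the pooled sample.
#' @param expected_cells,expected_fields Advisory protocol ranges.
#' @return An [er_sample] with `n_fields` set.
#' @export
aggregate_fields <- function(per_field_tables, sample_id = "specimen",
                             expected_cells = c(10000L, 15000L),
                             expected_fields = c(25L, 35L)) {
  if (is.data.frame(per_field_tables)) {
    n_fields <- if ("field_id" %in% names(per_field_tables))
      length(unique(per_field_tables$field_id)) else 1L
    tabs <- list(per_field_tables)
  } else {
    if (!is.list(per_field_tables) || length(per_field_tables) == 0L)
      stop("empty input: no field tables supplied")
    n_fields <- length(per_field_tables)
    tabs <- per_field_tables
  }
  ers <- unlist(lapply(tabs, function(tab) {
    if (nrow(tab) == 0L) return(numeric(0))
    if (!all(c("er", "qc_pass") %in% names(tab)))
      stop("cell tables need 'er' and 'qc_pass' columns")
    tab$er[as.logical(tab$qc_pass)]
  }), use.names = FALSE)
  if (length(ers) == 0L)
    stop("empty input: no QC-passing cells across fields")
  if (length(ers) < expected_cells[1L])
    warning(sprintf("specimen has %d QC-passing cells (protocol targets %d-%d)",
                    length(ers), expected_cells[1L], expected_cells[2L]))
  if (n_fields < expected_fields[1L] || n_fields > expected_fields[2L])
    warning(sprintf("specimen has %d fields (protocol targets %d-%d)",
                    n_fields, expected_fields[1L], expected_fields[2L]))
  er_sample(ers, sample_id = sample_id, n_fields = n_fields)
}
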