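#' Elongation ratio of a single cell
#'
#' The elongation ratio ER = A/B, where A and B are the cell's major and
#' minor axes under flow-induced shear. ER = 1 corresponds to a round,
#' undeformed (rigid) cell; larger values indicate stronger elongation.
#'
#' @param major_axis Major axis length A (any length unit, same as `minor_axis`).
#' @param minor_axis Minor axis length B.
#' @return The dimensionless ratio A/B, always >= 1. Vectorised.
#' @examples
#' elongation_ratio(13, 5)  # 2.6, a highly deformable cell
#' elongation_ratio(5, 5)   # 1.0, undeformed
#' @export
elongation_ratio <- function(major_axis, minor_axis) {
  if (length(major_axis) != length(minor_axis))
    stop("major_axis and minor_axis must have equal length")
  if (any(!is.finite(major_axis)) || any(!is.finite(minor_axis)))
    stop("invalid measurement: axes must be finite")
  if (any(major_axis <= 0) || any(minor_axis <= 0))
    stop("invalid measurement: axes must be positive")
  if (any(major_axis < minor_axis))
    stop("axis convention violation: major axis < minor axis (sort axes first)")
  major_axis / minor_axis
}

#' Construct a sample of per-cell elongation ratios
#'
#' Container for the ER values of one specimen (one blood unit or one
#' recipient sample), typically pooled over many microscopy fields.
#'
#' @param values Numeric vector of elongation ratios, each >= 1 and finite.
#' @param sample_id Character label for the specimen.
#' @param n_fields Number of microscopy fields the values came from, or
#'   `NA` when unknown (e.g. values loaded from a plain table).
#' @return An object of class `er_sample`.
#' @export
er_sample <- function(values, sample_id = "sample", n_fields = NA_integer_) {
  values <- as.numeric(values)
  if (length(values) == 0L)
    stop("empty input: an er_sample needs at least one value")
  if (any(!is.finite(values)))
    stop("invariant violation: ER values must be finite")
  if (any(values < 1))
    stop("invariant violation: ER values must be >= 1 (major/minor convention)")
  structure(
    list(values = values,
         sample_id = as.character(sample_id)[1L],
         n_fields = as.integer(n_fields)[1L]),
    class = "er_sample")
}

#' @export
print.er_sample <- function(x, ...) {
  cat(sprintf("ER sample '%s': %d cells%s\n", x$sample_id, length(x$values),
              if (is.na(x$n_fields)) "" else sprintf(" from %d fields", x$n_fields)))
  cat(sprintf("  median ER %.3f, mean ER %.3f, range [%.3f, %.3f]\n",
              stats::median(x$values), mean(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
length.er_sample <- function(x) length(x$values)

as_er_sample <- function(x, ...) {
  if (inherits(x, "er_sample")) x else er_sample(x, ...)
}

#' ER band thresholds for deformability subpopulations
#'
#' Defines the cut points separating undeformable (UDFC), low-deformable
#' (LDFC) and highly deformable (HDFC) cells on the ER axis. Defaults follow
#' the conventional bands: UDFC ER < 1.1, LDFC 1.1-1.3, HDFC ER >= 2.5.
#'
#' Two boundary conventions are supported. `"disjoint_bins"` (default)
#' partitions the ER axis into four half-open bands
#' `[1, 1.1)`, `[1.1, 1.3)`, `[1.3, 2.5)`, `[2.5, Inf)` whose percentages sum
#' to exactly 100. `"cumulative"` reports %UDFC as the fraction with
#' ER <= 1.1 and %LDFC as the fraction with ER <= 1.3 (the cumulative-curve
#' reading); under that convention the four numbers are not a partition.
#'
#' @param udfc_upper Upper ER bound of the undeformable band (default 1.1).
#' @param ldfc_upper Upper ER bound of the low-deformable band (default 1.3).
#' @param hdfc_lower Lower ER bound of the highly deformable band (default 2.5).
#' @param boundary_convention `"disjoint_bins"` or `"cumulative"`.
#' @return An object of class `threshold_scheme`.
#' @export
threshold_scheme <- function(udfc_upper = 1.1, ldfc_upper = 1.3,
                             hdfc_lower = 2.5,
                             boundary_convention = c("disjoint_bins",
                                                     "cumulative")) {
  boundary_convention <- match.arg(boundary_convention)
  for (v in c(udfc_upper, ldfc_upper, hdfc_lower))
    if (!is.finite(v)) stop("thresholds must be finite")
  if (!(1 < udfc_upper && udfc_upper < ldfc_upper && ldfc_upper < hdfc_lower))
    stop("invalid thresholds: need 1 < udfc_upper < ldfc_upper < hdfc_lower")
  structure(
    list(udfc_upper = udfc_upper, ldfc_upper = ldfc_upper,
         hdfc_lower = hdfc_lower, boundary_convention = boundary_convention),
    class = "threshold_scheme")
}

#' @export
print.threshold_scheme <- function(x, ...) {
  cat(sprintf(
    "ER thresholds (%s): UDFC < %.3g | LDFC < %.3g | mid | HDFC >= %.3g\n",
    x$boundary_convention, x$udfc_upper, x$ldfc_upper, x$hdfc_lower))
  invisible(x)
}
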