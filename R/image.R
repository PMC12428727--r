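#' A grayscale microscopy field image
#'
#' Wraps an intensity matrix with its physical pixel size. The coordinate
#' convention is x to the right (columns), y down (rows), 0-based, with
#' pixel centers at integer coordinates; cells are bright on a dark
#' background unless segmentation is told otherwise.
#'
#' @param pixels Numeric matrix of intensities (rows = y, columns = x).
#' @param pixel_size Pixel edge length in micrometres per pixel.
#' @param field_id Field label.
#' @return An object of class `field_image`; `$field_area_mm2` records the
#'   physical field area (the measurement protocol targets ~0.1 mm^2).
#' @export
field_image <- function(pixels, pixel_size, field_id = "field") {
  if (!is.matrix(pixels) || length(pixels) == 0L)
    stop("pixels must be a non-empty matrix")
  if (!is.numeric(pixel_size) || !is.finite(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be a positive number (micrometres per pixel)")
  structure(
    list(pixels = pixels, pixel_size = pixel_size,
         field_id = as.character(field_id)[1L],
         field_area_mm2 = nrow(pixels) * ncol(pixels) * pixel_size^2 / 1e6),
    class = "field_image")
}

#' @export
print.field_image <- function(x, ...) {
  cat(sprintf("Field image '%s': %d x %d px at %.3g um/px (%.4g mm^2)\n",
              x$field_id, ncol(x$pixels), nrow(x$pixels), x$pixel_size,
              x$field_area_mm2))
  invisible(x)
}

#' Read / write field images (TIFF or PNG)
#'
#' Grayscale images only; multi-channel files are collapsed by averaging.
#' The pixel size is supplied by the caller (it is configuration, not parsed
#' from image tags).
#'
#' @param path Image path ending in `.tif`, `.tiff` or `.png`.
#' @param pixel_size Micrometres per pixel.
#' @param field_id Field label; defaults to the file name.
#' @export
read_field_image <- function(path, pixel_size, field_id = NULL) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                tif = , tiff = tiff::readTIFF(path),
                png = png::readPNG(path),
                stop("unsupported image format: .", ext))
  if (length(dim(img)) == 3L) img <- apply(img, c(1L, 2L), mean)
  if (is.null(field_id)) field_id <- tools::file_path_sans_ext(basename(path))
  field_image(img, pixel_size, field_id)
}

#' @rdname read_field_image
#' @param image A [field_image]; intensities are clipped to `[0, 1]` on write.
#' @export
write_field_image <- function(image, path) {
  stopifnot(inherits(image, "field_image"))
  px <- pmin(pmax(image$pixels, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         tif = , tiff = tiff::writeTIFF(px, path, bits.per.sample = 16L),
         png = png::writePNG(px, path),
         stop("unsupported image format: .", ext))
  invisible(path)
}

#' Quality-control parameters for cell detection
#'
#' @param min_area_um2,max_area_um2 Accepted projected-area range in um^2.
#'   Defaults 20-200 bracket normal RBC projected areas.
#' @param exclude_border Drop components touching the field border (their
#'   axes cannot be measured reliably).
#' @param max_er Absurd-shape cutoff on the elongation ratio.
#' @param intensity_threshold_method `"otsu"` (default) or `"fixed"`.
#' @param fixed_threshold Intensity threshold when the method is `"fixed"`.
#' @param invert Set when cells are dark on a bright background.
#' @return An object of class `qc_params`.
#' @export
qc_params <- function(min_area_um2 = 20, max_area_um2 = 200,
                      exclude_border = TRUE, max_er = 6,
                      intensity_threshold_method = c("otsu", "fixed"),
                      fixed_threshold = NULL, invert = FALSE) {
  intensity_threshold_method <- match.arg(intensity_threshold_method)
  if (!(min_area_um2 > 0 && min_area_um2 < max_area_um2))
    stop("need 0 < min_area_um2 < max_area_um2")
  if (!is.numeric(max_er) || max_er <= 1)
    stop("max_er must exceed 1")
  if (intensity_threshold_method == "fixed" &&
      (is.null(fixed_threshold) || !is.finite(fixed_threshold)))
    stop("fixed threshold method needs a finite fixed_threshold")
  structure(
    list(min_area_um2 = min_area_um2, max_area_um2 = max_area_um2,
         exclude_border = isTRUE(exclude_border), max_er = max_er,
         intensity_threshold_method = intensity_threshold_method,
         fixed_threshold = fixed_threshold, invert = isTRUE(invert)),
    class = "qc_params")
}

# Moment ellipse from 0-based pixel-center coordinates. Axis lengths follow
# the 4*sqrt(eigenvalue) convention: a filled ellipse with semi-axes (a, b)
# has covariance eigenvalues (a^2/4, b^2/4), so the full axes 2a, 2b are
# recovered. Pixel centers under-count the mass spread within each unit
# cell; Sheppard's correction (+1/12 per axis) restores the continuous
# moments, which matters for minor axes under ~10 px.
.axes_from_coords <- function(x, y, pixel_size) {
  n <- length(x)
  if (n < 2L)
    stop("degenerate shape: component has fewer than 2 pixels")
  mx <- mean(x); my <- mean(y)
  cxx0 <- sum((x - mx)^2) / n
  cyy0 <- sum((y - my)^2) / n
  cxy <- sum((x - mx) * (y - my)) / n
  # degeneracy is judged on the raw pixel-center moments: a single pixel or
  # a collinear mask has no measurable minor axis
  disc0 <- sqrt(max((cxx0 - cyy0)^2 / 4 + cxy^2, 0))
  if ((cxx0 + cyy0) / 2 - disc0 <= 1e-9)
    stop("degenerate shape: collinear pixel mask")
  cxx <- cxx0 + 1 / 12
  cyy <- cyy0 + 1 / 12
  tr <- cxx + cyy
  disc <- sqrt(max((cxx - cyy)^2 / 4 + cxy^2, 0))
  l1 <- tr / 2 + disc
  l2 <- tr / 2 - disc
  list(major_um = 4 * sqrt(l1) * pixel_size,
       minor_um = 4 * sqrt(l2) * pixel_size,
       orientation = 0.5 * atan2(2 * cxy, cxx - cyy),
       centroid_x = mx, centroid_y = my)
}

#' Major/minor axes of a connected pixel mask
#'
#' Moment-based ellipse fit: the second-order central moments of the mask's
#' pixel coordinates (with Sheppard's +1/12 correction for the spread of
#' mass within each pixel cell) define an equivalent ellipse whose full
#' axis lengths are `4 * sqrt(eigenvalue)`, scaled so that an exact filled
#' ellipse recovers its true axes. Orientation is the angle of the major
#' axis from
#' the +x (flow) axis, in radians, measured toward +y (down).
#'
#' @param component_mask Logical or 0/1 matrix containing one connected
#'   component.
#' @param pixel_size Micrometres per pixel.
#' @return List with `major_um`, `minor_um`, `orientation` (radians) and the
#'   centroid in 0-based pixel coordinates; `major_um >= minor_um` always.
#' @export
fit_axes <- function(component_mask, pixel_size) {
  if (!is.matrix(component_mask))
    stop("component_mask must be a matrix")
  idx <- which(component_mask > 0)
  if (length(idx) == 0L) stop("degenerate shape: empty mask")
  rc <- arrayInd(idx, dim(component_mask))
  .axes_from_coords(x = rc[, 2L] - 1, y = rc[, 1L] - 1, pixel_size)
}

.empty_cell_table <- function(field_id = character(0)) {
  data.frame(field_id = field_id, cell_id = integer(0),
             centroid_x = numeric(0), centroid_y = numeric(0),
             major_um = numeric(0), minor_um = numeric(0), er = numeric(0),
             area_um2 = numeric(0), orientation = numeric(0),
             qc_pass = logical(0), qc_reason = character(0),
             stringsAsFactors = FALSE)
}

#' Detect and measure cells in one field image
#'
#' Foreground by global thresholding (Otsu by default), connected-component
#' labeling, then a moment ellipse fit per component. Components touching
#' the border, outside the accepted area range, too elongated, or degenerate
#' are kept in the table but flagged `qc_pass = FALSE` with a reason.
#'
#' @param image A [field_image].
#' @param qc A [qc_params] configuration.
#' @return A cell-measurement data frame (one row per detected component)
#'   with columns `field_id`, `cell_id`, `centroid_x`, `centroid_y`,
#'   `major_um`, `minor_um`, `er`, `area_um2`, `orientation`, `qc_pass`,
#'   `qc_reason`. A blank image yields a zero-row table.
#' @export
segment_field <- function(image, qc = qc_params()) {
  stopifnot(inherits(image, "field_image"), inherits(qc, "qc_params"))
  px <- image$pixels
  if (qc$invert) px <- max(px) - px
  rng <- range(px)
  if (qc$intensity_threshold_method == "otsu") {
    if (diff(rng) < .Machine$double.eps * 100)
      return(.empty_cell_table())          # constant image: no foreground
    scaled <- (px - rng[1L]) / diff(rng)
    thr <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
    mask <- scaled > thr
  } else {
    mask <- px > qc$fixed_threshold
    frac <- mean(mask)
    if (frac > 0.9)
      stop("degenerate threshold: fixed threshold classifies ",
           sprintf("%.0f%%", 100 * frac), " of the field as foreground")
  }
  if (!any(mask)) return(.empty_cell_table())
  lab <- EBImage::bwlabel(mask + 0)
  idx <- which(lab > 0)
  labs <- as.integer(lab[idx])
  rc <- arrayInd(idx, dim(lab))
  x <- rc[, 2L] - 1
  y <- rc[, 1L] - 1
  h <- nrow(px); w <- ncol(px)
  ps <- image$pixel_size

  # all component statistics in bulk: noisy images can produce tens of
  # thousands of speckle components and a per-component loop would crawl
  n <- tabulate(labs)
  k <- length(n)
  g <- seq_len(k)
  sx <- rowsum(x, labs)[, 1L]
  sy <- rowsum(y, labs)[, 1L]
  cx <- sx / n
  cy <- sy / n
  cxx0 <- rowsum(x^2, labs)[, 1L] / n - cx^2
  cyy0 <- rowsum(y^2, labs)[, 1L] / n - cy^2
  cxy <- rowsum(x * y, labs)[, 1L] / n - cx * cy
  border <- rowsum(as.numeric(x == 0 | x == w - 1 | y == 0 | y == h - 1),
                   labs)[, 1L] > 0
  area <- n * ps^2

  disc0 <- sqrt(pmax((cxx0 - cyy0)^2 / 4 + cxy^2, 0))
  l2_raw <- (cxx0 + cyy0) / 2 - disc0
  cxx <- cxx0 + 1 / 12
  cyy <- cyy0 + 1 / 12
  disc <- sqrt(pmax((cxx - cyy)^2 / 4 + cxy^2, 0))
  l1 <- (cxx + cyy) / 2 + disc
  l2 <- (cxx + cyy) / 2 - disc
  major <- 4 * sqrt(pmax(l1, 0)) * ps
  minor <- 4 * sqrt(pmax(l2, 0)) * ps
  er <- major / minor
  orient <- 0.5 * atan2(2 * cxy, cxx - cyy)

  degenerate <- l2_raw <= 1e-9
  reason <- rep("", k)
  pass <- rep(TRUE, k)
  bad_area <- area < qc$min_area_um2 | area > qc$max_area_um2
  bad_border <- qc$exclude_border & border
  reason[pass & bad_border] <- "border"; pass[bad_border] <- FALSE
  reason[pass & bad_area] <- "area"; pass[pass & bad_area] <- FALSE
  reason[pass & degenerate] <- "degenerate"; pass[pass & degenerate] <- FALSE
  too_long <- !degenerate & er > qc$max_er
  reason[pass & too_long] <- "elongation"; pass[pass & too_long] <- FALSE
  major[degenerate | bad_border | bad_area] <- NA_real_
  minor[degenerate | bad_border | bad_area] <- NA_real_
  er[degenerate | bad_border | bad_area] <- NA_real_
  orient[degenerate | bad_border | bad_area] <- NA_real_

  data.frame(field_id = image$field_id, cell_id = g,
             centroid_x = cx, centroid_y = cy,
             major_um = major, minor_um = minor, er = er,
             area_um2 = area, orientation = orient,
             qc_pass = pass, qc_reason = reason,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Segment a set of fields and profile the specimen
#'
#' Maps [segment_field()] over the fields, pools the QC-passing cells with
#' [aggregate_fields()] and summarises them with [compute_profile()].
#'
#' @param images List of [field_image] objects (one specimen).
#' @param qc A [qc_params].
#' @param scheme A [threshold_scheme].
#' @param sample_id Specimen label attached to the output.
#' @return List with `cells` (combined measurement table, `sample_id`
#'   prepended) and `profile` (a `deformability_profile`).
#' @export
analyze_specimen <- function(images, qc = qc_params(),
                             scheme = threshold_scheme(),
                             sample_id = "specimen") {
  if (!is.list(images) || length(images) == 0L)
    stop("need at least one field image")
  tabs <- lapply(images, segment_field, qc = qc)
  sample <- aggregate_fields(tabs, sample_id = sample_id)
  cells <- do.call(rbind, tabs)
  cells <- cbind(sample_id = sample_id, cells, stringsAsFactors = FALSE)
  list(cells = cells, profile = compute_profile(sample, scheme))
}
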