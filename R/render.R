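#' Imaging parameters for synthetic field rendering
#'
#' Geometry and noise settings for rendering shear-aligned RBCs into a
#' square field image of the configured physical area. Cells are drawn as
#' filled bright ellipses on a dark background, major axis along the flow
#' (+x) direction up to a small angular jitter, with projected area
#' preserved under elongation.
#'
#' @param pixel_size Micrometres per pixel (default 0.25, a high-NA 40x
#'   objective scale).
#' @param field_area_mm2 Physical field area (default 0.1 mm^2, the
#'   measurement-protocol field size).
#' @param cells_per_field Cells rendered per field (default 400: 25 fields
#'   then pool 10,000 cells).
#' @param cell_area_um2_mean,cell_area_um2_sd Projected-area distribution
#'   (defaults 55 +/- 8 um^2, an undeformed disc of ~8 um diameter).
#' @param angle_jitter_sd_deg SD of the cell-orientation jitter around the
#'   flow axis, degrees (default 5).
#' @param blur_sigma_px Gaussian blur sigma in pixels (0 disables).
#' @param noise_sd Additive Gaussian intensity noise SD (0 disables);
#'   intensities are clipped to `[0, 1]` after noise.
#' @param background,foreground Background and cell intensity levels in
#'   `[0, 1]`.
#' @param allow_overlap Skip the non-overlap rejection sampling.
#' @param max_tries Placement attempts per cell before a placement-failure
#'   error.
#' @return An object of class `imaging_params`.
#' @export
imaging_params <- function(pixel_size = 0.25, field_area_mm2 = 0.1,
                           cells_per_field = 400L,
                           cell_area_um2_mean = 55, cell_area_um2_sd = 8,
                           angle_jitter_sd_deg = 5,
                           blur_sigma_px = 0, noise_sd = 0,
                           background = 0.1, foreground = 0.8,
                           allow_overlap = FALSE, max_tries = 400L) {
  if (!is.finite(field_area_mm2) || field_area_mm2 <= 0)
    stop("field_area_mm2 must be positive")
  if (!is.finite(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be positive")
  if (cells_per_field < 0) stop("cells_per_field must be >= 0")
  structure(
    list(pixel_size = pixel_size, field_area_mm2 = field_area_mm2,
         cells_per_field = as.integer(cells_per_field),
         cell_area_um2_mean = cell_area_um2_mean,
         cell_area_um2_sd = cell_area_um2_sd,
         angle_jitter_sd_deg = angle_jitter_sd_deg,
         blur_sigma_px = blur_sigma_px, noise_sd = noise_sd,
         background = background, foreground = foreground,
         allow_overlap = isTRUE(allow_overlap),
         max_tries = as.integer(max_tries)),
    class = "imaging_params")
}

# Pixel-center coordinates (0-based) inside an ellipse at (cx, cy) with
# semi-axes (a, b) and orientation theta (from +x toward +y). Cell centers
# are continuous uniforms, so the rasterization phase is generic; the
# grid-aligned worst case (boundary running flat along a pixel row) has
# measure zero.
.ellipse_pixels <- function(cx, cy, a, b, theta, w, h) {
  r <- ceiling(max(a, b)) + 1L
  xr <- max(0L, floor(cx - r)):min(w - 1L, ceiling(cx + r))
  yr <- max(0L, floor(cy - r)):min(h - 1L, ceiling(cy + r))
  if (length(xr) == 0L || length(yr) == 0L) return(NULL)
  g <- expand.grid(x = xr, y = yr)
  dx <- g$x - cx; dy <- g$y - cy
  ct <- cos(theta); st <- sin(theta)
  u <- dx * ct + dy * st
  v <- -dx * st + dy * ct
  inside <- (u / a)^2 + (v / b)^2 <= 1
  g[inside, , drop = FALSE]
}

#' Render a synthetic field image with ground truth
#'
#' Places each cell of the input sample as a filled ellipse whose axis
#' ratio equals the cell's ER and whose projected area is drawn from the
#' configured distribution; optional Gaussian blur and additive noise
#' follow. Unless `allow_overlap`, placement uses rejection sampling with a
#' 2-pixel separation margin so detected components never merge. Cells are
#' kept fully inside the field (their axes are only measurable when whole).
#'
#' @param cells ER values to render: an [er_sample], numeric vector, or a
#'   data frame with column `er` (optionally `area_um2`).
#' @param params An [imaging_params].
#' @param field_id Field label.
#' @return List with `image` (a [field_image]) and `truth` (data frame of
#'   exact per-cell centers in 0-based pixels, axes in um, `er`, `area_um2`
#'   and `orientation` in radians).
#' @export
render_field <- function(cells, params = imaging_params(),
                         field_id = "field") {
  stopifnot(inherits(params, "imaging_params"))
  if (inherits(cells, "er_sample")) {
    ers <- cells$values
    areas <- NULL
  } else if (is.data.frame(cells)) {
    ers <- cells$er
    areas <- cells$area_um2
  } else {
    ers <- as.numeric(cells)
    areas <- NULL
  }
  if (length(ers) && any(!is.finite(ers) | ers < 1))
    stop("cell ER values must be finite and >= 1")
  side_um <- sqrt(params$field_area_mm2 * 1e6)
  side <- round(side_um / params$pixel_size)
  img <- matrix(params$background, nrow = side, ncol = side)
  truth <- data.frame(field_id = character(0), cell_id = integer(0),
                      centroid_x = numeric(0), centroid_y = numeric(0),
                      major_um = numeric(0), minor_um = numeric(0),
                      er = numeric(0), area_um2 = numeric(0),
                      orientation = numeric(0), stringsAsFactors = FALSE)
  if (length(ers) == 0L)
    return(list(image = field_image(img, params$pixel_size, field_id),
                truth = truth))
  occupied <- matrix(FALSE, nrow = side, ncol = side)
  rows <- vector("list", length(ers))
  for (i in seq_along(ers)) {
    er <- ers[i]
    area <- if (!is.null(areas)) areas[i] else
      max(stats::rnorm(1, params$cell_area_um2_mean, params$cell_area_um2_sd),
          10)
    b_um <- sqrt(area / (pi * er))
    a_um <- er * b_um
    a <- a_um / params$pixel_size
    b <- b_um / params$pixel_size
    theta <- stats::rnorm(1, 0, params$angle_jitter_sd_deg * pi / 180)
    placed <- FALSE
    margin <- a + 3
    if (2 * margin >= side)
      stop("placement failure: cell larger than the field")
    for (try in seq_len(params$max_tries)) {
      cx <- stats::runif(1, margin, side - 1 - margin)
      cy <- stats::runif(1, margin, side - 1 - margin)
      if (!params$allow_overlap) {
        guard <- .ellipse_pixels(cx, cy, a + 2, b + 2, theta, side, side)
        if (is.null(guard) || nrow(guard) == 0L) next
        if (any(occupied[cbind(guard$y + 1L, guard$x + 1L)])) next
      }
      pix <- .ellipse_pixels(cx, cy, a, b, theta, side, side)
      if (is.null(pix) || nrow(pix) == 0L) next
      img[cbind(pix$y + 1L, pix$x + 1L)] <- params$foreground
      if (!params$allow_overlap)
        occupied[cbind(guard$y + 1L, guard$x + 1L)] <- TRUE
      rows[[i]] <- data.frame(field_id = field_id, cell_id = i,
                              centroid_x = cx, centroid_y = cy,
                              major_um = 2 * a_um, minor_um = 2 * b_um,
                              er = er, area_um2 = area, orientation = theta,
                              stringsAsFactors = FALSE)
      placed <- TRUE
      break
    }
    if (!placed)
      stop(sprintf(
        "placement failure: could not place cell %d without overlap after %d tries",
        i, params$max_tries))
  }
  truth <- do.call(rbind, rows)
  if (params$blur_sigma_px > 0) {
    img <- EBImage::imageData(EBImage::gblur(EBImage::Image(img),
                                             sigma = params$blur_sigma_px))
    dim(img) <- c(side, side)
  }
  if (params$noise_sd > 0)
    img <- img + matrix(stats::rnorm(length(img), 0, params$noise_sd),
                        nrow = nrow(img))
  img <- pmin(pmax(img, 0), 1)
  list(image = field_image(img, params$pixel_size, field_id), truth = truth)
}

#' Render a whole specimen as a set of field images
#'
#' Splits a population sample across `n_fields` fields of
#' `params$cells_per_field` cells each (drawing fresh ER values from
#' `model` when given a model instead of a sample) and renders each field.
#'
#' @param model_or_sample A [population_model] or [er_sample].
#' @param n_fields Number of fields (default 25).
#' @param params An [imaging_params].
#' @param seed Integer seed covering ER draws, geometry and placement.
#' @return List with `images` (list of [field_image]), `truth` (combined
#'   truth table) and `sample_ers` (the rendered ER values).
#' @export
render_specimen <- function(model_or_sample, n_fields = 25L,
                            params = imaging_params(), seed = NULL) {
  with_seed(seed, {
    total <- n_fields * params$cells_per_field
    ers <- if (inherits(model_or_sample, "population_model")) {
      simulate_er_population(model_or_sample, total)$values
    } else if (inherits(model_or_sample, "er_sample")) {
      v <- model_or_sample$values
      if (length(v) < total)
        stop(sprintf("sample has %d cells but %d are needed", length(v),
                     total))
      v[seq_len(total)]
    } else stop("model_or_sample must be a population_model or er_sample")
    images <- vector("list", n_fields)
    truths <- vector("list", n_fields)
    for (f in seq_len(n_fields)) {
      idx <- ((f - 1L) * params$cells_per_field + 1L):(f * params$cells_per_field)
      fid <- sprintf("field%02d", f)
      rf <- render_field(ers[idx], params, field_id = fid)
      images[[f]] <- rf$image
      truths[[f]] <- rf$truth
    }
    list(images = images, truth = do.call(rbind, truths), sample_ers = ers)
  })
}
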