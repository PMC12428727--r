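test_that("fit_axes recovers known shapes from their pixel masks", {
  # filled circle, radius 8 px: both axes 8 um at 0.5 um/px, er ~ 1
  circ <- ellipse_mask(8, 8)
  ax <- fit_axes(circ, 0.5)
  expect_equal(ax$major_um, 8, tolerance = 0.02)
  expect_equal(ax$minor_um, 8, tolerance = 0.02)
  expect_lt(ax$major_um / ax$minor_um, 1.02)

  # axis-aligned rectangle: exact moment oracle (a solid w-wide bar has
  # variance w^2/12; pixel centers give (w^2-1)/12 and Sheppard's +1/12
  # restores it)
  rect <- matrix(FALSE, 30, 30); rect[10:16, 5:25] <- TRUE  # 21 x 7 px
  ax <- fit_axes(rect, 1)
  expect_equal(ax$major_um, 4 * sqrt(21^2 / 12), tolerance = 1e-12)
  expect_equal(ax$minor_um, 4 * sqrt(7^2 / 12), tolerance = 1e-12)

  # rotated ellipse, semi-axes (20, 10) at 30 degrees
  th <- 30 * pi / 180
  ell <- ellipse_mask(20, 10, th)
  ax <- fit_axes(ell, 1)
  expect_equal(ax$major_um / ax$minor_um, 2, tolerance = 0.02)
  expect_equal(ax$orientation, th, tolerance = 2 * pi / 180)
  # brute-force covariance oracle on the raw coordinates (+ cell variance)
  rc <- which(ell, arr.ind = TRUE)
  cv <- stats::cov(cbind(rc[, 2], rc[, 1])) * (nrow(rc) - 1) / nrow(rc) +
    diag(2) / 12
  ev <- eigen(cv, symmetric = TRUE)$values
  expect_equal(ax$major_um, 4 * sqrt(ev[1]), tolerance = 1e-9)
  expect_equal(ax$minor_um, 4 * sqrt(ev[2]), tolerance = 1e-9)

  # the highly deformable exemplar: semi-axes (13, 5) px, er ~ 2.6
  ax <- fit_axes(ellipse_mask(13, 5), 1)
  expect_equal(ax$major_um / ax$minor_um, 2.6, tolerance = 0.03 * 2.6)
})

test_that("fit_axes agrees with an independent moment implementation", {
  ell <- ellipse_mask(15, 9, 0.4)
  ax <- fit_axes(ell, 1)
  lab <- EBImage::bwlabel(ell + 0)
  ft <- EBImage::computeFeatures.moment(lab)
  # EBImage uses raw pixel-center moments (no within-cell correction), so
  # agreement is to the sub-percent level, not exact
  expect_equal(ax$major_um, unname(ft[1, "m.majoraxis"]), tolerance = 5e-3)
})

test_that("fit_axes rejects degenerate masks and scales with pixel size", {
  single <- matrix(FALSE, 5, 5); single[3, 3] <- TRUE
  expect_error(fit_axes(single, 1), "degenerate")
  line <- matrix(FALSE, 5, 9); line[3, 2:8] <- TRUE
  expect_error(fit_axes(line, 1), "degenerate")
  expect_error(fit_axes(matrix(FALSE, 3, 3), 1), "degenerate")

  ell <- ellipse_mask(12, 6, 0.2)
  a1 <- fit_axes(ell, 0.5)
  a2 <- fit_axes(ell, 1.0)
  expect_equal(a2$major_um, 2 * a1$major_um, tolerance = 1e-12)
  er1 <- a1$major_um / a1$minor_um
  er2 <- a2$major_um / a2$minor_um
  expect_equal(er1, er2, tolerance = 1e-6)
})

test_that("segment_field measures a rendered ellipse and handles blanks", {
  # solid ellipse with full axes 16 x 8 px at 0.5 um/px
  img <- matrix(0.1, 80, 80)
  m <- ellipse_mask(8, 4)
  img[20:(19 + nrow(m)), 20:(19 + ncol(m))][m] <- 0.8
  fi <- field_image(img, 0.5, "f")
  tab <- segment_field(fi)
  expect_equal(nrow(tab), 1L)
  expect_true(tab$qc_pass)
  expect_equal(tab$er, 2.0, tolerance = 0.03 / 2)

  blank <- field_image(matrix(0.1, 50, 50), 0.5)
  expect_equal(nrow(segment_field(blank)), 0L)

  # fixed threshold below the background marks everything foreground
  expect_error(
    segment_field(fi, qc_params(intensity_threshold_method = "fixed",
                                fixed_threshold = 0.01)),
    "degenerate threshold")

  # dark-on-bright dialect via the invert flag
  inv <- field_image(1 - img, 0.5)
  tab2 <- segment_field(inv, qc_params(invert = TRUE))
  expect_equal(tab2$er, tab$er, tolerance = 1e-9)
})

test_that("border, area and elongation QC filters flag with reasons", {
  img <- matrix(0.1, 60, 60)
  img[1:10, 20:34] <- 0.8  # solid blob touching the top border
  tab <- segment_field(field_image(img, 0.5))
  expect_equal(sum(tab$qc_pass), 0L)
  expect_equal(tab$qc_reason, "border")
  tab_keep <- segment_field(field_image(img, 0.5),
                            qc_params(exclude_border = FALSE))
  expect_equal(tab_keep$qc_reason, "")

  # a tiny speck fails the area filter
  img2 <- matrix(0.1, 60, 60); img2[30:31, 30:31] <- 0.8
  tab2 <- segment_field(field_image(img2, 0.5))
  expect_equal(tab2$qc_reason, "area")

  # an absurdly thin streak fails the elongation filter
  img3 <- matrix(0.1, 60, 60); img3[30:32, 5:55] <- 0.8
  tab3 <- segment_field(field_image(img3, 1))
  expect_equal(tab3$qc_reason, "elongation")
})

test_that("measured er is rotation robust", {
  ers <- vapply(seq(0, 170, by = 20), function(deg) {
    m <- ellipse_mask(12, 6, deg * pi / 180)
    ax <- fit_axes(m, 1)
    ax$major_um / ax$minor_um
  }, numeric(1))
  expect_lt((max(ers) - min(ers)) / 2, 0.03 * 2)
})

test_that("noise degrades er accuracy monotonically", {
  # fixed threshold so the degradation isolates the noise itself (Otsu
  # re-estimates the cut per image, which is not monotone in noise)
  truth_ers <- c(1.2, 1.6, 2.0, 2.6, 1.05, 1.4, 1.8, 3.0)
  qcf <- qc_params(intensity_threshold_method = "fixed",
                   fixed_threshold = 0.45)
  med_err <- vapply(c(0, 0.08, 0.2), function(ns) {
    set.seed(99)
    rf <- render_field(truth_ers,
                       imaging_params(cells_per_field = length(truth_ers),
                                      noise_sd = ns, blur_sigma_px = 1))
    det <- segment_field(rf$image, qcf)
    errs <- match_er_errors(rf$truth, det)
    median(errs, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(med_err) >= -1e-12))
})

test_that("analyze_specimen recovers a known specimen profile", {
  model <- calibrate_population(1.55, 1.12, 6.14)
  spec <- render_specimen(model, n_fields = 3,
                          params = imaging_params(cells_per_field = 150),
                          seed = 21)
  res <- suppressWarnings(analyze_specimen(spec$images, sample_id = "sp"))
  expect_equal(sum(res$cells$qc_pass), nrow(spec$truth))
  expect_lt(abs(res$profile$mer - median(spec$truth$er)), 0.02)
  errs <- match_er_errors(spec$truth, res$cells)
  expect_true(all(is.finite(errs)))
  expect_lt(max(errs), 0.03)

  blank <- field_image(matrix(0.1, 40, 40), 0.5)
  expect_error(suppressWarnings(analyze_specimen(list(blank))),
               "empty input")
})

test_that("field images round-trip through TIFF and PNG", {
  set.seed(5)
  rf <- render_field(c(1.3, 2.0), imaging_params(cells_per_field = 2))
  for (ext in c(".tiff", ".png")) {
    f <- tempfile(fileext = ext)
    write_field_image(rf$image, f)
    back <- read_field_image(f, pixel_size = rf$image$pixel_size)
    expect_equal(dim(back$pixels), dim(rf$image$pixels))
    tab <- segment_field(back)
    expect_equal(sort(tab$er[tab$qc_pass]),
                 sort(segment_field(rf$image)$er), tolerance = 1e-3)
  }
})
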