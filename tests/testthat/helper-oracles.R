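# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: loops, closed forms and raw pixel bookkeeping.

# Naive count/sort oracle for the deformability profile (disjoint bands).
naive_profile <- function(values, udfc = 1.1, ldfc = 1.3, hdfc = 2.5) {
  n <- length(values)
  counts <- c(udfc = 0, ldfc = 0, mid = 0, hdfc = 0)
  for (v in values) {
    if (v < udfc) counts["udfc"] <- counts["udfc"] + 1
    else if (v < ldfc) counts["ldfc"] <- counts["ldfc"] + 1
    else if (v < hdfc) counts["mid"] <- counts["mid"] + 1
    else counts["hdfc"] <- counts["hdfc"] + 1
  }
  s <- sort(values)
  mer <- if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  list(mer = mer, aer = sum(values) / n, pct = 100 * counts / n)
}

# Random ER samples covering the band boundaries exactly.
random_er_sample <- function(n) {
  pool <- c(1 + rexp(n, 2), 1 + runif(n), c(1, 1.1, 1.3, 2.5))
  sample(pool, n, replace = TRUE)
}

# Pixel mask of a filled ellipse (pixel-center-inside rasterization),
# built directly from the ellipse equation, independent of the package's
# renderer. The center sits at a generic sub-pixel offset: grid-aligned
# centers are the measure-zero worst case of rasterization (the boundary
# runs flat along a pixel row and a whole half-row flickers in or out),
# which real cells at continuous positions never hit exactly.
ellipse_mask <- function(a, b, theta = 0, pad = 4) {
  r <- ceiling(max(a, b)) + pad
  side <- 2 * r + 1
  cx <- r + 0.2; cy <- r + 0.3  # 0-based, generic phase
  xy <- expand.grid(x = 0:(side - 1), y = 0:(side - 1))
  dx <- xy$x - cx; dy <- xy$y - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  m <- matrix(FALSE, nrow = side, ncol = side)
  m[cbind(xy$y + 1, xy$x + 1)] <- inside
  m
}

# Student pooled-variance two-sample t computed from the textbook formula.
pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Pearson correlation from the raw sum formula.
pearson_sums <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# Match detected cells to truth rows by nearest centroid within one field;
# returns per-truth-cell relative ER error (NA where unmatched). All
# measured components count as detections, including ones QC flagged for
# extreme elongation (their axes are still measured).
match_er_errors <- function(truth, detected, max_dist_px = 5) {
  errs <- rep(NA_real_, nrow(truth))
  for (f in unique(truth$field_id)) {
    tr <- truth[truth$field_id == f, ]
    de <- detected[detected$field_id == f & is.finite(detected$er), ]
    if (nrow(de) == 0) next
    for (i in seq_len(nrow(tr))) {
      d2 <- (de$centroid_x - tr$centroid_x[i])^2 +
        (de$centroid_y - tr$centroid_y[i])^2
      j <- which.min(d2)
      if (d2[j] <= max_dist_px^2)
        errs[which(truth$field_id == f)[i]] <-
          abs(de$er[j] - tr$er[i]) / tr$er[i]
    }
  }
  errs
}
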