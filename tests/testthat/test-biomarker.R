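test_that("log_transform maps intensities and flags non-positive values", {
  expect_equal(log_transform(1), 0)
  expect_equal(log_transform(exp(1)), 1)
  expect_warning(out <- log_transform(c(10, 0, -3, NA)), "missing")
  expect_equal(is.na(out), c(FALSE, TRUE, TRUE, TRUE))
})

test_that("noise-free fits are recovered exactly", {
  x <- c(1, 2, 3, 4, 5)
  tab <- data.frame(unit_id = 1:5, P = x, mer = 2 * x + 1)
  # lm warns about the perfect fit; the exactness is the point here
  f <- suppressWarnings(fit_single(tab, "P"))
  expect_equal(unname(f$coefficients["P"]), 2, tolerance = 1e-9)
  expect_equal(f$intercept, 1, tolerance = 1e-9)
  expect_equal(f$R, 1, tolerance = 1e-9)

  set.seed(13)
  tab2 <- data.frame(unit_id = 1:10, P = rnorm(10, 25), HBB = rnorm(10, 25))
  tab2$mer <- 0.02 * tab2$P + 0.03 * tab2$HBB + 0.3
  f2 <- suppressWarnings(fit_combined(tab2, "P"))
  expect_equal(unname(f2$coefficients), c(0.02, 0.03), tolerance = 1e-9)
  expect_equal(f2$R, 1, tolerance = 1e-6)
})

test_that("single-predictor R matches the raw-sum Pearson formula", {
  x <- c(1, 2, 3, 4)
  y <- c(1.1, 1.2, 1.4, 1.5)
  tab <- data.frame(unit_id = 1:4, P = x, mer = y)
  f <- fit_single(tab, "P")
  expect_equal(f$R, abs(pearson_sums(x, y)), tolerance = 1e-12)
  # and the p-value matches the correlation t-test closed form
  r <- pearson_sums(x, y)
  tstat <- r * sqrt(2) / sqrt(1 - r^2)
  expect_equal(f$p_value, 2 * pt(-abs(tstat), 2), tolerance = 1e-12)
})

test_that("the combined model never has smaller R than its nested singles", {
  set.seed(29)
  for (i in 1:100) {
    n <- sample(6:30, 1)
    tab <- data.frame(unit_id = seq_len(n), P = rnorm(n), HBB = rnorm(n),
                      mer = rnorm(n, 1.5, 0.1))
    rc <- fit_combined(tab, "P")$R
    expect_gte(rc, fit_single(tab, "P")$R - 1e-9)
    expect_gte(rc, fit_single(tab, "HBB")$R - 1e-9)
  }
})

test_that("fits are invariant to row order and response shifts", {
  set.seed(37)
  tab <- simulate_proteomics(proteomics_sim_params(), seed = 4)
  f <- fit_combined(tab, "flotillin_1")
  shuf <- tab[sample(nrow(tab)), ]
  fs <- fit_combined(shuf, "flotillin_1")
  expect_equal(fs$coefficients, f$coefficients, tolerance = 1e-9)
  expect_equal(fs$R, f$R, tolerance = 1e-12)

  shifted <- tab; shifted$mer <- shifted$mer + 5
  ff <- fit_combined(shifted, "flotillin_1")
  expect_equal(ff$coefficients, f$coefficients, tolerance = 1e-9)
  expect_equal(ff$intercept, f$intercept + 5, tolerance = 1e-9)
})

test_that("degenerate and missing inputs are rejected informatively", {
  tab <- data.frame(unit_id = 1:5, P = rep(2, 5), mer = rnorm(5, 1.5))
  expect_error(fit_single(tab, "P"), "zero variance")
  expect_error(fit_single(tab, "nope"), "missing column")
  small <- data.frame(unit_id = 1:2, P = 1:2, mer = c(1.4, 1.5))
  expect_error(fit_single(small, "P"), "insufficient data")
  # LFQ zeros become NA and drop the unit from the fit
  raw <- data.frame(unit_id = 1:6, mer = c(1.4, 1.5, 1.6, 1.5, 1.45, 1.55))
  raw$P <- suppressWarnings(log_transform(c(10, 20, 0, 15, 12, 18)))
  f <- fit_single(raw, "P")
  expect_equal(f$n, 5L)
  expect_equal(f$n_excluded, 1L)
})

test_that("null fits reject at the nominal rate with null-level R", {
  set.seed(43)
  res <- t(vapply(1:200, function(i) {
    tab <- data.frame(unit_id = 1:15, P = rnorm(15),
                      mer = rnorm(15, 1.5, 0.1))
    f <- fit_single(tab, "P")
    c(f$R, f$p_value < 0.05)
  }, numeric(2)))
  # E|r| under the null at n = 15 is about sqrt(2 / (pi (n - 1))) ~ 0.213
  expect_lt(abs(mean(res[, 1]) - sqrt(2 / (pi * 14))), 0.05)
  expect_lt(abs(mean(res[, 2]) - 0.05), 0.05)
})

test_that("evaluate_panel reproduces the single + combined table structure", {
  tab <- simulate_proteomics(proteomics_sim_params(), seed = 15)
  panel <- evaluate_panel(tab)
  expect_equal(nrow(panel), 11L)  # 6 singles + 5 HBB pairs
  expect_equal(sum(grepl("^HBB and ", panel$predictors)), 5L)
  # every combined R at least matches its single components
  for (p in c("ezrin", "stomatin", "band_4.1", "flotillin_2",
              "flotillin_1")) {
    rc <- panel$R[panel$predictors == sprintf("HBB and %s", p)]
    expect_gte(rc, panel$R[panel$predictors == p] - 1e-9)
    expect_gte(rc, panel$R[panel$predictors == "HBB"] - 1e-9)
  }
  expect_error(evaluate_panel(tab, character(0)), "missing input")
  solo <- evaluate_panel(tab, "HBB")
  expect_equal(nrow(solo), 1L)
  sorted <- evaluate_panel(tab, sort_by_r = TRUE)
  expect_true(all(diff(sorted$R) <= 1e-12))
})

test_that("prediction-based selection matches the truth ranking", {
  tab <- simulate_proteomics(proteomics_sim_params(), seed = 19)
  fit <- fit_combined(tab, "flotillin_1")
  rk <- predict_and_select(fit, tab, recipient_response = 1.55,
                           tolerance = 0.01)
  expect_equal(nrow(rk$rankings), nrow(tab))
  expect_true(all(rk$rankings$verdict %in%
                    c("higher", "lower", "equal_within_tol")))

  # trivial verdicts
  one <- tab[1, ]; one$unit_id <- "X"
  pred <- predict(fit, one)
  r1 <- suppressWarnings(
    predict_and_select(fit, one, recipient_response = pred - 0.05))
  expect_equal(r1$rankings$verdict, "higher")
  r2 <- predict_and_select(fit, one, recipient_response = pred + 0.005)
  expect_equal(r2$rankings$verdict, "equal_within_tol")

  # units missing a predictor are flagged unrankable
  tab2 <- tab
  tab2$HBB[3] <- NA
  expect_warning(r3 <- predict_and_select(fit, tab2, 1.55), "unrankable")
  expect_equal(sum(r3$rankings$verdict == "unrankable"), 1L)

  # rank agreement with generator truth at the default noise level
  big <- simulate_proteomics(proteomics_sim_params(n_units = 30), seed = 27)
  fit30 <- fit_combined(big, "flotillin_1")
  rk30 <- predict_and_select(fit30, big, 1.55)
  m <- merge(rk30$rankings, big[, c("unit_id", "true_response")])
  expect_gte(cor(m$unit_mer, m$true_response, method = "spearman"), 0.8)
})

test_that("biomarker_fit methods behave like a regression object", {
  tab <- simulate_proteomics(proteomics_sim_params(), seed = 8)
  f <- fit_combined(tab, "flotillin_1")
  expect_named(coef(f), c("(Intercept)", "flotillin_1", "HBB"))
  expect_equal(length(residuals(f)), f$n)
  ci <- confint(f)
  expect_true(ci["flotillin_1", 1] < ci["flotillin_1", 2])
  expect_equal(unname(predict(f, tab)),
               unname(as.numeric(coef(f)[1] + coef(f)["flotillin_1"] *
                                   tab$flotillin_1 +
                                   coef(f)["HBB"] * tab$HBB)),
               tolerance = 1e-9)
  expect_output(print(f), "R = ")
  # no-intercept variant mirrors the bare two-coefficient equation
  f0 <- fit_combined(tab, "flotillin_1", intercept = FALSE)
  expect_equal(f0$intercept, 0)
  expect_named(coef(f0), c("flotillin_1", "HBB"))
})
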