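test_that("elongation_ratio follows the major/minor convention", {
  expect_identical(elongation_ratio(5, 5), 1)
  expect_equal(elongation_ratio(13, 5), 2.6)
  expect_equal(elongation_ratio(3, 2), 1.5)
  expect_equal(elongation_ratio(c(5, 13), c(5, 5)), c(1, 2.6))
  expect_error(elongation_ratio(0, 0), "invalid measurement")
  expect_error(elongation_ratio(5, -1), "invalid measurement")
  expect_error(elongation_ratio(5, Inf), "invalid measurement")
  expect_error(elongation_ratio(2, 5), "convention violation")
})

test_that("er_sample enforces its invariants", {
  s <- er_sample(c(1.2, 1.4), sample_id = "x", n_fields = 2)
  expect_s3_class(s, "er_sample")
  expect_length(s, 2L)
  expect_error(er_sample(numeric(0)), "empty input")
  expect_error(er_sample(c(1.2, 0.9)), "invariant violation")
  expect_error(er_sample(c(1.2, NA)), "invariant violation")
})

test_that("threshold schemes validate their ordering", {
  expect_error(threshold_scheme(1.3, 1.1), "invalid thresholds")
  expect_error(threshold_scheme(udfc_upper = 0.9), "invalid thresholds")
  sc <- threshold_scheme()
  expect_equal(sc$udfc_upper, 1.1)
  expect_equal(sc$boundary_convention, "disjoint_bins")
})

test_that("compute_profile matches hand-derived cases", {
  rigid <- compute_profile(er_sample(rep(1.0, 4)))
  expect_equal(rigid$mer, 1)
  expect_equal(rigid$aer, 1)
  expect_equal(rigid$pct_udfc, 100)
  expect_equal(rigid$pct_ldfc + rigid$pct_mid + rigid$pct_hdfc, 0)

  p <- compute_profile(er_sample(c(1.05, 1.2, 1.5, 2.6)))
  expect_equal(p$mer, 1.35)  # midpoint of 1.2 and 1.5
  expect_equal(p$pct_udfc, 25)
  expect_equal(p$pct_ldfc, 25)
  expect_equal(p$pct_mid, 25)
  expect_equal(p$pct_hdfc, 25)

  expect_error(compute_profile(er_sample(numeric(0))), "empty input")
  expect_error(compute_profile(c(1.2, 0.5)), "invariant violation")
})

test_that("band boundaries are deterministic under both conventions", {
  v <- c(1.1, 1.3, 2.5)
  disj <- compute_profile(er_sample(v))
  # half-open bins: 1.1 counts as LDFC, 1.3 as mid, 2.5 as HDFC
  expect_equal(disj$pct_udfc, 0)
  expect_equal(disj$pct_ldfc, 100 / 3)
  expect_equal(disj$pct_mid, 100 / 3)
  expect_equal(disj$pct_hdfc, 100 / 3)
  cum <- compute_profile(er_sample(v),
                         threshold_scheme(boundary_convention = "cumulative"))
  # cumulative reading: ER <= 1.1 is UDFC, ER <= 1.3 is LDFC
  expect_equal(cum$pct_udfc, 100 / 3)
  expect_equal(cum$pct_ldfc, 200 / 3)
})

test_that("profiles agree exactly with the naive count/sort oracle", {
  set.seed(41)
  for (i in 1:300) {
    v <- random_er_sample(sample(1:500, 1))
    p <- compute_profile(er_sample(v))
    o <- naive_profile(v)
    expect_identical(p$mer, o$mer)
    # mean() accumulates in long double; sum()/n differs in the last ulp
    expect_equal(p$aer, o$aer, tolerance = 1e-12)
    expect_identical(unname(p$pct_udfc), unname(o$pct["udfc"]))
    expect_identical(unname(p$pct_ldfc), unname(o$pct["ldfc"]))
    expect_identical(unname(p$pct_mid), unname(o$pct["mid"]))
    expect_identical(unname(p$pct_hdfc), unname(o$pct["hdfc"]))
    expect_equal(p$pct_udfc + p$pct_ldfc + p$pct_mid + p$pct_hdfc, 100,
                 tolerance = 1e-12)
  }
})

test_that("profiles are invariant under permutation and monotone in the tails", {
  set.seed(42)
  v <- random_er_sample(200)
  p1 <- compute_profile(er_sample(v))
  p2 <- compute_profile(er_sample(sample(v)))
  expect_equal(p1[c("mer", "aer", "pct_udfc", "pct_ldfc", "pct_mid",
                    "pct_hdfc")],
               p2[c("mer", "aer", "pct_udfc", "pct_ldfc", "pct_mid",
                    "pct_hdfc")])
  # appending an extreme value never decreases its own band share
  for (i in 1:20) {
    v <- random_er_sample(sample(5:100, 1))
    base <- compute_profile(er_sample(v))
    hi <- compute_profile(er_sample(c(v, 1 + runif(1, 1.5, 4))))
    lo <- compute_profile(er_sample(c(v, 1 + runif(1, 0, 0.09))))
    expect_gte(hi$pct_hdfc, base$pct_hdfc)
    expect_gte(lo$pct_udfc, base$pct_udfc)
  }
})

test_that("distribution curves integrate to one and locate the median", {
  flat <- distribution_curve(er_sample(rep(1.0, 50)), bin_width = 0.05)
  expect_equal(sum(flat$density > 0), 1L)
  expect_equal(flat$cumulative[1L], 1)

  set.seed(7)
  v <- 1 + runif(10000)
  cv <- distribution_curve(er_sample(v), bin_width = 0.1)
  expect_equal(sum(cv$density), 1, tolerance = 1e-9)
  # closed-form uniform density: each 0.1-wide bin holds ~10% of cells
  expect_true(all(abs(cv$density[1:10] - 0.1) < 0.02))
  expect_equal(cv$cumulative[length(cv$cumulative)], 1, tolerance = 1e-12)
  expect_true(all(diff(cv$cumulative) >= -1e-15))

  p <- compute_profile(er_sample(v))
  expect_lt(abs(curve_median(distribution_curve(er_sample(v), 0.05)) - p$mer),
            0.05)
  expect_error(distribution_curve(er_sample(1.2), bin_width = 0),
               "bin_width")
})

test_that("aggregate_fields pools QC-passing cells and flags protocol gaps", {
  t1 <- data.frame(er = 1.2, qc_pass = TRUE)
  t2 <- data.frame(er = 1.4, qc_pass = TRUE)
  s <- suppressWarnings(aggregate_fields(list(t1, t2), "sp"))
  expect_equal(sort(s$values), c(1.2, 1.4))
  expect_equal(s$n_fields, 2L)

  allfail <- data.frame(er = c(1.2, 1.3), qc_pass = c(FALSE, FALSE))
  expect_error(aggregate_fields(list(allfail)), "empty input")

  # 25 fields x 400 passing cells meets the protocol: no warning
  fields <- replicate(25, data.frame(er = rep(1.5, 400), qc_pass = TRUE),
                      simplify = FALSE)
  expect_silent(s2 <- aggregate_fields(fields))
  expect_equal(length(s2$values), 10000L)
  expect_equal(s2$n_fields, 25L)

  expect_warning(expect_warning(aggregate_fields(list(t1, t2)), "cells"),
                 "fields")
  few <- replicate(3, data.frame(er = rep(1.5, 4000), qc_pass = TRUE),
                   simplify = FALSE)
  expect_warning(aggregate_fields(few), "fields")
})

test_that("profile JSON and cell-table CSV round-trip", {
  p <- compute_profile(er_sample(c(1.05, 1.2, 1.5, 2.6), "sp", 2L))
  f <- tempfile(fileext = ".json")
  write_profile_json(p, f)
  q <- read_profile_json(f)
  expect_equal(q$mer, p$mer)
  expect_equal(q$pct_hdfc, p$pct_hdfc)
  expect_equal(q$thresholds$udfc_upper, 1.1)

  tab <- data.frame(sample_id = "sp", field_id = "f1", cell_id = 1:2,
                    major_um = c(10, 13), minor_um = c(10, 5),
                    er = c(1, 2.6), qc_pass = c(TRUE, TRUE))
  csv <- tempfile(fileext = ".csv")
  write_cell_table(tab, csv)
  back <- read_cell_table(csv)
  expect_equal(back$er, tab$er)
  s <- read_er_sample(csv, quiet = TRUE)
  expect_equal(sort(s$values), c(1, 2.6))
})
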