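test_that("fixed lower bounds are twice the two-star minimum contribution", {
  expect_equal(ct_fixed_lower_bound("LP"), 4.2)
  expect_equal(ct_fixed_lower_bound("P"), 8.4)
  expect_equal(ct_fixed_lower_bound("B"), -8.4)
  expect_equal(ct_fixed_lower_bound("LB"), -4.2)
  # antisymmetry of the bound pairs
  expect_equal(ct_fixed_lower_bound("P"), -ct_fixed_lower_bound("B"))
  expect_equal(ct_fixed_lower_bound("LP"), -ct_fixed_lower_bound("LB"))
  expect_error(ct_fixed_lower_bound("US"), "no fixed lower bound")
})

test_that("prediction interval lands on the c-th and r-th order statistics", {
  expect_equal(ct_prediction_interval(1:199, alpha = 0.05),
               c(low = 5, high = 195))
  set.seed(3)
  v9 <- sort(rnorm(9))
  expect_equal(ct_prediction_interval(v9, alpha = 0.5),
               c(low = v9[2], high = v9[8]))
  expect_error(ct_prediction_interval(1:9, alpha = 0.01), "too small")
})

test_that("prediction interval matches the direct sorted-indexing oracle", {
  set.seed(23)
  for (rep in 1:250) {
    n <- sample(30:400, 1)
    alpha <- runif(1, 0.02, 0.5)
    if (trunc(alpha / 2 * (n + 1)) < 1) next
    v <- rnorm(n, sd = runif(1, 0.5, 10))
    expect_equal(unname(ct_prediction_interval(v, alpha)), oracle_pi(v, alpha))
  }
})

test_that("higher-confidence intervals nest lower-confidence ones", {
  set.seed(5)
  v <- rexp(500)
  prev <- ct_prediction_interval(v, alpha = 0.5)
  for (alpha in c(0.3, 0.2, 0.1, 0.05, 0.01)) {
    cur <- ct_prediction_interval(v, alpha)
    expect_lte(cur[["low"]], prev[["low"]])
    expect_gte(cur[["high"]], prev[["high"]])
    prev <- cur
  }
})

test_that("interval coverage of held-out draws matches its confidence", {
  set.seed(17)
  for (conf in c(0.8, 0.95)) {
    v <- rnorm(2000)
    pi <- ct_prediction_interval(v, alpha = 1 - conf)
    fresh <- rnorm(4000)
    cover <- mean(fresh >= pi[["low"]] & fresh <= pi[["high"]])
    se <- sqrt(conf * (1 - conf) / 4000)
    expect_lt(abs(cover - conf), 4 * se + 1 / 2001)
  }
})

test_that("calibration set applies the star, significance and count filters", {
  a2 <- mk_assertions(c("P", "P"), c("2017-01-01", "2017-06-01"))
  recs <- ct_records(
    ct_record("1", cvcs = "P", stars = 2, assertions = a2),
    ct_record("2", cvcs = "P", stars = 3, assertions = a2),   # not two-star
    ct_record("3", cvcs = "PLP", stars = 2, assertions = a2), # combined class
    ct_record("4", cvcs = "CI", stars = 2, assertions = a2),  # conflicting
    ct_record("5", cvcs = "P", stars = 2,                      # one valid
              assertions = mk_assertions("P", "2017-01-01")),
    ct_record("6", cvcs = "B", stars = 2,
              assertions = mk_assertions(c("B", "B"),
                                         c("2017-01-01", "2017-06-01")))
  )
  sets <- ct_calibration_set(recs, EVAL_DATE)
  expect_named(sets, c("B", "P"))
  expect_length(sets$P, 1)
  expect_length(sets$B, 1)
  expect_equal(sets$P, ct_score(a2, EVAL_DATE))
})

test_that("confidence selection aligns the zero-side endpoint to the bound", {
  # benign-class sample engineered so the 95% interval's upper endpoint is
  # the first (scanning downward) not to cross -8.4 toward zero
  values <- c(seq(-40, -8.4, length.out = 195), -8, -7, -6, -5)
  stats <- ct_select_confidence(values, "B")
  expect_equal(stats$confidence_pct, 95)
  expect_equal(stats$pi_high, -8.4)
  expect_equal(stats$n, 199)

  # pathogenic-side sample of the control-group size whose interval first
  # clears +4.2 at 96%
  lp_values <- c(seq(3, 4.1, length.out = 9), seq(4.2, 14.7, length.out = 493))
  lp_stats <- ct_select_confidence(lp_values, "LP")
  expect_equal(lp_stats$confidence_pct, 96)
  expect_equal(lp_stats$pi_low, 4.2)

  # the uncertain class takes the highest computable confidence
  us_stats <- ct_select_confidence(rnorm(10000, 0, 0.5), "US")
  expect_equal(us_stats$confidence_pct, 99.9)

  expect_error(ct_select_confidence(values, "B", grid = numeric()), "empty")
  expect_error(ct_select_confidence(c(-5, -4, -3), "B", grid = 0.9),
               "no confidence")
})

test_that("the default ranges reproduce the shipped interval boundaries", {
  rng <- ct_default_ranges()
  expect_equal(rng$label, c("B", "BLB", "LB", "US", "LP", "PLP", "P"))
  expect_equal(rng$lower, c(-Inf, -26.7, -8.4, -4.2, 4.2, 8.4, 14.7))
  expect_equal(rng$upper, c(-26.7, -8.4, -4.2, 4.2, 8.4, 14.7, Inf))
  # overlap categories closed, uncertain open, fixed bounds owned by LB/LP
  expect_equal(rng$lower_closed, c(FALSE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE))
  expect_equal(rng$upper_closed, c(FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE))
})

test_that("ranges partition the real line and saturate at the extremes", {
  rng <- ct_default_ranges()
  grid <- c(seq(-60, 60, by = 0.05), rng$lower[-1], rng$upper[-7], -100, 1e6)
  labels <- ct_assign_ctps(grid, n_valid = 2, ranges = rng)
  expect_false(anyNA(labels))  # every score maps to exactly one label
  expect_equal(ct_assign_ctps(-100, 2, rng), "B")
  expect_equal(ct_assign_ctps(1e6, 2, rng), "P")
  # interval order matches ordinal order
  expect_equal(order(rng$lower), seq_len(7))
})

test_that("contradictory class intervals are rejected", {
  bad <- ct_default_calibration()
  bad$pi_high[bad$significance == "LB"] <- 5  # LB interval reaches past LP's bound
  expect_error(ct_build_ranges(bad), "contiguous")
  expect_error(ct_build_ranges(bad[bad$significance != "LB", ]),
               "must cover")
})

test_that("default ranges classify the worked-example scores", {
  expect_equal(ct_assign_ctps(24.903, 6), "P")
  expect_equal(ct_assign_ctps(11.97, 5), "PLP")
  expect_equal(ct_assign_ctps(8.4, 2), "PLP")   # boundary owned by the overlap
  expect_equal(ct_assign_ctps(0, 2), "US")
  expect_true(is.na(ct_assign_ctps(0, 1)))
})

test_that("calibration tables round-trip through the tabular resource", {
  cal <- ct_default_calibration()
  path <- withr::local_tempfile(fileext = ".tsv")
  ct_write_calibration(cal, path)
  expect_equal(ct_read_calibration(path), cal)
})
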