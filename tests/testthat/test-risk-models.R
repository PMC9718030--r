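# GEMM hazard ratio, log-linear relative risk, attributable fraction.

test_that("packaged GEMM parameter table satisfies its invariants", {
  p <- gemm_params()
  expect_equal(p$age_group, age_band_labels(from = 25))
  expect_true(all(p$alpha > 0) && all(p$nu > 0) && all(p$theta_se >= 0))
  expect_error(gemm_params_for(p, "10-14"), "available")
})

test_that("GEMM hazard ratio matches the closed-form oracle", {
  p25 <- gemm_params_for(gemm_params(), "25-29")
  # at the curve's internal counterfactual (z = 0) the HR is exactly 1
  expect_identical(gemm_hazard_ratio(2.4, p25), 1)
  expect_identical(gemm_hazard_ratio(0, p25), 1)
  # theta forced to zero flattens the curve
  expect_identical(gemm_hazard_ratio(123, p25, theta_override = 0), 1)
  # frozen value from an independent stand-alone evaluation of
  # exp(theta*log(1+z/alpha)/(1+exp(-(z-mu)/nu))), z = 40.8 - 2.4
  expect_equal(gemm_hazard_ratio(40.8, p25), 1.3492298998219505,
               tolerance = 1e-12)
  expect_equal(gemm_hazard_ratio(5, p25), 1.0586889489022115,
               tolerance = 1e-12)
  expect_error(gemm_hazard_ratio(-1, p25), "-1")
})

test_that("GEMM hazard ratio is non-decreasing in concentration", {
  p <- gemm_params()
  conc <- seq(0, 150, by = 0.5)
  for (i in seq_len(nrow(p))) {
    hr <- gemm_hazard_ratio(conc, p[i, ])
    expect_true(all(diff(hr) >= 0), label = p$age_group[i])
    expect_true(all(hr >= 1))
  }
})

test_that("log-linear relative risk follows the power law", {
  expect_identical(loglinear_rr(20, 20), 1)
  expect_identical(loglinear_rr(10, 20), 1)  # excess floored at zero
  expect_equal(loglinear_rr(15, 5), 1.062)   # definitional anchor per 10
  # frozen value: 1.062^3.58 evaluated independently
  expect_equal(loglinear_rr(40.8, 5), 1.2402972190713537, tolerance = 1e-12)
  expect_error(loglinear_rr(-3, 5), ">= 0")
  expect_error(loglinear_risk(rr_per_10 = 0), "positive")
  expect_error(loglinear_risk(ci_low = 1.07), "ci_low")
})

test_that("log-linear relative risk is multiplicative over increments", {
  risk <- loglinear_risk()
  withr::with_seed(11, {
    for (i in 1:20) {
      d1 <- runif(1, 0, 30); d2 <- runif(1, 0, 30)
      expect_equal(loglinear_rr(5 + d1 + d2, 5, risk),
                   loglinear_rr(5 + d1, 5, risk) * loglinear_rr(5 + d2, 5, risk),
                   tolerance = 1e-12)
    }
  })
})

test_that("attributable fraction implements the counterfactual contrast", {
  expect_identical(attributable_fraction(1.5, 1.5), 0)
  expect_equal(attributable_fraction(2, 1), 0.5)
  expect_identical(attributable_fraction(1.1, 1.4), 0)  # clamped, no negative burden
  expect_error(attributable_fraction(0, 1), "positive")
  # composition of independently computed GEMM hazard ratios (25-29 row)
  expect_equal(attributable_fraction(1.3492298998219505, 1.0586889489022115),
               0.21533835779808896, tolerance = 1e-12)
  # af(h, 1) = 1 - 1/h; monotone in both arguments
  h <- seq(1.05, 3, by = 0.05)
  expect_equal(attributable_fraction(h, 1), 1 - 1 / h)
  expect_true(all(diff(attributable_fraction(h, 1.02)) > 0))
  h_below <- h[h < 2]  # below the clamp, AF is strictly decreasing in hr_cf
  expect_true(all(diff(attributable_fraction(2, h_below)) < 0))
  expect_true(all(attributable_fraction(2, h[h >= 2]) == 0))
})

test_that("GEMM uncertainty bounds are ordered and widen with theta_se", {
  p <- gemm_params()
  sc <- scenario("AQG", 5)
  bands <- tibble::tibble(age_group = p$age_group,
                          age_start = age_starts_of(p$age_group))
  af <- scenario_af(bands, 40.8, sc, gemm = p)
  expect_true(all(af$af_low <= af$af & af$af <= af$af_high))
  expect_true(all(af$af_low > 0))
  # Monte-Carlo alternative stays close to the closed-form bounds
  af_mc <- scenario_af(bands, 40.8, sc, gemm = p, n_draws = 4000, seed = 9)
  expect_equal(af_mc$af, af$af)
  expect_equal(af_mc$af_low, af$af_low, tolerance = 0.05)
  expect_equal(af_mc$af_high, af$af_high, tolerance = 0.05)
})

test_that("GEMM vs log-linear attributable fractions cross over with concentration", {
  # at the lower end of the study's concentration range the GEMM NCD+LRI
  # attributable fraction exceeds the Hoek log-linear one for every adult
  # age group; at the top of the range the ordering reverses for the
  # flattest (oldest-age) GEMM curves — the published per-100,000 rate
  # ordering between the two models comes from their different population
  # denominators, not from the fractions themselves
  p <- gemm_params()
  risk <- loglinear_risk()
  gemm_af <- function(conc) {
    vapply(seq_len(nrow(p)), function(i) {
      attributable_fraction(gemm_hazard_ratio(conc, p[i, ]),
                            gemm_hazard_ratio(5, p[i, ]))
    }, numeric(1))
  }
  ll_af <- function(conc) attributable_fraction(loglinear_rr(conc, 5, risk), 1)
  for (conc in c(15.8, 20.9, 27.1, 31.5)) {
    expect_true(all(gemm_af(conc) > ll_af(conc)), label = paste("conc", conc))
  }
  af40 <- gemm_af(40.8)
  expect_lt(af40[p$age_group == "85+"], ll_af(40.8))
  expect_gt(af40[p$age_group == "30-34"], ll_af(40.8))
})
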