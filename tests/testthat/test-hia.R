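# Attributable deaths, YLL, LLE, rates and aggregation.

make_unit_schedule <- function(seed = 1) random_schedule(seed)

test_that("attributable deaths: clamping, stub arithmetic, band coverage", {
  sched <- make_unit_schedule(21)
  sc <- scenario("AQG", 5)
  # exposure at the counterfactual: zero in every band
  imp0 <- attributable_deaths(sched, 5, sc)
  expect_true(all(imp0$ad == 0) && all(imp0$ad_low == 0) &&
                all(imp0$ad_high == 0))
  expect_true(attr(imp0, "below_counterfactual"))
  # stub risk model forcing AF = 0.2: AD = deaths * 0.2 exactly
  stub <- scenario("stub", 5, risk_model = function(exposure, cf, bands) 0.2)
  one <- mortality_schedule(age_band_labels(from = 25),
                            population = rep(10000, 13),
                            deaths = c(100, rep(0, 11), 10))
  imp <- attributable_deaths(one, 30, stub)
  expect_equal(imp$ad[1], 20)  # 10000 * 0.01 * 0.2
  expect_equal(imp$ad, imp$deaths * 0.2)
  # adult bands must be complete
  trunc <- mortality_schedule(age_band_labels(from = 40),
                              population = rep(1000, 10),
                              deaths = rep(5, 10))
  expect_error(attributable_deaths(trunc, 30, sc), "age 25")
  expect_error(attributable_deaths(sched, -2, sc), "-2")
})

test_that("attributable deaths are bounded by observed deaths with ordered intervals", {
  sc <- scenario("AQG", 5)
  for (seed in 22:26) {
    sched <- make_unit_schedule(seed)
    imp <- attributable_deaths(sched, 35, sc)
    expect_true(all(imp$ad >= 0 & imp$ad <= imp$deaths))
    expect_true(all(imp$ad_low <= imp$ad & imp$ad <= imp$ad_high))
  }
})

test_that("YLL is attributable deaths weighted by remaining life expectancy", {
  sched <- make_unit_schedule(23)
  lt <- build_life_table(sched)
  sc <- scenario("AQG", 5)
  imp <- years_of_life_lost(attributable_deaths(sched, 40.8, sc), lt)
  # independent one-line oracle: sum of per-band products
  expect_equal(sum(imp$yll),
               sum(imp$ad * remaining_life_expectancy(lt, imp$age_group)))
  expect_true(all(imp$yll_low <= imp$yll & imp$yll <= imp$yll_high))
  # zero AD propagates to zero YLL
  imp0 <- years_of_life_lost(attributable_deaths(sched, 5, sc), lt)
  expect_true(all(imp0$yll == 0))
  # single-band arithmetic
  fake <- imp[1, ]
  fake$ad <- 10
  expect_equal(years_of_life_lost(fake, lt)$yll,
               10 * remaining_life_expectancy(lt, fake$age_group))
  expect_error(years_of_life_lost(tibble::tibble(age_group = "99+", ad = 1,
                                                 ad_low = 1, ad_high = 1),
                                  lt), "valid labels")
})

test_that("loss of life expectancy: sign, zero case, birth requirement", {
  sched <- make_unit_schedule(24)
  expect_identical(loss_of_life_expectancy(sched, 0), 0)
  af <- stats::setNames(rep(0.15, 13), age_band_labels(from = 25))
  lle <- loss_of_life_expectancy(sched, af)
  expect_gt(lle, 0)
  adult_only <- mortality_schedule(age_band_labels(from = 25),
                                   population = rep(1000, 13),
                                   deaths = rep(5, 13))
  expect_error(loss_of_life_expectancy(adult_only, 0.1), "age 0")
  # cross-check against the cohort microsimulation under both rate sets
  pert <- perturb_schedule(sched, af)
  lle_sim <- sim_cohort(pert, 4e5, seed = 31)(0) -
    sim_cohort(sched, 4e5, seed = 32)(0)
  expect_equal(lle, lle_sim, tolerance = 0.05)
})

test_that("rates per 100,000 divide correctly and reject bad denominators", {
  expect_identical(rate_per_100k(0, 123), 0)
  expect_equal(rate_per_100k(50, 1e5), 50)
  expect_equal(rate_per_100k(5090, 8057053), 5090 / 8057053 * 1e5)
  expect_error(rate_per_100k(10, 0), "positive")
})

test_that("aggregation is additive and rates are recomputed, never averaged", {
  cfg <- synthetic_config(n_provinces = 3, districts_per_province = 2,
                          seed = 11)
  sim <- simulate_study_region(cfg)
  res <- run_hia(sim$demography, sim$districts, scenario("AQG", 5))
  # district -> province additivity
  for (p in res$province$unit_id) {
    members <- res$district[res$district$province_id == p, ]
    expect_equal(sum(members$ad), res$province$ad[res$province$unit_id == p])
    expect_equal(sum(members$yll),
                 res$province$yll[res$province$unit_id == p])
    expect_equal(sum(members$denominator_population),
                 res$province$denominator_population[res$province$unit_id == p])
  }
  # province -> region additivity
  expect_equal(sum(res$province$ad), res$region$ad)
  expect_equal(sum(res$province$yll_high), res$region$yll_high)
  # rates recomputed from summed counts and denominators
  expect_equal(res$region$ad_rate,
               res$region$ad / res$region$denominator_population * 1e5)
  # single-district group equals the district itself
  solo <- aggregate_impacts(
    res$age_impacts[res$age_impacts$unit_id == sim$districts$district_id[1], ],
    sim$demography,
    group_of = stats::setNames("solo", sim$districts$district_id[1]))
  d1 <- res$district[res$district$unit_id == sim$districts$district_id[1], ]
  expect_equal(solo$ad, d1$ad)
  expect_equal(solo$lle_years, d1$lle_years)
  # orphan district rejected
  expect_error(aggregate_impacts(res$age_impacts, sim$demography,
                                 group_of = c(nonexistent = "g")),
               "without a group")
})

test_that("scale invariance: doubling population and deaths doubles counts only", {
  cfg <- synthetic_config(n_provinces = 2, districts_per_province = 2,
                          seed = 12)
  sim <- simulate_study_region(cfg)
  res1 <- run_hia(sim$demography, sim$districts, scenario("AQG", 5))
  demo2 <- sim$demography
  demo2$population <- demo2$population * 2
  demo2$deaths <- demo2$deaths * 2
  res2 <- run_hia(demo2, sim$districts, scenario("AQG", 5))
  expect_equal(res2$region$ad, 2 * res1$region$ad)
  expect_equal(res2$region$yll, 2 * res1$region$yll)
  expect_equal(res2$region$ad_rate, res1$region$ad_rate)
  expect_equal(res2$region$yll_rate, res1$region$yll_rate)
  expect_equal(res2$region$lle_years, res1$region$lle_years)
})

test_that("null exposure surface yields exactly zero impacts everywhere", {
  cfg <- synthetic_config(n_provinces = 2, districts_per_province = 2,
                          seed = 13)
  demo <- generate_demography(cfg)
  units <- unique(demo[c("unit_id", "province_id")])
  flat <- tibble::tibble(unit_id = units$unit_id,
                         province_id = units$province_id, annual_mean = 5)
  res <- run_hia(demo, flat, scenario("AQG", 5))
  expect_true(all(res$district$ad == 0) && all(res$district$yll == 0))
  expect_true(all(res$district$lle_years == 0))
  expect_identical(res$region$ad, 0)
  expect_identical(res$region$lle_years, 0)
  expect_true(all(res$district$below_counterfactual))
})

test_that("counterfactual monotonicity: stricter scenarios attribute more", {
  cfg <- synthetic_config(n_provinces = 3, districts_per_province = 2,
                          seed = 14)
  sim <- simulate_study_region(cfg)
  r5 <- run_hia(sim$demography, sim$districts, scenario("AQG", 5))
  r15 <- run_hia(sim$demography, sim$districts, scenario("QCVN", 15))
  above <- r5$district$annual_mean > 15
  expect_true(all(r5$district$ad[above] > r15$district$ad[above]))
  expect_true(all(r5$district$ad >= r15$district$ad))
  expect_gt(r5$region$yll, r15$region$yll)
})

test_that("comparison table responds monotonically to theta", {
  cfg <- synthetic_config(n_provinces = 2, districts_per_province = 1,
                          seed = 15)
  sim <- simulate_study_region(cfg)
  base <- gemm_params()
  doubled <- base
  doubled$theta <- base$theta * 2
  c1 <- run_comparison(sim$demography, sim$districts, gemm = base)
  c2 <- run_comparison(sim$demography, sim$districts, gemm = doubled)
  expect_true(all(c2$rate_gemm > c1$rate_gemm))
  expect_equal(c2$rate_loglinear, c1$rate_loglinear)
  # exposure at the counterfactual: both columns zero
  units <- unique(sim$demography[c("unit_id", "province_id")])
  flat <- tibble::tibble(unit_id = units$unit_id,
                         province_id = units$province_id, annual_mean = 5)
  c0 <- run_comparison(sim$demography, flat)
  expect_true(all(c0$rate_gemm == 0) && all(c0$rate_loglinear == 0))
})

test_that("exposure summary reports extremes and 2 d.p. exceedance ratios", {
  tbl <- tibble::tibble(unit_id = c("a", "b"), annual_mean = c(15, 40.8))
  s <- exposure_summary(tbl, thresholds = c(QCVN = 15))
  expect_equal(s$min, 15)
  expect_equal(s$max, 40.8)
  expect_equal(s$ratios$ratio, c(1, 2.72))
  expect_error(exposure_summary(tbl, thresholds = c(bad = 0)), "positive")
  expect_error(exposure_summary(tbl[0, ]), "empty")
})
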