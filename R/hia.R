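# The counterfactual health-impact pipeline: per-district, per-age-group
# attributable deaths under a scenario, years of life lost, loss of life
# expectancy at birth, rates per 100,000, uncertainty bounds, and
# district -> province -> study-region aggregation.

#' Define a counterfactual scenario
#'
#' @param name Scenario label, e.g. `"AQG"` (WHO guideline, 5 ug/m3) or
#'   `"QCVN"` (proposed Vietnamese regulation, 15 ug/m3).
#' @param counterfactual Counterfactual annual-mean concentration, ug/m3;
#'   exposure at or below it contributes no attributable burden.
#' @param risk_model `"GEMM"`, `"log-linear"`, or a function
#'   `f(exposure, counterfactual, bands)` returning attributable fractions
#'   (a vector, or a 3-column low/point/high matrix) — useful for stubs.
#' @param rate_denominator Population base for rates per 100,000:
#'   `"total-population"` (all ages, the reporting convention used here) or
#'   `"adults-only"` (the exposed 25+ population).
#' @return A list of class `hia_scenario`.
#' @examples
#' scenario("AQG", 5)
#' scenario("QCVN", 15)
#' @export
scenario <- function(name, counterfactual,
                     risk_model = "GEMM",
                     rate_denominator = c("total-population", "adults-only")) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(counterfactual) || counterfactual < 0) {
    stop("counterfactual concentration must be >= 0 ug/m3", call. = FALSE)
  }
  if (!is.function(risk_model)) {
    risk_model <- match.arg(risk_model, c("GEMM", "log-linear"))
  }
  structure(list(name = name, counterfactual = counterfactual,
                 risk_model = risk_model,
                 rate_denominator = match.arg(rate_denominator)),
            class = "hia_scenario")
}

#' Attributable deaths by age group for one unit
#'
#' For each adult band, `AD = population * baseline rate * AF`, with the
#' attributable fraction from the scenario's risk model and the unit's
#' annual-mean exposure. Units at or below the counterfactual get zero in
#' every band. GEMM applies from age 25, the log-linear model from the age
#' its risk estimate covers (30 by default).
#'
#' @param schedule A [mortality_schedule()] covering at least the adult
#'   bands (25 up to the open interval).
#' @param exposure Annual-mean PM2.5 of the unit, ug/m3.
#' @param scenario A [scenario()].
#' @param gemm,loglinear Risk-model parameters (see [gemm_params()],
#'   [loglinear_risk()]).
#' @param ... Passed to [scenario_af()] (e.g. `n_draws`, `seed`).
#' @return A tibble with one row per adult band: `age_group`, `population`,
#'   `deaths`, `af_low`, `af`, `af_high`, `ad_low`, `ad`, `ad_high`, plus a
#'   `below_counterfactual` attribute.
#' @export
attributable_deaths <- function(schedule, exposure, scenario,
                                gemm = gemm_params(),
                                loglinear = loglinear_risk(), ...) {
  schedule <- as_mortality_schedule(schedule)
  if (length(exposure) != 1L || !is.finite(exposure) || exposure < 0) {
    stop("exposure must be a single finite concentration >= 0 ug/m3; got ",
         exposure, call. = FALSE)
  }
  min_age <- if (identical(scenario$risk_model, "log-linear")) {
    loglinear$min_age
  } else 25
  adult <- schedule[schedule$age_start >= min_age, ]
  if (nrow(adult) == 0 || adult$age_start[1] > min_age) {
    stop("schedule must cover adult bands from age ", min_age,
         " to the open interval", call. = FALSE)
  }
  afs <- scenario_af(adult, exposure, scenario, gemm = gemm,
                     loglinear = loglinear, ...)
  out <- tibble::tibble(age_group = adult$age_group,
                        population = adult$population,
                        deaths = adult$deaths,
                        af_low = afs$af_low, af = afs$af,
                        af_high = afs$af_high,
                        ad_low = adult$deaths * afs$af_low,
                        ad = adult$deaths * afs$af,
                        ad_high = adult$deaths * afs$af_high)
  attr(out, "below_counterfactual") <- exposure <= scenario$counterfactual
  out
}

#' Years of life lost from age-group impacts
#'
#' `YLL = AD * ex`, the attributable deaths of each band weighted by the
#' remaining life expectancy of that band in the unit's baseline life
#' table; interval bounds propagate from the AD bounds.
#'
#' @param impacts Output of [attributable_deaths()].
#' @param baseline_table The unit's [build_life_table()] result.
#' @return `impacts` with `ex`, `yll_low`, `yll`, `yll_high` appended.
#' @export
years_of_life_lost <- function(impacts, baseline_table) {
  ex <- remaining_life_expectancy(baseline_table, impacts$age_group)
  impacts$ex <- ex
  impacts$yll_low <- impacts$ad_low * ex
  impacts$yll <- impacts$ad * ex
  impacts$yll_high <- impacts$ad_high * ex
  impacts
}

#' Loss of life expectancy at birth
#'
#' Difference in life-table `e0` between the counterfactual schedule (the
#' attributable share of mortality removed via [perturb_schedule()]) and
#' the observed schedule. Computed in days and returned in years
#' (divided by 365.25).
#'
#' @param schedule A full [mortality_schedule()] starting at age 0.
#' @param af Attributable fractions as accepted by [perturb_schedule()]
#'   (adult bands; others zero).
#' @param ... Passed to [build_life_table()] (e.g. `nax`).
#' @return Years of life expectancy at birth lost to the exposure
#'   (`>= 0`; 0 when `af` is all zero).
#' @export
loss_of_life_expectancy <- function(schedule, af, ...) {
  schedule <- as_mortality_schedule(schedule)
  if (schedule$age_start[1] != 0) {
    stop("loss of life expectancy is evaluated at birth: the schedule must ",
         "start at age 0 (found ", schedule$age_group[1], ")", call. = FALSE)
  }
  e0_obs <- build_life_table(schedule, ...)$ex[1]
  e0_cf <- build_life_table(perturb_schedule(schedule, af), ...)$ex[1]
  lle_days <- (e0_cf - e0_obs) * 365.25
  lle_days / 365.25
}

#' Rate per 100,000 population
#'
#' @param count Annual events (deaths, person-years, ...); vectorised.
#' @param denominator Population base, `> 0`.
#' @return `count / denominator * 100000`.
#' @export
rate_per_100k <- function(count, denominator) {
  if (any(denominator <= 0)) {
    stop("rate denominator must be positive", call. = FALSE)
  }
  count / denominator * 1e5
}
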