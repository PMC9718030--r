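# Run-level orchestration: the full scenario pipeline over many districts,
# aggregation to provinces and the study region, the GEMM vs log-linear
# comparison table, and exposure summaries.

# Split a long demography table into one mortality schedule per unit.
# `demography` columns: unit_id, age_group, population, deaths
# (province_id carried along when present).
split_schedules <- function(demography) {
  units <- unique(demography$unit_id)
  stats::setNames(lapply(units, function(u) {
    d <- demography[demography$unit_id == u, ]
    mortality_schedule(d$age_group, d$population, d$deaths)
  }), units)
}

# e0 gain when per-band attributable deaths are removed from a schedule;
# identical to perturbing rates by 1 - AF, but phrased in deaths so that
# pooled (multi-district) schedules follow the same code path.
lle_from_removed_deaths <- function(age_group, population, deaths, removed,
                                    nax = NULL) {
  base <- mortality_schedule(age_group, population, deaths)
  cf <- mortality_schedule(age_group, population, pmax(deaths - removed, 0))
  e0 <- function(s) build_life_table(s, nax = nax)$ex[1]
  (e0(cf) * 365.25 - e0(base) * 365.25) / 365.25
}

denominator_for <- function(schedule, rate_denominator) {
  if (identical(rate_denominator, "adults-only")) {
    sum(schedule$population[schedule$age_start >= 25])
  } else {
    sum(schedule$population)
  }
}

summarise_counts <- function(detail_rows, denominator, lle) {
  tibble::tibble(
    denominator_population = denominator,
    ad_low = sum(detail_rows$ad_low), ad = sum(detail_rows$ad),
    ad_high = sum(detail_rows$ad_high),
    ad_rate_low = rate_per_100k(sum(detail_rows$ad_low), denominator),
    ad_rate = rate_per_100k(sum(detail_rows$ad), denominator),
    ad_rate_high = rate_per_100k(sum(detail_rows$ad_high), denominator),
    yll_low = sum(detail_rows$yll_low), yll = sum(detail_rows$yll),
    yll_high = sum(detail_rows$yll_high),
    yll_rate_low = rate_per_100k(sum(detail_rows$yll_low), denominator),
    yll_rate = rate_per_100k(sum(detail_rows$yll), denominator),
    yll_rate_high = rate_per_100k(sum(detail_rows$yll_high), denominator),
    lle_low = lle[1], lle_years = lle[2], lle_high = lle[3])
}

#' Run the health-impact pipeline for one scenario
#'
#' For every district: builds the baseline life table, evaluates the
#' scenario's risk model at the district's annual-mean PM2.5, computes
#' attributable deaths and years of life lost per 5-year adult band with
#' 95% interval bounds, and the loss of life expectancy at birth. District
#' results are aggregated to provinces and the whole study region: counts
#' sum, rates are recomputed from summed counts and summed denominators,
#' and aggregate LLE is recomputed from the pooled (summed) mortality
#' schedules rather than averaged.
#'
#' @param demography Long tibble: `unit_id`, `province_id`, `age_group`,
#'   `population`, `deaths`; full age range from 0 per unit.
#' @param exposure District exposure tibble: `unit_id`, `province_id`,
#'   `annual_mean`.
#' @param scenario A [scenario()].
#' @param gemm,loglinear Risk-model parameters.
#' @param lle_aggregation `"pooled"` (recompute from summed schedules, the
#'   default) or `"population-weighted"` (average district LLE weighted by
#'   district population).
#' @param nax Optional life-table `nax` override (see [build_life_table()]).
#' @param ... Passed to [scenario_af()] (e.g. `n_draws`, `seed`).
#' @return A list of class `hia_result`: `$district`, `$province`,
#'   `$region` summary tibbles, `$age_impacts` (band-level detail) and
#'   `$scenario`.
#' @examples
#' sim <- simulate_study_region(synthetic_config(n_provinces = 2,
#'                                               districts_per_province = 2,
#'                                               seed = 7))
#' res <- run_hia(sim$demography, sim$districts, scenario("AQG", 5))
#' res$province
#' @export
run_hia <- function(demography, exposure, scenario,
                    gemm = gemm_params(), loglinear = loglinear_risk(),
                    lle_aggregation = c("pooled", "population-weighted"),
                    nax = NULL, ...) {
  lle_aggregation <- match.arg(lle_aggregation)
  if ("district_id" %in% names(exposure) && !"unit_id" %in% names(exposure)) {
    names(exposure)[names(exposure) == "district_id"] <- "unit_id"
  }
  if (!all(c("unit_id", "annual_mean") %in% names(exposure))) {
    stop("exposure table needs columns unit_id and annual_mean", call. = FALSE)
  }
  missing_units <- setdiff(exposure$unit_id, demography$unit_id)
  if (length(missing_units) > 0) {
    stop("no demography for exposure unit(s): ",
         paste(utils::head(missing_units, 5), collapse = ", "), call. = FALSE)
  }
  if (!"province_id" %in% names(exposure)) {
    stop("exposure table needs a province_id column mapping each district ",
         "to its province", call. = FALSE)
  }
  schedules <- split_schedules(demography)

  detail <- vector("list", nrow(exposure))
  district <- vector("list", nrow(exposure))
  for (i in seq_len(nrow(exposure))) {
    uid <- exposure$unit_id[i]
    conc <- exposure$annual_mean[i]
    sched <- schedules[[uid]]
    lt <- build_life_table(sched, nax = nax)
    imp <- attributable_deaths(sched, conc, scenario, gemm = gemm,
                               loglinear = loglinear, ...)
    imp <- years_of_life_lost(imp, lt)
    below <- attr(imp, "below_counterfactual")
    # per-band removed deaths aligned to the full schedule
    removed <- function(col) {
      r <- stats::setNames(numeric(nrow(sched)), sched$age_group)
      r[imp$age_group] <- imp[[col]]
      r
    }
    lle <- c(
      lle_from_removed_deaths(sched$age_group, sched$population,
                              sched$deaths, removed("ad_low"), nax = nax),
      lle_from_removed_deaths(sched$age_group, sched$population,
                              sched$deaths, removed("ad"), nax = nax),
      lle_from_removed_deaths(sched$age_group, sched$population,
                              sched$deaths, removed("ad_high"), nax = nax))
    denom <- denominator_for(sched, scenario$rate_denominator)
    row <- summarise_counts(imp, denom, lle)
    row <- tibble::add_column(row,
                              unit_id = uid,
                              province_id = exposure$province_id[i],
                              annual_mean = conc,
                              below_counterfactual = below,
                              .before = 1)
    district[[i]] <- row
    imp <- tibble::add_column(imp, unit_id = uid,
                              province_id = exposure$province_id[i],
                              .before = 1)
    detail[[i]] <- imp
  }
  district <- dplyr::bind_rows(district)
  detail <- dplyr::bind_rows(detail)

  province <- aggregate_impacts(detail, demography,
                                group_of = stats::setNames(
                                  exposure$province_id, exposure$unit_id),
                                rate_denominator = scenario$rate_denominator,
                                lle_aggregation = lle_aggregation,
                                district_summary = district, nax = nax)
  region <- aggregate_impacts(detail, demography,
                              group_of = stats::setNames(
                                rep("study_region", nrow(exposure)),
                                exposure$unit_id),
                              rate_denominator = scenario$rate_denominator,
                              lle_aggregation = lle_aggregation,
                              district_summary = district, nax = nax)
  structure(list(district = district, province = province, region = region,
                 age_impacts = detail, scenario = scenario),
            class = "hia_result")
}

#' Aggregate district impacts to a coarser level
#'
#' Counts sum; rates are recomputed from summed counts and summed
#' denominators (never averaged); LLE is recomputed from the pooled
#' mortality schedule of each group (or population-weighted on request).
#'
#' @param detail Band-level impacts (`$age_impacts` of [run_hia()]).
#' @param demography The demography table passed to [run_hia()].
#' @param group_of Named character vector mapping every `unit_id` to its
#'   group (e.g. province). Units without a group are an error.
#' @param rate_denominator As in [scenario()].
#' @param lle_aggregation `"pooled"` or `"population-weighted"`.
#' @param district_summary District summary tibble (required for the
#'   population-weighted LLE variant).
#' @param nax Optional life-table `nax` override.
#' @return One summary row per group.
#' @export
aggregate_impacts <- function(detail, demography, group_of,
                              rate_denominator = "total-population",
                              lle_aggregation = "pooled",
                              district_summary = NULL, nax = NULL) {
  units <- unique(detail$unit_id)
  orphan <- setdiff(units, names(group_of))
  if (length(orphan) > 0) {
    stop("district(s) without a group mapping: ",
         paste(utils::head(orphan, 5), collapse = ", "), call. = FALSE)
  }
  groups <- unique(unname(group_of[units]))
  out <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    members <- units[group_of[units] == groups[g]]
    rows <- detail[detail$unit_id %in% members, ]
    demo <- demography[demography$unit_id %in% members, ]
    pooled <- dplyr::summarise(
      dplyr::group_by(demo, .data$age_group),
      population = sum(.data$population), deaths = sum(.data$deaths),
      .groups = "drop")
    bands <- parse_age_groups(pooled$age_group)
    pooled <- pooled[order(bands$age_start), ]
    sched <- mortality_schedule(pooled$age_group, pooled$population,
                                pooled$deaths)
    denom <- denominator_for(sched, rate_denominator)
    if (identical(lle_aggregation, "population-weighted")) {
      if (is.null(district_summary)) {
        stop("population-weighted LLE aggregation needs the district summary",
             call. = FALSE)
      }
      ds <- district_summary[district_summary$unit_id %in% members, ]
      w <- ds$denominator_population / sum(ds$denominator_population)
      lle <- c(sum(w * ds$lle_low), sum(w * ds$lle_years),
               sum(w * ds$lle_high))
    } else {
      removed <- function(col) {
        agg <- tapply(rows[[col]], rows$age_group, sum)
        r <- stats::setNames(numeric(nrow(sched)), sched$age_group)
        r[names(agg)] <- agg
        r
      }
      lle <- c(
        lle_from_removed_deaths(sched$age_group, sched$population,
                                sched$deaths, removed("ad_low"), nax = nax),
        lle_from_removed_deaths(sched$age_group, sched$population,
                                sched$deaths, removed("ad"), nax = nax),
        lle_from_removed_deaths(sched$age_group, sched$population,
                                sched$deaths, removed("ad_high"), nax = nax))
    }
    row <- summarise_counts(rows, denom, lle)
    out[[g]] <- tibble::add_column(row, unit_id = groups[g], .before = 1)
  }
  dplyr::bind_rows(out)
}

#' GEMM vs log-linear attributable-death rates by province
#'
#' Reproduces the software comparison: attributable deaths are computed
#' per district under both risk models with the same counterfactual, then
#' aggregated to provinces. The GEMM column is expressed per the
#' configured denominator (total population by default, the convention of
#' the scenario tables); the log-linear (AirQ+-style) column is expressed
#' per its own exposed population — adults 30 and over, the population the
#' log-linear risk estimate applies to — which is how AirQ+ reports rates.
#' The two columns therefore have different population bases, recorded in
#' the `denominators` attribute.
#'
#' @inheritParams run_hia
#' @param counterfactual Counterfactual concentration, ug/m3 (default 5).
#' @param rate_denominator Denominator for the GEMM column.
#' @return One row per province: populations, AD and rate triplets under
#'   both models.
#' @export
run_comparison <- function(demography, exposure, counterfactual = 5,
                           gemm = gemm_params(), loglinear = loglinear_risk(),
                           rate_denominator = "total-population", ...) {
  sc_g <- scenario("GEMM", counterfactual, risk_model = "GEMM",
                   rate_denominator = rate_denominator)
  sc_l <- scenario("log-linear", counterfactual, risk_model = "log-linear")
  if ("district_id" %in% names(exposure) && !"unit_id" %in% names(exposure)) {
    names(exposure)[names(exposure) == "district_id"] <- "unit_id"
  }
  schedules <- split_schedules(demography)
  provinces <- unique(exposure$province_id)
  out <- vector("list", length(provinces))
  for (p in seq_along(provinces)) {
    idx <- which(exposure$province_id == provinces[p])
    acc <- list(g = c(0, 0, 0), l = c(0, 0, 0),
                pop_total = 0, pop_25 = 0, pop_30 = 0)
    for (i in idx) {
      sched <- schedules[[exposure$unit_id[i]]]
      conc <- exposure$annual_mean[i]
      ig <- attributable_deaths(sched, conc, sc_g, gemm = gemm,
                                loglinear = loglinear, ...)
      il <- attributable_deaths(sched, conc, sc_l, gemm = gemm,
                                loglinear = loglinear, ...)
      acc$g <- acc$g + c(sum(ig$ad_low), sum(ig$ad), sum(ig$ad_high))
      acc$l <- acc$l + c(sum(il$ad_low), sum(il$ad), sum(il$ad_high))
      acc$pop_total <- acc$pop_total + sum(sched$population)
      acc$pop_25 <- acc$pop_25 + sum(sched$population[sched$age_start >= 25])
      acc$pop_30 <- acc$pop_30 + sum(sched$population[sched$age_start >= 30])
    }
    denom_g <- if (identical(rate_denominator, "adults-only")) {
      acc$pop_25
    } else acc$pop_total
    out[[p]] <- tibble::tibble(
      province_id = provinces[p],
      population_total = acc$pop_total,
      population_25plus = acc$pop_25,
      population_30plus = acc$pop_30,
      ad_gemm_low = acc$g[1], ad_gemm = acc$g[2], ad_gemm_high = acc$g[3],
      rate_gemm_low = rate_per_100k(acc$g[1], denom_g),
      rate_gemm = rate_per_100k(acc$g[2], denom_g),
      rate_gemm_high = rate_per_100k(acc$g[3], denom_g),
      ad_loglinear_low = acc$l[1], ad_loglinear = acc$l[2],
      ad_loglinear_high = acc$l[3],
      rate_loglinear_low = rate_per_100k(acc$l[1], acc$pop_30),
      rate_loglinear = rate_per_100k(acc$l[2], acc$pop_30),
      rate_loglinear_high = rate_per_100k(acc$l[3], acc$pop_30))
  }
  out <- dplyr::bind_rows(out)
  attr(out, "denominators") <- c(
    gemm = rate_denominator,
    loglinear = "exposed population 30+ (AirQ+ reporting convention)")
  out
}

#' Summarise an exposure table against thresholds
#'
#' Minimum and maximum annual-mean concentration over units, and each
#' unit's exceedance ratio (concentration / threshold, reported to 2
#' decimal places) for every threshold.
#'
#' @param exposure Tibble with a unit column (`unit_id`, `district_id` or
#'   `province`) and a concentration column (`annual_mean` or
#'   `pm25_ugm3`).
#' @param thresholds Named positive concentrations, ug/m3.
#' @return A list with `min`, `max`, and a `ratios` tibble (`unit`,
#'   `threshold_name`, `threshold`, `ratio`).
#' @examples
#' exposure_summary(vietnam_provinces())
#' @export
exposure_summary <- function(exposure, thresholds = c(AQG = 5, QCVN = 15)) {
  if (nrow(exposure) == 0) stop("exposure table is empty", call. = FALSE)
  if (any(thresholds <= 0)) {
    stop("thresholds must be positive concentrations", call. = FALSE)
  }
  conc_col <- intersect(c("annual_mean", "pm25_ugm3"), names(exposure))[1]
  unit_col <- intersect(c("unit_id", "district_id", "province"),
                        names(exposure))[1]
  if (is.na(conc_col) || is.na(unit_col)) {
    stop("exposure table needs a unit column and a concentration column",
         call. = FALSE)
  }
  conc <- exposure[[conc_col]]
  if (is.null(names(thresholds))) {
    names(thresholds) <- paste0("threshold_", seq_along(thresholds))
  }
  ratios <- dplyr::bind_rows(lapply(names(thresholds), function(nm) {
    tibble::tibble(unit = exposure[[unit_col]],
                   threshold_name = nm,
                   threshold = thresholds[[nm]],
                   ratio = round(conc / thresholds[[nm]], 2))
  }))
  list(min = min(conc), max = max(conc), ratios = ratios)
}
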