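# Synthetic demography and exposure generator. Emulates the statistical
# structure of the study inputs — 11 provinces, annual PM2.5 means spanning
# 15.8-40.8 ug/m3, adult (25+) populations 0.29-5.8 M, crude 25+ death
# rates 4.1-8.3 per 1,000 — with Gompertz-Makeham mortality schedules and
# a quasi-stable age pyramid standing in for the unpublished age detail.

#' Configuration for the synthetic study region
#'
#' Defaults reproduce the study conditions: 11 provinces whose annual-mean
#' PM2.5 spans 15.8-40.8 ug/m3 and whose crude 25+ death rates fall in
#' 4.1-8.3 per 1,000, with adult populations drawn between 0.29 and 5.8
#' million. Age structure comes from a quasi-stable pyramid (growth rate
#' `pyramid_growth`) over a Gompertz-Makeham hazard
#' `mu(x) = gompertz_a * exp(gompertz_b * x) + makeham_c`, rescaled per
#' district to hit its target crude rate.
#'
#' @param n_provinces Number of provinces.
#' @param districts_per_province Districts per province.
#' @param crude_rate_range Target crude 25+ death-rate range, per 1,000.
#' @param exposure_range Province annual-mean PM2.5 range, ug/m3.
#' @param adult_pop_range Province 25+ population range, persons.
#' @param gompertz_a Baseline hazard level at age 0, per year.
#' @param gompertz_b Age slope of the log hazard, per year of age.
#' @param makeham_c Age-independent hazard, per year.
#' @param pyramid_growth Stable-population growth rate shaping the age
#'   pyramid, per year.
#' @param open_age Start of the open terminal band, years.
#' @param district_jitter Half-width of the spread of district means
#'   around their province mean, ug/m3.
#' @param cells_per_district Grid cells per district (rounded up to a
#'   square grid).
#' @param cell_sd Standard deviation of cell-level noise before spatial
#'   smoothing, ug/m3.
#' @param spatial_corr_length Exponential-kernel correlation length of the
#'   cell field, in cells (`> 0`).
#' @param poisson_deaths Draw death counts as Poisson instead of rounded
#'   expectations.
#' @param seed Seed; a fixed seed makes all generator output
#'   byte-identical.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_provinces = 11, districts_per_province = 3,
                             crude_rate_range = c(4.1, 8.3),
                             exposure_range = c(15.8, 40.8),
                             adult_pop_range = c(0.29e6, 5.8e6),
                             gompertz_a = 3.5e-5, gompertz_b = 0.095,
                             makeham_c = 6e-4, pyramid_growth = 0.015,
                             open_age = 85,
                             district_jitter = 1.5, cells_per_district = 36,
                             cell_sd = 2, spatial_corr_length = 2,
                             poisson_deaths = FALSE, seed = 1L) {
  stopifnot(n_provinces >= 1, districts_per_province >= 1)
  check_range <- function(rng, label) {
    if (length(rng) != 2 || any(rng <= 0) || rng[1] > rng[2]) {
      stop(label, " must be a positive non-empty range (low <= high)",
           call. = FALSE)
    }
  }
  check_range(crude_rate_range, "crude_rate_range")
  check_range(exposure_range, "exposure_range")
  check_range(adult_pop_range, "adult_pop_range")
  if (spatial_corr_length <= 0) {
    stop("spatial_corr_length must be positive", call. = FALSE)
  }
  stopifnot(gompertz_a > 0, gompertz_b >= 0, makeham_c >= 0)
  cfg <- as.list(environment())
  cfg$check_range <- NULL
  structure(cfg, class = "synthetic_config")
}

# Gompertz-Makeham hazard at exact age x.
gm_hazard <- function(x, config) {
  config$gompertz_a * exp(config$gompertz_b * x) + config$makeham_c
}

# Band-level baseline rates and quasi-stable pyramid weights for the
# configured band structure. The pyramid weights are exp(-r * x) times the
# baseline survivorship, the stable-population form.
synthetic_structure <- function(config) {
  bands <- parse_age_groups(age_band_labels(open_age = config$open_age))
  mid <- band_mid_age(bands)
  rate <- gm_hazard(mid, config)
  haz_start <- gm_hazard(bands$age_start, config)
  surv <- exp(-cumsum(c(0, 5 * haz_start[-nrow(bands)])))
  w <- exp(-config$pyramid_growth * mid) * surv
  list(bands = bands, rate = rate, pyramid = w / sum(w))
}

# Achievable crude 25+ rate range given that the rescaled hazard must keep
# the terminal-band rate below `max_rate`.
achievable_crude_range <- function(config, max_rate = 0.9) {
  s <- synthetic_structure(config)
  adult <- s$bands$age_start >= 25
  crude1 <- sum(s$pyramid[adult] * s$rate[adult]) / sum(s$pyramid[adult])
  k_max <- max_rate / max(s$rate)
  c(0, crude1 * k_max) * 1000
}

#' Generate synthetic district demography
#'
#' Populations follow the configured quasi-stable pyramid; death rates are
#' the Gompertz-Makeham hazard rescaled per district so the crude 25+
#' death rate hits its target; deaths are rounded expectations (or Poisson
#' draws when configured). Province targets are drawn from the configured
#' ranges, or taken from `provinces` when supplied.
#'
#' @param config A [synthetic_config()].
#' @param provinces Optional tibble pinning province targets: columns
#'   `province` (or `province_id`), `population_25plus` and
#'   `death_rate_25plus_per_1000` — e.g. [vietnam_provinces()].
#' @return A tibble `unit_id`, `province_id`, `age_group`, `population`,
#'   `deaths`, full age range 0 to the open band per district.
#' @examples
#' demo <- generate_demography(synthetic_config(n_provinces = 2, seed = 1))
#' @export
generate_demography <- function(config = synthetic_config(),
                                provinces = NULL) {
  s <- synthetic_structure(config)
  adult <- s$bands$age_start >= 25
  crude1 <- sum(s$pyramid[adult] * s$rate[adult]) / sum(s$pyramid[adult])
  max_rate <- 0.9
  withr::with_seed(config$seed, {
    if (is.null(provinces)) {
      prov_ids <- sprintf("P%02d", seq_len(config$n_provinces))
      # log-uniform adult populations, uniform crude-rate targets
      pop25 <- exp(stats::runif(config$n_provinces,
                                log(config$adult_pop_range[1]),
                                log(config$adult_pop_range[2])))
      target <- stats::runif(config$n_provinces,
                             config$crude_rate_range[1],
                             config$crude_rate_range[2]) / 1000
    } else {
      id_col <- intersect(c("province_id", "province"), names(provinces))[1]
      prov_ids <- provinces[[id_col]]
      pop25 <- provinces$population_25plus
      target <- provinces$death_rate_25plus_per_1000 / 1000
    }
    out <- vector("list", length(prov_ids))
    for (p in seq_along(prov_ids)) {
      nd <- config$districts_per_province
      shares <- stats::runif(nd, 0.5, 1.5)
      shares <- shares / sum(shares)
      rows <- vector("list", nd)
      for (d in seq_len(nd)) {
        k <- target[p] / crude1
        if (k * max(s$rate) > max_rate) {
          rng <- achievable_crude_range(config, max_rate)
          stop(sprintf(paste0(
            "crude 25+ rate target %.1f per 1,000 is unattainable with ",
            "these hazard parameters; achievable range is %.1f-%.1f per ",
            "1,000"), target[p] * 1000, rng[1], rng[2]), call. = FALSE)
        }
        pop_total <- shares[d] * pop25[p] / sum(s$pyramid[adult])
        population <- pmax(round(pop_total * s$pyramid), 1)
        rate <- k * s$rate
        deaths <- if (config$poisson_deaths) {
          stats::rpois(length(rate), population * rate)
        } else {
          round(population * rate)
        }
        deaths[length(deaths)] <- max(deaths[length(deaths)], 1)
        rows[[d]] <- tibble::tibble(
          unit_id = sprintf("%s_D%02d", prov_ids[p], d),
          province_id = prov_ids[p],
          age_group = s$bands$age_group,
          population = as.numeric(population),
          deaths = as.numeric(deaths))
      }
      out[[p]] <- dplyr::bind_rows(rows)
    }
    dplyr::bind_rows(out)
  })
}

# Separable exponential-kernel smoothing of a square noise matrix.
smooth_field <- function(mat, corr_length) {
  g <- nrow(mat)
  k <- exp(-abs(outer(seq_len(g), seq_len(g), "-")) / corr_length)
  k <- k / rowSums(k)
  k %*% mat %*% t(k)
}

#' Generate a synthetic gridded exposure surface
#'
#' Each district gets a square grid of cells whose concentrations are the
#' district mean plus spatially autocorrelated noise (separable
#' exponential-kernel smoothing of seeded white noise, centred so the
#' district mean is exact). Province means are spread evenly across the
#' configured exposure range (or pinned by `provinces$pm25_ugm3`), and
#' district means sit within `district_jitter` of their province mean.
#'
#' @param config A [synthetic_config()].
#' @param provinces Optional tibble with `province` (or `province_id`) and
#'   `pm25_ugm3` pinning province means — e.g. [vietnam_provinces()].
#' @return A tibble of cells: `cell_id`, `lon`, `lat`, `district_id`,
#'   `province_id`, `concentration`, `weight`.
#' @export
generate_exposure <- function(config = synthetic_config(), provinces = NULL) {
  if (is.null(provinces)) {
    prov_ids <- sprintf("P%02d", seq_len(config$n_provinces))
    targets <- if (config$n_provinces == 1) {
      mean(config$exposure_range)
    } else {
      seq(config$exposure_range[2], config$exposure_range[1],
          length.out = config$n_provinces)
    }
  } else {
    id_col <- intersect(c("province_id", "province"), names(provinces))[1]
    prov_ids <- provinces[[id_col]]
    targets <- provinces$pm25_ugm3
  }
  nd <- config$districts_per_province
  g <- ceiling(sqrt(config$cells_per_district))
  offsets <- if (nd == 1) 0 else {
    o <- seq(-config$district_jitter, config$district_jitter, length.out = nd)
    o - mean(o)
  }
  withr::with_seed(config$seed + 1L, {
    out <- vector("list", length(prov_ids) * nd)
    idx <- 0L
    for (p in seq_along(prov_ids)) {
      for (d in seq_len(nd)) {
        idx <- idx + 1L
        noise <- matrix(stats::rnorm(g * g, 0, config$cell_sd), g, g)
        field <- smooth_field(noise, config$spatial_corr_length)
        field <- field - mean(field)
        target <- targets[p] + offsets[d]
        conc <- pmax(field + target, 0)
        did <- sprintf("%s_D%02d", prov_ids[p], d)
        out[[idx]] <- tibble::tibble(
          cell_id = sprintf("%s_C%03d", did, seq_len(g * g)),
          lon = rep(seq_len(g), each = g) * 0.03 + p,
          lat = rep(seq_len(g), times = g) * 0.03 + d,
          district_id = did,
          province_id = prov_ids[p],
          concentration = as.vector(conc),
          weight = 1)
      }
    }
    dplyr::bind_rows(out)
  })
}

#' Simulate the full synthetic study region
#'
#' Convenience wrapper generating matched demography and exposure inputs
#' from one configuration (district identifiers agree across the two).
#'
#' @param config A [synthetic_config()].
#' @param provinces Optional province-target tibble (see
#'   [generate_demography()] and [generate_exposure()]); pass
#'   [vietnam_provinces()] to calibrate the region to the study's province
#'   table.
#' @return A list: `demography`, `cells`, and `districts` (the cell table
#'   aggregated with [aggregate_to_district()]).
#' @export
simulate_study_region <- function(config = synthetic_config(),
                                  provinces = NULL) {
  demography <- generate_demography(config, provinces = provinces)
  cells <- generate_exposure(config, provinces = provinces)
  districts <- aggregate_to_district(cells,
                                     districts = unique(demography$unit_id))
  list(demography = demography, cells = cells, districts = districts)
}
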