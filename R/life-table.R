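# Abridged (5-year) period life tables: the survivorship machinery behind
# years-of-life-lost weights and the loss-of-life-expectancy difference.

#' Build a mortality schedule
#'
#' A mortality schedule is an age-grouped table of population and
#' (non-injury) deaths with the derived central death rate. Bands must be
#' contiguous, ascending and end in exactly one open interval.
#'
#' @param age_group Band labels, e.g. from [age_band_labels()].
#' @param population Persons per band (all `> 0`).
#' @param deaths Deaths per year per band (all `>= 0`; terminal band `> 0`).
#' @return A tibble of class `mortality_schedule` with columns `age_group`,
#'   `age_start`, `width`, `population`, `deaths`, `rate`.
#' @examples
#' sched <- mortality_schedule(age_band_labels(),
#'                             population = rep(1000, 18),
#'                             deaths = c(rep(2, 17), 100))
#' @export
mortality_schedule <- function(age_group, population, deaths) {
  bands <- parse_age_groups(age_group)
  assert_contiguous_bands(bands, what = "schedule age bands")
  if (length(population) != nrow(bands) || length(deaths) != nrow(bands)) {
    stop("population and deaths must have one value per age band", call. = FALSE)
  }
  if (any(!is.finite(population)) || any(population <= 0)) {
    stop("population must be positive in every band; offending band(s): ",
         paste(age_group[!is.finite(population) | population <= 0],
               collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(deaths)) || any(deaths < 0)) {
    stop("deaths must be >= 0 in every band; offending band(s): ",
         paste(age_group[!is.finite(deaths) | deaths < 0], collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(bands)
  if (deaths[n] <= 0) {
    stop("terminal band \"", age_group[n], "\" must have a positive death ",
         "rate (open-interval person-years are deaths/rate)", call. = FALSE)
  }
  out <- tibble::tibble(age_group = bands$age_group,
                        age_start = bands$age_start,
                        width = bands$width,
                        population = as.numeric(population),
                        deaths = as.numeric(deaths),
                        rate = as.numeric(deaths) / as.numeric(population))
  class(out) <- c("mortality_schedule", class(out))
  out
}

#' Coerce a plain band table to a mortality schedule
#' @keywords internal
as_mortality_schedule <- function(x) {
  if (inherits(x, "mortality_schedule")) return(x)
  mortality_schedule(x$age_group, x$population, x$deaths)
}

#' Abridged period life table
#'
#' Standard construction on 5-year bands: the central rate `nMx` is
#' converted to a death probability `nqx = n * nMx / (1 + (n - nax) * nMx)`,
#' survivorship `lx` descends from a radix of 100,000, person-years are
#' `nLx = n * lx - (n - nax) * ndx` for closed bands and `lx / nMx` for the
#' open band (constant-hazard tail), and remaining life expectancy is
#' `ex = Tx / lx`. Life expectancy at birth `e0` is `ex` of the first band.
#'
#' @param schedule A [mortality_schedule()] (any first band age; `e0`
#'   semantics require it to start at 0).
#' @param nax Average years lived within a closed band by those dying in
#'   it; default half the band width. Supply a vector (one value per
#'   closed band, terminal entry ignored) to override, e.g. a
#'   Coale-Demeny-style infant separation factor for the first band.
#' @param radix Survivors at the first band start (default 100,000).
#' @return A tibble of class `life_table` with columns `age_group`,
#'   `age_start`, `width`, `nMx`, `nax`, `nqx`, `lx`, `ndx`, `nLx`, `Tx`,
#'   `ex`.
#' @examples
#' sched <- mortality_schedule(age_band_labels(),
#'                             population = rep(1e5, 18),
#'                             deaths = rep(1e5 * 0.02, 18))
#' lt <- build_life_table(sched)
#' lt$ex[1]  # e0
#' @export
build_life_table <- function(schedule, nax = NULL, radix = 1e5) {
  schedule <- as_mortality_schedule(schedule)
  nb <- nrow(schedule)
  n <- schedule$width
  m <- schedule$rate
  if (is.null(nax)) {
    nax <- n / 2
  } else {
    nax <- rep_len(as.numeric(nax), nb)
    if (any(nax[-nb] <= 0 | nax[-nb] > n[-nb])) {
      stop("nax must lie in (0, band width] for closed bands", call. = FALSE)
    }
  }
  nqx <- n * m / (1 + (n - nax) * m)
  nqx[nb] <- 1
  over <- which(nqx > 1)
  if (length(over) > 0) {
    warning("death probability exceeded 1 in band(s) ",
            paste(schedule$age_group[over], collapse = ", "),
            "; clamped to 1", call. = FALSE)
    nqx[over] <- 1
  }
  lx <- radix * cumprod(c(1, 1 - nqx[-nb]))
  ndx <- lx * nqx
  nLx <- n * lx - (n - nax) * ndx
  nLx[nb] <- lx[nb] / m[nb]
  Tx <- rev(cumsum(rev(nLx)))
  ex <- ifelse(lx > 0, Tx / lx, 0)
  nax[nb] <- 1 / m[nb]
  out <- tibble::tibble(age_group = schedule$age_group,
                        age_start = schedule$age_start,
                        width = n,
                        nMx = m, nax = nax, nqx = nqx,
                        lx = lx, ndx = ndx, nLx = nLx, Tx = Tx, ex = ex)
  class(out) <- c("life_table", class(out))
  out
}

#' Remaining life expectancy for one band
#'
#' @param table A [build_life_table()] result.
#' @param age_group Band label, e.g. `"25-29"`.
#' @return Years of remaining life expectancy at the band start.
#' @export
remaining_life_expectancy <- function(table, age_group) {
  i <- match(age_group, table$age_group)
  if (anyNA(i)) {
    stop("no life-table band labelled ",
         paste(age_group[is.na(i)], collapse = ", "),
         "; valid labels: ", paste(table$age_group, collapse = ", "),
         call. = FALSE)
  }
  table$ex[i]
}

#' Remove an attributable share of mortality from a schedule
#'
#' Returns the counterfactual ("without PM2.5") schedule in which each
#' band's death rate is scaled by `1 - af`. Bands not named in `af` keep
#' their rates; deaths are recomputed from the scaled rates.
#'
#' @param schedule A [mortality_schedule()].
#' @param af Attributable fractions in `[0, 1)`: either a named vector
#'   keyed by `age_group` label, or one value per band.
#' @return A new `mortality_schedule`.
#' @examples
#' sched <- mortality_schedule(age_band_labels(),
#'                             population = rep(1000, 18),
#'                             deaths = c(rep(2, 17), 100))
#' perturb_schedule(sched, c("60-64" = 0.5))
#' @export
perturb_schedule <- function(schedule, af) {
  schedule <- as_mortality_schedule(schedule)
  nb <- nrow(schedule)
  if (!is.null(names(af)) && any(nzchar(names(af)))) {
    unknown <- setdiff(names(af), schedule$age_group)
    if (length(unknown) > 0) {
      stop("af names not found in schedule: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    full <- stats::setNames(numeric(nb), schedule$age_group)
    full[names(af)] <- af
    af <- full
  } else if (length(af) == 1L) {
    af <- rep(af, nb)
  } else if (length(af) != nb) {
    stop("af must be named, scalar, or one value per band", call. = FALSE)
  }
  if (any(!is.finite(af)) || any(af < 0) || any(af >= 1)) {
    stop("attributable fractions must lie in [0, 1)", call. = FALSE)
  }
  rate_cf <- schedule$rate * (1 - af)
  mortality_schedule(schedule$age_group, schedule$population,
                     rate_cf * schedule$population)
}
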