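# Independent oracles used across the suite.

# Cohort microsimulation of a mortality schedule: individuals die in a
# closed band with probability n*m/(1 + (n - n/2)*m) (deaths uniform
# within the band) and follow an exponential tail in the open band.
# Sampling is by inverse CDF, so one uniform draw per person decides the
# death band and the within-band time. Returns a function giving the mean
# residual lifetime among survivors to any band start (e0 = at age 0).
sim_cohort <- function(schedule, n_persons = 1e6, seed = 1) {
  m <- schedule$deaths / schedule$population
  n <- ifelse(is.finite(schedule$width), schedule$width, NA)
  nb <- length(m)
  q <- n * m / (1 + (n - n / 2) * m)
  q <- pmin(q[-nb], 1)
  surv <- cumprod(c(1, 1 - q))           # survivorship to each band start
  starts <- schedule$age_start
  withr::with_seed(seed, {
    u <- stats::runif(n_persons)
    band <- findInterval(-u, -surv)      # death band: surv[band] >= u > surv[band+1]
    t_death <- numeric(n_persons)
    open <- band == nb
    t_death[open] <- starts[nb] +
      stats::rexp(sum(open), rate = m[nb])
    cl <- !open
    frac <- (surv[band[cl]] - u[cl]) /
      (surv[band[cl]] - surv[band[cl] + 1])
    t_death[cl] <- starts[band[cl]] + frac * n[band[cl]]
  })
  function(age = 0) {
    alive <- t_death > age
    mean(t_death[alive]) - age
  }
}

# Fully independent continuous-time model: hazard constant within each
# band (exponential tail in the open band); closed-form person-year
# integration, no shared formulas with the abridged table.
const_hazard_e0 <- function(schedule) {
  m <- schedule$deaths / schedule$population
  n <- schedule$width
  nb <- length(m)
  S <- cumprod(c(1, exp(-n[-nb] * m[-nb])))
  L <- numeric(nb)
  L[-nb] <- S[-nb] * ifelse(m[-nb] > 0,
                            (1 - exp(-n[-nb] * m[-nb])) / m[-nb], n[-nb])
  L[nb] <- S[nb] / m[nb]
  sum(L)
}

# Random Gompertz-Makeham-style schedules spanning the study's mortality
# conditions (registered old-age rates roughly 0.1-0.3/yr in the open
# band), for property and oracle-equivalence tests.
random_schedule <- function(seed) {
  withr::with_seed(seed, {
    a <- stats::runif(1, 2e-5, 8e-5)
    b <- stats::runif(1, 0.085, 0.105)
    cc <- stats::runif(1, 2e-4, 1.5e-3)
    labels <- pmhia::age_band_labels()
    starts <- c(seq(0, 80, 5), 85)
    mids <- ifelse(starts < 85, starts + 2.5, 90)
    rate <- a * exp(b * mids) + cc
    k <- stats::runif(1, 0.1, 0.3) / rate[18]  # scale to a target open-band rate
    rate <- k * rate
    pop <- round(stats::runif(18, 5e3, 5e4))
    pmhia::mortality_schedule(labels, pop, pop * rate)
  })
}

# Band start ages for a demography tibble (used when filtering adults).
age_starts_of <- function(age_group) {
  out <- numeric(length(age_group))
  open <- grepl("\\+$", age_group)
  out[open] <- as.numeric(sub("\\+$", "", age_group[open]))
  out[!open] <- as.numeric(sub("-.*$", "", age_group[!open]))
  out
}

# Crude 25+ death rate per 1,000 for each unit of a demography tibble.
crude_rates_25plus <- function(demography) {
  st <- age_starts_of(demography$age_group)
  adult <- demography[st >= 25, ]
  vapply(split(adult, adult$unit_id), function(d) {
    sum(d$deaths) / sum(d$population) * 1000
  }, numeric(1))
}
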