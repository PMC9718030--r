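# Exposure-response functions: the GEMM hazard ratio for NCD+LRI mortality
# and the AirQ+-style log-linear relative risk, plus the counterfactual
# attributable-fraction calculus that both feed.

#' GEMM NCD+LRI hazard-ratio parameters
#'
#' Loads the age-specific parameter table for the Global Exposure Mortality
#' Model (GEMM), non-communicable disease plus lower respiratory infection
#' outcome. Each 5-year adult band from 25-29 to 85+ carries a log-hazard
#' scale `theta` with standard error `theta_se`, and the shared shape
#' parameters `alpha` (curvature scale, ug/m3), `mu` (logistic-weight
#' location, ug/m3) and `nu` (logistic-weight width, ug/m3). The hazard
#' ratio at annual-mean concentration C is
#' `exp(theta * log(1 + z/alpha) / (1 + exp(-(z - mu)/nu)))` with
#' `z = max(0, C - zcf)`.
#'
#' @param path Optional path to an alternative parameter CSV with columns
#'   `age_group`, `theta`, `theta_se`, `alpha`, `mu`, `nu`.
#' @param zcf Internal counterfactual offset of the fitted curve, ug/m3
#'   (default 2.4). This is a property of the published fit, distinct from
#'   the policy counterfactual of a scenario.
#' @return A tibble of class `gemm_params` with one row per adult band and
#'   a `zcf` column.
#' @examples
#' gemm_params()
#' @export
gemm_params <- function(path = NULL, zcf = 2.4) {
  if (is.null(path)) {
    path <- system.file("extdata", "gemm_ncd_lri.csv",
                        package = "pmhia", mustWork = TRUE)
  }
  tbl <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  required <- c("age_group", "theta", "theta_se", "alpha", "mu", "nu")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    stop("GEMM parameter file is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(tbl$alpha <= 0) || any(tbl$nu <= 0) || any(tbl$theta_se < 0)) {
    stop("invalid GEMM parameters: require alpha > 0, nu > 0, theta_se >= 0",
         call. = FALSE)
  }
  bands <- parse_age_groups(tbl$age_group)
  assert_contiguous_bands(bands, from = 25, what = "GEMM parameter age bands")
  tbl$zcf <- zcf
  class(tbl) <- c("gemm_params", class(tbl))
  tbl
}

#' Look up the GEMM parameter row for one age band
#'
#' @param params A `gemm_params` table.
#' @param age_group Band label, e.g. `"60-64"`.
#' @return A one-row tibble.
#' @export
gemm_params_for <- function(params, age_group) {
  i <- match(age_group, params$age_group)
  if (anyNA(i)) {
    stop("no GEMM parameters for age group(s) ",
         paste(age_group[is.na(i)], collapse = ", "),
         "; available: ", paste(params$age_group, collapse = ", "),
         call. = FALSE)
  }
  params[i, ]
}

#' GEMM hazard ratio
#'
#' Evaluates `HR(C) = exp(theta * log(1 + z/alpha) * w(z))` with
#' `w(z) = 1/(1 + exp(-(z - mu)/nu))` and `z = max(0, C - zcf)`.
#'
#' @param concentration Annual-mean PM2.5, ug/m3; vectorised.
#' @param params A single parameter set: one row of [gemm_params()] (or any
#'   list with `theta`, `alpha`, `mu`, `nu` and optionally `zcf`).
#' @param theta_override Optional replacement for `theta`, used to evaluate
#'   uncertainty bounds at `theta +/- 1.96 * theta_se`.
#' @return Dimensionless hazard ratio(s), `>= 1` whenever `theta >= 0`.
#' @examples
#' p <- gemm_params_for(gemm_params(), "25-29")
#' gemm_hazard_ratio(40.8, p)
#' gemm_hazard_ratio(2.4, p)  # at the curve's own counterfactual: exactly 1
#' @export
gemm_hazard_ratio <- function(concentration, params, theta_override = NULL) {
  if (is.data.frame(params) && nrow(params) != 1L) {
    stop("`params` must be a single parameter set (one row); ",
         "use gemm_params_for() to select an age group", call. = FALSE)
  }
  if (any(!is.finite(concentration)) || any(concentration < 0)) {
    off <- concentration[!is.finite(concentration) | concentration < 0]
    stop("concentration must be finite and >= 0 ug/m3; offending value(s): ",
         paste(utils::head(off, 5), collapse = ", "), call. = FALSE)
  }
  theta <- if (is.null(theta_override)) params$theta else theta_override
  zcf <- if (is.null(params$zcf)) 2.4 else params$zcf
  z <- pmax(0, concentration - zcf)
  exp(theta * log1p(z / params$alpha) * stats::plogis((z - params$mu) / params$nu))
}

#' Log-linear relative-risk model (AirQ+ convention)
#'
#' All-cause (natural) mortality risk for adults 30+, expressed as a
#' relative risk per 10 ug/m3 of annual-mean PM2.5. The default 1.062
#' (95% CI 1.040-1.083) is the Hoek et al. meta-analytic estimate that
#' AirQ+ ships for its long-term mortality option.
#'
#' @param rr_per_10 Relative risk per 10 ug/m3.
#' @param ci_low,ci_high 95% interval bounds on `rr_per_10`.
#' @param min_age Youngest age (years) the risk estimate applies to.
#' @return A list of class `loglinear_risk`.
#' @export
loglinear_risk <- function(rr_per_10 = 1.062, ci_low = 1.040, ci_high = 1.083,
                           min_age = 30) {
  if (!is.numeric(rr_per_10) || rr_per_10 <= 0) {
    stop("rr_per_10 must be a positive number", call. = FALSE)
  }
  if (ci_low > rr_per_10 || ci_high < rr_per_10) {
    stop("require ci_low <= rr_per_10 <= ci_high", call. = FALSE)
  }
  structure(list(rr_per_10 = rr_per_10, ci_low = ci_low, ci_high = ci_high,
                 min_age = min_age),
            class = "loglinear_risk")
}

#' Log-linear relative risk between two concentrations
#'
#' `RR = rr_per_10 ^ (max(0, c_obs - c_cf) / 10)`; excess exposure below
#' the counterfactual is floored at zero, so the function returns 1 when
#' `c_obs <= c_cf`.
#'
#' @param c_obs Observed annual-mean concentration, ug/m3; vectorised.
#' @param c_cf Counterfactual concentration, ug/m3.
#' @param risk A [loglinear_risk()] object.
#' @param bound Which risk value to use: the point estimate or an interval
#'   bound.
#' @return Dimensionless relative risk(s), `>= 1`.
#' @examples
#' loglinear_rr(40.8, 5)  # 1.062^3.58
#' @export
loglinear_rr <- function(c_obs, c_cf, risk = loglinear_risk(),
                         bound = c("point", "low", "high")) {
  bound <- match.arg(bound)
  if (any(c_obs < 0) || any(c_cf < 0)) {
    stop("concentrations must be >= 0 ug/m3", call. = FALSE)
  }
  rr10 <- switch(bound, point = risk$rr_per_10, low = risk$ci_low,
                 high = risk$ci_high)
  if (rr10 <= 0) stop("relative risk per 10 ug/m3 must be positive", call. = FALSE)
  rr10 ^ (pmax(0, c_obs - c_cf) / 10)
}

#' Counterfactual attributable fraction
#'
#' `AF = 1 - hr_cf / hr_obs`, clamped to 0 when the observed hazard ratio
#' does not exceed the counterfactual one (no negative burden is
#' attributed).
#'
#' @param hr_obs Hazard ratio at the observed concentration; vectorised.
#' @param hr_cf Hazard ratio at the counterfactual concentration.
#' @return Fraction(s) in `[0, 1)`.
#' @examples
#' attributable_fraction(2, 1)  # 0.5
#' @export
attributable_fraction <- function(hr_obs, hr_cf) {
  if (any(hr_obs <= 0) || any(hr_cf <= 0)) {
    stop("hazard ratios must be positive", call. = FALSE)
  }
  pmax(0, 1 - hr_cf / hr_obs)
}

#' Age-specific attributable-fraction triplets for a scenario
#'
#' Evaluates the scenario's risk model at the observed and counterfactual
#' concentrations for each adult band and returns low/point/high
#' attributable fractions. GEMM bounds come from evaluating the whole
#' curve at `theta +/- 1.96 * theta_se` (uncertainty treated as perfectly
#' correlated across ages); log-linear bounds come from the published
#' interval on the risk per 10 ug/m3. With `n_draws > 0` a seeded normal
#' Monte-Carlo draw on `theta` (or on `log(rr_per_10)` scaled from its
#' interval) replaces the closed-form bounds.
#'
#' @param bands A tibble with `age_group` and `age_start` for the adult
#'   bands of interest.
#' @param exposure Observed annual-mean concentration, ug/m3 (scalar).
#' @param scenario A [scenario()] object (carries the counterfactual and
#'   the risk-model choice).
#' @param gemm A [gemm_params()] table.
#' @param loglinear A [loglinear_risk()] object.
#' @param n_draws Monte-Carlo draws for the interval (0 = closed-form
#'   normal bounds, the default).
#' @param seed Seed used when `n_draws > 0`.
#' @return A tibble `age_group`, `af_low`, `af`, `af_high`.
#' @export
scenario_af <- function(bands, exposure, scenario,
                        gemm = gemm_params(), loglinear = loglinear_risk(),
                        n_draws = 0, seed = 1L) {
  stopifnot(length(exposure) == 1L, exposure >= 0)
  cf <- scenario$counterfactual
  out <- tibble::tibble(age_group = bands$age_group,
                        af_low = 0, af = 0, af_high = 0)
  if (exposure <= cf) {
    return(out)  # below-counterfactual rule: nothing attributed
  }
  if (is.function(scenario$risk_model)) {
    raw <- scenario$risk_model(exposure, cf, bands)
    if (!is.matrix(raw)) {
      raw <- matrix(rep_len(as.numeric(raw), nrow(bands)), ncol = 1)
      raw <- cbind(raw, raw, raw)
    } else if (nrow(raw) == 1L) {
      raw <- raw[rep(1L, nrow(bands)), , drop = FALSE]
    }
    out$af_low <- as.numeric(raw[, 1])
    out$af <- as.numeric(raw[, 2])
    out$af_high <- as.numeric(raw[, 3])
    return(out)
  }
  if (identical(scenario$risk_model, "GEMM")) {
    prm <- gemm_params_for(gemm, bands$age_group)
    af_at <- function(theta) {
      attributable_fraction(gemm_hazard_ratio(exposure, prm_split, theta),
                            gemm_hazard_ratio(cf, prm_split, theta))
    }
    for (i in seq_len(nrow(out))) {
      prm_split <- prm[i, ]
      if (n_draws > 0) {
        draws <- withr::with_seed(seed, stats::rnorm(n_draws, prm_split$theta,
                                                     prm_split$theta_se))
        afs <- vapply(draws, af_at, numeric(1))
        out$af[i] <- af_at(prm_split$theta)
        qs <- stats::quantile(afs, c(0.025, 0.975), names = FALSE)
        out$af_low[i] <- qs[1]; out$af_high[i] <- qs[2]
      } else {
        out$af[i] <- af_at(prm_split$theta)
        out$af_low[i] <- af_at(prm_split$theta - 1.96 * prm_split$theta_se)
        out$af_high[i] <- af_at(prm_split$theta + 1.96 * prm_split$theta_se)
      }
    }
    return(out)
  }
  if (identical(scenario$risk_model, "log-linear")) {
    eligible <- bands$age_start >= loglinear$min_age
    af_of <- function(bound) {
      rr <- loglinear_rr(exposure, cf, loglinear, bound = bound)
      attributable_fraction(rr, 1)
    }
    if (n_draws > 0) {
      # normal draw on log RR, sd from the 95% interval width
      sd_log <- (log(loglinear$ci_high) - log(loglinear$ci_low)) / (2 * 1.96)
      draws <- withr::with_seed(seed, stats::rnorm(n_draws,
                                                   log(loglinear$rr_per_10),
                                                   sd_log))
      afs <- vapply(exp(draws), function(r) {
        attributable_fraction(r ^ ((exposure - cf) / 10), 1)
      }, numeric(1))
      qs <- stats::quantile(afs, c(0.025, 0.975), names = FALSE)
      out$af[eligible] <- af_of("point")
      out$af_low[eligible] <- qs[1]; out$af_high[eligible] <- qs[2]
    } else {
      out$af[eligible] <- af_of("point")
      out$af_low[eligible] <- af_of("low")
      out$af_high[eligible] <- af_of("high")
    }
    return(out)
  }
  stop("unknown risk model: ", scenario$risk_model, call. = FALSE)
}
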