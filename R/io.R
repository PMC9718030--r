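# CSV schemas, config parsing and run provenance. All readers validate
# with row-level diagnostics; all writers are deterministic (stable column
# order, stable rounding).

demography_cols <- c("unit_id", "age_group", "population",
                     "deaths_noninjury")

# read_csv with the reader-internal attributes stripped so loaded tables
# compare equal to in-memory ones
read_plain_csv <- function(path) {
  tbl <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  attr(tbl, "spec") <- NULL
  attr(tbl, "problems") <- NULL
  class(tbl) <- c("tbl_df", "tbl", "data.frame")
  tbl
}

#' Read a demography CSV
#'
#' Expected columns: `unit_id`, `age_group`, `population`,
#' `deaths_noninjury` (optionally `province_id` and a logical
#' `injury_excluded` flag column). Each unit's bands must be contiguous
#' 5-year groups ending in one open interval.
#'
#' @param path CSV path.
#' @param injury_excluded Assertion that injury deaths were removed
#'   upstream; the loader refuses files without this guarantee (or with an
#'   `injury_excluded` column containing `FALSE`).
#' @return A tibble `unit_id`, `province_id` (if present), `age_group`,
#'   `population`, `deaths`.
#' @export
load_demography <- function(path, injury_excluded = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tbl <- read_plain_csv(path)
  missing <- setdiff(demography_cols, names(tbl))
  if (length(missing) > 0) {
    stop("demography file is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if ("injury_excluded" %in% names(tbl)) {
    if (!all(tbl$injury_excluded)) {
      stop("demography file contains rows with injury_excluded = FALSE; ",
           "baseline deaths must exclude injuries", call. = FALSE)
    }
  } else if (!isTRUE(injury_excluded)) {
    stop("set injury_excluded = TRUE to confirm the death counts exclude ",
         "injury-related deaths", call. = FALSE)
  }
  bad <- which(!is.finite(tbl$population) | tbl$population <= 0 |
                 !is.finite(tbl$deaths_noninjury) | tbl$deaths_noninjury < 0)
  if (length(bad) > 0) {
    stop("invalid population/death counts at data row(s) ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  out <- tbl[, intersect(c("unit_id", "province_id", demography_cols),
                         names(tbl))]
  names(out)[names(out) == "deaths_noninjury"] <- "deaths"
  # validates band structure per unit (errors name the unit and the gap)
  for (u in unique(out$unit_id)) {
    d <- out[out$unit_id == u, ]
    tryCatch(mortality_schedule(d$age_group, d$population, d$deaths),
             error = function(e) {
               stop("unit ", u, ": ", conditionMessage(e), call. = FALSE)
             })
  }
  out
}

#' Write a demography table to CSV
#'
#' Inverse of [load_demography()]; round-trips exactly.
#' @param demography Tibble with `unit_id`, optional `province_id`,
#'   `age_group`, `population`, `deaths`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_demography <- function(demography, path) {
  out <- demography
  names(out)[names(out) == "deaths"] <- "deaths_noninjury"
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read an exposure CSV (cell level or district level)
#'
#' Cell tables carry `cell_id`, `district_id`, `concentration`; district
#' tables carry `district_id` (or `unit_id`) and `annual_mean`.
#'
#' @param path CSV path.
#' @return A tibble; district tables are normalised to `unit_id`,
#'   `province_id` (if present), `annual_mean`.
#' @export
load_exposure <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tbl <- read_plain_csv(path)
  if ("cell_id" %in% names(tbl)) {
    missing <- setdiff(c("district_id", "concentration"), names(tbl))
    if (length(missing) > 0) {
      stop("cell exposure file is missing column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    if (any(tbl$concentration < 0)) {
      stop("negative concentration at data row(s) ",
           paste(utils::head(which(tbl$concentration < 0), 10),
                 collapse = ", "), call. = FALSE)
    }
    return(tbl)
  }
  if ("district_id" %in% names(tbl) && !"unit_id" %in% names(tbl)) {
    names(tbl)[names(tbl) == "district_id"] <- "unit_id"
  }
  missing <- setdiff(c("unit_id", "annual_mean"), names(tbl))
  if (length(missing) > 0) {
    stop("district exposure file is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(tbl$annual_mean < 0)) {
    stop("negative annual mean at data row(s) ",
         paste(utils::head(which(tbl$annual_mean < 0), 10), collapse = ", "),
         call. = FALSE)
  }
  tbl
}

round_impact_cols <- function(tbl) {
  ad_cols <- grep("^ad(_low|_high)?$", names(tbl), value = TRUE)
  rate_cols <- grep("rate", names(tbl), value = TRUE)
  yll_cols <- grep("^yll", names(tbl), value = TRUE)
  lle_cols <- grep("^lle", names(tbl), value = TRUE)
  for (cc in ad_cols) tbl[[cc]] <- round(tbl[[cc]])
  for (cc in setdiff(c(rate_cols, yll_cols, lle_cols), ad_cols)) {
    tbl[[cc]] <- round(tbl[[cc]], 1)
  }
  tbl
}

#' Write impact summary tables to CSV
#'
#' Writes the district, province and region summaries of a [run_hia()]
#' result (or a single summary tibble) with the report rounding: deaths to
#' integers, rates, YLL and LLE to one decimal. Interval triplets must be
#' complete.
#'
#' @param summaries An `hia_result` or one summary tibble.
#' @param path Output directory (for an `hia_result`) or CSV path (for a
#'   single tibble).
#' @param rounded Apply report rounding (default `TRUE`); `FALSE` writes
#'   full precision.
#' @return The written path(s), invisibly.
#' @export
write_impact_tables <- function(summaries, path, rounded = TRUE) {
  write_one <- function(tbl, file) {
    for (stem in c("ad", "ad_rate", "yll", "yll_rate")) {
      trip <- paste0(stem, c("_low", "", "_high"))
      have <- trip %in% names(tbl)
      if (any(have) && !all(have)) {
        stop("incomplete interval triplet for ", stem, call. = FALSE)
      }
    }
    if (rounded) tbl <- round_impact_cols(tbl)
    readr::write_csv(tbl, file, progress = FALSE)
    file
  }
  if (inherits(summaries, "hia_result")) {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    files <- c(
      write_one(summaries$district, file.path(path, "impacts_district.csv")),
      write_one(summaries$province, file.path(path, "impacts_province.csv")),
      write_one(summaries$region, file.path(path, "impacts_region.csv")))
    return(invisible(files))
  }
  invisible(write_one(summaries, path))
}

default_config <- function() {
  list(
    scenarios = list(
      list(name = "AQG", counterfactual = 5, risk_model = "GEMM"),
      list(name = "QCVN", counterfactual = 15, risk_model = "GEMM")),
    rate_denominator = "total-population",
    open_age = 85,
    loglinear = list(rr_per_10 = 1.062, ci_low = 1.040, ci_high = 1.083),
    gemm_params = NULL,
    rounding = TRUE,
    seed = 1L)
}

#' Read a YAML run configuration
#'
#' Unknown keys are rejected; missing keys fall back to defaults
#' (scenarios AQG 5 and QCVN 15 under GEMM, total-population rates, open
#' age 85, Hoek log-linear risk 1.062 (1.040-1.083), report rounding on,
#' seed 1).
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return A config list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(user)] <- user
  for (sc in cfg$scenarios) {
    if (is.null(sc$name) || is.null(sc$counterfactual)) {
      stop("every scenario needs a name and a counterfactual", call. = FALSE)
    }
  }
  cfg
}

config_scenarios <- function(cfg) {
  lapply(cfg$scenarios, function(sc) {
    scenario(sc$name, sc$counterfactual,
             risk_model = if (is.null(sc$risk_model)) "GEMM" else sc$risk_model,
             rate_denominator = cfg$rate_denominator)
  })
}

#' Build a run provenance manifest
#'
#' Records input-file digests, the effective configuration, the packaged
#' parameter-file digest, timestamps, and the package version, so every
#' output file can be traced to its inputs.
#'
#' @param inputs Named character vector of input file paths.
#' @param outputs Character vector of output file paths.
#' @param config The effective config list.
#' @param path Optional path to write the manifest as JSON.
#' @return The manifest list, invisibly if written.
#' @export
run_manifest <- function(inputs = character(), outputs = character(),
                         config = default_config(), path = NULL) {
  digest <- function(files) {
    files <- files[file.exists(files)]
    if (length(files) == 0) return(list())
    as.list(tools::md5sum(files))
  }
  manifest <- list(
    package = "pmhia",
    version = as.character(utils::packageVersion("pmhia")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    parameter_file = digest(system.file("extdata", "gemm_ncd_lri.csv",
                                        package = "pmhia")),
    inputs = digest(unlist(inputs)),
    outputs = as.list(unname(unlist(outputs))),
    config = config)
  if (!is.null(path)) {
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
    return(invisible(manifest))
  }
  manifest
}
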