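# Packaged reference tables.

#' Total population of Vietnam, 2019 census
#'
#' Used as the denominator when expressing the exposed adult population of
#' the study region as a share of the national population.
#' @format A single number (persons).
#' @export
vietnam_population_2019 <- 96208984

#' Study-region province table, Vietnam 2019
#'
#' Annual-mean PM2.5 concentration, adult (25+) population and crude 25+
#' non-injury death rate for the 11 study provinces (10 northern provinces
#' plus Ho Chi Minh City).
#'
#' @param path Optional path to an alternative CSV with the same columns.
#' @return A tibble with columns `province`, `pm25_ugm3`,
#'   `population_25plus` and `death_rate_25plus_per_1000`.
#' @examples
#' vietnam_provinces()
#' @export
vietnam_provinces <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "vietnam_provinces_2019.csv",
                        package = "pmhia", mustWork = TRUE)
  }
  tbl <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  required <- c("province", "pm25_ugm3", "population_25plus",
                "death_rate_25plus_per_1000")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    stop("province table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tbl
}
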