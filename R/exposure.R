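# Zonal aggregation of a gridded annual-mean PM2.5 surface onto
# administrative districts, and month-to-year aggregation of cell series.

#' Aggregate grid cells to district annual means
#'
#' @param cells Tibble with `cell_id`, `district_id`, `concentration`
#'   (ug/m3), optionally `province_id` and `weight` (area fraction or
#'   population; required for `weighting = "weighted"`).
#' @param weighting `"uniform"` (arithmetic mean of member cells, the
#'   default) or `"weighted"` (weight-proportional mean).
#' @param districts Optional character vector of expected district ids;
#'   any expected district with no cells is an error.
#' @return A tibble `district_id` (plus `province_id` when present),
#'   `annual_mean`, `n_cells`; one row per district, in first-appearance
#'   order.
#' @examples
#' cells <- tibble::tibble(cell_id = 1:2, district_id = "d1",
#'                         concentration = c(10, 20))
#' aggregate_to_district(cells)
#' @export
aggregate_to_district <- function(cells, weighting = c("uniform", "weighted"),
                                  districts = NULL) {
  weighting <- match.arg(weighting)
  if (!is.null(districts)) {
    empty <- setdiff(districts, cells$district_id)
    if (length(empty) > 0) {
      stop("district(s) with zero cells: ",
           paste(utils::head(empty, 5), collapse = ", "), call. = FALSE)
    }
  }
  needed <- c("cell_id", "district_id", "concentration")
  missing <- setdiff(needed, names(cells))
  if (length(missing) > 0) {
    stop("cell table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(cells) == 0) stop("cell table is empty", call. = FALSE)
  if (any(cells$concentration < 0)) {
    stop("cell concentrations must be >= 0 ug/m3", call. = FALSE)
  }
  if (identical(weighting, "weighted")) {
    if (!"weight" %in% names(cells)) {
      stop("weighted aggregation needs a weight column", call. = FALSE)
    }
    if (any(cells$weight < 0)) stop("cell weights must be >= 0", call. = FALSE)
    w <- cells$weight
  } else {
    w <- rep(1, nrow(cells))
  }
  ids <- unique(cells$district_id)
  out <- lapply(ids, function(d) {
    sel <- cells$district_id == d
    wsum <- sum(w[sel])
    if (wsum <= 0) {
      stop("district ", d, " has zero total weight", call. = FALSE)
    }
    row <- tibble::tibble(
      district_id = d,
      annual_mean = sum(cells$concentration[sel] * w[sel]) / wsum,
      n_cells = sum(sel))
    if ("province_id" %in% names(cells)) {
      row <- tibble::add_column(row,
                                province_id = cells$province_id[sel][1],
                                .after = "district_id")
    }
    row
  })
  dplyr::bind_rows(out)
}

#' Annual mean from 12 monthly means per cell
#'
#' @param monthly Tibble with `cell_id`, `month` (1-12) and
#'   `concentration`; exactly one value per cell-month unless
#'   `max_missing_months` allows gaps.
#' @param day_weighted Weight months by their calendar-day counts
#'   (non-leap year) instead of the default unweighted mean.
#' @param max_missing_months Months a cell may lack before it is rejected
#'   (default 0).
#' @return A tibble `cell_id`, `annual_mean`.
#' @export
monthly_to_annual <- function(monthly, day_weighted = FALSE,
                              max_missing_months = 0) {
  needed <- c("cell_id", "month", "concentration")
  missing <- setdiff(needed, names(monthly))
  if (length(missing) > 0) {
    stop("monthly table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(!monthly$month %in% 1:12)) {
    stop("month must be an integer in 1..12", call. = FALSE)
  }
  if (anyDuplicated(monthly[c("cell_id", "month")])) {
    stop("duplicate cell-month entries", call. = FALSE)
  }
  days <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  ids <- unique(monthly$cell_id)
  out <- lapply(ids, function(cid) {
    rows <- monthly[monthly$cell_id == cid, ]
    n_miss <- 12L - nrow(rows)
    if (n_miss > max_missing_months) {
      stop("cell ", cid, " is missing ", n_miss,
           " month(s), more than the allowed ", max_missing_months,
           call. = FALSE)
    }
    w <- if (day_weighted) days[rows$month] else rep(1, nrow(rows))
    tibble::tibble(cell_id = cid,
                   annual_mean = sum(rows$concentration * w) / sum(w))
  })
  dplyr::bind_rows(out)
}
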