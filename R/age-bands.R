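# Age-band plumbing shared by the life-table, risk and synthetic modules.

#' Parse 5-year age-group labels
#'
#' Labels follow the abridged life-table convention: closed bands written
#' `"0-4"`, `"5-9"`, ..., and a single open terminal band written `"85+"`.
#'
#' @param labels Character vector of band labels, in table order.
#' @return A tibble with columns `age_group`, `age_start` (years) and
#'   `width` (years; `Inf` for the open band).
#' @keywords internal
parse_age_groups <- function(labels) {
  if (!is.character(labels) || length(labels) == 0) {
    stop("age-group labels must be a non-empty character vector", call. = FALSE)
  }
  open <- grepl("^[0-9]+\\+$", labels)
  closed <- grepl("^[0-9]+-[0-9]+$", labels)
  bad <- !(open | closed)
  if (any(bad)) {
    stop("unrecognised age-group label(s): ",
         paste(unique(labels[bad]), collapse = ", "),
         " (expected e.g. \"25-29\" or \"85+\")", call. = FALSE)
  }
  age_start <- numeric(length(labels))
  age_start[open] <- as.numeric(sub("\\+$", "", labels[open]))
  age_start[closed] <- as.numeric(sub("-.*$", "", labels[closed]))
  age_end <- rep(Inf, length(labels))
  age_end[closed] <- as.numeric(sub("^[0-9]+-", "", labels[closed])) + 1
  tibble::tibble(age_group = labels, age_start = age_start,
                 width = age_end - age_start)
}

#' Check that parsed bands are contiguous, ascending and end in one open band
#' @keywords internal
assert_contiguous_bands <- function(bands, from = NULL, what = "age bands") {
  n <- nrow(bands)
  if (is.unsorted(bands$age_start, strictly = TRUE)) {
    stop(what, " must be in strictly ascending order", call. = FALSE)
  }
  n_open <- sum(is.infinite(bands$width))
  if (n_open != 1L || !is.infinite(bands$width[n])) {
    stop(what, " must contain exactly one open-ended band, in terminal position",
         call. = FALSE)
  }
  if (n > 1L) {
    expected <- bands$age_start[-n] + bands$width[-n]
    gap <- which(bands$age_start[-1] != expected)
    if (length(gap) > 0) {
      stop("non-contiguous ", what, ": gap between \"",
           bands$age_group[gap[1]], "\" and \"", bands$age_group[gap[1] + 1],
           "\"", call. = FALSE)
    }
  }
  if (!is.null(from) && bands$age_start[1] != from) {
    stop(what, " must start at age ", from, ", found ",
         bands$age_group[1], call. = FALSE)
  }
  invisible(bands)
}

#' Standard 5-year band labels
#'
#' @param open_age Start of the open terminal band (default 85).
#' @param from Start of the first band (default 0).
#' @return Character vector of labels, e.g. `"0-4"` ... `"85+"`.
#' @examples
#' age_band_labels()
#' age_band_labels(from = 25)
#' @export
age_band_labels <- function(open_age = 85, from = 0) {
  stopifnot(open_age > from, (open_age - from) %% 5 == 0)
  starts <- seq(from, open_age - 5, by = 5)
  c(sprintf("%d-%d", starts, starts + 4), sprintf("%d+", open_age))
}

#' Representative age at the middle of each band
#'
#' Closed bands use their midpoint; the open band uses its start plus 5
#' years, a pragmatic stand-in for its mean age.
#' @keywords internal
band_mid_age <- function(bands) {
  ifelse(is.finite(bands$width),
         bands$age_start + bands$width / 2,
         bands$age_start + 5)
}
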