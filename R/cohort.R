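# Waitlist inclusion/exclusion rules and facility-identifier
# canonicalization. Listing intervals are trimmed to the study period and to
# the adult (>= 18 years) portion; open intervals are administratively
# censored on the last study day.

#' Define a study period
#'
#' @param start,end ISO dates; `start` must precede `end`.
#' @return A `study_period` list of two Dates.
#' @export
study_period <- function(start = "2008-01-01", end = "2018-12-31") {
  start <- as.Date(start); end <- as.Date(end)
  if (!(start < end)) stop("study start must precede study end")
  structure(list(start = start, end = end), class = "study_period")
}

#' Canonicalize facility identifiers and drop inactive centers
#'
#' Alias facility ids are replaced by their canonical center id via a
#' many-to-one crosswalk; entries whose canonical id is absent from the
#' active-center table are dropped and counted.
#'
#' @param entries Waitlist data frame (see [generate_waitlist()]).
#' @param facility_xwalk Data frame with columns `alias_id`, `canonical_id`.
#' @param active_centers Character vector of active canonical center ids.
#' @return List with `entries` (canonicalized, kept rows), `n_dropped`
#'   (entries at inactive centers), and `dropped_centers` (their ids).
#' @export
canonicalize_facilities <- function(entries, facility_xwalk, active_centers) {
  if (anyDuplicated(facility_xwalk$alias_id)) {
    bad <- unique(facility_xwalk$alias_id[duplicated(facility_xwalk$alias_id)])
    stop(sprintf("alias id(s) map to multiple canonical ids: %s",
                 paste(bad, collapse = ", ")))
  }
  map <- stats::setNames(facility_xwalk$canonical_id, facility_xwalk$alias_id)
  fid <- entries$facility_id
  hit <- fid %in% names(map)
  fid[hit] <- unname(map[fid[hit]])
  entries$facility_id <- fid
  keep <- fid %in% active_centers
  list(entries = entries[keep, , drop = FALSE],
       n_dropped = sum(!keep),
       dropped_centers = sort(unique(fid[!keep])))
}

# Adult threshold: 18 years after the birth date (Feb 29 maps to Feb 28).
adult_from <- function(birth) lubridate::`%m+%`(birth, lubridate::years(18))

#' Apply waitlist inclusion rules and trim intervals to the study period
#'
#' Rules, in order: (i) drop entries whose start date is missing or follows
#' the recorded end date; (ii) treat a missing end date as active and censor
#' at the study end; (iii) trim the interval to `[max(start, 18th birthday,
#' study start), min(end, study end)]`; (iv) drop entries whose trimmed
#' interval is empty (no day, inclusive, inside the study period as an
#' adult).
#'
#' @param entries Canonicalized waitlist data frame.
#' @param period A [study_period()].
#' @return List with `cohort` (kept rows plus `interval_start`,
#'   `interval_end`) and `tally` (named counts: `input`, `included`,
#'   `excluded_bad_dates`, `excluded_no_adult_overlap`, `n_censored`).
#' @export
filter_waitlist <- function(entries, period) {
  stopifnot(inherits(period, "study_period"))
  n_in <- nrow(entries)
  if (any(is.na(entries$birth_date))) {
    bad <- which(is.na(entries$birth_date))
    stop(sprintf("missing birth date in row(s): %s",
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  # (i) bad dates
  bad <- is.na(entries$start_date) |
    (!is.na(entries$end_date) & entries$start_date > entries$end_date)
  kept <- entries[!bad, , drop = FALSE]
  # (ii) administrative censoring
  cens <- is.na(kept$end_date)
  kept$end_date[cens] <- period$end
  # (iii) trim to study period and adult portion
  kept$interval_start <- pmax(kept$start_date, period$start,
                              adult_from(kept$birth_date))
  kept$interval_end <- pmin(kept$end_date, period$end)
  # (iv) at least one (inclusive) day inside the study period
  empty <- kept$interval_start > kept$interval_end
  cohort <- kept[!empty, , drop = FALSE]
  rownames(cohort) <- NULL
  list(cohort = cohort,
       tally = c(input = n_in,
                 included = nrow(cohort),
                 excluded_bad_dates = sum(bad),
                 excluded_no_adult_overlap = sum(empty),
                 n_censored = sum(cens & !empty)))
}

#' Write cohort and exclusion tally artifacts
#'
#' @param filtered Result of [filter_waitlist()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(filtered, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- filtered$cohort
  for (col in c("birth_date", "start_date", "end_date",
                "interval_start", "interval_end"))
    out[[col]] <- date_chr(out[[col]])
  utils::write.csv(out, file.path(dir, "cohort.csv"), row.names = FALSE)
  jsonlite::write_json(as.list(filtered$tally),
                       file.path(dir, "exclusions.json"), auto_unbox = TRUE)
  invisible(dir)
}
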