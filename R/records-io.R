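# Individual death records: one row per specimen, with the death date and the
# scratch counts from the two standard 0.16 mm^2 enamel areas.

record_columns <- c(
  "specimen_id", "sample_id", "species", "death_year", "death_month",
  "death_day", "count_area1", "count_area2", "hemisphere"
)

record_col_types <- readr::cols(
  specimen_id = readr::col_character(),
  sample_id = readr::col_character(),
  species = readr::col_character(),
  death_year = readr::col_integer(),
  death_month = readr::col_integer(),
  death_day = readr::col_integer(),
  count_area1 = readr::col_double(),
  count_area2 = readr::col_double(),
  hemisphere = readr::col_character()
)

#' Read individual death records from CSV
#'
#' Reads one row per specimen with the fixed header contract
#' `specimen_id, sample_id, species, death_year, death_month, death_day,
#' count_area1, count_area2, hemisphere`. `death_year`, `death_day` and
#' `count_area2` may be empty (missing); missing values are parsed as `NA`,
#' never as zero. A record with a missing `death_day` carries month-level
#' resolution and is placed mid-month for any date arithmetic.
#'
#' @param path Path to a CSV file (UTF-8, header required).
#' @return A tibble of validated records, one row per specimen.
#' @seealso [write_records()], [validate_records()]
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c(
#'   "specimen_id,sample_id,species,death_year,death_month,death_day,count_area1,count_area2,hemisphere",
#'   "cb001,1,Rangifer tarandus,1966,3,12,17.5,18.5,north"
#' ), f)
#' read_records(f)
#' @export
read_records <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: '%s'.", path))
  }
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  missing_cols <- setdiff(record_columns, header)
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "file '%s' is missing mandatory column(s): %s.",
      path, paste(missing_cols, collapse = ", ")
    ))
  }
  records <- readr::read_csv(path,
    col_types = record_col_types, na = c("", "NA"),
    progress = FALSE
  )
  validate_records(records[, record_columns])
}

#' Validate a tibble of individual death records
#'
#' Checks the invariants of the record contract: month in 1..12, day (when
#' present) valid for the month on a 365-day year, finite non-negative scratch
#' counts with at least area 1 present, and hemisphere `"north"` or
#' `"south"`. Violations raise a row-level error naming the offending rows.
#'
#' @param records A data frame with the columns of [read_records()].
#' @return The records, invisibly validated, as a tibble.
#' @export
validate_records <- function(records) {
  records <- as_tibble(records)
  missing_cols <- setdiff(record_columns, names(records))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "records are missing mandatory column(s): %s.",
      paste(missing_cols, collapse = ", ")
    ))
  }
  problems <- character(0)
  row_problem <- function(bad, what) {
    if (any(bad)) {
      problems <<- c(problems, sprintf(
        "%s in row(s) %s", what, paste(which(bad), collapse = ", ")
      ))
    }
  }
  m <- records$death_month
  row_problem(is.na(m) | m < 1 | m > 12, "death_month not in 1..12")
  ok_m <- !is.na(m) & m >= 1 & m <= 12
  d <- records$death_day
  bad_day <- !is.na(d) & ok_m & (d < 1 | d > days_in_month[ifelse(ok_m, m, 1L)])
  row_problem(bad_day, "death_day invalid for death_month")
  c1 <- records$count_area1
  row_problem(is.na(c1) | !is.finite(c1) | c1 < 0,
    "count_area1 missing, non-finite or negative")
  c2 <- records$count_area2
  row_problem(!is.na(c2) & (!is.finite(c2) | c2 < 0),
    "count_area2 non-finite or negative")
  row_problem(!records$hemisphere %in% c("north", "south"),
    "hemisphere not 'north' or 'south'")
  if (length(problems) > 0) {
    abort(c("invalid records:", setNames(problems, rep("x", length(problems)))))
  }
  records
}

#' Write individual death records to CSV
#'
#' Inverse of [read_records()]: writes the fixed header contract so that
#' `read_records(write_records(x, f))` reproduces `x` exactly.
#'
#' @param records A validated records tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  records <- validate_records(records)
  readr::write_csv(records[, record_columns], path, na = "")
  invisible(path)
}
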