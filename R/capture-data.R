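#' @useDynLib ringmiss, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm rpois rbinom runif pnorm qnorm quantile var sd
#'   coef vcov lm glm binomial confint plogis qlogis setNames resid
#' @importFrom utils read.csv write.csv
NULL

PLUMAGE_LEVELS <- c("female_colored", "paradoxus")

#' Age-sex class index
#'
#' Maps an (age, sex) pair to the age-class index used throughout the model:
#' young females (g = 1), young males (g = 2), adult females (g = 3) and
#' adult males (g = 4), i.e. \code{g = 1 + sex + 2 * age} with age coded
#' 0 = young / 1 = adult and sex coded 0 = female / 1 = male.
#'
#' @param age integer vector in \{0, 1\}; \code{NA} not allowed.
#' @param sex integer vector in \{0, 1\}; \code{NA} not allowed.
#' @return integer vector of class indices in 1..4.
#' @seealso [class_labels()] for the inverse mapping.
#' @export
#' @examples
#' class_index(age = 0, sex = 0)  # young female -> 1
#' class_index(age = 1, sex = 1)  # adult male  -> 4
class_index <- function(age, sex) {
  if (anyNA(age) || anyNA(sex))
    stop("label not observed: class_index() requires observed age and sex")
  if (!all(age %in% c(0L, 1L)) || !all(sex %in% c(0L, 1L)))
    stop("age and sex must be coded 0/1")
  as.integer(1L + sex + 2L * age)
}

#' Inverse of the age-sex class index
#'
#' @param g integer vector of class indices in 1..4.
#' @return data.frame with columns \code{age} and \code{sex}.
#' @export
class_labels <- function(g) {
  if (!all(g %in% 1:4)) stop("class index must be in 1..4")
  g <- as.integer(g)
  data.frame(age = (g - 1L) %/% 2L, sex = (g - 1L) %% 2L)
}

#' Construct a capture table
#'
#' A capture table holds one row per first-capture record with columns
#' \code{id}, \code{year}, \code{day} (1-based day of year), \code{age}
#' (0 young / 1 adult / NA), \code{sex} (0 female / 1 male / NA),
#' \code{weight_g}, \code{primary_mm} and \code{plumage}
#' ("female_colored" / "paradoxus" / NA), plus the coordinate anchors the
#' model needs: the day at the middle of the capture period (day 0 of the
#' seasonal covariate) and the reference year used for phenological day
#' correction.  The year covariate is centred at the study midpoint year.
#'
#' @param records data.frame with the columns above.  Optional columns
#'   \code{true_age} / \code{true_sex} (added by [apply_missingness()]) are
#'   carried through.
#' @param season_midpoint_day integer day of year at the middle of the
#'   capture period; must lie within the observed day range.
#' @param reference_year first study year, the anchor of [corrected_day()].
#' @return object of class \code{capture_table}.
#' @export
capture_table <- function(records, season_midpoint_day, reference_year) {
  required <- c("id", "year", "day", "age", "sex", "weight_g", "primary_mm",
                "plumage")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols))
    stop("missing mandatory columns: ", paste(missing_cols, collapse = ", "))
  records <- as.data.frame(records)
  validate_records(records)
  season_midpoint_day <- as.integer(season_midpoint_day)
  if (nrow(records) > 0 &&
      (season_midpoint_day < min(records$day) ||
       season_midpoint_day > max(records$day)))
    stop("season_midpoint_day must lie within the observed day range")
  structure(
    list(records = records,
         season_midpoint_day = season_midpoint_day,
         reference_year = as.integer(reference_year),
         midpoint_year = if (nrow(records)) mean(range(records$year))
                         else as.numeric(reference_year)),
    class = "capture_table")
}

validate_records <- function(records) {
  with(records, {
    if (!is.numeric(weight_g) || !is.numeric(primary_mm))
      stop("weight_g and primary_mm must be numeric")
    if (anyNA(weight_g) || anyNA(primary_mm) ||
        any(weight_g <= 0) || any(primary_mm <= 0))
      stop("weight_g and primary_mm must be present and positive; ",
           "filter rows first (see read_capture_table)")
    if (!all(age %in% c(0L, 1L, NA)) || !all(sex %in% c(0L, 1L, NA)))
      stop("age and sex must be coded 0/1/NA")
    if (!all(is.na(plumage) | plumage %in% PLUMAGE_LEVELS))
      stop("plumage must be 'female_colored', 'paradoxus' or NA")
    bad <- !is.na(plumage) & plumage == "paradoxus" &
      ((!is.na(age) & age != 0L) | (!is.na(sex) & sex != 1L))
    if (any(bad))
      stop("paradoxus plumage implies a young male: offending rows ",
           paste(which(bad), collapse = ", "))
  })
  invisible(records)
}

#' @export
print.capture_table <- function(x, ...) {
  r <- x$records
  cat(sprintf("capture_table: %d records, years %s-%s\n", nrow(r),
              min(r$year), max(r$year)))
  cat(sprintf("  day range %d-%d (midpoint day %d), midpoint year %.1f\n",
              min(r$day), max(r$day), x$season_midpoint_day, x$midpoint_year))
  cat(sprintf("  missing sex %.1f%%, missing age %.1f%%, paradoxus %d\n",
              100 * mean(is.na(r$sex)), 100 * mean(is.na(r$age)),
              sum(r$plumage == "paradoxus", na.rm = TRUE)))
  invisible(x)
}

#' Number of records in a capture table
#' @param table a [capture_table()].
#' @return integer count.
#' @export
n_records <- function(table) nrow(table$records)

#' Seasonal day covariate
#'
#' Day centred so that 0 is the middle of the capture period.
#'
#' @param table a [capture_table()].
#' @return numeric vector, \code{day - season_midpoint_day}.
#' @export
centered_day <- function(table) {
  table$records$day - table$season_midpoint_day
}

#' Year covariate centred at the study midpoint year
#' @param table a [capture_table()].
#' @return numeric vector in units of years.
#' @export
centered_year <- function(table) {
  table$records$year - table$midpoint_year
}

#' Phenology-corrected capture day
#'
#' The capture window is fixed while migration shifts later across years, so
#' a day observed late in the study corresponds to a relatively earlier
#' point of the migration period.  The correction subtracts
#' \code{shift_per_year} days for every year since \code{reference_year}:
#' with the default 0.2 d/yr, a bird captured on 10 October 2000 (day 283)
#' corresponds to one captured on 6 October (day 279) in 1980.
#'
#' @param day numeric day (of year or centred).
#' @param year calendar year of capture.
#' @param reference_year anchor year (correction is zero there).
#' @param shift_per_year phenological shift in days per year (default 0.2).
#' @return numeric corrected day.
#' @export
corrected_day <- function(day, year, reference_year, shift_per_year = 0.2) {
  stopifnot(is.finite(shift_per_year))
  day - shift_per_year * (year - reference_year)
}

#' Read a capture table from CSV
#'
#' Missing values may be coded as empty cells or \code{"NA"}.  Rows whose
#' weight or primary length is missing or non-positive are excluded (the
#' analysis is restricted to captures with complete morphometrics); the
#' number of rejected rows is reported via a message and attached as the
#' \code{"n_rejected"} attribute.
#'
#' @param path CSV file path.
#' @param season_midpoint_day,reference_year see [capture_table()]; by
#'   default derived from the data (rounded mid-range day, minimum year).
#' @return a [capture_table()].
#' @export
read_capture_table <- function(path, season_midpoint_day = NULL,
                               reference_year = NULL) {
  raw <- read.csv(path, na.strings = c("", "NA"), stringsAsFactors = FALSE)
  required <- c("id", "year", "day", "age", "sex", "weight_g", "primary_mm",
                "plumage")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop("missing mandatory columns: ", paste(missing_cols, collapse = ", "))
  for (col in c("year", "day", "age", "sex", "weight_g", "primary_mm")) {
    val <- raw[[col]]
    if (!is.numeric(val) && !all(is.na(val)))
      stop("non-numeric values in column ", col)
    raw[[col]] <- as.numeric(val)
  }
  if (!all(raw$age %in% c(0, 1, NA))) stop("out-of-domain age codes")
  if (!all(raw$sex %in% c(0, 1, NA))) stop("out-of-domain sex codes")
  raw$age <- as.integer(raw$age)
  raw$sex <- as.integer(raw$sex)
  raw$id <- as.character(raw$id)
  raw$plumage <- as.character(raw$plumage)
  keep <- !is.na(raw$weight_g) & !is.na(raw$primary_mm) &
    raw$weight_g > 0 & raw$primary_mm > 0
  n_rejected <- sum(!keep)
  if (n_rejected > 0)
    message(n_rejected, " row(s) rejected: missing or non-positive ",
            "weight/primary")
  rec <- raw[keep, , drop = FALSE]
  rownames(rec) <- NULL
  if (is.null(season_midpoint_day))
    season_midpoint_day <- round(mean(range(rec$day)))
  if (is.null(reference_year)) reference_year <- min(rec$year)
  out <- capture_table(rec, season_midpoint_day, reference_year)
  attr(out, "n_rejected") <- n_rejected
  out
}

#' Write a capture table to CSV
#'
#' Missing values are written as \code{"NA"}; [read_capture_table()] on the
#' result reproduces all fields including missingness.
#'
#' @param table a [capture_table()].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_capture_table <- function(table, path) {
  stopifnot(inherits(table, "capture_table"))
  write.csv(table$records, path, row.names = FALSE, na = "NA")
  invisible(path)
}
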