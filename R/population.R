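#' Fiscal-year date window
#'
#' New Zealand fiscal years run from 1 July to 30 June; \code{"2014/15"}
#' denotes 1 July 2014 through 30 June 2015 (closed interval).
#'
#' @param label fiscal-year label \code{"YYYY/YY"} with consecutive years.
#' @return named Date vector \code{c(start, end)}.
#' @export
#' @examples
#' fiscal_year_window("2014/15")
fiscal_year_window <- function(label) {
  m <- regmatches(label, regexec("^([0-9]{4})/([0-9]{2})$", label))[[1]]
  if (length(m) != 3L)
    stop("malformed fiscal-year label '", label, "'; expected e.g. 2014/15")
  y1 <- as.integer(m[2])
  if ((y1 + 1L) %% 100L != as.integer(m[3]))
    stop("fiscal-year label '", label, "' does not span consecutive years")
  c(start = as.Date(sprintf("%d-07-01", y1)),
    end = as.Date(sprintf("%d-06-30", y1 + 1L)))
}

#' Completed age in years at a date
#'
#' Birthday-anniversary convention: a person born 30 June 2000 is 15 on
#' 30 June 2015; a person born 1 July 2000 is still 14 on 30 June 2015.
#' Vectorised over both arguments.
#'
#' @param dob date(s) of birth.
#' @param on date(s) at which to compute age; must be \code{>= dob}.
#' @return integer vector of completed years.
#' @export
age_at <- function(dob, on) {
  dob <- as.Date(dob); on <- as.Date(on)
  if (any(on < dob)) stop("age_at: date precedes date of birth")
  db <- as.POSIXlt(dob); ob <- as.POSIXlt(on)
  age <- ob$year - db$year -
    as.integer(ob$mon < db$mon | (ob$mon == db$mon & ob$mday < db$mday))
  as.integer(age)
}

#' Read a person roster file
#'
#' The roster is tab- or comma-separated with header
#' \code{record_type person_id date_of_birth sex death_date overseas_from
#' overseas_to}. Rows with \code{record_type = "person"} carry
#' demographics (one per person); rows with \code{record_type =
#' "overseas"} carry one overseas interval each for an already-listed
#' person (repeatable).
#'
#' @param path roster file path.
#' @return list with \code{persons} (data.frame: \code{person_id},
#'   \code{date_of_birth}, \code{sex}, \code{death_date}) and
#'   \code{overseas} (data.frame: \code{person_id}, \code{from},
#'   \code{to}).
#' @export
read_roster <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  raw <- utils::read.delim(path, sep = sep, colClasses = "character",
                           stringsAsFactors = FALSE, quote = "")
  needed <- c("record_type", "person_id", "date_of_birth", "sex",
              "death_date", "overseas_from", "overseas_to")
  missing <- setdiff(needed, names(raw))
  if (length(missing))
    stop("roster is missing column(s): ", paste(missing, collapse = ", "))
  pp <- raw[raw$record_type == "person", , drop = FALSE]
  oo <- raw[raw$record_type == "overseas", , drop = FALSE]
  persons <- data.frame(
    person_id = pp$person_id,
    date_of_birth = as.Date(pp$date_of_birth),
    sex = pp$sex,
    death_date = as.Date(ifelse(nzchar(pp$death_date), pp$death_date, NA)),
    stringsAsFactors = FALSE
  )
  overseas <- data.frame(
    person_id = oo$person_id,
    from = as.Date(oo$overseas_from),
    to = as.Date(oo$overseas_to),
    stringsAsFactors = FALSE
  )
  list(persons = persons, overseas = overseas)
}

#' Construct the resident 0-24 denominator population for a fiscal year
#'
#' From an explicit person roster, retains persons aged 0-24 completed
#' years at the reference date who were not excluded: persons who died
#' before the window start are excluded, as are persons overseas for the
#' entire fiscal-year window (a single overseas interval covering it).
#' Persons dying \emph{during} the window remain members, so that cases
#' identified from the mortality collection (suicide deaths) have a
#' denominator. The reference date for age and strata is the window start
#' (1 July) by default; it can be moved to the window end or midpoint.
#'
#' @param roster list as returned by \code{\link{read_roster}}, or a
#'   persons data.frame (then \code{overseas} may be given separately).
#' @param fy fiscal-year label, e.g. \code{"2014/15"}.
#' @param reference one of \code{"start"}, \code{"end"}, \code{"midpoint"}.
#' @param overseas optional overseas-interval data.frame if \code{roster}
#'   is a plain persons data.frame.
#' @return a \code{population_roster}: list with \code{fiscal_year},
#'   \code{window}, \code{reference_date}, \code{members} (data.frame
#'   \code{person_id}, \code{age_years}, \code{band}), \code{strata}
#'   (named counts over the five bands), \code{total}, and
#'   \code{exclusions} (named counts by reason).
#' @export
build_population <- function(roster, fy, reference = c("start", "end", "midpoint"),
                             overseas = NULL) {
  reference <- match.arg(reference)
  if (is.data.frame(roster)) {
    persons <- roster
    if (is.null(overseas))
      overseas <- data.frame(person_id = character(),
                             from = as.Date(character()),
                             to = as.Date(character()))
  } else {
    persons <- roster$persons
    overseas <- roster$overseas
  }
  if (anyDuplicated(persons$person_id))
    stop("duplicate person_id in roster: ",
         persons$person_id[duplicated(persons$person_id)][1])
  win <- fiscal_year_window(fy)
  ref <- switch(reference,
    start = win[["start"]],
    end = win[["end"]],
    midpoint = win[["start"]] + as.integer((win[["end"]] - win[["start"]]) / 2))

  born <- persons$date_of_birth <= ref
  age <- rep(NA_integer_, nrow(persons))
  age[born] <- age_at(persons$date_of_birth[born], ref)
  in_age <- born & age >= 0L & age <= 24L
  died_before <- !is.na(persons$death_date) &
    persons$death_date < win[["start"]]
  away_ids <- unique(overseas$person_id[
    overseas$from <= win[["start"]] & overseas$to >= win[["end"]]])
  away <- persons$person_id %in% away_ids

  keep <- in_age & !died_before & !away
  members <- data.frame(
    person_id = persons$person_id[keep],
    age_years = age[keep],
    band = age_band(age[keep]),
    stringsAsFactors = FALSE
  )
  strata <- table(members$band)
  structure(list(
    fiscal_year = fy, window = win, reference_date = ref,
    members = members,
    strata = stats::setNames(as.integer(strata), names(strata)),
    total = nrow(members),
    exclusions = c(
      not_aged_0_24 = sum(!in_age),
      died_before_window = sum(in_age & died_before),
      overseas_entire_window = sum(in_age & !died_before & away))
  ), class = "population_roster")
}

#' @export
print.population_roster <- function(x, ...) {
  cat("<population_roster> ", x$fiscal_year, ": ", x$total,
      " members aged 0-24 at ", format(x$reference_date), "\n", sep = "")
  print(x$strata)
  invisible(x)
}

# members of the roster within a completed-age range at the reference date
roster_age_count <- function(roster, min_age, max_age) {
  sum(roster$members$age_years >= min_age & roster$members$age_years <= max_age)
}
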