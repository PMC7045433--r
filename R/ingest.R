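# Per-source input schema descriptors. Each source table is a delimited
# text file with a header; columns differ per collection but every row
# reduces to the same event tuple (person, source, date, code, system, rank).
source_schemas <- function() {
  list(
    primhd_diagnosis = list(
      source = "PRIMHD", subtype = "diagnosis",
      columns = c("person_id", "event_date", "code", "system", "rank"),
      date_col = "event_date", system_col = "system", rank_col = "rank",
      systems = c("ICD10AM", "DSMIV"), secondary_ok = TRUE),
    primhd_activity = list(
      source = "PRIMHD", subtype = "activity",
      columns = c("person_id", "event_date", "code", "system"),
      date_col = "event_date", system_col = "system", rank_col = NULL,
      systems = c("ACTIVITY_TYPE", "TEAM_TYPE"), secondary_ok = FALSE),
    nmds = list(
      source = "NMDS", subtype = NA_character_,
      columns = c("person_id", "event_date", "code", "rank"),
      date_col = "event_date", system_col = NULL, rank_col = "rank",
      systems = "ICD10AM", secondary_ok = TRUE),
    pharms = list(
      source = "PHARMS", subtype = NA_character_,
      columns = c("person_id", "dispense_date", "chemical_id"),
      date_col = "dispense_date", system_col = NULL, rank_col = NULL,
      code_col = "chemical_id",
      systems = "CHEMICAL_ID", secondary_ok = FALSE),
    socrates = list(
      source = "SOCRATES", subtype = NA_character_,
      columns = c("person_id", "referral_date", "code", "system"),
      date_col = "referral_date", system_col = "system", rank_col = NULL,
      systems = c("ICD10AM", "DSMIV"), secondary_ok = FALSE),
    mortality = list(
      source = "MORTALITY", subtype = NA_character_,
      columns = c("person_id", "death_date", "code"),
      date_col = "death_date", system_col = NULL, rank_col = NULL,
      systems = "ICD10AM", secondary_ok = FALSE)
  )
}

empty_events <- function() {
  data.frame(person_id = character(), source = character(),
             subtype = character(), event_date = as.Date(character()),
             code = character(), system = character(), rank = character(),
             stringsAsFactors = FALSE)
}

#' Read one source event table into the uniform event stream
#'
#' Reads a delimited file (tab- or comma-separated, detected from the
#' header) in the documented schema of one of the six source tables, and
#' returns events that pass schema and best-quality-window checks. Rows
#' with malformed dates, blank identifiers/codes, or a code system the
#' source does not carry are skipped and logged by row number; rows dated
#' outside the source's best-quality window (e.g. pharmaceutical
#' dispensings before 2007, hospital discharges before 1994) are dropped
#' and counted. Row order is preserved, and duplicated rows are retained:
#' de-duplication happens implicitly when events are collapsed to
#' per-person indicators.
#'
#' @param path input file path.
#' @param source schema key: one of \code{"primhd_diagnosis"},
#'   \code{"primhd_activity"}, \code{"nmds"}, \code{"pharms"},
#'   \code{"socrates"}, \code{"mortality"}.
#' @param window optional closed date window \code{c(start, end)}
#'   overriding the source default (see details in the package vignette).
#' @return list with \code{events} (data.frame: \code{person_id},
#'   \code{source}, \code{subtype}, \code{event_date}, \code{code},
#'   \code{system}, \code{rank}) and \code{log} (one-row data.frame of
#'   counts: \code{rows_read}, \code{emitted}, \code{dropped_window},
#'   \code{dropped_malformed}, plus attribute \code{malformed_rows} with
#'   the offending row numbers).
#' @export
read_events <- function(path, source, window = NULL) {
  schemas <- source_schemas()
  if (!source %in% names(schemas))
    stop("unknown source schema '", source, "'; expected one of: ",
         paste(names(schemas), collapse = ", "))
  sc <- schemas[[source]]
  if (is.null(window)) window <- source_windows()[[source]]
  if (!file.exists(path)) stop("event file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  raw <- utils::read.delim(path, sep = sep, colClasses = "character",
                           stringsAsFactors = FALSE, quote = "")
  missing <- setdiff(sc$columns, names(raw))
  if (length(missing))
    stop("file '", basename(path), "' is missing column(s): ",
         paste(missing, collapse = ", "))
  n <- nrow(raw)
  if (n == 0L) {
    return(list(events = empty_events(), log = ingest_log(path, 0, 0, 0, 0)))
  }
  code_col <- if (!is.null(sc$code_col)) sc$code_col else "code"
  dates <- as.Date(raw[[sc$date_col]], format = "%Y-%m-%d")
  system <- if (!is.null(sc$system_col)) raw[[sc$system_col]]
            else rep(sc$systems[1], n)
  rank <- if (!is.null(sc$rank_col)) raw[[sc$rank_col]]
          else rep("not_applicable", n)
  malformed <- is.na(dates) |
    !nzchar(trimws(raw$person_id)) | !nzchar(trimws(raw[[code_col]])) |
    !system %in% sc$systems |
    (!is.null(sc$rank_col) & !rank %in% c("primary", "secondary"))
  out_of_window <- !malformed &
    (dates < window[["start"]] | dates > window[["end"]])
  keep <- !malformed & !out_of_window
  events <- data.frame(
    person_id = raw$person_id[keep], source = sc$source,
    subtype = sc$subtype, event_date = dates[keep],
    code = raw[[code_col]][keep], system = system[keep],
    rank = rank[keep], stringsAsFactors = FALSE
  )
  log <- ingest_log(path, n, sum(keep), sum(out_of_window), sum(malformed))
  attr(log, "malformed_rows") <- which(malformed)
  list(events = events, log = log)
}

ingest_log <- function(path, read, emitted, win, mal) {
  data.frame(file = basename(path), rows_read = read, emitted = emitted,
             dropped_window = win, dropped_malformed = mal,
             stringsAsFactors = FALSE)
}

#' Restrict events to a closed date window
#'
#' @param events event data.frame as returned by \code{\link{read_events}}.
#' @param window closed date interval \code{c(start, end)},
#'   \code{start <= end}; both endpoints inclusive.
#' @return the rows of \code{events} whose \code{event_date} lies in the
#'   window, order preserved.
#' @export
#' @examples
#' w <- fiscal_year_window("2014/15")
#' # an event on 1 July 2014 is retained; 1 July 2015 is not
filter_window <- function(events, window) {
  if (window[["start"]] > window[["end"]])
    stop("window start after end")
  events[events$event_date >= window[["start"]] &
           events$event_date <= window[["end"]], , drop = FALSE]
}

#' Read all six source tables from a directory
#'
#' Convenience wrapper over \code{\link{read_events}}: looks for files
#' named \code{<schema>.tsv} (or \code{.csv}) for each of the six schema
#' keys, reads those present, and concatenates the event streams.
#'
#' @param dir directory containing the event files.
#' @return list with combined \code{events} and a \code{log} data.frame
#'   with one row per file read.
#' @export
read_event_dir <- function(dir) {
  keys <- names(source_schemas())
  evs <- list(); logs <- list()
  for (k in keys) {
    for (ext in c(".tsv", ".csv")) {
      p <- file.path(dir, paste0(k, ext))
      if (file.exists(p)) {
        r <- read_events(p, k)
        evs[[k]] <- r$events
        logs[[k]] <- r$log
        break
      }
    }
  }
  list(events = if (length(evs)) do.call(rbind, c(evs, list(make.row.names = FALSE)))
                else empty_events(),
       log = if (length(logs)) do.call(rbind, c(logs, list(make.row.names = FALSE)))
             else ingest_log("<none>", 0, 0, 0, 0)[0, ])
}
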