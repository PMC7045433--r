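#' Collapse coded events to per-person problem indicators
#'
#' The core of the case-identification method: every event inside the
#' fiscal-year window, belonging to a person in the denominator roster, is
#' matched against the codebook at the person's completed age on the event
#' date. Each match sets the corresponding dichotomous category indicator
#' to 1 and adds the event's source dataset to that category's attribution
#' set; a single qualifying code in any source is sufficient, so duplicate
#' events are harmless. Only persons with at least one indicator appear in
#' the output. By default the "mental health not defined" precedence rule
#' (\code{\link{apply_precedence}}) is then applied.
#'
#' Events for person_ids absent from the demographics map are logged and
#' skipped (case identifications are restricted to the roster population).
#'
#' @param events event data.frame (see \code{\link{read_events}}), already
#'   filtered to each source's best-quality window.
#' @param roster a \code{population_roster} from
#'   \code{\link{build_population}}.
#' @param persons data.frame with \code{person_id} and
#'   \code{date_of_birth} (e.g. \code{read_roster(path)$persons}), used to
#'   compute age at each event date.
#' @param rules validated \code{code_ruleset}.
#' @param fy fiscal-year label; events outside its window are ignored.
#' @param precedence apply the precedence rule before returning
#'   (default \code{TRUE}).
#' @param specific_set categories that knock out \code{mh_not_defined}
#'   under precedence; see \code{\link{apply_precedence}}.
#' @return an \code{indicator_set}: data.frame with \code{person_id}, 13
#'   0/1 indicator columns named after \code{problem_categories()}, and 13
#'   attribution columns \code{src_<category>} holding semicolon-delimited
#'   source sets. Attribution is retained for audit even where precedence
#'   zeroes the \code{mh_not_defined} indicator.
#' @export
identify <- function(events, roster, persons, rules, fy,
                     precedence = TRUE,
                     specific_set = c(specific_categories(), "other_mh")) {
  cats <- problem_categories()
  win <- fiscal_year_window(fy)
  ev <- filter_window(events, win)
  ev <- ev[ev$person_id %in% roster$members$person_id, , drop = FALSE]
  known <- ev$person_id %in% persons$person_id
  n_unknown <- length(unique(ev$person_id[!known]))
  if (n_unknown > 0)
    message("identify: skipped events for ", n_unknown,
            " person_id(s) missing from the demographics map")
  ev <- ev[known, , drop = FALSE]

  out <- empty_indicator_set()
  if (nrow(ev)) {
    dob <- persons$date_of_birth[match(ev$person_id, persons$person_id)]
    age <- age_at(dob, ev$event_date)
    ok <- age >= 0L & age <= 24L
    ev <- ev[ok, , drop = FALSE]; age <- age[ok]
    cat_hit <- match_events_vec(ev$system, ev$code, ev$source, age, rules)
    hit <- !is.na(cat_hit)
    if (any(hit)) {
      trip <- unique(data.frame(person_id = ev$person_id[hit],
                                category = cat_hit[hit],
                                source = ev$source[hit],
                                stringsAsFactors = FALSE))
      ids <- sort(unique(trip$person_id))
      ind <- matrix(0L, nrow = length(ids), ncol = length(cats),
                    dimnames = list(ids, cats))
      src <- matrix("", nrow = length(ids), ncol = length(cats),
                    dimnames = list(ids, cats))
      # per (person, category): indicator 1, sorted unique source set
      pid_i <- match(trip$person_id, ids)
      cat_i <- match(trip$category, cats)
      grp <- split(trip$source, list(pid = pid_i, cat = cat_i), drop = TRUE)
      sets <- vapply(grp, function(s) paste(sort(unique(s)), collapse = ";"),
                     character(1))
      at <- do.call(rbind, lapply(strsplit(names(sets), ".", fixed = TRUE),
                                  as.integer))
      ind[at] <- 1L
      src[at] <- sets
      out <- data.frame(person_id = ids, ind,
                        stats::setNames(as.data.frame(src,
                                                      stringsAsFactors = FALSE),
                                        paste0("src_", cats)),
                        stringsAsFactors = FALSE, row.names = NULL,
                        check.names = FALSE)
      class(out) <- c("indicator_set", "data.frame")
    }
  }
  if (precedence) out <- apply_precedence(out, specific_set)
  out
}

empty_indicator_set <- function() {
  cats <- problem_categories()
  cols <- c(list(person_id = character()),
            stats::setNames(rep(list(integer()), 13), cats),
            stats::setNames(rep(list(character()), 13),
                            paste0("src_", cats)))
  out <- do.call(data.frame,
                 c(cols, stringsAsFactors = FALSE, check.names = FALSE))
  class(out) <- c("indicator_set", "data.frame")
  out
}

#' Apply the "mental health not defined" precedence rule
#'
#' A person whose records only support the residual category "mental
#' health not defined" keeps that indicator; but if the person also has a
#' specific problem-group indicator (self-harm excluded), the residual
#' indicator is set to zero so they are not double-represented. By default
#' the knock-out set is the 10 specific-disorder categories plus
#' \code{other_mh}; self-harm never participates. Attribution columns are
#' left untouched for audit.
#'
#' @param v an \code{indicator_set} (one or many rows).
#' @param specific_set categories whose presence zeroes
#'   \code{mh_not_defined}; must contain neither \code{self_harm} nor
#'   \code{mh_not_defined}.
#' @return the modified \code{indicator_set}; pure function.
#' @export
#' @examples
#' # a person with anxiety and mh_not_defined keeps only anxiety;
#' # a person with self-harm and mh_not_defined keeps both
apply_precedence <- function(v, specific_set = c(specific_categories(),
                                                 "other_mh")) {
  if (any(specific_set %in% c("self_harm", "mh_not_defined")))
    stop("specific_set must exclude self_harm and mh_not_defined")
  if (!all(specific_set %in% problem_categories()))
    stop("unknown category in specific_set")
  if (!nrow(v)) return(v)
  knock <- Reduce(`|`, lapply(specific_set, function(cc) v[[cc]] == 1L))
  v$mh_not_defined[knock] <- 0L
  v
}

#' Person-level summary flags
#'
#' \code{any_specific} is the OR over the 10 specific-disorder categories
#' (the "Sub Total (Any Problem)" rows); \code{any_problem} is the OR over
#' all 13 categories including self-harm, other and not-defined (the
#' "Total (Any Problem)" row). Precedence is assumed already applied.
#'
#' @param v an \code{indicator_set}.
#' @return data.frame with \code{person_id}, \code{any_specific},
#'   \code{any_problem} (0/1).
#' @export
summarise_person <- function(v) {
  if (!nrow(v))
    return(data.frame(person_id = character(), any_specific = integer(),
                      any_problem = integer(), stringsAsFactors = FALSE))
  spec <- as.matrix(v[specific_categories()])
  all13 <- as.matrix(v[problem_categories()])
  data.frame(person_id = v$person_id,
             any_specific = as.integer(rowSums(spec) > 0),
             any_problem = as.integer(rowSums(all13) > 0),
             stringsAsFactors = FALSE)
}

#' Write / read an indicator set as a delimited file
#'
#' One row per identified person: \code{person_id}, 13 indicator columns,
#' then 13 semicolon-delimited attribution columns, in the canonical
#' category order.
#'
#' @param v an \code{indicator_set}.
#' @param path output (input) file path; tab-separated.
#' @export
write_indicators <- function(v, path) {
  utils::write.table(v, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_indicators
#' @export
read_indicators <- function(path) {
  v <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                         check.names = FALSE,
                         colClasses = "character")
  for (cc in problem_categories()) v[[cc]] <- as.integer(v[[cc]])
  for (sc in paste0("src_", problem_categories()))
    v[[sc]][is.na(v[[sc]])] <- ""
  class(v) <- c("indicator_set", "data.frame")
  v
}
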