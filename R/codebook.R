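#' Load and validate a case-identification codebook
#'
#' A codebook is the rule set that assigns a code observed in a given data
#' source, at a given patient age, to one of the 13 problem categories.
#' The file is UTF-8 tab-separated with header
#' \code{system code wildcard category min_age max_age sources note};
#' \code{sources} is a semicolon-delimited list of source tokens and
#' \code{wildcard} is 0/1 (1 = the code is a prefix pattern for hierarchical
#' ICD codes). The package ships an exemplar codebook
#' (\code{exemplar_codebook_path()}) containing the medication-inference
#' rules stated for the method (e.g. fluoxetine to emotional problems at all
#' ages; amitriptyline to depression at ages 20 and over only; risperidone,
#' which has several plausible indications, to "mental health not defined")
#' plus placeholder diagnosis rules for every supported category-source
#' cell. The codebook is user-replaceable input: the method, not any
#' particular code list, is what the package implements.
#'
#' @param path path to a codebook file.
#' @param table1 category-by-source logical support matrix; rules outside
#'   it are rejected. Default \code{\link{category_source_matrix}()}.
#' @return a \code{code_ruleset}: data.frame with columns \code{system},
#'   \code{code}, \code{wildcard} (logical), \code{category},
#'   \code{min_age}, \code{max_age}, \code{sources} (list of character
#'   vectors), \code{note}, plus attributes \code{name} and \code{version}.
#' @seealso \code{\link{validate_ruleset}}, \code{\link{match_event}}
#' @export
#' @examples
#' rules <- load_ruleset(exemplar_codebook_path())
#' nrow(rules)
load_ruleset <- function(path, table1 = category_source_matrix()) {
  if (!file.exists(path)) stop("codebook file not found: ", path)
  raw <- utils::read.delim(path, colClasses = "character",
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "#")
  needed <- c("system", "code", "wildcard", "category",
              "min_age", "max_age", "sources", "note")
  missing <- setdiff(needed, names(raw))
  if (length(missing))
    stop("codebook is missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(raw) == 0L) {
    warning("codebook '", basename(path), "' contains no rules")
    rules <- empty_ruleset(name = basename(path))
    return(rules)
  }
  min_age <- suppressWarnings(as.integer(raw$min_age))
  max_age <- suppressWarnings(as.integer(raw$max_age))
  bad_age <- which(is.na(min_age) | is.na(max_age))
  if (length(bad_age))
    stop("malformed age in codebook row(s): ",
         paste(bad_age, collapse = ", "))
  rules <- data.frame(
    system = raw$system, code = raw$code,
    wildcard = raw$wildcard %in% c("1", "TRUE", "true"),
    category = raw$category, min_age = min_age, max_age = max_age,
    note = raw$note, stringsAsFactors = FALSE
  )
  rules$sources <- lapply(strsplit(raw$sources, ";", fixed = TRUE), trimws)
  class(rules) <- c("code_ruleset", "data.frame")
  attr(rules, "name") <- basename(path)
  attr(rules, "version") <- "1"
  viol <- validate_ruleset(rules, table1)
  if (nrow(viol))
    stop("invalid codebook (", nrow(viol), " violation(s)):\n",
         paste(sprintf("  row %s: %s", viol$rule_row, viol$message),
               collapse = "\n"))
  rules
}

empty_ruleset <- function(name = "empty") {
  rules <- data.frame(
    system = character(), code = character(), wildcard = logical(),
    category = character(), min_age = integer(), max_age = integer(),
    note = character(), stringsAsFactors = FALSE
  )
  rules$sources <- list()
  class(rules) <- c("code_ruleset", "data.frame")
  attr(rules, "name") <- name
  attr(rules, "version") <- "1"
  rules
}

#' Path to the exemplar codebook shipped with the package
#' @return file path.
#' @export
exemplar_codebook_path <- function() {
  system.file("extdata", "codebook_exemplar.tsv", package = "mhcasefind",
              mustWork = TRUE)
}

#' Validate a code rule set
#'
#' Checks every rule against the structural invariants of the method:
#' known category, system and source tokens; age range inside 0-24 with
#' \code{min_age <= max_age}; each listed source admits the rule's code
#' system; the (category, source) pair is ticked in the support matrix; and
#' no two rules can resolve the same (system, code, source, age) to
#' different categories. Ambiguity is assessed under the same resolution
#' order used by \code{\link{match_event}} (exact match beats wildcard;
#' among wildcards the longest matching prefix wins), so two wildcard rules
#' conflict only when they share the identical prefix, an overlapping age
#' range, a shared source, and different categories.
#'
#' Violations are returned as data, not raised: an empty report means the
#' rule set is valid.
#'
#' @param rules a \code{code_ruleset} (need not be valid).
#' @param table1 category-by-source logical support matrix.
#' @return data.frame with columns \code{rule_row}, \code{type},
#'   \code{message}; zero rows iff valid.
#' @export
validate_ruleset <- function(rules, table1 = category_source_matrix()) {
  viol <- list()
  add <- function(row, type, msg) {
    viol[[length(viol) + 1L]] <<- data.frame(
      rule_row = row, type = type, message = msg, stringsAsFactors = FALSE)
  }
  cats <- problem_categories()
  srcs <- source_datasets()
  syss <- code_systems()
  n <- nrow(rules)
  for (i in seq_len(n)) {
    if (!rules$category[i] %in% cats)
      add(i, "unknown_category",
          paste0("unknown category '", rules$category[i], "'"))
    if (!rules$system[i] %in% syss)
      add(i, "unknown_system",
          paste0("unknown code system '", rules$system[i], "'"))
    if (is.na(rules$min_age[i]) || is.na(rules$max_age[i]) ||
        rules$min_age[i] < 0L || rules$max_age[i] > 24L ||
        rules$min_age[i] > rules$max_age[i])
      add(i, "age_range",
          sprintf("age range %s-%s outside 0 <= min <= max <= 24",
                  rules$min_age[i], rules$max_age[i]))
    ss <- rules$sources[[i]]
    if (length(ss) == 0L) {
      add(i, "no_sources", "empty source list")
      next
    }
    for (s in ss) {
      if (!s %in% srcs) {
        add(i, "unknown_source", paste0("unknown source '", s, "'"))
        next
      }
      if (rules$system[i] %in% syss &&
          !rules$system[i] %in% admissible_systems(s))
        add(i, "system_source",
            sprintf("source %s does not carry system %s", s, rules$system[i]))
      if (rules$category[i] %in% cats && !table1[rules$category[i], s])
        add(i, "table1",
            sprintf("category '%s' is not identified from source %s",
                    rules$category[i], s))
    }
  }
  # pairwise ambiguity under exact/longest-prefix resolution
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        if (rules$system[i] != rules$system[j]) next
        if (rules$category[i] == rules$category[j]) next
        if (rules$wildcard[i] != rules$wildcard[j]) next
        if (rules$code[i] != rules$code[j]) next
        if (!length(intersect(rules$sources[[i]], rules$sources[[j]]))) next
        if (rules$max_age[i] < rules$min_age[j] ||
            rules$max_age[j] < rules$min_age[i]) next
        add(j, "ambiguity",
            sprintf(paste0("rules %d and %d map (%s, %s) to both '%s' and ",
                           "'%s' over overlapping ages"),
                    i, j, rules$system[i], rules$code[i],
                    rules$category[i], rules$category[j]))
      }
    }
  }
  if (!length(viol))
    return(data.frame(rule_row = integer(), type = character(),
                      message = character(), stringsAsFactors = FALSE))
  do.call(rbind, viol)
}

# Vectorised rule matcher used by match_event() and identify().
# Returns a character vector of categories (NA where no rule matches).
# Resolution: exact match beats wildcard; among wildcard matches the
# longest prefix wins; a tie between different categories at the same
# specificity is an integrity error (precluded by validate_ruleset()).
match_events_vec <- function(system, code, source, age_years, rules) {
  n <- max(length(system), length(code), length(source), length(age_years))
  system <- rep_len(system, n); code <- rep_len(code, n)
  source <- rep_len(source, n); age_years <- rep_len(age_years, n)
  best_cat <- rep(NA_character_, n)
  best_spec <- rep(-1L, n)           # specificity: wildcard = nchar, exact = 1000
  ambig <- rep(FALSE, n)
  for (i in seq_len(nrow(rules))) {
    spec <- if (rules$wildcard[i]) nchar(rules$code[i]) else 1000L
    hit <- system == rules$system[i] &
      age_years >= rules$min_age[i] & age_years <= rules$max_age[i] &
      source %in% rules$sources[[i]]
    if (!any(hit)) next
    hit <- hit & (if (rules$wildcard[i])
      startsWith(code, rules$code[i]) else code == rules$code[i])
    if (!any(hit)) next
    tie <- hit & best_spec == spec & !is.na(best_cat) &
      best_cat != rules$category[i]
    ambig <- ambig | tie
    upd <- hit & spec > best_spec
    best_cat[upd] <- rules$category[i]
    best_spec[upd] <- spec
  }
  if (any(ambig))
    stop("integrity error: ambiguous code resolution for ",
         sum(ambig), " event(s); validate the codebook")
  best_cat
}

#' Match one coded event against a rule set
#'
#' Resolves a (code system, code, source, age) tuple to its problem
#' category, or \code{NA} if no rule applies (unmapped codes are simply not
#' evidence of any problem). ICD-style hierarchical codes resolve by exact
#' match first, then the longest declared prefix; chemical IDs, DSM-IV,
#' activity and team codes are exact-match only. The function is pure and
#' deterministic; a tie between two categories at equal specificity raises
#' an integrity error, which \code{\link{validate_ruleset}} makes
#' impossible for a validated codebook.
#'
#' @param system code system token, one of \code{code_systems()}.
#' @param code code string as recorded in the source.
#' @param source source dataset token, one of \code{source_datasets()}.
#' @param age_years completed age at the event, 0-24.
#' @param rules a validated \code{code_ruleset}.
#' @return single category token or \code{NA_character_}.
#' @export
#' @examples
#' rules <- load_ruleset(exemplar_codebook_path())
#' match_event("CHEMICAL_ID", "fluoxetine", "PHARMS", 16, rules)
#' match_event("CHEMICAL_ID", "amitriptyline", "PHARMS", 12, rules)  # NA
#' match_event("CHEMICAL_ID", "amitriptyline", "PHARMS", 21, rules)
match_event <- function(system, code, source, age_years, rules) {
  stopifnot(length(system) == 1L, length(code) == 1L,
            length(source) == 1L, length(age_years) == 1L)
  if (age_years < 0 || age_years > 24)
    stop("age_years must be within 0..24")
  match_events_vec(system, code, source, as.integer(age_years), rules)
}

#' @export
print.code_ruleset <- function(x, ...) {
  cat("<code_ruleset> '", attr(x, "name"), "': ", nrow(x), " rules, ",
      length(unique(x$category)), " categories\n", sep = "")
  invisible(x)
}
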