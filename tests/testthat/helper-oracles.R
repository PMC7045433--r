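# Independent naive re-implementations used as oracles. These deliberately
# share no code with the package internals: plain loops, no vectorisation.

# Naive matcher: scan every rule, collect all hits, resolve exact over
# wildcard then longest prefix by explicit sort.
naive_match <- function(system, code, source, age, rules) {
  hits <- data.frame(cat = character(), spec = integer(),
                     stringsAsFactors = FALSE)
  for (i in seq_len(nrow(rules))) {
    if (rules$system[i] != system) next
    if (!source %in% rules$sources[[i]]) next
    if (age < rules$min_age[i] || age > rules$max_age[i]) next
    matched <- if (rules$wildcard[i])
      substr(code, 1, nchar(rules$code[i])) == rules$code[i]
    else code == rules$code[i]
    if (matched)
      hits <- rbind(hits, data.frame(
        cat = rules$category[i],
        spec = if (rules$wildcard[i]) nchar(rules$code[i]) else 9999L,
        stringsAsFactors = FALSE))
  }
  if (nrow(hits) == 0) return(NA_character_)
  hits <- hits[order(-hits$spec), , drop = FALSE]
  hits$cat[1]
}

# Naive per-(person, event, rule) identification: triple loop, no
# precedence. Returns a named list person_id -> list(ind = named 0/1,
# att = named list of source sets).
naive_identify <- function(events, roster, persons, rules, fy) {
  cats <- problem_categories()
  win <- fiscal_year_window(fy)
  out <- list()
  for (r in seq_len(nrow(events))) {
    e <- events[r, ]
    if (e$event_date < win[["start"]] || e$event_date > win[["end"]]) next
    if (!e$person_id %in% roster$members$person_id) next
    pi <- match(e$person_id, persons$person_id)
    if (is.na(pi)) next
    age <- age_at(persons$date_of_birth[pi], e$event_date)
    if (age < 0 || age > 24) next
    cc <- naive_match(e$system, e$code, e$source, age, rules)
    if (is.na(cc)) next
    if (is.null(out[[e$person_id]]))
      out[[e$person_id]] <- list(
        ind = stats::setNames(rep(0L, 13), cats),
        att = stats::setNames(vector("list", 13), cats))
    out[[e$person_id]]$ind[cc] <- 1L
    out[[e$person_id]]$att[[cc]] <-
      sort(unique(c(out[[e$person_id]]$att[[cc]], e$source)))
  }
  out
}

# Convert an indicator_set row into the naive structure for comparison.
indicator_row_as_naive <- function(v, i) {
  cats <- problem_categories()
  att <- lapply(cats, function(cc) {
    s <- v[[paste0("src_", cc)]][i]
    if (nzchar(s)) sort(strsplit(s, ";", fixed = TRUE)[[1]]) else NULL
  })
  list(ind = stats::setNames(as.integer(v[i, cats]), cats),
       att = stats::setNames(att, cats))
}

# Small helper: write a codebook data.frame to a temp TSV.
write_codebook <- function(df) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# All-zero indicator_set of n rows.
empty_ind <- function(n) {
  cats <- problem_categories()
  v <- data.frame(person_id = sprintf("P%d", seq_len(n)),
                  stringsAsFactors = FALSE)
  for (cc in cats) v[[cc]] <- rep(0L, n)
  for (cc in cats) v[[paste0("src_", cc)]] <- rep("", n)
  class(v) <- c("indicator_set", "data.frame")
  v
}

# Build a code_ruleset object without running validation (for testing
# validate_ruleset itself on invalid inputs).
load_ruleset_raw <- function(df) {
  rules <- data.frame(system = df$system, code = df$code,
                      wildcard = df$wildcard %in% c(1, "1", TRUE),
                      category = df$category,
                      min_age = as.integer(df$min_age),
                      max_age = as.integer(df$max_age),
                      note = df$note, stringsAsFactors = FALSE)
  rules$sources <- strsplit(df$sources, ";", fixed = TRUE)
  class(rules) <- c("code_ruleset", "data.frame")
  rules
}

codebook_row <- function(system, code, wildcard, category, min_age, max_age,
                         sources, note = "") {
  data.frame(system = system, code = code, wildcard = wildcard,
             category = category, min_age = min_age, max_age = max_age,
             sources = sources, note = note, stringsAsFactors = FALSE)
}

exemplar_rules <- function() load_ruleset(exemplar_codebook_path())

# Minimal roster with one adult-age person, reusable across tests.
tiny_roster <- function(ids = "P1", dob = "1998-01-15") {
  persons <- data.frame(person_id = ids,
                        date_of_birth = as.Date(dob),
                        sex = "F",
                        death_date = as.Date(NA),
                        stringsAsFactors = FALSE)
  list(persons = persons,
       overseas = data.frame(person_id = character(),
                             from = as.Date(character()),
                             to = as.Date(character())))
}

make_events <- function(person_id, date, code, system, source,
                        subtype = NA_character_, rank = "not_applicable") {
  data.frame(person_id = person_id, source = source, subtype = subtype,
             event_date = as.Date(date), code = code, system = system,
             rank = rank, stringsAsFactors = FALSE)
}
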