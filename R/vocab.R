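#' Problem categories, data sources, and code systems
#'
#' The case-identification method assigns coded events to 13 mental-health
#' and related problem categories. The first ten are "specific disorder"
#' groups; \code{self_harm}, \code{other_mh} and \code{mh_not_defined} play
#' distinct roles in reporting (self-harm sits outside the "any specific
#' problem" subtotal, and \code{mh_not_defined} is subject to the precedence
#' rule, see \code{\link{apply_precedence}}).
#'
#' @return \code{problem_categories()}: character vector of the 13 category
#'   tokens in canonical order. \code{specific_categories()}: the 10
#'   specific-disorder tokens.
#' @export
#' @examples
#' problem_categories()
problem_categories <- function() {
  c("anxiety", "depression", "emotional", "bipolar", "substance",
    "eating", "disruptive", "psychosis", "personality", "sleep",
    "self_harm", "other_mh", "mh_not_defined")
}

#' @rdname problem_categories
#' @export
specific_categories <- function() problem_categories()[1:10]

#' @rdname problem_categories
#' @export
source_datasets <- function() {
  c("PRIMHD", "NMDS", "PHARMS", "SOCRATES", "MORTALITY")
}

#' @rdname problem_categories
#' @export
code_systems <- function() {
  c("ICD10AM", "DSMIV", "CHEMICAL_ID", "ACTIVITY_TYPE", "TEAM_TYPE")
}

# code systems each source may carry (PRIMHD spans both subtypes)
admissible_systems <- function(source) {
  switch(source,
    PRIMHD    = c("ICD10AM", "DSMIV", "ACTIVITY_TYPE", "TEAM_TYPE"),
    NMDS      = "ICD10AM",
    PHARMS    = "CHEMICAL_ID",
    SOCRATES  = c("ICD10AM", "DSMIV"),
    MORTALITY = "ICD10AM",
    stop("unknown source dataset: ", source)
  )
}

#' Category-by-source support matrix
#'
#' Which data sources may identify each problem category. Cells not ticked
#' here are rejected at codebook validation and can never appear in an
#' attribution set. Hospital discharges (NMDS) contribute to every category;
#' mortality identifies suicide deaths (self-harm) only; eating problems are
#' identified from hospital and specialist mental-health diagnoses only.
#' The default encodes the method's published support pattern; pass a
#' modified copy to \code{\link{validate_ruleset}} to change it.
#'
#' @return Logical matrix, rows = \code{problem_categories()}, columns =
#'   \code{source_datasets()}.
#' @export
#' @examples
#' category_source_matrix()["eating", ]
category_source_matrix <- function() {
  cats <- problem_categories()
  srcs <- source_datasets()
  m <- matrix(FALSE, nrow = length(cats), ncol = length(srcs),
              dimnames = list(cats, srcs))
  tick <- function(cat, ...) m[cat, c(...)] <<- TRUE
  tick("anxiety",        "NMDS", "PRIMHD", "PHARMS", "SOCRATES")
  tick("depression",     "NMDS", "PRIMHD", "PHARMS", "SOCRATES")
  tick("emotional",      "NMDS", "PRIMHD", "PHARMS")
  tick("bipolar",        "NMDS", "PRIMHD", "PHARMS")
  tick("substance",      "NMDS", "PRIMHD", "PHARMS", "SOCRATES")
  tick("eating",         "NMDS", "PRIMHD")
  tick("disruptive",     "NMDS", "PRIMHD", "PHARMS", "SOCRATES")
  tick("psychosis",      "NMDS", "PRIMHD", "PHARMS", "SOCRATES")
  tick("personality",    "NMDS", "PRIMHD", "SOCRATES")
  tick("sleep",          "NMDS", "PRIMHD", "PHARMS")
  tick("self_harm",      "NMDS", "MORTALITY")
  tick("other_mh",       "NMDS", "PRIMHD")
  tick("mh_not_defined", "NMDS", "PRIMHD", "PHARMS")
  m
}

#' Canonical five-year age bands
#'
#' The reporting strata 0-4, 5-9, 10-14, 15-19 and 20-24, which partition
#' ages 0-24 with no gap or overlap.
#'
#' @param age_years integer vector of completed ages.
#' @return factor with levels \code{"0-4" ... "20-24"}; \code{NA} outside
#'   0-24.
#' @export
#' @examples
#' age_band(c(0, 4, 5, 24))
age_band <- function(age_years) {
  cut(age_years, breaks = c(-1, 4, 9, 14, 19, 24),
      labels = c("0-4", "5-9", "10-14", "15-19", "20-24"))
}

# closed best-quality date windows per source table; Socrates has no stated
# upper bound so a far-future sentinel is used
source_windows <- function() {
  w <- function(a, b) c(start = as.Date(a), end = as.Date(b))
  list(
    primhd_diagnosis = w("2008-07-01", "2016-12-31"),
    primhd_activity  = w("2008-07-01", "2018-06-30"),
    nmds             = w("1994-01-01", "2017-12-31"),
    pharms           = w("2007-01-01", "2017-12-31"),
    socrates         = w("2010-01-01", "9999-12-31"),
    mortality        = w("1988-01-01", "2015-12-31")
  )
}
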