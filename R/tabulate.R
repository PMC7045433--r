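#' Category-specific denominator age ranges
#'
#' Most categories are reported against the full 0-24 population; some are
#' reported against age-restricted denominators reflecting where the
#' disorder can plausibly be ascertained: substance and psychosis against
#' ages 10-24, bipolar against 15-24, and personality disorders against
#' 18-24. The mapping is configurable.
#'
#' @param category category token.
#' @param roster a \code{population_roster}.
#' @param mapping named list of \code{c(min, max)} overrides per category.
#' @return list with \code{count}, \code{min_age}, \code{max_age}.
#' @export
category_denominator <- function(category, roster,
                                 mapping = default_denominator_map()) {
  rng <- if (category %in% names(mapping)) mapping[[category]] else c(0L, 24L)
  list(count = roster_age_count(roster, rng[1], rng[2]),
       min_age = rng[1], max_age = rng[2])
}

#' @rdname category_denominator
#' @export
default_denominator_map <- function() {
  list(substance = c(10L, 24L), psychosis = c(10L, 24L),
       personality = c(18L, 24L), bipolar = c(15L, 24L))
}

#' Prevalence rate per 100,000
#'
#' @param count non-negative case count.
#' @param denominator positive population count.
#' @return integer rate: \code{count / denominator * 100000} rounded to
#'   the nearest whole number.
#' @export
#' @examples
#' rate_per_100k(5318, 100000)
rate_per_100k <- function(count, denominator) {
  if (any(denominator <= 0)) stop("denominator must be positive")
  as.integer(round(count / denominator * 1e5))
}

#' Raw category-by-source prevalence table
#'
#' For each of the 13 categories: the number of unique persons identified
#' from each source (a person identified by two sources counts once in
#' each source column), the unique total (persons with the indicator set),
#' the category-specific denominator, and the 12-month rate per 100,000.
#' Two summary rows follow: \code{sub_total_any} (any of the 10 specific
#' disorder groups) and \code{total_any} (any of the 13 categories).
#'
#' @param vectors an \code{indicator_set} with precedence applied.
#' @param roster the \code{population_roster} used as denominator.
#' @param denominator_map see \code{\link{category_denominator}}.
#' @return a \code{prevalence_table}: data.frame with one row per
#'   category plus the two totals; columns \code{category}, one count
#'   column per source, \code{total}, \code{denominator}, \code{age_range},
#'   \code{rate_per_100k}.
#' @export
count_table <- function(vectors, roster,
                        denominator_map = default_denominator_map()) {
  cats <- problem_categories()
  srcs <- source_datasets()
  rows <- vector("list", length(cats) + 2L)
  flags <- summarise_person(vectors)
  for (k in seq_along(cats)) {
    cc <- cats[k]
    on <- vectors[[cc]] == 1L
    att <- strsplit(vectors[[paste0("src_", cc)]][on], ";", fixed = TRUE)
    per_src <- vapply(srcs, function(s)
      sum(vapply(att, function(a) s %in% a, logical(1))), integer(1))
    den <- category_denominator(cc, roster, denominator_map)
    rows[[k]] <- data.frame(
      category = cc, t(per_src), total = sum(on),
      denominator = den$count,
      age_range = paste0(den$min_age, "-", den$max_age),
      rate_per_100k = if (den$count > 0) rate_per_100k(sum(on), den$count)
                      else NA_integer_,
      stringsAsFactors = FALSE)
  }
  den_all <- category_denominator("__all__", roster, denominator_map)
  for (nm in c("sub_total_any", "total_any")) {
    cset <- if (nm == "sub_total_any") specific_categories() else cats
    on <- rowSums(as.matrix(vectors[cset])) > 0
    per_src <- vapply(srcs, function(s) {
      hit <- rep(FALSE, nrow(vectors))
      for (cc in cset) {
        att <- strsplit(vectors[[paste0("src_", cc)]], ";", fixed = TRUE)
        hit <- hit | (vectors[[cc]] == 1L &
                        vapply(att, function(a) s %in% a, logical(1)))
      }
      sum(hit)
    }, integer(1))
    rows[[length(cats) + 1L + (nm == "total_any")]] <- data.frame(
      category = nm, t(per_src), total = sum(on),
      denominator = den_all$count, age_range = "0-24",
      rate_per_100k = if (den_all$count > 0) rate_per_100k(sum(on), den_all$count)
                      else NA_integer_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("prevalence_table", "data.frame")
  out
}

#' Graduated random rounding to base 3 (RR3)
#'
#' The statistical disclosure control used for official NZ count tables:
#' multiples of 3 are returned unchanged; any other count moves to the
#' nearer adjacent multiple of 3 with probability 2/3 and to the farther
#' one with probability 1/3. The scheme is unbiased
#' (\code{E[rr3(c)] = c}) and never returns a negative value. Vectorised;
#' consumes R's RNG stream, so wrap in \code{set.seed()} for
#' reproducibility.
#'
#' @param count non-negative integer vector.
#' @param p_nearer probability of rounding to the nearer multiple
#'   (default 2/3, the graduated unbiased convention).
#' @return integer vector of multiples of 3.
#' @export
#' @examples
#' set.seed(1); rr3(c(6, 7, 2))
rr3 <- function(count, p_nearer = 2 / 3) {
  count <- as.integer(count)
  if (any(count < 0)) stop("rr3: counts must be non-negative")
  rem <- count %% 3L
  lower <- count - rem
  nearer <- ifelse(rem == 1L, lower, lower + 3L)
  farther <- ifelse(rem == 1L, lower + 3L, lower)
  pick <- stats::runif(length(count)) < p_nearer
  out <- count
  moved <- rem != 0L
  out[moved] <- ifelse(pick[moved], nearer[moved], farther[moved])
  as.integer(out)
}

#' Confidentialised rendering of a prevalence table
#'
#' Produces the releasable twin of a raw \code{\link{count_table}}: every
#' nonzero count is randomly rounded to base 3, then replaced by the
#' suppression marker \code{"S"} if the \emph{raw} count is below the
#' threshold (default 6) — suppression is decided on raw values so
#' rounding can never rescue a small cell. Zero cells render blank,
#' mirroring the empty cells of official tables. Rates are computed from
#' the raw (unrounded) unique totals. The RNG seed used is recorded so an
#' identical seed reproduces the identical rendered table.
#'
#' @param table raw \code{prevalence_table}.
#' @param seed integer RNG seed for the random rounding.
#' @param threshold counts below this render as \code{"S"} (default 6).
#' @param rates_from_raw compute printed rates from raw totals (default
#'   \code{TRUE}).
#' @return list of class \code{rendered_prevalence_table}: \code{raw} (the
#'   input), \code{rendered} (character data.frame), \code{seed},
#'   \code{threshold}.
#' @export
render <- function(table, seed, threshold = 6L, rates_from_raw = TRUE) {
  srcs <- source_datasets()
  set.seed(seed)
  cell_cols <- c(srcs, "total")
  rendered <- data.frame(category = table$category,
                         stringsAsFactors = FALSE)
  for (col in cell_cols) {
    raw <- table[[col]]
    shown <- as.character(rr3(raw))
    shown[raw > 0L & raw < threshold] <- "S"
    shown[raw == 0L] <- ""
    rendered[[col]] <- shown
  }
  rendered$rate_per_100k <- if (rates_from_raw) {
    ifelse(is.na(table$rate_per_100k), "",
           as.character(table$rate_per_100k))
  } else {
    rr_tot <- suppressWarnings(as.integer(rendered$total))
    ifelse(is.na(rr_tot), "S",
           as.character(rate_per_100k(rr_tot, table$denominator)))
  }
  structure(list(raw = table, rendered = rendered, seed = seed,
                 threshold = as.integer(threshold)),
            class = "rendered_prevalence_table")
}

#' @export
print.rendered_prevalence_table <- function(x, ...) {
  cat("Confidentialised category x source counts (RR3, suppression < ",
      x$threshold, ", seed ", x$seed, ")\n", sep = "")
  print(x$rendered, row.names = FALSE)
  invisible(x)
}

#' Write a rendered prevalence table
#'
#' Writes the releasable table as tab-separated text and, alongside it, a
#' machine-readable JSON twin carrying the raw counts, denominators, seed
#' and suppression threshold.
#'
#' @param x a \code{rendered_prevalence_table}.
#' @param path output path for the delimited table; the JSON twin gets
#'   extension \code{.json}.
#' @export
write_prevalence <- function(x, path) {
  utils::write.table(x$rendered, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- list(seed = x$seed, threshold = x$threshold,
               raw = x$raw, rendered = x$rendered)
  jsonlite::write_json(meta, paste0(sub("\\.[a-z]+$", "", path), ".json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
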