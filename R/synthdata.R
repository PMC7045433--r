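#' Scenario configuration for the synthetic-data generator
#'
#' Defines a ground-truth world the pipeline can be run against: how many
#' persons, their age distribution, which fiscal year, the true prevalence
#' of each problem category, pairwise comorbidity, and the probability
#' that each data source captures a true case. Capture probabilities may
#' be nonzero only where \code{\link{category_source_matrix}} permits the
#' (category, source) pair.
#'
#' Defaults emulate the published application of the method: per-category
#' prevalences follow the reported per-100,000 rates, and capture
#' probabilities are set so the pharmaceutical collection is the largest
#' single source of identifications.
#'
#' @param n_persons number of persons to simulate.
#' @param fiscal_year fiscal-year label, default \code{"2014/15"}.
#' @param prevalence named vector of true prevalences over
#'   \code{problem_categories()} (missing names default to 0).
#' @param capture numeric matrix (category x source) of capture
#'   probabilities; default \code{default_capture_matrix()}.
#' @param comorbidity data.frame \code{cat1, cat2, odds_multiplier}:
#'   having \code{cat1} multiplies the odds of \code{cat2} (applied
#'   sequentially in canonical category order); default none.
#' @param events_per_case_mean mean number of events emitted per captured
#'   (person, category, source); geometric, minimum 1. Default 2.
#' @param age_weights sampling weights over completed ages 0..24 at the
#'   reference date; default uniform.
#' @param death_rate fraction of persons assigned a death before the
#'   window start (exercises denominator exclusion). Default 0.
#' @param overseas_rate fraction assigned an overseas interval covering
#'   the whole window. Default 0.
#' @param noise_unmapped expected unmapped (non-codebook) events per
#'   person; default 0.
#' @param noise_outwindow expected out-of-window events per person
#'   (dropped at ingest); default 0.
#' @param seed integer RNG seed; recorded in every output.
#' @return validated list of class \code{scenario_config}.
#' @export
scenario_config <- function(n_persons,
                            fiscal_year = "2014/15",
                            prevalence = default_prevalence(),
                            capture = default_capture_matrix(),
                            comorbidity = NULL,
                            events_per_case_mean = 2,
                            age_weights = rep(1, 25),
                            death_rate = 0,
                            overseas_rate = 0,
                            noise_unmapped = 0,
                            noise_outwindow = 0,
                            seed = 1L) {
  cats <- problem_categories()
  pi_c <- stats::setNames(rep(0, 13), cats)
  pi_c[names(prevalence)] <- prevalence
  if (any(pi_c < 0 | pi_c > 1)) stop("prevalences must lie in [0, 1]")
  tab1 <- category_source_matrix()
  full <- matrix(0, 13, 5, dimnames = dimnames(tab1))
  full[rownames(capture), colnames(capture)] <- capture
  if (any(full < 0 | full > 1)) stop("capture probabilities must lie in [0, 1]")
  off <- full > 0 & !tab1
  if (any(off))
    stop("capture probability set for unsupported (category, source) cell(s): ",
         paste(apply(which(off, arr.ind = TRUE), 1, function(ix)
       paste0(rownames(tab1)[ix[1]], "/", colnames(tab1)[ix[2]])),
       collapse = ", "))
  fiscal_year_window(fiscal_year)   # validates the label
  stopifnot(n_persons >= 1, events_per_case_mean >= 1,
            length(age_weights) == 25, all(age_weights >= 0),
            death_rate >= 0, death_rate <= 1,
            overseas_rate >= 0, overseas_rate <= 1)
  if (!is.null(comorbidity))
    stopifnot(all(c("cat1", "cat2", "odds_multiplier") %in% names(comorbidity)),
              all(comorbidity$cat1 %in% cats), all(comorbidity$cat2 %in% cats))
  structure(list(
    n_persons = as.integer(n_persons), fiscal_year = fiscal_year,
    prevalence = pi_c, capture = full, comorbidity = comorbidity,
    events_per_case_mean = events_per_case_mean,
    age_weights = age_weights / sum(age_weights),
    death_rate = death_rate, overseas_rate = overseas_rate,
    noise_unmapped = noise_unmapped, noise_outwindow = noise_outwindow,
    seed = as.integer(seed)
  ), class = "scenario_config")
}

#' @rdname scenario_config
#' @export
default_prevalence <- function() {
  # per-category 12-month identified-prevalence proportions of the kind
  # reported for linked NZ administrative data (rates per 100k / 1e5)
  c(anxiety = 0.0068, depression = 0.0067, emotional = 0.0202,
    bipolar = 0.00065, substance = 0.0174, eating = 0.00076,
    disruptive = 0.0089, psychosis = 0.0020, personality = 0.0012,
    sleep = 0.0062, self_harm = 0.00186, other_mh = 0.00074,
    mh_not_defined = 0.0065)
}

#' @rdname scenario_config
#' @export
default_capture_matrix <- function() {
  tab1 <- category_source_matrix()
  base <- c(PRIMHD = 0.35, NMDS = 0.12, PHARMS = 0.70,
            SOCRATES = 0.03, MORTALITY = 0.02)
  m <- matrix(rep(base, each = nrow(tab1)), nrow = nrow(tab1),
              dimnames = dimnames(tab1))
  m[!tab1] <- 0
  # self-harm is ascertained almost entirely from hospital discharges
  m["self_harm", "NMDS"] <- 0.90
  m
}

# date of birth uniform within the year of completed age `a` at `ref`
dob_for_age <- function(a, ref, n) {
  hi <- seq(ref, by = paste0("-", a, " years"), length.out = 2)[2]
  lo <- seq(ref, by = paste0("-", a + 1, " years"), length.out = 2)[2] + 1
  lo + sample.int(as.integer(hi - lo) + 1L, n, replace = TRUE) - 1L
}

# synthetic code for a rule: expand wildcard ICD prefixes into full codes
code_for_rule <- function(rules, i) {
  if (!rules$wildcard[i]) return(rules$code[i])
  p <- rules$code[i]
  if (nchar(p) == 2L)
    paste0(p, sample(0:9, 1), ".", sample(0:9, 1))
  else
    paste0(p, ".", sample(0:9, 1))
}

#' Generate a synthetic roster and source event files with ground truth
#'
#' Draws true category statuses per person from the prevalence/comorbidity
#' model, then lets each permitted source capture each true (person,
#' category) with its capture probability, emitting events whose codes are
#' sampled from the codebook's rules for that category and source, dated
#' uniformly inside the fiscal-year window. Codes respect the codebook's
#' age restrictions: if no rule for the (category, source) covers the
#' person's age on the sampled date, that source does not capture the
#' person. Mortality captures additionally set the person's death date
#' (deaths during the window keep the person in the denominator).
#'
#' All output is plain delimited text; identical configurations (including
#' seed) produce byte-identical files.
#'
#' @param config a \code{\link{scenario_config}}.
#' @param dir output directory (created if needed).
#' @param rules codebook used for code emission; default the exemplar.
#' @return invisible list with file paths (\code{roster}, one per source
#'   table, \code{ground_truth}, \code{scenario}) and the in-memory
#'   \code{truth} matrix.
#' @export
generate <- function(config, dir, rules = load_ruleset(exemplar_codebook_path())) {
  stopifnot(inherits(config, "scenario_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  cats <- problem_categories()
  win <- fiscal_year_window(config$fiscal_year)
  ref <- win[["start"]]
  n <- config$n_persons

  ids <- sprintf("P%06d", seq_len(n))
  ages <- sample(0:24, n, replace = TRUE, prob = config$age_weights)
  dob <- as.Date(rep(NA_integer_, n), origin = "1970-01-01")
  for (a in unique(ages)) {
    at <- ages == a
    dob[at] <- dob_for_age(a, ref, sum(at))
  }
  sex <- sample(c("F", "M"), n, replace = TRUE)

  # exclusion flags: death before window, overseas covering the window
  dead_before <- stats::runif(n) < config$death_rate
  away <- !dead_before & stats::runif(n) < config$overseas_rate
  death_date <- as.Date(rep(NA_integer_, n), origin = "1970-01-01")
  death_date[dead_before] <- win[["start"]] -
    sample.int(365L, sum(dead_before), replace = TRUE)
  eligible <- !dead_before & !away

  # ground truth: sequential draws with pairwise odds multipliers
  truth <- matrix(FALSE, n, 13, dimnames = list(ids, cats))
  for (cc in cats) {
    p <- config$prevalence[[cc]]
    if (p <= 0) next
    odds <- rep(p / (1 - p), n)
    cm <- config$comorbidity
    if (!is.null(cm)) {
      for (r in which(cm$cat2 == cc)) {
        prior <- truth[, cm$cat1[r]]
        odds[prior] <- odds[prior] * cm$odds_multiplier[r]
      }
    }
    truth[, cc] <- stats::runif(n) < odds / (1 + odds)
  }
  truth[!eligible, ] <- FALSE   # truth is defined over the study population

  ev <- list(primhd_diagnosis = list(), primhd_activity = list(),
             nmds = list(), pharms = list(), socrates = list(),
             mortality = list())
  p_mean <- config$events_per_case_mean
  swin <- source_windows()
  schema_of <- function(source, system) {
    if (source == "PRIMHD")
      if (system %in% c("ACTIVITY_TYPE", "TEAM_TYPE")) "primhd_activity"
      else "primhd_diagnosis"
    else tolower(source)
  }
  # age at window start, and the in-window birthday (NA if none)
  a0 <- age_at(dob, win[["start"]])
  bday <- as.Date(vapply(seq_len(n), function(i)
    as.integer(seq(dob[i], by = paste0(a0[i] + 1L, " years"),
                   length.out = 2)[2]),
    integer(1)), origin = "1970-01-01")
  bday[bday > win[["end"]]] <- NA
  for (cc in cats) {
    true_i <- which(truth[, cc])
    if (!length(true_i)) next
    for (src in source_datasets()) {
      p_cs <- config$capture[cc, src]
      if (p_cs <= 0) next
      cap_i <- true_i[stats::runif(length(true_i)) < p_cs]
      cand <- which(rules$category == cc &
                      vapply(rules$sources, function(s) src %in% s, logical(1)))
      if (!length(cand)) next
      for (i in cap_i) {
        # rules usable at the person's age(s) during the window
        ok0 <- cand[rules$min_age[cand] <= a0[i] & rules$max_age[cand] >= a0[i]]
        ok1 <- if (!is.na(bday[i]))
          cand[rules$min_age[cand] <= a0[i] + 1L &
                 rules$max_age[cand] >= a0[i] + 1L]
        else integer(0)
        usable <- union(ok0, ok1)
        if (!length(usable)) next   # age-uncapturable by this source
        n_ev <- 1L + stats::rgeom(1L, prob = 1 / p_mean)
        for (k in seq_len(n_ev)) {
          ri <- if (length(usable) == 1L) usable else sample(usable, 1L)
          sch <- schema_of(src, rules$system[ri])
          # date range where the rule's age restriction holds, clipped to
          # the source table's best-quality window
          lo <- if (ri %in% ok0) win[["start"]] else bday[i]
          hi <- if (ri %in% ok1 || is.na(bday[i])) win[["end"]] else bday[i] - 1L
          lo <- max(lo, swin[[sch]][["start"]])
          hi <- min(hi, swin[[sch]][["end"]])
          if (lo > hi) next
          d <- lo + sample.int(as.integer(hi - lo) + 1L, 1L) - 1L
          if (src == "MORTALITY") {
            death_date[i] <- d
            ev$mortality[[length(ev$mortality) + 1L]] <-
              c(ids[i], format(d), code_for_rule(rules, ri))
            break                   # one death event at most
          }
          row <- switch(sch,
            primhd_diagnosis = c(ids[i], format(d), code_for_rule(rules, ri),
                                 rules$system[ri],
                                 sample(c("primary", "secondary"), 1,
                                        prob = c(0.7, 0.3))),
            primhd_activity = c(ids[i], format(d), code_for_rule(rules, ri),
                                rules$system[ri]),
            nmds = c(ids[i], format(d), code_for_rule(rules, ri),
                     sample(c("primary", "secondary"), 1, prob = c(0.7, 0.3))),
            pharms = c(ids[i], format(d), code_for_rule(rules, ri)),
            socrates = c(ids[i], format(d), code_for_rule(rules, ri),
                         rules$system[ri]))
          ev[[sch]][[length(ev[[sch]]) + 1L]] <- row
        }
      }
    }
  }

  # optional noise: unmapped codes and out-of-window dispensings
  if (config$noise_unmapped > 0) {
    n_noise <- stats::rpois(1, config$noise_unmapped * n)
    if (n_noise > 0) {
      who <- sample.int(n, n_noise, replace = TRUE)
      d <- win[["start"]] +
        sample.int(as.integer(win[["end"]] - win[["start"]]) + 1L, n_noise,
                   replace = TRUE) - 1L
      for (k in seq_len(n_noise))
        ev$nmds[[length(ev$nmds) + 1L]] <-
          c(ids[who[k]], format(d[k]), "Z99.9", "primary")
    }
  }
  if (config$noise_outwindow > 0) {
    n_noise <- stats::rpois(1, config$noise_outwindow * n)
    if (n_noise > 0) {
      who <- sample.int(n, n_noise, replace = TRUE)
      for (k in seq_len(n_noise))
        ev$pharms[[length(ev$pharms) + 1L]] <-
          c(ids[who[k]], "2006-05-01", "fluoxetine")
    }
  }

  # write everything
  schemas <- source_schemas()
  paths <- list()
  for (sch in names(ev)) {
    cols <- schemas[[sch]]$columns
    df <- if (length(ev[[sch]]))
      stats::setNames(as.data.frame(do.call(rbind, ev[[sch]]),
                                    stringsAsFactors = FALSE), cols)
    else stats::setNames(as.data.frame(matrix(character(), 0, length(cols)),
                                       stringsAsFactors = FALSE), cols)
    paths[[sch]] <- file.path(dir, paste0(sch, ".tsv"))
    utils::write.table(df, paths[[sch]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  roster <- data.frame(
    record_type = "person", person_id = ids,
    date_of_birth = format(dob), sex = sex,
    death_date = ifelse(is.na(death_date), "", format(death_date)),
    overseas_from = "", overseas_to = "", stringsAsFactors = FALSE)
  if (any(away)) {
    roster <- rbind(roster, data.frame(
      record_type = "overseas", person_id = ids[away],
      date_of_birth = "", sex = "", death_date = "",
      overseas_from = format(win[["start"]] - 30),
      overseas_to = format(win[["end"]] + 30), stringsAsFactors = FALSE))
  }
  paths$roster <- file.path(dir, "roster.tsv")
  utils::write.table(roster, paths$roster, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ti <- which(truth, arr.ind = TRUE)
  gt <- data.frame(person_id = ids[ti[, 1]], category = cats[ti[, 2]],
                   true_flag = rep(1L, nrow(ti)), stringsAsFactors = FALSE)
  gt <- gt[order(gt$person_id, gt$category), , drop = FALSE]
  paths$ground_truth <- file.path(dir, "ground_truth.tsv")
  utils::write.table(gt, paths$ground_truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths$scenario <- file.path(dir, "scenario.json")
  jsonlite::write_json(
    list(seed = config$seed, n_persons = config$n_persons,
         fiscal_year = config$fiscal_year,
         prevalence = as.list(config$prevalence)),
    paths$scenario, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, list(truth = truth)))
}

#' Compare identified cases against synthetic ground truth
#'
#' Per-category sensitivity of the identification pipeline on a generated
#' scenario: the fraction of true cases that carry the indicator, the
#' undercount fraction (1 - sensitivity), and the number of false-positive
#' identifications. Without injected noise the pipeline can only identify
#' persons who truly have the category, so false positives must be zero.
#'
#' @param ground_truth_path \code{ground_truth.tsv} from
#'   \code{\link{generate}}.
#' @param indicators an \code{indicator_set}, or a path to one written by
#'   \code{\link{write_indicators}}.
#' @return data.frame with one row per category: \code{category},
#'   \code{true_n}, \code{identified_n}, \code{identified_true},
#'   \code{sensitivity}, \code{undercount}, \code{false_positives}.
#' @export
evaluate_recovery <- function(ground_truth_path, indicators) {
  gt <- utils::read.delim(ground_truth_path, stringsAsFactors = FALSE,
                          colClasses = c("character", "character", "integer"))
  v <- if (is.character(indicators)) read_indicators(indicators) else indicators
  rows <- lapply(problem_categories(), function(cc) {
    true_ids <- gt$person_id[gt$category == cc & gt$true_flag == 1L]
    id_ids <- v$person_id[v[[cc]] == 1L]
    tp <- sum(id_ids %in% true_ids)
    data.frame(category = cc, true_n = length(true_ids),
               identified_n = length(id_ids), identified_true = tp,
               sensitivity = if (length(true_ids)) tp / length(true_ids) else NA_real_,
               undercount = if (length(true_ids)) 1 - tp / length(true_ids) else NA_real_,
               false_positives = length(id_ids) - tp,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
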