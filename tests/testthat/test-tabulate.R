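roster_of_ages <- function(ages, fy = "2014/15") {
  ref <- fiscal_year_window(fy)[["start"]]
  persons <- data.frame(
    person_id = sprintf("P%04d", seq_along(ages)),
    date_of_birth = ref - (ages * 365L + 100L),
    sex = "F", death_date = as.Date(NA), stringsAsFactors = FALSE)
  build_population(persons, fy)
}

test_that("per-source counts, unique totals and overlap behave like set cardinalities", {
  pop <- roster_of_ages(rep(12, 10))
  v <- empty_ind(10)
  v$person_id <- pop$members$person_id
  # one person with anxiety from two sources counts once in the total
  v$anxiety[1] <- 1L; v$src_anxiety[1] <- "NMDS;PHARMS"
  v$anxiety[2] <- 1L; v$src_anxiety[2] <- "PHARMS"
  v$self_harm[3] <- 1L; v$src_self_harm[3] <- "NMDS"
  tab <- count_table(v, pop)
  anx <- tab[tab$category == "anxiety", ]
  expect_identical(anx$PHARMS, 2L)
  expect_identical(anx$NMDS, 1L)
  expect_identical(anx$total, 2L)
  expect_identical(tab[tab$category == "sub_total_any", "total"], 2L)
  expect_identical(tab[tab$category == "total_any", "total"], 3L)
  # raw unique total bounded by per-source counts
  srcs <- source_datasets()
  for (i in seq_len(nrow(tab))) {
    expect_lte(tab$total[i], sum(unlist(tab[i, srcs])))
    expect_gte(tab$total[i], max(unlist(tab[i, srcs])))
  }
})

test_that("count_table equals an independent set-counting oracle on a synthetic cohort", {
  rules <- exemplar_rules()
  cfg <- scenario_config(n_persons = 800, seed = 271)
  dir <- tempfile()
  generate(cfg, dir)
  ros <- read_roster(file.path(dir, "roster.tsv"))
  pop <- build_population(ros, "2014/15")
  ing <- read_event_dir(dir)
  v <- identify(ing$events, pop, ros$persons, rules, "2014/15")
  tab <- count_table(v, pop)
  for (cc in problem_categories()) {
    row <- tab[tab$category == cc, ]
    ids_oracle <- character(0)
    per_src_oracle <- stats::setNames(integer(5), source_datasets())
    for (i in seq_len(nrow(v))) {
      if (v[[cc]][i] == 1L) {
        ids_oracle <- c(ids_oracle, v$person_id[i])
        for (s in strsplit(v[[paste0("src_", cc)]][i], ";")[[1]])
          per_src_oracle[s] <- per_src_oracle[s] + 1L
      }
    }
    expect_identical(row$total, length(ids_oracle))
    for (s in source_datasets())
      expect_identical(row[[s]], per_src_oracle[[s]], label = paste(cc, s))
  }
})

test_that("zero identified persons give an all-zero table", {
  pop <- roster_of_ages(rep(10, 5))
  tab <- count_table(empty_ind(0), pop)
  expect_true(all(tab$total == 0L))
  # rates are zero wherever the age-restricted denominator is non-empty
  expect_true(all(tab$rate_per_100k[tab$denominator > 0] == 0L))
})

test_that("category-specific denominators follow the age-restricted mapping", {
  pop <- roster_of_ages(c(2, 8, 12, 16, 21, 23))
  expect_identical(category_denominator("anxiety", pop)$count, 6L)
  d_sub <- category_denominator("substance", pop)
  expect_identical(c(d_sub$min_age, d_sub$max_age), c(10L, 24L))
  expect_identical(d_sub$count, 4L)
  expect_identical(category_denominator("psychosis", pop)$count, 4L)
  expect_identical(category_denominator("bipolar", pop)$count, 3L)   # 15-24
  expect_identical(category_denominator("personality", pop)$count, 2L) # 18-24
})

test_that("rate_per_100k rounds to integers and rejects a zero denominator", {
  expect_identical(rate_per_100k(0, 1e6), 0L)
  expect_identical(rate_per_100k(50, 1e6), 5L)
  expect_identical(rate_per_100k(5318, 1e5), 5318L)
  expect_error(rate_per_100k(1, 0), "positive")
})

test_that("rr3 has the exact two-outcome unbiased distribution", {
  # analytic check for every count 0..1000: support = adjacent multiples
  # of 3, expectation = the count itself
  for (cc in 0:1000) {
    rem <- cc %% 3
    if (rem == 0) {
      expect_identical(unique(replicate(3, rr3(cc))), cc)
    } else {
      lower <- cc - rem
      nearer <- if (rem == 1) lower else lower + 3
      farther <- if (rem == 1) lower + 3 else lower
      ev <- 2 / 3 * nearer + 1 / 3 * farther
      expect_equal(ev, cc)
      expect_true(abs(nearer - cc) == 1 && abs(farther - cc) == 2)
    }
  }
  # outputs are always non-negative multiples of 3
  set.seed(31)
  out <- rr3(sample(0:100, 5000, replace = TRUE))
  expect_true(all(out %% 3 == 0))
  expect_true(all(out >= 0))
  expect_identical(rr3(c(0L, 6L, 9L)), c(0L, 6L, 9L))
})

test_that("rr3 empirical frequencies match 2/3-1/3 within Monte-Carlo error", {
  set.seed(1001)
  n <- 1e5
  draws7 <- rr3(rep(7L, n))
  expect_setequal(unique(draws7), c(6L, 9L))
  p6 <- mean(draws7 == 6L)
  se <- sqrt(2 / 3 * 1 / 3 / n)
  expect_lt(abs(p6 - 2 / 3), 3 * se)
  expect_lt(abs(mean(draws7) - 7), 3 * sd(draws7) / sqrt(n))
  draws2 <- rr3(rep(2L, n))
  expect_setequal(unique(draws2), c(0L, 3L))
  expect_lt(abs(mean(draws2) - 2), 3 * sd(draws2) / sqrt(n))
})

test_that("rendering rounds, suppresses on raw values, and reproduces under a seed", {
  pop <- roster_of_ages(rep(12, 40))
  v <- empty_ind(40)
  v$person_id <- pop$members$person_id
  v$anxiety[1:5] <- 1L;  v$src_anxiety[1:5] <- "PHARMS"   # raw 5 -> S
  v$depression[1:6] <- 1L; v$src_depression[1:6] <- "NMDS" # raw 6 -> 6
  v$sleep[1:8] <- 1L; v$src_sleep[1:8] <- "PHARMS"         # raw 8 -> 6 or 9
  tab <- count_table(v, pop)
  rt <- render(tab, seed = 42)
  r <- rt$rendered
  expect_identical(r[r$category == "anxiety", "total"], "S")
  expect_identical(r[r$category == "depression", "total"], "6")
  expect_true(r[r$category == "sleep", "total"] %in% c("6", "9"))
  # zero cells are blank; every numeric cell is a multiple of 3
  expect_identical(r[r$category == "eating", "total"], "")
  cells <- unlist(r[c(source_datasets(), "total")])
  nums <- suppressWarnings(as.integer(cells[cells != "" & cells != "S"]))
  expect_true(all(nums %% 3 == 0))
  # rates come from raw counts, not rounded ones
  expect_identical(r[r$category == "sleep", "rate_per_100k"],
                   as.character(rate_per_100k(8, 40)))
  # identical seed, identical table; different seed may differ
  expect_identical(render(tab, seed = 42)$rendered, r)
  # rendered total differs from raw by at most 2
  raw_tot <- tab[tab$category == "total_any", "total"]
  shown <- as.integer(r[r$category == "total_any", "total"])
  expect_lte(abs(shown - raw_tot), 2)
})

test_that("suppression marker appears iff the raw count is in 1..threshold-1", {
  pop <- roster_of_ages(rep(12, 30))
  for (raw in c(1L, 2L, 5L, 6L, 7L, 0L)) {
    v <- empty_ind(30)
    v$person_id <- pop$members$person_id
    if (raw > 0) {
      v$anxiety[seq_len(raw)] <- 1L
      v$src_anxiety[seq_len(raw)] <- "PHARMS"
    }
    rt <- render(count_table(v, pop), seed = 9)
    cell <- rt$rendered[rt$rendered$category == "anxiety", "total"]
    if (raw == 0) expect_identical(cell, "")
    else if (raw < 6) expect_identical(cell, "S")
    else expect_false(cell %in% c("S", ""))
  }
})
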