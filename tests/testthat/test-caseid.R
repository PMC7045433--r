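test_that("a single qualifying dispensing identifies the person; duplicates are idempotent", {
  rules <- exemplar_rules()
  ros <- tiny_roster("P1", "1998-01-15")   # age 16 at 2014-07-01
  pop <- build_population(ros, "2014/15")
  ev1 <- make_events("P1", "2014-09-10", "fluoxetine", "CHEMICAL_ID", "PHARMS")
  v1 <- identify(ev1, pop, ros$persons, rules, "2014/15")
  expect_identical(nrow(v1), 1L)
  expect_identical(v1$emotional, 1L)
  expect_identical(v1$src_emotional, "PHARMS")
  expect_identical(sum(as.matrix(v1[problem_categories()])), 1L)
  # the same dispensing duplicated 10 times changes nothing
  v10 <- identify(ev1[rep(1, 10), ], pop, ros$persons, rules, "2014/15")
  expect_identical(v10, v1)
})

test_that("age at the event date (not the reference date) drives rule matching", {
  rules <- exemplar_rules()
  # born 1994-12-01: 19 at window start, turns 20 on 2014-12-01
  ros <- tiny_roster("P1", "1994-12-01")
  pop <- build_population(ros, "2014/15")
  before <- make_events("P1", "2014-11-30", "amitriptyline", "CHEMICAL_ID", "PHARMS")
  after <- make_events("P1", "2014-12-01", "amitriptyline", "CHEMICAL_ID", "PHARMS")
  expect_identical(nrow(identify(before, pop, ros$persons, rules, "2014/15")), 0L)
  v <- identify(after, pop, ros$persons, rules, "2014/15")
  expect_identical(v$depression, 1L)
})

test_that("events outside the fiscal year or for non-roster persons are ignored", {
  rules <- exemplar_rules()
  ros <- tiny_roster("P1")
  pop <- build_population(ros, "2014/15")
  ev <- make_events(c("P1", "P1", "GHOST"),
                    c("2014-06-30", "2014-07-01", "2014-07-01"),
                    "fluoxetine", "CHEMICAL_ID", "PHARMS")
  v <- identify(ev, pop, ros$persons, rules, "2014/15")
  expect_identical(v$person_id, "P1")
  expect_identical(v$src_emotional, "PHARMS")
})

test_that("precedence zeroes mh_not_defined only against the knock-out set", {
  v <- empty_ind(3)
  v$person_id <- c("A", "B", "C")
  v$mh_not_defined[] <- 1L
  v$anxiety[1] <- 1L        # A: knocked out
  v$self_harm[2] <- 1L      # B: self-harm exempt, retained
  out <- apply_precedence(v)
  expect_identical(out$mh_not_defined, c(0L, 1L, 1L))
  expect_identical(out$anxiety, v$anxiety)
  # other_mh participates by default but is configurable
  v2 <- empty_ind(1)
  v2$mh_not_defined <- 1L
  v2$other_mh <- 1L
  expect_identical(apply_precedence(v2)$mh_not_defined, 0L)
  expect_identical(
    apply_precedence(v2, specific_set = specific_categories())$mh_not_defined,
    1L)
  expect_error(apply_precedence(v2, specific_set = c("anxiety", "self_harm")),
               "exclude self_harm")
})

test_that("precedence safety holds over random indicator vectors", {
  set.seed(99)
  n <- 500
  v <- empty_ind(n)
  v$person_id <- sprintf("P%03d", 1:n)
  for (cc in problem_categories())
    v[[cc]] <- rbinom(n, 1, 0.3)
  out <- apply_precedence(v)
  spec <- c(specific_categories(), "other_mh")
  conj <- out$mh_not_defined == 1L &
    rowSums(as.matrix(out[spec])) > 0
  expect_false(any(conj))
  # all other indicators unchanged
  for (cc in setdiff(problem_categories(), "mh_not_defined"))
    expect_identical(out[[cc]], v[[cc]])
})

test_that("summary flags: self-harm contributes to any_problem but not any_specific", {
  v <- empty_ind(3)
  v$person_id <- c("A", "B", "C")
  v$anxiety[1] <- 1L
  v$self_harm[2] <- 1L
  s <- summarise_person(v)
  expect_identical(s$any_specific, c(1L, 0L, 0L))
  expect_identical(s$any_problem, c(1L, 1L, 0L))
})

test_that("identify matches the naive per-(person,event,rule) oracle on 500 scripted persons", {
  rules <- exemplar_rules()
  cfg <- scenario_config(n_persons = 500, seed = 314,
                         noise_unmapped = 0.05)
  dir <- tempfile()
  generate(cfg, dir)
  ros <- read_roster(file.path(dir, "roster.tsv"))
  pop <- build_population(ros, "2014/15")
  ing <- read_event_dir(dir)
  v <- identify(ing$events, pop, ros$persons, rules, "2014/15",
                precedence = FALSE)
  oracle <- naive_identify(ing$events, pop, ros$persons, rules, "2014/15")
  expect_setequal(v$person_id, names(oracle))
  for (i in seq_len(nrow(v))) {
    got <- indicator_row_as_naive(v, i)
    want <- oracle[[v$person_id[i]]]
    expect_identical(got$ind, want$ind)
    expect_identical(got$att[!vapply(got$att, is.null, logical(1))],
                     want$att[!vapply(want$att, is.null, logical(1))])
  }
})

test_that("event order never changes the identification output", {
  rules <- exemplar_rules()
  cfg <- scenario_config(n_persons = 200, seed = 2718)
  dir <- tempfile()
  generate(cfg, dir)
  ros <- read_roster(file.path(dir, "roster.tsv"))
  pop <- build_population(ros, "2014/15")
  ing <- read_event_dir(dir)
  v1 <- identify(ing$events, pop, ros$persons, rules, "2014/15")
  set.seed(5)
  shuffled <- ing$events[sample.int(nrow(ing$events)), ]
  v2 <- identify(shuffled, pop, ros$persons, rules, "2014/15")
  rownames(v2) <- NULL
  expect_identical(v1, v2)
})

test_that("adding an event never flips an indicator off (pre-precedence)", {
  rules <- exemplar_rules()
  cfg <- scenario_config(n_persons = 200, seed = 1234)
  dir <- tempfile()
  generate(cfg, dir)
  ros <- read_roster(file.path(dir, "roster.tsv"))
  pop <- build_population(ros, "2014/15")
  ing <- read_event_dir(dir)
  v1 <- identify(ing$events, pop, ros$persons, rules, "2014/15",
                 precedence = FALSE)
  extra <- make_events(pop$members$person_id[1], "2014-10-01",
                       "fluoxetine", "CHEMICAL_ID", "PHARMS")
  v2 <- identify(rbind(ing$events, extra), pop, ros$persons, rules, "2014/15",
                 precedence = FALSE)
  for (i in seq_len(nrow(v1))) {
    j <- match(v1$person_id[i], v2$person_id)
    expect_false(is.na(j))
    for (cc in problem_categories())
      expect_gte(v2[[cc]][j], v1[[cc]][i])
  }
  s1 <- summarise_person(v1); s2 <- summarise_person(v2)
  expect_gte(sum(s2$any_problem), sum(s1$any_problem))
})

test_that("attribution sets only ever contain sources the matrix permits", {
  rules <- exemplar_rules()
  cfg <- scenario_config(n_persons = 1000, seed = 161)
  dir <- tempfile()
  generate(cfg, dir)
  ros <- read_roster(file.path(dir, "roster.tsv"))
  pop <- build_population(ros, "2014/15")
  ing <- read_event_dir(dir)
  v <- identify(ing$events, pop, ros$persons, rules, "2014/15")
  tab1 <- category_source_matrix()
  for (cc in problem_categories()) {
    srcs <- unique(unlist(strsplit(v[[paste0("src_", cc)]], ";", fixed = TRUE)))
    srcs <- srcs[nzchar(srcs)]
    expect_true(all(tab1[cc, srcs]), label = paste("attribution for", cc))
  }
})

test_that("indicator files round-trip through write/read", {
  rules <- exemplar_rules()
  ros <- tiny_roster("P1")
  pop <- build_population(ros, "2014/15")
  ev <- make_events("P1", "2014-09-10", "fluoxetine", "CHEMICAL_ID", "PHARMS")
  v <- identify(ev, pop, ros$persons, rules, "2014/15")
  p <- tempfile(fileext = ".tsv")
  write_indicators(v, p)
  v2 <- read_indicators(p)
  expect_identical(v2$person_id, v$person_id)
  expect_identical(v2$emotional, v$emotional)
  expect_identical(v2$src_emotional, v$src_emotional)
})
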