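# Table reading, outlier trimming, and the exclusion cascade.

write_tiny_tables <- function(vitals, stays, dir = tempfile()) {
  dir.create(dir)
  vp <- file.path(dir, "vitals.csv"); sp <- file.path(dir, "stays.csv")
  write.csv(vitals, vp, row.names = FALSE)
  write.csv(stays, sp, row.names = FALSE)
  list(vitals = vp, stays = sp)
}

tiny_stays <- function(n = 2) {
  data.frame(stay_id = seq_len(n), hospital_id = 1L, age = 60,
             gender = "male", bmi = 28,
             admit_time = "2014-03-01T10:00:00Z",
             discharge_time = "2014-03-04T10:00:00Z",
             icu_mortality = 0L, hospital_mortality = 0L)
}

test_that("tables are read, grouped per stay and sorted by time", {
  v <- data.frame(stay_id = rep(c(2L, 1L), each = 5),
                  clock_time = rep(c("2014-03-01T10:05:00Z",
                                     "2014-03-01T10:00:00Z",
                                     "2014-03-01T10:10:00Z",
                                     "2014-03-01T10:15:00Z",
                                     "2014-03-01T10:20:00Z"), 2),
                  heart_rate = 60:69)
  p <- write_tiny_tables(v, tiny_stays())
  rt <- read_tables(p$vitals, p$stays)
  expect_equal(nrow(rt$vitals), 10)
  expect_equal(length(unique(rt$vitals$stay_id)), 2)
  expect_true(all(diff(rt$vitals$t_min[rt$vitals$stay_id == 1]) > 0))
})

test_that("duplicate timestamps collapse to their mean with a warning", {
  v <- data.frame(stay_id = 1L,
                  clock_time = rep("2014-03-01T10:00:00Z", 2),
                  heart_rate = c(60, 80))
  p <- write_tiny_tables(v, tiny_stays(1))
  expect_warning(rt <- read_tables(p$vitals, p$stays), "duplicate")
  expect_equal(nrow(rt$vitals), 1)
  expect_equal(rt$vitals$heart_rate, 70)
})

test_that("an empty vitals file yields zero series without crashing", {
  v <- data.frame(stay_id = integer(0), clock_time = character(0),
                  heart_rate = numeric(0))
  p <- write_tiny_tables(v, tiny_stays(1))
  rt <- read_tables(p$vitals, p$stays)
  expect_equal(nrow(rt$vitals), 0)
})

test_that("a missing mandatory column raises a schema error naming it", {
  v <- data.frame(stay_id = 1L, clock_time = "2014-03-01T10:00:00Z")
  p <- write_tiny_tables(v, tiny_stays(1))
  expect_error(read_tables(p$vitals, p$stays), "heart_rate")
})

test_that("3-SD trimming removes strictly-beyond points, single pass", {
  # constructed series with mean exactly 80 and SD exactly 5
  d <- sqrt(1963 / 98)
  x <- c(rep(80 - d, 49), rep(80 + d, 49), 96, 64)
  s <- data.frame(stay_id = 1L, t_min = seq(0, by = 5, length.out = 100),
                  heart_rate = x)
  expect_equal(mean(s$heart_rate), 80)
  expect_equal(sd(s$heart_rate), 5)
  out <- remove_hr_outliers(s)
  expect_equal(out$n_removed, 2L) # 96 and 64: |16| > 15
  expect_false(any(out$series$heart_rate %in% c(96, 64)))

  # a point exactly at m + 3s is retained ("more than" is strict)
  d2 <- sqrt(2025 / 98)
  x2 <- c(rep(80 - d2, 49), rep(80 + d2, 49), 95, 65)
  s2 <- data.frame(stay_id = 1L, t_min = seq(0, by = 5, length.out = 100),
                   heart_rate = x2)
  expect_equal(sd(s2$heart_rate), 5)
  expect_equal(remove_hr_outliers(s2)$n_removed, 0L)

  # constant series: SD 0, nothing removed
  cs <- data.frame(stay_id = 1L, t_min = seq(0, by = 5, length.out = 10),
                   heart_rate = 72)
  expect_equal(remove_hr_outliers(cs)$n_removed, 0L)

  # one-sided option only trims the upper tail
  expect_equal(remove_hr_outliers(s, side = "upper")$n_removed, 1L)
})

test_that("an underage stay is excluded under rule 4", {
  co <- small_cohort()
  stays <- co$stays
  stays$age[1] <- 17
  ex <- apply_exclusions(stays, co$vitals)
  expect_equal(ex$ledger$n_excluded[4], 1)
  expect_false(stays$stay_id[1] %in% ex$stays$stay_id)
})

test_that("a clean cohort passes every rule", {
  co <- small_cohort()
  ex <- apply_exclusions(co$stays, co$vitals)
  expect_true(all(ex$ledger$n_excluded == 0))
  expect_equal(attr(ex$ledger, "n_included"), nrow(co$stays))
})

test_that("planted violations land on their intended rules exactly", {
  cfg <- ndhri_sim_config(n_stays = 60, n_hospitals = 4,
                          exclusion_case_fractions = rep(0.05, 10))
  co <- simulate_cohort(cfg, seed = 23)
  ex <- apply_exclusions(co$stays, co$vitals)
  want <- table(factor(co$manifest$rule_id, levels = 1:10))
  expect_equal(ex$ledger$n_excluded, as.integer(want))
  # attribution, not only counts: each planted stay fell on its own rule
  got <- ex$excluded
  m <- merge(co$manifest, got, by = "stay_id")
  expect_equal(m$rule_id.x, m$rule_id.y)
})

test_that("the ledger conserves stays and first-match attribution is stable", {
  cfg <- ndhri_sim_config(n_stays = 50, n_hospitals = 4,
                          exclusion_case_fractions = c(0.1, 0, 0.1, 0, 0.1,
                                                       0, 0, 0, 0.1, 0))
  co <- simulate_cohort(cfg, seed = 29)
  ex <- apply_exclusions(co$stays, co$vitals)
  led <- ex$ledger
  expect_equal(attr(led, "n_input"),
               attr(led, "n_included") + sum(led$n_excluded))
  # permuting the rule order may move counts but never changes who is in
  for (perm in list(10:1, c(2:10, 1), sample(10))) {
    ex2 <- apply_exclusions(co$stays, co$vitals, rule_order = perm)
    expect_equal(sort(ex2$stays$stay_id), sort(ex$stays$stay_id))
    expect_equal(attr(ex2$ledger, "n_included"), attr(led, "n_included"))
  }
})

test_that("relaxed mode disables only the heart-rate quality rules", {
  cfg <- ndhri_sim_config(n_stays = 40, n_hospitals = 4,
                          exclusion_case_fractions = c(0.1, 0, 0, 0.1,
                                                       rep(0, 6)))
  co <- simulate_cohort(cfg, seed = 31)
  ex <- apply_exclusions(co$stays, co$vitals, relaxed = TRUE)
  expect_equal(ex$ledger$n_excluded[1], 0)
  expect_equal(ex$ledger$n_excluded[8], 0)
  expect_equal(ex$ledger$n_excluded[4], 4)
})

test_that("repeat stays keep the earliest admission by default", {
  co <- small_cohort()
  stays <- co$stays
  # make stay 2 a later admission of patient 1
  stays$patient_id[2] <- stays$patient_id[1]
  shift <- 1e6 # ~2 years: later than any first admission
  stays$admit_min[2] <- stays$admit_min[2] + shift
  stays$discharge_min[2] <- stays$discharge_min[2] + shift
  v <- co$vitals
  v$t_min[v$stay_id == 2] <- v$t_min[v$stay_id == 2] + shift
  ex <- apply_exclusions(stays, v)
  expect_equal(ex$ledger$n_excluded[2], 1)
  expect_false(2 %in% ex$stays$stay_id)
  ex_last <- apply_exclusions(stays, v, keep_stay = "last")
  expect_false(1 %in% ex_last$stays$stay_id)
})

test_that("ledger writes CSV and JSON", {
  co <- small_cohort()
  ex <- apply_exclusions(co$stays, co$vitals)
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  write_ledger(ex$ledger, csv, js)
  back <- read.csv(csv)
  expect_equal(nrow(back), 10)
  j <- jsonlite::read_json(js)
  expect_equal(j$n_input, 40)
})
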