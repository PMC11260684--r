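# Synthetic-data generator: config validation, determinism, ground-truth
# identities, outcome calibration, planted exclusion violations.

test_that("config validation rejects impossible settings", {
  expect_error(ndhri_sim_config(n_stays = 0), "n_stays")
  expect_error(ndhri_sim_config(mean_hr = -5), "mean_hr")
  expect_error(ndhri_sim_config(ar_coefficient = 1), "ar_coefficient")
  expect_error(ndhri_sim_config(circadian_dip_mean = 1.2), "circadian_dip_mean")
  expect_error(ndhri_sim_config(u_curvature = -1), "u_curvature")
  expect_error(ndhri_sim_config(exclusion_case_fractions = rep(0.2, 10)),
               "sum")
  expect_error(ndhri_sim_config(exclusion_case_fractions = rep(0.05, 9)),
               "length 10")
})

test_that("the same seed reproduces the cohort exactly", {
  cfg <- ndhri_sim_config(n_stays = 5, n_hospitals = 2,
                          exclusion_case_fractions = c(0.2, rep(0, 9)))
  a <- simulate_cohort(cfg, seed = 3)
  b <- simulate_cohort(cfg, seed = 3)
  expect_identical(a$vitals, b$vitals)
  expect_identical(a$stays, b$stays)
  expect_identical(a$truth, b$truth)
  c <- simulate_cohort(cfg, seed = 4)
  expect_false(identical(a$vitals, c$vitals))
})

test_that("true NDHRI identity (1 - dip)/2 holds through the full stack", {
  # noise-free generator: measured daily NDHRI must equal the closed form
  for (dip in c(0, 0.2, 0.63)) {
    cfg <- ndhri_sim_config(n_stays = 2, n_hospitals = 1, noise_sd = 0,
                            dip_day_sd = 0, missingness_rate = 0,
                            circadian_dip_mean = dip, circadian_dip_sd = 0)
    co <- simulate_cohort(cfg, seed = 9)
    expect_equal(co$truth$true_ndhri, rep((1 - dip) / 2, 2))
    d <- compute_daily_ndhri(co$vitals[c("stay_id", "t_min", "heart_rate")])
    expect_lt(max(abs(d$ndhri[d$usable] - (1 - dip) / 2)), 1e-12)
  }
})

test_that("series generation respects the grid, stay span and HR bounds", {
  cfg <- ndhri_sim_config(n_stays = 1, missingness_rate = 0.3, noise_sd = 8)
  set.seed(2)
  st <- simulate_true_states(cfg, seed = NULL)
  s <- simulate_hr_series(st[1, ], cfg, seed = 21)
  expect_true(all(s$t_min %% 5 == 0))
  expect_true(all(s$t_min >= st$admit_min[1] & s$t_min < st$discharge_min[1]))
  expect_true(all(s$heart_rate >= 20 & s$heart_rate <= 250))
  n_slots <- (st$discharge_min[1] - st$admit_min[1]) / 5
  # dropped slots: binomial count within 4 SD of the configured rate
  expect_lt(abs(nrow(s) / n_slots - 0.7), 4 * sqrt(0.3 * 0.7 / n_slots))
  s2 <- simulate_hr_series(st[1, ], cfg, seed = 21)
  expect_identical(s, s2)
})

test_that("flat truth reproduces the baseline mortality rate", {
  cfg <- ndhri_sim_config(n_stays = 20000, u_curvature = 0, hospital_sd = 0,
                          covariate_effects = c(age = 0, gender = 0, bmi = 0,
                                                apache_iv = 0))
  d <- exposure_data(cfg, seed = 33)
  p0 <- cfg$baseline_mortality
  mc_se <- sqrt(p0 * (1 - p0) / nrow(d))
  expect_lt(abs(mean(d$hospital_mortality) - p0), 3 * mc_se)
  # ICU deaths are a sub-event of hospital deaths
  expect_true(all(d$icu_mortality <= d$hospital_mortality))
})

test_that("mortality is lowest at the nadir under a U-shaped truth", {
  cfg <- ndhri_sim_config(n_stays = 3, hospital_sd = 0,
                          covariate_effects = c(age = 0, gender = 0, bmi = 0,
                                                apache_iv = 0))
  n <- 1e5
  # three synthetic populations pinned at nadir and +/- 0.05
  rates <- vapply(c(0.375, 0.425, 0.475), function(x) {
    truth <- data.frame(stay_id = 1:n, true_ndhri = x, true_prop_in_range = 0,
                        age = 62.6, gender = "female", bmi = 29.3,
                        apache_iv = 54, hospital_effect = 0)
    mean(simulate_outcomes(truth, cfg, seed = 44)$hospital_mortality)
  }, numeric(1))
  expect_lt(rates[2], rates[1])
  expect_lt(rates[2], rates[3])
})

test_that("zero hospital SD gives identical risk for identical covariates", {
  cfg <- ndhri_sim_config(n_stays = 2, hospital_sd = 0)
  truth <- data.frame(stay_id = 1:2, true_ndhri = 0.43,
                      true_prop_in_range = 0.5, age = 60, gender = "male",
                      bmi = 30, apache_iv = 50, hospital_effect = c(0, 0))
  p <- simulate_outcomes(truth, cfg, seed = 1)$true_mortality_prob
  expect_equal(p[1], p[2])
})

test_that("planted violations hit the configured counts, rule by rule", {
  cfg <- ndhri_sim_config(n_stays = 100, n_hospitals = 5,
                          exclusion_case_fractions = c(0, 0, 0, 0.1, 0,
                                                       rep(0, 5)))
  co <- simulate_cohort(cfg, seed = 13)
  expect_equal(sum(co$stays$age < 18, na.rm = TRUE), 10)
  expect_equal(nrow(co$manifest), 10)
  expect_true(all(co$manifest$rule_id == 4))

  cfg0 <- ndhri_sim_config(n_stays = 20, n_hospitals = 2)
  co0 <- simulate_cohort(cfg0, seed = 13)
  expect_equal(nrow(co0$manifest), 0)
  expect_true(all(!is.na(co0$stays$age)))
})

test_that("cohort bookkeeping: stays count and vitals slots line up", {
  cfg <- ndhri_sim_config(n_stays = 5, n_hospitals = 1,
                          missingness_rate = 0)
  co <- simulate_cohort(cfg, seed = 17)
  expect_equal(nrow(co$stays), 5)
  expect_equal(nrow(co$vitals),
               sum((co$truth$discharge_min - co$truth$admit_min) / 5))
  expect_true(all(co$vitals$offset_min >= 0))
})

test_that("cohort files round-trip through CSV identically", {
  co <- small_cohort()
  dir1 <- tempfile(); dir2 <- tempfile()
  write_cohort(co, dir1)
  write_cohort(co, dir2)
  for (f in list.files(dir1)) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  }
  rt <- read_tables(file.path(dir1, "vitals.csv"), file.path(dir1, "stays.csv"))
  expect_equal(nrow(rt$vitals), nrow(co$vitals))
  ord_in <- order(co$vitals$stay_id, co$vitals$t_min)
  expect_equal(rt$vitals$t_min, co$vitals$t_min[ord_in])
  expect_equal(rt$vitals$heart_rate, co$vitals$heart_rate[ord_in],
               tolerance = 1e-12)
})

test_that("YAML config round-trips", {
  cfg <- ndhri_sim_config(n_stays = 7, u_nadir = 0.41)
  path <- tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  back <- read_sim_config(path)
  expect_equal(back$n_stays, 7L)
  expect_equal(back$u_nadir, 0.41)
  expect_equal(back$covariate_effects, cfg$covariate_effects)
})
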