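## Synthetic eICU-style cohort generator with known ground truth.

# Marginal covariate distributions for the synthetic population (locations and
# spreads chosen to resemble a large mixed US ICU cohort).
.ETHNICITIES <- c(caucasian = 0.746, african_american = 0.118, hispanic = 0.052,
                  asian = 0.021, native_american = 0.008, other_unknown = 0.055)
.ICU_TYPES <- c(med_surg_icu = 0.530, cardiac_icu = 0.080, ccu_cticu = 0.090,
                csicu = 0.030, cticu = 0.030, micu = 0.090, neuro_icu = 0.080,
                sicu = 0.070)
.COMORBIDITIES <- c(hypertension = 0.528, coronary_artery_disease = 0.123,
                    heart_failure = 0.148, copd = 0.089, diabetes = 0.266,
                    chronic_liver_disease = 0.061, ugi_bleed = 0.023,
                    chronic_renal_insufficiency = 0.103, stroke = 0.085,
                    cancer = 0.124, bone_fractures = 0.017)

#' Draw stay-level ground-truth states
#'
#' Generates one row per stay: hospital assignment and effect, the true
#' nocturnal dip and the implied true NDHRI (`(1 - dip) / 2` under the
#' two-level circadian model), the true proportion of days expected inside
#' `cfg$target_range`, covariates, admission time and stay length.
#'
#' @param cfg an [ndhri_sim_config()].
#' @param seed integer seed (overrides `cfg$seed`).
#' @return data.frame with one row per stay (the truth table).
#' @export
simulate_true_states <- function(cfg, seed = cfg$seed) {
  validate_sim_config(cfg)
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n_stays
  hospital_id <- sample.int(cfg$n_hospitals, n, replace = TRUE)
  hospital_effects <- rnorm(cfg$n_hospitals, 0, cfg$hospital_sd)

  dip <- rnorm(n, cfg$circadian_dip_mean, cfg$circadian_dip_sd)
  dip <- pmin(pmax(dip, -0.45), 0.95)
  true_ndhri <- (1 - dip) / 2

  # expected fraction of circadian days with daily NDHRI inside target_range;
  # daily NDHRI ~ N(true_ndhri, dip_day_sd / 2) under day-to-day dip variation
  s_daily <- cfg$dip_day_sd / 2
  lo <- cfg$target_range[1]; hi <- cfg$target_range[2]
  true_prop_in_range <- if (s_daily > 0) {
    pnorm((hi - true_ndhri) / s_daily) - pnorm((lo - true_ndhri) / s_daily)
  } else {
    as.numeric(true_ndhri >= lo & true_ndhri <= hi)
  }

  age <- pmin(pmax(rnorm(n, 62.6, 16.4), 18), 100)
  gender <- ifelse(runif(n) < 0.549, "male", "female")
  bmi <- pmin(pmax(rnorm(n, 29.3, 7.9), 13), 70)
  apache_iv <- pmin(pmax(rlnorm(n, log(54), 0.425), 1), 220)
  ethnicity <- sample(names(.ETHNICITIES), n, replace = TRUE, prob = .ETHNICITIES)
  icu_type <- sample(names(.ICU_TYPES), n, replace = TRUE, prob = .ICU_TYPES)
  comorb <- vapply(.COMORBIDITIES, function(p) rbinom(n, 1L, p),
                   integer(n))
  if (n == 1L) comorb <- matrix(comorb, nrow = 1,
                                dimnames = list(NULL, names(.COMORBIDITIES)))

  n_days <- pmax(cfg$min_stay_days, as.integer(round(
    rlnorm(n, cfg$stay_length_meanlog, cfg$stay_length_sdlog))))
  start_min <- .minutes(.parse_time(paste0(cfg$admit_start, " 00:00:00")))
  admit_min <- start_min +
    (sample.int(cfg$admit_spread_days, n, replace = TRUE) - 1L) * 1440 +
    (sample.int(288L, n, replace = TRUE) - 1L) * .SLOT_MIN

  out <- data.frame(stay_id = seq_len(n),
                    patient_id = seq_len(n),
                    hospital_id = hospital_id,
                    hospital_effect = hospital_effects[hospital_id],
                    true_dip = dip,
                    true_ndhri = true_ndhri,
                    true_prop_in_range = true_prop_in_range,
                    age = age, gender = gender, bmi = bmi,
                    apache_iv = apache_iv,
                    ethnicity = ethnicity, icu_type = icu_type,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(comorb))
  out$n_days <- n_days
  out$admit_min <- admit_min
  out$discharge_min <- admit_min + n_days * 1440
  out
}

#' Simulate a 5-min heart-rate series for one stay
#'
#' Two-level circadian profile plus stationary AR(1) noise, on the 5-min
#' grid from admission to discharge, clipped to the physiologic range
#' 20-250 bpm, with slots dropped independently at `cfg$missingness_rate`.
#' The per-circadian-day dip is `true_dip` plus `N(0, dip_day_sd)` jitter.
#'
#' @param state one row of the truth table from [simulate_true_states()]
#'   (a list or single-row data.frame with `stay_id`, `true_dip`,
#'   `admit_min`, `discharge_min`).
#' @param cfg an [ndhri_sim_config()].
#' @param seed optional integer seed for reproducibility of this one series.
#' @return data.frame with columns `stay_id`, `t_min` (minutes since epoch,
#'   UTC), `heart_rate`.
#' @export
simulate_hr_series <- function(state, cfg, seed = NULL) {
  validate_sim_config(cfg)
  if (!is.null(seed)) set.seed(seed)
  if (state$discharge_min - state$admit_min < 1440)
    .stopf("stay must span at least one circadian day")
  t_min <- seq(.snap5(state$admit_min), .snap5(state$discharge_min) - .SLOT_MIN,
               by = .SLOT_MIN)
  cd <- .circadian_day(t_min)
  cds <- sort(unique(cd))
  dip_day <- state$true_dip + rnorm(length(cds), 0, cfg$dip_day_sd)
  dip_slot <- dip_day[match(cd, cds)]
  night <- .is_night(t_min)
  level <- cfg$mean_hr * (1 - dip_slot * night)

  m <- length(t_min)
  if (cfg$noise_sd > 0 && m > 0) {
    innov_sd <- cfg$noise_sd * sqrt(1 - cfg$ar_coefficient^2)
    e <- rnorm(m, 0, innov_sd)
    noise <- as.numeric(stats::filter(e, cfg$ar_coefficient,
                                      method = "recursive",
                                      init = rnorm(1, 0, cfg$noise_sd)))
  } else {
    noise <- numeric(m)
  }
  hr <- pmin(pmax(level + noise, 20), 250)
  keep <- if (cfg$missingness_rate > 0) runif(m) >= cfg$missingness_rate
          else rep(TRUE, m)
  data.frame(stay_id = rep(state$stay_id, sum(keep)),
             t_min = t_min[keep], heart_rate = hr[keep])
}

# All-stay vitals (single RNG stream; deterministic given prior set.seed()).
.simulate_vitals <- function(truth, cfg) {
  pieces <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    pieces[[i]] <- simulate_hr_series(truth[i, ], cfg)
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Simulate mortality outcomes from ground truth
#'
#' Log-odds of hospital death:
#' `logit(p) = logit(baseline) + u_curvature * (true_ndhri - u_nadir)^2 +
#'  tir_effect * true_prop_in_range + centered covariate terms +
#'  hospital effect`. ICU death is drawn as a sub-event of hospital death
#' with conditional probability `icu_mortality_fraction`.
#'
#' @param truth truth table from [simulate_true_states()].
#' @param cfg an [ndhri_sim_config()].
#' @param seed optional integer seed.
#' @return data.frame `stay_id`, `true_mortality_prob`, `hospital_mortality`,
#'   `icu_mortality`.
#' @export
simulate_outcomes <- function(truth, cfg, seed = NULL) {
  validate_sim_config(cfg)
  if (!is.null(seed)) set.seed(seed)
  be <- cfg$covariate_effects
  eta <- qlogis(cfg$baseline_mortality) +
    cfg$u_curvature * (truth$true_ndhri - cfg$u_nadir)^2 +
    cfg$tir_effect * truth$true_prop_in_range +
    be[["age"]] * (truth$age - 62.6) +
    be[["gender"]] * ((truth$gender == "male") - 0.549) +
    be[["bmi"]] * (truth$bmi - 29.3) +
    be[["apache_iv"]] * (truth$apache_iv - 54) +
    truth$hospital_effect
  p <- plogis(eta)
  dead <- rbinom(nrow(truth), 1L, p)
  icu_dead <- dead * rbinom(nrow(truth), 1L, cfg$icu_mortality_fraction)
  data.frame(stay_id = truth$stay_id, true_mortality_prob = p,
             hospital_mortality = dead, icu_mortality = icu_dead)
}

.RULE_LABELS <- c(
  "No usable consecutive heart-rate coverage",
  "Repeat ICU stay for the same patient",
  "Missing age",
  "Age under 18 years",
  "Missing gender",
  "Missing BMI",
  "Discharged or deceased within a single calendar day",
  "No usable day after heart-rate outlier removal",
  "History of arrhythmia, cardiac arrest, or pacemaker",
  "Missing mortality outcome"
)

#' Plant per-rule exclusion violations in a clean cohort
#'
#' For each of the ten exclusion rules, mutates
#' `round(fraction * n_stays)` distinct stays so that each violates exactly
#' its assigned rule (and, barring pathological configurations, no earlier
#' rule), and returns a manifest mapping stay ids to planted rules. The
#' mutations are: (1) all vitals removed; (2) the stay is re-attributed to
#' another patient and shifted later in time, making it a repeat stay;
#' (3-6) age/gender/BMI set missing, or age drawn under 18; (7) admission
#' metadata rewritten to a same-calendar-day interval (vitals untouched, a
#' realistic timestamp pathology); (8) just enough extreme heart-rate spikes
#' planted in every night window that 3-SD trimming pushes each night below
#' the coverage threshold; (9) the arrhythmia/pacemaker flag set; (10) both
#' mortality outcomes set missing.
#'
#' @param cohort list with elements `vitals`, `stays` (as produced inside
#'   [simulate_cohort()]).
#' @param cfg an [ndhri_sim_config()]; `cfg$exclusion_case_fractions` drives
#'   the counts.
#' @param seed optional integer seed.
#' @param coverage_threshold the window coverage threshold the downstream
#'   cascade will use (needed to size rule-8 spikes).
#' @return the cohort list with mutated `vitals`/`stays` plus a `manifest`
#'   data.frame (`stay_id`, `rule_id`, `rule_label`).
#' @export
inject_exclusion_cases <- function(cohort, cfg, seed = NULL,
                                   coverage_threshold = 0.8) {
  validate_sim_config(cfg)
  if (!is.null(seed)) set.seed(seed)
  stays <- cohort$stays
  vitals <- cohort$vitals
  n <- nrow(stays)
  counts <- round(cfg$exclusion_case_fractions * n)
  if (sum(counts) > n) .stopf("planted violations exceed cohort size")
  if (sum(counts) == 0) {
    cohort$manifest <- data.frame(stay_id = integer(0), rule_id = integer(0),
                                  rule_label = character(0))
    return(cohort)
  }
  ord <- sample.int(n)
  sel <- split(stays$stay_id[ord[seq_len(sum(counts))]],
               rep(seq_along(counts), counts))
  names(sel) <- as.character(which(counts > 0))
  clean_ids <- if (sum(counts) < n)
    stays$stay_id[ord[seq(sum(counts) + 1, n)]] else integer(0)

  get <- function(r) if (as.character(r) %in% names(sel)) sel[[as.character(r)]] else integer(0)

  ## rule 1: drop all vitals
  vitals <- vitals[!(vitals$stay_id %in% get(1)), ]

  ## rule 2: re-attribute to an existing patient, shifted later. Donors must
  ## still be active when the repeat-stay rule runs, so they are drawn from
  ## clean stays or stays planted for rules 3-10 (never rules 1 or 2).
  r2 <- get(2)
  if (length(r2)) {
    donor_pool <- c(clean_ids,
                    unlist(sel[setdiff(names(sel), c("1", "2"))],
                           use.names = FALSE))
    if (length(donor_pool) < length(r2))
      .stopf("not enough eligible stays to donate patient ids for rule 2")
    donors <- donor_pool[seq_along(r2)]
    shift <- (cfg$admit_spread_days + 30) * 1440
    for (j in seq_along(r2)) {
      i <- match(r2[j], stays$stay_id)
      stays$patient_id[i] <- stays$patient_id[match(donors[j], stays$stay_id)]
      stays$admit_min[i] <- stays$admit_min[i] + shift
      stays$discharge_min[i] <- stays$discharge_min[i] + shift
      vi <- vitals$stay_id == r2[j]
      vitals$t_min[vi] <- vitals$t_min[vi] + shift
    }
  }

  stays$age[stays$stay_id %in% get(3)] <- NA_real_
  r4 <- get(4)
  stays$age[stays$stay_id %in% r4] <- sample(1:17, length(r4), replace = TRUE)
  stays$gender[stays$stay_id %in% get(5)] <- NA_character_
  stays$bmi[stays$stay_id %in% get(6)] <- NA_real_

  ## rule 7: same-calendar-day admission metadata
  r7 <- get(7)
  if (length(r7)) {
    i <- match(r7, stays$stay_id)
    day0 <- (stays$admit_min[i] %/% 1440) * 1440
    stays$admit_min[i] <- day0 + 8 * 60
    stays$discharge_min[i] <- day0 + 20 * 60
  }

  ## rule 8: spike enough night slots that trimming breaks every night window
  r8 <- get(8)
  max_present <- floor(coverage_threshold * .N_NIGHT_SLOTS)  # usable needs > this
  for (sid in r8) {
    vi <- which(vitals$stay_id == sid)
    if (!length(vi)) next
    t <- vitals$t_min[vi]
    night <- .is_night(t)
    cd <- .circadian_day(t)
    for (d in unique(cd[night])) {
      slots <- vi[night & cd == d]
      k <- length(slots) - max_present
      if (k > 0) vitals$heart_rate[slots[seq_len(k)]] <- 245
    }
  }

  stays$arrhythmia_or_pacemaker_history[stays$stay_id %in% get(9)] <- 1L
  r10 <- get(10)
  stays$hospital_mortality[stays$stay_id %in% r10] <- NA_integer_
  stays$icu_mortality[stays$stay_id %in% r10] <- NA_integer_

  manifest <- do.call(rbind, lapply(as.integer(names(sel)), function(r) {
    data.frame(stay_id = sel[[as.character(r)]], rule_id = r,
               rule_label = .RULE_LABELS[r])
  }))
  manifest <- manifest[order(manifest$stay_id), ]
  rownames(manifest) <- NULL
  cohort$stays <- stays
  cohort$vitals <- vitals
  cohort$manifest <- manifest
  cohort
}

#' Simulate a full synthetic cohort
#'
#' Runs the whole generator: ground-truth states, 5-min heart-rate streams,
#' mortality outcomes, assembly of eICU-style stays/vitals tables, and (if
#' configured) planted exclusion violations.
#'
#' @param cfg an [ndhri_sim_config()].
#' @param seed integer seed (defaults to `cfg$seed`).
#' @return list with data.frames `vitals` (`stay_id`, `hospital_id`,
#'   `offset_min`, `t_min`, `heart_rate`), `stays` (covariates, timestamps,
#'   outcomes), `truth`, and `manifest` (planted violations, possibly empty).
#' @export
simulate_cohort <- function(cfg, seed = cfg$seed) {
  validate_sim_config(cfg)
  if (is.null(seed)) seed <- 1L
  set.seed(seed)
  truth <- simulate_true_states(cfg, seed = NULL)
  vitals <- .simulate_vitals(truth, cfg)
  outcomes <- simulate_outcomes(truth, cfg, seed = NULL)
  truth$true_mortality_prob <- outcomes$true_mortality_prob

  stays <- data.frame(stay_id = truth$stay_id,
                      patient_id = truth$patient_id,
                      hospital_id = truth$hospital_id,
                      age = truth$age, gender = truth$gender, bmi = truth$bmi,
                      ethnicity = truth$ethnicity, icu_type = truth$icu_type,
                      stringsAsFactors = FALSE)
  stays <- cbind(stays, truth[names(.COMORBIDITIES)])
  stays$apache_iv <- truth$apache_iv
  stays$admit_min <- truth$admit_min
  stays$discharge_min <- truth$discharge_min
  stays$icu_mortality <- outcomes$icu_mortality
  stays$hospital_mortality <- outcomes$hospital_mortality
  stays$arrhythmia_or_pacemaker_history <- 0L

  cohort <- list(vitals = vitals, stays = stays, truth = truth)
  cohort <- inject_exclusion_cases(cohort, cfg, seed = NULL)
  # attach hospital and offset columns for the external vitals schema
  cohort$vitals$hospital_id <-
    stays$hospital_id[match(cohort$vitals$stay_id, stays$stay_id)]
  cohort$vitals$offset_min <- cohort$vitals$t_min -
    stays$admit_min[match(cohort$vitals$stay_id, stays$stay_id)]
  cohort$vitals <- cohort$vitals[c("stay_id", "hospital_id", "offset_min",
                                   "t_min", "heart_rate")]
  cohort$seed <- seed
  cohort
}

#' Write a simulated cohort to CSV files
#'
#' Writes `vitals.csv`, `stays.csv`, `truth.csv` and (when violations were
#' planted) `manifest.csv` into `dir`, with ISO-8601 clock times.
#'
#' @param cohort output of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  v <- cohort$vitals
  v$clock_time <- .format_time(v$t_min)
  write.csv(v[c("stay_id", "hospital_id", "offset_min", "clock_time",
                "heart_rate")],
            file.path(dir, "vitals.csv"), row.names = FALSE)
  s <- cohort$stays
  s$admit_time <- .format_time(s$admit_min)
  s$discharge_time <- .format_time(s$discharge_min)
  s$admit_min <- s$discharge_min <- NULL
  write.csv(s, file.path(dir, "stays.csv"), row.names = FALSE)
  write.csv(cohort$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  if (!is.null(cohort$manifest) && nrow(cohort$manifest))
    write.csv(cohort$manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}
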