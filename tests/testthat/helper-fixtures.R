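# Shared fixtures, built once per test run and cached.

.fix <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fix[[name]])) .fix[[name]] <- builder()
  .fix[[name]]
}

# minutes-since-epoch for a clock time on a reference date
t_at <- function(day, hh, mm = 0) {
  as.numeric(as.Date("2014-03-01")) * 1440 + (day - 1) * 1440 + hh * 60 + mm
}

# Build a gap-free series for one stay: `days` whole circadian days starting
# at 06:00, with night/day heart-rate levels (scalars or per-day vectors).
two_level_series <- function(stay_id = 1L, days = 2, day_hr = 80,
                             night_hr = 80) {
  start <- t_at(1, 6)
  t <- seq(start, start + days * 1440 - 5, by = 5)
  night <- ((t - 360) %% 1440) >= 960
  cd <- ((t - 360) %/% 1440) - ((start - 360) %/% 1440) + 1
  dh <- rep(day_hr, length.out = days)[cd]
  nh <- rep(night_hr, length.out = days)[cd]
  data.frame(stay_id = stay_id, t_min = t,
             heart_rate = ifelse(night, nh, dh))
}

# Random gap-containing series (fixed RNG state assumed set by caller)
random_gap_series <- function(stay_id, days = 3, drop = 0.3) {
  s <- two_level_series(stay_id, days = days)
  s$heart_rate <- runif(nrow(s), 40, 160)
  keep <- runif(nrow(s)) >= drop
  s[keep, , drop = FALSE]
}

# Brute-force per-bar oracle: loops over every circadian day and slot,
# summing 5 * hr separately for the night and day window.
brute_daily <- function(series) {
  cd <- (series$t_min - 360) %/% 1440
  out <- NULL
  for (d in sort(unique(cd))) {
    night_area <- 0; day_area <- 0; n_n <- 0L; n_d <- 0L
    for (i in seq_len(nrow(series))) {
      if (cd[i] != d) next
      pos <- (series$t_min[i] - 360) %% 1440
      if (pos >= 960) {
        night_area <- night_area + 5 * series$heart_rate[i]
        n_n <- n_n + 1L
      } else {
        day_area <- day_area + 5 * series$heart_rate[i]
        n_d <- n_d + 1L
      }
    }
    out <- rbind(out, data.frame(cal_day = d, night_area = night_area,
                                 day_area = day_area,
                                 night_coverage = n_n / 96,
                                 day_coverage = n_d / 192))
  }
  out
}

# Stay-level analysis table straight from the generator's truth (no vitals
# stage): true exposure, outcomes, covariates, hospital ids.
exposure_data <- function(cfg, seed) {
  set.seed(seed)
  truth <- simulate_true_states(cfg, seed = NULL)
  oc <- simulate_outcomes(truth, cfg, seed = NULL)
  d <- truth
  d$hospital_mortality <- oc$hospital_mortality
  d$icu_mortality <- oc$icu_mortality
  d$mean_ndhri <- d$true_ndhri
  d$prop_in_range <- d$true_prop_in_range
  d
}

# A moderately sized U-truth fit on true exposure, reused by several tests.
u_fit <- function() fixture("u_fit", function() {
  cfg <- ndhri_sim_config(n_stays = 4000, seed = NULL)
  d <- exposure_data(cfg, seed = 42)
  ndhri_gam(d)
})

# Small complete simulated cohort, reused across cohort/pipeline tests.
small_cohort <- function() fixture("small_cohort", function() {
  cfg <- ndhri_sim_config(n_stays = 40, n_hospitals = 4)
  simulate_cohort(cfg, seed = 11)
})
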