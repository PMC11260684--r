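#' Simulation configuration for synthetic ICU cohorts
#'
#' Builds and validates the configuration object consumed by
#' [simulate_cohort()] and friends. The defaults describe a cohort whose
#' marginal distributions mirror a large multi-center US ICU population:
#' stay-level mean heart rate around 85 bpm with a nocturnal dip giving a
#' nocturnal-diurnal heart rate index (NDHRI) of about 43% +/- 6%, hospital
#' mortality near 12% at the bottom of the U, and covariates (age, BMI,
#' APACHE IV severity) with realistic locations and spreads.
#'
#' The generator uses a two-level (square-wave) circadian heart-rate profile:
#' daytime heart rate \code{mean_hr}, nighttime heart rate
#' \code{mean_hr * (1 - dip)}. Under that profile the true daily NDHRI is
#' exactly \code{(1 - dip) / 2}, which makes the index analytically checkable.
#' Mortality follows a logistic model whose log-odds is, by default, a
#' U-shaped (quadratic) function of the stay's true mean NDHRI with nadir
#' \code{u_nadir}; setting \code{tir_effect} nonzero instead (or additionally)
#' ties log-odds linearly to the true proportion of days spent inside
#' \code{target_range}.
#'
#' @param n_stays number of ICU stays to generate (>= 1).
#' @param n_hospitals number of hospitals stays are clustered in.
#' @param hospital_sd SD (log-odds) of the Gaussian hospital random intercept.
#' @param mean_hr daytime heart rate level, bpm (> 0).
#' @param circadian_dip_mean,circadian_dip_sd mean and SD of the stay-level
#'   relative nocturnal heart-rate reduction (dimensionless fraction; the
#'   mean must lie in `[0, 1)`). Individual dips are clamped to (-0.45, 0.95),
#'   allowing nocturnal risers.
#' @param dip_day_sd SD of day-to-day variation of the dip within a stay;
#'   this is what makes the daily NDHRI (and hence time-in-range) vary.
#' @param noise_sd marginal SD of the AR(1) heart-rate noise, bpm.
#' @param ar_coefficient AR(1) autocorrelation of consecutive 5-min slots,
#'   in `[0, 1)`.
#' @param stay_length_meanlog,stay_length_sdlog log-normal parameters for the
#'   ICU stay length in days (rounded, floored at `min_stay_days`).
#' @param min_stay_days minimum stay length in whole days (>= 1).
#' @param missingness_rate fraction of 5-min slots dropped at random.
#' @param baseline_mortality mortality probability at the nadir for a
#'   reference patient (covariates at their centers, hospital effect 0).
#' @param icu_mortality_fraction fraction of hospital deaths that occur in
#'   the ICU (conditional probability).
#' @param u_curvature curvature of the U: log-odds per squared NDHRI
#'   fraction (>= 0; 0 is the flat/null model).
#' @param u_nadir NDHRI fraction at the bottom of the U.
#' @param tir_effect log-odds per unit of true proportion-in-range
#'   (0 disables the time-in-range outcome channel).
#' @param target_range length-2 numeric, the NDHRI range used for the true
#'   proportion-in-range.
#' @param covariate_effects named numeric vector of log-odds per unit of the
#'   centered covariates `age` (years), `gender` (male = 1), `bmi` (kg/m^2),
#'   `apache_iv` (points).
#' @param exclusion_case_fractions numeric length 10; per-rule fractions of
#'   stays deliberately mutated to violate exactly that exclusion rule
#'   (see [inject_exclusion_cases()]). Must each be in `[0, 1]` and sum to
#'   at most 1.
#' @param admit_start date (string) of the first possible admission.
#' @param admit_spread_days admissions are spread uniformly over this many
#'   days.
#' @param seed optional default seed recorded in the config (functions also
#'   take an explicit `seed` argument, which wins).
#'
#' @return an object of class `ndhri_sim_config` (a validated named list).
#' @seealso [simulate_cohort()], [read_sim_config()]
#' @examples
#' cfg <- ndhri_sim_config(n_stays = 10, n_hospitals = 2)
#' cfg$u_nadir
#' @export
ndhri_sim_config <- function(n_stays = 1000L,
                             n_hospitals = 20L,
                             hospital_sd = 0.3,
                             mean_hr = 85,
                             circadian_dip_mean = 0.136,
                             circadian_dip_sd = 0.112,
                             dip_day_sd = 0.02,
                             noise_sd = 5,
                             ar_coefficient = 0.7,
                             stay_length_meanlog = log(4),
                             stay_length_sdlog = 0.35,
                             min_stay_days = 2L,
                             missingness_rate = 0.1,
                             baseline_mortality = 0.117,
                             icu_mortality_fraction = 0.538,
                             u_curvature = 3000,
                             u_nadir = 0.425,
                             tir_effect = 0,
                             target_range = c(0.40, 0.45),
                             covariate_effects = c(age = 0.02, gender = 0.10,
                                                   bmi = 0.01, apache_iv = 0.03),
                             exclusion_case_fractions = rep(0, 10),
                             admit_start = "2014-01-01",
                             admit_spread_days = 365L,
                             seed = NULL) {
  cfg <- list(n_stays = as.integer(n_stays),
              n_hospitals = as.integer(n_hospitals),
              hospital_sd = hospital_sd,
              mean_hr = mean_hr,
              circadian_dip_mean = circadian_dip_mean,
              circadian_dip_sd = circadian_dip_sd,
              dip_day_sd = dip_day_sd,
              noise_sd = noise_sd,
              ar_coefficient = ar_coefficient,
              stay_length_meanlog = stay_length_meanlog,
              stay_length_sdlog = stay_length_sdlog,
              min_stay_days = as.integer(min_stay_days),
              missingness_rate = missingness_rate,
              baseline_mortality = baseline_mortality,
              icu_mortality_fraction = icu_mortality_fraction,
              u_curvature = u_curvature,
              u_nadir = u_nadir,
              tir_effect = tir_effect,
              target_range = as.numeric(target_range),
              covariate_effects = covariate_effects,
              exclusion_case_fractions = as.numeric(exclusion_case_fractions),
              admit_start = admit_start,
              admit_spread_days = as.integer(admit_spread_days),
              seed = seed)
  class(cfg) <- "ndhri_sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @rdname ndhri_sim_config
#' @param cfg an `ndhri_sim_config` object to validate.
#' @export
validate_sim_config <- function(cfg) {
  chk <- function(cond, msg) if (!isTRUE(cond)) .stopf("invalid config: %s", msg)
  chk(cfg$n_stays >= 1L, "n_stays must be >= 1")
  chk(cfg$n_hospitals >= 1L, "n_hospitals must be >= 1")
  chk(cfg$mean_hr > 0, "mean_hr must be positive")
  chk(cfg$hospital_sd >= 0, "hospital_sd must be >= 0")
  chk(cfg$circadian_dip_mean >= 0 && cfg$circadian_dip_mean < 1,
      "circadian_dip_mean must be in [0, 1)")
  chk(cfg$circadian_dip_sd >= 0, "circadian_dip_sd must be >= 0")
  chk(cfg$dip_day_sd >= 0, "dip_day_sd must be >= 0")
  chk(cfg$noise_sd >= 0, "noise_sd must be >= 0")
  chk(cfg$ar_coefficient >= 0 && cfg$ar_coefficient < 1,
      "ar_coefficient must be in [0, 1)")
  chk(cfg$min_stay_days >= 1L, "min_stay_days must be >= 1")
  chk(cfg$missingness_rate >= 0 && cfg$missingness_rate <= 1,
      "missingness_rate must be a probability")
  chk(cfg$baseline_mortality >= 0 && cfg$baseline_mortality <= 1,
      "baseline_mortality must be a probability")
  chk(cfg$icu_mortality_fraction >= 0 && cfg$icu_mortality_fraction <= 1,
      "icu_mortality_fraction must be a probability")
  chk(cfg$u_curvature >= 0, "u_curvature must be >= 0")
  chk(cfg$u_nadir > 0 && cfg$u_nadir < 1, "u_nadir must be in (0, 1)")
  chk(length(cfg$target_range) == 2 && cfg$target_range[1] < cfg$target_range[2],
      "target_range must be an increasing pair")
  chk(length(cfg$exclusion_case_fractions) == 10,
      "exclusion_case_fractions must have length 10")
  chk(all(cfg$exclusion_case_fractions >= 0 & cfg$exclusion_case_fractions <= 1),
      "exclusion_case_fractions must be probabilities")
  chk(sum(cfg$exclusion_case_fractions) <= 1,
      "exclusion_case_fractions must sum to at most 1")
  need <- c("age", "gender", "bmi", "apache_iv")
  chk(all(need %in% names(cfg$covariate_effects)),
      "covariate_effects must name age, gender, bmi, apache_iv")
  invisible(cfg)
}

#' Read / write a simulation config as YAML
#'
#' The YAML file mirrors the field names of [ndhri_sim_config()]; missing
#' fields take the defaults.
#'
#' @param path file path.
#' @return `read_sim_config()` returns an `ndhri_sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(ndhri_sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    .stopf("unknown config fields: %s", paste(unknown, collapse = ", "))
  for (v in c("covariate_effects", "target_range",
              "exclusion_case_fractions")) {
    if (!is.null(raw[[v]])) raw[[v]] <- unlist(raw[[v]])
  }
  do.call(ndhri_sim_config, raw)
}

#' @rdname read_sim_config
#' @param cfg an `ndhri_sim_config`.
#' @export
write_sim_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$covariate_effects <- as.list(cfg$covariate_effects)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @export
print.ndhri_sim_config <- function(x, ...) {
  cat("NDHRI simulation config\n")
  cat(sprintf("  stays: %d in %d hospitals (random-intercept SD %.2f)\n",
              x$n_stays, x$n_hospitals, x$hospital_sd))
  cat(sprintf("  HR: %.0f bpm, dip %.3f +/- %.3f (day-to-day SD %.3f), AR(1) phi %.2f, noise %.1f bpm\n",
              x$mean_hr, x$circadian_dip_mean, x$circadian_dip_sd,
              x$dip_day_sd, x$ar_coefficient, x$noise_sd))
  cat(sprintf("  outcome: baseline %.3f, U curvature %.0f at nadir %.3f, TIR effect %.2f\n",
              x$baseline_mortality, x$u_curvature, x$u_nadir, x$tir_effect))
  invisible(x)
}
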