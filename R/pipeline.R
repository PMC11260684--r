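## Study orchestration: optimal-range rule, time-in-range model, subgroup
## analyses, descriptive table, end-to-end study report, and the
## parameter-recovery experiment.

#' Range rule arithmetic
#'
#' The pure arithmetic behind [derive_optimal_range()]: extend the nadir by
#' `half_width` on both sides, round each endpoint to `rounding_step`, clamp
#' to `clamp`.
#'
#' @param nadir nadir location (exposure fraction).
#' @param half_width,rounding_step rule parameters.
#' @param clamp optional length-2 numeric to clamp the endpoints to.
#' @return numeric `c(lo, hi)`.
#' @examples
#' range_from_nadir(0.425) # 0.400 0.450
#' range_from_nadir(0.430) # 0.405 0.455
#' @export
range_from_nadir <- function(nadir, half_width = 0.025,
                             rounding_step = 0.005, clamp = NULL) {
  lo <- .round_step(nadir - half_width, rounding_step)
  hi <- .round_step(nadir + half_width, rounding_step)
  if (!is.null(clamp)) {
    lo <- max(lo, clamp[1]); hi <- min(hi, clamp[2])
  }
  c(lo, hi)
}

#' Derive the optimal NDHRI range from a fitted U-curve
#'
#' Codifies the post-hoc range rule as: take the nadir of the fitted risk
#' curve, extend symmetrically by `half_width` on each side, round both
#' endpoints to `rounding_step`, and clamp to the observed exposure range.
#' With the defaults (half-width 0.025, step 0.005) a nadir at 0.425 yields
#' the range `[0.400, 0.450]`. A boundary nadir (monotone fitted curve)
#' returns a failure status instead of a range.
#'
#' @param fit an [ndhri_gam()] fit of the primary exposure.
#' @param half_width half-width of the range around the nadir (fraction).
#' @param rounding_step endpoints are rounded to multiples of this.
#' @param step nadir grid step passed to [find_nadir()].
#' @return list of class `ndhri_range`: `success`, `nadir`, `boundary`,
#'   `half_width`, `rounding_step`, `lo`, `hi` (the last two `NA` on
#'   failure).
#' @export
derive_optimal_range <- function(fit, half_width = 0.025,
                                 rounding_step = 0.005, step = 0.001) {
  nad <- find_nadir(fit, step = step)
  out <- list(success = !nad$boundary, nadir = nad$nadir,
              boundary = nad$boundary, half_width = half_width,
              rounding_step = rounding_step, lo = NA_real_, hi = NA_real_)
  if (!nad$boundary) {
    r <- range_from_nadir(nad$nadir, half_width, rounding_step,
                          clamp = fit$exposure_range)
    lo <- r[1]; hi <- r[2]
    if (lo >= hi) {
      out$success <- FALSE
    } else {
      out$lo <- lo; out$hi <- hi
    }
  }
  class(out) <- "ndhri_range"
  out
}

#' @export
print.ndhri_range <- function(x, ...) {
  if (x$success) {
    cat(sprintf("Optimal NDHRI range: [%.3f, %.3f] (nadir %.3f +/- %.3f, rounded to %.3f)\n",
                x$lo, x$hi, x$nadir, x$half_width, x$rounding_step))
  } else {
    cat(sprintf("No optimal range: nadir %.3f is at the boundary of the fitted curve\n",
                x$nadir))
  }
  invisible(x)
}

#' Time-in-range mortality model
#'
#' Refits the same GAM machinery with the proportion of usable days spent
#' inside the target NDHRI range as the smooth exposure, and summarizes the
#' direction of the association as the average derivative of the fitted
#' linear predictor over the observed exposure span (negative = more time in
#' range, lower mortality). A degenerate exposure (all stays equal) yields a
#' flat-model warning and no fit.
#'
#' @param data cohort analysis table containing `prop_in_range` (see
#'   [summarize_stays()]) plus outcome/covariates/hospital.
#' @param range the `ndhri_range` (or numeric length-2) that
#'   `prop_in_range` was computed against; recorded in the result.
#' @param exposure exposure column name (default `"prop_in_range"`).
#' @param n_grid grid size for the average-derivative summary.
#' @param ... passed to [ndhri_gam()].
#' @return list of class `ndhri_tir`: `model` (an `ndhri_gam` or `NULL`),
#'   `avg_derivative`, `smooth_p`, `range`, `flat`.
#' @export
fit_time_in_range_model <- function(data, range = c(0.40, 0.45),
                                    exposure = "prop_in_range",
                                    n_grid = 101, ...) {
  rng_vec <- if (inherits(range, "ndhri_range")) c(range$lo, range$hi)
             else as.numeric(range)
  x <- data[[exposure]]
  if (is.null(x)) .stopf("data is missing column(s): %s", exposure)
  if (length(unique(x[!is.na(x)])) < 2) {
    warning("time-in-range exposure is constant across the cohort; flat model",
            call. = FALSE)
    out <- list(model = NULL, avg_derivative = 0, smooth_p = NA_real_,
                range = rng_vec, flat = TRUE)
    class(out) <- "ndhri_tir"
    return(out)
  }
  m <- ndhri_gam(data, exposure = exposure, ...)
  grid <- seq(m$exposure_range[1], m$exposure_range[2], length.out = n_grid)
  eta <- as.numeric(.lpmatrix_at(m, grid) %*% coef(m$fit))
  avg_d <- mean(diff(eta) / diff(grid))
  out <- list(model = m, avg_derivative = avg_d,
              smooth_p = smooth_significance(m), range = rng_vec,
              flat = FALSE)
  class(out) <- "ndhri_tir"
  out
}

#' @export
print.ndhri_tir <- function(x, ...) {
  cat(sprintf("Time-in-range model (range [%.3f, %.3f]):\n",
              x$range[1], x$range[2]))
  if (x$flat) {
    cat("  degenerate exposure; flat model\n")
  } else {
    cat(sprintf("  average derivative of the linear predictor: %.2f (%s trend), smooth p = %.3g\n",
                x$avg_derivative,
                if (x$avg_derivative < 0) "declining" else "rising",
                x$smooth_p))
  }
  invisible(x)
}

#' Subgroup analyses
#'
#' Repeats the primary NDHRI analysis (and optionally the time-in-range
#' analysis) independently per stratum of a stratifying column; no pooling,
#' shared smoothing, or interaction testing. Strata with fewer rows than
#' `min_stratum_n` (default `10 * k`) are skipped with a recorded reason.
#'
#' @param data cohort analysis table.
#' @param stratifier column name to stratify by (e.g. `"ethnicity"`,
#'   `"icu_type"`, or a comorbidity flag).
#' @param min_stratum_n minimum stratum size to fit.
#' @param tir also run the time-in-range model per stratum (needs
#'   `prop_in_range`).
#' @param tir_range range recorded with the time-in-range fits.
#' @param ... passed to [ndhri_gam()].
#' @return named list per stratum: either
#'   `list(fit, nadir, range, n, tir)` or `list(skipped = TRUE, reason, n)`.
#' @export
run_subgroup_analyses <- function(data, stratifier, min_stratum_n = NULL,
                                  tir = FALSE, tir_range = c(0.40, 0.45),
                                  ...) {
  if (!stratifier %in% names(data))
    .stopf("unknown stratifier '%s'", stratifier)
  dots <- list(...)
  k <- if (!is.null(dots$k)) dots$k else 10
  if (is.null(min_stratum_n)) min_stratum_n <- 10 * k
  out <- list()
  for (lev in sort(unique(as.character(data[[stratifier]])))) {
    sub <- data[data[[stratifier]] == lev, , drop = FALSE]
    if (nrow(sub) < min_stratum_n) {
      message(sprintf("subgroup '%s' = %s skipped: n = %d < %d",
                      stratifier, lev, nrow(sub), min_stratum_n))
      out[[lev]] <- list(skipped = TRUE, n = nrow(sub),
                         reason = sprintf("n below %d", min_stratum_n))
      next
    }
    fit <- ndhri_gam(sub, ...)
    res <- list(skipped = FALSE, n = nrow(sub), fit = fit,
                nadir = find_nadir(fit), range = derive_optimal_range(fit))
    if (tir) res$tir <- fit_time_in_range_model(sub, range = tir_range, ...)
    out[[lev]] <- res
  }
  out
}

#' Descriptive cohort table
#'
#' One row per study variable, with the field's standard summary kinds:
#' mean +/- SD for symmetric continuous variables, median [IQR] for skewed
#' ones, and n (%) for binary/categorical ones, plus the recorded-nights
#' accounting split by survival.
#'
#' @param stays included stay records (with outcomes).
#' @param summaries stay-level NDHRI summaries from [summarize_stays()]
#'   (matched by `stay_id`).
#' @return data.frame `variable`, `kind` (`"mean_sd"`, `"median_iqr"`,
#'   `"n_pct"`, `"count"`), `v1`, `v2`, `v3` (numeric components) and
#'   `formatted`.
#' @export
make_descriptive_table <- function(stays, summaries) {
  s <- merge(stays, summaries, by = "stay_id")
  n <- nrow(s)
  rows <- list()
  add <- function(variable, kind, v1, v2 = NA_real_, v3 = NA_real_) {
    fmt <- switch(kind,
      mean_sd = sprintf("%.1f ± %.1f", v1, v2),
      median_iqr = sprintf("%.0f [%.0f, %.0f]", v1, v2, v3),
      n_pct = sprintf("%d (%.1f%%)", as.integer(v1), v2),
      pct_mean_sd = sprintf("%.1f%% ± %.1f%%", v1, v2),
      count = sprintf("%d", as.integer(v1)))
    rows[[length(rows) + 1]] <<- data.frame(variable = variable, kind = kind,
                                            v1 = v1, v2 = v2, v3 = v3,
                                            formatted = fmt)
  }
  npct <- function(variable, x) add(variable, "n_pct", sum(x, na.rm = TRUE),
                                    100 * mean(x, na.rm = TRUE))
  med_iqr <- function(variable, x) {
    q <- quantile(x, c(0.5, 0.25, 0.75), na.rm = TRUE, names = FALSE)
    add(variable, "median_iqr", q[1], q[2], q[3])
  }

  add("age_years", "mean_sd", mean(s$age), sd(s$age))
  npct("male", s$gender == "male")
  add("bmi", "mean_sd", mean(s$bmi), sd(s$bmi))
  if (!is.null(s$ethnicity))
    for (e in sort(unique(s$ethnicity))) npct(paste0("ethnicity_", e),
                                              s$ethnicity == e)
  if (!is.null(s$icu_type))
    for (u in sort(unique(s$icu_type))) npct(paste0("icu_type_", u),
                                             s$icu_type == u)
  for (cm in intersect(names(.COMORBIDITIES), names(s)))
    npct(cm, s[[cm]] == 1)
  if (!is.null(s$apache_iv)) med_iqr("apache_iv", s$apache_iv)
  if (!is.null(s$admit_min))
    med_iqr("icu_length_of_stay_days",
            (s$discharge_min - s$admit_min) / 1440)
  surv <- s$hospital_mortality == 0
  med_iqr("recorded_nights_survivors", s$n_usable_days[surv])
  med_iqr("recorded_nights_nonsurvivors", s$n_usable_days[!surv])
  med_iqr("recorded_nights_total", s$n_usable_days)
  add("total_recorded_nights_survivors", "count", sum(s$n_usable_days[surv]))
  add("total_recorded_nights_nonsurvivors", "count",
      sum(s$n_usable_days[!surv]))
  add("total_recorded_nights", "count", sum(s$n_usable_days))
  npct("icu_mortality", s$icu_mortality == 1)
  npct("hospital_mortality", s$hospital_mortality == 1)
  add("mean_ndhri_pct", "pct_mean_sd", 100 * mean(s$mean_ndhri),
      100 * sd(s$mean_ndhri))
  add("prop_in_range_pct", "pct_mean_sd", 100 * mean(s$prop_in_range),
      100 * sd(s$prop_in_range))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Build the per-stay analysis table: included stays joined with NDHRI
# summaries, usable stays only.
.analysis_table <- function(stays, summaries) {
  d <- merge(stays, summaries[summaries$usable, ], by = "stay_id")
  d
}

#' Run the full study end-to-end
#'
#' Simulates (or takes) a cohort, applies the exclusion cascade, computes
#' daily and stay-level NDHRI, fits the primary U-shape model (adjusted and
#' unadjusted), locates the nadir, derives the optimal range, recomputes
#' time-in-range against that range (unless overridden), fits the
#' time-in-range model, and assembles the descriptive table. With `out_dir`
#' set, writes every table as CSV/JSON plus a run manifest (config hash,
#' seed, n); outputs are deterministic given `(cfg, seed)`.
#'
#' @param cfg an [ndhri_sim_config()] (used when `tables` is `NULL`).
#' @param seed integer seed for the simulated cohort.
#' @param tables optional list with `vitals` and `stays` (as from
#'   [read_tables()]) to analyze instead of simulating.
#' @param outcome `"hospital_mortality"` or `"icu_mortality"`.
#' @param range optional numeric length-2 override of the derived range
#'   (recorded in the manifest as an override).
#' @param coverage_threshold usable-day coverage threshold.
#' @param relaxed disable exclusion rules 1 and 8 (sensitivity refit).
#' @param contrast_offsets exposure offsets from the nadir at which
#'   odds-ratio contrasts are reported.
#' @param out_dir optional output directory.
#' @return list of class `ndhri_report`.
#' @export
run_study <- function(cfg = NULL, seed = 1L, tables = NULL,
                      outcome = "hospital_mortality", range = NULL,
                      coverage_threshold = 0.8, relaxed = FALSE,
                      contrast_offsets = c(-0.025, 0.025),
                      out_dir = NULL) {
  if (is.null(tables)) {
    if (is.null(cfg)) .stopf("either cfg or tables must be given")
    cohort <- simulate_cohort(cfg, seed = seed)
    tables <- cohort[c("vitals", "stays")]
  }
  excl <- apply_exclusions(tables$stays, tables$vitals,
                           coverage_threshold = coverage_threshold,
                           relaxed = relaxed)
  daily <- excl$daily
  summaries0 <- summarize_stays(daily, 0.40, 0.45)
  adat <- .analysis_table(excl$stays, summaries0)

  fit_adj <- ndhri_gam(adat, outcome = outcome, adjust = TRUE)
  fit_unadj <- ndhri_gam(adat, outcome = outcome, adjust = FALSE)
  nadir <- find_nadir(fit_adj)
  rng <- derive_optimal_range(fit_adj)
  range_overridden <- !is.null(range)
  use_range <- if (range_overridden) as.numeric(range)
               else if (rng$success) c(rng$lo, rng$hi) else c(0.40, 0.45)

  summaries <- summarize_stays(daily, use_range[1], use_range[2])
  adat <- .analysis_table(excl$stays, summaries)
  tir <- fit_time_in_range_model(adat, range = use_range, outcome = outcome)

  contr_x1 <- pmin(pmax(nadir$nadir + contrast_offsets,
                        fit_adj$exposure_range[1]),
                   fit_adj$exposure_range[2])
  contrasts <- list(
    adjusted = contrast_odds_ratio(fit_adj, contr_x1, nadir$nadir),
    unadjusted = contrast_odds_ratio(fit_unadj, contr_x1, nadir$nadir))
  curve_primary <- predict(fit_adj)
  curve_tir <- if (!tir$flat) predict(tir$model) else NULL
  descr <- make_descriptive_table(excl$stays, summaries)

  report <- list(ledger = excl$ledger, daily = daily, summaries = summaries,
                 analysis = adat, fit_adjusted = fit_adj,
                 fit_unadjusted = fit_unadj, nadir = nadir, range = rng,
                 range_used = use_range, range_overridden = range_overridden,
                 contrasts = contrasts, curve_primary = curve_primary,
                 tir = tir, curve_tir = curve_tir, descriptive = descr,
                 outcome = outcome, seed = seed, relaxed = relaxed,
                 n_outliers_removed = excl$n_outliers_removed)
  class(report) <- "ndhri_report"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(descr, file.path(out_dir, "descriptive.csv"), row.names = FALSE)
    write_ledger(excl$ledger, file.path(out_dir, "ledger.csv"),
                 file.path(out_dir, "ledger.json"))
    write.csv(daily, file.path(out_dir, "daily_ndhri.csv"), row.names = FALSE)
    write.csv(summaries, file.path(out_dir, "stay_summaries.csv"),
              row.names = FALSE)
    write.csv(curve_primary, file.path(out_dir, "curve_primary.csv"),
              row.names = FALSE)
    if (!is.null(curve_tir))
      write.csv(curve_tir, file.path(out_dir, "curve_tir.csv"),
                row.names = FALSE)
    .write_json(list(adjusted = as.data.frame(contrasts$adjusted),
                     unadjusted = as.data.frame(contrasts$unadjusted)),
                file.path(out_dir, "contrasts.json"))
    .write_json(list(outcome = outcome, n = fit_adj$n,
                     nadir = nadir$nadir, nadir_boundary = nadir$boundary,
                     range_lo = use_range[1], range_hi = use_range[2],
                     range_overridden = range_overridden,
                     smooth_p_adjusted = smooth_significance(fit_adj),
                     smooth_p_unadjusted = smooth_significance(fit_unadj),
                     tir_avg_derivative = tir$avg_derivative,
                     tir_smooth_p = tir$smooth_p,
                     hospital_re_sd = random_intercept_sd(fit_adj)),
                file.path(out_dir, "fit_summary.json"))
    manifest <- list(seed = seed, outcome = outcome, relaxed = relaxed,
                     coverage_threshold = coverage_threshold,
                     range_overridden = range_overridden,
                     config_hash = if (!is.null(cfg)) .config_hash(unclass(cfg))
                                   else NA,
                     n_input = attr(excl$ledger, "n_input"),
                     n_included = attr(excl$ledger, "n_included"))
    .write_json(manifest, file.path(out_dir, "manifest.json"))
  }
  report
}

#' @export
print.ndhri_report <- function(x, ...) {
  cat("NDHRI study report\n")
  print(x$ledger)
  cat(sprintf("analyzed stays: %d (%s)\n", x$fit_adjusted$n, x$outcome))
  cat(sprintf("nadir: %.3f%s; smooth p (adjusted) = %.3g\n", x$nadir$nadir,
              if (x$nadir$boundary) " (boundary)" else "",
              smooth_significance(x$fit_adjusted)))
  print(x$range)
  cat("contrasts (adjusted):\n"); print(x$contrasts$adjusted)
  print(x$tir)
  invisible(x)
}

#' Parameter-recovery experiment
#'
#' Runs the pipeline over `n_replicates` independent synthetic cohorts and
#' aggregates recovery metrics for the generator's known truth: nadir bias
#' and RMSE, how often the derived range equals the rounded truth, the
#' direction of the odds-ratio contrasts on both arms of the U (adjusted and
#' unadjusted), the smooth-term rejection rate at `alpha`, and the
#' time-in-range direction. Replicates that fail at any stage are recorded
#' and skipped.
#'
#' @param cfg an [ndhri_sim_config()]; `cfg$u_nadir` is the recovery target.
#' @param n_replicates number of replicates (>= 1).
#' @param seed base seed; replicate r uses `seed + r`.
#' @param mode `"full"` simulates vitals and runs the entire pipeline
#'   (exclusions, NDHRI, fits); `"exposure_only"` skips the vitals stage and
#'   fits directly on the true stay-level exposure — the cheap configuration
#'   for smooth-test calibration studies.
#' @param contrast_delta offsets from the true nadir for the contrast checks.
#' @param alpha level of the smooth-significance rejection count.
#' @param adjust_only in `"exposure_only"` mode, skip the unadjusted refit.
#' @param tir also fit the time-in-range model per replicate (`"full"` mode).
#' @return list of class `ndhri_recovery` with `replicates` (one row per
#'   replicate) and `metrics`.
#' @export
run_recovery_experiment <- function(cfg, n_replicates, seed = 1L,
                                    mode = c("full", "exposure_only"),
                                    contrast_delta = 0.025, alpha = 0.05,
                                    adjust_only = FALSE, tir = TRUE) {
  mode <- match.arg(mode)
  validate_sim_config(cfg)
  if (is.na(n_replicates) || n_replicates < 1)
    .stopf("n_replicates must be >= 1")
  nu <- cfg$u_nadir
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    res <- tryCatch({
      if (mode == "full") {
        rep_out <- run_study(cfg, seed = seed + r,
                             contrast_offsets = c(-contrast_delta,
                                                  contrast_delta))
        fit_adj <- rep_out$fit_adjusted
        fit_un <- rep_out$fit_unadjusted
        nad <- rep_out$nadir
        rng <- rep_out$range
        co_a <- contrast_odds_ratio(fit_adj, nu + c(-1, 1) * contrast_delta, nu)
        co_u <- contrast_odds_ratio(fit_un, nu + c(-1, 1) * contrast_delta, nu)
        data.frame(replicate = r, failed = FALSE,
                   n = fit_adj$n, nadir = nad$nadir,
                   boundary = nad$boundary,
                   range_lo = rng$lo, range_hi = rng$hi,
                   or_low_adj = co_a$odds_ratio[1],
                   or_high_adj = co_a$odds_ratio[2],
                   or_low_unadj = co_u$odds_ratio[1],
                   or_high_unadj = co_u$odds_ratio[2],
                   smooth_p = smooth_significance(fit_adj),
                   tir_avg_derivative = rep_out$tir$avg_derivative,
                   tir_smooth_p = if (rep_out$tir$flat) NA_real_
                                  else rep_out$tir$smooth_p)
      } else {
        set.seed(seed + r)
        truth <- simulate_true_states(cfg, seed = NULL)
        oc <- simulate_outcomes(truth, cfg, seed = NULL)
        d <- truth
        d$hospital_mortality <- oc$hospital_mortality
        d$mean_ndhri <- d$true_ndhri
        d$prop_in_range <- d$true_prop_in_range
        fit_adj <- ndhri_gam(d, outcome = "hospital_mortality",
                             exposure = "mean_ndhri")
        nad <- find_nadir(fit_adj)
        rng <- derive_optimal_range(fit_adj)
        lo_ok <- nu - contrast_delta >= fit_adj$exposure_range[1]
        hi_ok <- nu + contrast_delta <= fit_adj$exposure_range[2]
        co_a <- if (lo_ok && hi_ok)
          contrast_odds_ratio(fit_adj, nu + c(-1, 1) * contrast_delta, nu)
        else data.frame(odds_ratio = c(NA_real_, NA_real_))
        co_u <- if (!adjust_only) {
          fit_un <- ndhri_gam(d, outcome = "hospital_mortality",
                              exposure = "mean_ndhri", adjust = FALSE)
          if (lo_ok && hi_ok)
            contrast_odds_ratio(fit_un, nu + c(-1, 1) * contrast_delta, nu)
          else data.frame(odds_ratio = c(NA_real_, NA_real_))
        } else data.frame(odds_ratio = c(NA_real_, NA_real_))
        data.frame(replicate = r, failed = FALSE, n = fit_adj$n,
                   nadir = nad$nadir, boundary = nad$boundary,
                   range_lo = rng$lo, range_hi = rng$hi,
                   or_low_adj = co_a$odds_ratio[1],
                   or_high_adj = co_a$odds_ratio[2],
                   or_low_unadj = co_u$odds_ratio[1],
                   or_high_unadj = co_u$odds_ratio[2],
                   smooth_p = smooth_significance(fit_adj),
                   tir_avg_derivative = NA_real_, tir_smooth_p = NA_real_)
      }
    }, error = function(e) {
      data.frame(replicate = r, failed = TRUE, n = NA_integer_,
                 nadir = NA_real_, boundary = NA, range_lo = NA_real_,
                 range_hi = NA_real_, or_low_adj = NA_real_,
                 or_high_adj = NA_real_, or_low_unadj = NA_real_,
                 or_high_unadj = NA_real_, smooth_p = NA_real_,
                 tir_avg_derivative = NA_real_, tir_smooth_p = NA_real_)
    })
    rows[[r]] <- res
  }
  reps <- do.call(rbind, rows)
  ok <- reps[!reps$failed, , drop = FALSE]
  n_ok <- nrow(ok)
  mse <- function(x) sqrt(mean(x^2, na.rm = TRUE))
  metrics <- list(
    n_replicates = n_replicates,
    n_failed = sum(reps$failed),
    true_nadir = nu,
    nadir_bias = mean(ok$nadir - nu, na.rm = TRUE),
    nadir_mean_abs_error = mean(abs(ok$nadir - nu), na.rm = TRUE),
    nadir_rmse = mse(ok$nadir - nu),
    prop_range_recovered = mean(!is.na(ok$range_lo) &
                                abs(ok$range_lo - .round_step(nu - 0.025, 0.005)) < 1e-9 &
                                abs(ok$range_hi - .round_step(nu + 0.025, 0.005)) < 1e-9),
    prop_or_low_gt1_adj = mean(ok$or_low_adj > 1, na.rm = TRUE),
    prop_or_high_gt1_adj = mean(ok$or_high_adj > 1, na.rm = TRUE),
    prop_or_low_gt1_unadj = mean(ok$or_low_unadj > 1, na.rm = TRUE),
    prop_or_high_gt1_unadj = mean(ok$or_high_unadj > 1, na.rm = TRUE),
    rejection_rate = mean(ok$smooth_p < alpha, na.rm = TRUE),
    rejection_rate_mc_se = if (n_ok > 0)
      sqrt(mean(ok$smooth_p < alpha, na.rm = TRUE) *
           (1 - mean(ok$smooth_p < alpha, na.rm = TRUE)) / n_ok) else NA_real_,
    tir_negative_share = mean(ok$tir_avg_derivative < 0, na.rm = TRUE),
    seeds = seed + seq_len(n_replicates))
  out <- list(replicates = reps, metrics = metrics, mode = mode, cfg = cfg)
  class(out) <- "ndhri_recovery"
  out
}

#' @export
print.ndhri_recovery <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("Recovery experiment (%s mode): %d replicates, %d failed\n",
              x$mode, m$n_replicates, m$n_failed))
  cat(sprintf("  nadir: truth %.3f, bias %+0.4f, mean|err| %.4f, RMSE %.4f\n",
              m$true_nadir, m$nadir_bias, m$nadir_mean_abs_error,
              m$nadir_rmse))
  cat(sprintf("  rounded range recovered: %.0f%%\n",
              100 * m$prop_range_recovered))
  cat(sprintf("  OR > 1 below/above nadir: adj %.0f%%/%.0f%%, unadj %.0f%%/%.0f%%\n",
              100 * m$prop_or_low_gt1_adj, 100 * m$prop_or_high_gt1_adj,
              100 * m$prop_or_low_gt1_unadj, 100 * m$prop_or_high_gt1_unadj))
  cat(sprintf("  smooth-term rejection rate at alpha: %.3f (MC SE %.3f)\n",
              m$rejection_rate, m$rejection_rate_mc_se))
  invisible(x)
}
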