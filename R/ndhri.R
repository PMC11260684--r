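## Core index computation: per-circadian-day night/day cumulative heart-rate
## areas, their ratio (NDHRI), stay-level summaries.
##
## A circadian day is the daytime window [06:00, 22:00) followed by the night
## window [22:00, 06:00 next day) that begins the same evening, so each daily
## index describes one contiguous 24-h physiological cycle. Each 5-min
## observation contributes a bar of area 5 * heart_rate (bpm*min); missing
## slots contribute nothing and are never imputed -- they only reduce window
## coverage, and a day is usable only when both windows reach the coverage
## threshold.

#' Cumulative heart-rate area of a window
#'
#' Each recorded heart rate is treated as the average over its 5-min slot, so
#' the area of one bar is `5 * hr` (bpm*min) and the window area is the sum
#' of the bars present.
#'
#' @param heart_rate numeric vector of heart rates (bpm) present in the
#'   window.
#' @return the cumulative area in bpm*min.
#' @examples
#' compute_window_area(rep(80, 96)) # a fully covered 8-h night at 80 bpm
#' @export
compute_window_area <- function(heart_rate) {
  sum(.SLOT_MIN * heart_rate)
}

#' Segment one stay's series into circadian day/night windows
#'
#' Emits every circadian day overlapping the recorded series (and, when
#' given, the admission interval), with per-window slot counts and coverage.
#' Coverage is relative to the full window size (192 daytime slots, 96 night
#' slots), so partially overlapped first/last windows simply show low
#' coverage; there is no special-casing.
#'
#' @param series data.frame with `t_min` (minutes since epoch, on the 5-min
#'   grid) and `heart_rate`.
#' @param admit_time,discharge_time optional stay boundaries (POSIXct,
#'   ISO-8601 string, or minutes).
#' @return data.frame with one row per (circadian day, window): `cal_day`
#'   (circadian day id), `window` ("day"/"night"), `n_present`, `n_expected`,
#'   `coverage`.
#' @export
segment_circadian_days <- function(series, admit_time = NULL,
                                   discharge_time = NULL) {
  if (!is.null(admit_time) && !is.null(discharge_time)) {
    a <- .minutes(admit_time); d <- .minutes(discharge_time)
    if (d < a) .stopf("discharge before admission")
  }
  lo <- hi <- NULL
  if (nrow(series)) {
    lo <- min(series$t_min); hi <- max(series$t_min)
  }
  if (!is.null(admit_time)) {
    a <- .minutes(admit_time); d <- .minutes(discharge_time)
    lo <- min(lo, a); hi <- max(hi, d - .SLOT_MIN)
  }
  if (is.null(lo)) {
    return(data.frame(cal_day = integer(0), window = character(0),
                      n_present = integer(0), n_expected = integer(0),
                      coverage = numeric(0)))
  }
  days <- seq(.circadian_day(lo), .circadian_day(hi))
  cd <- .circadian_day(series$t_min)
  night <- .is_night(series$t_min)
  n_day <- vapply(days, function(d) sum(cd == d & !night), integer(1))
  n_night <- vapply(days, function(d) sum(cd == d & night), integer(1))
  out <- data.frame(
    cal_day = rep(days, each = 2L),
    window = rep(c("day", "night"), length(days)),
    n_present = as.integer(rbind(n_day, n_night)),
    n_expected = rep(c(.N_DAY_SLOTS, .N_NIGHT_SLOTS), length(days)))
  out$coverage <- out$n_present / out$n_expected
  out
}

#' Per-circadian-day NDHRI for a whole vitals table
#'
#' Vectorized over all stays: for every circadian day with any data, computes
#' the night and day cumulative areas, their ratio (the NDHRI), window
#' coverages, and the usability flag (both coverages at or above the
#' threshold and a positive daytime area).
#'
#' @param vitals data.frame with `stay_id`, `t_min` (minutes since epoch on
#'   the 5-min grid) and `heart_rate`.
#' @param coverage_threshold minimum fraction of slots that must be present
#'   in both the day and the night window for the day to be usable
#'   (default 0.8).
#' @return data.frame with columns `stay_id`, `day_index` (ordinal within
#'   stay), `cal_day`, `night_area`, `day_area`, `ndhri`, `night_coverage`,
#'   `day_coverage`, `usable`.
#' @export
compute_daily_ndhri <- function(vitals, coverage_threshold = 0.8) {
  if (!nrow(vitals)) {
    return(data.frame(stay_id = integer(0), day_index = integer(0),
                      cal_day = integer(0), night_area = numeric(0),
                      day_area = numeric(0), ndhri = numeric(0),
                      night_coverage = numeric(0), day_coverage = numeric(0),
                      usable = logical(0)))
  }
  cd <- .circadian_day(vitals$t_min)
  night <- .is_night(vitals$t_min)
  sid <- vitals$stay_id
  cd0 <- cd - min(cd)
  span <- max(cd0) + 1
  sid_f <- match(sid, sort(unique(sid)))
  g <- as.integer((sid_f - 1) * span + cd0) # unique (stay, circadian day) key

  area <- .SLOT_MIN * vitals$heart_rate
  keys <- sort(unique(g))
  K <- length(keys)
  ki <- match(g, keys)
  acc <- function(x, sel) {
    out <- numeric(K)
    if (any(sel)) {
      tmp <- rowsum(x[sel], ki[sel])
      out[as.integer(rownames(tmp))] <- tmp[, 1]
    }
    out
  }
  night_area <- acc(area, night)
  day_area <- acc(area, !night)
  n_night <- tabulate(ki[night], K)
  n_day <- tabulate(ki[!night], K)

  sids <- sort(unique(sid))
  out <- data.frame(
    stay_id = sids[keys %/% span + 1],
    cal_day = keys %% span + min(cd),
    night_area = night_area,
    day_area = day_area,
    night_coverage = n_night / .N_NIGHT_SLOTS,
    day_coverage = n_day / .N_DAY_SLOTS)
  out$ndhri <- ifelse(out$day_area > 0, out$night_area / out$day_area, NA_real_)
  out$usable <- out$night_coverage >= coverage_threshold &
    out$day_coverage >= coverage_threshold & out$day_area > 0
  out <- out[order(out$stay_id, out$cal_day), ]
  out$day_index <- stats::ave(seq_len(nrow(out)), out$stay_id,
                              FUN = seq_along)
  rownames(out) <- NULL
  out[c("stay_id", "day_index", "cal_day", "night_area", "day_area", "ndhri",
        "night_coverage", "day_coverage", "usable")]
}

#' Stay-level NDHRI summaries
#'
#' Mean NDHRI over a stay's usable circadian days and the proportion of
#' usable days whose NDHRI falls inside the closed target interval
#' `[range_lo, range_hi]`. Stays without a usable day are flagged rather
#' than erroring.
#'
#' @param daily output of [compute_daily_ndhri()].
#' @param range_lo,range_hi target-range endpoints (NDHRI fractions;
#'   the interval is closed at both ends).
#' @return data.frame `stay_id`, `n_usable_days`, `mean_ndhri`,
#'   `prop_in_range`, `usable`.
#' @export
summarize_stays <- function(daily, range_lo = 0.40, range_hi = 0.45) {
  if (range_lo >= range_hi) .stopf("range_lo must be below range_hi")
  sids <- sort(unique(daily$stay_id))
  use <- daily[daily$usable & !is.na(daily$ndhri), ]
  n_us <- rowsum(rep(1L, nrow(use)), use$stay_id)
  sum_nd <- rowsum(use$ndhri, use$stay_id)
  in_rng <- as.numeric(use$ndhri >= range_lo & use$ndhri <= range_hi)
  sum_in <- rowsum(in_rng, use$stay_id)
  idx <- match(as.character(sids), rownames(n_us))
  n_usable <- ifelse(is.na(idx), 0L, n_us[idx, 1])
  mean_ndhri <- ifelse(n_usable > 0, sum_nd[idx, 1] / n_usable, NA_real_)
  prop <- ifelse(n_usable > 0, sum_in[idx, 1] / n_usable, NA_real_)
  data.frame(stay_id = sids, n_usable_days = as.integer(n_usable),
             mean_ndhri = mean_ndhri, prop_in_range = prop,
             usable = n_usable > 0)
}
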