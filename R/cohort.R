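## Reading eICU-style tables and the ten-rule exclusion cascade with an
## auditable attrition ledger.

.VITALS_REQUIRED <- c("stay_id", "clock_time", "heart_rate")
.STAYS_REQUIRED <- c("stay_id", "hospital_id", "age", "gender", "bmi",
                     "admit_time", "discharge_time", "icu_mortality",
                     "hospital_mortality")

#' Read vitals and stays CSV tables
#'
#' Parses ISO-8601 clock times, snaps timestamps to the nearest 5-min grid
#' slot, sorts vitals within stay by time, and collapses duplicate
#' `(stay_id, clock_time)` rows to their mean with a warning. Missing
#' mandatory columns raise a schema error naming the column. A missing
#' `patient_id` column makes each stay its own patient (so the repeat-stay
#' rule never fires); a missing `arrhythmia_or_pacemaker_history` column is
#' treated as all-negative.
#'
#' @param vitals_path,stays_path CSV paths matching the schemas written by
#'   [write_cohort()].
#' @return list with `vitals` (data.frame `stay_id`, `t_min`, `heart_rate`,
#'   sorted by stay and time) and `stays` (with `admit_min`/`discharge_min`
#'   numeric minutes).
#' @export
read_tables <- function(vitals_path, stays_path) {
  v <- read.csv(vitals_path, stringsAsFactors = FALSE)
  s <- read.csv(stays_path, stringsAsFactors = FALSE)
  miss_v <- setdiff(.VITALS_REQUIRED, names(v))
  if (length(miss_v))
    .stopf("vitals table is missing column(s): %s", paste(miss_v, collapse = ", "))
  miss_s <- setdiff(.STAYS_REQUIRED, names(s))
  if (length(miss_s))
    .stopf("stays table is missing column(s): %s", paste(miss_s, collapse = ", "))

  if (nrow(v)) {
    v$t_min <- .snap5(.minutes(.parse_time(v$clock_time)))
  } else {
    v$t_min <- numeric(0)
  }
  v <- v[order(v$stay_id, v$t_min), , drop = FALSE]
  key <- paste(v$stay_id, v$t_min)
  if (anyDuplicated(key)) {
    n_dup <- sum(duplicated(key))
    hr <- rowsum(v$heart_rate, key, reorder = FALSE) /
      rowsum(rep(1, nrow(v)), key, reorder = FALSE)
    first <- !duplicated(key)
    v <- v[first, , drop = FALSE]
    v$heart_rate <- as.numeric(hr[, 1])
    warning(sprintf("collapsed %d duplicate (stay_id, clock_time) row(s) to slot means",
                    n_dup), call. = FALSE)
  }
  vitals <- data.frame(stay_id = v$stay_id, t_min = v$t_min,
                       heart_rate = v$heart_rate)

  s$admit_min <- .minutes(.parse_time(s$admit_time))
  s$discharge_min <- .minutes(.parse_time(s$discharge_time))
  bad <- !is.na(s$admit_min) & !is.na(s$discharge_min) &
    s$discharge_min < s$admit_min
  if (any(bad)) .stopf("discharge before admission for stay(s): %s",
                       paste(head(s$stay_id[bad]), collapse = ", "))
  if (is.null(s$patient_id)) s$patient_id <- s$stay_id
  if (is.null(s$arrhythmia_or_pacemaker_history))
    s$arrhythmia_or_pacemaker_history <- 0L
  list(vitals = vitals, stays = s)
}

#' Remove heart-rate outliers from one stay's series
#'
#' Single-pass rule: the per-stay mean `m` and SD `s` are computed once on
#' the raw series, then points with `|hr - m| > 3 s` (strictly more than;
#' a point exactly at `m + 3s` is retained) are removed. With
#' `side = "upper"` only points above `m + 3s` are removed (the literal
#' one-sided reading of "exceeding the mean by").
#'
#' @param series data.frame with a `heart_rate` column (one stay).
#' @param n_sd the multiplier (default 3).
#' @param side `"two"` (default) or `"upper"`.
#' @return list with `series` (filtered) and `n_removed`.
#' @export
remove_hr_outliers <- function(series, n_sd = 3, side = c("two", "upper")) {
  side <- match.arg(side)
  if (!nrow(series)) return(list(series = series, n_removed = 0L))
  m <- mean(series$heart_rate)
  s <- sd(series$heart_rate)
  if (is.na(s)) s <- 0
  dev <- if (side == "two") abs(series$heart_rate - m) else series$heart_rate - m
  keep <- dev <= n_sd * s
  list(series = series[keep, , drop = FALSE], n_removed = sum(!keep))
}

# Vectorized across stays; same single-pass contract as remove_hr_outliers().
.trim_outliers_all <- function(vitals, n_sd = 3, side = "two") {
  if (!nrow(vitals)) return(list(vitals = vitals, n_removed = 0L))
  ui <- unique(vitals$stay_id)
  gi <- match(vitals$stay_id, ui)
  ni_g <- tabulate(gi, length(ui))
  sm_g <- as.numeric(rowsum(vitals$heart_rate, gi, reorder = FALSE))
  sq_g <- as.numeric(rowsum(vitals$heart_rate^2, gi, reorder = FALSE))
  m_g <- sm_g / ni_g
  var_g <- pmax((sq_g - ni_g * m_g^2) / pmax(ni_g - 1, 1), 0)
  m <- m_g[gi]
  s <- sqrt(var_g)[gi]
  dev <- if (side == "two") abs(vitals$heart_rate - m) else vitals$heart_rate - m
  keep <- dev <= n_sd * s
  list(vitals = vitals[keep, , drop = FALSE], n_removed = sum(!keep))
}

#' Apply the ten-rule exclusion cascade
#'
#' Applies the eligibility rules in their fixed order 1-10, attributing each
#' excluded stay to the first rule it violates:
#' \enumerate{
#'   \item no usable consecutive heart-rate coverage: no circadian day has at
#'     least `coverage_threshold` of its 5-min slots present in both the day
#'     and the night window (computed from the recorded vitals);
#'   \item repeat ICU stay: for each patient only the earliest admission is
#'     kept (`keep_stay = "last"` keeps the latest instead);
#'   \item missing age; \item age under 18; \item missing gender;
#'   \item missing BMI;
#'   \item admission and discharge on the same calendar date;
#'   \item 3-SD outlier trimming (see [remove_hr_outliers()]) leaves no
#'     usable circadian day;
#'   \item documented arrhythmia / cardiac arrest / pacemaker history;
#'   \item missing hospital or ICU mortality outcome.
#' }
#' Outlier trimming deletes points, not stays; it is applied exactly once and
#' the returned vitals are the trimmed ones. With `relaxed = TRUE` the two
#' heart-rate-quality rules (1 and 8) are disabled — the sensitivity refit
#' configuration.
#'
#' @param stays,vitals tables as returned by [read_tables()] (or
#'   [simulate_cohort()]).
#' @param coverage_threshold window coverage needed for a usable day.
#' @param keep_stay which stay to keep for multi-stay patients.
#' @param outlier_side passed to the 3-SD rule (`"two"` or `"upper"`).
#' @param relaxed disable rules 1 and 8.
#' @param rule_order evaluation order of the rules (a permutation of 1:10);
#'   the default is the canonical printed order. Permuting it can move stays
#'   between rule counts but never changes who is included.
#' @return list with `stays` (included), `vitals` (trimmed, included stays
#'   only), `daily` (post-trim per-day NDHRI table for included stays),
#'   `ledger` (an `ndhri_ledger`), `excluded` (stay_id and attributed
#'   rule), and `n_outliers_removed`.
#' @export
apply_exclusions <- function(stays, vitals, coverage_threshold = 0.8,
                             keep_stay = c("first", "last"),
                             outlier_side = c("two", "upper"),
                             relaxed = FALSE,
                             rule_order = 1:10) {
  keep_stay <- match.arg(keep_stay)
  outlier_side <- match.arg(outlier_side)
  rule_order <- as.integer(rule_order)
  if (!identical(sort(rule_order), 1:10))
    .stopf("rule_order must be a permutation of 1:10")
  n <- nrow(stays)
  excl_rule <- integer(n) # 0 = still active

  daily_raw <- compute_daily_ndhri(vitals, coverage_threshold)
  usable_ids_raw <- unique(daily_raw$stay_id[daily_raw$usable])

  trimmed <- .trim_outliers_all(vitals, side = outlier_side)
  daily_trim <- compute_daily_ndhri(trimmed$vitals, coverage_threshold)
  usable_ids_trim <- unique(daily_trim$stay_id[daily_trim$usable])

  violates <- function(r, active) {
    v <- switch(as.character(r),
      "1" = if (relaxed) rep(FALSE, n) else !(stays$stay_id %in% usable_ids_raw),
      "2" = {
        out <- rep(FALSE, n)
        act <- which(active)
        if (length(act)) {
          ord <- if (keep_stay == "first")
            order(stays$admit_min[act], stays$stay_id[act])
          else order(-stays$admit_min[act], stays$stay_id[act])
          dup <- duplicated(stays$patient_id[act][ord])
          out[act[ord]] <- dup
        }
        out
      },
      "3" = is.na(stays$age),
      "4" = !is.na(stays$age) & stays$age < 18,
      "5" = is.na(stays$gender) | stays$gender == "",
      "6" = is.na(stays$bmi),
      "7" = !is.na(stays$admit_min) & !is.na(stays$discharge_min) &
        .calendar_date(stays$admit_min) == .calendar_date(stays$discharge_min),
      "8" = if (relaxed) rep(FALSE, n) else
        !(stays$stay_id %in% usable_ids_trim),
      "9" = !is.na(stays$arrhythmia_or_pacemaker_history) &
        stays$arrhythmia_or_pacemaker_history == 1,
      "10" = is.na(stays$hospital_mortality) | is.na(stays$icu_mortality))
    v & active
  }

  for (r in rule_order) {
    active <- excl_rule == 0L
    hit <- violates(r, active)
    excl_rule[hit] <- r
  }

  counts <- vapply(1:10, function(r) sum(excl_rule == r), integer(1))
  ledger <- data.frame(rule_id = 1:10, rule_label = .RULE_LABELS,
                       n_excluded = counts)
  attr(ledger, "n_input") <- n
  attr(ledger, "n_included") <- n - sum(counts)
  class(ledger) <- c("ndhri_ledger", "data.frame")

  inc <- stays[excl_rule == 0L, , drop = FALSE]
  vit_inc <- trimmed$vitals[trimmed$vitals$stay_id %in% inc$stay_id, ,
                            drop = FALSE]
  daily_inc <- daily_trim[daily_trim$stay_id %in% inc$stay_id, , drop = FALSE]
  list(stays = inc, vitals = vit_inc, daily = daily_inc, ledger = ledger,
       excluded = data.frame(stay_id = stays$stay_id,
                             rule_id = excl_rule)[excl_rule > 0L, ],
       n_outliers_removed = trimmed$n_removed)
}

#' @export
print.ndhri_ledger <- function(x, ...) {
  cat(sprintf("Exclusion ledger: %d stays in, %d included\n",
              attr(x, "n_input"), attr(x, "n_included")))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %2d. %-55s %6d\n", x$rule_id[i], x$rule_label[i],
                x$n_excluded[i]))
  }
  invisible(x)
}

#' Write an exclusion ledger to CSV and/or JSON
#'
#' @param ledger an `ndhri_ledger` from [apply_exclusions()].
#' @param csv_path,json_path output paths (either may be `NULL`).
#' @return the ledger, invisibly.
#' @export
write_ledger <- function(ledger, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    df <- as.data.frame(ledger)
    write.csv(df, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    .write_json(list(n_input = attr(ledger, "n_input"),
                     n_included = attr(ledger, "n_included"),
                     rules = as.data.frame(ledger)), json_path)
  }
  invisible(ledger)
}
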