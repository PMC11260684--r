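## Internal time helpers. All clock arithmetic is done on integer minutes
## since the Unix epoch, UTC; CSV boundaries use ISO-8601 strings.

.minutes <- function(x) {
  if (inherits(x, "POSIXct")) return(as.numeric(x) / 60)
  if (inherits(x, "Date")) return(as.numeric(x) * 1440)
  if (is.character(x)) return(as.numeric(.parse_time(x)) / 60)
  as.numeric(x)
}

.as_clock <- function(t_min) {
  .POSIXct(t_min * 60, tz = "UTC")
}

.format_time <- function(t_min) {
  format(.as_clock(t_min), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

.parse_time <- function(x) {
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%SZ", "%Y-%m-%dT%H:%M:%S",
                                   "%Y-%m-%d %H:%M:%S", "%Y-%m-%d"))
  out
}

## Snap times to the 5-min observation grid.
.snap5 <- function(t_min) round(t_min / .SLOT_MIN) * .SLOT_MIN

## Circadian decomposition: a circadian day starts at 06:00 and consists of
## the 16-h daytime window followed by the 8-h night window ending 06:00 the
## next calendar day.
.circadian_day <- function(t_min) (t_min - .DAY_START_MIN) %/% 1440
.circadian_pos <- function(t_min) (t_min - .DAY_START_MIN) %% 1440
.is_night <- function(t_min) .circadian_pos(t_min) >= 960

.calendar_date <- function(t_min) as.Date(floor(t_min / 1440), origin = "1970-01-01")

.round_step <- function(x, step) round(x / step) * step

.mode_value <- function(x) {
  tab <- table(x)
  names(tab)[which.max(tab)]
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

## md5 of an object's JSON rendering, via a temp file (used for run manifests)
.config_hash <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(x, tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}
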