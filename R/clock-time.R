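#' Clock times as seconds since midnight
#'
#' A `clock_time` is an integer vector of seconds since midnight in
#' `[0, 86399]`, the representation used for every clock-valued sleep
#' variable (bed time, sleep onset/offset, device start/end). Durations are
#' plain integer seconds; wall-clock wrap (a sleep crossing midnight) is
#' handled by [elapsed_wrap()] and the anchored mapping used by
#' [mean_clock()].
#'
#' @param x integer-like seconds since midnight, each in `[0, 86399]`.
#' @return An integer vector of class `clock_time`.
#' @seealso [parse_clock()], [elapsed_wrap()], [mean_clock()]
#' @export
#' @examples
#' clock_time(c(1182, 26860))
clock_time <- function(x) {
  x <- as.numeric(x)
  if (any(!is.finite(x) | x != floor(x), na.rm = TRUE))
    stop("clock_time values must be whole seconds", call. = FALSE)
  if (any(x < 0 | x > 86399, na.rm = TRUE))
    stop("clock_time values must lie in [0, 86399] seconds", call. = FALSE)
  structure(as.integer(x), class = "clock_time")
}

#' @export
format.clock_time <- function(x, ...) {
  s <- unclass(x)
  out <- sprintf("%02d:%02d:%02d", s %/% 3600L, (s %% 3600L) %/% 60L, s %% 60L)
  out[is.na(s)] <- NA_character_
  out
}

#' @export
print.clock_time <- function(x, ...) {
  print(format(x), quote = FALSE, ...)
  invisible(x)
}

#' @export
`[.clock_time` <- function(x, i) clock_time(unclass(x)[i])

#' Seconds-since-midnight accessor
#' @param x a `clock_time` or numeric seconds.
#' @return integer seconds since midnight.
#' @export
clock_seconds <- function(x) {
  if (inherits(x, "clock_time")) as.integer(unclass(x)) else as.integer(x)
}

#' Parse clock strings to clock times
#'
#' Accepts 24-hour `"H:MM"` / `"H:MM:SS"` (hour 0--24; `"24:00"` wraps to
#' midnight) and 12-hour times with an `AM`/`PM` marker
#' (`"12:28:21 AM"` is 28 minutes past midnight). ISO 8601 timestamps are
#' handled by the record readers, not here.
#'
#' @param text character vector of clock strings.
#' @return a [clock_time()] vector.
#' @export
#' @examples
#' parse_clock(c("12:19:42 AM", "24:00", "7:27:40 AM"))
parse_clock <- function(text) {
  text <- trimws(as.character(text))
  m <- regmatches(text, regexec(
    "^([0-9]{1,2}):([0-9]{2})(?::([0-9]{2}))?(?:\\s*([AaPp])\\.?[Mm]\\.?)?$",
    text))
  out <- integer(length(text))
  for (i in seq_along(text)) {
    g <- m[[i]]
    if (!length(g)) stop("malformed clock string: '", text[i], "'", call. = FALSE)
    hh <- as.integer(g[2]); mm <- as.integer(g[3])
    ss <- if (nzchar(g[4])) as.integer(g[4]) else 0L
    mer <- toupper(g[5])
    if (mm > 59L) stop("minute out of range in '", text[i], "'", call. = FALSE)
    if (ss > 59L) stop("second out of range in '", text[i], "'", call. = FALSE)
    if (nzchar(mer)) {
      if (hh < 1L || hh > 12L)
        stop("hour out of range for 12-hour time in '", text[i], "'", call. = FALSE)
      hh <- hh %% 12L + if (mer == "P") 12L else 0L
    } else {
      if (hh > 24L) stop("hour out of range in '", text[i], "'", call. = FALSE)
      hh <- hh %% 24L  # "24:00" is the midnight wrap convention
    }
    out[i] <- hh * 3600L + mm * 60L + ss
  }
  clock_time(out)
}

#' Parse chatbot button responses (hour 1--24, minute on the 5-minute grid)
#'
#' The chatbot presents 24 hour buttons ("1:00".."24:00") and 12 minute
#' buttons ("0".."55" in steps of 5); "24:00" means midnight.
#'
#' @param hour integer vector in 1..24.
#' @param minute integer vector in `{0, 5, ..., 55}`.
#' @return a [clock_time()] vector.
#' @export
parse_clock_buttons <- function(hour, minute) {
  hour <- as.integer(hour); minute <- as.integer(minute)
  if (any(is.na(hour) | hour < 1L | hour > 24L))
    stop("chatbot hour button must be in 1..24", call. = FALSE)
  if (any(is.na(minute) | minute < 0L | minute > 55L | minute %% 5L != 0L))
    stop("chatbot minute button must be one of 0, 5, ..., 55", call. = FALSE)
  clock_time((hour %% 24L) * 3600L + minute * 60L)
}

#' Wrap-aware elapsed time between two clock instants
#'
#' `elapsed_wrap(start, end)` is `(end - start) mod 24 h`, strictly inside
#' `(0, 86400)`: a sleep from 23:00 to 01:00 lasts 2 hours, never -22. A
#' zero-length interval is rejected (a degenerate sleep is never valid).
#'
#' @param start,end `clock_time` (or seconds) vectors, recycled.
#' @return integer seconds in `(0, 86400)`.
#' @export
#' @examples
#' elapsed_wrap(parse_clock("00:19:42"), parse_clock("07:27:40"))  # 25678
elapsed_wrap <- function(start, end) {
  s <- clock_seconds(start); e <- clock_seconds(end)
  d <- (e - s) %% 86400L
  if (any(d == 0L, na.rm = TRUE))
    stop("degenerate interval: start equals end", call. = FALSE)
  as.integer(d)
}

# Anchored (circular) mapping ------------------------------------------------
#
# Clock times are lifted onto a signed axis relative to an anchor (default
# noon): times in [12:00, 24:00) of the evening map to negative seconds,
# morning times to positive, range (-43200, +43200]. This is the "add 24 h
# where needed" device expressed as a bijection, so means of times straddling
# midnight are well defined.

ANCHOR_NOON <- 43200L

#' Map clock times onto the signed anchored axis
#' @param x `clock_time` or seconds.
#' @param anchor anchor instant (seconds since midnight); default noon.
#' @return signed integer seconds in `(-43200, 43200]` relative to the point
#'   opposite the anchor (midnight, for the noon anchor).
#' @export
as_anchored <- function(x, anchor = ANCHOR_NOON) {
  t <- clock_seconds(x); a <- clock_seconds(anchor)
  ((t - a - 1L) %% 86400L) + 1L - 43200L
}

#' Map anchored seconds back to clock times
#' @param a signed anchored seconds.
#' @inheritParams as_anchored
#' @return a [clock_time()] vector.
#' @export
from_anchored <- function(a, anchor = ANCHOR_NOON) {
  clock_time((as.integer(round(a)) + 43200L + clock_seconds(anchor)) %% 86400L)
}

#' Anchored (circular) mean of times of day
#'
#' Times are mapped to the signed anchored axis (evening negative, morning
#' positive for the default noon anchor), averaged arithmetically, and mapped
#' back; `mean_clock(c("23:00", "01:00"))` is midnight, not noon. The result
#' is rounded to the nearest whole second. A time falling exactly on the
#' anchor has no defined night and is an error.
#'
#' @param times `clock_time` vector (or parseable strings), non-empty.
#' @inheritParams as_anchored
#' @return a length-1 [clock_time()].
#' @export
mean_clock <- function(times, anchor = ANCHOR_NOON) {
  if (is.character(times)) times <- parse_clock(times)
  t <- clock_seconds(times)
  if (!length(t)) stop("mean_clock of an empty set is undefined", call. = FALSE)
  if (anyNA(t)) stop("mean_clock: missing values", call. = FALSE)
  if (any(t == clock_seconds(anchor)))
    stop("time exactly on the anchor boundary: night is ambiguous", call. = FALSE)
  from_anchored(mean(as_anchored(t, anchor)), anchor)
}

#' Format seconds as a signed h:mm:ss duration
#' @param seconds numeric seconds (may be negative).
#' @return character like `"-0:08:39"` or `"7:07:58"`.
#' @export
format_hms <- function(seconds) {
  s <- as.integer(round(seconds))
  sgn <- ifelse(s < 0, "-", "")
  s <- abs(s)
  sprintf("%s%d:%02d:%02d", sgn, s %/% 3600L, (s %% 3600L) %/% 60L, s %% 60L)
}
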