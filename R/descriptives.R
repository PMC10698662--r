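#' Rounding-tendency (digit-preference) minute profile
#'
#' Counts minute-of-hour values on the 12-bin 5-minute grid
#' (0, 5, ..., 55) and reports the share sitting on the :00/:30 half-hour
#' grid (`grid_fraction`) — the heaping signature of self-reported times.
#'
#' Sources and variables:
#' * `chat`: `bed_time`, `fall_asleep`, `wake`, `ast` — already on the
#'   button grid.
#' * `psqi`: `bed_time`, `wake`, `ast` (reported sleep hours), and
#'   `fall_asleep`, derived as bed time + sleep-onset latency.
#' * `fitbit`: `fall_asleep` (start), `wake` (end), `ast` (TST - WASO);
#'   second-resolution values are snapped to the nearest 5-minute bin first
#'   (ties, exactly 2.5 min, round down).
#'
#' @param records the matching record stream (diary, survey, or device
#'   data frame in reader layout).
#' @param source one of `"chat"`, `"psqi"`, `"fitbit"`.
#' @param variable one of `"bed_time"`, `"fall_asleep"`, `"wake"`, `"ast"`.
#' @return object of class `rounding_histogram`: source, variable, `counts`
#'   (named 0..55), `n`, `grid_fraction`.
#' @export
minute_profile <- function(records, source = c("chat", "psqi", "fitbit"),
                           variable = c("bed_time", "fall_asleep", "wake",
                                        "ast")) {
  source <- match.arg(source); variable <- match.arg(variable)
  if (!nrow(records)) stop("empty input", call. = FALSE)

  snap5_down <- function(secs) {
    # nearest 5-minute bin, tie at exactly 2.5 min rounds down
    r <- secs %% 300
    (as.integer(secs - r + ifelse(r > 150, 300, 0))) %% 86400L
  }
  mins <- switch(source,
    chat = switch(variable,
      bed_time = (records$bed_time %/% 60L) %% 60L,
      fall_asleep = (records$asleep_time %/% 60L) %% 60L,
      wake = (records$wake_time %/% 60L) %% 60L,
      ast = records$ast_minutes %% 60L),
    psqi = switch(variable,
      bed_time = (records$bed_time %/% 60L) %% 60L,
      fall_asleep = (((records$bed_time + records$sol_minutes * 60L) %%
                        86400L) %/% 60L) %% 60L,
      wake = (records$wake_time %/% 60L) %% 60L,
      ast = as.integer(round(records$reported_sleep_h * 60)) %% 60L),
    fitbit = {
      tst <- elapsed_wrap(records$start_time, records$end_time)
      switch(variable,
        bed_time = stop("device records have no bed time", call. = FALSE),
        fall_asleep = (snap5_down(records$start_time) %/% 60L) %% 60L,
        wake = (snap5_down(records$end_time) %/% 60L) %% 60L,
        ast = (snap5_down(tst - records$minutes_awake * 60L) %/% 60L) %% 60L)
    })
  if (any(mins %% 5L != 0L))
    stop("minute values off the 5-minute grid after snapping", call. = FALSE)
  counts <- table(factor(mins, levels = seq(0L, 55L, by = 5L)))
  n <- sum(counts)
  structure(list(source = source, variable = variable,
                 counts = counts, n = n,
                 grid_fraction = unname((counts["0"] + counts["30"]) / n)),
            class = "rounding_histogram")
}

#' @export
print.rounding_histogram <- function(x, ...) {
  cat(sprintf("%s / %s: n=%d, on :00/:30 grid %.1f%%\n",
              x$source, x$variable, x$n, 100 * x$grid_fraction))
  print(x$counts)
  invisible(x)
}

#' Threshold coverage of device values for diary responses
#'
#' For each night, how often is the diary value within a tolerance of the
#' device value — the practical question of whether device data can stand in
#' for the self-report. Optionally re-centres the differences first:
#' `"global_mean"` subtracts the full-sample mean difference;
#' `"by_qos"` subtracts the good/poor-night stratum mean difference
#' (stratum means computed per night over the same input). No night is ever
#' dropped by a correction.
#'
#' @param nights [derive_nights()] output.
#' @param pair `"tst_vs_tst"` (diary TST vs device TST) or
#'   `"ast_vs_tstwaso"` (diary AST vs device TST - WASO).
#' @param threshold_minutes tolerance (e.g. 30 or 60).
#' @param correction `"none"`, `"global_mean"`, or `"by_qos"`.
#' @param inclusive if `TRUE` (default) the boundary counts
#'   (|diff| <= threshold); the strict variant uses `<`. Diary values sit on
#'   the half-hour grid, so the boundary mass is not negligible.
#' @return object of class `coverage_result`: threshold, correction,
#'   `n_within`, `n_total`, `percent` (one decimal).
#' @export
coverage <- function(nights, pair = c("tst_vs_tst", "ast_vs_tstwaso"),
                     threshold_minutes, correction = c("none", "global_mean",
                                                       "by_qos"),
                     inclusive = TRUE) {
  pair <- match.arg(pair); correction <- match.arg(correction)
  if (!nrow(nights)) stop("empty night set", call. = FALSE)
  d <- switch(pair, tst_vs_tst = nights$d_tst, ast_vs_tstwaso = nights$d_ast)
  d <- as.numeric(d)
  if (correction == "global_mean") {
    d <- d - mean(d)
  } else if (correction == "by_qos") {
    g <- classify_qos(nights$qos)
    d <- d - stats::ave(d, g)
  }
  thr <- threshold_minutes * 60
  within <- if (inclusive) abs(d) <= thr else abs(d) < thr
  structure(list(pair = pair, threshold_minutes = threshold_minutes,
                 correction = correction, inclusive = inclusive,
                 n_within = sum(within), n_total = length(d),
                 percent = percent1(sum(within), length(d))),
            class = "coverage_result")
}

#' @export
print.coverage_result <- function(x, ...) {
  cat(sprintf("%s, +/-%d min, correction=%s: %d of %d (%.1f%%)\n",
              x$pair, x$threshold_minutes, x$correction,
              x$n_within, x$n_total, x$percent))
  invisible(x)
}
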