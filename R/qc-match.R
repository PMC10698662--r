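#' Match diary and device nights and apply input-error QC
#'
#' Joins device main-sleep records and diary records on
#' `(participant_id, sleep_date)` (the date the sleep ends) and assigns each
#' matched night a QC status:
#'
#' * `ampm_error` — the diary asleep or wake time differs from the device
#'   value by more than `ampm_hours` on the anchored (noon-to-noon)
#'   timeline, with the absolute difference within 3 h of 12 h — the
#'   signature of an AM/PM button slip. Checked first, because a 12-hour
#'   slip on one field usually also breaks the bed/asleep/wake order.
#' * `order_violation` — bed -> asleep -> wake is not monotone on the
#'   anchored timeline (bed may equal asleep; asleep must precede wake).
#' * `overlarge_difference` — beyond `ampm_hours` but not AM/PM-like.
#' * `valid` — everything else; only these flow downstream.
#'
#' Excluded nights are never corrected (no 12-hour re-shifting): they are
#' input errors and are tallied, matching how such responses are treated in
#' agreement studies of this design.
#'
#' @param fitbit device records ([read_fitbit()] layout); only
#'   `is_main_sleep` rows participate. Two main sleeps for one
#'   (participant, date) is a fatal inconsistency.
#' @param chat diary records ([read_chat()] layout).
#' @param ampm_hours exclusion threshold in hours (default 9).
#' @return data frame of matched nights: ids, date, device fields
#'   (`fitbit_` prefix), diary fields (`chat_` prefix), `qos`, and
#'   `qc_status`.
#' @export
validate_and_match <- function(fitbit, chat, ampm_hours = 9) {
  fb <- fitbit[fitbit$is_main_sleep, , drop = FALSE]
  key_f <- paste(fb$participant_id, fb$sleep_date)
  if (anyDuplicated(key_f))
    stop("duplicate main sleep for one (participant, date) pair",
         call. = FALSE)
  key_c <- paste(chat$participant_id, chat$sleep_date)
  if (anyDuplicated(key_c))
    stop("duplicate diary record for one (participant, date) pair",
         call. = FALSE)
  i <- match(key_c, key_f)
  keep <- !is.na(i)
  ch <- chat[keep, , drop = FALSE]; fb <- fb[i[keep], , drop = FALSE]

  m <- data.frame(
    participant_id = ch$participant_id,
    sleep_date = ch$sleep_date,
    fitbit_onset = fb$start_time, fitbit_offset = fb$end_time,
    fitbit_minutes_awake = fb$minutes_awake,
    chat_bed = ch$bed_time, chat_asleep = ch$asleep_time,
    chat_wake = ch$wake_time,
    chat_ast_minutes = ch$ast_minutes,
    chat_n_awakenings = ch$n_awakenings,
    qos = ch$qos,
    stringsAsFactors = FALSE)

  lim <- ampm_hours * 3600
  d_on <- as_anchored(m$fitbit_onset) - as_anchored(m$chat_asleep)
  d_off <- as_anchored(m$fitbit_offset) - as_anchored(m$chat_wake)
  big <- pmax(abs(d_on), abs(d_off))
  over <- big > lim
  ampm_like <- over & (abs(abs(d_on) - 43200) <= 10800 |
                         abs(abs(d_off) - 43200) <= 10800)
  order_ok <- as_anchored(m$chat_bed) <= as_anchored(m$chat_asleep) &
    as_anchored(m$chat_asleep) < as_anchored(m$chat_wake)

  m$qc_status <- ifelse(ampm_like, "ampm_error",
                 ifelse(!order_ok, "order_violation",
                 ifelse(over, "overlarge_difference", "valid")))
  m
}

#' Select the analysis set: day cap and minimum-day inclusion
#'
#' Per participant, only the chronologically first `cap_days` calendar days
#' of device data are considered; a participant is included iff at least
#' `min_days` of those nights are QC-valid matched nights.
#'
#' @param matched output of [validate_and_match()].
#' @param min_days minimum valid matched nights for inclusion (default 7).
#' @param cap_days device-day cap per participant (default 14).
#' @param fitbit optional device records; if supplied, the cap is applied to
#'   the participant's device dates (as in the source design), otherwise to
#'   matched dates.
#' @return list of class `analysis_set`: `nights` (valid nights of included
#'   participants), `participants` (per-participant `n_valid`, `included`),
#'   `exclusions` (tally by reason, including `beyond_cap` and
#'   `under_min_days` nights).
#' @export
select_analysis_set <- function(matched, min_days = 7, cap_days = 14,
                                fitbit = NULL) {
  date_src <- if (!is.null(fitbit)) {
    fb <- fitbit[fitbit$is_main_sleep, c("participant_id", "sleep_date")]
    fb
  } else {
    matched[, c("participant_id", "sleep_date")]
  }
  # first cap_days distinct device dates per participant
  date_src <- date_src[order(date_src$participant_id, date_src$sleep_date), ]
  keep_key <- unlist(lapply(split(date_src$sleep_date, date_src$participant_id),
                            function(d) {
                              d <- sort(unique(d))
                              as.character(utils::head(d, cap_days))
                            }), use.names = FALSE)
  pid_rep <- rep(names(split(date_src$sleep_date, date_src$participant_id)),
                 vapply(split(date_src$sleep_date, date_src$participant_id),
                        function(d) min(length(unique(d)), as.integer(cap_days)),
                        1L))
  allowed <- paste(pid_rep, keep_key)

  in_cap <- paste(matched$participant_id, matched$sleep_date) %in% allowed
  capped <- matched[in_cap, , drop = FALSE]

  valid <- capped[capped$qc_status == "valid", , drop = FALSE]
  n_valid <- table(factor(valid$participant_id,
                          levels = unique(matched$participant_id)))
  participants <- data.frame(
    participant_id = names(n_valid),
    n_valid = as.integer(n_valid),
    stringsAsFactors = FALSE)
  participants$included <- participants$n_valid >= min_days

  inc_ids <- participants$participant_id[participants$included]
  nights <- valid[valid$participant_id %in% inc_ids, , drop = FALSE]

  excl <- c(table(capped$qc_status[capped$qc_status != "valid"]))
  exclusions <- data.frame(
    reason = c(names(excl), "beyond_cap", "under_min_days_nights",
               "participants_excluded"),
    n = c(as.integer(excl), sum(!in_cap),
          nrow(valid) - nrow(nights), sum(!participants$included)),
    stringsAsFactors = FALSE)

  structure(list(nights = nights, participants = participants,
                 exclusions = exclusions,
                 min_days = min_days, cap_days = cap_days),
            class = "analysis_set")
}

#' @export
print.analysis_set <- function(x, ...) {
  cat(sprintf("analysis set: %d participants included (of %d), %d valid nights\n",
              sum(x$participants$included), nrow(x$participants),
              nrow(x$nights)))
  cat("exclusions:\n")
  print(x$exclusions, row.names = FALSE)
  invisible(x)
}

DAY_BUCKETS <- c("0", "1-3", "4-6", "7-9", "10", "11", "12", "13", "14",
                 "15", "16-18", "19-21", "22")
LATENCY_BUCKETS <- c("within_3h", "within_6h", "within_9h", "within_12h",
                     "within_15h", "after_15h")

bucket_days <- function(n) {
  cut(pmin(n, 22L),
      breaks = c(-0.5, 0.5, 3.5, 6.5, 9.5, 10.5, 11.5, 12.5, 13.5, 14.5,
                 15.5, 18.5, 21.5, 22.5),
      labels = DAY_BUCKETS)
}

# half-open [0,3), [3,6), ..., [15, Inf) hours
bucket_latency <- function(hours) {
  cut(hours, breaks = c(0, 3, 6, 9, 12, 15, Inf),
      labels = LATENCY_BUCKETS, right = FALSE)
}

#' Wear-compliance and response-latency summary
#'
#' Buckets each participant's number of device main-sleep days
#' (0, 1-3, ..., 22, with 22 topping out the two-week + re-request design)
#' and their mean prompt-to-response latency into half-open 3-hour bands
#' `[0,3), [3,6), ..., [15, Inf)`.
#'
#' @param fitbit device records.
#' @param chat diary records.
#' @return list with `device_days` (participant counts and percent per
#'   bucket), `latency` (counts, percent and cumulative per bucket), and
#'   `per_participant` detail.
#' @export
compliance_summary <- function(fitbit, chat) {
  fb <- fitbit[fitbit$is_main_sleep, , drop = FALSE]
  days <- tapply(as.character(fb$sleep_date), fb$participant_id,
                 function(d) length(unique(d)))
  dd <- data.frame(participant_id = names(days), device_days = as.integer(days),
                   stringsAsFactors = FALSE)
  dd$bucket <- bucket_days(dd$device_days)
  dev_tab <- as.data.frame(table(bucket = dd$bucket), stringsAsFactors = FALSE)
  names(dev_tab)[2] <- "n"
  dev_tab$percent <- percent1(dev_tab$n, sum(dev_tab$n))

  lat_h <- (as.numeric(chat$response_date - chat$prompt_date) * 86400 +
              (chat$response_time - chat$prompt_time)) / 3600
  if (any(lat_h < 0))
    stop("response before prompt in chat records", call. = FALSE)
  mean_lat <- tapply(lat_h, chat$participant_id, mean)
  ll <- data.frame(participant_id = names(mean_lat),
                   mean_latency_h = as.numeric(mean_lat),
                   stringsAsFactors = FALSE)
  ll$bucket <- bucket_latency(ll$mean_latency_h)
  lat_tab <- as.data.frame(table(bucket = ll$bucket), stringsAsFactors = FALSE)
  names(lat_tab)[2] <- "n"
  lat_tab$percent <- percent1(lat_tab$n, sum(lat_tab$n))
  lat_tab$cumulative_n <- cumsum(lat_tab$n)
  lat_tab$cumulative_percent <- percent1(lat_tab$cumulative_n, sum(lat_tab$n))

  list(device_days = dev_tab, latency = lat_tab,
       per_participant = merge(dd[, c("participant_id", "device_days")],
                               ll[, c("participant_id", "mean_latency_h")],
                               by = "participant_id", all = TRUE))
}
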