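#' Raw record streams
#'
#' Three delimited-text streams feed the pipeline: device (tracker) per-night
#' sleep records, chatbot sleep-diary records, and the PSQI / profile
#' metadata pair. Readers never silently drop rows: rows failing an
#' invariant are collected on a reject list (attribute `"rejects"`, accessor
#' [rejects()]) with machine-readable reason codes, and
#' `nrow(accepted) + nrow(rejects)` always equals the file's row count.
#'
#' Device records may also arrive as a JSON array mirroring the vendor web
#' API (`startTime`/`endTime`/`minutesAwake`/`isMainSleep`, ISO 8601
#' timestamps).
#'
#' @name records_io
NULL

# ISO 8601 "YYYY-MM-DDTHH:MM:SS" (or space separator) -> list(date, secs)
split_iso <- function(ts) {
  ts <- trimws(as.character(ts))
  parts <- regmatches(ts, regexec(
    "^([0-9]{4}-[0-9]{2}-[0-9]{2})[T ]([0-9]{2}:[0-9]{2}(?::[0-9]{2})?)", ts))
  bad <- !lengths(parts)
  if (any(bad))
    stop("malformed ISO 8601 timestamp: '", ts[which(bad)[1]], "'", call. = FALSE)
  list(date = as.Date(vapply(parts, `[`, "", 2)),
       secs = clock_seconds(parse_clock(vapply(parts, `[`, "", 3))))
}

join_iso <- function(date, secs) {
  paste0(format(date, "%Y-%m-%d"), "T", format(clock_time(secs)))
}

as_flag <- function(x) {
  if (is.logical(x)) return(x)
  tolower(as.character(x)) %in% c("true", "t", "1", "yes")
}

with_rejects <- function(records, rejects) {
  attr(records, "rejects") <- rejects
  records
}

#' Reject list of a read record stream
#' @param x a data frame returned by [read_fitbit()], [read_chat()] or
#'   [read_cohort_metadata()] components.
#' @return data frame with columns `row` and `reason` (empty if none).
#' @export
rejects <- function(x) {
  attr(x, "rejects") %||% data.frame(row = integer(), reason = character())
}

QOS_LEVELS <- c("very_good", "quite_good", "quite_poor", "very_poor")

need_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, ": missing mandatory column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
}

#' Read device per-night sleep records
#'
#' @param path CSV with header (columns `participant_id`, `start_time`,
#'   `end_time`, `minutes_awake`, `is_main_sleep`; ISO 8601 timestamps), or a
#'   `.json` array of objects with vendor-API keys `participantId`,
#'   `startTime`, `endTime`, `minutesAwake`, `isMainSleep`.
#' @return data frame with columns `participant_id`, `sleep_date` (the date
#'   the sleep ends), `start_date`, `start_time`, `end_date`, `end_time`
#'   (clock seconds), `minutes_awake`, `is_main_sleep`; rejects on
#'   `rejects()`.
#' @export
read_fitbit <- function(path) {
  if (!file.exists(path)) stop("cannot read device file: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    if (!is.data.frame(raw)) raw <- as.data.frame(raw)
    nm <- names(raw)
    names(raw)[nm == "participantId"] <- "participant_id"
    names(raw)[nm == "startTime"] <- "start_time"
    names(raw)[nm == "endTime"] <- "end_time"
    names(raw)[nm == "minutesAwake"] <- "minutes_awake"
    names(raw)[nm == "isMainSleep"] <- "is_main_sleep"
  } else {
    raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  }
  need_cols(raw, c("participant_id", "start_time", "end_time",
                   "minutes_awake", "is_main_sleep"), "device records")
  st <- split_iso(raw$start_time); en <- split_iso(raw$end_time)
  out <- data.frame(
    participant_id = as.character(raw$participant_id),
    sleep_date     = en$date,
    start_date     = st$date,
    start_time     = st$secs,
    end_date       = en$date,
    end_time       = en$secs,
    minutes_awake  = as.integer(raw$minutes_awake),
    is_main_sleep  = as_flag(raw$is_main_sleep),
    stringsAsFactors = FALSE)

  span <- as.numeric(out$end_date - out$start_date) * 86400 +
    (out$end_time - out$start_time)
  reason <- rep(NA_character_, nrow(out))
  reason[is.na(out$minutes_awake) | out$minutes_awake < 0] <- "bad minutes_awake"
  reason[span <= 0] <- "end not after start"
  reason[is.na(reason) & out$minutes_awake * 60 >= span] <- "WASO exceeds interval"
  keep <- is.na(reason)
  with_rejects(out[keep, , drop = FALSE],
               data.frame(row = which(!keep), reason = reason[!keep]))
}

#' Write device records (CSV, or vendor-style JSON for a `.json` path)
#' @param records data frame in [read_fitbit()] layout.
#' @param path output file.
#' @export
write_fitbit <- function(records, path) {
  df <- data.frame(
    participant_id = records$participant_id,
    start_time = join_iso(records$start_date, records$start_time),
    end_time   = join_iso(records$end_date, records$end_time),
    minutes_awake = records$minutes_awake,
    is_main_sleep = tolower(records$is_main_sleep))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    names(df) <- c("participantId", "startTime", "endTime",
                   "minutesAwake", "isMainSleep")
    df$isMainSleep <- df$isMainSleep == "true"
    jsonlite::write_json(df, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read chatbot sleep-diary records
#'
#' Clock fields use the chatbot button dialect and must sit on the 5-minute
#' grid; off-grid minutes are rejected (reason `"off-grid minute"`), as are
#' responses timestamped before their prompt. Ordering and AM/PM checks are
#' semantic QC and live in [validate_and_match()], not here.
#'
#' @param path CSV with header: `participant_id`, `sleep_date`, `bed_time`,
#'   `asleep_time`, `wake_time` (clock strings), `n_awakenings`,
#'   `ast_minutes`, `qos`, `strenuous_activity`, `sitting_minutes`,
#'   `prompt_ts`, `response_ts` (ISO 8601).
#' @return data frame (clock fields as seconds); rejects on `rejects()`.
#' @export
read_chat <- function(path) {
  if (!file.exists(path)) stop("cannot read chat file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need_cols(raw, c("participant_id", "sleep_date", "bed_time", "asleep_time",
                   "wake_time", "n_awakenings", "ast_minutes", "qos",
                   "strenuous_activity", "sitting_minutes",
                   "prompt_ts", "response_ts"), "chat records")
  pr <- split_iso(raw$prompt_ts); rs <- split_iso(raw$response_ts)
  out <- data.frame(
    participant_id = as.character(raw$participant_id),
    sleep_date = as.Date(raw$sleep_date),
    bed_time    = clock_seconds(parse_clock(raw$bed_time)),
    asleep_time = clock_seconds(parse_clock(raw$asleep_time)),
    wake_time   = clock_seconds(parse_clock(raw$wake_time)),
    n_awakenings = as.integer(raw$n_awakenings),
    ast_minutes  = as.integer(raw$ast_minutes),
    qos = as.character(raw$qos),
    strenuous_activity = as_flag(raw$strenuous_activity),
    sitting_minutes = as.integer(raw$sitting_minutes),
    prompt_date = pr$date, prompt_time = pr$secs,
    response_date = rs$date, response_time = rs$secs,
    stringsAsFactors = FALSE)

  off_grid <- (out$bed_time %% 300 != 0) | (out$asleep_time %% 300 != 0) |
    (out$wake_time %% 300 != 0)
  resp_num <- as.numeric(out$response_date) * 86400 + out$response_time
  prom_num <- as.numeric(out$prompt_date) * 86400 + out$prompt_time
  reason <- rep(NA_character_, nrow(out))
  reason[!out$qos %in% QOS_LEVELS] <- "unknown qos level"
  reason[is.na(out$ast_minutes) | out$ast_minutes <= 0] <- "non-positive AST"
  reason[resp_num < prom_num] <- "response before prompt"
  reason[off_grid] <- "off-grid minute"
  keep <- is.na(reason)
  with_rejects(out[keep, , drop = FALSE],
               data.frame(row = which(!keep), reason = reason[!keep]))
}

#' Write chatbot records as CSV
#' @param records data frame in [read_chat()] layout.
#' @param path output file.
#' @export
write_chat <- function(records, path) {
  df <- data.frame(
    participant_id = records$participant_id,
    sleep_date = format(records$sleep_date, "%Y-%m-%d"),
    bed_time    = format(clock_time(records$bed_time)),
    asleep_time = format(clock_time(records$asleep_time)),
    wake_time   = format(clock_time(records$wake_time)),
    n_awakenings = records$n_awakenings,
    ast_minutes = records$ast_minutes,
    qos = records$qos,
    strenuous_activity = tolower(records$strenuous_activity),
    sitting_minutes = records$sitting_minutes,
    prompt_ts   = join_iso(records$prompt_date, records$prompt_time),
    response_ts = join_iso(records$response_date, records$response_time))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read PSQI survey records and participant profiles
#'
#' A missing PSQI total score is preserved as `NA` (it drives the
#' "not classified" stratum downstream). Ids present in only one of the two
#' files are listed in the `availability` component; duplicate ids within a
#' file are a fatal inconsistency.
#'
#' @param psqi_path CSV: `participant_id`, `bed_time`, `sol_minutes`,
#'   `wake_time`, `reported_sleep_h`, `total_score` (0--21 or blank).
#' @param profile_path CSV: `participant_id`, `gender` (`men`/`women`),
#'   `age_years`, `bmi`.
#' @return list with `psqi`, `profiles`, `availability` data frames.
#' @export
read_cohort_metadata <- function(psqi_path, profile_path) {
  praw <- utils::read.csv(psqi_path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need_cols(praw, c("participant_id", "bed_time", "sol_minutes", "wake_time",
                    "reported_sleep_h", "total_score"), "psqi records")
  if (anyDuplicated(praw$participant_id))
    stop("duplicate participant_id in PSQI file", call. = FALSE)
  score <- suppressWarnings(as.integer(praw$total_score))
  if (any(!is.na(score) & (score < 0 | score > 21)))
    stop("PSQI total score outside [0, 21]", call. = FALSE)
  psqi <- data.frame(
    participant_id = as.character(praw$participant_id),
    bed_time  = clock_seconds(parse_clock(praw$bed_time)),
    sol_minutes = as.integer(praw$sol_minutes),
    wake_time = clock_seconds(parse_clock(praw$wake_time)),
    reported_sleep_h = as.numeric(praw$reported_sleep_h),
    total_score = score,
    stringsAsFactors = FALSE)

  graw <- utils::read.csv(profile_path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need_cols(graw, c("participant_id", "gender", "age_years", "bmi"),
            "profile records")
  if (anyDuplicated(graw$participant_id))
    stop("duplicate participant_id in profile file", call. = FALSE)
  profiles <- data.frame(
    participant_id = as.character(graw$participant_id),
    gender = as.character(graw$gender),
    age_years = as.integer(graw$age_years),
    bmi = as.numeric(graw$bmi),
    stringsAsFactors = FALSE)
  if (!all(profiles$gender %in% c("men", "women")))
    stop("profile gender must be 'men' or 'women'", call. = FALSE)
  if (any(profiles$bmi <= 0)) stop("profile bmi must be positive", call. = FALSE)

  ids <- union(psqi$participant_id, profiles$participant_id)
  availability <- data.frame(
    participant_id = ids,
    in_psqi = ids %in% psqi$participant_id,
    in_profile = ids %in% profiles$participant_id,
    stringsAsFactors = FALSE)
  list(psqi = psqi, profiles = profiles,
       availability = availability[!(availability$in_psqi &
                                       availability$in_profile), , drop = FALSE])
}

#' Write PSQI records as CSV
#' @param psqi data frame as returned in [read_cohort_metadata()].
#' @param path output file.
#' @export
write_psqi <- function(psqi, path) {
  df <- data.frame(
    participant_id = psqi$participant_id,
    bed_time = format(clock_time(psqi$bed_time)),
    sol_minutes = psqi$sol_minutes,
    wake_time = format(clock_time(psqi$wake_time)),
    reported_sleep_h = psqi$reported_sleep_h,
    total_score = ifelse(is.na(psqi$total_score), "", psqi$total_score))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write participant profiles as CSV
#' @param profiles data frame with `participant_id`, `gender`, `age_years`, `bmi`.
#' @param path output file.
#' @export
write_profiles <- function(profiles, path) {
  utils::write.csv(profiles[, c("participant_id", "gender", "age_years", "bmi")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
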