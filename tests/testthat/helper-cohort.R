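# Small cohorts and hand-built record fixtures shared across test files.

tiny_params <- function(...) {
  args <- utils::modifyList(
    list(n_participants = 12L, nights_per_participant = 10L,
         rng_seed = 424242L),
    list(...))
  do.call(cohort_params, args)
}

# a noiseless, error-free world: diary == device up to the 5-minute grid
degenerate_params <- function(...) {
  cohort_params(
    n_participants = 8L, nights_per_participant = 8L,
    onset_sd_between = 0, onset_sd_within = 0,
    tst_sd_between = 0, tst_sd_within = 0,
    waso_sd = 0, device_noise_sd = 0, sol_sd = 0,
    report_onset_bias_mean = 0, report_onset_bias_sd = 0,
    report_offset_bias_mean = 0, report_offset_bias_sd = 0,
    report_night_noise_sd = 0,
    report_bias_good = 0, report_bias_poor = 0,
    ast_bias_sd_between = 0, ast_night_noise_sd = 0,
    heap_prob_30 = 0, ampm_error_rate = 0, order_error_rate = 0,
    missing_chat_rate = 0, missing_fitbit_rate = 0,
    rng_seed = 7L, ...)
}

# one hand-built matched-night row in the validate_and_match() layout
matched_row <- function(fit_on = "23:40", fit_off = "07:05", waso = 55L,
                        bed = "23:30", asleep = "23:45", wake = "07:00",
                        ast = 420L, qos = "quite_good", status = "valid",
                        id = "P1", date = as.Date("2021-03-02")) {
  data.frame(
    participant_id = id, sleep_date = date,
    fitbit_onset = clock_seconds(parse_clock(fit_on)),
    fitbit_offset = clock_seconds(parse_clock(fit_off)),
    fitbit_minutes_awake = waso,
    chat_bed = clock_seconds(parse_clock(bed)),
    chat_asleep = clock_seconds(parse_clock(asleep)),
    chat_wake = clock_seconds(parse_clock(wake)),
    chat_ast_minutes = ast, chat_n_awakenings = 1L, qos = qos,
    qc_status = status, stringsAsFactors = FALSE)
}

# device + diary record pair for one participant/night, reader layouts
raw_night <- function(id, date, fit_on, fit_off, waso, bed, asleep, wake,
                      ast = 420L, qos = "quite_good") {
  date <- as.Date(date)
  on_s <- clock_seconds(parse_clock(fit_on))
  fitbit <- data.frame(
    participant_id = id, sleep_date = date,
    start_date = date - (as_anchored(on_s) < 0),
    start_time = on_s, end_date = date,
    end_time = clock_seconds(parse_clock(fit_off)),
    minutes_awake = waso, is_main_sleep = TRUE, stringsAsFactors = FALSE)
  chat <- data.frame(
    participant_id = id, sleep_date = date,
    bed_time = clock_seconds(parse_clock(bed)),
    asleep_time = clock_seconds(parse_clock(asleep)),
    wake_time = clock_seconds(parse_clock(wake)),
    n_awakenings = 1L, ast_minutes = ast, qos = qos,
    strenuous_activity = FALSE, sitting_minutes = 400L,
    prompt_date = date, prompt_time = 32400L,
    response_date = date, response_time = 40000L, stringsAsFactors = FALSE)
  list(fitbit = fitbit, chat = chat)
}

bind_nights <- function(...) {
  ns <- list(...)
  list(fitbit = do.call(rbind, lapply(ns, `[[`, "fitbit")),
       chat = do.call(rbind, lapply(ns, `[[`, "chat")))
}
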