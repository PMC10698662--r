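#' Synthetic cohort parameters
#'
#' Defaults are the "paper-calibrated" world: a cohort whose device sleep
#' onset averages 00:19:42 with a roughly 70-minute between-night marginal
#' SD, mean device total sleep time (TST) just over 7 h, wake after sleep
#' onset (WASO) of 58 (SD 24) minutes, self-reports biased about +9 min late
#' on onset and -6 min early on offset, a +19/-2.5 minute self-reported
#' actual-sleep-time (AST) bias on self-rated good/poor nights, about 70% of
#' nights rated good, and roughly half of all diary times heaped onto the
#' :00/:30 half-hour grid. Marginal SDs are split into a between-participant
#' component and a within-participant (night) component, since self-report
#' deviation in such studies is dominated by stable per-person tendencies.
#'
#' All time parameters are in minutes unless suffixed `_clock` (a clock
#' string). Report biases are chat-minus-device, so a positive AST bias means
#' the sleeper over-reports sleep.
#'
#' @param n_participants,nights_per_participant cohort shape.
#' @param fitbit_onset_mean_clock mean device sleep-onset clock time.
#' @param onset_sd_between,onset_sd_within onset SD split (minutes).
#' @param fitbit_tst_mean,tst_sd_between,tst_sd_within device TST (minutes).
#' @param waso_mean,waso_sd device WASO (minutes), truncated at 0 and TST.
#' @param device_noise_sd zero-mean device measurement noise (minutes).
#' @param sol_mean,sol_sd bed-to-asleep latency (minutes, truncated >= 0).
#' @param report_onset_bias_mean,report_onset_bias_sd chat onset bias:
#'   per-participant intercept mean/SD (minutes).
#' @param report_offset_bias_mean,report_offset_bias_sd chat offset bias.
#' @param report_night_noise_sd nightly noise added to chat clock reports.
#' @param report_bias_good,report_bias_poor chat AST bias (minutes) on
#'   good / poor self-rated nights.
#' @param ast_bias_sd_between,ast_night_noise_sd AST bias spread split.
#' @param heap_prob_30 probability a diary value snaps to the nearest :00/:30.
#' @param qos_good_prob marginal probability a night is rated good.
#' @param qos_corr latent-trait loading coupling PSQI group and nightly
#'   quality ratings (0 = independent).
#' @param psqi_good_prob marginal probability of PSQI total score <= 5.
#' @param psqi_missing_rate probability the PSQI total score is missing.
#' @param ampm_error_rate,order_error_rate input-error injection rates.
#' @param missing_chat_rate,missing_fitbit_rate per-night missingness.
#' @param start_date first sleep date of the cohort.
#' @param rng_seed integer seed; the run is fully deterministic given it.
#' @return a validated `cohort_params` list.
#' @export
cohort_params <- function(
    n_participants = 543L, nights_per_participant = 14L,
    fitbit_onset_mean_clock = "00:19:42",
    onset_sd_between = 55, onset_sd_within = 43,
    fitbit_tst_mean = 428, tst_sd_between = 40, tst_sd_within = 35,
    waso_mean = 58, waso_sd = 24,
    device_noise_sd = 0,
    sol_mean = 15, sol_sd = 10,
    report_onset_bias_mean = 8.65, report_onset_bias_sd = 25,
    report_offset_bias_mean = -5.65, report_offset_bias_sd = 25,
    report_night_noise_sd = 15,
    report_bias_good = 19.2, report_bias_poor = -2.5,
    ast_bias_sd_between = 30, ast_night_noise_sd = 35,
    heap_prob_30 = 0.49,
    qos_good_prob = 0.70, qos_corr = 0.6,
    psqi_good_prob = 0.60, psqi_missing_rate = 0.018,
    ampm_error_rate = 0.01, order_error_rate = 0.01,
    missing_chat_rate = 0.15, missing_fitbit_rate = 0.05,
    start_date = as.Date("2021-03-01"),
    rng_seed = 20201010L) {
  p <- as.list(environment())
  p$fitbit_onset_mean_s <- clock_seconds(parse_clock(fitbit_onset_mean_clock))
  probs <- c(heap_prob_30, qos_good_prob, psqi_good_prob, psqi_missing_rate,
             ampm_error_rate, order_error_rate,
             missing_chat_rate, missing_fitbit_rate)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  sds <- c(onset_sd_between, onset_sd_within, tst_sd_between, tst_sd_within,
           waso_sd, device_noise_sd, sol_sd, report_onset_bias_sd,
           report_offset_bias_sd, report_night_noise_sd,
           ast_bias_sd_between, ast_night_noise_sd)
  if (any(sds < 0)) stop("standard deviations must be >= 0", call. = FALSE)
  if (nights_per_participant < 1L || n_participants < 1L)
    stop("cohort shape must be at least 1 x 1", call. = FALSE)
  if (fitbit_tst_mean <= waso_mean)
    stop("infeasible params: mean TST must exceed mean WASO", call. = FALSE)
  if (abs(qos_corr) > 1) stop("qos_corr must lie in [-1, 1]", call. = FALSE)
  structure(p, class = "cohort_params")
}

# -- 5-minute button grid and half-hour heaping -------------------------------

snap5 <- function(secs) (as.integer(round(secs / 300)) * 300L) %% 86400L

# Nearest :00/:30; a tie (exactly 15 min from both) breaks toward the full
# hour, i.e. toward :00.
heap30_sec <- function(secs) {
  r <- secs %% 1800L
  low <- secs - r
  snapped <- ifelse(r < 900L, low,
             ifelse(r > 900L, low + 1800L,
                    ifelse(low %% 3600L == 0L, low, low + 1800L)))
  as.integer(snapped) %% 86400L
}

heap30_min <- function(mins) {
  r <- mins %% 30L
  low <- mins - r
  as.integer(ifelse(r < 15L, low,
             ifelse(r > 15L, low + 30L,
                    ifelse(low %% 60L == 0L, low, low + 30L))))
}

#' Generate a synthetic device + diary + survey cohort
#'
#' Produces the four record streams in exactly the layouts the readers
#' return, plus a ground-truth ledger carrying every latent quantity and
#' every injected error label, enabling parameter-recovery tests. Each
#' participant draws from an RNG sub-stream derived by stable hashing, so
#' enlarging the cohort does not perturb existing participants.
#'
#' @param params a [cohort_params()] object.
#' @return list of class `nightfit_cohort`: `fitbit`, `chat`, `psqi`,
#'   `profiles`, `ledger` data frames and the `params` used.
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  p <- params
  ids <- sprintf("P%04d", seq_len(p$n_participants))
  nts <- p$nights_per_participant

  fit_l <- vector("list", length(ids)); chat_l <- fit_l
  psqi_l <- fit_l; prof_l <- fit_l; led_l <- fit_l
  thr_psqi <- stats::qnorm(p$psqi_good_prob)
  thr_qos <- stats::qnorm(p$qos_good_prob)
  load <- p$qos_corr; resid <- sqrt(1 - load^2)

  for (k in seq_along(ids)) {
    id <- ids[k]
    set.seed(derive_seed(p$rng_seed, paste0("participant:", id)))
    q <- stats::rnorm(1)                       # latent sleep-quality trait

    # participant-level profile and survey
    gender <- if (stats::runif(1) < 0.715) "women" else "men"
    age <- sample(30:59, 1)
    bmi <- round(rtnorm(1, 23.6, 3.4, 16, 45), 1)
    psqi_good <- (load * q + resid * stats::rnorm(1)) < thr_psqi
    score <- if (psqi_good) sample(0:5, 1) else sample(6:15, 1)
    if (stats::runif(1) < p$psqi_missing_rate) score <- NA_integer_

    # participant-level means and report intercepts (minutes)
    onset_p <- p$fitbit_onset_mean_s / 60 + stats::rnorm(1, 0, p$onset_sd_between)
    tst_p <- stats::rnorm(1, p$fitbit_tst_mean, p$tst_sd_between)
    b_on <- stats::rnorm(1, p$report_onset_bias_mean, p$report_onset_bias_sd)
    b_off <- stats::rnorm(1, p$report_offset_bias_mean, p$report_offset_bias_sd)
    b_ast <- stats::rnorm(1, 0, p$ast_bias_sd_between)
    sol_p <- rtnorm(1, p$sol_mean, p$sol_sd, 0, 120)

    # nightly truth
    tst <- rtnorm(nts, tst_p, p$tst_sd_within, p$waso_mean + 60, 720)
    onset <- (onset_p + stats::rnorm(nts, 0, p$onset_sd_within)) * 60
    onset <- as.integer(round(onset)) %% 86400L
    waso <- rtnorm(nts, p$waso_mean, p$waso_sd, 0, tst - 30)
    offset <- (onset + as.integer(round(tst * 60))) %% 86400L

    qos_good <- (load * q + resid * stats::rnorm(nts)) < thr_qos
    u_lab <- stats::runif(nts)
    qos <- ifelse(qos_good,
                  ifelse(u_lab < 0.25, "very_good", "quite_good"),
                  ifelse(u_lab < 0.20, "very_poor", "quite_poor"))

    # device record = truth + zero-mean device noise
    dn <- function(n) as.integer(round(stats::rnorm(n, 0, p$device_noise_sd) * 60))
    dev_on <- (onset + dn(nts)) %% 86400L
    dev_off <- (offset + dn(nts)) %% 86400L
    minutes_awake <- as.integer(round(waso))

    # diary report = truth + participant intercept + nightly noise,
    # then 5-minute button grid, then half-hour heaping
    nn <- function(n) stats::rnorm(n, 0, p$report_night_noise_sd) * 60
    chat_on <- (onset + as.integer(round(b_on * 60 + nn(nts)))) %% 86400L
    chat_off <- (offset + as.integer(round(b_off * 60 + nn(nts)))) %% 86400L
    sol <- rtnorm(nts, sol_p, 5, 0, 180)
    ast_bias <- ifelse(qos_good, p$report_bias_good, p$report_bias_poor) +
      b_ast + stats::rnorm(nts, 0, p$ast_night_noise_sd)
    ast <- pmax(30, (tst - waso) + ast_bias)

    chat_on <- snap5(chat_on); chat_off <- snap5(chat_off)
    chat_bed <- (chat_on - as.integer(round(sol / 5) * 5) * 60L) %% 86400L
    ast_m <- as.integer(round(ast / 5) * 5)
    hp <- function(n) stats::runif(n) < p$heap_prob_30
    h_bed <- hp(nts); h_on <- hp(nts); h_off <- hp(nts); h_ast <- hp(nts)
    chat_bed[h_bed] <- heap30_sec(chat_bed[h_bed])
    chat_on[h_on] <- heap30_sec(chat_on[h_on])
    chat_off[h_off] <- heap30_sec(chat_off[h_off])
    ast_m[h_ast] <- heap30_min(ast_m[h_ast])

    # the noon anchor instant has no defined night; never emit it
    dev_on[dev_on == 43200L] <- 43199L
    dev_off[dev_off == 43200L] <- 43199L
    chat_bed[chat_bed == 43200L] <- 42900L
    chat_on[chat_on == 43200L] <- 42900L
    chat_off[chat_off == 43200L] <- 42900L

    # independent heaping of bed and asleep can cross them by <= 30 min;
    # a real diary UI would still show bed <= asleep, so clamp (no label)
    bed_a <- as_anchored(chat_bed); on_a <- as_anchored(chat_on)
    fixup <- bed_a > on_a
    chat_bed[fixup] <- chat_on[fixup]

    miss_chat <- stats::runif(nts) < p$missing_chat_rate
    miss_fit <- stats::runif(nts) < p$missing_fitbit_rate

    dates <- p$start_date + seq_len(nts) - 1L
    start_date <- dates - as.integer(as_anchored(dev_on) < 0L)
    lat <- pmin(round(exp(stats::rnorm(nts, log(2.5 * 3600), 1.0))), 86000)
    resp_raw <- 9L * 3600L + as.integer(lat)
    awaken <- pmin(stats::rpois(nts, 1.2) + 1L, 26L)

    fit_l[[k]] <- data.frame(
      participant_id = id, sleep_date = dates, start_date = start_date,
      start_time = dev_on, end_date = dates, end_time = dev_off,
      minutes_awake = minutes_awake, is_main_sleep = TRUE,
      stringsAsFactors = FALSE)[!miss_fit, , drop = FALSE]

    chat_l[[k]] <- data.frame(
      participant_id = id, sleep_date = dates,
      bed_time = chat_bed, asleep_time = chat_on, wake_time = chat_off,
      n_awakenings = awaken, ast_minutes = ast_m, qos = qos,
      strenuous_activity = stats::runif(nts) < 0.2,
      sitting_minutes = as.integer(round(rtnorm(nts, 420, 120, 60, 960))),
      prompt_date = dates, prompt_time = 9L * 3600L,
      response_date = dates + resp_raw %/% 86400L,
      response_time = resp_raw %% 86400L,
      stringsAsFactors = FALSE)[!miss_chat, , drop = FALSE]

    # PSQI: habitual values, strongly heaped (survey answers about a month)
    psqi_bed <- snap5((chat_bed[1] %/% 60L) * 60L)
    if (stats::runif(1) < 0.93) psqi_bed <- heap30_sec(psqi_bed)
    psqi_wake <- snap5(as.integer(round(mean(chat_off))))
    if (stats::runif(1) < 0.80) psqi_wake <- heap30_sec(psqi_wake)
    psqi_l[[k]] <- data.frame(
      participant_id = id, bed_time = psqi_bed,
      sol_minutes = as.integer(round(sol_p / 5) * 5),
      wake_time = psqi_wake,
      reported_sleep_h = round(tst_p / 60 * 2) / 2,
      total_score = score, stringsAsFactors = FALSE)
    prof_l[[k]] <- data.frame(
      participant_id = id, gender = gender, age_years = age, bmi = bmi,
      stringsAsFactors = FALSE)

    led_l[[k]] <- data.frame(
      participant_id = id, sleep_date = dates,
      true_onset_s = onset, true_offset_s = offset,
      true_tst_s = as.integer(round(tst * 60)),
      true_waso_s = as.integer(round(waso * 60)),
      qos = qos, qos_good = qos_good, latent_quality = q,
      onset_bias_min = b_on, offset_bias_min = b_off,
      ast_bias_min = ast_bias,
      label = "none", ampm_field = NA_character_,
      missing_chat = miss_chat, missing_fitbit = miss_fit,
      stringsAsFactors = FALSE)
  }

  cohort <- list(
    fitbit = do.call(rbind, fit_l), chat = do.call(rbind, chat_l),
    psqi = do.call(rbind, psqi_l), profiles = do.call(rbind, prof_l),
    ledger = do.call(rbind, led_l), params = p)
  rownames(cohort$fitbit) <- rownames(cohort$chat) <- NULL
  rownames(cohort$ledger) <- NULL
  cohort <- inject_errors(cohort)
  class(cohort) <- "nightfit_cohort"
  cohort
}

#' Inject AM/PM and ordering input errors into diary records
#'
#' With rate `ampm_error_rate` one clock field (asleep or wake) of a diary
#' row is shifted by 12 hours; with rate `order_error_rate` the asleep time
#' is pulled 30 minutes before bed time, breaking the bed -> asleep -> wake
#' order. At most one injection per row; every injection is recorded in the
#' ledger (`label`, `ampm_field`). Draws are derived per row from the cohort
#' seed, so injection is deterministic and per-row stable.
#'
#' @param cohort a `nightfit_cohort` (or a bare list with `chat`, `ledger`,
#'   `params`).
#' @return the cohort with modified `chat` and updated `ledger`.
#' @export
inject_errors <- function(cohort) {
  p <- cohort$params
  chat <- cohort$chat; ledger <- cohort$ledger
  if (p$ampm_error_rate == 0 && p$order_error_rate == 0) return(cohort)
  set.seed(derive_seed(p$rng_seed, "inject-errors"))
  n <- nrow(chat)
  u <- stats::runif(n); u2 <- stats::runif(n); u3 <- stats::runif(n)
  key_chat <- paste(chat$participant_id, chat$sleep_date)
  key_led <- paste(ledger$participant_id, ledger$sleep_date)
  idx <- match(key_chat, key_led)

  do_ampm <- u < p$ampm_error_rate
  do_order <- !do_ampm & u < (p$ampm_error_rate + p$order_error_rate)

  fld <- ifelse(u2 < 0.5, "asleep_time", "wake_time")
  for (i in which(do_ampm)) {
    f <- fld[i]
    chat[[f]][i] <- (chat[[f]][i] + 43200L) %% 86400L
    ledger$label[idx[i]] <- "ampm_swap"
    ledger$ampm_field[idx[i]] <- f
  }
  for (i in which(do_order)) {
    chat$asleep_time[i] <- (chat$bed_time[i] - 1800L) %% 86400L
    ledger$label[idx[i]] <- "order_violation"
  }
  # u3 reserved to keep the draw layout stable across rate changes
  invisible(u3)
  cohort$chat <- chat; cohort$ledger <- ledger
  cohort
}

#' Write a synthetic cohort to a directory in the reader formats
#' @param cohort a `nightfit_cohort`.
#' @param dir output directory (created if needed).
#' @param fitbit_format `"csv"` or `"json"` (vendor-API dialect).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir, fitbit_format = c("csv", "json")) {
  fitbit_format <- match.arg(fitbit_format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fitbit(cohort$fitbit,
               file.path(dir, paste0("fitbit.", fitbit_format)))
  write_chat(cohort$chat, file.path(dir, "chat.csv"))
  write_psqi(cohort$psqi, file.path(dir, "psqi.csv"))
  write_profiles(cohort$profiles, file.path(dir, "profiles.csv"))
  led <- cohort$ledger
  led$sleep_date <- format(led$sleep_date, "%Y-%m-%d")
  utils::write.csv(led, file.path(dir, "truth_ledger.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}
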