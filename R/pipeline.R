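#' Pipeline run configuration
#'
#' A flat configuration driving [run_pipeline()]: either paths to the four
#' input streams, or `simulate = TRUE` plus generator parameters. Thresholds
#' default to the study design values: 7-day minimum inclusion, 14-day cap,
#' 9-hour AM/PM exclusion, coverage at 30 and 60 minutes.
#'
#' @param fitbit_path,chat_path,psqi_path,profile_path input files (ignored
#'   when simulating).
#' @param simulate generate inputs with [generate_cohort()] instead.
#' @param sim_params a [cohort_params()] for simulation.
#' @param min_days,cap_days,ampm_hours,coverage_thresholds QC thresholds.
#' @param outdir report bundle directory.
#' @param seed overrides `sim_params$rng_seed` when simulating.
#' @param verbose stage-level logging via `message()`.
#' @return a `run_config` list.
#' @export
run_config <- function(fitbit_path = NULL, chat_path = NULL,
                       psqi_path = NULL, profile_path = NULL,
                       simulate = FALSE, sim_params = cohort_params(),
                       min_days = 7, cap_days = 14, ampm_hours = 9,
                       coverage_thresholds = c(30, 60),
                       outdir = tempfile("nightfit_run_"),
                       seed = NULL, verbose = TRUE) {
  if (any(c(min_days, cap_days, ampm_hours, coverage_thresholds) <= 0))
    stop("thresholds must be positive", call. = FALSE)
  if (!simulate &&
      (is.null(fitbit_path) || is.null(chat_path) ||
         is.null(psqi_path) || is.null(profile_path)))
    stop("either set simulate = TRUE or provide all four input paths",
         call. = FALSE)
  structure(as.list(environment()), class = "run_config")
}

#' Read a flat key = value configuration file
#'
#' Lines are `key = value`; `#` starts a comment. Generator parameters are
#' prefixed `sim_` (e.g. `sim_n_participants = 100`); everything else maps
#' onto [run_config()] arguments. `coverage_thresholds` is comma-separated.
#'
#' @param path configuration file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_]+)\\s*=\\s*(.*)$", lines))
  if (any(!lengths(kv))) stop("malformed config line: ",
                              lines[which(!lengths(kv))[1]], call. = FALSE)
  keys <- vapply(kv, `[`, "", 2); vals <- trimws(vapply(kv, `[`, "", 3))
  coerce <- function(v) {
    if (tolower(v) %in% c("true", "false")) return(tolower(v) == "true")
    n <- suppressWarnings(as.numeric(v))
    if (!is.na(n)) n else v
  }
  sim_keys <- grepl("^sim_", keys)
  sim_args <- stats::setNames(lapply(vals[sim_keys], coerce),
                              sub("^sim_", "", keys[sim_keys]))
  run_args <- stats::setNames(lapply(vals[!sim_keys], coerce), keys[!sim_keys])
  if (!is.null(run_args$coverage_thresholds))
    run_args$coverage_thresholds <-
      as.numeric(strsplit(as.character(run_args$coverage_thresholds), ",")[[1]])
  if (length(sim_args)) {
    if ("start_date" %in% names(sim_args))
      sim_args$start_date <- as.Date(sim_args$start_date)
    run_args$sim_params <- do.call(cohort_params, sim_args)
  }
  do.call(run_config, run_args)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Source-vs-source agreement overview (means, SDs, differences)
#'
#' The per-variable summary over participant means: diary and device mean
#' (clock fields via the anchored circular mean) with between-participant
#' SDs, and Bland-Altman statistics of the device-minus-diary differences.
#'
#' @param pm [participant_means()] output.
#' @return data frame, one row per variable (onset, offset, tst,
#'   ast_vs_tstwaso), with formatted means, SDs in minutes, mean difference
#'   (h:mm:ss and minutes), LoA and p-value.
#' @export
agreement_overview <- function(pm) {
  clock_row <- function(chat, fit, d) {
    s <- agreement_stats(d)
    data.frame(
      chat_mean = format(mean_clock(clock_time(chat))),
      chat_sd_min = round_half_away(stats::sd(as_anchored(chat)) / 60, 1),
      fitbit_mean = format(mean_clock(clock_time(fit))),
      fitbit_sd_min = round_half_away(stats::sd(as_anchored(fit)) / 60, 1),
      diff_mean_hms = format_hms(s$mean_diff),
      diff_mean_min = round_half_away(s$mean_diff / 60, 1),
      diff_sd196_min = round_half_away(s$half_width / 60, 1),
      loa_low_min = round_half_away(s$loa_low / 60, 1),
      loa_high_min = round_half_away(s$loa_high / 60, 1),
      p = s$p_paired_t, stringsAsFactors = FALSE)
  }
  dur_row <- function(chat, fit, d) {
    s <- agreement_stats(d)
    data.frame(
      chat_mean = format_hms(mean(chat)),
      chat_sd_min = round_half_away(stats::sd(chat) / 60, 1),
      fitbit_mean = format_hms(mean(fit)),
      fitbit_sd_min = round_half_away(stats::sd(fit) / 60, 1),
      diff_mean_hms = format_hms(s$mean_diff),
      diff_mean_min = round_half_away(s$mean_diff / 60, 1),
      diff_sd196_min = round_half_away(s$half_width / 60, 1),
      loa_low_min = round_half_away(s$loa_low / 60, 1),
      loa_high_min = round_half_away(s$loa_high / 60, 1),
      p = s$p_paired_t, stringsAsFactors = FALSE)
  }
  out <- rbind(
    cbind(variable = "sleep_onset",
          clock_row(pm$chat_onset, pm$fitbit_onset, pm$d_onset)),
    cbind(variable = "sleep_offset",
          clock_row(pm$chat_offset, pm$fitbit_offset, pm$d_offset)),
    cbind(variable = "tst", dur_row(pm$chat_tst, pm$fitbit_tst, pm$d_tst)),
    cbind(variable = "ast_vs_tstwaso",
          dur_row(pm$chat_ast, pm$fitbit_ast, pm$d_ast)))
  rownames(out) <- NULL
  out
}

demographics_table <- function(included_ids, profiles, psqi) {
  idx <- match(included_ids, profiles$participant_id)
  g <- data.frame(
    participant_id = included_ids,
    gender = profiles$gender[idx],
    age = classify_age(profiles$age_years[idx]),
    bmi = as.character(classify_bmi(profiles$bmi[idx])),
    psqi = classify_psqi(
      psqi$total_score[match(included_ids, psqi$participant_id)]),
    stringsAsFactors = FALSE)
  row_for <- function(stratum, level, sub) {
    n <- nrow(sub)
    data.frame(stratum = stratum, level = level,
               total_n = n, total_pct = percent1(n, nrow(g)),
               good_n = sum(sub$psqi == "good"),
               good_pct = percent1(sum(sub$psqi == "good"), max(n, 1)),
               poor_n = sum(sub$psqi == "poor"),
               poor_pct = percent1(sum(sub$psqi == "poor"), max(n, 1)),
               unclassified_n = sum(sub$psqi == "unclassified"),
               unclassified_pct = percent1(sum(sub$psqi == "unclassified"),
                                           max(n, 1)))
  }
  out <- list(row_for("all", "all", g))
  for (st in c("gender", "age", "bmi"))
    for (lev in sort(unique(g[[st]])))
      out[[length(out) + 1]] <- row_for(st, lev, g[g[[st]] == lev, ])
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

rounding_table <- function(chat, psqi, fitbit) {
  grab <- function(records, source, vars) {
    do.call(rbind, lapply(vars, function(v) {
      h <- minute_profile(records, source, v)
      data.frame(source = source, variable = v, n = h$n,
                 on_grid_n = sum(h$counts[c("0", "30")]),
                 on_grid_pct = percent1(sum(h$counts[c("0", "30")]), h$n))
    }))
  }
  out <- rbind(
    grab(psqi, "psqi", c("bed_time", "fall_asleep", "wake", "ast")),
    grab(chat, "chat", c("bed_time", "fall_asleep", "wake", "ast")),
    grab(fitbit, "fitbit", c("fall_asleep", "wake", "ast")))
  rownames(out) <- NULL
  out
}

coverage_table <- function(nights, thresholds) {
  rows <- list()
  for (pair in c("tst_vs_tst", "ast_vs_tstwaso"))
    for (thr in thresholds)
      for (corr in c("none", "global_mean", "by_qos")) {
        cv <- coverage(nights, pair, thr, corr)
        rows[[length(rows) + 1]] <- data.frame(
          pair = pair, threshold_min = thr, correction = corr,
          n_within = cv$n_within, n_total = cv$n_total, percent = cv$percent)
      }
  do.call(rbind, rows)
}

#' Run the full agreement pipeline and write a report bundle
#'
#' Simulate (or read) the record streams, summarize compliance, match and
#' QC nights, select the analysis set, derive night variables, and write
#' delimited-text report tables: exclusions, compliance, demographics by
#' PSQI group, rounding profile, overall and stratified agreement, coverage,
#' Bland-Altman point sets, and a JSON run manifest with stage-by-stage
#' record counts (so count conservation can be audited from the manifest
#' alone).
#'
#' @param config a [run_config()].
#' @return invisibly, a list with every intermediate product and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (config$verbose) message("[nightfit] ", sprintf(...))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)

  if (config$simulate) {
    p <- config$sim_params
    if (!is.null(config$seed)) {
      p$rng_seed <- as.integer(config$seed)
    }
    say("simulate: %d participants x %d nights (seed %d)",
        p$n_participants, p$nights_per_participant, p$rng_seed)
    cohort <- generate_cohort(p)
    fitbit <- cohort$fitbit; chat <- cohort$chat
    psqi <- cohort$psqi; profiles <- cohort$profiles
    n_raw_fit <- nrow(fitbit); n_raw_chat <- nrow(chat)
  } else {
    say("read: %s", config$fitbit_path)
    fitbit <- read_fitbit(config$fitbit_path)
    chat <- read_chat(config$chat_path)
    meta <- read_cohort_metadata(config$psqi_path, config$profile_path)
    psqi <- meta$psqi; profiles <- meta$profiles
    cohort <- NULL
    n_raw_fit <- nrow(fitbit) + nrow(rejects(fitbit))
    n_raw_chat <- nrow(chat) + nrow(rejects(chat))
    say("device rows: %d accepted, %d rejected",
        nrow(fitbit), nrow(rejects(fitbit)))
  }

  say("compliance summary")
  comp <- compliance_summary(fitbit, chat)
  say("match + QC (ampm threshold %g h)", config$ampm_hours)
  matched <- validate_and_match(fitbit, chat, config$ampm_hours)
  aset <- select_analysis_set(matched, config$min_days, config$cap_days,
                              fitbit = fitbit)
  say("analysis set: %d participants, %d nights",
      sum(aset$participants$included), nrow(aset$nights))
  nights <- derive_nights(aset$nights)
  pm <- participant_means(nights)

  overview <- agreement_overview(pm)
  strata <- stratified_agreement(nights, profiles, psqi)
  demog <- demographics_table(pm$participant_id, profiles, psqi)
  rounding <- rounding_table(chat, psqi, fitbit)
  cover <- coverage_table(nights, config$coverage_thresholds)

  excl_detail <- matched[matched$qc_status != "valid",
                         c("participant_id", "sleep_date", "qc_status")]
  write_tsv(excl_detail, file.path(config$outdir, "exclusions.tsv"))
  write_tsv(aset$exclusions, file.path(config$outdir, "exclusion_tally.tsv"))
  write_tsv(comp$device_days, file.path(config$outdir, "compliance_days.tsv"))
  write_tsv(comp$latency, file.path(config$outdir, "compliance_latency.tsv"))
  write_tsv(demog, file.path(config$outdir, "demographics.tsv"))
  write_tsv(rounding, file.path(config$outdir, "rounding.tsv"))
  write_tsv(overview, file.path(config$outdir, "agreement_overall.tsv"))
  write_tsv(strata, file.path(config$outdir, "agreement_strata.tsv"))
  write_tsv(cover, file.path(config$outdir, "coverage.tsv"))
  for (v in c("onset", "offset", "tst", "ast"))
    write_tsv(bland_altman_points(nights, v),
              file.path(config$outdir, paste0("bland_altman_", v, ".tsv")))

  manifest <- list(
    config = list(simulate = config$simulate,
                  min_days = config$min_days, cap_days = config$cap_days,
                  ampm_hours = config$ampm_hours,
                  coverage_thresholds = config$coverage_thresholds,
                  seed = if (config$simulate) config$sim_params$rng_seed
                         else NULL),
    counts = list(
      raw_fitbit_rows = n_raw_fit, raw_chat_rows = n_raw_chat,
      matched_pairs = nrow(matched),
      qc = as.list(table(matched$qc_status)),
      participants_total = nrow(aset$participants),
      participants_included = sum(aset$participants$included),
      participants_excluded = sum(!aset$participants$included),
      analysis_nights = nrow(nights)))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("report bundle written to %s", config$outdir)

  invisible(list(cohort = cohort, fitbit = fitbit, chat = chat, psqi = psqi,
                 profiles = profiles, compliance = comp, matched = matched,
                 analysis_set = aset, nights = nights,
                 participant_means = pm, overview = overview,
                 strata = strata, demographics = demog, rounding = rounding,
                 coverage = cover, manifest = manifest,
                 outdir = config$outdir))
}
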