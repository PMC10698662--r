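#' Per-night derived sleep variables
#'
#' From each QC-valid matched night derives, in integer seconds:
#' diary TST (`wake - asleep`, wrap-aware), diary AST (the reported actual
#' sleep time), device TST (`end - start`, wrap-aware), device WASO
#' (`minutes_awake * 60`), device AST (`TST - WASO`), and the four paired
#' differences, signed device-minus-diary so a positive difference means the
#' device value is later (clock fields) or longer (durations).
#'
#' @param matched matched nights from [validate_and_match()]; only
#'   `qc_status == "valid"` rows are used.
#' @return data frame of night variables, one row per valid night.
#' @export
derive_nights <- function(matched) {
  v <- matched[matched$qc_status == "valid", , drop = FALSE]
  if (!nrow(v)) stop("no valid nights to derive", call. = FALSE)
  out <- data.frame(
    participant_id = v$participant_id,
    sleep_date = v$sleep_date,
    qos = v$qos,
    qos_good = v$qos %in% c("very_good", "quite_good"),
    chat_onset = v$chat_asleep, chat_offset = v$chat_wake,
    chat_tst = elapsed_wrap(v$chat_asleep, v$chat_wake),
    chat_ast = v$chat_ast_minutes * 60L,
    fitbit_onset = v$fitbit_onset, fitbit_offset = v$fitbit_offset,
    fitbit_tst = elapsed_wrap(v$fitbit_onset, v$fitbit_offset),
    fitbit_waso = v$fitbit_minutes_awake * 60L,
    stringsAsFactors = FALSE)
  out$fitbit_ast <- out$fitbit_tst - out$fitbit_waso
  out$d_onset <- as_anchored(out$fitbit_onset) - as_anchored(out$chat_onset)
  out$d_offset <- as_anchored(out$fitbit_offset) - as_anchored(out$chat_offset)
  out$d_tst <- out$fitbit_tst - out$chat_tst
  out$d_ast <- out$fitbit_ast - out$chat_ast
  durs <- c(out$chat_tst, out$chat_ast, out$fitbit_tst, out$fitbit_ast)
  if (any(durs <= 0 | durs >= 86400))
    stop("derived duration outside (0, 24 h): QC leak upstream", call. = FALSE)
  out
}

#' Per-participant means of night variables
#'
#' Clock fields are averaged with the anchored circular mean
#' ([mean_clock()]); durations and differences with the arithmetic mean.
#' Participant-level agreement analyses run on these means, weighting every
#' participant equally regardless of night count.
#'
#' @param nights output of [derive_nights()].
#' @param min_days drop participants with fewer nights (default 1: assume
#'   selection already happened).
#' @return data frame, one row per participant, columns as in `nights` plus
#'   `n_nights`.
#' @export
participant_means <- function(nights, min_days = 1) {
  sp <- split(nights, nights$participant_id)
  sp <- sp[vapply(sp, nrow, 1L) >= min_days]
  rows <- lapply(sp, function(d) {
    data.frame(
      participant_id = d$participant_id[1],
      n_nights = nrow(d),
      chat_onset = clock_seconds(mean_clock(clock_time(d$chat_onset))),
      chat_offset = clock_seconds(mean_clock(clock_time(d$chat_offset))),
      chat_tst = mean(d$chat_tst), chat_ast = mean(d$chat_ast),
      fitbit_onset = clock_seconds(mean_clock(clock_time(d$fitbit_onset))),
      fitbit_offset = clock_seconds(mean_clock(clock_time(d$fitbit_offset))),
      fitbit_tst = mean(d$fitbit_tst), fitbit_waso = mean(d$fitbit_waso),
      fitbit_ast = mean(d$fitbit_ast),
      d_onset = mean(d$d_onset), d_offset = mean(d$d_offset),
      d_tst = mean(d$d_tst), d_ast = mean(d$d_ast),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bland-Altman agreement statistics for paired differences
#'
#' Mean difference, sample SD (n-1 denominator), limits of agreement
#' `mean +/- 1.96 * SD`, and the two-sided paired-t p-value for zero mean
#' difference. With zero variance the limits collapse onto the mean and the
#' p-value is undefined (`NA`).
#'
#' @param diffs numeric vector of signed paired differences (seconds, or any
#'   single unit), length >= 2.
#' @return object of class `agreement_stats`: `n`, `mean_diff`, `sd_diff`,
#'   `half_width`, `loa_low`, `loa_high`, `p_paired_t` (same unit as input).
#' @export
agreement_stats <- function(diffs) {
  diffs <- as.numeric(diffs)
  if (length(diffs) < 2) stop("need at least 2 differences", call. = FALSE)
  m <- mean(diffs); s <- stats::sd(diffs)
  p <- if (s == 0) NA_real_ else stats::t.test(diffs, mu = 0)$p.value
  structure(list(n = length(diffs), mean_diff = m, sd_diff = s,
                 half_width = 1.96 * s,
                 loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
                 p_paired_t = p),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman (n=%d): mean %.1f, SD %.1f, LoA [%.1f, %.1f], p=%s\n",
    x$n, x$mean_diff, x$sd_diff, x$loa_low, x$loa_high,
    ifelse(is.na(x$p_paired_t), "NA", format.pval(x$p_paired_t, digits = 2))))
  invisible(x)
}

# -- classification -----------------------------------------------------------

#' Group classifications for stratified agreement
#'
#' `classify_psqi`: `good` (score <= 5), `poor` (> 5), `unclassified`
#' (missing). `classify_age`: decade label (`"30s"`...). `classify_bmi`:
#' Asian-Pacific classes `underweight` (<18.5), `normal` (18.5-22.9),
#' `preobese` (23-24.9), `obesity_1` (25.0-29.9), `obesity_2` (>= 30).
#' `classify_qos`: a night is good iff the response is very/quite good.
#'
#' @param score integer PSQI total score, `NA` allowed.
#' @return character vector of group labels.
#' @export
classify_psqi <- function(score) {
  ifelse(is.na(score), "unclassified", ifelse(score <= 5, "good", "poor"))
}

#' @rdname classify_psqi
#' @param age_years integer age.
#' @export
classify_age <- function(age_years) {
  if (any(is.na(age_years) | age_years < 10 | age_years > 110))
    stop("age outside plausible range", call. = FALSE)
  paste0((age_years %/% 10) * 10, "s")
}

#' @rdname classify_psqi
#' @param bmi body-mass index, kg/m^2.
#' @export
classify_bmi <- function(bmi) {
  if (any(is.na(bmi) | bmi <= 0)) stop("bmi must be positive", call. = FALSE)
  cut(bmi, breaks = c(0, 18.5, 23, 25, 30, Inf),
      labels = c("underweight", "normal", "preobese", "obesity_1", "obesity_2"),
      right = FALSE)
}

#' @rdname classify_psqi
#' @param qos nightly quality-of-sleep response
#'   (`very_good`/`quite_good`/`quite_poor`/`very_poor`).
#' @export
classify_qos <- function(qos) {
  if (any(!qos %in% QOS_LEVELS)) stop("unknown qos level", call. = FALSE)
  ifelse(qos %in% c("very_good", "quite_good"), "good", "poor")
}

#' All group keys for one participant
#' @param profile one-row profile data frame (gender, age_years, bmi).
#' @param psqi_score PSQI total score or `NA`.
#' @return named character vector: psqi, gender, age, bmi groups.
#' @export
classify_participant <- function(profile, psqi_score = NA_integer_) {
  c(psqi = classify_psqi(psqi_score),
    gender = profile$gender,
    age = classify_age(profile$age_years),
    bmi = as.character(classify_bmi(profile$bmi)))
}

#' Stratified Bland-Altman agreement
#'
#' Participant-level strata (PSQI group, gender, age decade, BMI class) are
#' computed on per-participant mean differences (equal weight per
#' participant); the nightly quality-of-sleep stratum pools per-night
#' differences across participants (weight per night). Strata with fewer
#' than 2 observations are reported with `NA` statistics.
#'
#' @param nights [derive_nights()] output for the analysis set.
#' @param profiles,psqi metadata data frames (profile mandatory for
#'   participant-level strata).
#' @param variable which difference column to analyze (default `"d_ast"`,
#'   device TST-WASO minus diary AST).
#' @param strata subset of `c("psqi", "gender", "age", "bmi", "qos")`.
#' @return data frame: stratum, level, n (participants or nights),
#'   mean difference / SD / LoA (minutes), p-value.
#' @export
stratified_agreement <- function(nights, profiles, psqi = NULL,
                                 variable = "d_ast",
                                 strata = c("psqi", "gender", "age", "bmi",
                                            "qos")) {
  strata <- match.arg(strata, several.ok = TRUE)
  pm <- participant_means(nights)
  pm$psqi_score <- if (is.null(psqi)) NA_integer_ else
    psqi$total_score[match(pm$participant_id, psqi$participant_id)]
  idx <- match(pm$participant_id, profiles$participant_id)
  if (any(is.na(idx)) && any(strata != "qos"))
    stop("profile missing for some participants", call. = FALSE)
  pm$g_psqi <- classify_psqi(pm$psqi_score)
  pm$g_gender <- profiles$gender[idx]
  pm$g_age <- classify_age(profiles$age_years[idx])
  pm$g_bmi <- as.character(classify_bmi(profiles$bmi[idx]))

  one <- function(vals, stratum, level) {
    if (length(vals) < 2)
      return(data.frame(stratum = stratum, level = level, n = length(vals),
                        mean_diff_min = NA_real_, sd_min = NA_real_,
                        loa_low_min = NA_real_, loa_high_min = NA_real_,
                        p = NA_real_))
    s <- agreement_stats(vals / 60)
    data.frame(stratum = stratum, level = level, n = s$n,
               mean_diff_min = s$mean_diff, sd_min = s$sd_diff,
               loa_low_min = s$loa_low, loa_high_min = s$loa_high,
               p = s$p_paired_t)
  }
  out <- list()
  for (st in setdiff(strata, "qos")) {
    g <- pm[[paste0("g_", st)]]
    for (lev in sort(unique(g)))
      out[[length(out) + 1]] <- one(pm[[variable]][g == lev], st, lev)
  }
  if ("qos" %in% strata) {
    g <- classify_qos(nights$qos)
    for (lev in sort(unique(g)))
      out[[length(out) + 1]] <- one(nights[[variable]][g == lev], "qos", lev)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Bland-Altman point set for external plotting
#'
#' x is the device value, y the device-minus-diary difference, both in
#' minutes (clock x-values as minutes on the anchored axis).
#'
#' @param nights [derive_nights()] output.
#' @param variable one of `"onset"`, `"offset"`, `"tst"`, `"ast"`.
#' @return data frame with `participant_id`, `x_min`, `y_min`.
#' @export
bland_altman_points <- function(nights,
                                variable = c("onset", "offset", "tst", "ast")) {
  variable <- match.arg(variable)
  x <- switch(variable,
              onset = as_anchored(nights$fitbit_onset),
              offset = as_anchored(nights$fitbit_offset),
              tst = nights$fitbit_tst,
              ast = nights$fitbit_ast)
  y <- nights[[paste0("d_", variable)]]
  data.frame(participant_id = nights$participant_id,
             x_min = x / 60, y_min = y / 60)
}
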