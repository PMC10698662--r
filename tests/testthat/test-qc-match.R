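test_that("QC statuses follow the ordering and 9-hour rules", {
  nights <- bind_nights(
    raw_night("P1", "2021-03-02", "23:40", "07:05", 55L,
              bed = "23:30", asleep = "23:45", wake = "07:00"),      # valid
    raw_night("P1", "2021-03-03", "23:40", "07:05", 55L,
              bed = "23:00", asleep = "22:30", wake = "07:00"),      # order
    raw_night("P1", "2021-03-04", "00:20", "07:30", 55L,
              bed = "12:00", asleep = "12:30", wake = "19:30"))      # AM/PM
  m <- validate_and_match(nights$fitbit, nights$chat)
  expect_equal(m$qc_status,
               c("valid", "order_violation", "ampm_error"))
})

test_that("bed equal to asleep is allowed; wake equal to asleep is not", {
  ok <- raw_night("P1", "2021-03-02", "23:40", "07:05", 40L,
                  bed = "23:45", asleep = "23:45", wake = "07:00")
  m <- validate_and_match(ok$fitbit, ok$chat)
  expect_equal(m$qc_status, "valid")
  bad <- raw_night("P1", "2021-03-02", "23:40", "07:05", 40L,
                   bed = "23:45", asleep = "07:00", wake = "07:00")
  m <- validate_and_match(bad$fitbit, bad$chat)
  expect_equal(m$qc_status, "order_violation")
})

test_that("a >9h difference that is not AM/PM-like is overlarge_difference", {
  # device onset just past noon, diary asleep just before noon: a 23-hour
  # anchored gap, far from the 12-hour AM/PM signature, order intact
  x <- raw_night("P1", "2021-03-02", "12:30", "19:30", 40L,
                 bed = "10:00", asleep = "11:30", wake = "11:55", ast = 420L)
  m <- validate_and_match(x$fitbit, x$chat)
  expect_equal(m$qc_status, "overlarge_difference")
})

test_that("duplicate main sleep or diary for one night is fatal", {
  a <- raw_night("P1", "2021-03-02", "23:40", "07:05", 40L,
                 "23:30", "23:45", "07:00")
  two <- bind_nights(a, a)
  expect_error(validate_and_match(two$fitbit, a$chat), "duplicate main sleep")
  expect_error(validate_and_match(a$fitbit, two$chat), "duplicate diary")
})

test_that("analysis-set selection enforces min-days and the 14-day cap", {
  mk <- function(id, dates, status = "valid") {
    do.call(rbind, lapply(seq_along(dates), function(i)
      matched_row(id = id, date = as.Date(dates[i]), status = status)))
  }
  d <- as.Date("2021-03-01") + 0:21
  matched <- rbind(mk("A", d),            # 22 valid nights -> capped at 14
                   mk("B", d[1:6]),       # 6 valid nights  -> excluded
                   mk("C", d[1:8]))       # 8 valid nights  -> included
  aset <- select_analysis_set(matched, min_days = 7, cap_days = 14)
  inc <- aset$participants
  expect_equal(inc$included[match(c("A", "B", "C"), inc$participant_id)],
               c(TRUE, FALSE, TRUE))
  expect_equal(sum(aset$nights$participant_id == "A"), 14L)
  expect_true(all(aset$nights$sleep_date[aset$nights$participant_id == "A"]
                  <= d[14]))
  # conservation: every matched row is a valid night, tallied exclusion,
  # or beyond the cap
  ex <- aset$exclusions
  expect_equal(nrow(aset$nights) +
                 sum(ex$n[ex$reason %in% c("beyond_cap",
                                           "under_min_days_nights")]),
               nrow(matched))
})

test_that("relaxing min_days never shrinks, tightening 9h never grows", {
  co <- generate_cohort(tiny_params(ampm_error_rate = 0.05,
                                    order_error_rate = 0.05))
  m9 <- validate_and_match(co$fitbit, co$chat, ampm_hours = 9)
  m6 <- validate_and_match(co$fitbit, co$chat, ampm_hours = 6)
  expect_lte(sum(m6$qc_status == "valid"), sum(m9$qc_status == "valid"))
  for (md in c(9, 7, 5, 1)) {
    inc <- sum(select_analysis_set(m9, min_days = md)$participants$included)
    if (md == 9) prev <- inc
    expect_gte(inc, prev)
    prev <- inc
  }
})

test_that("forced injections are excluded with the matching reason code", {
  co <- generate_cohort(tiny_params(ampm_error_rate = 1, missing_chat_rate = 0,
                                    missing_fitbit_rate = 0))
  m <- validate_and_match(co$fitbit, co$chat)
  expect_true(all(m$qc_status == "ampm_error"))

  co <- generate_cohort(tiny_params(order_error_rate = 1, ampm_error_rate = 0,
                                    missing_chat_rate = 0,
                                    missing_fitbit_rate = 0))
  m <- validate_and_match(co$fitbit, co$chat)
  expect_true(all(m$qc_status == "order_violation"))
})

test_that("compliance buckets follow the table layout and half-open latency bands", {
  co <- generate_cohort(tiny_params())
  # hand-build streams with known day counts and latencies
  d <- as.Date("2021-03-01") + 0:11
  nights <- do.call(bind_nights, lapply(seq_along(d), function(i)
    raw_night("X", d[i], "23:40", "07:05", 40L, "23:30", "23:45", "07:00")))
  nights$chat$response_time <- nights$chat$prompt_time + 7800L  # 2 h 10 m
  cs <- compliance_summary(nights$fitbit, nights$chat)
  expect_equal(cs$device_days$n[cs$device_days$bucket == "12"], 1L)
  expect_equal(cs$latency$n[cs$latency$bucket == "within_3h"], 1L)

  nights$chat$response_time <- nights$chat$prompt_time + 3L * 3600L  # exactly 3 h
  cs <- compliance_summary(nights$fitbit, nights$chat)
  expect_equal(cs$latency$n[cs$latency$bucket == "within_6h"], 1L)
  expect_equal(sum(cs$latency$n), 1L)
  expect_equal(cs$latency$cumulative_percent[nrow(cs$latency)], 100)
})

test_that("QC exclusions recover ledger labels with zero false negatives", {
  co <- generate_cohort(tiny_params(ampm_error_rate = 0.15,
                                    order_error_rate = 0.15,
                                    missing_chat_rate = 0,
                                    missing_fitbit_rate = 0))
  m <- validate_and_match(co$fitbit, co$chat)
  key <- function(df) paste(df$participant_id, df$sleep_date)
  lab <- co$ledger$label[match(key(m), key(co$ledger))]
  expect_true(all(m$qc_status[lab == "ampm_swap"] == "ampm_error"))
  expect_true(all(m$qc_status[lab == "order_violation"] == "order_violation"))
})
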