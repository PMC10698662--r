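test_that("derive_nights computes the per-night variables and sign convention", {
  m <- matched_row(fit_on = "00:20", fit_off = "07:28", waso = 58L,
                   bed = "23:55", asleep = "00:30", wake = "07:20", ast = 390L)
  nv <- derive_nights(m)
  expect_equal(nv$chat_tst, 24600L)          # 00:30 -> 07:20
  expect_equal(nv$fitbit_tst, 25680L)        # 00:20 -> 07:28
  expect_equal(nv$fitbit_ast, 25680L - 58L * 60L)  # 22200
  expect_equal(nv$chat_ast, 390L * 60L)
  expect_equal(nv$d_onset, -600L)            # device onset 10 min earlier
  expect_equal(nv$d_offset, 480L)            # device offset 8 min later
  expect_equal(nv$d_tst, 1080L)
  expect_equal(nv$d_ast, 22200L - 23400L)

  z <- derive_nights(matched_row(waso = 0L))
  expect_equal(z$fitbit_ast, z$fitbit_tst)   # zero WASO: AST == TST
})

test_that("nightly TST difference decomposes into offset minus onset diffs", {
  co <- generate_cohort(tiny_params())
  m <- validate_and_match(co$fitbit, co$chat)
  nv <- derive_nights(m)
  expect_equal(nv$d_tst, nv$d_offset - nv$d_onset)
})

test_that("derived diffs match an independent naive-expansion oracle", {
  co <- generate_cohort(tiny_params())
  m <- validate_and_match(co$fitbit, co$chat)
  nv <- derive_nights(m)
  v <- m[m$qc_status == "valid", ]
  lift <- function(s) ifelse(s >= 43200, s - 86400, s)  # +24h expansion
  expect_equal(nv$d_onset, lift(v$fitbit_onset) - lift(v$chat_asleep))
  expect_equal(nv$d_offset, lift(v$fitbit_offset) - lift(v$chat_wake))
  span <- function(a, b) (b - a) %% 86400
  expect_equal(nv$d_tst,
               as.integer(span(v$fitbit_onset, v$fitbit_offset) -
                            span(v$chat_asleep, v$chat_wake)))
})

test_that("agreement_stats: formulas, degenerate input, guards", {
  s <- agreement_stats(c(-3, 1, 5, 9))
  expect_equal(s$mean_diff, 3)
  expect_equal(s$sd_diff, sd(c(-3, 1, 5, 9)))
  expect_equal(s$half_width, 1.96 * s$sd_diff)
  expect_equal(s$loa_low, s$mean_diff - s$half_width)
  expect_equal(s$loa_high, s$mean_diff + s$half_width)
  expect_equal(s$p_paired_t, t.test(c(-3, 1, 5, 9))$p.value)

  z <- agreement_stats(rep(0, 5))
  expect_equal(z$mean_diff, 0)
  expect_equal(c(z$loa_low, z$loa_high), c(0, 0))
  expect_true(is.na(z$p_paired_t))
  expect_error(agreement_stats(1), "at least 2")
})

test_that("agreement_stats is shift-equivariant with invariant SD", {
  withr::with_seed(11, {
    d <- rnorm(40, 10, 30)
    a <- agreement_stats(d); b <- agreement_stats(d + 17)
    expect_equal(b$mean_diff, a$mean_diff + 17)
    expect_equal(b$sd_diff, a$sd_diff)
    expect_equal(b$loa_low, a$loa_low + 17)
    expect_equal(b$loa_high, a$loa_high + 17)
  })
})

test_that("classification rules match the printed group bounds", {
  expect_equal(classify_psqi(c(5L, 6L, NA)), c("good", "poor", "unclassified"))
  expect_equal(as.character(classify_bmi(c(18.4, 18.5, 22.9, 23, 24.9, 25,
                                           29.9, 30))),
               c("underweight", "normal", "normal", "preobese", "preobese",
                 "obesity_1", "obesity_1", "obesity_2"))
  expect_equal(classify_age(c(30, 39, 40, 59)), c("30s", "30s", "40s", "50s"))
  expect_error(classify_age(200), "plausible")
  expect_error(classify_bmi(-1), "positive")
  expect_equal(classify_qos(c("very_good", "quite_good", "quite_poor",
                              "very_poor")),
               c("good", "good", "poor", "poor"))
  prof <- data.frame(participant_id = "P", gender = "women",
                     age_years = 44L, bmi = 22.1)
  expect_equal(unname(classify_participant(prof, 4L)),
               c("good", "women", "40s", "normal"))
})

test_that("participant means use circular means for clocks, plain for durations", {
  m <- rbind(matched_row(date = as.Date("2021-03-02"), asleep = "23:30",
                         wake = "07:00", ast = 400L),
             matched_row(date = as.Date("2021-03-03"), asleep = "00:30",
                         wake = "07:30", ast = 420L))
  pm <- participant_means(derive_nights(m))
  expect_equal(pm$chat_onset, 0L)  # straddles midnight: circular mean 00:00
  expect_equal(pm$chat_ast, 410 * 60)
  expect_equal(pm$n_nights, 2L)
})

test_that("stratified agreement: identical strata, conservation, small n", {
  co <- generate_cohort(tiny_params())
  m <- validate_and_match(co$fitbit, co$chat)
  nv <- derive_nights(m)
  aset <- select_analysis_set(m, min_days = 1)
  nv <- derive_nights(aset$nights)
  st <- stratified_agreement(nv, co$profiles, co$psqi)
  # per-night qos strata pool to the full night set
  qos_rows <- st[st$stratum == "qos", ]
  expect_equal(sum(qos_rows$n), nrow(nv))
  # participant-level strata pool to the participant set
  pm <- participant_means(nv)
  expect_equal(sum(st$n[st$stratum == "gender"]), nrow(pm))
  # two strata fed identical diffs give identical stats
  fake_prof <- co$profiles
  fake_prof$gender <- rep(c("men", "women"), length.out = nrow(fake_prof))
  half <- stratified_agreement(nv, fake_prof, strata = "gender")
  dup_nv <- nv
  dup_prof <- fake_prof; dup_prof$gender <- "men"
  all_men <- stratified_agreement(dup_nv, dup_prof, strata = "gender")
  pooled <- agreement_stats(participant_means(nv)$d_ast / 60)
  expect_equal(all_men$mean_diff_min, pooled$mean_diff)
  # a singleton stratum reports NA stats, not an error
  one_prof <- fake_prof
  one_prof$gender <- c("men", rep("women", nrow(one_prof) - 1))
  st1 <- stratified_agreement(nv, one_prof, strata = "gender")
  if (any(st1$n == 1)) expect_true(all(is.na(st1$mean_diff_min[st1$n == 1])))
})

test_that("bland_altman_points exports device-x, difference-y in minutes", {
  m <- matched_row()
  nv <- derive_nights(m)
  ba <- bland_altman_points(nv, "ast")
  expect_equal(ba$x_min, nv$fitbit_ast / 60)
  expect_equal(ba$y_min, nv$d_ast / 60)
})
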