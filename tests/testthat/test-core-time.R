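test_that("parse_clock handles 12/24-hour dialects and rejects malformed input", {
  expect_equal(clock_seconds(parse_clock("12:19:42 AM")), 1182L)
  expect_equal(clock_seconds(parse_clock("12:28:21 AM")), 1701L)
  expect_equal(clock_seconds(parse_clock("24:00")), 0L)
  expect_equal(clock_seconds(parse_clock("7:27:40 AM")), 26860L)
  expect_equal(clock_seconds(parse_clock("12:30 PM")), 45000L)
  expect_equal(clock_seconds(parse_clock("23:05")), 83100L)
  expect_error(parse_clock("25:00"), "hour")
  expect_error(parse_clock("7:65"), "minute")
  expect_error(parse_clock("noonish"), "malformed")
  expect_error(parse_clock("13:00 PM"), "hour")
})

test_that("parse/format round trip is the identity on random instants", {
  withr::with_seed(1, {
    s <- sample(0:86399, 300)
    expect_equal(clock_seconds(parse_clock(format(clock_time(s)))), s)
  })
})

test_that("chatbot button dialect enforces the 5-minute grid", {
  expect_equal(clock_seconds(parse_clock_buttons(24, 0)), 0L)
  expect_equal(clock_seconds(parse_clock_buttons(23, 55)), 86100L)
  expect_error(parse_clock_buttons(0, 0), "hour")
  expect_error(parse_clock_buttons(25, 0), "hour")
  expect_error(parse_clock_buttons(7, 17), "minute")
})

test_that("elapsed_wrap crosses midnight and rejects degenerate intervals", {
  expect_equal(elapsed_wrap(parse_clock("00:19:42"), parse_clock("07:27:40")),
               25678L)
  expect_equal(elapsed_wrap(parse_clock("23:00"), parse_clock("01:00")), 7200L)
  expect_error(elapsed_wrap(clock_time(100), clock_time(100)), "degenerate")
})

test_that("elapsed_wrap: complement and translation-invariance properties", {
  withr::with_seed(2, {
    a <- sample(0:86399, 1000, replace = TRUE)
    b <- sample(0:86399, 1000, replace = TRUE)
    keep <- a != b
    a <- a[keep]; b <- b[keep]
    expect_true(all(elapsed_wrap(a, b) + elapsed_wrap(b, a) == 86400L))
    expect_true(all(elapsed_wrap(a, b) > 0 & elapsed_wrap(a, b) < 86400))
    cc <- sample(0:86399, 1)
    expect_equal(elapsed_wrap((a + cc) %% 86400, (b + cc) %% 86400),
                 elapsed_wrap(a, b))
  })
})

test_that("anchored mapping is a bijection with evening negative, morning positive", {
  s <- c(0L, 1L, 43199L, 43201L, 86399L, 82800L, 26860L)
  expect_equal(clock_seconds(from_anchored(as_anchored(s))), s)
  expect_lt(as_anchored(clock_seconds(parse_clock("23:00"))), 0)
  expect_gt(as_anchored(clock_seconds(parse_clock("07:00"))), 0)
  withr::with_seed(3, {
    t <- sample(0:86399, 500, replace = TRUE)
    anch <- sample(0:86399, 1)
    expect_equal(clock_seconds(from_anchored(as_anchored(t, anch), anch)), t)
    expect_true(all(as_anchored(t, anch) > -43200 &
                      as_anchored(t, anch) <= 43200))
  })
})

test_that("mean_clock matches spec examples and guards its domain", {
  expect_equal(format(mean_clock(c("23:00", "01:00"))), "00:00:00")
  expect_equal(format(mean_clock("07:22:01")), "07:22:01")
  expect_error(mean_clock(clock_time(integer())), "empty")
  expect_error(mean_clock(c("12:00:00", "13:00")), "anchor")
})

test_that("mean_clock equals the naive +24 h expansion oracle", {
  naive_mean <- function(secs) {
    expanded <- ifelse(secs >= 43200, secs - 86400, secs)  # noon-to-noon lift
    round(mean(expanded)) %% 86400
  }
  withr::with_seed(4, {
    for (i in 1:500) {
      n <- sample(1:12, 1)
      # evening/morning cluster around midnight, the study's regime
      secs <- (round(stats::rnorm(n, 0, 3 * 3600))) %% 86400
      expect_equal(clock_seconds(mean_clock(clock_time(secs))),
                   as.integer(naive_mean(secs)))
    }
  })
})

test_that("mean_clock is shift-equivariant and reduces to the plain mean", {
  withr::with_seed(5, {
    secs <- sample(0:20000, 50)  # all-morning: no wrap involved
    expect_equal(clock_seconds(mean_clock(clock_time(secs))),
                 as.integer(round(mean(secs))))
    shift <- 3600L
    expect_equal(
      clock_seconds(mean_clock(clock_time((secs + shift) %% 86400))),
      (clock_seconds(mean_clock(clock_time(secs))) + shift) %% 86400)
  })
})

test_that("format_hms prints signed h:mm:ss", {
  expect_equal(format_hms(-519), "-0:08:39")
  expect_equal(format_hms(25678), "7:07:58")
  expect_equal(format_hms(0), "0:00:00")
})
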