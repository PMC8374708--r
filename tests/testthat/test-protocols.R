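# Stimulus protocol encoding and timeline rendering.

test_that("simple cooling protocol has the published step series", {
  p <- build_protocol("simple_cooling")
  expect_equal(p$trials$end_temp, c(27, 22, 17, 12, 7, 4))
  expect_equal(p$trials$baseline_temp, rep(32, 6))
  expect_equal(p$trials$rate_on, rep(2, 6))
  expect_equal(p$trials$rate_off, rep(4, 6))
  expect_equal(p$trials$hold_s, rep(5, 6))
  expect_equal(p$trials$pre_baseline_s, rep(90, 6))
})

test_that("rate-of-change heating uses 0.2/0.5/2 C/s up and 8 C/s return", {
  p <- build_protocol("rate_of_change_heating")
  expect_equal(p$trials$rate_on, c(0.2, 0.5, 2))
  expect_equal(p$trials$rate_off, rep(8, 3))
  expect_equal(p$trials$end_temp, rep(50, 3))
  # total on-stimulus time equalised to the slowest ramp (90 s)
  expect_equal((50 - 32) / p$trials$rate_on + p$trials$hold_s, rep(90, 3))
})

test_that("unknown protocol name errors and names the valid set", {
  expect_error(build_protocol("banana"), "simple_cooling")
})

test_that("ramp segment durations equal |dT| / rate on the sampled grid", {
  # simple-heating trial to 50 C: up 9 s, hold 5 s, return 4.5 s
  tl <- render_timeline(build_protocol("simple_heating"), sampling_rate = 4)
  tr <- tl$trials[tl$trials$end_temp == 50, ]
  expect_equal(tr$offset_s - tr$onset_s, 18 / 2 + 5)
  # slow rate-of-change cooling: down-ramp lasts 110 s
  tlc <- render_timeline(build_protocol("rate_of_change_cooling"))
  tr1 <- tlc$trials[1, ]
  i_on <- which(tlc$data$time_s == tr1$onset_s)
  expect_equal(tlc$data$temperature_c[i_on], 32)
  expect_equal(tlc$data$temperature_c[which(tlc$data$time_s == tr1$onset_s + 110)], 10)
  # still above 10 one sample before the ramp end
  expect_gt(tlc$data$temperature_c[which(tlc$data$time_s == tr1$onset_s + 110) - 1], 10)
})

test_that("ramp endpoints hit declared temperatures to machine precision", {
  for (nm in grep("heating|cooling", protocol_names(), value = TRUE)) {
    p <- build_protocol(nm)
    tl <- render_timeline(p, sampling_rate = 4)
    interp <- function(t) approx(tl$breakpoints$time_s,
                                 tl$breakpoints$temperature_c, xout = t)$y
    for (i in seq_len(nrow(tl$trials))) {
      tr <- tl$trials[i, ]
      ramp_dur <- abs(tr$end_temp - tr$baseline_temp) / p$trials$rate_on[i]
      expect_equal(interp(tr$onset_s), tr$baseline_temp, tolerance = 1e-12)
      expect_equal(interp(tr$onset_s + ramp_dur), tr$end_temp, tolerance = 1e-12)
      expect_equal(interp(tr$offset_s), tr$end_temp, tolerance = 1e-12)
    }
  }
})

test_that("timeline temperature is continuous at the fastest declared rate", {
  for (nm in grep("heating|cooling", protocol_names(), value = TRUE)) {
    p <- build_protocol(nm)
    tl <- render_timeline(p, sampling_rate = 4)
    max_rate <- max(p$trials$rate_on, p$trials$rate_off)
    max_jump <- max(abs(diff(tl$data$temperature_c)))
    expect_lte(max_jump, max_rate * 0.25 + 1e-9)
    expect_true(all(tl$data$temperature_c >= 4 - 1e-9 &
                      tl$data$temperature_c <= 50 + 1e-9))
  }
})

test_that("all protocols round-trip through YAML", {
  for (nm in protocol_names()) {
    p <- build_protocol(nm)
    f <- withr::local_tempfile(fileext = ".yaml")
    write_protocol_yaml(p, f)
    q <- read_protocol_yaml(f)
    expect_equal(q$name, p$name)
    expect_equal(as.data.frame(q$trials), as.data.frame(p$trials))
    expect_equal(as.data.frame(q$events), as.data.frame(p$events))
  }
})

test_that("stimulus windows use a 5 s baseline starting 10 s before onset", {
  tl <- render_timeline(build_protocol("simple_cooling"), 4, lead_in = 100)
  w <- stimulus_windows(tl, post_lag = 10)
  expect_equal(w$baseline_start_s, tl$trials$onset_s - 10)
  expect_equal(w$baseline_end_s - w$baseline_start_s, rep(5, nrow(w)))
  # response windows never reach into the next trial's baseline window
  expect_true(all(w$response_end_s[-nrow(w)] <= w$baseline_start_s[-1]))
  # a trial onset at 100 s has baseline [90, 95)
  expect_equal(w$baseline_start_s[1], 90)
  expect_equal(w$baseline_end_s[1], 95)
})

test_that("windows are refused when the first onset is under 10 s", {
  tl <- render_timeline(build_protocol("pinch"), 4, lead_in = 60)
  tl$trials$onset_s[1] <- 5
  expect_error(stimulus_windows(tl), "insufficient baseline")
})

test_that("zero-trial thermal protocol renders a flat baseline trace", {
  p <- build_protocol("simple_heating")
  p$trials <- p$trials[0, ]
  tl <- render_timeline(p, sampling_rate = 4, lead_in = 40)
  expect_equal(unique(tl$data$temperature_c), 32)
  expect_equal(max(tl$data$time_s), 40)
  expect_equal(nrow(tl$trials), 0)
})

test_that("event protocols carry labelled non-overlapping events at 32 C", {
  for (nm in c("brush", "pinch", "electrical_supra")) {
    tl <- render_timeline(build_protocol(nm), 4, lead_in = 60)
    expect_equal(unique(tl$data$temperature_c), 32)
    expect_equal(nrow(tl$events), 3)
    expect_true(all(diff(tl$events$onset_s) > 0))
    expect_true(all(tl$events$offset_s[-3] <= tl$events$onset_s[-1]))
    expect_equal(unique(tl$events$label), nm)
  }
})

test_that("out-of-range sampling rate warns; invalid lead-in errors", {
  expect_warning(render_timeline(build_protocol("pinch"), sampling_rate = 10),
                 "0.5-4")
  expect_error(render_timeline(build_protocol("pinch"), lead_in = 10), "30")
})

test_that("timeline CSV export has the documented columns", {
  tl <- render_timeline(build_protocol("pinch"), 4)
  f <- withr::local_tempfile(fileext = ".csv")
  write_timeline_csv(tl, f)
  d <- readr::read_csv(f, show_col_types = FALSE)
  expect_equal(names(d), c("time_s", "temperature_c", "event_label"))
  expect_equal(nrow(d), nrow(tl$data))
})
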