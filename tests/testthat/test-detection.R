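# The 70% + 4 SD responder criterion and thermal-threshold estimation.

test_that("criterion arithmetic: flat baseline responds at 70, noisy baseline raises the bar", {
  times <- seq(0, 80, by = 0.5)
  w <- make_window(onset = 40, offset = 50)
  # flat zero baseline, peak 75% during the stimulus -> responder at 70
  v <- numeric(length(times)); v[times >= 45 & times < 47] <- 75
  calls <- detect_responses(make_dff(times, v), w)
  expect_true(calls$responded)
  expect_equal(calls$threshold_pct, 70)
  expect_equal(calls$peak_pct, 75)
  expect_equal(calls$t_cross_s, 45)
  # baseline SD of 5% pushes the threshold to 90: an 85% peak no longer counts
  base <- rep(c(-5, 5), length.out = length(times))  # sample SD ~5.03
  v2 <- base; v2[times >= 45 & times < 47] <- 85
  calls2 <- detect_responses(make_dff(times, v2), w)
  sd_b <- sd(base[times >= 30 & times < 35])
  expect_equal(calls2$threshold_pct, 70 + 4 * sd_b)
  expect_false(calls2$responded)
  expect_true(is.na(calls2$t_cross_s))
})

test_that("a peak occurring only before onset is not a response", {
  times <- seq(0, 80, by = 0.5)
  v <- numeric(length(times)); v[times >= 36 & times < 38] <- 500
  calls <- detect_responses(make_dff(times, v), make_window(40, 50))
  expect_false(calls$responded)
})

test_that("ties at exactly threshold count as responses", {
  times <- seq(0, 80, by = 0.5)
  v <- numeric(length(times)); v[times == 45] <- 70
  calls <- detect_responses(make_dff(times, v), make_window(40, 50))
  expect_true(calls$responded)
})

test_that("raising a peak never demotes a responder (monotonicity)", {
  set.seed(8)
  times <- seq(0, 80, by = 0.25)
  w <- make_window(40, 50)
  for (rep_i in 1:25) {
    base <- rnorm(length(times), sd = runif(1, 1, 8))
    peak0 <- runif(1, 0, 150)
    v <- base; v[times >= 44 & times < 46] <- v[times >= 44 & times < 46] + peak0
    r0 <- detect_responses(make_dff(times, v), w)$responded
    v2 <- v; v2[times >= 44 & times < 46] <- v2[times >= 44 & times < 46] + 50
    r1 <- detect_responses(make_dff(times, v2), w)$responded
    expect_true(r1 >= r0)
  }
})

test_that("windows outside the recording and short baselines error", {
  times <- seq(0, 30, by = 0.5)
  v <- numeric(length(times))
  expect_error(detect_responses(make_dff(times, v), make_window(100, 110)),
               "outside")
  w <- make_window(12, 20)
  w$baseline_end_s <- w$baseline_start_s + 0.6  # two samples only
  expect_error(detect_responses(make_dff(times, v), w), "fewer than 3")
})

test_that("false-positive rate on stimulus-free noise is far below 0.1%", {
  # spot check at sigma = 8%; the full 10,000-window sweep runs in the
  # acceptance suite
  set.seed(13)
  times <- seq(0, 60, by = 0.25)
  w <- make_window(30, 40)
  dff <- purrr::map_dfr(1:200, function(i) {
    make_dff(times, rnorm(length(times), sd = 8), cell_id = i)
  })
  calls <- detect_responses(dff, w)
  expect_equal(sum(calls$responded), 0)
})

test_that("heat thresholds scan to the lowest responded end temperature", {
  calls <- tibble::tibble(
    cell_id = 1L, trial_id = 1:9, modality = "heat", baseline_temp = 32,
    end_temp = seq(34, 50, 2), responded = seq(34, 50, 2) %in% c(46, 48, 50))
  est <- estimate_thermal_threshold(calls)
  expect_equal(est$threshold_c, 46)
  # responding at every cooling step gives the first (warmest) step, 27 C
  callsc <- tibble::tibble(
    cell_id = 1L, trial_id = 1:6, modality = "cold", baseline_temp = 32,
    end_temp = c(27, 22, 17, 12, 7, 4), responded = TRUE)
  expect_equal(estimate_thermal_threshold(callsc)$threshold_c, 27)
  # no responses -> NA
  none <- dplyr::mutate(callsc, responded = FALSE)
  expect_true(is.na(estimate_thermal_threshold(none)$threshold_c))
})

test_that("threshold estimation refuses variable-baseline calls", {
  calls <- tibble::tibble(
    cell_id = 1L, trial_id = 1:2, modality = "cold",
    baseline_temp = c(17, 22), end_temp = c(7, 12), responded = TRUE)
  expect_error(estimate_thermal_threshold(calls), "simple ramp")
  expect_error(estimate_thermal_threshold(
    tibble::tibble(cell_id = 1, trial_id = 1, modality = "pinch",
                   baseline_temp = 32, end_temp = 32, responded = TRUE)),
    "no thermal")
})

test_that("noiseless simple-ramp recovery lands on the grid step beside the true threshold", {
  # deterministic mini-population away from grid edges
  pop <- dplyr::bind_rows(
    make_cell(heat = TRUE, heat_threshold = 41.0, cell_id = 1L),
    make_cell(heat = TRUE, heat_threshold = 44.9, cell_id = 2L),
    make_cell(cold = TRUE, cold_threshold = 25.0, cell_id = 3L),
    make_cell(cold = TRUE, cold_threshold = 13.5, cell_id = 4L))
  for (proto in c("simple_heating", "simple_cooling")) {
    tl <- render_timeline(build_protocol(proto), 4, 60)
    ts <- simulate_traces(pop, tl, noise = noise_model(sd = 0), seed = 1)
    dff <- tidy(ts) |> subtract_background() |> delta_f_over_f(c(0, 30))
    calls <- detect_responses(dff, stimulus_windows(tl))
    est <- estimate_thermal_threshold(calls)
    if (proto == "simple_heating") {
      got <- est$threshold_c[order(est$cell_id)][1:2]
      expect_equal(got, c(42, 46))  # smallest grid temp above theta (+margin)
    } else {
      got <- est$threshold_c[order(est$cell_id)][3:4]
      expect_equal(got, c(22, 12))  # largest grid temp below theta (-margin)
    }
  }
})
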