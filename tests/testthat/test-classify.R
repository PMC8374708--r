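# Modality labels, postmortem-normalised percentages, polymodality tables
# and correlation-sorted trace summaries.

calls_row <- function(cell, modality, responded, trial = 1L) {
  tibble::tibble(cell_id = cell, trial_id = trial, modality = modality,
                 responded = responded)
}

test_that("modality labels are the set of responded modalities", {
  calls <- dplyr::bind_rows(
    calls_row(1, "pinch", TRUE), calls_row(1, "cold", TRUE),
    calls_row(1, "heat", FALSE),
    calls_row(2, "pinch", FALSE), calls_row(2, "cold", FALSE),
    calls_row(3, "pinch", TRUE), calls_row(3, "cold", TRUE),
    calls_row(3, "heat", TRUE),
    # a second cold trial must not double-count
    calls_row(3, "cold", TRUE, trial = 2L),
    # electrical calls never enter the label
    calls_row(4, "electrical_supra", TRUE), calls_row(4, "cold", TRUE))
  lab <- classify_modality(calls)
  expect_equal(lab$label, c("pinch+cold", "none", "pinch+cold+heat", "cold"))
})

test_that("percent responding normalises to the postmortem count", {
  calls <- dplyr::bind_rows(
    purrr::map_dfr(1:12, ~calls_row(.x, "cold", TRUE)),
    purrr::map_dfr(13:15, ~calls_row(.x, "cold", FALSE)))
  pct <- percent_responding(calls, 20)
  expect_equal(pct$per_animal$percent, 60)  # 12 of 20 postmortem cells
  expect_equal(pct$summary$mean_percent, 60)
  # 0 responders -> 0%; all postmortem cells responding -> 100%
  none <- dplyr::mutate(calls, responded = FALSE)
  expect_equal(percent_responding(none, 20)$per_animal$percent, 0)
  all15 <- dplyr::mutate(calls, responded = TRUE)
  expect_equal(percent_responding(all15, 15)$per_animal$percent, 100)
  expect_error(percent_responding(calls, 0), "positive")
  expect_error(percent_responding(calls, 10), "smaller")
})

test_that("per-animal percentages aggregate with mean and SEM across animals", {
  calls <- dplyr::bind_rows(
    dplyr::mutate(purrr::map_dfr(1:4, ~calls_row(.x, "cold", .x <= 2)), animal = 1L),
    dplyr::mutate(purrr::map_dfr(1:4, ~calls_row(.x, "cold", .x <= 3)), animal = 2L))
  pct <- percent_responding(calls, tibble::tibble(animal = 1:2,
                                                  postmortem_count = c(5, 10)))
  expect_equal(sort(pct$per_animal$percent), c(30, 40))
  expect_equal(pct$summary$mean_percent, 35)
  expect_equal(pct$summary$sem_percent, sd(c(40, 30)) / sqrt(2))
})

test_that("polymodality table reproduces printed conditional percentages", {
  # the 96-cell thermal cohort: 60 cold, 21 heat, 16 responding to both
  labels96 <- make_labels(c(cold = 44, heat = 5, cold_heat = 16, none = 31))
  tab <- polymodality_table(labels96)
  hc <- tab$pairwise
  expect_equal(hc$percent[hc$modality_a == "heat" & hc$modality_b == "cold"], 76)
  expect_equal(hc$percent[hc$modality_a == "cold" & hc$modality_b == "heat"], 27)
  # symmetry of the intersection count
  expect_equal(hc$n_both[hc$modality_a == "heat" & hc$modality_b == "cold"],
               hc$n_both[hc$modality_a == "cold" & hc$modality_b == "heat"])
  # empty labels give an all-zero table
  empty <- polymodality_table(make_labels(c(none = 0)))
  expect_equal(nrow(empty$categories), 0)
  expect_true(all(empty$pairwise$n_both == 0))
})

test_that("z-scored rows have mean 0 and SD 1; order follows |r| with ties by id", {
  times <- seq(0, 99, by = 1)
  temp <- 32 + 10 * sin(times / 8)
  norm <- dplyr::bind_rows(
    make_dff(times, temp * 3 + 5, cell_id = 1L),        # |r| = 1 (affine)
    make_dff(times, rep(4, length(times)), cell_id = 2L), # constant: |r| = 0
    make_dff(times, -temp, cell_id = 3L),               # |r| = 1 (anti)
    make_dff(times, sin(times / 3), cell_id = 4L))      # weakly correlated
  s <- summarize_traces(norm, tibble::tibble(time_s = times,
                                             temperature_c = temp))
  # perfect (anti-)correlates lead, the constant trace is last with |r| = 0
  expect_setequal(s$order$cell_id[1:2], c(1, 3))
  expect_equal(s$order$abs_r[1:2], c(1, 1), tolerance = 1e-12)
  expect_equal(s$order$cell_id[4], 2)
  expect_equal(s$order$abs_r[4], 0)
  # exact |r| ties break by cell id
  tied <- dplyr::bind_rows(make_dff(times, temp, cell_id = 9L),
                           make_dff(times, temp, cell_id = 7L))
  st <- summarize_traces(tied, temp)
  expect_equal(st$order$cell_id, c(7, 9))
  zz <- s$zscores |> dplyr::group_by(cell_id) |>
    dplyr::summarise(m = mean(z), s = sd(z))
  expect_true(all(abs(zz$m) < 1e-9))
  expect_true(all(abs(zz$s[zz$cell_id != 2] - 1) < 1e-9))
  # constant rows z-score to all zeros rather than NaN
  expect_true(all(s$zscores$z[s$zscores$cell_id == 2] == 0))
})

test_that("heatmap order is invariant under positive affine transforms", {
  set.seed(3)
  times <- 0:199
  temp <- 32 - 15 * pmin(1, pmax(0, (times - 50) / 30))
  norm <- purrr::map_dfr(1:6, function(i) {
    make_dff(times, rnorm(200) + i * 0.4 * temp, cell_id = i)
  })
  s1 <- summarize_traces(norm, temp)
  norm2 <- norm |> dplyr::mutate(dff_pct = dff_pct * 2.5 + 11)
  s2 <- summarize_traces(norm2, temp)
  expect_equal(s1$order$cell_id, s2$order$cell_id)
})

test_that("mean trace and SEM are computed across the responding subset", {
  times <- 0:9
  norm <- dplyr::bind_rows(
    make_dff(times, rep(10, 10), cell_id = 1L),
    make_dff(times, rep(30, 10), cell_id = 2L),
    make_dff(times, rep(1000, 10), cell_id = 3L))
  s <- summarize_traces(norm, rep(32, 10), subset = c(1, 2))
  expect_equal(unique(s$mean_trace$mean_dff), 20)
  expect_equal(unique(s$mean_trace$sem_dff), sd(c(10, 30)) / sqrt(2))
  expect_equal(unique(s$mean_trace$n_cells), 2L)
})
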