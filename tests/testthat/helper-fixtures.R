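# Shared fixtures, all built in code.

# one fully specified tuned cell as a one-row tibble
make_cell <- function(cold = FALSE, heat = FALSE, pinch = FALSE,
                      electrical_c = FALSE, electrical_a = FALSE,
                      cold_threshold = NA_real_, heat_threshold = NA_real_,
                      gain = 100, tau_adapt = 10, priming_coef = 0.05,
                      event_gain = 150, silent = FALSE, cell_id = 1L) {
  tibble::tibble(cell_id = cell_id, category = "custom",
                 cold = cold, heat = heat, pinch = pinch,
                 electrical_c = electrical_c, electrical_a = electrical_a,
                 silent = silent, cold_threshold = cold_threshold,
                 heat_threshold = heat_threshold, gain = gain,
                 tau_adapt = tau_adapt, priming_coef = priming_coef,
                 event_gain = event_gain)
}

# hand-built timeline from breakpoints (piecewise linear), one trial spanning
# the whole stimulus; used where a protocol object would get in the way
make_timeline <- function(bp_time, bp_temp, sampling_rate = 4,
                          onset = NULL, offset = NULL, baseline_temp = 32) {
  dt <- 1 / sampling_rate
  time <- seq(0, max(bp_time), by = dt)
  temp <- approx(bp_time, bp_temp, xout = time, rule = 2)$y
  trials <- if (is.null(onset)) {
    tibble::tibble(trial_id = integer(), onset_s = numeric(),
                   offset_s = numeric(), baseline_temp = numeric(),
                   end_temp = numeric(), modality = character(),
                   label = character())
  } else {
    tibble::tibble(trial_id = 1L, onset_s = onset, offset_s = offset,
                   baseline_temp = baseline_temp, end_temp = min(bp_temp),
                   modality = "cold", label = "cold_custom")
  }
  structure(
    list(data = tibble::tibble(time_s = time, temperature_c = temp,
                               event_label = NA_character_),
         trials = trials,
         events = tibble::tibble(label = character(), onset_s = numeric(),
                                 offset_s = numeric()),
         sampling_rate = sampling_rate, lead_in = 0,
         protocol_name = "custom"),
    class = "stim_timeline")
}

# modality-label table with given category counts (category names as used by
# the population generator: pinch_cold, cold, none, ...)
make_labels <- function(counts) {
  labels <- rep(names(counts), counts)
  tibble::tibble(
    cell_id = seq_along(labels),
    pinch = grepl("pinch", labels),
    cold = grepl("cold", labels),
    heat = grepl("heat", labels)
  ) |>
    dplyr::mutate(label = purrr::pmap_chr(
      list(pinch, cold, heat),
      function(p, c_, h) {
        on <- c("pinch", "cold", "heat")[c(p, c_, h)]
        if (length(on) == 0) "none" else paste(on, collapse = "+")
      }))
}

# synthetic dF/F table for detection tests: one cell, flat baseline plus an
# injected peak
make_dff <- function(times, values, cell_id = 1L) {
  tibble::tibble(time_s = times, cell_id = cell_id, dff_pct = values)
}

# minimal window table
make_window <- function(onset, offset, post_lag = 10, trial_id = 1L,
                        modality = "heat", end_temp = 50) {
  tibble::tibble(
    trial_id = trial_id, label = paste0(modality, "_", end_temp),
    modality = modality,
    baseline_start_s = onset - 10, baseline_end_s = onset - 5,
    response_start_s = onset, response_end_s = offset + post_lag,
    end_temp = end_temp, baseline_temp = 32)
}
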