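# Stimulus-driven activity ("drive") of a tuned cell, prior to indicator
# convolution. Units: dF/F percent at steady state.

# Adaptation state s(t) for cold responses: resets to 1 while temperature is
# falling, decays exponentially (tau_adapt) while temperature is stable, and
# holds its value while temperature rises. Vectorised over the sample grid.
.adaptation_state <- function(temp, dt, tau_adapt, eps = 0.05) {
  n <- length(temp)
  if (n == 0) return(numeric(0))
  dTdt <- c(diff(temp) / dt, 0)
  falling <- dTdt < -eps
  stable <- abs(dTdt) <= eps
  # cumulative decay exponent over stable samples, exclusive of the current
  # sample: the state at the moment a hold begins is still 1
  inc <- ifelse(stable, dt / tau_adapt, 0)
  decay <- cumsum(inc) - inc
  # index of the most recent falling sample at or before each sample
  reset_idx <- cummax(ifelse(falling, seq_len(n), 0L))
  # before any fall the state is fully recovered (s = 1, no decay applied
  # from recording start); treat index 0 as decay reference 0
  ref <- ifelse(reset_idx == 0L, 0, decay[pmax(reset_idx, 1L)])
  s <- exp(-(decay - ref))
  # while rising, hold the value reached at the end of the last non-rising
  # stretch rather than recovering: s is already constant there because the
  # decay exponent does not advance on rising samples
  s
}

# priming multiplier per sample for heat drive: each sample is referred to
# the baseline (adaptation) temperature of the trial whose context it falls
# in; baselines below skin temperature (32 C) abolish heat responses, warmer
# baselines scale them up by 1 + priming_coef * (baseline - 32). Trial
# context covers the trial and its return ramp, switching to the next trial
# halfway through the inter-trial baseline hold.
.priming_multiplier <- function(time, trials, priming_coef) {
  m <- rep(1, length(time))
  if (nrow(trials) == 0) return(m)
  n <- nrow(trials)
  switch_t <- if (n > 1) {
    (trials$offset_s[-n] + trials$onset_s[-1]) / 2
  } else {
    numeric(0)
  }
  idx <- findInterval(time, switch_t) + 1L
  base <- trials$baseline_temp[idx]
  ifelse(base < 32, 0, 1 + priming_coef * (base - 32))
}

#' Compute a cell's stimulus-driven activity trace
#'
#' Applies the cell's tuning to a stimulus timeline and returns the
#' noiseless, indicator-free drive per sample (dF/F percent at steady state).
#'
#' Cold drive is `gain * max(0, cold_threshold - T(t)) * s(t)` where the
#' adaptation state `s` resets to 1 while temperature falls and decays
#' exponentially (time constant `tau_adapt`) while temperature is stable —
#' cold responses encode the absolute end temperature and decline during
#' maintained cold. Heat drive is `gain * max(0, T(t) - heat_threshold) * m`
#' with priming multiplier `m = 0` when the trial baseline is below 32 C
#' (responses abolished even for stimuli reaching 50 C) and
#' `1 + priming_coef * (baseline - 32)` otherwise; heat responses do not
#' adapt. Event drive adds `event_gain` during pinch/electrical events the
#' cell is sensitive to; brush never drives projection neurons.
#'
#' @param cell One-row tibble (or list) of cell tuning, as produced by
#'   [sample_population()].
#' @param timeline A `stim_timeline`.
#' @param stable_eps Rate below which temperature counts as stable, C/s.
#' @return Numeric vector, one drive value per timeline sample.
#' @export
compute_drive <- function(cell, timeline, stable_eps = 0.05) {
  stopifnot(inherits(timeline, "stim_timeline"))
  cell <- as.list(cell)
  temp <- timeline$data$temperature_c
  time <- timeline$data$time_s
  dt <- 1 / timeline$sampling_rate
  drive <- numeric(length(temp))
  if (isTRUE(cell$silent)) return(drive)

  if (isTRUE(cell$cold) && is.finite(cell$cold_threshold)) {
    s <- .adaptation_state(temp, dt, cell$tau_adapt, eps = stable_eps)
    drive <- drive + cell$gain * pmax(0, cell$cold_threshold - temp) * s
  }
  if (isTRUE(cell$heat) && is.finite(cell$heat_threshold)) {
    m <- .priming_multiplier(time, timeline$trials, cell$priming_coef)
    drive <- drive + cell$gain * pmax(0, temp - cell$heat_threshold) * m
  }
  if (nrow(timeline$events) > 0) {
    sensitive <- c(
      pinch = isTRUE(cell$pinch),
      brush = FALSE,
      electrical_supra = isTRUE(cell$electrical_c),
      electrical_abeta = isTRUE(cell$electrical_a),
      electrical_adelta = isTRUE(cell$electrical_a)
    )
    for (i in seq_len(nrow(timeline$events))) {
      lab <- timeline$events$label[i]
      if (isTRUE(sensitive[lab])) {
        on <- time >= timeline$events$onset_s[i] & time < timeline$events$offset_s[i]
        drive[on] <- drive[on] + cell$event_gain
      }
    }
  }
  drive
}
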