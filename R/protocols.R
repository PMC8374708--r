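#' @importFrom rlang .data
#' @importFrom stats approx sd rnorm runif qnorm pnorm cor
NULL

# Closed set of stimulation protocols. Thermal protocols are ramp-and-hold
# series delivered by a Peltier probe on the plantar hind paw; the rest are
# labelled non-thermal events (brush/pinch of the paw, sciatic-nerve cuff
# stimulation at three intensities).
.protocol_names <- c(
  "simple_heating", "rate_of_change_heating", "baseline_variable_heating",
  "end_temp_stable_heating",
  "simple_cooling", "rate_of_change_cooling", "baseline_variable_cooling",
  "end_temp_stable_cooling",
  "brush", "pinch",
  "electrical_abeta", "electrical_adelta", "electrical_supra"
)

#' Names of the available stimulation protocols
#'
#' Eight thermal ramp protocols plus mechanical (brush, pinch) and
#' electrical (A-beta, A-delta, suprathreshold) event protocols.
#'
#' @return Character vector of protocol names accepted by [build_protocol()].
#' @export
protocol_names <- function() .protocol_names

# trial tibble for a thermal protocol. `pre_baseline_s` is how long the
# baseline temperature is held before each ramp (90 s for fixed-baseline
# protocols, 120 s where the baseline itself is the variable).
.thermal_trials <- function(baseline, end, rate_on, rate_off, hold_s, pre_s) {
  n <- length(end)
  tibble::tibble(
    trial         = seq_len(n),
    baseline_temp = rep_len(baseline, n),
    end_temp      = end,
    rate_on       = rep_len(rate_on, n),
    rate_off      = rep_len(rate_off, n),
    hold_s        = rep_len(hold_s, n),
    pre_baseline_s = rep_len(pre_s, n)
  )
}

#' Build a stimulation protocol
#'
#' Returns the full parameterisation of one of the closed set of stimulation
#' protocols: per-trial baseline and end temperatures, on/off ramp rates and
#' hold durations for thermal protocols, or event timing for mechanical and
#' electrical protocols. Temperatures are degrees Celsius, rates degrees
#' Celsius per second, durations seconds. 32 degrees is used as standard skin
#' temperature throughout.
#'
#' The "rate of change" protocols hold the end temperature so that the total
#' on-stimulus time is the same for all three ramp speeds (equal to the
#' slowest ramp's duration); the "end temperature stable" protocols use
#' per-trial ramp rates that equalise ramp duration at 4 s across trials.
#'
#' @param name Protocol name; one of [protocol_names()].
#' @param hold_duration Hold at the end temperature for the simple ramp
#'   protocols, seconds (default 5; the long-hold variant uses 30).
#' @param event_duration Duration of brush/pinch/electrical events, seconds.
#' @param n_events Number of repeated events for event protocols.
#' @return An object of class `stim_protocol`: a list with `name`, `kind`
#'   ("thermal" or "event"), `baseline_temp`, and either a `trials` tibble
#'   (thermal) or an `events` tibble (event protocols).
#' @examples
#' build_protocol("simple_cooling")$trials
#' @export
build_protocol <- function(name, hold_duration = 5, event_duration = 5,
                           n_events = 3) {
  if (length(name) != 1L || !name %in% .protocol_names) {
    stop("unknown protocol '", paste(name, collapse = ","),
         "'; valid names are: ", paste(.protocol_names, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(hold_duration > 0, event_duration > 0, n_events >= 1)

  trials <- NULL
  events <- NULL
  baseline <- 32

  switch(name,
    simple_heating = {
      trials <- .thermal_trials(32, seq(34, 50, by = 2), 2, 4, hold_duration, 90)
    },
    simple_cooling = {
      # six decrements: 5 C steps down to 7 C, then a final 3 C step to 4 C
      trials <- .thermal_trials(32, c(27, 22, 17, 12, 7, 4), 2, 4, hold_duration, 90)
    },
    rate_of_change_heating = {
      rates <- c(0.2, 0.5, 2)
      ramp <- (50 - 32) / rates
      trials <- .thermal_trials(32, rep(50, 3), rates, 8, max(ramp) - ramp, 90)
    },
    rate_of_change_cooling = {
      rates <- c(0.2, 0.5, 2)
      ramp <- (32 - 10) / rates
      trials <- .thermal_trials(32, rep(10, 3), rates, 8, max(ramp) - ramp, 90)
    },
    baseline_variable_heating = {
      trials <- .thermal_trials(c(22, 27, 32, 34, 37),
                                c(35, 40, 45, 47, 50), 3.2, 8, 5, 120)
    },
    baseline_variable_cooling = {
      trials <- .thermal_trials(c(17, 22, 27, 32, 37, 42),
                                c(7, 12, 17, 22, 27, 32), 2.5, 8, 5, 120)
    },
    end_temp_stable_heating = {
      base <- c(22, 27, 32, 37, 42)
      # equalised ramp duration: largest step (28 C) at the fastest printed
      # rate (7 C/s) = 4 s; per-trial rate = step / 4 s (range 2-7 C/s)
      trials <- .thermal_trials(base, rep(50, 5), (50 - base) / 4, 8, 5, 120)
    },
    end_temp_stable_cooling = {
      base <- c(17, 22, 27, 32, 37, 42)
      trials <- .thermal_trials(base, rep(10, 6), (base - 10) / 4, 8, 5, 120)
    },
    {
      # event protocols: flat 32 C, repeated labelled events 90 s apart
      events <- tibble::tibble(
        trial    = seq_len(n_events),
        label    = name,
        duration = event_duration,
        pre_baseline_s = 90
      )
    }
  )

  structure(
    list(name = name, kind = if (is.null(events)) "thermal" else "event",
         baseline_temp = baseline, trials = trials, events = events),
    class = "stim_protocol"
  )
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat("<stim_protocol> ", x$name, " (", x$kind, ")\n", sep = "")
  print(if (x$kind == "thermal") x$trials else x$events)
  invisible(x)
}

# Piecewise-linear breakpoints (time, temp) for a thermal protocol plus the
# trial table in exact (un-gridded) seconds. The inter-trial baseline hold is
# placed before each trial; returns to baseline ramp toward the NEXT trial's
# baseline so the trace stays continuous when the baseline varies.
.protocol_breakpoints <- function(protocol, lead_in) {
  tr <- protocol$trials
  n <- nrow(tr)
  t <- 0
  temp0 <- if (n > 0) tr$baseline_temp[1] else protocol$baseline_temp
  bp_t <- c(0); bp_T <- c(temp0)
  add <- function(dt, temp) {
    t <<- t + dt
    bp_t <<- c(bp_t, t); bp_T <<- c(bp_T, temp)
  }
  onset <- offset <- numeric(n)
  add(lead_in, temp0)
  for (i in seq_len(n)) {
    if (i > 1) {
      # baseline hold before this trial (the first trial's is the lead-in)
      add(tr$pre_baseline_s[i], tr$baseline_temp[i])
    }
    onset[i] <- t
    ramp_on <- abs(tr$end_temp[i] - tr$baseline_temp[i]) / tr$rate_on[i]
    add(ramp_on, tr$end_temp[i])
    if (tr$hold_s[i] > 0) add(tr$hold_s[i], tr$end_temp[i])
    offset[i] <- t
    next_base <- if (i < n) tr$baseline_temp[i + 1] else tr$baseline_temp[i]
    ramp_off <- abs(tr$end_temp[i] - next_base) / tr$rate_off[i]
    if (ramp_off > 0) add(ramp_off, next_base)
    if (i == n) add(tr$pre_baseline_s[i], next_base)  # recovery tail
  }
  list(time = bp_t, temp = bp_T,
       trials = tibble::tibble(
         trial_id = seq_len(n), onset_s = onset, offset_s = offset,
         baseline_temp = tr$baseline_temp, end_temp = tr$end_temp,
         modality = ifelse(tr$end_temp >= tr$baseline_temp, "heat", "cold"),
         label = paste0(ifelse(tr$end_temp >= tr$baseline_temp, "heat_", "cold_"),
                        tr$end_temp)))
}

#' Render a protocol to a sampled stimulus timeline
#'
#' Samples the protocol's piecewise-linear temperature program onto a uniform
#' time grid and tabulates trial onsets/offsets. Event protocols render a flat
#' 32 degree trace with labelled event intervals. A lead-in period at the
#' first trial's baseline temperature precedes any stimulation and serves as
#' the global F0 baseline window.
#'
#' @param protocol A `stim_protocol` from [build_protocol()].
#' @param sampling_rate Frames per second (Hz). The acquisition range used in
#'   vivo was 0.5-4 Hz; other positive values are accepted with a warning.
#' @param lead_in Stimulus-free lead-in, seconds (>= 30).
#' @return An object of class `stim_timeline`: list with `data` (tibble
#'   `time_s`, `temperature_c`, `event_label`), `trials` (tibble `trial_id`,
#'   `onset_s`, `offset_s`, `baseline_temp`, `end_temp`, `modality`, `label`),
#'   `events`, `breakpoints` (the exact piecewise-linear corners),
#'   `sampling_rate`, `protocol_name`.
#' @examples
#' tl <- render_timeline(build_protocol("simple_heating"), sampling_rate = 4)
#' head(tl$data)
#' @export
render_timeline <- function(protocol, sampling_rate = 4, lead_in = 60) {
  stopifnot(inherits(protocol, "stim_protocol"))
  if (!(sampling_rate > 0)) stop("sampling_rate must be positive", call. = FALSE)
  if (sampling_rate < 0.5 || sampling_rate > 4) {
    warning("sampling_rate ", sampling_rate,
            " Hz is outside the 0.5-4 Hz acquisition range")
  }
  if (lead_in < 30) stop("lead_in must be >= 30 s (global F0 period)", call. = FALSE)
  dt <- 1 / sampling_rate

  if (protocol$kind == "thermal") {
    bp <- .protocol_breakpoints(protocol, lead_in)
    total <- max(bp$time)
    time <- seq(0, total, by = dt)
    temp <- approx(bp$time, bp$temp, xout = time, rule = 2)$y
    trials <- bp$trials
    breakpoints <- tibble::tibble(time_s = bp$time, temperature_c = bp$temp)
    events <- tibble::tibble(label = character(), onset_s = numeric(),
                             offset_s = numeric())
  } else {
    ev <- protocol$events
    onset <- lead_in + c(0, cumsum(ev$duration + ev$pre_baseline_s))[seq_len(nrow(ev))]
    offset <- onset + ev$duration
    total <- max(offset) + ev$pre_baseline_s[nrow(ev)]
    time <- seq(0, total, by = dt)
    temp <- rep(protocol$baseline_temp, length(time))
    trials <- tibble::tibble(
      trial_id = ev$trial, onset_s = onset, offset_s = offset,
      baseline_temp = protocol$baseline_temp, end_temp = protocol$baseline_temp,
      modality = ev$label, label = paste0(ev$label, "_", ev$trial))
    events <- tibble::tibble(label = ev$label, onset_s = onset, offset_s = offset)
    breakpoints <- tibble::tibble(time_s = c(0, total),
                                  temperature_c = rep(protocol$baseline_temp, 2))
  }

  lab <- rep(NA_character_, length(time))
  if (nrow(events) > 0) {
    for (i in seq_len(nrow(events))) {
      lab[time >= events$onset_s[i] & time < events$offset_s[i]] <- events$label[i]
    }
  }
  structure(
    list(data = tibble::tibble(time_s = time, temperature_c = temp,
                               event_label = lab),
         trials = trials, events = events, breakpoints = breakpoints,
         sampling_rate = sampling_rate, lead_in = lead_in,
         protocol_name = protocol$name),
    class = "stim_timeline"
  )
}

#' @export
print.stim_timeline <- function(x, ...) {
  cat("<stim_timeline> ", x$protocol_name, ": ",
      nrow(x$data), " samples at ", x$sampling_rate, " Hz (",
      round(max(x$data$time_s), 1), " s), ", nrow(x$trials), " trials\n", sep = "")
  print(x$trials)
  invisible(x)
}

#' Peristimulus analysis windows for a timeline
#'
#' For every trial (thermal step or labelled event) returns the per-stimulus
#' baseline window — the 5 s period starting 10 s before stimulus onset, used
#' to re-reference the response criterion so signal drift is not scored as a
#' response — and the response window from onset to offset plus `post_lag`,
#' truncated so it never reaches into the next trial's baseline window.
#'
#' @param timeline A `stim_timeline`.
#' @param post_lag Seconds after stimulus offset during which a response may
#'   still be counted (covers slow indicator decay). Default 10.
#' @return Tibble with columns `trial_id`, `label`, `modality`,
#'   `baseline_start_s`, `baseline_end_s`, `response_start_s`,
#'   `response_end_s`, `end_temp`, `baseline_temp`.
#' @export
stimulus_windows <- function(timeline, post_lag = 10) {
  stopifnot(inherits(timeline, "stim_timeline"))
  tr <- timeline$trials
  if (nrow(tr) == 0) return(tibble::tibble(
    trial_id = integer(), label = character(), modality = character(),
    baseline_start_s = numeric(), baseline_end_s = numeric(),
    response_start_s = numeric(), response_end_s = numeric(),
    end_temp = numeric(), baseline_temp = numeric()))
  if (any(tr$onset_s < 10)) {
    stop("trial onset before 10 s: insufficient baseline period", call. = FALSE)
  }
  next_baseline_start <- c(tr$onset_s[-1] - 10, Inf)
  tibble::tibble(
    trial_id = tr$trial_id, label = tr$label, modality = tr$modality,
    baseline_start_s = tr$onset_s - 10,
    baseline_end_s = tr$onset_s - 5,
    response_start_s = tr$onset_s,
    response_end_s = pmin(tr$offset_s + post_lag, next_baseline_start),
    end_temp = tr$end_temp, baseline_temp = tr$baseline_temp
  )
}

#' Serialise a protocol to YAML
#'
#' @param protocol A `stim_protocol`.
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_protocol_yaml <- function(protocol, path) {
  stopifnot(inherits(protocol, "stim_protocol"))
  x <- list(name = protocol$name, kind = protocol$kind,
            baseline_temp = protocol$baseline_temp)
  if (!is.null(protocol$trials)) x$trials <- lapply(
    seq_len(nrow(protocol$trials)), function(i) as.list(protocol$trials[i, ]))
  if (!is.null(protocol$events)) x$events <- lapply(
    seq_len(nrow(protocol$events)), function(i) as.list(protocol$events[i, ]))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a protocol from YAML
#'
#' @param path File written by [write_protocol_yaml()].
#' @return A `stim_protocol`.
#' @export
read_protocol_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  structure(
    list(name = x$name, kind = x$kind, baseline_temp = x$baseline_temp,
         trials = if (!is.null(x$trials)) dplyr::bind_rows(x$trials),
         events = if (!is.null(x$events)) dplyr::bind_rows(x$events)),
    class = "stim_protocol"
  )
}

#' Export a timeline's sampled trace to CSV
#'
#' Columns `time_s`, `temperature_c`, `event_label`.
#'
#' @param timeline A `stim_timeline`.
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_timeline_csv <- function(timeline, path) {
  stopifnot(inherits(timeline, "stim_timeline"))
  readr::write_csv(timeline$data, path)
  invisible(path)
}

#' Plot a stimulus timeline
#'
#' Temperature trace with stimulus intervals shaded and events marked.
#'
#' @param object A `stim_timeline`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot stim_timeline
#' @export
autoplot.stim_timeline <- function(object, ...) {
  p <- ggplot2::ggplot(object$data,
                       ggplot2::aes(x = .data$time_s, y = .data$temperature_c)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "time (s)", y = "temperature (°C)",
                  title = object$protocol_name)
  if (nrow(object$trials) > 0) {
    p <- p + ggplot2::geom_rect(
      data = object$trials, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$onset_s, xmax = .data$offset_s,
                   ymin = -Inf, ymax = Inf),
      alpha = 0.12, fill = "grey40")
  }
  p
}
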