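# Indicator kinetics and fluorescence rendering.

#' Indicator kinetics model
#'
#' Difference-of-exponentials impulse response emulating a slow genetically
#' encoded calcium indicator (GCaMP6s-like). The kernel is normalised to unit
#' peak; with `alpha = "auto"` the amplitude scale is set to
#' `1 / (100 * integral(k))` so that a sustained drive of x (dF/F percent)
#' produces a steady-state dF/F of x percent.
#'
#' @param tau_on Rise time constant, s.
#' @param tau_off Decay time constant, s (must exceed `tau_on`).
#' @param f_rest Resting fluorescence, a.u.
#' @param alpha Amplitude scale, or `"auto"`.
#' @return List of class `indicator_model`.
#' @export
indicator_model <- function(tau_on = 0.2, tau_off = 1.8, f_rest = 100,
                            alpha = "auto") {
  stopifnot(tau_on > 0, tau_off > tau_on, f_rest > 0)
  structure(list(tau_on = tau_on, tau_off = tau_off, f_rest = f_rest,
                 alpha = alpha), class = "indicator_model")
}

#' Noise model for rendered fluorescence
#'
#' @param sd Additive Gaussian noise SD per sample, a.u.
#' @param drift_amplitude,drift_period Slow sinusoidal drift, a.u. / s.
#' @param background Ambient background fluorescence level, a.u.
#' @return List of class `noise_model`.
#' @export
noise_model <- function(sd = 1.5, drift_amplitude = 0, drift_period = 300,
                        background = 20) {
  stopifnot(sd >= 0, drift_amplitude >= 0, drift_period > 0, background >= 0)
  structure(list(sd = sd, drift_amplitude = drift_amplitude,
                 drift_period = drift_period, background = background),
            class = "noise_model")
}

#' Sampled indicator impulse-response kernel
#'
#' `k(t) = exp(-t/tau_off) - exp(-t/tau_on)`, normalised to unit peak. The
#' analytic peak time is `tau_on*tau_off/(tau_off - tau_on) * log(tau_off/tau_on)`.
#'
#' @param indicator An [indicator_model()].
#' @param dt Sample interval, s.
#' @param duration Kernel support, s (default covers 8 decay constants).
#' @return Numeric vector of kernel samples.
#' @export
indicator_kernel <- function(indicator, dt, duration = 8 * indicator$tau_off) {
  t <- seq(0, duration, by = dt)
  k <- exp(-t / indicator$tau_off) - exp(-t / indicator$tau_on)
  k / max(k)
}

.kernel_alpha <- function(indicator, k, dt) {
  if (identical(indicator$alpha, "auto")) 1 / (100 * sum(k) * dt)
  else indicator$alpha
}

#' Render a fluorescence trace from an activity trace
#'
#' Convolves the drive with the indicator kernel and adds resting
#' fluorescence, background, optional drift and Gaussian noise:
#' `F(t) = background + drift(t) + f_rest * (1 + alpha * (k * a)(t)) + noise`.
#' Deterministic for a given seed.
#'
#' @param activity Non-negative drive trace (dF/F percent units).
#' @param dt Sample interval, s.
#' @param indicator An [indicator_model()].
#' @param noise A [noise_model()].
#' @param seed RNG seed for the noise draw (NULL = use current RNG state).
#' @return Numeric fluorescence trace, a.u.
#' @export
render_fluorescence <- function(activity, dt, indicator = indicator_model(),
                                noise = noise_model(), seed = NULL) {
  stopifnot(all(activity >= 0), dt > 0)
  n <- length(activity)
  k <- indicator_kernel(indicator, dt)
  alpha <- .kernel_alpha(indicator, k, dt)
  conv <- .causal_convolve(activity, k) * dt
  f <- indicator$f_rest * (1 + alpha * conv) + noise$background
  if (noise$drift_amplitude > 0) {
    t <- (seq_len(n) - 1) * dt
    f <- f + noise$drift_amplitude * sin(2 * pi * t / noise$drift_period)
  }
  if (noise$sd > 0) {
    if (!is.null(seed)) {
      old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
      set.seed(seed)
    }
    f <- f + rnorm(n, sd = noise$sd)
  }
  pmax(f, 0)
}

# causal discrete convolution, output length = length(x)
.causal_convolve <- function(x, k) {
  n <- length(x)
  out <- stats::convolve(c(x, numeric(length(k))), rev(k), type = "open")
  out[seq_len(n)]
}

#' Simulate a full trace set for a population on a timeline
#'
#' Computes each cell's drive, renders noisy fluorescence, and bundles the
#' result with a background trace, the timeline and the ground-truth tuning —
#' the synthetic stand-in for a registered in vivo time-lapse recording. The
#' postmortem count defaults to the full population size: after death all
#' labelled cells (including silent ones) accumulate calcium and become
#' visible, so the postmortem count is the denominator for percent-responding.
#'
#' @param population Tibble from [sample_population()].
#' @param timeline A `stim_timeline`.
#' @param indicator An [indicator_model()].
#' @param noise A [noise_model()].
#' @param seed Seed controlling all noise draws.
#' @param postmortem_count Total cells visible postmortem (>= non-silent cells).
#' @return Object of class `trace_set`: list with `time_s`, `f` (cells x
#'   samples matrix, a.u.), `background` (trace, a.u.), `population`,
#'   `timeline`, `postmortem_count`, `indicator`, `noise`.
#' @export
simulate_traces <- function(population, timeline,
                            indicator = indicator_model(),
                            noise = noise_model(), seed = 1L,
                            postmortem_count = nrow(population)) {
  stopifnot(inherits(timeline, "stim_timeline"))
  n_nonsilent <- sum(!population$silent)
  if (postmortem_count < n_nonsilent) {
    stop("postmortem_count must be >= number of non-silent cells", call. = FALSE)
  }
  dt <- 1 / timeline$sampling_rate
  n_t <- nrow(timeline$data)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)

  f <- matrix(0, nrow = nrow(population), ncol = n_t)
  for (i in seq_len(nrow(population))) {
    a <- compute_drive(population[i, ], timeline)
    f[i, ] <- render_fluorescence(a, dt, indicator, noise, seed = NULL)
  }
  rownames(f) <- population$cell_id
  background <- noise$background +
    if (noise$sd > 0) rnorm(n_t, sd = noise$sd) else numeric(n_t)

  structure(
    list(time_s = timeline$data$time_s, f = f, background = background,
         population = population, timeline = timeline,
         postmortem_count = postmortem_count,
         indicator = indicator, noise = noise, seed = seed),
    class = "trace_set"
  )
}

#' @export
print.trace_set <- function(x, ...) {
  cat("<trace_set> ", nrow(x$f), " cells x ", ncol(x$f), " samples (",
      x$timeline$protocol_name, "), postmortem count ", x$postmortem_count,
      "\n", sep = "")
  invisible(x)
}

#' Trace set as a tidy raw trace table
#'
#' Long tibble in the raw-trace-table layout used by the extraction stage:
#' one row per ROI per frame, with the background ROI flagged.
#'
#' @param x A `trace_set`.
#' @param ... Unused.
#' @return Tibble with `time_s`, `roi_id`, `fluorescence_au`, `is_background`.
#' @method tidy trace_set
#' @export
tidy.trace_set <- function(x, ...) {
  cells <- tibble::tibble(
    time_s = rep(x$time_s, times = nrow(x$f)),
    roi_id = rep(x$population$cell_id, each = length(x$time_s)),
    fluorescence_au = as.vector(t(x$f)),
    is_background = FALSE
  )
  bg <- tibble::tibble(
    time_s = x$time_s,
    roi_id = 0L,
    fluorescence_au = x$background,
    is_background = TRUE
  )
  dplyr::bind_rows(cells, bg)
}
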