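# Ground-truthed synthetic populations of lamina I projection neurons.

#' Default modality mixture
#'
#' Proportions of response-profile categories among recorded cells,
#' reconstructed from the published cohort of 139 cells: pinch+cold 41,
#' pinch+cold+heat 18, cold only 20, pinch only 8, heat only 2, pinch+heat 5,
#' cold+heat 6, non-responding 39. Under this mixture 61% of cells respond to
#' cooling, 82% of mechanosensitive cells also respond to cold, and cold-only
#' cells are 14% of all cells.
#'
#' @return Named numeric vector summing to 1.
#' @export
default_modality_mixture <- function() {
  c(pinch_cold = 41, pinch_cold_heat = 18, cold = 20, pinch = 8, heat = 2,
    pinch_heat = 5, cold_heat = 6, none = 39) / 139
}

#' Population configuration
#'
#' Bundles the generative parameters of a synthetic population: category
#' mixture, thermal-threshold distributions (truncated normals), response
#' gain, adaptation and priming constants, and event-response probabilities.
#'
#' @param n_cells Number of cells.
#' @param mixture Named vector of category proportions (must sum to 1); names
#'   from `default_modality_mixture()`. Cells in category `none` are silent.
#' @param cold_threshold_mean,cold_threshold_sd,cold_threshold_range Cold
#'   threshold distribution: mean 23, SD 5, truncated to \[10, 31\] degrees C.
#' @param heat_threshold_mean,heat_threshold_sd,heat_threshold_range Heat
#'   threshold distribution: mean 44, SD 4, truncated to \[40, 50\] degrees C.
#' @param gain Response gain, dF/F percent per degree C beyond threshold.
#' @param tau_adapt Adaptation time constant during stable temperatures, s.
#' @param priming_coef Gain increase per degree of baseline above 32 C for
#'   heat responses (per degree C).
#' @param event_gain dF/F percent amplitude of pinch/electrical event drive.
#' @param p_electrical_c,p_electrical_a Per-cell probabilities of responding
#'   to suprathreshold (C-fibre) and A-fibre strength sciatic stimulation.
#' @param seed RNG seed for [sample_population()].
#' @return A list of class `population_config`.
#' @export
population_config <- function(n_cells = 139,
                              mixture = default_modality_mixture(),
                              cold_threshold_mean = 23, cold_threshold_sd = 5,
                              cold_threshold_range = c(10, 31),
                              heat_threshold_mean = 44, heat_threshold_sd = 4,
                              heat_threshold_range = c(40, 50),
                              gain = 100, tau_adapt = 10, priming_coef = 0.05,
                              event_gain = 150,
                              p_electrical_c = 0.6, p_electrical_a = 0.04,
                              seed = 1L) {
  if (abs(sum(mixture) - 1) > 1e-8) {
    stop("mixture proportions must sum to 1", call. = FALSE)
  }
  if (is.null(names(mixture)) ||
      !all(names(mixture) %in% names(default_modality_mixture()))) {
    stop("mixture names must be a subset of: ",
         paste(names(default_modality_mixture()), collapse = ", "),
         call. = FALSE)
  }
  if (n_cells < 0) stop("n_cells must be >= 0", call. = FALSE)
  structure(as.list(environment()), class = "population_config")
}

# inverse-CDF sampler for a truncated normal
rtruncnorm <- function(n, mean, sd, lower, upper) {
  lo <- pnorm(lower, mean, sd)
  hi <- pnorm(upper, mean, sd)
  qnorm(lo + runif(n) * (hi - lo), mean, sd)
}

#' Sample a ground-truth population of tuned cells
#'
#' Draws per-cell response profiles (modality flags) from the category
#' mixture and thermal thresholds from the truncated-normal distributions in
#' the configuration. Deterministic for a given seed.
#'
#' @param config A [population_config()].
#' @return Tibble with one row per cell: `cell_id`, `category`, modality
#'   flags (`cold`, `heat`, `pinch`, `electrical_c`, `electrical_a`,
#'   `silent`), `cold_threshold`, `heat_threshold` (NA where the modality is
#'   absent), `gain`, `tau_adapt`, `priming_coef`, `event_gain`.
#' @examples
#' pop <- sample_population(population_config(n_cells = 20, seed = 7))
#' dplyr::count(pop, category)
#' @export
sample_population <- function(config = population_config()) {
  stopifnot(inherits(config, "population_config"))
  n <- config$n_cells
  if (n == 0) {
    return(tibble::tibble(
      cell_id = integer(), category = character(), cold = logical(),
      heat = logical(), pinch = logical(), electrical_c = logical(),
      electrical_a = logical(), silent = logical(),
      cold_threshold = numeric(), heat_threshold = numeric(),
      gain = numeric(), tau_adapt = numeric(), priming_coef = numeric(),
      event_gain = numeric()))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  cat_names <- names(config$mixture)
  category <- sample(cat_names, n, replace = TRUE, prob = config$mixture)
  cold <- grepl("cold", category)
  heat <- grepl("heat", category)
  pinch <- grepl("pinch", category)
  silent <- category == "none"
  # electrical sensitivity rides on top of natural-stimulus profiles; silent
  # cells stay silent for every stimulus
  electrical_c <- runif(n) < config$p_electrical_c & !silent
  electrical_a <- runif(n) < config$p_electrical_a & !silent

  cold_thr <- rep(NA_real_, n)
  heat_thr <- rep(NA_real_, n)
  cold_thr[cold] <- rtruncnorm(sum(cold), config$cold_threshold_mean,
                               config$cold_threshold_sd,
                               config$cold_threshold_range[1],
                               config$cold_threshold_range[2])
  heat_thr[heat] <- rtruncnorm(sum(heat), config$heat_threshold_mean,
                               config$heat_threshold_sd,
                               config$heat_threshold_range[1],
                               config$heat_threshold_range[2])

  tibble::tibble(
    cell_id = seq_len(n), category = category,
    cold = cold, heat = heat, pinch = pinch,
    electrical_c = electrical_c, electrical_a = electrical_a, silent = silent,
    cold_threshold = cold_thr, heat_threshold = heat_thr,
    gain = config$gain, tau_adapt = config$tau_adapt,
    priming_coef = config$priming_coef, event_gain = config$event_gain
  )
}

# save/restore global RNG state so seeded generators do not disturb the
# caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
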