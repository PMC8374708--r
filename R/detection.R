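# Per-stimulus responder criterion and thermal-threshold estimation.

#' Detect per-stimulus responses with the 70% + 4 SD criterion
#'
#' For every (cell, stimulus window) pair: the baseline mean `b` and sample
#' SD `sigma` of dF/F are computed over the window's 5 s baseline period (the
#' period starting 10 s before onset), and the cell is a responder iff the
#' maximum of `dF/F - b` over the response window reaches
#' `threshold_base + threshold_sd_mult * sigma` (defaults 70 and 4, all in
#' dF/F percent). Re-referencing each stimulus to its own baseline keeps slow
#' drift from being scored as a response. Ties at exactly threshold count as
#' responses.
#'
#' @param norm Normalised trace table (`time_s`, `cell_id`, `dff_pct`).
#' @param windows Window table from [stimulus_windows()].
#' @param threshold_base Additive criterion floor, dF/F percent.
#' @param threshold_sd_mult Multiplier on the baseline SD.
#' @return Tibble of response calls: `cell_id`, `trial_id`, `label`,
#'   `modality`, `end_temp`, `baseline_temp`, `responded`, `threshold_pct`,
#'   `peak_pct` (baseline-referenced), `t_cross_s` (first crossing, NA if
#'   none), `baseline_mean_pct`, `baseline_sd_pct`.
#' @export
detect_responses <- function(norm, windows, threshold_base = 70,
                             threshold_sd_mult = 4) {
  stopifnot(all(c("time_s", "cell_id", "dff_pct") %in% names(norm)),
            nrow(windows) > 0)
  t_max <- max(norm$time_s)
  t_min <- min(norm$time_s)
  if (any(windows$baseline_start_s < t_min) ||
      any(windows$response_start_s > t_max)) {
    stop("stimulus window outside the recording", call. = FALSE)
  }

  # wide matrix: cells x samples (times are a shared uniform grid)
  times <- sort(unique(norm$time_s))
  cells <- sort(unique(norm$cell_id))
  m <- matrix(NA_real_, nrow = length(cells), ncol = length(times),
              dimnames = list(cells, NULL))
  m[cbind(match(norm$cell_id, cells), match(norm$time_s, times))] <- norm$dff_pct

  purrr::map_dfr(seq_len(nrow(windows)), function(w) {
    bi <- which(times >= windows$baseline_start_s[w] &
                  times < windows$baseline_end_s[w])
    ri <- which(times >= windows$response_start_s[w] &
                  times < windows$response_end_s[w])
    if (length(bi) < 3) {
      stop("baseline window of trial ", windows$trial_id[w],
           " has fewer than 3 samples", call. = FALSE)
    }
    bmat <- m[, bi, drop = FALSE]
    b <- unname(rowMeans(bmat))
    sigma <- unname(apply(bmat, 1, sd))
    rel <- m[, ri, drop = FALSE] - b
    peak <- unname(apply(rel, 1, max))
    thr <- threshold_base + threshold_sd_mult * sigma
    responded <- peak >= thr
    t_cross <- vapply(seq_along(cells), function(i) {
      j <- which(rel[i, ] >= thr[i])[1]
      if (is.na(j)) NA_real_ else times[ri[j]]
    }, numeric(1))
    tibble::tibble(
      cell_id = cells, trial_id = windows$trial_id[w],
      label = windows$label[w], modality = windows$modality[w],
      end_temp = windows$end_temp[w], baseline_temp = windows$baseline_temp[w],
      responded = responded, threshold_pct = thr, peak_pct = peak,
      t_cross_s = t_cross, baseline_mean_pct = b, baseline_sd_pct = sigma
    )
  })
}

#' Estimate per-cell thermal thresholds from simple-ramp calls
#'
#' On the simple ramp series (fixed 32 C baseline, graded end temperatures)
#' the thermal threshold of a cell is read off the call table: for heating,
#' the lowest end temperature of any responded trial; for cooling, the
#' highest. Cells with no responded trial of a modality get NA.
#'
#' @param calls Call table from [detect_responses()] covering simple heating
#'   and/or cooling trials (modalities `heat`/`cold` with a common 32 C
#'   baseline; calls from variable-baseline protocols are refused since end
#'   temperature no longer orders stimulus strength there).
#' @return Tibble `cell_id`, `modality`, `threshold_c` (one row per cell per
#'   thermal modality present in `calls`).
#' @examples
#' calls <- tibble::tibble(cell_id = 1, trial_id = 1:9, modality = "heat",
#'                         baseline_temp = 32, end_temp = seq(34, 50, 2),
#'                         responded = seq(34, 50, 2) >= 46)
#' estimate_thermal_threshold(calls)
#' @export
estimate_thermal_threshold <- function(calls) {
  thermal <- dplyr::filter(calls, .data$modality %in% c("cold", "heat"))
  if (nrow(thermal) == 0) {
    stop("no thermal trials in calls", call. = FALSE)
  }
  if (any(thermal$baseline_temp != 32)) {
    stop("thermal thresholds are defined on the simple ramp protocols ",
         "(32 C baseline); got variable-baseline trials", call. = FALSE)
  }
  thermal |>
    dplyr::group_by(.data$cell_id, .data$modality) |>
    dplyr::summarise(
      threshold_c = {
        r <- .data$end_temp[.data$responded]
        if (length(r) == 0) NA_real_
        else if (.data$modality[1] == "heat") min(r) else max(r)
      },
      .groups = "drop"
    )
}

#' Population summary of thermal thresholds
#'
#' @param thresholds Output of [estimate_thermal_threshold()].
#' @return One row per modality: `modality`, `n` (cells with a threshold),
#'   `mean_c`, `sd_c`.
#' @export
threshold_summary <- function(thresholds) {
  thresholds |>
    dplyr::filter(!is.na(.data$threshold_c)) |>
    dplyr::group_by(.data$modality) |>
    dplyr::summarise(n = dplyr::n(), mean_c = mean(.data$threshold_c),
                     sd_c = sd(.data$threshold_c), .groups = "drop")
}
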