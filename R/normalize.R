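# Background subtraction and dF/F normalisation of raw ROI traces.

.check_raw_table <- function(raw) {
  need <- c("time_s", "roi_id", "fluorescence_au", "is_background")
  if (!all(need %in% names(raw))) {
    stop("raw trace table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!any(raw$is_background)) stop("no background ROI in table", call. = FALSE)
}

#' Subtract the background ROI trace from every cell trace
#'
#' Frame-wise subtraction of the background region's signal from each cell
#' ROI, removing ambient fluorescence before normalisation. Negative values
#' (background exceeding a cell trace) are preserved and reported via a
#' message.
#'
#' @param raw Raw trace table (`time_s`, `roi_id`, `fluorescence_au`,
#'   `is_background`), e.g. from [extract_roi_traces()] or [tidy.trace_set()].
#' @return Tibble of cell rows only, with `fluorescence_au` background-
#'   subtracted.
#' @export
subtract_background <- function(raw) {
  .check_raw_table(raw)
  bg <- raw |>
    dplyr::filter(.data$is_background) |>
    dplyr::group_by(.data$time_s) |>
    dplyr::summarise(bg_au = mean(.data$fluorescence_au), .groups = "drop")
  out <- raw |>
    dplyr::filter(!.data$is_background) |>
    dplyr::left_join(bg, by = "time_s") |>
    dplyr::mutate(fluorescence_au = .data$fluorescence_au - .data$bg_au) |>
    dplyr::select(-"bg_au")
  n_neg <- sum(out$fluorescence_au < 0)
  if (n_neg > 0) {
    message(n_neg, " background-subtracted samples are negative")
  }
  out
}

#' Normalise traces to dF/F percent
#'
#' `dF/F(t) = 100 * (F_t - F0) / F0`, with F0 the mean background-subtracted
#' fluorescence of each ROI over a stimulus-free baseline recording period at
#' the start of the session.
#'
#' @param raw Background-subtracted trace table (cell rows).
#' @param f0_window `c(start, end)` seconds of the global baseline period;
#'   must precede any stimulation.
#' @return Tibble `time_s`, `cell_id`, `dff_pct`, with the per-cell F0 table
#'   attached as attribute `"f0"`.
#' @examples
#' raw <- tibble::tibble(time_s = rep(0:9, 2), roi_id = rep(1:2, each = 10),
#'                       fluorescence_au = rep(c(50, 100), each = 10),
#'                       is_background = FALSE)
#' delta_f_over_f(raw, f0_window = c(0, 5))
#' @export
delta_f_over_f <- function(raw, f0_window = c(0, 30)) {
  if (!all(c("time_s", "roi_id", "fluorescence_au") %in% names(raw))) {
    stop("expected columns time_s, roi_id, fluorescence_au", call. = FALSE)
  }
  if (any(raw$is_background %||% FALSE)) {
    raw <- dplyr::filter(raw, !.data$is_background)
  }
  f0 <- raw |>
    dplyr::filter(.data$time_s >= f0_window[1], .data$time_s < f0_window[2]) |>
    dplyr::group_by(cell_id = .data$roi_id) |>
    dplyr::summarise(f0 = mean(.data$fluorescence_au), .groups = "drop")
  if (nrow(f0) == 0) stop("f0_window contains no samples", call. = FALSE)
  bad <- f0$cell_id[f0$f0 <= 0]
  if (length(bad) > 0) {
    stop("F0 <= 0 for cell(s) ", paste(bad, collapse = ", "),
         ": cannot normalise", call. = FALSE)
  }
  out <- raw |>
    dplyr::inner_join(f0, by = c(roi_id = "cell_id")) |>
    dplyr::transmute(time_s = .data$time_s, cell_id = .data$roi_id,
                     dff_pct = 100 * (.data$fluorescence_au - .data$f0) / .data$f0)
  attr(out, "f0") <- f0
  attr(out, "f0_window") <- f0_window
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ground-truth noiseless dF/F for a simulated trace set
#'
#' The generator-side counterpart of the extraction pipeline: the drive
#' convolved with the indicator kernel, scaled exactly as rendered, with no
#' noise. Used to validate that extract -> subtract -> normalise recovers the
#' generated signal.
#'
#' @param traceset A `trace_set`.
#' @return Tibble `time_s`, `cell_id`, `dff_pct`.
#' @export
truth_dff <- function(traceset) {
  stopifnot(inherits(traceset, "trace_set"))
  dt <- 1 / traceset$timeline$sampling_rate
  k <- indicator_kernel(traceset$indicator, dt)
  alpha <- .kernel_alpha(traceset$indicator, k, dt)
  purrr::map_dfr(seq_len(nrow(traceset$population)), function(i) {
    a <- compute_drive(traceset$population[i, ], traceset$timeline)
    tibble::tibble(
      time_s = traceset$time_s,
      cell_id = traceset$population$cell_id[i],
      dff_pct = 100 * alpha * .causal_convolve(a, k) * dt
    )
  })
}
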