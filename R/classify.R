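# Modality classification, postmortem-normalised percentages, polymodality
# tables and correlation-sorted heatmap summaries.

.modality_order <- c("pinch", "cold", "heat")

#' Classify each cell's modality profile from its calls
#'
#' A cell carries a modality (pinch, cold, heat) if it responded to at least
#' one trial of that modality; the label is the combination, or `none`.
#' Electrical and brush calls do not enter the label (the closed label set
#' covers the natural-stimulus profile).
#'
#' @param calls Call table from [detect_responses()], possibly pooled across
#'   protocols/recordings for the same cells.
#' @return Tibble `cell_id`, `pinch`, `cold`, `heat` (logicals), `label`
#'   (one of none, pinch, cold, heat, pinch+cold, pinch+heat, cold+heat,
#'   pinch+cold+heat).
#' @export
classify_modality <- function(calls) {
  calls |>
    dplyr::filter(.data$modality %in% .modality_order) |>
    dplyr::group_by(.data$cell_id, .data$modality) |>
    dplyr::summarise(responded = any(.data$responded), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "modality", values_from = "responded",
                       values_fill = FALSE) |>
    (\(d) {
      for (mm in .modality_order) if (!mm %in% names(d)) d[[mm]] <- FALSE
      d
    })() |>
    dplyr::mutate(
      label = purrr::pmap_chr(
        list(.data$pinch, .data$cold, .data$heat),
        function(p, c_, h) {
          on <- .modality_order[c(p, c_, h)]
          if (length(on) == 0) "none" else paste(on, collapse = "+")
        })
    ) |>
    dplyr::select("cell_id", dplyr::all_of(.modality_order), "label") |>
    dplyr::arrange(.data$cell_id)
}

#' Percentage of cells responding, normalised to the postmortem count
#'
#' Because all labelled cells brighten postmortem, the postmortem count is
#' the denominator for percent-responding: cells silent throughout the
#' session still count in the population. Computed per animal and per
#' stimulus modality, with the cross-animal mean and SEM.
#'
#' @param calls Call table; an `animal` column groups recordings (a single
#'   animal is assumed if absent).
#' @param postmortem_counts Either a single count or a tibble
#'   `animal`, `postmortem_count`.
#' @return List with `per_animal` (tibble `animal`, `modality`,
#'   `n_responding`, `postmortem_count`, `percent`) and `summary` (tibble
#'   `modality`, `mean_percent`, `sem_percent`, `n_animals`).
#' @export
percent_responding <- function(calls, postmortem_counts) {
  if (!"animal" %in% names(calls)) calls$animal <- 1L
  if (!is.data.frame(postmortem_counts)) {
    postmortem_counts <- tibble::tibble(
      animal = unique(calls$animal), postmortem_count = postmortem_counts)
  }
  if (any(postmortem_counts$postmortem_count <= 0)) {
    stop("postmortem count must be positive", call. = FALSE)
  }
  n_cells <- calls |>
    dplyr::distinct(.data$animal, .data$cell_id) |>
    dplyr::count(.data$animal, name = "n_recorded")
  chk <- dplyr::inner_join(n_cells, postmortem_counts, by = "animal")
  if (any(chk$postmortem_count < chk$n_recorded)) {
    stop("postmortem count smaller than the number of recorded cells",
         call. = FALSE)
  }
  per_animal <- calls |>
    dplyr::group_by(.data$animal, .data$modality, .data$cell_id) |>
    dplyr::summarise(responded = any(.data$responded), .groups = "drop") |>
    dplyr::group_by(.data$animal, .data$modality) |>
    dplyr::summarise(n_responding = sum(.data$responded), .groups = "drop") |>
    dplyr::inner_join(postmortem_counts, by = "animal") |>
    dplyr::mutate(percent = 100 * .data$n_responding / .data$postmortem_count)
  summary <- per_animal |>
    dplyr::group_by(.data$modality) |>
    dplyr::summarise(
      mean_percent = mean(.data$percent),
      sem_percent = sd(.data$percent) / sqrt(dplyr::n()),
      n_animals = dplyr::n(), .groups = "drop")
  list(per_animal = per_animal, summary = summary)
}

#' Polymodality tables from modality labels
#'
#' Cross-tabulates the modality profile of the population the way the
#' headline statistics are reported: category counts and shares, the
#' unimodal/polymodal breakdown, and conditional overlap percentages
#' ("x% of A-responsive cells also respond to B", computed as
#' `100 * |A and B| / |A|` and rounded to integer percent for display;
#' full precision is kept alongside).
#'
#' @param labels Label table from [classify_modality()].
#' @return List of class `polymodality_table`: `categories` (per-label count,
#'   percent of all cells, percent of responsive cells), `unimodal` (count
#'   and percent unimodal overall plus each modality's share of unimodal
#'   cells), `pairwise` (conditional overlaps, including the share of
#'   mechanosensitive cells polymodal for both thermal modalities), and
#'   `n_cells`/`n_responsive`.
#' @export
polymodality_table <- function(labels) {
  n <- nrow(labels)
  n_resp <- sum(labels$label != "none")
  categories <- labels |>
    dplyr::count(.data$label, name = "n") |>
    dplyr::mutate(
      percent_all = round(100 * .data$n / !!n),
      percent_all_exact = 100 * .data$n / !!n,
      percent_responsive = round(100 * .data$n / !!n_resp),
      percent_responsive_exact = 100 * .data$n / !!n_resp)

  uni <- labels$label %in% .modality_order
  n_uni <- sum(uni)
  uni_n <- c(n_uni, vapply(.modality_order,
                           function(mm) sum(labels$label == mm), integer(1)))
  uni_den <- c(n, rep(n_uni, 3))
  unimodal <- tibble::tibble(
    modality = c("any", .modality_order),
    n = uni_n,
    denominator = uni_den,
    percent = ifelse(uni_den > 0, round(100 * uni_n / uni_den), 0),
    percent_exact = ifelse(uni_den > 0, 100 * uni_n / uni_den, 0)
  )

  sets <- list(pinch = labels$pinch, cold = labels$cold, heat = labels$heat)
  pairs <- tidyr::expand_grid(a = .modality_order, b = .modality_order) |>
    dplyr::filter(.data$a != .data$b)
  pairwise <- purrr::pmap_dfr(pairs, function(a, b) {
    na <- sum(sets[[a]])
    nab <- sum(sets[[a]] & sets[[b]])
    tibble::tibble(modality_a = a, modality_b = b, n_a = na, n_both = nab,
                   percent = ifelse(na > 0, round(100 * nab / na), 0),
                   percent_exact = ifelse(na > 0, 100 * nab / na, 0))
  })
  n_pinch <- sum(sets$pinch)
  n_triple <- sum(sets$pinch & sets$cold & sets$heat)
  pairwise <- dplyr::bind_rows(pairwise, tibble::tibble(
    modality_a = "pinch", modality_b = "cold+heat",
    n_a = n_pinch, n_both = n_triple,
    percent = ifelse(n_pinch > 0, round(100 * n_triple / n_pinch), 0),
    percent_exact = ifelse(n_pinch > 0, 100 * n_triple / n_pinch, 0)))

  structure(list(categories = categories, unimodal = unimodal,
                 pairwise = pairwise, n_cells = n, n_responsive = n_resp),
            class = "polymodality_table")
}

#' @export
print.polymodality_table <- function(x, ...) {
  cat("<polymodality_table> ", x$n_cells, " cells (", x$n_responsive,
      " responsive)\n\ncategories:\n", sep = "")
  print(x$categories)
  cat("\npairwise overlap:\n")
  print(x$pairwise)
  invisible(x)
}

#' @method tidy polymodality_table
#' @export
tidy.polymodality_table <- function(x, ...) {
  dplyr::bind_rows(
    x$categories |>
      dplyr::transmute(statistic = paste0("category_", .data$label),
                       n = .data$n, percent = .data$percent_all_exact),
    x$pairwise |>
      dplyr::transmute(statistic = paste0(.data$modality_a, "_also_",
                                          .data$modality_b),
                       n = .data$n_both, percent = .data$percent_exact)
  )
}

#' @method glance polymodality_table
#' @export
glance.polymodality_table <- function(x, ...) {
  tibble::tibble(
    n_cells = x$n_cells, n_responsive = x$n_responsive,
    n_unimodal = x$unimodal$n[x$unimodal$modality == "any"],
    percent_polymodal_of_responsive =
      100 * (x$n_responsive - x$unimodal$n[x$unimodal$modality == "any"]) /
      max(x$n_responsive, 1L))
}

#' Correlation-sorted heatmap order, z-scored traces and mean +/- SEM
#'
#' Rows (cells) are ordered by descending absolute Pearson correlation of
#' their dF/F trace with the temperature profile; constant traces get |r| = 0
#' and sort last (ties broken by cell id). Each cell's trace is z-scored
#' (mean subtracted, divided by SD) for heatmap display, and the mean +/- SEM
#' across a responding subset is computed per sample (SEM over cells).
#'
#' @param norm Normalised trace table (`time_s`, `cell_id`, `dff_pct`).
#' @param temperature Tibble `time_s`, `temperature_c` on the same grid (e.g.
#'   `timeline$data`), or a numeric vector matching the time grid.
#' @param subset Cell ids for the mean trace (default: all cells).
#' @return List of class `trace_summary`: `order` (tibble `cell_id`,
#'   `abs_r`, `rank`), `zscores` (long tibble `cell_id`, `time_s`, `z`),
#'   `mean_trace` (tibble `time_s`, `mean_dff`, `sem_dff`, `n_cells`).
#' @export
summarize_traces <- function(norm, temperature, subset = NULL) {
  times <- sort(unique(norm$time_s))
  if (is.data.frame(temperature)) {
    temp <- temperature$temperature_c[match(times, temperature$time_s)]
  } else {
    temp <- temperature
  }
  if (length(temp) != length(times) || anyNA(temp)) {
    stop("temperature profile does not share the trace time grid", call. = FALSE)
  }
  wide <- norm |>
    dplyr::arrange(.data$cell_id, .data$time_s) |>
    tidyr::pivot_wider(names_from = "time_s", values_from = "dff_pct") |>
    dplyr::arrange(.data$cell_id)
  ids <- wide$cell_id
  m <- as.matrix(wide[, -1])

  sds <- apply(m, 1, sd)
  abs_r <- vapply(seq_along(ids), function(i) {
    if (sds[i] == 0) 0 else abs(cor(m[i, ], temp))
  }, numeric(1))
  ord <- order(-abs_r, ids)
  order_tbl <- tibble::tibble(cell_id = ids[ord], abs_r = abs_r[ord],
                              rank = seq_along(ord))

  z <- (m - rowMeans(m)) / ifelse(sds == 0, 1, sds)
  zscores <- tibble::tibble(
    cell_id = rep(ids, times = ncol(z)),
    time_s = rep(times, each = nrow(z)),
    z = as.vector(z))

  keep <- if (is.null(subset)) rep(TRUE, length(ids)) else ids %in% subset
  ms <- m[keep, , drop = FALSE]
  mean_trace <- tibble::tibble(
    time_s = times,
    mean_dff = colMeans(ms),
    sem_dff = apply(ms, 2, sd) / sqrt(nrow(ms)),
    n_cells = nrow(ms))

  structure(list(order = order_tbl, zscores = zscores,
                 mean_trace = mean_trace, temperature = temp),
            class = "trace_summary")
}

#' @export
print.trace_summary <- function(x, ...) {
  cat("<trace_summary> ", nrow(x$order), " cells, ",
      nrow(x$mean_trace), " samples; top |r| = ",
      round(x$order$abs_r[1], 3), "\n", sep = "")
  invisible(x)
}

#' Heatmap of z-scored traces in correlation-sorted order
#'
#' @param object A `trace_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot trace_summary
#' @export
autoplot.trace_summary <- function(object, ...) {
  df <- object$zscores |>
    dplyr::inner_join(object$order, by = "cell_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = -.data$rank,
                                   fill = .data$z)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick") +
    ggplot2::labs(x = "time (s)", y = "cell (sorted by |r| with ramp)",
                  fill = "z")
}

#' Mean +/- SEM trace plot for a responding subset
#'
#' @param summary A `trace_summary`.
#' @return A ggplot.
#' @export
plot_mean_trace <- function(summary) {
  stopifnot(inherits(summary, "trace_summary"))
  ggplot2::ggplot(summary$mean_trace, ggplot2::aes(x = .data$time_s)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_dff - .data$sem_dff,
                                      ymax = .data$mean_dff + .data$sem_dff),
                         fill = "grey70") +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_dff), colour = "darkgreen") +
    ggplot2::labs(x = "time (s)", y = expression(Delta * "F/F (%)"))
}
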