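# Orchestration: simulate -> extract -> normalise -> detect -> classify ->
# report, as one seeded, configured, reproducible run.

#' Run configuration for the full pipeline
#'
#' Every parameter of a pipeline run in one serialisable object; all defaults
#' match the analysis conventions used throughout the package (4 Hz sampling,
#' 60 s lead-in, 70% + 4 SD criterion, 10 s post-stimulus lag, postmortem
#' denominator).
#'
#' @param protocols Character vector of protocol names to simulate
#'   (each rendered and recorded as a separate session of the same cells).
#' @param population A [population_config()].
#' @param indicator An [indicator_model()].
#' @param noise A [noise_model()].
#' @param sampling_rate Hz.
#' @param lead_in Seconds of stimulus-free baseline before stimulation.
#' @param f0_window Global F0 window, seconds.
#' @param post_lag Seconds after stimulus offset counted in the response
#'   window.
#' @param threshold_base,threshold_sd_mult Responder criterion constants.
#' @param use_postmortem_count Logical flag: use the postmortem cell count as
#'   the percent-responding denominator (the recorded-cell count otherwise).
#'   Must be set explicitly `TRUE`/`FALSE`.
#' @param seed Master seed for the run.
#' @param out_dir Output directory (NULL = no files written).
#' @return List of class `run_config`.
#' @export
run_config <- function(protocols = c("simple_heating", "simple_cooling", "pinch"),
                       population = population_config(),
                       indicator = indicator_model(),
                       noise = noise_model(),
                       sampling_rate = 4, lead_in = 60,
                       f0_window = c(0, 30), post_lag = 10,
                       threshold_base = 70, threshold_sd_mult = 4,
                       use_postmortem_count = TRUE,
                       seed = 1L, out_dir = NULL) {
  cfg <- as.list(environment())
  required <- c("protocols", "population", "indicator", "noise",
                "sampling_rate", "lead_in", "f0_window", "post_lag",
                "threshold_base", "threshold_sd_mult", "use_postmortem_count",
                "seed")
  for (f in required) {
    if (is.null(cfg[[f]]) || (f != "out_dir" && length(cfg[[f]]) == 0)) {
      stop("run_config field '", f, "' is missing", call. = FALSE)
    }
  }
  if (!is.logical(cfg$use_postmortem_count) || is.na(cfg$use_postmortem_count)) {
    stop("run_config field 'use_postmortem_count' must be TRUE or FALSE",
         call. = FALSE)
  }
  bad <- setdiff(cfg$protocols, protocol_names())
  if (length(bad) > 0) {
    stop("unknown protocol(s) in config: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

.validate_config <- function(cfg) {
  required <- c("protocols", "population", "indicator", "noise",
                "sampling_rate", "lead_in", "f0_window", "post_lag",
                "threshold_base", "threshold_sd_mult", "use_postmortem_count",
                "seed")
  for (f in required) {
    if (is.null(cfg[[f]])) {
      stop("run_config field '", f, "' is missing", call. = FALSE)
    }
  }
  invisible(cfg)
}

#' Execute the full simulate-to-report pipeline
#'
#' Samples a ground-truth population once, then for each configured protocol
#' renders the stimulus timeline, simulates a recording of the same cells,
#' normalises the traces, and applies the responder criterion. Calls are
#' pooled across protocols into modality labels, polymodality tables,
#' postmortem-normalised response percentages, thermal-threshold estimates
#' (simple ramps only) and correlation-sorted trace summaries. When
#' `out_dir` is set, all stage outputs are written (CSV per table, JSON
#' report, YAML manifest with the config snapshot, seed and package version)
#' and the run is bit-for-bit reproducible from the manifest.
#'
#' @param config A [run_config()].
#' @return Object of class `l1_report`: list with `population`, `calls`,
#'   `labels`, `polymodality`, `percent_responding`, `thresholds`,
#'   `threshold_summary`, `trace_summaries` (per thermal protocol),
#'   `config`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  .validate_config(config)
  population <- sample_population(config$population)
  per_protocol_seed <- config$seed + seq_along(config$protocols)

  calls <- list()
  dff_tables <- list()
  trace_summaries <- list()
  for (i in seq_along(config$protocols)) {
    pn <- config$protocols[i]
    timeline <- render_timeline(build_protocol(pn),
                                sampling_rate = config$sampling_rate,
                                lead_in = config$lead_in)
    ts <- simulate_traces(population, timeline,
                          indicator = config$indicator, noise = config$noise,
                          seed = per_protocol_seed[i])
    raw <- tidy.trace_set(ts)
    dff <- raw |> subtract_background() |> delta_f_over_f(config$f0_window)
    windows <- stimulus_windows(timeline, post_lag = config$post_lag)
    calls[[pn]] <- detect_responses(dff, windows,
                                    threshold_base = config$threshold_base,
                                    threshold_sd_mult = config$threshold_sd_mult) |>
      dplyr::mutate(protocol = pn)
    dff_tables[[pn]] <- dff
    if (build_protocol(pn)$kind == "thermal") {
      responders <- unique(calls[[pn]]$cell_id[calls[[pn]]$responded])
      trace_summaries[[pn]] <- summarize_traces(
        dff, timeline$data,
        subset = if (length(responders) > 0) responders else NULL)
    }
  }
  calls <- dplyr::bind_rows(calls)

  labels <- classify_modality(calls)
  poly <- polymodality_table(labels)
  # all labelled cells brighten postmortem, so the postmortem count is the
  # whole population; without it only cells active during the session (the
  # non-silent ones) are visible and countable
  if (config$use_postmortem_count) {
    pct <- percent_responding(calls, nrow(population))
  } else {
    active <- population$cell_id[!population$silent]
    pct <- percent_responding(dplyr::filter(calls, .data$cell_id %in% active),
                              max(length(active), 1L))
  }

  simple <- calls |>
    dplyr::filter(.data$protocol %in% c("simple_heating", "simple_cooling"))
  thresholds <- if (nrow(simple) > 0) estimate_thermal_threshold(simple) else NULL
  thr_summary <- if (!is.null(thresholds)) threshold_summary(thresholds) else NULL

  report <- structure(
    list(population = population, calls = calls, labels = labels,
         polymodality = poly, percent_responding = pct,
         thresholds = thresholds, threshold_summary = thr_summary,
         trace_summaries = trace_summaries, config = config),
    class = "l1_report")

  if (!is.null(config$out_dir)) {
    .write_report(report, dff_tables, config)
  }
  report
}

.config_snapshot <- function(config) {
  list(
    protocols = config$protocols,
    population = lapply(unclass(config$population), function(x)
      if (is.numeric(x)) as.numeric(x) else x),
    indicator = unclass(config$indicator),
    noise = unclass(config$noise),
    sampling_rate = config$sampling_rate, lead_in = config$lead_in,
    f0_window = config$f0_window, post_lag = config$post_lag,
    threshold_base = config$threshold_base,
    threshold_sd_mult = config$threshold_sd_mult,
    use_postmortem_count = config$use_postmortem_count,
    seed = config$seed)
}

.write_report <- function(report, dff_tables, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(config$out_dir, ...)
  readr::write_csv(report$calls, p("calls.csv"))
  readr::write_csv(report$labels, p("modality_labels.csv"))
  readr::write_csv(report$population, p("truth_population.csv"))
  for (pn in names(dff_tables)) {
    readr::write_csv(dff_tables[[pn]], p(paste0("dff_", pn, ".csv")))
  }
  if (!is.null(report$thresholds)) {
    readr::write_csv(report$thresholds, p("thresholds.csv"))
  }
  tables <- list(
    percent_responding = report$percent_responding$summary,
    percent_responding_per_animal = report$percent_responding$per_animal,
    polymodality_categories = report$polymodality$categories,
    polymodality_pairwise = report$polymodality$pairwise,
    polymodality_unimodal = report$polymodality$unimodal,
    threshold_summary = report$threshold_summary,
    heatmap_order = lapply(report$trace_summaries, function(s) s$order))
  jsonlite::write_json(tables, p("report.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  manifest <- list(
    package = "l1resp",
    version = as.character(utils::packageVersion("l1resp")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = .config_snapshot(config))
  yaml::write_yaml(manifest, p("manifest.yaml"))
  invisible(NULL)
}

#' @export
print.l1_report <- function(x, ...) {
  cat("<l1_report> ", nrow(x$population), " cells, protocols: ",
      paste(x$config$protocols, collapse = ", "), "\n\n", sep = "")
  cat("percent responding (postmortem-normalised):\n")
  print(x$percent_responding$summary)
  if (!is.null(x$threshold_summary)) {
    cat("\nthermal thresholds:\n")
    print(x$threshold_summary)
  }
  cat("\nmodality categories:\n")
  print(x$polymodality$categories)
  invisible(x)
}

#' One-row overview of a pipeline run
#'
#' @param x An `l1_report`.
#' @param ... Unused.
#' @return Tibble with cell counts, percent cold/heat/pinch responders and
#'   recovered threshold means.
#' @method glance l1_report
#' @export
glance.l1_report <- function(x, ...) {
  g <- function(mod, col) {
    v <- x$percent_responding$summary
    out <- v[[col]][v$modality == mod]
    if (length(out) == 0) NA_real_ else out
  }
  thr <- function(mod) {
    if (is.null(x$threshold_summary)) return(NA_real_)
    v <- x$threshold_summary$mean_c[x$threshold_summary$modality == mod]
    if (length(v) == 0) NA_real_ else v
  }
  tibble::tibble(
    n_cells = nrow(x$population),
    n_responsive = x$polymodality$n_responsive,
    pct_cold = g("cold", "mean_percent"),
    pct_heat = g("heat", "mean_percent"),
    pct_pinch = g("pinch", "mean_percent"),
    mean_cold_threshold_c = thr("cold"),
    mean_heat_threshold_c = thr("heat"))
}

#' Ground-truth agreement of classified modality labels
#'
#' Compares classified pinch/cold/heat flags against the generator's tuning
#' for the non-silent cells of a simulated run.
#'
#' @param report An `l1_report` from [run_pipeline()].
#' @return List with `agreement` (fraction of non-silent cells whose full
#'   label matches the ground truth) and `per_cell` comparison tibble.
#' @export
classification_agreement <- function(report) {
  stopifnot(inherits(report, "l1_report"))
  truth <- report$population |>
    dplyr::transmute(
      cell_id = .data$cell_id, silent = .data$silent,
      truth_label = purrr::pmap_chr(
        list(.data$pinch, .data$cold, .data$heat),
        function(p, c_, h) {
          on <- .modality_order[c(p, c_, h)]
          if (length(on) == 0) "none" else paste(on, collapse = "+")
        }))
  per_cell <- dplyr::inner_join(truth, report$labels, by = "cell_id") |>
    dplyr::mutate(match = .data$truth_label == .data$label)
  nonsilent <- dplyr::filter(per_cell, !.data$silent)
  list(agreement = mean(nonsilent$match), per_cell = per_cell)
}
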