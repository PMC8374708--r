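# Rendering trace sets as image stacks and extracting ROI traces back out.
# Stacks are plain numeric arrays (height x width x frames) in memory; TIFF
# read/write goes through the tiff package.

# lay cells out on a grid with at least 2*radius+gap spacing
.cell_layout <- function(n_cells, image_shape, radius) {
  h <- image_shape[1]; w <- image_shape[2]
  pitch <- 2 * radius + 4
  # reserve the last column strip for the background ROI
  cols <- max(1, floor((w - pitch) / pitch))
  rows <- max(1, floor(h / pitch))
  if (n_cells > rows * cols) {
    stop("cells do not fit inside image bounds without overlap", call. = FALSE)
  }
  idx <- seq_len(n_cells) - 1L
  tibble::tibble(
    cell_id = seq_len(n_cells),
    y = (idx %% rows) * pitch + pitch / 2,
    x = (idx %/% rows) * pitch + pitch / 2
  )
}

#' Render a trace set as a synthetic image stack
#'
#' Draws each cell as a Gaussian blob whose mean intensity over its ROI
#' equals the cell's fluorescence trace value, on top of the uniform
#' background trace, emulating a registered time-lapse recording
#' (default frame size 256 x 512). Also returns an ROI label mask (one label
#' per cell plus one background label in a cell-free region) and a postmortem
#' frame in which every cell — including silent ones — is rendered bright, as
#' dying cells accumulate calcium.
#'
#' @param traceset A `trace_set` from [simulate_traces()].
#' @param image_shape `c(height, width)` in pixels.
#' @param radius ROI radius in pixels.
#' @param blob_sigma Gaussian profile SD in pixels.
#' @param postmortem_level Fluorescence of every cell in the postmortem
#'   frame, a.u.
#' @param pixel_noise_sd Additional per-pixel Gaussian noise, a.u.
#' @return List of class `synthetic_dataset`: `stack` (h x w x frames array),
#'   `mask` (integer h x w matrix; 0 outside ROIs, 1..n cells, n+1
#'   background), `postmortem_frame` (h x w matrix), `layout`, `truth`
#'   (tuning tibble), `time_s`, `background_label`.
#' @export
render_dataset <- function(traceset, image_shape = c(256, 512), radius = 4,
                           blob_sigma = 2, postmortem_level = 400,
                           pixel_noise_sd = 0) {
  stopifnot(inherits(traceset, "trace_set"))
  n_cells <- nrow(traceset$f)
  n_t <- ncol(traceset$f)
  h <- image_shape[1]; w <- image_shape[2]
  layout <- .cell_layout(n_cells, image_shape, radius)

  mask <- matrix(0L, h, w)
  # per-cell ROI pixel indices and normalised blob weights (mean over ROI = 1)
  roi_pix <- vector("list", n_cells)
  roi_w <- vector("list", n_cells)
  yy <- row(mask); xx <- col(mask)
  for (i in seq_len(n_cells)) {
    d2 <- (yy - layout$y[i])^2 + (xx - layout$x[i])^2
    pix <- which(d2 <= radius^2)
    if (any(mask[pix] != 0L)) stop("overlapping ROIs", call. = FALSE)
    mask[pix] <- i
    wgt <- exp(-d2[pix] / (2 * blob_sigma^2))
    roi_pix[[i]] <- pix
    roi_w[[i]] <- wgt / mean(wgt)
  }
  bg_label <- n_cells + 1L
  # background ROI: right-hand strip kept free of cells
  bg_pix <- which(xx > w - radius * 2 & yy <= radius * 4 & mask == 0L)
  if (length(bg_pix) == 0) stop("no room for a background ROI", call. = FALSE)
  mask[bg_pix] <- bg_label

  stack <- array(0, dim = c(h, w, n_t))
  for (t in seq_len(n_t)) {
    frame <- matrix(traceset$background[t], h, w)
    for (i in seq_len(n_cells)) {
      # blob on top of background so that ROI mean equals the trace value
      frame[roi_pix[[i]]] <- traceset$background[t] +
        roi_w[[i]] * (traceset$f[i, t] - traceset$background[t])
    }
    if (pixel_noise_sd > 0) frame <- frame + rnorm(h * w, sd = pixel_noise_sd)
    stack[, , t] <- pmax(frame, 0)
  }

  pm <- matrix(mean(traceset$background), h, w)
  for (i in seq_len(n_cells)) {
    pm[roi_pix[[i]]] <- mean(traceset$background) +
      roi_w[[i]] * (postmortem_level - mean(traceset$background))
  }

  structure(
    list(stack = stack, mask = mask, postmortem_frame = pm,
         layout = layout, truth = traceset$population,
         time_s = traceset$time_s, background_label = bg_label),
    class = "synthetic_dataset"
  )
}

#' Extract per-ROI mean-intensity traces from an image stack
#'
#' Averages pixel intensity under each ROI label for every frame — the
#' hand-drawn-ROI measurement step of the analysis, applied to a label mask.
#'
#' @param stack Numeric array, height x width x frames.
#' @param mask Integer label matrix matching the frame shape; 0 = unassigned.
#' @param background_label Label of the background ROI.
#' @param time_s Optional frame times (defaults to frame index - 1).
#' @return Raw trace table: tibble with `time_s`, `roi_id`,
#'   `fluorescence_au`, `is_background` (one row per ROI per frame).
#' @export
extract_roi_traces <- function(stack, mask, background_label, time_s = NULL) {
  stopifnot(length(dim(stack)) == 3)
  if (!all(dim(stack)[1:2] == dim(mask))) {
    stop("mask and frames must share the same shape", call. = FALSE)
  }
  labels <- sort(unique(as.vector(mask)))
  labels <- labels[labels != 0]
  if (!background_label %in% labels) {
    stop("background label ", background_label, " absent from mask", call. = FALSE)
  }
  if (length(labels) < 2) stop("need at least one cell ROI", call. = FALSE)
  n_t <- dim(stack)[3]
  if (is.null(time_s)) time_s <- seq_len(n_t) - 1
  flat <- matrix(stack, nrow = prod(dim(mask)), ncol = n_t)
  purrr::map_dfr(labels, function(lab) {
    pix <- which(mask == lab)
    if (length(pix) == 0) stop("empty ROI for label ", lab, call. = FALSE)
    tibble::tibble(
      time_s = time_s,
      roi_id = as.integer(lab),
      fluorescence_au = colMeans(flat[pix, , drop = FALSE]),
      is_background = lab == background_label
    )
  })
}

#' Write a synthetic dataset to TIFF files
#'
#' Writes the stack as a multi-page 16-bit TIFF, the ROI mask as a 16-bit
#' label TIFF and the postmortem frame as a single 16-bit page, plus the
#' truth table as CSV. Intensities are scaled by `scale` into the 16-bit
#' range.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @param scale a.u. per 16-bit full scale.
#' @return Invisibly, the paths written.
#' @export
write_dataset_tiff <- function(dataset, dir, scale = 1000) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required to write TIFF files", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  clamp <- function(x) pmin(pmax(x / scale, 0), 1)
  frames <- lapply(seq_len(dim(dataset$stack)[3]),
                   function(t) clamp(dataset$stack[, , t]))
  p_stack <- file.path(dir, "stack.tif")
  tiff::writeTIFF(frames, p_stack, bits.per.sample = 16)
  p_mask <- file.path(dir, "roi_mask.tif")
  tiff::writeTIFF(dataset$mask / 65535, p_mask, bits.per.sample = 16)
  p_pm <- file.path(dir, "postmortem.tif")
  tiff::writeTIFF(clamp(dataset$postmortem_frame), p_pm, bits.per.sample = 16)
  p_truth <- file.path(dir, "truth_tuning.csv")
  readr::write_csv(dataset$truth, p_truth)
  invisible(c(stack = p_stack, mask = p_mask, postmortem = p_pm,
              truth = p_truth))
}

#' Read a TIFF stack and ROI label mask
#'
#' Counterpart of [write_dataset_tiff()]; returns numeric arrays on the
#' original intensity scale.
#'
#' @param stack_path Multi-page TIFF of frames.
#' @param mask_path 16-bit label TIFF.
#' @param scale a.u. per 16-bit full scale used at write time.
#' @return List with `stack` (h x w x frames) and `mask` (integer matrix).
#' @export
read_dataset_tiff <- function(stack_path, mask_path, scale = 1000) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required to read TIFF files", call. = FALSE)
  }
  frames <- tiff::readTIFF(stack_path, all = TRUE)
  stack <- array(0, dim = c(dim(frames[[1]]), length(frames)))
  for (t in seq_along(frames)) stack[, , t] <- frames[[t]] * scale
  mask <- round(tiff::readTIFF(mask_path) * 65535)
  storage.mode(mask) <- "integer"
  list(stack = stack, mask = mask)
}
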