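# Per-cell intensity quantification and control-derived threshold calibration.

#' Measure per-cell channel intensities with background subtraction
#'
#' For every labelled cell and every channel, the raw mean over the label
#' footprint is recorded together with a background-subtracted mean.
#' Background is the median intensity of pixels at least
#' \code{bg_exclusion_px} away from any cell (robust to dim debris);
#' subtracted means are floored at 0.
#'
#' @param image an \code{\link{mcimage}}.
#' @param labels a \code{\link{labelmap}} of the same frame.
#' @param bg_exclusion_px exclusion ring width around cells (pixels).
#' @return a cell-records data frame: \code{cell_id}, \code{centroid_row},
#'   \code{centroid_col}, \code{area_px}, \code{area_um2}, then per channel
#'   \code{<chan>_raw}, \code{<chan>_bg} (background-subtracted, floored at
#'   0) and \code{<chan>_bg_signed} (not floored — used when calibrating
#'   thresholds from control populations, where flooring would shrink the
#'   control sd and bias mean+k*sd rules low), plus \code{class_label}
#'   (\code{"UNSET"}), \code{puncta_count} (NA) and \code{region}
#'   (\code{"NONE"}).
#' @export
measure_cell_intensities <- function(image, labels, bg_exclusion_px = 5) {
  stopifnot(inherits(image, "mcimage"), inherits(labels, "labelmap"))
  if (!all(dim(image) == dim(labels$labels))) {
    stop("label map shape does not match the image")
  }
  props <- label_properties(labels, image$pixel_size)
  rec <- data.frame(cell_id = props$cell_id,
                    centroid_row = props$centroid_row,
                    centroid_col = props$centroid_col,
                    area_px = props$area_px, area_um2 = props$area_um2)
  lab <- labels$labels
  fg <- lab > 0
  if (any(fg)) {
    brush <- EBImage::makeBrush(2L * as.integer(bg_exclusion_px) + 1L, "disc")
    excl <- as.matrix(EBImage::imageData(
      EBImage::dilate(matrix(as.numeric(fg), nrow(fg)), brush))) > 0
  } else {
    excl <- fg
  }
  bgpix <- !excl
  idx <- which(fg)
  l <- lab[idx]
  f <- factor(l, levels = props$cell_id)
  for (ch in names(image$channels)) {
    m <- image$channels[[ch]]
    bg <- if (any(bgpix)) stats::median(m[bgpix]) else 0
    if (nrow(rec) > 0) {
      raw <- as.numeric(tapply(m[idx], f, mean))
      rec[[paste0(ch, "_raw")]] <- raw
      rec[[paste0(ch, "_bg")]] <- pmax(raw - bg, 0)
      rec[[paste0(ch, "_bg_signed")]] <- raw - bg
    } else {
      rec[[paste0(ch, "_raw")]] <- numeric(0)
      rec[[paste0(ch, "_bg")]] <- numeric(0)
      rec[[paste0(ch, "_bg_signed")]] <- numeric(0)
    }
  }
  rec$class_label <- rep("UNSET", nrow(rec))
  rec$puncta_count <- rep(NA_integer_, nrow(rec))
  rec$region <- rep("NONE", nrow(rec))
  rec
}

#' Calibrate a positivity threshold from a control population
#'
#' Two rules are supported, both anchored to a named control population
#' (non-transduced cells for the eGFP gate; secondary-antibody-only staining
#' for the HA background gate):
#' \itemize{
#'   \item \code{PERCENTILE_OF_CONTROL}: the empirical percentile (linear
#'     interpolation) of the control intensities; \code{param} in (50, 100].
#'   \item \code{MEAN_PLUS_K_SD}: control mean + \code{param} x control sd;
#'     \code{param} > 0.
#' }
#'
#' @param control_values numeric vector of per-cell control intensities (ADU).
#' @param rule \code{"PERCENTILE_OF_CONTROL"} or \code{"MEAN_PLUS_K_SD"}.
#' @param param percentile (in (50, 100]) or k (> 0).
#' @param channel channel name the threshold applies to.
#' @param control_description free-text provenance of the control population.
#' @param min_control_cells floor below which the entry is flagged
#'   low-confidence (default 20).
#' @return one-row data frame (a ThresholdSet entry): \code{channel},
#'   \code{threshold}, \code{rule}, \code{param}, \code{n_control_cells},
#'   \code{control_description}, \code{low_confidence}, \code{flagged}.
#' @export
calibrate_threshold <- function(control_values,
                                rule = c("PERCENTILE_OF_CONTROL", "MEAN_PLUS_K_SD"),
                                param = 99,
                                channel = NA_character_,
                                control_description = "",
                                min_control_cells = 20L) {
  rule <- match.arg(rule)
  if (length(control_values) < 1) stop("control population is empty")
  if (any(!is.finite(control_values))) stop("control values must be finite")
  flagged <- FALSE
  if (rule == "PERCENTILE_OF_CONTROL") {
    if (param <= 50 || param > 100) stop("percentile must be in (50, 100]")
    thr <- as.numeric(stats::quantile(control_values, param / 100, type = 7))
  } else {
    if (param <= 0) stop("k must be > 0")
    s <- stats::sd(control_values)
    if (length(control_values) == 1L || is.na(s)) s <- 0
    if (s == 0) flagged <- TRUE  # degenerate control distribution
    thr <- mean(control_values) + param * s
  }
  data.frame(channel = channel, threshold = thr, rule = rule, param = param,
             n_control_cells = length(control_values),
             control_description = control_description,
             low_confidence = length(control_values) < min_control_cells,
             flagged = flagged, stringsAsFactors = FALSE)
}

#' Assemble a threshold set
#' @param ... one-row entries from \code{\link{calibrate_threshold}}.
#' @return data frame with one row per channel.
#' @export
threshold_set <- function(...) {
  ts <- do.call(rbind, list(...))
  if (anyDuplicated(ts$channel)) stop("duplicate channel in threshold set")
  ts
}

get_threshold <- function(thresholds, channel) {
  i <- match(channel, thresholds$channel)
  if (is.na(i)) {
    stop(sprintf("threshold set has no entry for channel '%s'", channel))
  }
  thresholds$threshold[i]
}

#' Flow-style scramblase index: median FITC of mCherry-gated events
#'
#' The mCherry-positive gate is placed at a percentile of non-expressing
#' control events; the index is the median (configurable to mean) FITC of
#' gated events, optionally normalized to the same index computed on a
#' control condition (so a control condition normalized to itself is 1).
#'
#' @param events data frame with columns \code{mCherry}, \code{FITC}.
#' @param gate_control events from a non-expressing control used to place
#'   the mCherry gate.
#' @param norm_control optional condition to normalize the index to.
#' @param gate_percentile percentile of control mCherry for the gate.
#' @param stat \code{"median"} (default) or \code{"mean"}.
#' @return scalar index.
#' @export
flow_gate_index <- function(events, gate_control, norm_control = NULL,
                            gate_percentile = 99, stat = c("median", "mean")) {
  stat <- match.arg(stat)
  for (tb in list(events, gate_control)) {
    if (!is.data.frame(tb) || nrow(tb) == 0 ||
        !all(c("mCherry", "FITC") %in% names(tb))) {
      stop("event tables must be non-empty with columns mCherry and FITC")
    }
  }
  gate <- as.numeric(stats::quantile(gate_control$mCherry,
                                     gate_percentile / 100, type = 7))
  gated <- events$FITC[events$mCherry > gate]
  if (length(gated) == 0) {
    stop(sprintf("mCherry gate at %.4g ADU (percentile %g of control) captures zero events",
                 gate, gate_percentile))
  }
  fun <- if (stat == "median") stats::median else mean
  idx <- fun(gated)
  if (!is.null(norm_control)) {
    ref <- flow_gate_index(norm_control, gate_control, NULL,
                           gate_percentile, stat)
    idx <- idx / ref
  }
  idx
}
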