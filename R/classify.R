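# Donor / recipient / untransduced gating, puncta scoring, annexin index.
#
# Gating logic (strict inequality at thresholds; a cell exactly at threshold
# is negative):
#   in vitro  (over morphology-gated cells): eGFP+ & HA+ -> DONOR;
#     eGFP- & HA+ -> RECIPIENT; eGFP- & HA- -> UNTRANSDUCED;
#     eGFP+ & HA- -> AMBIGUOUS (biologically unexpected under P2A
#     co-expression; excluded from all denominators, counted and reported).
#   in vivo (triple reporter): cells failing the mCherry gate are UNSET
#     (outside the knockdown-reporting population); among mCherry+ cells the
#     in-vitro table applies, so RECIPIENT = mCherry+ & eGFP- & HA+.

#' Gate cultured cells into donor/recipient/untransduced classes
#'
#' @param records cell-records data frame from
#'   \code{\link{measure_cell_intensities}} (background-subtracted means).
#' @param thresholds threshold set containing entries for the eGFP and HA
#'   channels (see \code{\link{calibrate_threshold}}).
#' @param egfp_channel,ha_channel channel names.
#' @return \code{records} with \code{class_label} filled in.
#' @export
classify_in_vitro <- function(records, thresholds,
                              egfp_channel = "eGFP", ha_channel = "HA") {
  thr_e <- get_threshold(thresholds, egfp_channel)
  thr_h <- get_threshold(thresholds, ha_channel)
  ge <- records[[paste0(egfp_channel, "_bg")]]
  ha <- records[[paste0(ha_channel, "_bg")]]
  if (is.null(ge) || is.null(ha)) {
    stop("records lack background-subtracted intensities for the gating channels")
  }
  ep <- ge > thr_e
  hp <- ha > thr_h
  records$class_label <- ifelse(ep & hp, "DONOR",
                         ifelse(!ep & hp, "RECIPIENT",
                         ifelse(!ep & !hp, "UNTRANSDUCED", "AMBIGUOUS")))
  records
}

#' Gate brain-section cells (triple reporter)
#'
#' @param records cell-records data frame.
#' @param thresholds threshold set with mCherry, eGFP and HA entries.
#' @param mcherry_channel,egfp_channel,ha_channel channel names.
#' @return \code{records} with \code{class_label} filled in (mCherry-negative
#'   cells stay \code{"UNSET"}).
#' @export
classify_in_vivo <- function(records, thresholds,
                             mcherry_channel = "mCherry",
                             egfp_channel = "eGFP", ha_channel = "HA") {
  thr_m <- get_threshold(thresholds, mcherry_channel)
  out <- classify_in_vitro(records, thresholds, egfp_channel, ha_channel)
  mc <- records[[paste0(mcherry_channel, "_bg")]]
  if (is.null(mc)) stop("records lack mCherry intensities")
  out$class_label[!(mc > thr_m)] <- "UNSET"
  out
}

#' Detect aggregation puncta within segmented cells
#'
#' A white top-hat (disc radius \code{tophat_radius}) suppresses the smooth
#' soma signal; within each cell footprint, puncta are connected components
#' of top-hat intensity exceeding the cell's top-hat median + \code{k_sigma}
#' robust sd (1.4826 x MAD — the mean/sd pair would be inflated by the very
#' puncta being detected) with area >= \code{min_puncta_area}. A cell is
#' aggregate-positive when it carries at least \code{min_puncta_per_cell}
#' puncta.
#'
#' @param image an \code{\link{mcimage}}.
#' @param channel channel carrying the aggregate stain (HA or proteostat).
#' @param labels a \code{\link{labelmap}}.
#' @param records optional cell-records data frame to fill
#'   \code{puncta_count} into; defaults to fresh records.
#' @param tophat_radius top-hat structuring-element radius (px).
#' @param k_sigma threshold stringency in within-cell sd units.
#' @param min_puncta_area minimum punctum area (px^2).
#' @param min_puncta_per_cell puncta needed to call a cell positive.
#' @return list: \code{records} (with \code{puncta_count} and logical
#'   \code{puncta_positive}), \code{percent_positive} (percentage of cells
#'   aggregate-positive).
#' @export
detect_puncta <- function(image, channel = "HA", labels, records = NULL,
                          tophat_radius = 3L, k_sigma = 3,
                          min_puncta_area = 4, min_puncta_per_cell = 2L) {
  stopifnot(inherits(image, "mcimage"), inherits(labels, "labelmap"))
  img <- get_channel(image, channel)
  if (is.null(records)) records <- measure_cell_intensities(image, labels)
  if (nrow(records) == 0) {
    return(list(records = records, percent_positive = NA_real_))
  }
  props <- label_properties(labels)
  med_r <- sqrt(stats::median(props$area_px) / pi)
  if (tophat_radius >= med_r) {
    warning("tophat_radius is not smaller than the typical soma radius; puncta may be erased")
  }
  brush <- EBImage::makeBrush(2L * as.integer(tophat_radius) + 1L, "disc")
  th <- as.matrix(EBImage::imageData(EBImage::whiteTopHat(img, brush)))
  lab <- labels$labels
  counts <- integer(nrow(records))
  for (i in seq_len(nrow(records))) {
    id <- records$cell_id[i]
    sel <- lab == id
    vals <- th[sel]
    cut <- stats::median(vals) + k_sigma * 1.4826 * stats::mad(vals, constant = 1)
    if (!is.finite(cut)) cut <- stats::median(vals)
    hot <- matrix(0, nrow(th), ncol(th))
    hot[sel] <- as.numeric(th[sel] > cut)
    cc <- as.matrix(EBImage::imageData(EBImage::bwlabel(hot)))
    if (max(cc) > 0) {
      areas <- tabulate(cc[cc > 0])
      counts[i] <- sum(areas >= min_puncta_area)
    }
  }
  records$puncta_count <- counts
  records$puncta_positive <- counts >= min_puncta_per_cell
  list(records = records,
       percent_positive = 100 * mean(records$puncta_positive))
}

#' Annexin-V imaging index for a field
#'
#' Ratio of total background-subtracted FITC to total background-subtracted
#' morphology (NFH) signal over all cell footprints — the per-field readout
#' of surface phosphatidylserine exposure. Normalize across conditions with
#' \code{\link{normalize_to_control}}.
#'
#' @param image an \code{\link{mcimage}}.
#' @param fitc_channel,morphology_channel channel names.
#' @param labels a \code{\link{labelmap}}.
#' @param bg_exclusion_px background exclusion ring (px), as in
#'   \code{\link{measure_cell_intensities}}.
#' @return scalar index for the field.
#' @export
annexin_imaging_index <- function(image, fitc_channel = "FITC",
                                  morphology_channel = "NFH", labels,
                                  bg_exclusion_px = 5) {
  stopifnot(inherits(image, "mcimage"), inherits(labels, "labelmap"))
  fitc <- get_channel(image, fitc_channel)
  nfh <- get_channel(image, morphology_channel)
  lab <- labels$labels
  fg <- lab > 0
  if (!any(fg)) stop("no cell footprints in the label map")
  brush <- EBImage::makeBrush(2L * as.integer(bg_exclusion_px) + 1L, "disc")
  excl <- as.matrix(EBImage::imageData(
    EBImage::dilate(matrix(as.numeric(fg), nrow(fg)), brush))) > 0
  bgpix <- !excl
  bg_f <- if (any(bgpix)) stats::median(fitc[bgpix]) else 0
  bg_n <- if (any(bgpix)) stats::median(nfh[bgpix]) else 0
  denom <- sum(pmax(nfh[fg] - bg_n, 0))
  if (denom <= 0) stop("no morphology signal above background in cell footprints")
  sum(pmax(fitc[fg] - bg_f, 0)) / denom
}
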