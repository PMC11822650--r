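# Pipeline orchestration: config validation, stage sequencing, result bundle.
#
# One entry point, run_pipeline(config, mode), drives segment -> measure ->
# calibrate -> classify -> metrics for the chosen assay mode and writes
# re-readable outputs (CSV cell records, JSON thresholds/metrics, run log).
# A YAML file maps onto the same config structure via pipeline_config().

#' Build / validate a pipeline configuration
#'
#' @param image path to the assay image (TIFF with sidecar JSON).
#' @param control_image path to the control image used for threshold
#'   calibration (non-transduced / secondary-only population).
#' @param out_dir output directory for the result bundle.
#' @param channels named character vector mapping roles to channel names;
#'   roles used: \code{morphology}, \code{egfp}, \code{ha}, \code{mcherry},
#'   \code{fitc} (whichever the mode needs).
#' @param mask optional path to a manual label-mask TIFF (skips segmentation).
#' @param region_cortical_fraction for IN_VIVO: horizontal cortical split
#'   fraction (see \code{\link{region_layout}}).
#' @param params list of stage parameters overriding the defaults of
#'   \code{\link{segment_somata}}, \code{\link{calibrate_threshold}},
#'   \code{\link{detect_puncta}}, \code{\link{measure_neurites}}.
#' @param condition condition label for reporting.
#' @param seed integer seed recorded in the run log.
#' @return a list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(image, control_image = NULL, out_dir,
                            channels = c(morphology = "NFH", egfp = "eGFP",
                                         ha = "HA"),
                            mask = NULL, region_cortical_fraction = 0.4,
                            params = list(), condition = "condition",
                            seed = 1L) {
  cfg <- list(image = image, control_image = control_image, out_dir = out_dir,
              channels = channels, mask = mask,
              region_cortical_fraction = region_cortical_fraction,
              params = params, condition = condition, seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with the fields of \code{\link{pipeline_config}}.
#' @return a \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, c(
    y[setdiff(names(y), "channels")],
    list(channels = unlist(y$channels))
  ))
}

default_params <- function() {
  list(window = 51L, offset = 10, min_area = 50, max_area = Inf,
       split_touching = FALSE, bg_exclusion_px = 5,
       egfp_rule = "PERCENTILE_OF_CONTROL", egfp_param = 99,
       ha_rule = "MEAN_PLUS_K_SD", ha_param = 3,
       mcherry_rule = "SEGMENTATION_GATE", mcherry_param = 99,
       tophat_radius = 3L, k_sigma = 3, min_puncta_area = 4,
       min_puncta_per_cell = 2L)
}

validate_pipeline_config <- function(config, mode) {
  stopifnot(inherits(config, "pipeline_config"))
  need <- switch(mode,
                 IN_VITRO = c("morphology", "egfp", "ha"),
                 IN_VIVO = c("mcherry", "egfp", "ha"),
                 PUNCTA = c("morphology", "ha"),
                 ANNEXIN = c("morphology", "fitc"),
                 MORPHOMETRY = "morphology")
  missing_roles <- setdiff(need, names(config$channels))
  if (length(missing_roles) > 0) {
    stop(sprintf("config lacks channel mapping for role(s): %s (mode %s)",
                 paste(missing_roles, collapse = ", "), mode), call. = FALSE)
  }
  if (mode %in% c("IN_VITRO", "IN_VIVO") && is.null(config$control_image)) {
    stop("modes IN_VITRO/IN_VIVO need a control_image for threshold calibration",
         call. = FALSE)
  }
  for (f in c(config$image, config$control_image, config$mask)) {
    if (!is.null(f) && !file.exists(f)) stop("input file not found: ", f,
                                             call. = FALSE)
  }
  invisible(TRUE)
}

segment_or_import <- function(image, config, prm, morph) {
  if (!is.null(config$mask)) {
    mp <- import_label_mask(config$mask)
    if (!all(dim(mp$labels) == dim(image))) {
      stop("manual mask shape does not match the image")
    }
    mp
  } else {
    segment_somata(image, morph, window = prm$window, offset = prm$offset,
                   min_area = prm$min_area, max_area = prm$max_area,
                   split_touching = prm$split_touching)
  }
}

# hash of the analysis-defining configuration (the output location does not
# change what is computed, so it is excluded)
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, force = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the quantification pipeline
#'
#' Executes segment -> measure -> calibrate -> classify -> metrics for the
#' chosen mode and writes the result bundle to \code{config$out_dir}:
#' \code{cell_records.csv}, \code{thresholds.json} (gating modes),
#' \code{metrics.json}, \code{labels.tif}, and \code{run_log.json} (seed,
#' package version, config hash). Identical config + seed give identical
#' tables.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param mode one of \code{"IN_VITRO"}, \code{"IN_VIVO"}, \code{"PUNCTA"},
#'   \code{"ANNEXIN"}, \code{"MORPHOMETRY"}.
#' @return list with the in-memory results (records, thresholds, metrics,
#'   paths), invisibly.
#' @export
run_pipeline <- function(config, mode = c("IN_VITRO", "IN_VIVO", "PUNCTA",
                                          "ANNEXIN", "MORPHOMETRY")) {
  mode <- match.arg(mode)
  validate_pipeline_config(config, mode)
  prm <- utils::modifyList(default_params(), config$params)
  ch <- config$channels
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s | %s] %s", name, config$image,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  image <- stage("read", read_mcimage(config$image))
  morph <- if ("morphology" %in% names(ch)) ch[["morphology"]] else ch[["mcherry"]]
  labels <- stage("segment", segment_or_import(image, config, prm, morph))
  records <- stage("measure",
                   measure_cell_intensities(image, labels,
                                            bg_exclusion_px = prm$bg_exclusion_px))
  thresholds <- NULL
  metrics <- NULL
  if (mode %in% c("IN_VITRO", "IN_VIVO")) {
    ctl_img <- stage("read-control", read_mcimage(config$control_image))
    ctl_lab <- stage("segment-control",
                     segment_or_import(ctl_img,
                                       utils::modifyList(config, list(mask = NULL)),
                                       prm, morph))
    ctl_rec <- stage("measure-control",
                     measure_cell_intensities(ctl_img, ctl_lab,
                                              bg_exclusion_px = prm$bg_exclusion_px))
    thr <- list(
      calibrate_threshold(ctl_rec[[paste0(ch[["egfp"]], "_bg_signed")]],
                          rule = prm$egfp_rule, param = prm$egfp_param,
                          channel = ch[["egfp"]],
                          control_description = "non-transduced control cells"),
      calibrate_threshold(ctl_rec[[paste0(ch[["ha"]], "_bg_signed")]],
                          rule = prm$ha_rule, param = prm$ha_param,
                          channel = ch[["ha"]],
                          control_description = "secondary-antibody-only control")
    )
    if (mode == "IN_VIVO") {
      # brain sections carry no separate morphology stain: somata are
      # detected on the mCherry channel itself, so detection already gates
      # mCherry+; the threshold entry records that provenance (threshold 0,
      # any detected cell with reporter signal above background passes).
      # a percentile/k rule on a reporter-negative control remains available
      # through params$mcherry_rule.
      mc_entry <- if (prm$mcherry_rule == "SEGMENTATION_GATE") {
        data.frame(channel = ch[["mcherry"]], threshold = 0,
                   rule = "SEGMENTATION_GATE", param = NA_real_,
                   n_control_cells = NA_integer_,
                   control_description = "somata detected on the reporter channel",
                   low_confidence = FALSE, flagged = FALSE,
                   stringsAsFactors = FALSE)
      } else {
        calibrate_threshold(ctl_rec[[paste0(ch[["mcherry"]], "_bg_signed")]],
                            rule = prm$mcherry_rule, param = prm$mcherry_param,
                            channel = ch[["mcherry"]],
                            control_description = "reporter-negative control")
      }
      thr <- c(thr, list(mc_entry))
    }
    thresholds <- do.call(threshold_set, thr)
    records <- stage("classify",
                     if (mode == "IN_VITRO") {
                       classify_in_vitro(records, thresholds,
                                         egfp_channel = ch[["egfp"]],
                                         ha_channel = ch[["ha"]])
                     } else {
                       classify_in_vivo(records, thresholds,
                                        mcherry_channel = ch[["mcherry"]],
                                        egfp_channel = ch[["egfp"]],
                                        ha_channel = ch[["ha"]])
                     })
    metrics <- stage("metrics",
                     compute_spread_metrics(records, config$condition))
    if (mode == "IN_VIVO") {
      lay <- region_layout(config$region_cortical_fraction, "full")
      rmask <- build_region_mask(lay, dim(image), image$pixel_size)
      rg <- stage("regions", count_recipients_by_region(records, rmask))
      metrics <- cbind(metrics, rg$counts,
                       section_area_mm2 = rg$section_area_mm2)
      records$region <- c("NONE", "CORTICAL", "SUBCORTICAL")[
        rmask$regions[cbind(round(records$centroid_row),
                            round(records$centroid_col))] + 1L]
    }
  } else if (mode == "PUNCTA") {
    pk <- stage("puncta",
                detect_puncta(image, ch[["ha"]], labels, records,
                              tophat_radius = prm$tophat_radius,
                              k_sigma = prm$k_sigma,
                              min_puncta_area = prm$min_puncta_area,
                              min_puncta_per_cell = prm$min_puncta_per_cell))
    records <- pk$records
    metrics <- data.frame(n_cells = nrow(records),
                          percent_puncta_positive = pk$percent_positive,
                          condition = config$condition)
  } else if (mode == "ANNEXIN") {
    idx <- stage("annexin",
                 annexin_imaging_index(image, ch[["fitc"]], morph, labels,
                                       bg_exclusion_px = prm$bg_exclusion_px))
    metrics <- data.frame(n_cells = nrow(records), annexin_index = idx,
                          condition = config$condition)
  } else if (mode == "MORPHOMETRY") {
    nm <- stage("morphometry",
                measure_neurites(image, morph, labels,
                                 window = prm$window, offset = prm$offset))
    records <- merge(records, nm, by.x = "cell_id", by.y = "neuron_id",
                     all.x = TRUE, sort = TRUE)
    metrics <- data.frame(
      n_cells = nrow(records),
      mean_single_neurite_length_um = mean(nm$mean_single_neurite_length_um),
      mean_total_tree_length_um = mean(nm$total_tree_length_um),
      mean_soma_area_um2 = mean(nm$soma_area_um2),
      condition = config$condition)
  }

  paths <- list(records = file.path(config$out_dir, "cell_records.csv"),
                metrics = file.path(config$out_dir, "metrics.json"),
                labels = file.path(config$out_dir, "labels.tif"),
                log = file.path(config$out_dir, "run_log.json"))
  utils::write.csv(format(records, digits = 15, trim = TRUE,
                          scientific = FALSE),
                   paths$records, row.names = FALSE, quote = FALSE)
  write_label_tiff(labels, paths$labels)
  jsonlite::write_json(as.list(metrics), paths$metrics, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  if (!is.null(thresholds)) {
    paths$thresholds <- file.path(config$out_dir, "thresholds.json")
    jsonlite::write_json(thresholds, paths$thresholds, digits = NA,
                         pretty = TRUE)
  }
  log <- list(mode = mode, seed = config$seed,
              package_version = as.character(utils::packageVersion("synspread")),
              config_hash = config_hash(config),
              parameters = prm[order(names(prm))])
  jsonlite::write_json(log, paths$log, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(records = records, thresholds = thresholds,
                 metrics = metrics, labels = labels, paths = paths))
}
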