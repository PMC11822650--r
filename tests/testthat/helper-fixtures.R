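# Shared fixture builders: small, fast configurations used across test files.

small_config <- function(...) {
  args <- utils::modifyList(
    list(n_cells = 30, image_shape = c(320, 320), noise_sd = 0, seed = 7L),
    list(...))
  do.call(syn_config, args)
}

# flat-background image with hard bright discs at given centres
disc_image <- function(shape = c(128, 128), centers = rbind(c(40, 40)),
                       radius = 10, level = 1000, background = 100,
                       pixel_size = 0.5, channel = "NFH") {
  m <- matrix(background, shape[1], shape[2])
  for (i in seq_len(nrow(centers))) {
    d <- sqrt(outer((seq_len(shape[1]) - centers[i, 1])^2,
                    (seq_len(shape[2]) - centers[i, 2])^2, "+"))
    m[d <= radius] <- background + level
  }
  chans <- list(m)
  names(chans) <- channel
  mcimage(chans, pixel_size = pixel_size)
}

# thresholds fixed by hand for direct gating-table tests
fixed_thresholds <- function(egfp = 50, ha = 50, mcherry = NULL) {
  entries <- list(
    data.frame(channel = "eGFP", threshold = egfp, rule = "FIXED", param = NA,
               n_control_cells = NA, control_description = "test",
               low_confidence = FALSE, flagged = FALSE),
    data.frame(channel = "HA", threshold = ha, rule = "FIXED", param = NA,
               n_control_cells = NA, control_description = "test",
               low_confidence = FALSE, flagged = FALSE))
  if (!is.null(mcherry)) {
    entries <- c(entries, list(
      data.frame(channel = "mCherry", threshold = mcherry, rule = "FIXED",
                 param = NA, n_control_cells = NA,
                 control_description = "test", low_confidence = FALSE,
                 flagged = FALSE)))
  }
  do.call(rbind, entries)
}

# minimal cell-records table for classification tests
make_records <- function(egfp_bg, ha_bg, mcherry_bg = NULL) {
  n <- length(egfp_bg)
  rec <- data.frame(cell_id = seq_len(n), centroid_row = 10, centroid_col = 10,
                    area_px = 100, area_um2 = 25,
                    eGFP_bg = egfp_bg, HA_bg = ha_bg,
                    class_label = "UNSET", puncta_count = NA_integer_,
                    region = "NONE", stringsAsFactors = FALSE)
  if (!is.null(mcherry_bg)) rec$mCherry_bg <- mcherry_bg
  rec
}
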