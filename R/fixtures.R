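# Versioned on-disk fixture suite: every assay the pipeline quantifies, with
# ground truth, written as TIFF + CSV/JSON so each file round-trips through
# the package's own readers.

write_truth_csv <- function(truth, path) {
  utils::write.csv(format(truth, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
}

#' Generate the full fixture suite
#'
#' Writes a deterministic set of synthetic datasets with ground truth:
#' noiseless and noisy cultures, a brain-section mosaic, a puncta field with
#' a known positive fraction, a neurite field with analytically known
#' lengths, control-only images (non-transduced culture for the eGFP gate;
#' secondary-antibody-only field for the HA gate), and a flow-style event
#' table. A manifest lists every file with its ground-truth companion and
#' generation parameters. Identical (out_dir-independent) seed gives
#' byte-identical ground-truth tables.
#'
#' @param out_dir writable output directory (created if absent).
#' @param seed integer master seed; per-fixture seeds are derived from it.
#' @param n_cells cells per culture fixture.
#' @return the manifest (list), invisibly written to \code{manifest.json}.
#' @export
generate_fixture_suite <- function(out_dir, seed = 1L, n_cells = 60L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  manifest <- list(version = "1", seed = seed, fixtures = list())
  add <- function(name, files, params, truth_file = NULL) {
    manifest$fixtures[[name]] <<- list(files = as.list(files),
                                       truth = truth_file, params = params)
  }
  pth <- function(...) file.path(out_dir, paste0(...))

  # 1. noiseless culture
  cfg0 <- syn_config(n_cells = n_cells, image_shape = c(360, 360),
                     noise_sd = 0, seed = seed)
  cult0 <- generate_culture(cfg0)
  write_mcimage(cult0$image, pth("culture_noiseless.tif"))
  write_truth_csv(cult0$truth, pth("culture_noiseless_truth.csv"))
  add("culture_noiseless", "culture_noiseless.tif",
      unclass(cfg0), "culture_noiseless_truth.csv")

  # 2. noisy culture (read noise at 5% of reporter signal)
  cfg1 <- syn_config(n_cells = n_cells, image_shape = c(360, 360),
                     noise_sd = 50, seed = seed + 1L)
  cult1 <- generate_culture(cfg1)
  write_mcimage(cult1$image, pth("culture_noisy.tif"))
  write_truth_csv(cult1$truth, pth("culture_noisy_truth.csv"))
  add("culture_noisy", "culture_noisy.tif", unclass(cfg1), "culture_noisy_truth.csv")

  # 3. brain section
  cfg2 <- syn_config(n_cells = n_cells, image_shape = c(400, 400),
                     pixel_size = 2, noise_sd = 0, seed = seed + 2L)
  lay <- region_layout(cortical_fraction = 0.4, footprint = "full")
  sect <- generate_brain_section(cfg2, lay)
  write_mcimage(sect$image, pth("brain_section.tif"))
  write_truth_csv(sect$truth, pth("brain_section_truth.csv"))
  tiff::writeTIFF(sect$region_mask$regions / 65535, pth("brain_section_regions.tif"),
                  bits.per.sample = 16L, compression = "none")
  add("brain_section", c("brain_section.tif", "brain_section_regions.tif"),
      c(unclass(cfg2), cortical_fraction = lay$cortical_fraction),
      "brain_section_truth.csv")

  # 4. puncta field: exactly 15% of cells bear 3 puncta each
  cfg3 <- syn_config(n_cells = n_cells, image_shape = c(360, 360),
                     noise_sd = 0, seed = seed + 3L)
  pf <- generate_puncta_field(cfg3, puncta_fraction = 0.15, n_puncta = 3L)
  write_mcimage(pf$image, pth("puncta_field.tif"))
  write_truth_csv(pf$truth, pth("puncta_field_truth.csv"))
  add("puncta_field", "puncta_field.tif",
      c(unclass(cfg3), puncta_fraction = 0.15, n_puncta = 3),
      "puncta_field_truth.csv")

  # 5. neurite field: one straight 200-px horizontal neurite at 0.5 um/px
  #    (ground-truth length 100 um) plus a diagonal and a Y-tree neuron
  cfg4 <- syn_config(n_cells = 3, image_shape = c(760, 760), pixel_size = 0.5,
                     noise_sd = 0, min_separation = 240, seed = seed + 4L)
  spec_nf <- list(
    list(c(0, 200)),              # straight horizontal
    list(c(100, 100)),            # 45-degree diagonal
    list(c(-80, 80), c(80, 80))   # two primary neurites, one neuron
  )
  nf <- generate_neurite_field(cfg4, spec_nf)
  write_mcimage(nf$image, pth("neurite_field.tif"))
  write_label_tiff(nf$soma_map, pth("neurite_field_somata.tif"))
  write_truth_csv(nf$neurite_truth, pth("neurite_field_truth.csv"))
  add("neurite_field", c("neurite_field.tif", "neurite_field_somata.tif"),
      c(unclass(cfg4),
        straight_neurite_length_um = nf$neurite_truth$total_length_um[1]),
      "neurite_field_truth.csv")

  # 6. control: non-transduced culture (eGFP gate calibration)
  cfg5 <- syn_config(n_cells = n_cells, image_shape = c(360, 360),
                     p_transduce = 0, p_spread = 0,
                     noise_sd = 0, seed = seed + 5L)
  ctl <- generate_culture(cfg5)
  write_mcimage(ctl$image, pth("control_nontransduced.tif"))
  write_truth_csv(ctl$truth, pth("control_nontransduced_truth.csv"))
  add("control_nontransduced", "control_nontransduced.tif", unclass(cfg5),
      "control_nontransduced_truth.csv")

  # 7. control: secondary-antibody-only field (HA gate calibration) —
  #    morphology present, HA pure background
  cfg6 <- syn_config(n_cells = n_cells, image_shape = c(360, 360),
                     p_transduce = 0, p_spread = 0, recipient_ha_level = 0,
                     noise_sd = 0, seed = seed + 6L)
  ctl2 <- generate_culture(cfg6)
  write_mcimage(ctl2$image, pth("control_secondary_only.tif"))
  write_truth_csv(ctl2$truth, pth("control_secondary_only_truth.csv"))
  add("control_secondary_only", "control_secondary_only.tif", unclass(cfg6),
      "control_secondary_only_truth.csv")

  # 8. flow-style event table
  ev <- generate_flow_events(n_events = 4000, seed = seed + 7L)
  utils::write.csv(format(ev, digits = 15, trim = TRUE, scientific = FALSE),
                   pth("flow_events.csv"), row.names = FALSE, quote = FALSE)
  add("flow_events", "flow_events.csv",
      list(n_events = 4000, frac_expressing = 0.7, fitc_median = 1000))

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
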