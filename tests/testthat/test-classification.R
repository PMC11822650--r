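# Gating tables, brain-section classification, puncta scoring, annexin index.

test_that("the in vitro gating table assigns every quadrant correctly", {
  thr <- fixed_thresholds(egfp = 100, ha = 100)
  rec <- make_records(egfp_bg = c(700, 50, 50, 700),
                      ha_bg = c(500, 500, 50, 50))
  out <- classify_in_vitro(rec, thr)
  expect_identical(out$class_label,
                   c("DONOR", "RECIPIENT", "UNTRANSDUCED", "AMBIGUOUS"))
})

test_that("cells exactly at threshold gate negative", {
  thr <- fixed_thresholds(egfp = 100, ha = 100)
  rec <- make_records(egfp_bg = c(100, 100.0001), ha_bg = c(100, 100.0001))
  out <- classify_in_vitro(rec, thr)
  expect_identical(out$class_label, c("UNTRANSDUCED", "DONOR"))
})

test_that("missing threshold entries raise errors", {
  rec <- make_records(1, 1)
  thr <- fixed_thresholds()[1, ]  # eGFP only
  expect_error(classify_in_vitro(rec, thr), "HA")
})

test_that("in vivo gating requires mCherry and leaves non-reporting cells UNSET", {
  thr <- fixed_thresholds(egfp = 100, ha = 100, mcherry = 100)
  rec <- make_records(egfp_bg = c(50, 700, 50, 50),
                      ha_bg = c(500, 500, 500, 50),
                      mcherry_bg = c(700, 700, 50, 700))
  out <- classify_in_vivo(rec, thr)
  expect_identical(out$class_label,
                   c("RECIPIENT", "DONOR", "UNSET", "UNTRANSDUCED"))
})

test_that("gating classes always partition the gated population", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 200
    rec <- make_records(egfp_bg = rlnorm(n, 3, 2), ha_bg = rlnorm(n, 3, 2))
    out <- classify_in_vitro(rec, fixed_thresholds(egfp = 60, ha = 40))
    tab <- table(factor(out$class_label,
                        levels = c("DONOR", "RECIPIENT", "UNTRANSDUCED",
                                   "AMBIGUOUS")))
    expect_equal(sum(tab), n)
  }
})

test_that("noiseless culture pipeline reproduces ground-truth classes exactly", {
  cu <- generate_culture(small_config(n_cells = 40, image_shape = c(360, 360),
                                      p_spread = 0.3, seed = 23L))
  ctl <- generate_culture(small_config(n_cells = 30, image_shape = c(320, 320),
                                       p_transduce = 0, p_spread = 0,
                                       seed = 24L))
  lm <- segment_somata(cu$image, "NFH")
  rec <- measure_cell_intensities(cu$image, lm)
  ctl_rec <- measure_cell_intensities(ctl$image, segment_somata(ctl$image, "NFH"))
  thr <- threshold_set(
    calibrate_threshold(ctl_rec$eGFP_bg, "PERCENTILE_OF_CONTROL", 99, "eGFP"),
    calibrate_threshold(ctl_rec$HA_bg, "MEAN_PLUS_K_SD", 3, "HA"))
  out <- classify_in_vitro(rec, thr)
  # match each detected cell to the nearest true centre
  truth_cls <- cu$truth$true_class[
    vapply(seq_len(nrow(out)), function(i) {
      which.min((cu$truth$center_row - out$centroid_row[i])^2 +
                (cu$truth$center_col - out$centroid_col[i])^2)
    }, 0L)]
  expect_identical(out$class_label, truth_cls)
})

test_that("noiseless brain-section gating recovers the ground-truth recipient set", {
  cfg <- small_config(n_cells = 50, image_shape = c(440, 440), pixel_size = 2,
                      p_spread = 0.3, seed = 31L)
  sect <- generate_brain_section(cfg)
  lmap <- truth_labelmap(sect$truth, c(440, 440))
  rec <- measure_cell_intensities(sect$image, lmap)
  thr <- fixed_thresholds(egfp = 50, ha = 50, mcherry = 50)
  out <- classify_in_vivo(rec, thr)
  got_recip <- sort(out$cell_id[out$class_label == "RECIPIENT"])
  true_recip <- sort(sect$truth$cell_id[sect$truth$true_class == "RECIPIENT"])
  expect_identical(got_recip, true_recip)
})

test_that("uniform cells carry no puncta; seeded puncta are counted", {
  cu <- generate_culture(small_config(n_cells = 12, image_shape = c(240, 240),
                                      p_transduce = 1, seed = 3L))
  lmap <- truth_labelmap(cu$truth, c(240, 240))
  none <- detect_puncta(cu$image, "HA", lmap)
  expect_true(all(none$records$puncta_count == 0))
  expect_equal(none$percent_positive, 0)

  pf <- generate_puncta_field(small_config(n_cells = 20,
                                           image_shape = c(280, 280),
                                           p_transduce = 1, seed = 5L),
                              puncta_fraction = 0.25, n_puncta = 3L)
  lmap2 <- truth_labelmap(pf$truth, c(280, 280))
  got <- detect_puncta(pf$image, "HA", lmap2)
  m <- merge(got$records, pf$truth, by = "cell_id")
  expect_true(all(m$puncta_count[m$has_puncta] >= 2))
  expect_true(all(m$puncta_count[!m$has_puncta] == 0))
})

test_that("a noiseless 15% puncta field scores exactly 15% positive", {
  pf <- generate_puncta_field(small_config(n_cells = 40,
                                           image_shape = c(360, 360),
                                           seed = 7L),
                              puncta_fraction = 0.15, n_puncta = 3L)
  lmap <- truth_labelmap(pf$truth, c(360, 360))
  got <- detect_puncta(pf$image, "HA", lmap)
  expect_equal(got$percent_positive, 15)
})

test_that("raising min_puncta_per_cell never raises the positive percentage", {
  pf <- generate_puncta_field(small_config(n_cells = 30,
                                           image_shape = c(320, 320),
                                           seed = 9L),
                              puncta_fraction = 0.3, n_puncta = 3L)
  lmap <- truth_labelmap(pf$truth, c(320, 320))
  pct <- vapply(1:5, function(k) {
    detect_puncta(pf$image, "HA", lmap,
                  min_puncta_per_cell = k)$percent_positive
  }, 0)
  expect_true(all(diff(pct) <= 0))
})

test_that("annexin index satisfies its closed-form cases", {
  cu <- generate_culture(small_config(n_cells = 15, image_shape = c(240, 240),
                                      seed = 11L))
  lmap <- truth_labelmap(cu$truth, c(240, 240))
  im <- cu$image
  # FITC identical to NFH -> 1.0
  im$channels$FITC <- im$channels$NFH
  expect_equal(annexin_imaging_index(im, "FITC", "NFH", lmap), 1.0)
  # FITC flat background -> 0.0
  im$channels$FITC <- matrix(100, 240, 240)
  expect_equal(annexin_imaging_index(im, "FITC", "NFH", lmap), 0.0)
  # FITC at half the NFH signal -> 0.5
  im$channels$FITC <- (im$channels$NFH - 100) * 0.5 + 100
  expect_lt(abs(annexin_imaging_index(im, "FITC", "NFH", lmap) - 0.5), 0.01)
})

test_that("annexin index is invariant to common gain on both channels", {
  cu <- generate_culture(small_config(n_cells = 10, image_shape = c(220, 220),
                                      seed = 13L))
  lmap <- truth_labelmap(cu$truth, c(220, 220))
  im <- cu$image
  im$channels$FITC <- (im$channels$NFH - 100) * 0.7 + 100
  i1 <- annexin_imaging_index(im, "FITC", "NFH", lmap)
  im2 <- im
  im2$channels$FITC <- im$channels$FITC * 2.5
  im2$channels$NFH <- im$channels$NFH * 2.5
  i2 <- annexin_imaging_index(im2, "FITC", "NFH", lmap)
  expect_lt(abs(i1 - i2) / i1, 1e-6)
})
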