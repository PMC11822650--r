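# Synthetic generator: determinism, degenerate probabilities, draw-order
# oracle, monotonicity under common random numbers, noiseless pixel
# guarantees, brain-section region labelling, fixture suite contracts.

test_that("degenerate probabilities produce pure populations", {
  all_donor <- generate_culture(small_config(p_transduce = 1))
  expect_true(all(all_donor$truth$true_class == "DONOR"))

  none <- generate_culture(small_config(p_transduce = 0, p_spread = 0))
  expect_true(all(none$truth$true_class == "UNTRANSDUCED"))
  # reporter channels are pure background in a noiseless untransduced culture
  expect_equal(unique(as.vector(none$image$channels$eGFP)), 100)
  expect_equal(unique(as.vector(none$image$channels$HA)), 100)
})

test_that("class draws match an independent seeded re-sampling oracle", {
  cfg <- small_config(n_cells = 100, image_shape = c(560, 560),
                      p_transduce = 0.6, p_spread = 0.2, seed = 42L)
  got <- generate_culture(cfg)$truth$true_class

  # independent oracle: replay the documented draw order
  set.seed(42L)
  oracle <- character(100)
  for (i in 1:100) {
    if (runif(1) < 0.6) {
      oracle[i] <- "DONOR"
    } else if (runif(1) < 0.2) {
      oracle[i] <- "RECIPIENT"
    } else {
      oracle[i] <- "UNTRANSDUCED"
    }
  }
  expect_identical(got, oracle)
})

test_that("identical config and seed give bit-identical output", {
  cfg <- small_config(noise_sd = 30, seed = 11L)
  a <- generate_culture(cfg)
  b <- generate_culture(cfg)
  expect_identical(a$image$channels, b$image$channels)
  expect_identical(a$truth, b$truth)
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(123)
  r1 <- runif(1)
  set.seed(123)
  invisible(generate_culture(small_config()))
  expect_identical(runif(1), r1)
})

test_that("recipient count is monotone in p_spread under common seeds", {
  for (seed in c(1L, 2L, 3L)) {
    counts <- vapply(c(0.05, 0.1, 0.2, 0.4), function(ps) {
      tr <- generate_culture(small_config(n_cells = 60,
                                          image_shape = c(420, 420),
                                          p_spread = ps, seed = seed))$truth
      sum(tr$true_class == "RECIPIENT")
    }, 0)
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("donor fraction converges to p_transduce over seeds", {
  n <- 400
  fr <- vapply(1:25, function(s) {
    tr <- simulate_cell_records(small_config(n_cells = n, seed = s))$truth
    mean(tr$true_class == "DONOR")
  }, 0)
  se <- sqrt(0.6 * 0.4 / (n * 25))
  expect_lt(abs(mean(fr) - 0.6), 3 * se)
})

test_that("noiseless donor somata strictly exceed background; recipients sit at it", {
  cu <- generate_culture(small_config(n_cells = 40, image_shape = c(360, 360),
                                      p_spread = 0.5, seed = 5L))
  bg <- 100
  for (i in seq_len(nrow(cu$truth))) {
    r <- cu$truth$radius_px[i]
    rows <- cu$truth$center_row[i] + seq(-floor(r), floor(r))
    # sample the soma footprint along the central row/column
    px_e <- cu$image$channels$eGFP[rows, cu$truth$center_col[i]]
    px_h <- cu$image$channels$HA[rows, cu$truth$center_col[i]]
    if (cu$truth$true_class[i] == "DONOR") {
      expect_true(all(px_e > bg) && all(px_h > bg))
    } else {
      expect_true(all(px_e == bg))
      if (cu$truth$true_class[i] == "RECIPIENT") expect_true(all(px_h > bg))
    }
  }
})

test_that("placement respects min_separation and errors when impossible", {
  cu <- generate_culture(small_config(n_cells = 25, image_shape = c(300, 300),
                                      min_separation = 30, seed = 2L))
  ctr <- as.matrix(cu$truth[, c("center_row", "center_col")])
  d <- as.matrix(stats::dist(ctr))
  diag(d) <- Inf
  expect_gte(min(d), 30)
  expect_error(generate_culture(small_config(n_cells = 500,
                                             image_shape = c(100, 100))),
               "min_separation")
})

test_that("config validation rejects bad values", {
  expect_error(syn_config(p_transduce = 1.5), "\\[0, 1\\]")
  expect_error(syn_config(noise_sd = -1), ">= 0")
  expect_error(syn_config(background_level = NaN), "finite")
  expect_error(syn_config(soma_radius_mean = 0), "soma_radius_mean")
})

test_that("brain sections carry region labels and section-size QC", {
  cfg <- small_config(n_cells = 40, image_shape = c(400, 400), pixel_size = 2)
  sect <- generate_brain_section(cfg, region_layout(cortical_fraction = 0.4))
  expect_setequal(names(sect$image$channels), c("mCherry", "eGFP", "HA"))
  expect_true(all(sect$truth$region %in% c("CORTICAL", "SUBCORTICAL")))
  # region label agrees with the centre row against the split line
  split <- floor(400 * 0.4)
  expect_identical(sect$truth$region,
                   ifelse(sect$truth$center_row <= split,
                          "CORTICAL", "SUBCORTICAL"))

  # all-cortical layout
  allc <- generate_brain_section(cfg, region_layout(cortical_fraction = 1))
  expect_true(all(allc$truth$region == "CORTICAL"))

  # full-frame footprint: 1000 x 1000 px at 10 um/px = 100 mm^2
  lay <- region_layout(0.5, "full")
  big <- synspread:::build_region_mask(lay, c(1000, 1000), 10)
  expect_equal(section_area_mm2(big), 100)
})

test_that("brain-section recipient draws match a seeded oracle per region", {
  cfg <- small_config(n_cells = 80, image_shape = c(560, 560),
                      p_transduce = 0.5, p_spread = 0.1, p_mcherry = 0.9,
                      seed = 9L)
  sect <- generate_brain_section(cfg)
  set.seed(9L)
  oracle <- character(80)
  for (i in 1:80) {
    if (runif(1) < 0.5) {
      oracle[i] <- "DONOR"; runif(2)
    } else {
      m <- runif(1) < 0.9
      v <- runif(1)
      oracle[i] <- if (m && v < 0.1) "RECIPIENT" else "UNTRANSDUCED"
    }
  }
  expect_identical(sect$truth$true_class, oracle)
})

test_that("fixture suite is deterministic and its manifest is complete", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- generate_fixture_suite(d1, seed = 21L, n_cells = 20L)
  m2 <- generate_fixture_suite(d2, seed = 21L, n_cells = 20L)

  truth_files <- vapply(m1$fixtures, function(f) {
    if (is.null(f$truth)) "" else f$truth
  }, "")
  truth_files <- truth_files[nzchar(truth_files)]
  for (tf in truth_files) {
    expect_identical(readLines(file.path(d1, tf)), readLines(file.path(d2, tf)))
  }
  # manifest lists every written fixture file
  listed <- unlist(lapply(m1$fixtures, function(f) c(unlist(f$files), f$truth)))
  for (f in listed) expect_true(file.exists(file.path(d1, f)))

  # straight 200-px horizontal neurite at 0.5 um/px -> 100 um in the manifest
  expect_equal(m1$fixtures$neurite_field$params$straight_neurite_length_um, 100)
})
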