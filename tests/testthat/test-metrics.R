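# Spread metrics, normalization, region counts, delta-delta-Ct, group stats.

test_that("spread metrics follow their defining ratios", {
  cls <- c(rep("DONOR", 120), rep("RECIPIENT", 16), rep("UNTRANSDUCED", 64))
  rec <- data.frame(class_label = cls)
  m <- compute_spread_metrics(rec)
  expect_equal(m$n_gated, 200)
  expect_equal(m$transduction_efficiency, 0.60)
  expect_equal(m$spread_fraction, 16 / 80)

  none <- data.frame(class_label = c(rep("DONOR", 20), rep("UNTRANSDUCED", 80)))
  expect_equal(compute_spread_metrics(none)$spread_fraction, 0)

  amb <- data.frame(class_label = c(rep("DONOR", 10), rep("RECIPIENT", 5),
                                    rep("UNTRANSDUCED", 5), rep("AMBIGUOUS", 4)))
  ma <- compute_spread_metrics(amb)
  expect_equal(ma$n_ambiguous, 4)
  expect_equal(ma$transduction_efficiency, 10 / 20)  # ambiguous excluded
  expect_equal(ma$spread_fraction, 5 / 10)

  expect_error(compute_spread_metrics(data.frame(class_label = character(0))),
               "zero gated")
  expect_error(compute_spread_metrics(data.frame(class_label = rep("UNSET", 5))),
               "zero gated")
})

test_that("normalization to the control mean has its closed forms", {
  expect_equal(normalize_to_control(c(2, 4), c(2, 4)), c(2 / 3, 4 / 3))
  expect_equal(normalize_to_control(c(1, 1, 1), c(2, 2)), c(0.5, 0.5, 0.5))
  ctl <- c(3.2, 4.1, 2.7)
  expect_equal(mean(normalize_to_control(ctl, ctl)), 1.0)
  expect_error(normalize_to_control(1:3, numeric(0)), "empty")
  expect_error(normalize_to_control(1:3, c(0, 0)), "non-zero")
})

test_that("region counting conserves recipients and reports section QC", {
  reg <- matrix(2L, 100, 100)
  reg[1:40, ] <- 1L
  rmask <- region_mask(reg, matrix(TRUE, 100, 100), pixel_size = 10)
  rec <- data.frame(
    class_label = c(rep("RECIPIENT", 10), "DONOR", "UNTRANSDUCED"),
    centroid_row = c(rep(20, 6), rep(80, 4), 20, 80),
    centroid_col = c(seq(10, 60, 10), seq(10, 40, 10), 50, 50))
  out <- count_recipients_by_region(rec, rmask)
  expect_equal(out$counts$cortical, 6)
  expect_equal(out$counts$subcortical, 4)
  expect_equal(out$counts$whole_brain, 10)
  expect_equal(out$counts$none, 0)
  expect_equal(out$section_area_mm2, 100 * 100 * 100 / 1e6)

  # empty subcortical region
  rmask2 <- region_mask(matrix(1L, 100, 100), matrix(TRUE, 100, 100), 10)
  out2 <- count_recipients_by_region(rec, rmask2)
  expect_equal(out2$counts$subcortical, 0)
  expect_equal(out2$counts$whole_brain, 10)

  # centroid outside the footprint -> NONE
  fp <- matrix(TRUE, 100, 100); fp[, 60:100] <- FALSE
  reg3 <- reg; reg3[, 60:100] <- 0L
  out3 <- count_recipients_by_region(rec, region_mask(reg3, fp, 10))
  expect_equal(out3$counts$none, 1)  # the recipient at col 60
  expect_equal(out3$counts$whole_brain, 9)
})

test_that("brain-section fixture region counts match ground truth", {
  cfg <- small_config(n_cells = 60, image_shape = c(480, 480), pixel_size = 2,
                      p_spread = 0.4, seed = 37L)
  sect <- generate_brain_section(cfg)
  lmap <- truth_labelmap(sect$truth, c(480, 480))
  rec <- measure_cell_intensities(sect$image, lmap)
  out <- classify_in_vivo(rec, fixed_thresholds(50, 50, mcherry = 50))
  counts <- count_recipients_by_region(out, sect$region_mask)$counts
  truth_tab <- table(sect$truth$region[sect$truth$true_class == "RECIPIENT"])
  expect_equal(counts$cortical, unname(truth_tab["CORTICAL"]))
  expect_equal(counts$subcortical, unname(truth_tab["SUBCORTICAL"]))
  expect_equal(counts$whole_brain, sum(truth_tab))
})

test_that("delta-delta-Ct has its closed-form identities", {
  tb <- data.frame(ct_target = c(25, 26, 28), ct_reference = c(20, 21, 20),
                   group = c("CONTROL", "CONTROL", "TREATED"))
  out <- delta_delta_ct(tb)
  # control with dCt equal to the control mean -> exactly 1
  expect_equal(out$dct, c(5, 5, 8))
  expect_equal(out$rel_expression[1], 1.0)
  # treated dCt 8 vs control mean 5 -> 2^-3
  expect_equal(out$rel_expression[3], 2^-3)
  # control geometric mean is 1 by construction
  expect_equal(exp(mean(log(out$rel_expression[out$group == "CONTROL"]))), 1.0)

  # ddCt = 5 vs control mean 3 -> 0.25
  tb2 <- data.frame(ct_target = c(8, 10), ct_reference = c(5, 5),
                    group = c("CONTROL", "TREATED"))
  expect_equal(delta_delta_ct(tb2)$rel_expression[2], 0.25)
  expect_error(delta_delta_ct(data.frame(ct_target = 1, ct_reference = 1,
                                         group = "TREATED")), "CONTROL")
})

test_that("delta-delta-Ct matches a spreadsheet-style recomputation on random tables", {
  set.seed(77)
  for (rep in 1:5) {
    n <- 12
    tb <- data.frame(ct_target = runif(n, 18, 32),
                     ct_reference = runif(n, 15, 22),
                     group = sample(c("CONTROL", "TREATED"), n, TRUE,
                                    prob = c(0.5, 0.5)))
    if (!any(tb$group == "CONTROL")) tb$group[1] <- "CONTROL"
    out <- delta_delta_ct(tb)
    # independent cell-by-cell recomputation
    dct <- tb$ct_target - tb$ct_reference
    base <- mean(dct[tb$group == "CONTROL"])
    expect_equal(out$rel_expression, 2^(-(dct - base)), tolerance = 1e-12)
  }
})

test_that("CT shift invariance: adding a constant to every CT changes nothing", {
  tb <- data.frame(ct_target = c(25, 26, 28, 24), ct_reference = c(20, 21, 20, 19),
                   group = c("CONTROL", "CONTROL", "TREATED", "TREATED"))
  out1 <- delta_delta_ct(tb)
  tb2 <- tb
  tb2$ct_target <- tb2$ct_target + 3
  tb2$ct_reference <- tb2$ct_reference + 3
  out2 <- delta_delta_ct(tb2)
  expect_equal(out2$rel_expression, out1$rel_expression)
})

test_that("group comparisons have their degenerate closed forms", {
  g <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  tt <- group_compare(g, "TWO_GROUP")
  expect_equal(tt$statistic, 0)
  expect_equal(tt$p_value, 1)

  g3 <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  an <- group_compare(g3, "MULTI_GROUP")
  expect_equal(an$statistic, 0)
  expect_equal(an$p_value, 1)

  expect_error(group_compare(list(a = 1, b = c(1, 2)), "TWO_GROUP"),
               "at least 2")
})

test_that("t and F agree with hand-computed textbook formulas", {
  set.seed(11)
  for (rep in 1:5) {
    x <- rnorm(8, 5, 2); y <- rnorm(11, 6, 2)
    got <- group_compare(list(x = x, y = y), "TWO_GROUP")
    sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
      (length(x) + length(y) - 2)
    t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
    df <- length(x) + length(y) - 2
    p_hand <- 2 * pt(-abs(t_hand), df)
    expect_lt(abs(got$statistic - t_hand), 1e-8)
    expect_lt(abs(got$p_value - p_hand), 1e-8)

    z <- rnorm(7, 5.5, 2)
    ga <- group_compare(list(x = x, y = y, z = z), "MULTI_GROUP")
    all_v <- c(x, y, z)
    ns <- c(length(x), length(y), length(z))
    means <- c(mean(x), mean(y), mean(z))
    ssb <- sum(ns * (means - mean(all_v))^2)
    ssw <- sum((x - mean(x))^2) + sum((y - mean(y))^2) + sum((z - mean(z))^2)
    f_hand <- (ssb / 2) / (ssw / (sum(ns) - 3))
    p_hand_f <- pf(f_hand, 2, sum(ns) - 3, lower.tail = FALSE)
    expect_lt(abs(ga$statistic - f_hand), 1e-8)
    expect_lt(abs(ga$p_value - p_hand_f), 1e-8)
    expect_equal(nrow(ga$posthoc), 3)
  }
})

test_that("class counts and region counts stay conserved end to end", {
  cu <- generate_culture(small_config(n_cells = 30, seed = 41L,
                                      p_spread = 0.4))
  lmap <- truth_labelmap(cu$truth, c(320, 320))
  rec <- measure_cell_intensities(cu$image, lmap)
  out <- classify_in_vitro(rec, fixed_thresholds(50, 50))
  m <- compute_spread_metrics(out)
  expect_equal(m$n_donor + m$n_recipient + m$n_untransduced + m$n_ambiguous,
               m$n_gated)
  expect_equal(m$n_gated, nrow(rec))
})
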