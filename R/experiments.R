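# Replication-level experiments: parameter-recovery sweeps and the
# synthetic knockdown/control power study. These drive the same pipeline
# stages end to end and are what the acceptance checks and the
# reproducibility script run.

# thresholds calibrated from a control culture's cell records, using the
# default rules (eGFP: percentile 99 of non-transduced; HA: mean + 3 sd of
# secondary-only background). Calibration uses the signed (unfloored)
# background-subtracted values: flooring halves the control sd and would
# bias the mean+k*sd cut low.
calibrate_from_control_records <- function(ctl_rec) {
  egfp <- if ("eGFP_bg_signed" %in% names(ctl_rec)) ctl_rec$eGFP_bg_signed else ctl_rec$eGFP_bg
  ha <- if ("HA_bg_signed" %in% names(ctl_rec)) ctl_rec$HA_bg_signed else ctl_rec$HA_bg
  threshold_set(
    calibrate_threshold(egfp, "PERCENTILE_OF_CONTROL", 99, "eGFP",
                        control_description = "non-transduced control cells"),
    calibrate_threshold(ha, "MEAN_PLUS_K_SD", 3, "HA",
                        control_description = "secondary-antibody-only control"))
}

#' Parameter-recovery sweep over spread probabilities
#'
#' For every \code{p_spread} value and seed, renders a full culture image,
#' runs segmentation, intensity measurement, control-based threshold
#' calibration and gating, and records the estimated transduction efficiency
#' and spread fraction. The same seeds are used across settings (common
#' random numbers), so the generated recipient sets are nested in
#' \code{p_spread}.
#'
#' @param p_spread_values spread probabilities to sweep.
#' @param n_seeds seeds per setting.
#' @param n_cells cells per field.
#' @param noise_sd read-noise sd (ADU); the reporter signal is 1000 ADU, so
#'   50 is 5\% of signal.
#' @param p_transduce transduction probability (default 0.6).
#' @param base_seed offset added to every derived seed.
#' @param seg_offset adaptive-threshold offset passed to
#'   \code{\link{segment_somata}}; defaults to 3x the noise sd (plus the
#'   noiseless default of 10).
#' @return data frame: p_spread, seed, n_detected, transduction_efficiency,
#'   spread_fraction.
#' @export
spread_recovery_sweep <- function(p_spread_values = c(0.05, 0.1, 0.2, 0.4),
                                  n_seeds = 20, n_cells = 1000,
                                  noise_sd = 50, p_transduce = 0.6,
                                  base_seed = 1000L,
                                  seg_offset = 10 + 3 * noise_sd) {
  shape <- field_shape_for(n_cells)
  rows <- list()
  for (ps in p_spread_values) {
    for (s in seq_len(n_seeds)) {
      cfg <- syn_config(n_cells = n_cells, image_shape = shape,
                        p_transduce = p_transduce, p_spread = ps,
                        noise_sd = noise_sd, seed = base_seed + s)
      cu <- generate_culture(cfg)
      lmap <- segment_somata(cu$image, "NFH", offset = seg_offset)
      rec <- measure_cell_intensities(cu$image, lmap)

      ctl_cfg <- syn_config(n_cells = 150, image_shape = c(460, 460),
                            p_transduce = 0, p_spread = 0,
                            noise_sd = noise_sd, seed = base_seed + 500L + s)
      ctl <- generate_culture(ctl_cfg)
      ctl_rec <- measure_cell_intensities(
        ctl$image, segment_somata(ctl$image, "NFH", offset = seg_offset))
      thr <- calibrate_from_control_records(ctl_rec)

      m <- compute_spread_metrics(classify_in_vitro(rec, thr))
      rows[[length(rows) + 1L]] <- data.frame(
        p_spread = ps, seed = s, n_detected = m$n_gated,
        transduction_efficiency = m$transduction_efficiency,
        spread_fraction = m$spread_fraction)
    }
  }
  do.call(rbind, rows)
}

# smallest frame whose jittered placement grid holds n_cells at the default
# separation of 25 px
field_shape_for <- function(n_cells, min_separation = 25) {
  spacing <- ceiling(1.4 * min_separation)
  margin <- ceiling(min_separation / 2) + 4
  side <- ceiling(sqrt(n_cells))
  px <- (side - 1) * spacing + 2 * margin + spacing
  c(px, px)
}

#' Synthetic knockdown vs control power study
#'
#' The in-silico analogue of a two-condition spread experiment: per
#' repetition, \code{n_fields} replicate fields per condition are simulated
#' at the record level (\code{\link{simulate_cell_records}}), gated with
#' control-calibrated thresholds, reduced to spread fractions, normalized to
#' the control-condition mean, and compared with the two-tailed t-test of
#' \code{\link{group_compare}}.
#'
#' @param n_reps repetitions of the whole experiment.
#' @param n_fields replicate fields per condition.
#' @param n_cells cells per field.
#' @param p_spread_control,p_spread_depleted spread probabilities of the two
#'   conditions.
#' @param noise_sd read-noise sd (ADU).
#' @param base_seed offset added to derived seeds.
#' @return data frame, one row per repetition: mean normalized spread per
#'   condition, t statistic, p value, and \code{detected} (depleted lower
#'   with p < 0.05).
#' @export
knockdown_power_study <- function(n_reps = 100, n_fields = 5, n_cells = 200,
                                  p_spread_control = 0.2,
                                  p_spread_depleted = 0.05,
                                  noise_sd = 50, base_seed = 5000L) {
  one_field <- function(ps, seed, thr) {
    sim <- simulate_cell_records(
      syn_config(n_cells = n_cells, image_shape = field_shape_for(n_cells),
                 p_spread = ps, noise_sd = noise_sd, seed = seed))
    compute_spread_metrics(classify_in_vitro(sim$records, thr))$spread_fraction
  }
  out <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    s0 <- base_seed + 37L * r
    ctl_sim <- simulate_cell_records(
      syn_config(n_cells = 150, image_shape = c(460, 460), p_transduce = 0,
                 p_spread = 0, noise_sd = noise_sd, seed = s0))
    thr <- calibrate_from_control_records(ctl_sim$records)
    ctl <- vapply(seq_len(n_fields),
                  function(f) one_field(p_spread_control, s0 + f, thr), 0)
    dep <- vapply(seq_len(n_fields),
                  function(f) one_field(p_spread_depleted, s0 + 100L + f, thr), 0)
    norm_ctl <- normalize_to_control(ctl, ctl)
    norm_dep <- normalize_to_control(dep, ctl)
    gc_ <- group_compare(list(control = norm_ctl, depleted = norm_dep),
                         "TWO_GROUP")
    out[[r]] <- data.frame(
      rep = r, mean_norm_control = mean(norm_ctl),
      mean_norm_depleted = mean(norm_dep),
      t_statistic = gc_$statistic, p_value = gc_$p_value,
      detected = mean(norm_dep) < mean(norm_ctl) & gc_$p_value < 0.05)
  }
  do.call(rbind, out)
}
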