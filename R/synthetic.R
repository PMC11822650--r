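# Synthetic multi-channel microscopy generator with per-cell ground truth.
#
# Emulates the statistical structure of reporter-based spread assays:
# donor neurons (morphology+, eGFP+, HA+), recipient neurons that acquired
# tagged alpha-synuclein without being transduced (morphology+, eGFP-, HA+),
# and untransduced neurons (neither reporter). Somata are rendered as discs
# with an error-function edge profile (equivalent to a Gaussian-blurred hard
# disc, sigma 1 px) on a flat additive background, with optional Gaussian
# read noise and Poisson shot noise.
#
# RNG draw order (fixed, so an independent re-sampling script with the same
# seed reproduces the class assignment):
#   1. per-cell class draws: u ~ U(0,1) for transduction; v ~ U(0,1) for
#      spread, drawn for EVERY non-donor cell (so the recipient set grows
#      monotonically in p_spread under common random numbers);
#   2. placement jitter on the grid;
#   3. soma radii;
#   4. per-cell intensity jitter (all channels, all cells);
#   5. pixel noise.

#' Configuration for the synthetic microscopy generator
#'
#' Defaults reflect the assay being emulated: 60\% transduction efficiency,
#' 16-bit range, 100 ADU background, 1000 ADU reporter signal in transduced
#' somata.
#'
#' @param n_cells number of neurons to place.
#' @param image_shape c(rows, cols) in pixels.
#' @param pixel_size micrometres per pixel.
#' @param p_transduce probability a cell is a transduced donor.
#' @param p_spread probability an untransduced cell becomes a recipient.
#' @param donor_egfp_level,donor_ha_level mean added intensity (ADU) of the
#'   eGFP and HA reporters in donor somata.
#' @param recipient_ha_level mean added HA intensity (ADU) in recipient somata.
#' @param nfh_level mean added morphology-channel intensity (ADU), all cells.
#' @param background_level flat background (ADU) in every channel.
#' @param noise_sd sd of additive Gaussian read noise (ADU); 0 = noiseless.
#' @param poisson_noise logical; also apply Poisson shot noise to the clean
#'   signal before adding read noise.
#' @param intensity_cv lognormal coefficient of variation of per-cell reporter
#'   levels (cell-to-cell expression variability).
#' @param soma_radius_mean,soma_radius_sd soma radius distribution (pixels).
#' @param min_separation minimum centre-to-centre distance (pixels).
#' @param p_mcherry probability a cell expresses the mCherry knockdown
#'   reporter (brain sections only).
#' @param mcherry_level mean added mCherry intensity (ADU).
#' @param seed integer RNG seed.
#' @return a validated list of class \code{syn_config}.
#' @export
syn_config <- function(n_cells = 200,
                       image_shape = c(512, 512),
                       pixel_size = 0.5,
                       p_transduce = 0.6,
                       p_spread = 0.2,
                       donor_egfp_level = 1000,
                       donor_ha_level = 1000,
                       recipient_ha_level = 600,
                       nfh_level = 1000,
                       background_level = 100,
                       noise_sd = 0,
                       poisson_noise = FALSE,
                       intensity_cv = 0.1,
                       soma_radius_mean = 8,
                       soma_radius_sd = 1,
                       min_separation = 25,
                       p_mcherry = 0.9,
                       mcherry_level = 800,
                       seed = 1L) {
  cfg <- list(n_cells = as.integer(n_cells), image_shape = as.integer(image_shape),
              pixel_size = pixel_size, p_transduce = p_transduce,
              p_spread = p_spread, donor_egfp_level = donor_egfp_level,
              donor_ha_level = donor_ha_level,
              recipient_ha_level = recipient_ha_level, nfh_level = nfh_level,
              background_level = background_level, noise_sd = noise_sd,
              poisson_noise = isTRUE(poisson_noise), intensity_cv = intensity_cv,
              soma_radius_mean = soma_radius_mean, soma_radius_sd = soma_radius_sd,
              min_separation = min_separation, p_mcherry = p_mcherry,
              mcherry_level = mcherry_level, seed = as.integer(seed))
  num <- unlist(cfg[!names(cfg) %in% "poisson_noise"])
  if (any(!is.finite(num))) stop("all configuration values must be finite")
  for (p in c("p_transduce", "p_spread", "p_mcherry")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must be in [0, 1]")
  }
  lv <- c("donor_egfp_level", "donor_ha_level", "recipient_ha_level",
          "nfh_level", "background_level", "noise_sd", "mcherry_level")
  if (any(unlist(cfg[lv]) < 0)) stop("intensity levels and noise_sd must be >= 0")
  if (cfg$soma_radius_mean <= 0) stop("soma_radius_mean must be > 0")
  if (cfg$n_cells < 1) stop("n_cells must be >= 1")
  if (length(cfg$image_shape) != 2L || any(cfg$image_shape < 8L)) {
    stop("image_shape must be two pixel counts >= 8")
  }
  class(cfg) <- "syn_config"
  cfg
}

# classes drawn first in RNG order; documented re-sampling oracle target
draw_classes <- function(n, p_transduce, p_spread) {
  cls <- character(n)
  for (i in seq_len(n)) {
    if (stats::runif(1) < p_transduce) {
      cls[i] <- "DONOR"
    } else if (stats::runif(1) < p_spread) {
      cls[i] <- "RECIPIENT"
    } else {
      cls[i] <- "UNTRANSDUCED"
    }
  }
  cls
}


# radii clamped to [3, mean + 3 sd] so soft-edge stamps (reach r + 3 px)
# cannot bleed across the min_separation gap between neighbouring somata
draw_radii <- function(n, config) {
  r <- stats::rnorm(n, config$soma_radius_mean, config$soma_radius_sd)
  pmin(pmax(3, r), config$soma_radius_mean + 3 * config$soma_radius_sd)
}

# jittered-grid placement: guarantees pairwise distance >= min_separation
place_cells <- function(n, shape, min_sep) {
  spacing <- ceiling(1.4 * min_sep)
  jit <- floor((spacing - min_sep) / 2)
  margin <- ceiling(min_sep / 2) + 4
  rows_avail <- shape[1] - 2 * margin
  cols_avail <- shape[2] - 2 * margin
  nr <- max(0L, floor(rows_avail / spacing) + 1L)
  nc <- max(0L, floor(cols_avail / spacing) + 1L)
  if (nr * nc < n) {
    stop(sprintf(paste0("cannot place %d cells at min_separation %g px in a ",
                        "%d x %d frame (capacity %d); enlarge the image or ",
                        "reduce min_separation"),
                 n, min_sep, shape[1], shape[2], nr * nc))
  }
  sites <- as.matrix(expand.grid(r = margin + spacing * (seq_len(nr) - 1L),
                                 c = margin + spacing * (seq_len(nc) - 1L)))
  sites <- sites[seq_len(n), , drop = FALSE]
  if (jit > 0) {
    sites[, 1] <- sites[, 1] + round(stats::runif(n, -jit, jit))
    sites[, 2] <- sites[, 2] + round(stats::runif(n, -jit, jit))
  }
  sites
}

# soft-edged disc stamp: weight 1 in the core, error-function falloff of
# width sigma=1 px across the rim, hard zero beyond r + 3 px
disc_stamp <- function(r) {
  ext <- ceiling(r) + 3L
  ix <- -ext:ext
  d <- sqrt(outer(ix^2, ix^2, "+"))
  w <- stats::pnorm(r - d)
  w[d > r + 3] <- 0
  w
}

add_stamp <- function(img, center, stamp) {
  ext <- (nrow(stamp) - 1L) %/% 2L
  r0 <- center[1] - ext; r1 <- center[1] + ext
  c0 <- center[2] - ext; c1 <- center[2] + ext
  sr <- max(1, r0):min(nrow(img), r1)
  sc <- max(1, c0):min(ncol(img), c1)
  img[sr, sc] <- img[sr, sc] + stamp[sr - r0 + 1L, sc - c0 + 1L]
  img
}

# render all soma stamps for one channel in a single pass; keeping the frame
# a local matrix lets subassignment mutate in place instead of copying the
# full frame per cell
render_channel <- function(shape, centers, radii, levels) {
  img <- matrix(0, shape[1], shape[2])
  for (i in which(levels > 0)) {
    st <- disc_stamp(radii[i]) * levels[i]
    ext <- (nrow(st) - 1L) %/% 2L
    r0 <- centers[i, 1] - ext; r1 <- centers[i, 1] + ext
    c0 <- centers[i, 2] - ext; c1 <- centers[i, 2] + ext
    sr <- max(1, r0):min(shape[1], r1)
    sc <- max(1, c0):min(shape[2], c1)
    img[sr, sc] <- img[sr, sc] + st[sr - r0 + 1L, sc - c0 + 1L]
  }
  img
}

apply_noise <- function(clean, cfg) {
  out <- clean
  if (cfg$poisson_noise) {
    out <- matrix(stats::rpois(length(out), lambda = pmax(out, 0)), nrow(out))
  }
  if (cfg$noise_sd > 0) {
    out <- out + stats::rnorm(length(out), sd = cfg$noise_sd)
  }
  pmin(pmax(out, 0), 2^16 - 1)
}

#' Generate a synthetic neuronal culture
#'
#' Produces channels \code{NFH} (all cells), \code{eGFP} (donors only) and
#' \code{HA} (donors and recipients) plus the per-cell ground truth. In the
#' noiseless case recipient and untransduced eGFP pixels equal the background
#' exactly, while every donor soma pixel strictly exceeds it.
#'
#' @param config a \code{\link{syn_config}}.
#' @return list with elements \code{image} (an \code{\link{mcimage}}) and
#'   \code{truth} (data frame: cell_id, true_class, center_row, center_col,
#'   radius_px, true_nfh, true_egfp, true_ha — totals including background).
#' @export
generate_culture <- function(config) {
  stopifnot(inherits(config, "syn_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  n <- config$n_cells
  cls <- draw_classes(n, config$p_transduce, config$p_spread)
  centers <- place_cells(n, config$image_shape, config$min_separation)
  radii <- draw_radii(n, config)
  jit <- matrix(exp(stats::rnorm(3 * n, 0, config$intensity_cv)), ncol = 3)
  colnames(jit) <- c("NFH", "eGFP", "HA")

  lv_nfh <- config$nfh_level * jit[, "NFH"]
  lv_egfp <- ifelse(cls == "DONOR", config$donor_egfp_level * jit[, "eGFP"], 0)
  lv_ha <- ifelse(cls == "DONOR", config$donor_ha_level * jit[, "HA"],
                  ifelse(cls == "RECIPIENT",
                         config$recipient_ha_level * jit[, "HA"], 0))

  sh <- config$image_shape
  chans <- list(NFH = render_channel(sh, centers, radii, lv_nfh),
                eGFP = render_channel(sh, centers, radii, lv_egfp),
                HA = render_channel(sh, centers, radii, lv_ha))
  chans <- lapply(chans, function(m) apply_noise(m + config$background_level, config))

  truth <- data.frame(
    cell_id = seq_len(n), true_class = cls,
    center_row = centers[, 1], center_col = centers[, 2],
    radius_px = radii,
    true_nfh = config$background_level + lv_nfh,
    true_egfp = config$background_level + lv_egfp,
    true_ha = config$background_level + lv_ha,
    region = "NONE", stringsAsFactors = FALSE
  )
  list(image = mcimage(chans, config$pixel_size), truth = truth)
}

#' Region layout for a synthetic brain section
#'
#' Partitions the section footprint into cortical and subcortical regions by
#' a horizontal split: the top \code{cortical_fraction} of footprint rows is
#' cortical, the remainder subcortical.
#'
#' @param cortical_fraction fraction of rows assigned to cortex, in [0, 1].
#' @param footprint \code{"full"} (whole frame) or \code{"ellipse"}
#'   (inscribed ellipse, emulating a coronal section outline).
#' @return a list of class \code{region_layout}.
#' @export
region_layout <- function(cortical_fraction = 0.4,
                          footprint = c("full", "ellipse")) {
  footprint <- match.arg(footprint)
  if (cortical_fraction < 0 || cortical_fraction > 1) {
    stop("cortical_fraction must be in [0, 1]")
  }
  structure(list(cortical_fraction = cortical_fraction, footprint = footprint),
            class = "region_layout")
}

build_region_mask <- function(layout, shape, pixel_size) {
  fp <- matrix(TRUE, shape[1], shape[2])
  if (layout$footprint == "ellipse") {
    rc <- (shape[1] + 1) / 2; cc <- (shape[2] + 1) / 2
    d <- outer(((seq_len(shape[1]) - rc) / (shape[1] / 2))^2,
               ((seq_len(shape[2]) - cc) / (shape[2] / 2))^2, "+")
    fp <- d <= 1
  }
  split_row <- floor(shape[1] * layout$cortical_fraction)
  reg <- matrix(0L, shape[1], shape[2])
  if (split_row >= 1) reg[seq_len(split_row), ] <- 1L
  reg[reg == 0L] <- 2L
  reg[!fp] <- 0L
  region_mask(reg, fp, pixel_size)
}

#' Region mask of a brain section
#'
#' @param regions integer matrix: 0 outside, 1 cortical, 2 subcortical.
#' @param footprint logical matrix: TRUE inside the section outline.
#' @param pixel_size micrometres per pixel.
#' @return a list of class \code{region_mask}.
#' @export
region_mask <- function(regions, footprint, pixel_size) {
  stopifnot(is.matrix(regions), is.matrix(footprint),
            all(dim(regions) == dim(footprint)))
  if (!all(regions %in% 0:2)) stop("regions must contain only 0, 1, 2")
  if (any(regions > 0 & !footprint)) {
    stop("regions must lie inside the section footprint")
  }
  storage.mode(regions) <- "integer"
  structure(list(regions = regions, footprint = footprint,
                 pixel_size = pixel_size,
                 region_names = c("CORTICAL", "SUBCORTICAL")),
            class = "region_mask")
}

#' Section area in square millimetres
#' @param mask a \code{\link{region_mask}}.
#' @export
section_area_mm2 <- function(mask) {
  stopifnot(inherits(mask, "region_mask"))
  sum(mask$footprint) * mask$pixel_size^2 / 1e6
}

#' Generate a synthetic brain-section mosaic
#'
#' Channels \code{mCherry} (knockdown-reporter coverage), \code{eGFP} and
#' \code{HA}. Per cell: donor with \code{p_transduce}; otherwise the cell
#' carries the mCherry reporter with \code{p_mcherry}, and an mCherry+
#' non-donor becomes a recipient with \code{p_spread}. Ground-truth rows
#' carry the region (cortical/subcortical) containing the soma centre.
#'
#' @param config a \code{\link{syn_config}}.
#' @param layout a \code{\link{region_layout}}.
#' @return list with \code{image}, \code{truth} (adds \code{true_mcherry} and
#'   \code{region}), and \code{region_mask}.
#' @export
generate_brain_section <- function(config, layout = region_layout()) {
  stopifnot(inherits(config, "syn_config"), inherits(layout, "region_layout"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  n <- config$n_cells
  # class + mCherry draws, fixed order: u (donor), m (mCherry), v (spread)
  cls <- character(n); mch <- logical(n)
  for (i in seq_len(n)) {
    if (stats::runif(1) < config$p_transduce) {
      cls[i] <- "DONOR"; mch[i] <- TRUE
      stats::runif(2)  # keep draw alignment with non-donor branch
    } else {
      mch[i] <- stats::runif(1) < config$p_mcherry
      v <- stats::runif(1)
      cls[i] <- if (mch[i] && v < config$p_spread) "RECIPIENT" else "UNTRANSDUCED"
    }
  }
  centers <- place_cells(n, config$image_shape, config$min_separation)
  radii <- draw_radii(n, config)
  jit <- matrix(exp(stats::rnorm(3 * n, 0, config$intensity_cv)), ncol = 3)

  lv_mch <- ifelse(mch, config$mcherry_level * jit[, 1], 0)
  lv_egfp <- ifelse(cls == "DONOR", config$donor_egfp_level * jit[, 2], 0)
  lv_ha <- ifelse(cls == "DONOR", config$donor_ha_level * jit[, 3],
                  ifelse(cls == "RECIPIENT",
                         config$recipient_ha_level * jit[, 3], 0))

  sh <- config$image_shape
  rmask <- build_region_mask(layout, sh, config$pixel_size)
  # keep somata inside the footprint: snap centres outside it onto it
  inside <- rmask$footprint[cbind(centers[, 1], centers[, 2])]
  if (any(!inside)) {
    idx <- which(rmask$footprint, arr.ind = TRUE)
    for (i in which(!inside)) {
      d2 <- (idx[, 1] - centers[i, 1])^2 + (idx[, 2] - centers[i, 2])^2
      centers[i, ] <- idx[which.min(d2), ]
    }
  }
  chans <- list(mCherry = render_channel(sh, centers, radii, lv_mch),
                eGFP = render_channel(sh, centers, radii, lv_egfp),
                HA = render_channel(sh, centers, radii, lv_ha))
  chans <- lapply(chans, function(m) apply_noise(m + config$background_level, config))
  regv <- rmask$regions[cbind(centers[, 1], centers[, 2])]
  truth <- data.frame(
    cell_id = seq_len(n), true_class = cls,
    center_row = centers[, 1], center_col = centers[, 2],
    radius_px = radii,
    true_mcherry = config$background_level + lv_mch,
    true_egfp = config$background_level + lv_egfp,
    true_ha = config$background_level + lv_ha,
    region = c("NONE", "CORTICAL", "SUBCORTICAL")[regv + 1L],
    stringsAsFactors = FALSE
  )
  list(image = mcimage(chans, config$pixel_size), truth = truth,
       region_mask = rmask)
}

#' True label map from generator ground truth
#'
#' Renders the exact soma footprints (hard discs at the true radii) as a
#' label map — the segmentation-free oracle used when a test must isolate a
#' downstream stage from segmentation error.
#'
#' @param truth ground-truth data frame from a generator.
#' @param shape image shape c(rows, cols).
#' @return a \code{labelmap} (provenance MANUAL).
#' @export
truth_labelmap <- function(truth, shape) {
  lab <- matrix(0L, shape[1], shape[2])
  for (i in seq_len(nrow(truth))) {
    r <- truth$radius_px[i]; ext <- ceiling(r)
    rr <- max(1, truth$center_row[i] - ext):min(shape[1], truth$center_row[i] + ext)
    cc <- max(1, truth$center_col[i] - ext):min(shape[2], truth$center_col[i] + ext)
    d <- sqrt(outer((rr - truth$center_row[i])^2, (cc - truth$center_col[i])^2, "+"))
    blk <- lab[rr, cc]
    blk[d <= r] <- truth$cell_id[i]
    lab[rr, cc] <- blk
  }
  labelmap(lab, provenance = "MANUAL")
}

#' Generate a puncta field
#'
#' A culture in which an exact fraction of cells carries bright intracellular
#' aggregation puncta in the \code{HA} channel (round(puncta_fraction *
#' n_cells) cells, chosen at random), each bearing \code{n_puncta} small
#' spots of amplitude \code{puncta_level} ADU.
#'
#' @param config a \code{\link{syn_config}}.
#' @param puncta_fraction fraction of cells bearing puncta.
#' @param n_puncta puncta per positive cell.
#' @param puncta_radius punctum radius in pixels.
#' @param puncta_level added punctum amplitude (ADU).
#' @return list with \code{image}, \code{truth} (adds \code{has_puncta},
#'   \code{n_puncta}).
#' @export
generate_puncta_field <- function(config, puncta_fraction = 0.15,
                                  n_puncta = 3L, puncta_radius = 1.5,
                                  puncta_level = 5000) {
  stopifnot(inherits(config, "syn_config"))
  base <- generate_culture(config)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 101L)
  n <- config$n_cells
  n_pos <- round(puncta_fraction * n)
  pos <- sort(sample.int(n, n_pos))
  ha <- base$image$channels$HA
  # hard-disc punctum stamp: sharp spots the top-hat passes cleanly
  pext <- ceiling(puncta_radius)
  pd <- sqrt(outer((-pext:pext)^2, (-pext:pext)^2, "+"))
  pstamp <- (pd <= puncta_radius) * puncta_level
  for (i in pos) {
    r_soma <- base$truth$radius_px[i]
    rot <- stats::runif(1, 0, 2 * pi)  # per-cell rotation of the spot ring
    for (k in seq_len(n_puncta)) {
      # evenly spaced on a ring at 0.55 r: keeps puncta separated and inside
      ang <- rot + 2 * pi * (k - 1) / n_puncta
      rad <- 0.55 * r_soma
      ctr <- c(round(base$truth$center_row[i] + rad * sin(ang)),
               round(base$truth$center_col[i] + rad * cos(ang)))
      ha <- add_stamp(ha, ctr, pstamp)
    }
  }
  ha <- pmin(ha, 2^16 - 1)
  base$image$channels$HA <- ha
  base$truth$has_puncta <- seq_len(n) %in% pos
  base$truth$n_puncta <- ifelse(base$truth$has_puncta, n_puncta, 0L)
  base
}

# chain-code length of a digital straight segment, in pixels
segment_chain_length <- function(dr, dc) {
  a <- abs(dr); b <- abs(dc)
  (max(a, b) - min(a, b)) + min(a, b) * sqrt(2)
}

# rasterize a straight segment (Bresenham-like via rounding the longer axis)
raster_segment <- function(p0, p1) {
  nsteps <- max(abs(p1 - p0))
  if (nsteps == 0) return(matrix(p0, ncol = 2))
  t <- seq(0, 1, length.out = nsteps + 1)
  unique(cbind(round(p0[1] + t * (p1[1] - p0[1])),
               round(p0[2] + t * (p1[2] - p0[2]))))
}

#' Generate a neurite field with analytically known lengths
#'
#' Places neurons whose neurites are digital straight segments (and optional
#' Y-branches) drawn in the morphology channel; ground truth records the
#' chain-code length (orthogonal step 1 px, diagonal step sqrt(2) px, times
#' pixel size) of every neurite outside the soma.
#'
#' @param config a \code{\link{syn_config}}; classes are ignored (all cells
#'   untransduced), only the morphology channel carries neurites.
#' @param neurite_spec list, one element per neuron, each a list of segments;
#'   a segment is \code{c(dr1, dc1)} or a two-row matrix of consecutive
#'   offsets for branched paths. \code{NULL} = one straight 100 px neurite
#'   per neuron, direction alternating.
#' @return list with \code{image}, \code{truth}, \code{soma_map} (true label
#'   map), and \code{neurite_truth} data frame (neuron_id, n_primary,
#'   total_length_um, mean_single_length_um).
#' @export
generate_neurite_field <- function(config, neurite_spec = NULL) {
  stopifnot(inherits(config, "syn_config"))
  cfg <- config
  cfg$p_transduce <- 0; cfg$p_spread <- 0
  base <- generate_culture(cfg)
  n <- cfg$n_cells
  sh <- cfg$image_shape
  if (is.null(neurite_spec)) {
    dirs <- list(c(0, 100), c(100, 0), c(0, -100), c(-100, 0))
    neurite_spec <- lapply(seq_len(n), function(i) list(dirs[[(i - 1) %% 4 + 1]]))
  }
  nfh <- base$image$channels$NFH
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    r_soma <- base$truth$radius_px[i]
    ctr <- c(base$truth$center_row[i], base$truth$center_col[i])
    segs <- neurite_spec[[i]]
    lens <- numeric(0)
    for (sg in segs) {
      if (is.null(dim(sg))) sg <- matrix(sg, ncol = 2, byrow = TRUE)
      # start 2 px beyond the soma rim along the first segment direction
      u <- sg[1, ] / sqrt(sum(sg[1, ]^2))
      p <- round(ctr + u * (r_soma + 2))
      total_len <- 0
      for (j in seq_len(nrow(sg))) {
        q <- p + sg[j, ]
        pix <- raster_segment(p, q)
        pix <- pix[pix[, 1] >= 1 & pix[, 1] <= sh[1] &
                   pix[, 2] >= 1 & pix[, 2] <= sh[2], , drop = FALSE]
        nfh[pix] <- pmax(nfh[pix], cfg$background_level + cfg$nfh_level)
        total_len <- total_len + segment_chain_length(sg[j, 1], sg[j, 2])
        p <- q
      }
      lens <- c(lens, total_len)
    }
    rows[[i]] <- data.frame(
      neuron_id = i, n_primary = length(segs),
      total_length_um = sum(lens) * cfg$pixel_size,
      mean_single_length_um = mean(lens) * cfg$pixel_size
    )
  }
  base$image$channels$NFH <- nfh
  list(image = base$image, truth = base$truth,
       soma_map = truth_labelmap(base$truth, sh),
       neurite_truth = do.call(rbind, rows))
}

#' Generate flow-cytometry-style event tables
#'
#' Emulates annexin-V FITC readout gated on an mCherry expression reporter:
#' expressing events draw mCherry from a bright lognormal and FITC around
#' \code{fitc_median}; non-expressing events sit at autofluorescence levels.
#'
#' @param n_events number of events.
#' @param frac_expressing fraction of mCherry-expressing events.
#' @param fitc_median median FITC of expressing events (ADU).
#' @param fitc_cv lognormal CV of FITC.
#' @param seed RNG seed.
#' @return data frame with columns \code{mCherry}, \code{FITC},
#'   \code{expressing} (ground truth).
#' @export
generate_flow_events <- function(n_events = 5000, frac_expressing = 0.7,
                                 fitc_median = 1000, fitc_cv = 0.3,
                                 seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  expressing <- stats::runif(n_events) < frac_expressing
  mch <- ifelse(expressing,
                stats::rlnorm(n_events, log(5000), 0.4),
                stats::rlnorm(n_events, log(50), 0.5))
  fitc <- ifelse(expressing,
                 stats::rlnorm(n_events, log(fitc_median), sqrt(log(1 + fitc_cv^2))),
                 stats::rlnorm(n_events, log(80), 0.5))
  data.frame(mCherry = mch, FITC = fitc, expressing = expressing)
}

# save/restore of the global RNG state so generators are pure in (config, seed)
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Simulate measured per-cell records without pixel rendering
#'
#' Draws the same generative model as \code{\link{generate_culture}} but
#' emits the measured quantities directly: per-cell background-subtracted
#' mean intensities with standard error \code{noise_sd / sqrt(area)},
#' exactly what \code{\link{measure_cell_intensities}} recovers from pixels.
#' Used for large replication studies (e.g. power analyses over hundreds of
#' fields) where rendering adds nothing to the stages under test.
#'
#' @param config a \code{\link{syn_config}}.
#' @return list with \code{records} (a cell-records data frame compatible
#'   with \code{\link{classify_in_vitro}}) and \code{truth}.
#' @export
simulate_cell_records <- function(config) {
  stopifnot(inherits(config, "syn_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  n <- config$n_cells
  cls <- draw_classes(n, config$p_transduce, config$p_spread)
  radii <- draw_radii(n, config)
  area <- pi * radii^2
  jit <- matrix(exp(stats::rnorm(3 * n, 0, config$intensity_cv)), ncol = 3)
  lv_egfp <- ifelse(cls == "DONOR", config$donor_egfp_level * jit[, 2], 0)
  lv_ha <- ifelse(cls == "DONOR", config$donor_ha_level * jit[, 3],
                  ifelse(cls == "RECIPIENT",
                         config$recipient_ha_level * jit[, 3], 0))
  se <- config$noise_sd / sqrt(area)
  rec <- data.frame(
    cell_id = seq_len(n),
    centroid_row = NA_real_, centroid_col = NA_real_,
    area_px = area, area_um2 = area * config$pixel_size^2,
    NFH_raw = config$background_level + config$nfh_level * jit[, 1],
    eGFP_raw = config$background_level + lv_egfp,
    HA_raw = config$background_level + lv_ha,
    NFH_bg = config$nfh_level * jit[, 1],
    eGFP_bg = 0, HA_bg = 0, NFH_bg_signed = config$nfh_level * jit[, 1],
    eGFP_bg_signed = lv_egfp + stats::rnorm(n, 0, se),
    HA_bg_signed = lv_ha + stats::rnorm(n, 0, se),
    class_label = "UNSET", puncta_count = NA_integer_,
    region = "NONE", stringsAsFactors = FALSE
  )
  rec$eGFP_bg <- pmax(rec$eGFP_bg_signed, 0)
  rec$HA_bg <- pmax(rec$HA_bg_signed, 0)
  truth <- data.frame(cell_id = seq_len(n), true_class = cls,
                      stringsAsFactors = FALSE)
  list(records = rec, truth = truth)
}
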