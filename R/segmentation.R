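# Cell-body detection from the morphology channel.
#
# The detector mirrors the common Fiji workflow: an adaptive local-mean
# threshold (pixel > mean of a square window minus/plus an offset) on the
# neurofilament channel, connected-component labelling, an area filter, and
# an optional distance-transform watershed to split touching somata.

# local arithmetic mean in a square window via an integral image, edges
# handled by replicate padding; exact, O(n) in pixels
local_mean <- function(img, window) {
  w2 <- (window - 1L) %/% 2L
  nr <- nrow(img); nc <- ncol(img)
  pad <- img[c(rep(1L, w2), seq_len(nr), rep(nr, w2)),
             c(rep(1L, w2), seq_len(nc), rep(nc, w2)), drop = FALSE]
  S <- apply(pad, 2, cumsum)
  S <- t(apply(S, 1, cumsum))
  S <- rbind(0, cbind(0, S))
  i1 <- seq_len(nr); j1 <- seq_len(nc)
  box <- S[i1 + window, j1 + window, drop = FALSE] -
    S[i1, j1 + window, drop = FALSE] -
    S[i1 + window, j1, drop = FALSE] + S[i1, j1, drop = FALSE]
  box / (window^2)
}

# renumber labels 1..K in raster order (row-major) of each label's first pixel
renumber_raster <- function(lab) {
  nr <- nrow(lab)
  idx <- which(lab > 0)
  if (length(idx) == 0) {
    storage.mode(lab) <- "integer"
    return(lab)
  }
  # row-major scan index of each pixel
  rm_idx <- ((idx - 1L) %% nr) * ncol(lab) + ((idx - 1L) %/% nr) + 1L
  first <- tapply(rm_idx, lab[idx], min)
  ord <- names(sort(first))
  remap <- integer(max(lab))
  remap[as.integer(ord)] <- seq_along(ord)
  out <- lab
  out[idx] <- remap[lab[idx]]
  storage.mode(out) <- "integer"
  out
}

#' Segment neuronal cell bodies by adaptive local-mean thresholding
#'
#' A pixel is foreground when it exceeds the local mean of a square window
#' by more than \code{offset} ADU; foreground is labelled into connected
#' components, components outside \code{[min_area, max_area]} px^2 are
#' dropped, and (optionally) touching somata are split by a
#' distance-transform watershed. Because the threshold is relative to the
#' local mean, adding a constant to the whole channel leaves the result
#' unchanged.
#'
#' @param image an \code{\link{mcimage}}.
#' @param morphology_channel channel name carrying cell-body signal
#'   (e.g. \code{"NFH"}).
#' @param window odd window edge length in pixels (>= 3).
#' @param offset ADU above the local mean required for foreground; raise it
#'   to roughly 3x the read-noise sd on noisy acquisitions.
#' @param min_area,max_area component area bounds in px^2.
#' @param split_touching logical: apply watershed splitting.
#' @return a \code{\link{labelmap}} with provenance \code{AUTO}, labels
#'   numbered 1..K in raster order of first pixel.
#' @export
segment_somata <- function(image, morphology_channel = "NFH",
                           window = 51L, offset = 10,
                           min_area = 50, max_area = Inf,
                           split_touching = FALSE) {
  img <- get_channel(image, morphology_channel)
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) stop("`window` must be odd and >= 3")
  if (window >= min(dim(img))) stop("`window` must be smaller than the image")
  mask <- img > (local_mean(img, window) + offset)
  if (!any(mask)) {
    return(labelmap(matrix(0L, nrow(img), ncol(img)), provenance = "AUTO"))
  }
  m <- matrix(as.numeric(mask), nrow(img))
  if (split_touching) {
    dm <- EBImage::distmap(m)
    lab <- EBImage::watershed(dm, tolerance = 1, ext = 1)
    lab <- as.matrix(EBImage::imageData(lab))
  } else {
    lab <- as.matrix(EBImage::imageData(EBImage::bwlabel(m)))
  }
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_area & areas <= max_area)
  lab[!(lab %in% keep)] <- 0
  labelmap(renumber_raster(lab), provenance = "AUTO")
}

#' Centroids and areas of a label map
#'
#' @param map a \code{\link{labelmap}}.
#' @param pixel_size micrometres per pixel (for areas in um^2).
#' @return data frame: cell_id, centroid_row, centroid_col, area_px, area_um2.
#' @export
label_properties <- function(map, pixel_size = 1) {
  stopifnot(inherits(map, "labelmap"))
  lab <- map$labels
  idx <- which(lab > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(data.frame(cell_id = integer(0), centroid_row = numeric(0),
                      centroid_col = numeric(0), area_px = numeric(0),
                      area_um2 = numeric(0)))
  }
  l <- lab[idx]
  ids <- sort(unique(l))
  f <- factor(l, levels = ids)  # numeric level order, not lexicographic
  out <- data.frame(
    cell_id = ids,
    centroid_row = as.numeric(tapply(idx[, 1], f, mean)),
    centroid_col = as.numeric(tapply(idx[, 2], f, mean)),
    area_px = as.numeric(tabulate(as.integer(f)))
  )
  out$area_um2 <- out$area_px * pixel_size^2
  out
}
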