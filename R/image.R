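#' Multi-channel fluorescence image
#'
#' Container for a single 2D field of view: a named set of equally shaped
#' intensity matrices (one per fluorescence channel, in arbitrary detector
#' units, ADU), the pixel size in micrometres, and the acquisition bit depth.
#'
#' @param channels named list of numeric matrices, all the same dimension.
#'   Typical channel names: \code{"NFH"} (neurofilament morphology),
#'   \code{"eGFP"}, \code{"HA"}, \code{"mCherry"}, \code{"FITC"}.
#' @param pixel_size pixel edge length in micrometres per pixel (> 0).
#' @param bit_depth integer bit depth of the detector (default 16).
#' @return an object of class \code{mcimage}.
#' @export
mcimage <- function(channels, pixel_size, bit_depth = 16L) {
  if (!is.list(channels) || is.null(names(channels)) ||
      any(!nzchar(names(channels)))) {
    stop("`channels` must be a named list of matrices")
  }
  dims <- lapply(channels, dim)
  if (any(vapply(channels, function(m) !is.matrix(m) || !is.numeric(m), TRUE))) {
    stop("every channel must be a numeric matrix")
  }
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L) {
    stop("all channels must have identical dimensions")
  }
  if (any(vapply(channels, function(m) any(!is.finite(m)), TRUE))) {
    stop("channel intensities must be finite")
  }
  if (any(vapply(channels, min, 0) < 0)) {
    stop("channel intensities must be non-negative")
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L ||
      !is.finite(pixel_size) || pixel_size <= 0) {
    stop("`pixel_size` must be a single positive number (um/pixel)")
  }
  structure(
    list(channels = channels, pixel_size = pixel_size,
         bit_depth = as.integer(bit_depth)),
    class = "mcimage"
  )
}

#' @export
print.mcimage <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<mcimage> %d x %d px, %.3g um/px, %d-bit\n",
              d[1], d[2], x$pixel_size, x$bit_depth))
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.mcimage <- function(x) dim(x$channels[[1]])

#' Extract one channel as a matrix
#' @param image an \code{mcimage}.
#' @param channel channel name.
#' @return numeric matrix of intensities (ADU).
#' @export
get_channel <- function(image, channel) {
  stopifnot(inherits(image, "mcimage"))
  if (!channel %in% names(image$channels)) {
    stop(sprintf("channel '%s' not present (have: %s)", channel,
                 paste(names(image$channels), collapse = ", ")))
  }
  image$channels[[channel]]
}

#' Label map of segmented cell bodies
#'
#' Integer-labelled segmentation: 0 is background, labels 1..K index cells.
#'
#' @param labels integer matrix, non-negative.
#' @param provenance \code{"AUTO"} (from \code{\link{segment_somata}}) or
#'   \code{"MANUAL"} (imported mask).
#' @return an object of class \code{labelmap}.
#' @export
labelmap <- function(labels, provenance = c("AUTO", "MANUAL")) {
  provenance <- match.arg(provenance)
  if (!is.matrix(labels) || any(!is.finite(labels)) || any(labels < 0)) {
    stop("`labels` must be a non-negative integer matrix")
  }
  if (any(labels != round(labels))) stop("labels must be integers")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, provenance = provenance), class = "labelmap")
}

#' @export
print.labelmap <- function(x, ...) {
  cat(sprintf("<labelmap> %d x %d px, %d cells, provenance %s\n",
              nrow(x$labels), ncol(x$labels), n_cells(x), x$provenance))
  invisible(x)
}

#' Number of labelled cells in a label map
#' @param map a \code{labelmap}.
#' @export
n_cells <- function(map) {
  stopifnot(inherits(map, "labelmap"))
  length(setdiff(unique(as.vector(map$labels)), 0L))
}

# ---- TIFF I/O ---------------------------------------------------------------
# Multi-page TIFF, one channel per page, plus a sidecar JSON naming channels,
# pixel size and bit depth. tiff::writeTIFF stores [0,1]-scaled samples, so
# ADU are mapped onto the full integer range of the declared bit depth.

#' Write a multi-channel image to TIFF + sidecar JSON
#'
#' @param image an \code{mcimage}.
#' @param path output TIFF path; the sidecar is written at \code{<path>.json}.
#' @return \code{path}, invisibly.
#' @export
write_mcimage <- function(image, path) {
  stopifnot(inherits(image, "mcimage"))
  maxval <- 2^image$bit_depth - 1
  pages <- lapply(image$channels, function(m) pmin(pmax(m, 0), maxval) / maxval)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  meta <- list(channels = as.list(names(image$channels)),
               pixel_size_um = image$pixel_size,
               bit_depth = image$bit_depth)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a multi-channel image written by \code{\link{write_mcimage}}
#'
#' @param path TIFF path with sidecar \code{<path>.json}.
#' @return an \code{mcimage}.
#' @export
read_mcimage <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop("sidecar JSON not found: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  maxval <- 2^meta$bit_depth - 1
  # writeTIFF scales [0,1] to 16-bit sample range; undo to the declared depth
  chans <- lapply(pages, function(p) {
    m <- p * (maxval / (2^16 - 1))
    storage.mode(m) <- "double"
    m
  })
  names(chans) <- unlist(meta$channels)
  mcimage(chans, pixel_size = meta$pixel_size_um,
          bit_depth = as.integer(meta$bit_depth))
}

#' Write a label map as 16-bit TIFF
#' @param map a \code{labelmap}.
#' @param path output path.
#' @export
write_label_tiff <- function(map, path) {
  stopifnot(inherits(map, "labelmap"))
  if (max(map$labels) > 65535) stop("more than 65535 labels; cannot store in 16-bit TIFF")
  tiff::writeTIFF(map$labels / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' Import a manually drawn label mask from TIFF
#'
#' Labels are preserved verbatim and the map is tagged with provenance
#' \code{MANUAL} (e.g. cell bodies outlined by hand in an image editor).
#'
#' @param path TIFF path holding an integer label image.
#' @return a \code{labelmap} with provenance \code{MANUAL}.
#' @export
import_label_mask <- function(path) {
  pg <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (is.list(pg)) pg <- pg[[1]]
  if (any(pg != round(pg))) stop("label mask must contain integer pixels")
  labelmap(pg, provenance = "MANUAL")
}
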