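# Skeleton-based neurite morphometry.
#
# The neurite mask (morphology mask minus soma footprints) is thinned to a
# 1-px skeleton (Zhang-Suen), the skeleton is turned into a pixel graph with
# chain-code edge weights (1 for orthogonal steps, sqrt(2) for diagonal,
# redundant diagonals pruned), components are assigned to the nearest soma,
# and per-neuron totals and primary-branch lengths are read off the graph.

# one Zhang-Suen pass; vectorized over the whole frame
zs_neighbors <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  z <- matrix(0L, nr + 2L, nc + 2L)
  z[2:(nr + 1), 2:(nc + 1)] <- m
  shift <- function(dr, dc) z[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  list(p2 = shift(-1, 0), p3 = shift(-1, 1), p4 = shift(0, 1),
       p5 = shift(1, 1), p6 = shift(1, 0), p7 = shift(1, -1),
       p8 = shift(0, -1), p9 = shift(-1, -1))
}

#' Skeletonize a binary mask (Zhang-Suen thinning)
#'
#' @param mask logical or 0/1 matrix.
#' @return integer 0/1 matrix of the 1-px-wide 8-connected skeleton.
#' @export
skeletonize <- function(mask) {
  m <- matrix(as.integer(mask > 0), nrow(mask))
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      nb <- zs_neighbors(m)
      B <- nb$p2 + nb$p3 + nb$p4 + nb$p5 + nb$p6 + nb$p7 + nb$p8 + nb$p9
      seqs <- list(nb$p2, nb$p3, nb$p4, nb$p5, nb$p6, nb$p7, nb$p8, nb$p9, nb$p2)
      A <- matrix(0L, nrow(m), ncol(m))
      for (k in 1:8) A <- A + (seqs[[k]] == 0L & seqs[[k + 1]] == 1L)
      if (pass == 1) {
        cond <- nb$p2 * nb$p4 * nb$p6 == 0L & nb$p4 * nb$p6 * nb$p8 == 0L
      } else {
        cond <- nb$p2 * nb$p4 * nb$p8 == 0L & nb$p2 * nb$p6 * nb$p8 == 0L
      }
      del <- m == 1L & B >= 2L & B <= 6L & A == 1L & cond
      if (any(del)) {
        m[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# skeleton pixel graph: vertices are skeleton pixels, edges between
# 8-neighbours; a diagonal edge is dropped when the two pixels share a
# skeleton orthogonal neighbour (standard chain-code redundancy pruning)
skeleton_graph <- function(skel) {
  idx <- which(skel == 1L, arr.ind = TRUE)
  if (nrow(idx) == 0) return(NULL)
  nr <- nrow(skel)
  key <- (idx[, 2] - 1L) * nr + idx[, 1]
  vid <- integer(nrow(skel) * ncol(skel))
  vid[key] <- seq_along(key)
  has <- function(r, c) {
    ok <- r >= 1 & r <= nr & c >= 1 & c <= ncol(skel)
    out <- logical(length(r)); out[ok] <- skel[cbind(r[ok], c[ok])] == 1L
    out
  }
  edges <- list(); wts <- list(); k <- 0
  for (d in list(c(0, 1), c(1, 0))) {
    r2 <- idx[, 1] + d[1]; c2 <- idx[, 2] + d[2]
    ok <- has(r2, c2)
    if (any(ok)) {
      k <- k + 1
      edges[[k]] <- rbind(vid[key[ok]], vid[(c2[ok] - 1L) * nr + r2[ok]])
      wts[[k]] <- rep(1, sum(ok))
    }
  }
  for (d in list(c(1, 1), c(1, -1))) {
    r2 <- idx[, 1] + d[1]; c2 <- idx[, 2] + d[2]
    ok <- has(r2, c2)
    # prune if either shared orthogonal neighbour is skeleton
    shared <- has(idx[, 1] + d[1], idx[, 2]) | has(idx[, 1], idx[, 2] + d[2])
    ok <- ok & !shared
    if (any(ok)) {
      k <- k + 1
      edges[[k]] <- rbind(vid[key[ok]], vid[(c2[ok] - 1L) * nr + r2[ok]])
      wts[[k]] <- rep(sqrt(2), sum(ok))
    }
  }
  if (k == 0) {
    g <- igraph::make_empty_graph(n = nrow(idx), directed = FALSE)
    return(list(graph = g, coords = idx))
  }
  el <- do.call(cbind, edges)
  g <- igraph::graph_from_edgelist(t(el), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(idx) - igraph::vcount(g)))
  igraph::E(g)$weight <- unlist(wts)
  list(graph = g, coords = idx)
}

#' Measure neurite morphometry per neuron
#'
#' The morphology channel is thresholded (same adaptive local-mean rule as
#' \code{\link{segment_somata}}), soma footprints are removed, the remainder
#' is skeletonized, and each skeleton component is assigned to the nearest
#' soma centroid. Lengths use chain-code steps (1 px orthogonal, sqrt(2) px
#' diagonal) times the pixel size. Primary neurites are skeleton branches
#' entering a 2-px dilation of the soma boundary; each primary's
#' "single neurite length" is its longest root-to-tip geodesic.
#'
#' @param image an \code{\link{mcimage}}.
#' @param morphology_channel channel carrying neurites (e.g. \code{"NFH"}).
#' @param soma_map a \code{\link{labelmap}} of cell bodies in the same frame.
#' @param window,offset adaptive-threshold parameters for the neurite mask.
#' @param soma_dilate_px the soma footprint is dilated by this many pixels
#'   before subtraction, suppressing the bright halo at the soma rim that
#'   would otherwise skeletonize into a spurious loop (default 3).
#' @param max_assign_dist_px skeleton components farther than this from every
#'   soma centroid are left unassigned (default Inf).
#' @return data frame, one row per neuron: \code{neuron_id},
#'   \code{mean_single_neurite_length_um}, \code{total_tree_length_um},
#'   \code{n_primary_neurites}, \code{soma_area_px}, \code{soma_area_um2}.
#' @export
measure_neurites <- function(image, morphology_channel = "NFH", soma_map,
                             window = 51L, offset = 10, soma_dilate_px = 3L,
                             max_assign_dist_px = Inf) {
  stopifnot(inherits(soma_map, "labelmap"))
  img <- get_channel(image, morphology_channel)
  if (!all(dim(img) == dim(soma_map$labels))) {
    stop("soma_map shape does not match the image")
  }
  props <- label_properties(soma_map, image$pixel_size)
  empty <- data.frame(neuron_id = integer(0),
                      mean_single_neurite_length_um = numeric(0),
                      total_tree_length_um = numeric(0),
                      n_primary_neurites = integer(0),
                      soma_area_px = numeric(0), soma_area_um2 = numeric(0))
  if (nrow(props) == 0) return(empty)

  mask <- img > (local_mean(img, as.integer(window)) + offset)
  soma <- soma_map$labels > 0
  dil <- function(m, r) {
    as.matrix(EBImage::imageData(
      EBImage::dilate(matrix(as.numeric(m), nrow(m)),
                      EBImage::makeBrush(2L * as.integer(r) + 1L, "disc")))) > 0
  }
  soma_x <- if (soma_dilate_px > 0) dil(soma, soma_dilate_px) else soma
  neur <- mask & !soma_x
  skel <- skeletonize(neur)
  # primary-branch detection ring: 2-px dilation of the subtracted boundary
  ring <- dil(soma_x, 2) & !soma_x

  sg <- skeleton_graph(skel)
  res <- data.frame(neuron_id = props$cell_id,
                    mean_single_neurite_length_um = 0,
                    total_tree_length_um = 0,
                    n_primary_neurites = 0L,
                    soma_area_px = props$area_px,
                    soma_area_um2 = props$area_um2)
  if (is.null(sg) || igraph::vcount(sg$graph) == 0) return(res)

  comp <- igraph::components(sg$graph)$membership
  px_size <- image$pixel_size
  # assign each component to the nearest soma centroid
  for (ci in seq_len(max(comp))) {
    vs <- which(comp == ci)
    co <- sg$coords[vs, , drop = FALSE]
    d2 <- outer(co[, 1], props$centroid_row, "-")^2 +
      outer(co[, 2], props$centroid_col, "-")^2
    mind <- sqrt(apply(d2, 2, min))
    ni <- which.min(mind)
    if (mind[ni] > max_assign_dist_px) next
    row <- which(res$neuron_id == props$cell_id[ni])
    sub <- igraph::induced_subgraph(sg$graph, vs)
    tot <- sum(igraph::E(sub)$weight) * px_size
    res$total_tree_length_um[row] <- res$total_tree_length_um[row] + tot

    # roots: component vertices inside this soma's boundary ring
    in_ring <- ring[co]
    if (any(in_ring)) {
      # cluster adjacent root pixels: components of the ring-restricted subgraph
      rg <- igraph::induced_subgraph(sub, which(in_ring))
      rcomp <- igraph::components(rg)$membership
      dmat <- igraph::distances(sub, v = which(in_ring))
      lens <- vapply(seq_len(max(rcomp)), function(rc) {
        dd <- dmat[rcomp == rc, , drop = FALSE]
        dd[!is.finite(dd)] <- NA
        max(apply(dd, 1, max, na.rm = TRUE)) * px_size
      }, 0)
      res$n_primary_neurites[row] <- res$n_primary_neurites[row] + max(rcomp)
      # pool primaries across components of the same neuron by weighted mean
      prev_n <- res$n_primary_neurites[row] - max(rcomp)
      prev_m <- res$mean_single_neurite_length_um[row]
      res$mean_single_neurite_length_um[row] <-
        (prev_m * prev_n + sum(lens)) / (prev_n + max(rcomp))
    }
  }
  res
}
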