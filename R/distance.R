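# 26-neighborhood offsets (the unit ball of the Chebyshev metric)
.cheb_offsets <- local({
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off[rowSums(abs(off)) > 0L, , drop = FALSE]
})

# level-synchronous BFS over the grey-matter voxel graph from a single
# source (linear index). Unit step cost to any of the 26 Chebyshev
# neighbors inside the mask. Returns an integer array of step counts,
# NA where unreachable.
.bfs_steps <- function(mask, src_lin) {
  d <- dim(mask)
  n12 <- d[1L] * d[2L]
  dist <- array(NA_integer_, d)
  dist[src_lin] <- 0L
  frontier <- src_lin
  level <- 0L
  noff <- nrow(.cheb_offsets)
  while (length(frontier)) {
    co <- arrayInd(frontier, d)
    k <- nrow(co)
    nb <- co[rep.int(seq_len(k), noff), , drop = FALSE] +
      .cheb_offsets[rep(seq_len(noff), each = k), , drop = FALSE]
    keep <- nb[, 1L] >= 1L & nb[, 1L] <= d[1L] &
      nb[, 2L] >= 1L & nb[, 2L] <= d[2L] &
      nb[, 3L] >= 1L & nb[, 3L] <= d[3L]
    nb <- nb[keep, , drop = FALSE]
    lin <- nb[, 1L] + (nb[, 2L] - 1L) * d[1L] + (nb[, 3L] - 1L) * n12
    lin <- unique(lin)
    lin <- lin[mask[lin] & is.na(dist[lin])]
    dist[lin] <- level + 1L
    frontier <- lin
    level <- level + 1L
  }
  dist
}

.as_lin <- function(mask, v) {
  d <- dim(mask)
  v[1L] + (v[2L] - 1L) * d[1L] + (v[3L] - 1L) * d[1L] * d[2L]
}

#' Grey-matter-constrained Chebyshev geodesic between two voxels
#'
#' Shortest-path step count between voxels `a` and `b` where a single step
#' moves to any of the 26 adjacent voxels (the Chebyshev neighborhood) that
#' lie inside the grey-matter mask. The count is the number of steps, i.e.
#' voxels visited minus one: adjacent (including diagonal) voxels are at
#' distance 1 and a voxel is at distance 0 from itself. On a fully open
#' mask this reduces to the Chebyshev metric
#' `max(|dx|, |dy|, |dz|)`.
#'
#' @param mask logical 3-D array of grey-matter voxels.
#' @param a,b integer voxel coordinates (1-based, length 3), inside the mask.
#' @return nonnegative integer step count.
#' @export
grey_matter_geodesic <- function(mask, a, b) {
  a <- as.integer(a)
  b <- as.integer(b)
  if (!mask[a[1L], a[2L], a[3L]] || !mask[b[1L], b[2L], b[3L]]) {
    stop("both endpoints must lie inside the grey-matter mask")
  }
  dist <- .bfs_steps(mask, .as_lin(mask, a))
  s <- dist[b[1L], b[2L], b[3L]]
  if (is.na(s)) {
    stop(sprintf(
      "voxels (%s) and (%s) are in disconnected mask components (component of a: %d voxels; mask: %d voxels)",
      paste(a, collapse = ","), paste(b, collapse = ","),
      sum(!is.na(dist)), sum(mask)))
  }
  s
}

#' Geodesic center of mass of an ROI
#'
#' The ROI voxel minimizing the sum, over all other ROI voxels, of the
#' grey-matter-constrained Chebyshev geodesic. Paths may leave the ROI as
#' long as they stay inside the mask. Ties break lexicographically on
#' voxel coordinates.
#'
#' @param mask logical 3-D grey-matter mask.
#' @param roi_voxels integer matrix (k x 3) of 1-based ROI voxel
#'   coordinates, all inside the mask and mutually reachable through it.
#' @return length-3 integer voxel coordinate.
#' @export
roi_center_of_mass <- function(mask, roi_voxels) {
  roi_voxels <- matrix(as.integer(roi_voxels), ncol = 3L)
  if (nrow(roi_voxels) == 0L) stop("empty ROI")
  ord <- order(roi_voxels[, 1L], roi_voxels[, 2L], roi_voxels[, 3L])
  roi_voxels <- roi_voxels[ord, , drop = FALSE]
  lin <- apply(roi_voxels, 1L, function(v) .as_lin(mask, v))
  if (!all(mask[lin])) stop("ROI voxels must lie inside the mask")
  best <- NULL
  best_cost <- Inf
  for (i in seq_len(nrow(roi_voxels))) {
    dist <- .bfs_steps(mask, lin[i])
    costs <- dist[lin]
    if (anyNA(costs)) {
      stop("ROI is disconnected through the mask (from voxel ",
           paste(roi_voxels[i, ], collapse = ","), ")")
    }
    cost <- sum(costs)
    if (cost < best_cost) {  # first (lexicographically smallest) min wins
      best_cost <- cost
      best <- roi_voxels[i, ]
    }
  }
  best
}

# voxel coordinate sets per ROI label from a label volume
roi_voxel_sets <- function(labels) {
  ks <- sort(unique(labels[labels > 0L]))
  out <- lapply(ks, function(k) which(labels == k, arr.ind = TRUE))
  names(out) <- paste0("ROI", formatC(ks, width = 3, flag = "0"))
  out
}

#' Pairwise grey-matter geodesic distances between ROI centers
#'
#' Finds each ROI's geodesic center of mass, computes the
#' grey-matter-constrained Chebyshev step count between every pair of
#' centers, and splits edges at the median distance: an edge is
#' long-distance when its step count exceeds the median of all pairwise
#' distances (strictly, under the default rule; `long_rule = "inclusive"`
#' also counts edges at the median). For an even edge count the median is
#' the mean of the two middle order statistics.
#'
#' @param mask logical 3-D grey-matter mask.
#' @param rois either an integer label volume (0 = background) or a named
#'   list of k x 3 voxel coordinate matrices.
#' @param long_rule `"strict"` (default) or `"inclusive"` median split.
#' @return an object of class `gm_distance`: `roi_labels`, `steps`
#'   (symmetric integer matrix), `centers`, `median_steps`,
#'   `long_edge_mask`, `long_rule`.
#' @export
pairwise_distance_matrix <- function(mask, rois, long_rule = c("strict", "inclusive")) {
  long_rule <- match.arg(long_rule)
  if (!is.list(rois)) rois <- roi_voxel_sets(rois)
  R <- length(rois)
  if (R < 2L) stop("need at least 2 ROIs")
  centers <- t(vapply(rois, function(v) roi_center_of_mass(mask, v), integer(3)))
  steps <- matrix(0L, R, R, dimnames = list(names(rois), names(rois)))
  for (i in seq_len(R)) {
    dist <- .bfs_steps(mask, .as_lin(mask, centers[i, ]))
    for (j in seq_len(R)) {
      if (j == i) next
      s <- dist[centers[j, 1L], centers[j, 2L], centers[j, 3L]]
      if (is.na(s)) {
        stop("ROI centers '", names(rois)[i], "' and '", names(rois)[j],
             "' are in disconnected mask components")
      }
      steps[i, j] <- s
    }
  }
  steps <- pmax(steps, t(steps))  # BFS is symmetric; guard against asymmetry
  med <- stats::median(steps[upper.tri(steps)])
  long <- if (long_rule == "strict") steps > med else steps >= med
  diag(long) <- FALSE
  structure(list(roi_labels = names(rois), steps = steps, centers = centers,
                 median_steps = med, long_edge_mask = long,
                 long_rule = long_rule),
            class = "gm_distance")
}

#' @export
print.gm_distance <- function(x, ...) {
  E <- sum(upper.tri(x$steps))
  cat(sprintf(
    "Grey-matter distance matrix: %d ROIs, median %.1f steps, %d/%d long edges (%s rule)\n",
    length(x$roi_labels), x$median_steps,
    sum(x$long_edge_mask[upper.tri(x$long_edge_mask)]), E, x$long_rule))
  invisible(x)
}

#' Metabolic correlation strength over long-distance edges only
#'
#' Restricts the Z-scale strength average to edges beyond the median
#' grey-matter geodesic distance, removing the shared effect of spatial
#' proximity (e.g. partial-volume inflation between neighboring regions).
#'
#' @param network a [build_network()] result.
#' @param dm a [pairwise_distance_matrix()] result with the same ROI order.
#' @return correlation-scale scalar.
#' @export
long_distance_strength <- function(network, dm) {
  if (!identical(network$roi_labels, dm$roi_labels)) {
    stop("network and distance matrix have mismatched ROI labels")
  }
  sel <- upper.tri(network$z) & dm$long_edge_mask
  if (!any(sel)) stop("no long-distance edges under the current median split")
  tanh(mean(network$z[sel]))
}

# long-distance edge-Z vector, for feeding edge_anova/tukey on the
# restricted edge set
long_edge_z_values <- function(network, dm) {
  sel <- upper.tri(network$z) & dm$long_edge_mask
  network$z[sel]
}

#' Correlation between edge strength and inter-ROI distance
#'
#' Pearson correlation, across the unique edges, between the Fisher-Z edge
#' value and the grey-matter geodesic step count, with its two-sided
#' p-value. A strongly negative value indicates decay of metabolic
#' coupling with anatomical distance.
#'
#' @param network a [build_network()] result.
#' @param dm a matching [pairwise_distance_matrix()] result.
#' @return list with `r`, `p`, `n_edges`.
#' @export
distance_correlation <- function(network, dm) {
  if (!identical(network$roi_labels, dm$roi_labels)) {
    stop("network and distance matrix have mismatched ROI labels")
  }
  z <- upper_edges(network$z)
  s <- dm$steps[upper.tri(dm$steps)]
  if (stats::sd(z) == 0 || stats::sd(s) == 0) {
    stop("zero variance in edge strengths or distances")
  }
  ct <- stats::cor.test(z, s, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n_edges = length(z))
}

#' Read / write volumes as NIfTI (optional)
#'
#' Thin wrappers over the RNifti package for users whose masks and label
#' volumes live in NIfTI files; the plain-text voxel list
#' ([write_voxel_list()]) is the package's canonical exchange format.
#'
#' @param path NIfTI file path.
#' @param x array to write.
#' @return `read_volume_nifti()` returns an array.
#' @export
read_volume_nifti <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("NIfTI support requires the RNifti package")
  }
  a <- RNifti::readNifti(path)
  array(as.vector(a), dim = dim(a))
}

#' @rdname read_volume_nifti
#' @export
write_volume_nifti <- function(x, path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("NIfTI support requires the RNifti package")
  }
  RNifti::writeNifti(RNifti::asNifti(x), path)
  invisible(path)
}
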