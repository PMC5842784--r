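#' Mean SUVR per ROI from a labeled voxel volume
#'
#' Regional uptake is summarized as the arithmetic mean intensity over the
#' voxels carrying each ROI label; background (label 0) is excluded.
#'
#' @param volume numeric array of voxel intensities.
#' @param labels integer array of the same shape; 0 = background, 1..k = ROIs.
#' @param expected optional vector of ROI labels that must all be present.
#' @return named numeric vector of per-ROI mean intensities, ordered by label.
#' @export
roi_mean_suvr <- function(volume, labels, expected = NULL) {
  if (!identical(dim(volume), dim(labels))) {
    stop("'volume' and 'labels' must have identical dimensions")
  }
  lab <- as.integer(labels)
  present <- sort(unique(lab[lab > 0L]))
  want <- if (is.null(expected)) present else sort(as.integer(expected))
  missing <- setdiff(want, present)
  if (length(missing)) {
    stop("ROI label(s) with zero voxels: ", paste(missing, collapse = ", "))
  }
  means <- vapply(want, function(l) mean(volume[lab == l]), numeric(1))
  names(means) <- paste0("ROI", formatC(want, width = 3, flag = "0"))
  means
}

#' Build a group metabolic brain network
#'
#' Computes the sample Pearson correlation of every pair of ROI columns
#' across the subjects of one group. The result is a fully weighted,
#' symmetric ROI x ROI adjacency matrix: edges are cross-subject covariance
#' relationships of regional metabolism, not within-subject time series
#' correlations. Correlations are kept signed throughout.
#'
#' Missing entries are an error rather than being handled pairwise: all edges
#' of a group network must be estimated from the identical subject set.
#'
#' @param table a [suvr_table()] (or plain subjects x ROIs matrix) with at
#'   least 3 subjects and no missing values.
#' @param group group label; defaults to the table's own label.
#' @return an object of class `metabolic_network` with fields `roi_labels`,
#'   `corr` (unit-diagonal symmetric correlation matrix), `z` (Fisher-Z
#'   matrix, diagonal `NA` and never aggregated), `n_subjects`, `group`,
#'   and `n_clamped` (count of correlations clamped before `atanh`).
#' @seealso [mean_strength()], [regional_strength()], [edge_anova()]
#' @export
build_network <- function(table, group = NULL) {
  x <- unclass(table)
  if (is.null(group)) {
    group <- attr(table, "group")
    if (is.null(group)) group <- NA_character_
  }
  if (!is.matrix(x) || !is.numeric(x)) stop("'table' must be a numeric matrix")
  if (nrow(x) < 3L) stop("need at least 3 subjects to correlate ROIs")
  if (anyNA(x)) stop("missing SUVR entries are not allowed (no imputation)")
  if (is.null(colnames(x))) colnames(x) <- sprintf("ROI%03d", seq_len(ncol(x)))
  v <- apply(x, 2L, stats::var)
  if (any(v == 0)) {
    stop("zero-variance ROI(s), correlation undefined: ",
         paste(colnames(x)[v == 0], collapse = ", "))
  }
  corr <- stats::cor(x)
  corr <- (corr + t(corr)) / 2
  diag(corr) <- 1
  off <- corr
  diag(off) <- 0
  z <- fisher_z(off)
  n_clamped <- attr(z, "n_clamped")
  z <- as.vector(z)
  z <- matrix(z, nrow(corr), ncol(corr), dimnames = dimnames(corr))
  diag(z) <- NA_real_
  structure(
    list(roi_labels = colnames(x), corr = corr, z = z,
         n_subjects = nrow(x), group = group,
         n_clamped = if (is.null(n_clamped)) 0L else n_clamped / 2L),
    class = "metabolic_network")
}

#' @export
print.metabolic_network <- function(x, ...) {
  r <- length(x$roi_labels)
  cat(sprintf("Metabolic network '%s': %d ROIs, %d edges, n = %d subjects\n",
              x$group, r, r * (r - 1L) / 2L, x$n_subjects))
  cat(sprintf("  mean correlation strength (Z-averaged): %.4f\n",
              mean_strength(x)))
  invisible(x)
}

# strict upper-triangle edge values; the unit of aggregation everywhere
upper_edges <- function(m) m[upper.tri(m)]

#' Edge-level Fisher-Z values of a network
#'
#' Strict upper-triangle Z values: the R(R-1)/2 unique undirected edges
#' (3160 for an 80-ROI parcellation).
#'
#' @param network a [build_network()] result.
#' @return numeric vector of length `R (R - 1) / 2`.
#' @export
edge_z_values <- function(network) upper_edges(network$z)

#' Global metabolic correlation strength
#'
#' Mean of the Fisher-Z edge values over the strict upper triangle,
#' inverse-transformed back to the correlation scale.
#'
#' @param network a [build_network()] result.
#' @return scalar in (-1, 1).
#' @export
mean_strength <- function(network) {
  tanh(mean(upper_edges(network$z)))
}

#' Regional metabolic correlation strength
#'
#' For each ROI, the mean of its R-1 off-diagonal Fisher-Z values with all
#' other ROIs, inverse-transformed.
#'
#' @param network a [build_network()] result.
#' @return named numeric vector, one value per ROI.
#' @export
regional_strength <- function(network) {
  tanh(rowMeans(network$z, na.rm = TRUE))
}

# per-ROI mean Z (not inverse-transformed); used where differences must be
# taken on the Z scale before the final tanh
regional_z <- function(network) rowMeans(network$z, na.rm = TRUE)

#' Write a network as CSV adjacency and long-format edge list
#'
#' @param network a [build_network()] result.
#' @param adjacency_path,edges_path output file paths (either may be `NULL`
#'   to skip).
#' @return invisibly, a list of the paths written.
#' @export
write_network_csv <- function(network, adjacency_path = NULL, edges_path = NULL) {
  out <- list()
  if (!is.null(adjacency_path)) {
    df <- data.frame(roi = network$roi_labels,
                     as.data.frame(network$corr), check.names = FALSE)
    utils::write.csv(df, adjacency_path, row.names = FALSE, quote = FALSE)
    out$adjacency <- adjacency_path
  }
  if (!is.null(edges_path)) {
    ut <- which(upper.tri(network$corr), arr.ind = TRUE)
    df <- data.frame(roi_a = network$roi_labels[ut[, 1L]],
                     roi_b = network$roi_labels[ut[, 2L]],
                     r = network$corr[ut], z = network$z[ut])
    utils::write.csv(df, edges_path, row.names = FALSE, quote = FALSE)
    out$edges <- edges_path
  }
  invisible(out)
}
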