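#' ROI membership in intrinsic connectivity networks
#'
#' Maps each ROI of a functional parcellation to exactly one named
#' intrinsic connectivity network (ICN). The reference functional atlas
#' this mirrors has 84 ROIs grouped into 14 ICNs (dorsal/ventral default
#' mode, precuneus, left/right executive control, anterior/posterior
#' salience, sensorimotor, visuospatial, high/primary visual, language,
#' auditory, basal ganglia); its real geometry is not bundled, only the
#' name/count structure with synthetic stand-in ROIs.
#'
#' @param roi character vector of ROI labels.
#' @param icn character vector, same length: the ICN of each ROI.
#' @return an object of class `icn_membership`: a data frame with columns
#'   `roi` and `icn`, `icn` a factor whose level order fixes row/column
#'   order in [icn_matrix()].
#' @export
icn_membership <- function(roi, icn) {
  if (length(roi) != length(icn)) stop("'roi' and 'icn' must have equal length")
  if (anyDuplicated(roi)) stop("each ROI must map to exactly one ICN")
  icn <- factor(icn, levels = unique(icn))
  if (any(table(icn) < 1L)) stop("every named ICN needs at least one ROI")
  structure(data.frame(roi = as.character(roi), icn = icn,
                       stringsAsFactors = FALSE),
            class = c("icn_membership", "data.frame"))
}

#' @rdname icn_membership
#' @param path two-column CSV (`roi_label`, `icn_name`) or JSON mapping.
#' @export
read_icn_membership <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    m <- jsonlite::read_json(path, simplifyVector = TRUE)
    icn_membership(names(m), unlist(m, use.names = FALSE))
  } else {
    df <- utils::read.csv(path)
    icn_membership(df[[1L]], df[[2L]])
  }
}

#' The 14 canonical ICN names of the reference functional atlas
#' @export
icn_reference_names <- function() {
  c("dDMN", "vDMN", "Prec", "lECN", "rECN", "aSal", "pSal",
    "SM", "VS", "hVis", "pVis", "Lang", "Aud", "BG")
}

#' Synthetic 84-ROI / 14-ICN membership
#'
#' A synthetic stand-in for the reference functional atlas: 84 ROI labels
#' distributed over the 14 canonical ICN names (six per ICN). Only the
#' name and count structure matches the reference; ROI identities are
#' synthetic. Also shipped as
#' `inst/extdata/icn_membership_synthetic.csv`.
#'
#' @return an [icn_membership()].
#' @export
synthetic_icn_membership <- function() {
  nm <- icn_reference_names()
  icn_membership(roi = paste0(rep(nm, each = 6L), "_", rep(1:6, times = 14L)),
                 icn = rep(nm, each = 6L))
}

.member_rois <- function(network, m, icn) {
  rois <- m$roi[m$icn == icn]
  idx <- match(rois, network$roi_labels)
  if (anyNA(idx)) {
    stop("ICN '", icn, "' has member ROIs absent from the network: ",
         paste(rois[is.na(idx)], collapse = ", "))
  }
  idx
}

#' Within-ICN metabolic correlation strength
#'
#' Z-scale mean of the edges among all unordered pairs of an ICN's member
#' ROIs, inverse-transformed. Undefined (an error) for singleton ICNs.
#'
#' @param network a [build_network()] result (built on the functional
#'   parcellation the membership refers to).
#' @param m an [icn_membership()].
#' @param icn ICN name.
#' @return correlation-scale scalar.
#' @export
within_icn_strength <- function(network, m, icn) {
  idx <- .member_rois(network, m, icn)
  if (length(idx) < 2L) stop("ICN '", icn, "' has a single ROI; within-ICN strength undefined")
  sub <- network$z[idx, idx]
  tanh(mean(sub[upper.tri(sub)]))
}

#' Between-ICN metabolic correlation strength
#'
#' Z-scale mean over all cross pairs (one ROI from each ICN),
#' inverse-transformed; symmetric in its ICN arguments.
#'
#' @inheritParams within_icn_strength
#' @param icn_a,icn_b two distinct ICN names.
#' @return correlation-scale scalar.
#' @export
between_icn_strength <- function(network, m, icn_a, icn_b) {
  if (identical(icn_a, icn_b)) stop("ICNs must differ; use within_icn_strength()")
  ia <- .member_rois(network, m, icn_a)
  ib <- .member_rois(network, m, icn_b)
  if (length(intersect(ia, ib))) stop("overlapping ICN membership")
  tanh(mean(network$z[ia, ib]))
}

#' ICN-by-ICN matrix of metabolic correlation strengths
#'
#' Diagonal cells hold within-ICN strength, off-diagonal cells the
#' between-ICN strength of each ICN pair (14 x 14 for the reference
#' atlas structure). The pair-count-weighted Z-scale grand mean of all
#' cells equals the network's overall [mean_strength()] restricted to the
#' atlas ROIs — the cells partition the edge set.
#'
#' @inheritParams within_icn_strength
#' @return symmetric matrix with ICN names on both dimensions, `NA` on the
#'   diagonal for singleton ICNs; attribute `"pair_counts"` holds the
#'   number of edges aggregated into each cell.
#' @export
icn_matrix <- function(network, m) {
  nms <- levels(m$icn)
  k <- length(nms)
  out <- matrix(NA_real_, k, k, dimnames = list(nms, nms))
  counts <- matrix(0, k, k, dimnames = list(nms, nms))
  idx <- lapply(nms, function(n) .member_rois(network, m, n))
  for (i in seq_len(k)) {
    ni <- length(idx[[i]])
    if (ni >= 2L) {
      sub <- network$z[idx[[i]], idx[[i]]]
      out[i, i] <- tanh(mean(sub[upper.tri(sub)]))
      counts[i, i] <- ni * (ni - 1L) / 2L
    }
    for (j in seq_len(k)) {
      if (j <= i) next
      out[i, j] <- out[j, i] <- tanh(mean(network$z[idx[[i]], idx[[j]]]))
      counts[i, j] <- counts[j, i] <- ni * length(idx[[j]])
    }
  }
  attr(out, "pair_counts") <- counts
  out
}

#' Write an ICN strength matrix as CSV
#'
#' @param x an [icn_matrix()] result.
#' @param path output file.
#' @export
write_icn_csv <- function(x, path) {
  df <- data.frame(icn = rownames(x), as.data.frame(unclass(x)[, , drop = FALSE]),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
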