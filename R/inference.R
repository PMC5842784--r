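#' Edge-level one-way ANOVA across group networks
#'
#' Treats each group's strict-upper-triangle Fisher-Z edge values as
#' observations in a one-way fixed-effects ANOVA of mean metabolic
#' correlation strength. With k groups and E unique edges per network,
#' the degrees of freedom are k - 1 between and kE - k error (12,636 for
#' four 80-ROI groups; 18,954 for six). Edges are treated as independent
#' observations, a simplification inherent to this design: edges of one
#' network share subjects, so the nominal error df overstates the
#' effective information (see the package vignette).
#'
#' @param groups named list of [build_network()] results sharing one ROI set.
#' @return list with `F`, `df_between`, `df_error`, `p`, `n_edges`, and
#'   `group_means` (per-group mean edge Z, also inverse-transformed).
#' @export
edge_anova <- function(groups) {
  stopifnot(length(groups) >= 2L)
  ref <- groups[[1L]]$roi_labels
  for (g in groups) {
    if (!identical(g$roi_labels, ref)) stop("networks have mismatched ROI sets")
  }
  zs <- lapply(groups, edge_z_values)
  E <- length(zs[[1L]])
  d <- data.frame(z = unlist(zs, use.names = FALSE),
                  group = factor(rep(names(groups), each = E),
                                 levels = names(groups)))
  an <- summary(stats::aov(z ~ group, data = d))[[1L]]
  zm <- vapply(zs, mean, numeric(1))
  list(F = an$`F value`[1L],
       df_between = as.integer(an$Df[1L]), df_error = as.integer(an$Df[2L]),
       p = an$`Pr(>F)`[1L], n_edges = E,
       group_means = data.frame(group = names(groups), z_mean = zm,
                                r_mean = tanh(zm), row.names = NULL))
}

#' Tukey HSD contrasts between groups of edge-Z observations
#'
#' Pairwise comparisons of mean edge Z with Tukey--Kramer simultaneous
#' confidence intervals at family-wise error rate `fwe`. Mean differences
#' are reported on the Z scale (the scale of the test) and, for display,
#' group means inverse-transformed to correlations.
#'
#' @param z_by_group named list of numeric vectors of edge Z values (e.g.
#'   from [edge_z_values()]), or a named list of networks.
#' @param fwe family-wise error rate (default 0.05).
#' @return list with `contrasts` (data frame: pair, diff_z, lwr, upr,
#'   p_adj, significant) and `group_means`.
#' @export
tukey_hsd_edges <- function(z_by_group, fwe = 0.05) {
  if (inherits(z_by_group[[1L]], "metabolic_network")) {
    z_by_group <- lapply(z_by_group, edge_z_values)
  }
  stopifnot(length(z_by_group) >= 2L)
  sizes <- lengths(z_by_group)
  if (any(sizes < 2L)) {
    stop("group(s) with < 2 edge observations: ",
         paste(names(z_by_group)[sizes < 2L], collapse = ", "))
  }
  d <- data.frame(z = unlist(z_by_group, use.names = FALSE),
                  group = factor(rep(names(z_by_group), times = sizes),
                                 levels = names(z_by_group)))
  fit <- stats::aov(z ~ group, data = d)
  tk <- stats::TukeyHSD(fit, conf.level = 1 - fwe)$group
  zm <- vapply(z_by_group, mean, numeric(1))
  contrasts <- data.frame(pair = rownames(tk), diff_z = tk[, "diff"],
                          lwr = tk[, "lwr"], upr = tk[, "upr"],
                          p_adj = tk[, "p adj"],
                          significant = tk[, "p adj"] <= fwe,
                          row.names = NULL)
  list(contrasts = contrasts,
       group_means = data.frame(group = names(z_by_group), z_mean = zm,
                                r_mean = tanh(zm), row.names = NULL))
}

# per-ROI mean Fisher-Z strength straight from a subjects x ROIs matrix;
# returns NULL if any ROI is degenerate (zero variance) so permutation
# loops can resample. Kept lean: it sits inside the 100k-replicate loop.
.regional_z_of <- function(x, clamp = 1 - 1e-12) {
  C <- stats::cor(x)
  if (anyNA(C)) return(NULL)
  C[C > clamp] <- clamp
  C[C < -clamp] <- -clamp
  Z <- atanh(C)
  diag(Z) <- NA_real_
  rowMeans(Z, na.rm = TRUE)
}

#' Permutation test of regional metabolic strength differences
#'
#' Tests, for every ROI, whether the regional correlation strength of group
#' A differs from group B. The observed statistic is the difference of
#' per-ROI mean Fisher-Z strengths (A minus B), inverse-transformed to the
#' correlation scale. The null distribution is built by pooling the two
#' groups' subjects and randomly reassigning `n_a` of them to the first
#' group (the rest to the second), rebuilding both networks, and recording
#' the same statistic; assignments are drawn uniformly at random with
#' replacement across repetitions. A region is significant when its
#' observed difference falls outside the central `ci` interval of its null
#' distribution (inverse-ECDF percentile bounds, so decisions stay
#' rank-consistent even on the discrete null of an exhaustive
#' enumeration). A two-sided
#' empirical p-value with add-one correction is reported alongside,
#' uncorrected across ROIs.
#'
#' A reassignment that yields a zero-variance ROI column in either half is
#' redrawn (counted in `n_resampled`, hard-capped).
#'
#' @param table_a,table_b [suvr_table()] objects sharing ROI columns, each
#'   with >= 3 subjects.
#' @param n_perm number of random reassignments (default 100,000).
#' @param seed integer seed; results are bit-reproducible given
#'   `(inputs, n_perm, seed)`.
#' @param ci central interval mass (default 0.95).
#' @param exhaustive if `TRUE`, enumerate all `choose(n_a + n_b, n_a)`
#'   assignments instead of sampling (`n_perm` is ignored); feasible only
#'   for small pooled groups.
#' @param max_resample cap on redraws of degenerate reassignments.
#' @return an object of class `permutation_result`: `roi_labels`,
#'   `observed_diff`, `null_lower`, `null_upper`, `significant`,
#'   `p_uncorrected`, `n_perm`, `seed`, `n_resampled`, and `null` (the
#'   permutation-by-ROI null matrix).
#' @export
permutation_regional_diff <- function(table_a, table_b, n_perm = 100000L,
                                      seed = 1L, ci = 0.95,
                                      exhaustive = FALSE,
                                      max_resample = 1000L) {
  xa <- unclass(table_a)
  xb <- unclass(table_b)
  if (!identical(colnames(xa), colnames(xb))) stop("ROI columns differ between tables")
  na <- nrow(xa)
  nb <- nrow(xb)
  if (na < 3L || nb < 3L) stop("both groups need >= 3 subjects")
  za <- .regional_z_of(xa)
  zb <- .regional_z_of(xb)
  if (is.null(za) || is.null(zb)) stop("zero-variance ROI in an observed table")
  obs <- tanh(za - zb)
  pooled <- rbind(xa, xb)
  n <- na + nb
  R <- ncol(pooled)

  stat_of <- function(idx) {
    pa <- .regional_z_of(pooled[idx, , drop = FALSE])
    pb <- .regional_z_of(pooled[-idx, , drop = FALSE])
    if (is.null(pa) || is.null(pb)) return(NULL)
    tanh(pa - pb)
  }

  n_resampled <- 0L
  if (exhaustive) {
    combs <- utils::combn(n, na)
    n_perm <- ncol(combs)
    null <- matrix(NA_real_, n_perm, R)
    for (i in seq_len(n_perm)) {
      s <- stat_of(combs[, i])
      if (is.null(s)) stop("degenerate reassignment during exhaustive enumeration")
      null[i, ] <- s
    }
  } else {
    set.seed(as.integer(seed))
    null <- matrix(NA_real_, n_perm, R)
    for (i in seq_len(n_perm)) {
      s <- NULL
      while (is.null(s)) {
        s <- stat_of(sample.int(n, na))
        if (is.null(s)) {
          n_resampled <- n_resampled + 1L
          if (n_resampled > max_resample) {
            stop("exceeded cap of ", max_resample, " degenerate reassignments")
          }
        }
      }
      null[i, ] <- s
    }
  }
  alpha <- (1 - ci) / 2
  # inverse-ECDF (order-statistic) percentile bounds: rank-consistent on
  # the discrete null of an exhaustive enumeration, indistinguishable from
  # interpolated percentiles at large n_perm
  qs <- apply(null, 2L, stats::quantile, probs = c(alpha, 1 - alpha),
              names = FALSE, type = 1L)
  lower <- qs[1L, ]
  upper <- qs[2L, ]
  pvals <- (1 + colSums(abs(null) >= matrix(abs(obs), n_perm, R, byrow = TRUE))) /
    (n_perm + 1)
  structure(
    list(roi_labels = colnames(pooled),
         observed_diff = stats::setNames(obs, colnames(pooled)),
         null_lower = stats::setNames(lower, colnames(pooled)),
         null_upper = stats::setNames(upper, colnames(pooled)),
         significant = stats::setNames(obs < lower | obs > upper, colnames(pooled)),
         p_uncorrected = stats::setNames(pvals, colnames(pooled)),
         n_perm = n_perm, seed = if (exhaustive) NA_integer_ else as.integer(seed),
         n_resampled = n_resampled, exhaustive = exhaustive, null = null),
    class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "Permutation test: %d ROIs, %d %s, %d significant at interval exclusion\n",
    length(x$roi_labels), x$n_perm,
    if (x$exhaustive) "exhaustive reassignments" else "random reassignments",
    sum(x$significant)))
  invisible(x)
}

#' Tabulate a permutation result
#'
#' @param x a [permutation_regional_diff()] result.
#' @param ... unused.
#' @return data frame with one row per ROI.
#' @export
as.data.frame.permutation_result <- function(x, ...) {
  data.frame(roi = x$roi_labels, observed_diff = x$observed_diff,
             null_lower = x$null_lower, null_upper = x$null_upper,
             significant = x$significant, p_uncorrected = x$p_uncorrected,
             row.names = NULL)
}
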