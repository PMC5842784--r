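#' PIB index from regional amyloid composites
#'
#' The PIB index is the arithmetic mean of the amyloid tracer distribution
#' volume ratio (DVR) over four cortical composites: prefrontal, lateral
#' temporal, parietal and cingulate.
#'
#' @param regional_dvr numeric vector of the four composite DVR values
#'   (order irrelevant); all must be present and positive unless
#'   `allow_missing` is set, in which case `NA` is returned.
#' @param allow_missing visual-read override: permits a missing index for
#'   subjects whose amyloid scan was incomplete but read positive/negative
#'   by a clinician.
#' @return DVR-scale scalar (or `NA` under the override).
#' @examples
#' pib_index(c(1.2, 1.3, 1.25, 1.45))  # 1.30
#' @export
pib_index <- function(regional_dvr, allow_missing = FALSE) {
  if (length(regional_dvr) != 4L) stop("expected exactly 4 regional DVR composites")
  if (anyNA(regional_dvr)) {
    if (allow_missing) return(NA_real_)
    stop("missing DVR composite; set allow_missing = TRUE for visual-read subjects")
  }
  if (any(regional_dvr <= 0)) stop("DVR composites must be positive")
  mean(regional_dvr)
}

#' Dichotomize amyloid status from the PIB index
#'
#' Subjects at or above the threshold (default 1.08 DVR, a cutoff validated
#' against post-mortem amyloid burden) are amyloid-positive; the boundary is
#' inclusive.
#'
#' @param index PIB index (DVR scale), positive.
#' @param threshold DVR cutoff, default 1.08.
#' @param allow_missing permit `NA` index (visual-read override); returns `NA`.
#' @return `"PIB+"` or `"PIB-"` (vectorized).
#' @export
classify_amyloid <- function(index, threshold = 1.08, allow_missing = FALSE) {
  if (anyNA(index) && !allow_missing) {
    stop("missing PIB index; set allow_missing = TRUE for visual-read subjects")
  }
  if (any(index <= 0, na.rm = TRUE)) stop("PIB index must be positive")
  ifelse(is.na(index), NA_character_, ifelse(index >= threshold, "PIB+", "PIB-"))
}

#' Stratify a cohort into amyloid-by-ApoE subgroups
#'
#' Old subjects are partitioned into the four cells of PIB status crossed
#' with ApoE e4 carriage; young and Alzheimer's-disease subjects pass
#' through unchanged. The partition is exhaustive and disjoint.
#'
#' @param subjects data frame of subject records with columns `group`
#'   (`young`, `ad`, or `old`/an old subgroup label), `pib_index` (or
#'   `amyloid_status`) and `apoe4` (logical).
#' @param threshold DVR cutoff passed to [classify_amyloid()].
#' @return named list of data frames: `young`, `ad` (when present) and the
#'   four old subgroups `PIB-/e4-`, `PIB-/e4+`, `PIB+/e4-`, `PIB+/e4+`.
#' @export
stratify <- function(subjects, threshold = 1.08) {
  stopifnot(is.data.frame(subjects))
  grp <- subjects$group
  is_old <- !grp %in% c("young", "ad")
  out <- list()
  if (any(grp == "young")) out$young <- subjects[grp == "young", , drop = FALSE]
  if (any(grp == "ad")) out$ad <- subjects[grp == "ad", , drop = FALSE]
  old <- subjects[is_old, , drop = FALSE]
  if (nrow(old)) {
    status <- old$amyloid_status
    if (is.null(status)) status <- classify_amyloid(old$pib_index, threshold)
    bad <- is.na(status) | is.na(old$apoe4)
    if (any(bad)) {
      stop("unresolved amyloid/ApoE status for: ",
           paste(old$subject_id[bad], collapse = ", "))
    }
    key <- paste0(status, "/e4", ifelse(old$apoe4, "+", "-"))
    for (cell in c("PIB-/e4-", "PIB-/e4+", "PIB+/e4-", "PIB+/e4+")) {
      out[[cell]] <- old[key == cell, , drop = FALSE]
    }
  }
  out
}

#' Select demographically matched subjects from a pool
#'
#' Picks the `k` pool members that best match a reference group on age,
#' education and sex. Age and education are z-scored over the union of
#' reference and pool; each candidate's cost is the mean absolute deviation
#' of its z-scores from the reference-group mean z-scores, plus a sex
#' mismatch penalty (the absolute deviation of the candidate's
#' female-indicator from the reference female fraction). Candidates are
#' taken greedily in increasing cost; ties break lexicographically on
#' `subject_id`, making the selection deterministic.
#'
#' @param reference data frame of reference subjects.
#' @param pool data frame of candidates (columns `subject_id`, `age`,
#'   `education`, `sex`).
#' @param k number of subjects to select.
#' @param features continuous features to match on (default age, education).
#' @return the selected rows of `pool`, in selection order.
#' @export
match_subgroups <- function(reference, pool, k,
                            features = c("age", "education")) {
  if (nrow(pool) < k) stop("pool smaller than k (", nrow(pool), " < ", k, ")")
  for (f in c(features, "sex")) {
    if (anyNA(reference[[f]]) || anyNA(pool[[f]])) {
      stop("feature '", f, "' missing for some candidates")
    }
  }
  all_vals <- rbind(reference[features], pool[features])
  mu <- colMeans(all_vals)
  sdv <- apply(all_vals, 2L, stats::sd)
  sdv[sdv == 0] <- 1
  zref <- colMeans(scale(reference[features], mu, sdv))
  zpool <- scale(pool[features], mu, sdv)
  fem_ref <- mean(reference$sex == "F")
  cost <- rowMeans(abs(sweep(zpool, 2L, zref))) +
    abs(as.numeric(pool$sex == "F") - fem_ref)
  ord <- order(cost, pool$subject_id)
  pool[ord[seq_len(k)], , drop = FALSE]
}

#' Test demographic balance across groups
#'
#' Continuous features (age, education) are compared with a one-way ANOVA
#' followed by Tukey's HSD; dichotomous features (sex, ApoE e4) with an
#' omnibus chi-squared test followed by pairwise chi-squared tests with
#' Bonferroni-adjusted p-values. Tests are without continuity correction so
#' statistics match the closed-form expected-count arithmetic. Subjects
#' missing a feature are dropped from that feature's test only, with the
#' dropped count reported. When a pairwise table has an expected cell count
#' of zero the chi-squared statistic is undefined; Fisher's exact test is
#' substituted and flagged.
#'
#' @param groups named list of subject data frames.
#' @param continuous,dichotomous feature names to test.
#' @param fwe family-wise error rate for flagging (default 0.05).
#' @return list with per-feature results: `anova` F/p and `tukey` table for
#'   continuous features; `omnibus` and Bonferroni-adjusted `pairwise`
#'   tables for dichotomous ones; and `significant`, the flagged contrasts.
#' @export
demographics_tests <- function(groups, continuous = c("age", "education"),
                               dichotomous = c("sex", "apoe4"), fwe = 0.05) {
  stopifnot(length(groups) >= 2L)
  sizes <- vapply(groups, nrow, integer(1))
  if (any(sizes < 2L)) {
    stop("group(s) of size < 2: ", paste(names(groups)[sizes < 2L], collapse = ", "))
  }
  stacked <- do.call(rbind, lapply(names(groups), function(g) {
    data.frame(.group = g, groups[[g]], stringsAsFactors = FALSE)
  }))
  stacked$.group <- factor(stacked$.group, levels = names(groups))
  res <- list(continuous = list(), dichotomous = list(), significant = character(0))

  for (f in intersect(continuous, names(stacked))) {
    d <- stacked[!is.na(stacked[[f]]), c(".group", f)]
    fit <- stats::aov(stats::reformulate(".group", f), data = d)
    an <- summary(fit)[[1L]]
    tk <- stats::TukeyHSD(fit, conf.level = 1 - fwe)$.group
    sig <- rownames(tk)[tk[, "p adj"] <= fwe]
    res$continuous[[f]] <- list(
      F = an$`F value`[1L], df = an$Df, p = an$`Pr(>F)`[1L],
      tukey = tk, n_dropped = sum(is.na(stacked[[f]])))
    if (an$`Pr(>F)`[1L] <= fwe) {
      res$significant <- c(res$significant, paste0(f, ": ", sig))
    }
  }

  for (f in intersect(dichotomous, names(stacked))) {
    d <- stacked[!is.na(stacked[[f]]), c(".group", f)]
    tabl <- table(d$.group, d[[f]])
    omni <- if (ncol(tabl) < 2L) {
      # feature constant across all groups: no association testable
      list(statistic = 0, parameter = 0L, p.value = 1)
    } else {
      suppressWarnings(stats::chisq.test(tabl, correct = FALSE))
    }
    prs <- utils::combn(names(groups), 2L)
    pw <- data.frame(a = prs[1L, ], b = prs[2L, ], statistic = NA_real_,
                     p_raw = NA_real_, method = "chisq", stringsAsFactors = FALSE)
    for (i in seq_len(ncol(prs))) {
      sub <- d[d$.group %in% prs[, i], ]
      t2 <- table(droplevels(sub$.group), sub[[f]])
      if (ncol(t2) < 2L || nrow(t2) < 2L) {
        pw$statistic[i] <- 0
        pw$p_raw[i] <- 1
        pw$method[i] <- "degenerate (no variation)"
        next
      }
      exp0 <- outer(rowSums(t2), colSums(t2)) / sum(t2)
      if (any(exp0 == 0)) {
        ft <- stats::fisher.test(t2)
        pw$p_raw[i] <- ft$p.value
        pw$method[i] <- "fisher (zero expected count)"
      } else {
        ct <- suppressWarnings(stats::chisq.test(t2, correct = FALSE))
        pw$statistic[i] <- unname(ct$statistic)
        pw$p_raw[i] <- ct$p.value
      }
    }
    pw$p_bonferroni <- stats::p.adjust(pw$p_raw, method = "bonferroni")
    # protected testing: pairwise contrasts count only under a significant omnibus
    sig <- pw$p_bonferroni <= fwe & omni$p.value <= fwe
    res$dichotomous[[f]] <- list(
      omnibus = list(statistic = unname(omni$statistic),
                     df = unname(omni$parameter), p = omni$p.value),
      pairwise = pw, n_dropped = sum(is.na(stacked[[f]])))
    if (any(sig)) {
      res$significant <- c(res$significant,
                           paste0(f, ": ", pw$a[sig], " vs ", pw$b[sig]))
    }
  }
  res
}
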