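#' Configuration for an end-to-end pipeline run
#'
#' @param out_dir output directory (created if absent).
#' @param seed master seed; per-stage seeds are derived from it with
#'   [derive_seeds()]'s splitting rule (one `sample.int` draw per stage
#'   under the master seed), so each stage is independently reproducible.
#' @param specs named list of [cohort_spec()] objects to simulate, or
#'   `NULL` with `tables` supplied instead.
#' @param tables named list of pre-built [suvr_table()] objects (used when
#'   `specs` is `NULL`).
#' @param threshold PIB dichotomization threshold (DVR, default 1.08).
#' @param n_perm permutation count for the regional test.
#' @param ci central interval mass for the permutation test.
#' @param compare list of 2-vectors of group names to compare by
#'   permutation; default the first two groups.
#' @param volume optional `list(labels =, mask =)` for the distance stage
#'   (skipped, and logged as skipped, when absent).
#' @param icn optional [icn_membership()] for the ICN stage (requires the
#'   networks' ROI labels to match the membership).
#' @param long_rule `"strict"` or `"inclusive"` median split.
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir, seed = 1L, specs = NULL, tables = NULL,
                       threshold = 1.08, n_perm = 1000L, ci = 0.95,
                       compare = NULL, volume = NULL, icn = NULL,
                       long_rule = "strict") {
  if (is.null(specs) && is.null(tables)) stop("supply either 'specs' or 'tables'")
  structure(list(out_dir = out_dir, seed = as.integer(seed), specs = specs,
                 tables = tables, threshold = threshold,
                 n_perm = as.integer(n_perm), ci = ci, compare = compare,
                 volume = volume, icn = icn, long_rule = long_rule),
            class = "run_config")
}

#' Run the full metabolic-network pipeline
#'
#' Sequences the package's stages: simulate (or ingest) per-group SUVR
#' tables and metadata, stratify and test demographics, build group
#' networks, compute global/regional strength, compare groups with the
#' edge-level ANOVA + Tukey HSD and the permutation test, and — when the
#' inputs are provided — the grey-matter distance control and the ICN
#' aggregation. Every intermediate artifact is written under
#' `config$out_dir` together with a JSON manifest recording the seed,
#' per-stage seeds, stage status and file checksums. Identical configs
#' produce identical artifacts.
#'
#' @param config a [run_config()].
#' @return the run report (invisibly also written as `manifest.json`):
#'   a list with per-stage results and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- c("simulate", "stratify", "build", "anova", "permute",
              "distance", "icn")
  seeds <- stats::setNames(derive_seeds(config$seed, length(stages)), stages)
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))
  report <- list(seed = config$seed, stage_seeds = as.list(seeds))

  # --- simulate / ingest ------------------------------------------------
  if (!is.null(config$specs)) {
    cohorts <- lapply(config$specs, generate_cohort)
    tables <- lapply(cohorts, `[[`, "table")
    subjects <- do.call(rbind, lapply(cohorts, `[[`, "subjects"))
    rownames(subjects) <- NULL
    utils::write.csv(subjects, file.path(config$out_dir, "subjects.csv"),
                     row.names = FALSE, quote = FALSE)
    note("simulate: %d groups generated", length(tables))
  } else {
    tables <- config$tables
    subjects <- NULL
    note("simulate: skipped (tables supplied)")
  }
  for (g in names(tables)) {
    write_suvr_csv(tables[[g]], file.path(config$out_dir, paste0("suvr_", g, ".csv")))
  }

  # --- stratify / demographics -----------------------------------------
  if (!is.null(subjects)) {
    strata <- stratify(subjects, threshold = config$threshold)
    usable <- strata[vapply(strata, nrow, integer(1)) >= 2L]
    report$demographics <- if (length(usable) >= 2L) {
      demographics_tests(usable)
    } else NULL
    report$strata_sizes <- vapply(strata, nrow, integer(1))
    note("stratify: %s", paste(names(strata), report$strata_sizes,
                               sep = "=", collapse = ", "))
  } else {
    note("stratify: skipped (no subject metadata)")
  }

  # --- build ------------------------------------------------------------
  nets <- lapply(names(tables), function(g) build_network(tables[[g]], group = g))
  names(nets) <- names(tables)
  for (g in names(nets)) {
    write_network_csv(nets[[g]],
                      adjacency_path = file.path(config$out_dir, paste0("adj_", g, ".csv")),
                      edges_path = file.path(config$out_dir, paste0("edges_", g, ".csv")))
  }
  clamped <- sum(vapply(nets, `[[`, numeric(1), "n_clamped"))
  if (clamped > 0) note("build: %d correlations clamped before atanh", clamped)
  report$mean_strength <- vapply(nets, mean_strength, numeric(1))
  report$regional_strength <- lapply(nets, regional_strength)
  note("build: %d networks of %d ROIs", length(nets),
       length(nets[[1L]]$roi_labels))

  # --- anova + tukey ----------------------------------------------------
  if (length(nets) >= 2L) {
    report$anova <- edge_anova(nets)
    report$tukey <- tukey_hsd_edges(nets)
    utils::write.csv(report$tukey$contrasts,
                     file.path(config$out_dir, "tukey_contrasts.csv"),
                     row.names = FALSE, quote = FALSE)
    note("anova: F = %.2f on df (%d, %d)", report$anova$F,
         report$anova$df_between, report$anova$df_error)
  } else {
    note("anova: skipped (single group)")
  }

  # --- permutation ------------------------------------------------------
  compare <- config$compare
  if (is.null(compare) && length(tables) >= 2L) {
    compare <- list(names(tables)[1:2])
  }
  report$permutation <- list()
  for (pair in compare) {
    pr <- permutation_regional_diff(tables[[pair[1L]]], tables[[pair[2L]]],
                                    n_perm = config$n_perm,
                                    seed = seeds[["permute"]], ci = config$ci)
    key <- paste(pair, collapse = "_vs_")
    report$permutation[[key]] <- pr
    utils::write.csv(as.data.frame(pr),
                     file.path(config$out_dir, paste0("perm_", key, ".csv")),
                     row.names = FALSE, quote = FALSE)
    if (pr$n_resampled > 0) note("permute %s: %d degenerate reassignments redrawn",
                                 key, pr$n_resampled)
    note("permute %s: %d/%d ROIs significant", key, sum(pr$significant),
         length(pr$roi_labels))
  }

  # --- distance control -------------------------------------------------
  if (!is.null(config$volume)) {
    dm <- pairwise_distance_matrix(config$volume$mask, config$volume$labels,
                                   long_rule = config$long_rule)
    report$distance <- dm
    utils::write.csv(data.frame(roi = dm$roi_labels, dm$steps),
                     file.path(config$out_dir, "distance_steps.csv"),
                     row.names = FALSE, quote = FALSE)
    vol_nets <- nets[vapply(nets, function(n)
      identical(n$roi_labels, dm$roi_labels), logical(1))]
    if (length(vol_nets)) {
      report$long_distance_strength <-
        vapply(vol_nets, long_distance_strength, numeric(1), dm = dm)
      report$distance_correlation <-
        lapply(vol_nets, distance_correlation, dm = dm)
      note("distance: median %.1f steps", dm$median_steps)
    } else {
      note("distance: computed, but no network matches the volume's ROI set")
    }
  } else {
    note("distance: skipped (no volume inputs)")
  }

  # --- icn --------------------------------------------------------------
  if (!is.null(config$icn)) {
    ok <- vapply(nets, function(n) all(config$icn$roi %in% n$roi_labels), logical(1))
    if (any(ok)) {
      report$icn <- lapply(nets[ok], icn_matrix, m = config$icn)
      for (g in names(report$icn)) {
        write_icn_csv(report$icn[[g]],
                      file.path(config$out_dir, paste0("icn_", g, ".csv")))
      }
      note("icn: %d x %d strength matrices for %d group(s)",
           nlevels(config$icn$icn), nlevels(config$icn$icn), sum(ok))
    } else {
      note("icn: skipped (membership ROIs not present in any network)")
    }
  } else {
    note("icn: skipped (no membership)")
  }

  # --- manifest ---------------------------------------------------------
  files <- sort(list.files(config$out_dir, full.names = TRUE, pattern = "\\.csv$"))
  manifest <- list(
    package = "metcovnet",
    version = as.character(utils::packageVersion("metcovnet")),
    seed = config$seed, stage_seeds = as.list(seeds),
    threshold = config$threshold, n_perm = config$n_perm, ci = config$ci,
    log = log,
    checksums = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  report$log <- log
  report$manifest <- manifest
  invisible(report)
}

#' Univariate versus bivariate group differences at two ROIs
#'
#' Contrasts what univariate (per-ROI mean) and bivariate (cross-subject
#' correlation) analyses see at a pair of ROIs: two groups can differ in
#' mean uptake while sharing an identical within-group linear relation, or
#' share identical marginals while differing sharply in the coupling
#' between the regions. For each group the report holds per-ROI means and
#' SDs, the least-squares fit of ROI j on ROI i, its R-squared, and the
#' Pearson correlation; `univariate_p` gives Welch two-sample p-values per
#' ROI and `bivariate_r` the two correlations.
#'
#' @param table_a,table_b [suvr_table()] objects (>= 3 subjects each).
#' @param roi_i,roi_j ROI labels present in both tables.
#' @return list with per-group summaries and the cross-group contrasts.
#' @export
bivariate_demo <- function(table_a, table_b, roi_i, roi_j) {
  tabs <- list(a = table_a, b = table_b)
  for (t in tabs) {
    if (nrow(t) < 3L) stop("each group needs >= 3 subjects")
    if (!all(c(roi_i, roi_j) %in% colnames(t))) {
      stop("ROIs '", roi_i, "'/'", roi_j, "' must be present in both tables")
    }
  }
  per_group <- lapply(tabs, function(t) {
    xi <- t[, roi_i]
    xj <- t[, roi_j]
    fit <- stats::lm(xj ~ xi)
    list(mean_i = mean(xi), mean_j = mean(xj),
         sd_i = stats::sd(xi), sd_j = stats::sd(xj),
         slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         r = stats::cor(xi, xj),
         r_squared = summary(fit)$r.squared)
  })
  list(roi_i = roi_i, roi_j = roi_j, groups = per_group,
       univariate_p = c(
         i = stats::t.test(table_a[, roi_i], table_b[, roi_i])$p.value,
         j = stats::t.test(table_a[, roi_j], table_b[, roi_j])$p.value),
       bivariate_r = c(a = per_group$a$r, b = per_group$b$r))
}
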