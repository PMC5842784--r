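#' Specification of a synthetic cohort
#'
#' Describes one simulated group: its size, regional mean uptake profile, the
#' planted cross-subject covariance regime, and the distributions of its
#' amyloid (PIB index), ApoE e4 and demographic variables. Four regimes are
#' available, emulating qualitatively distinct covariance structures:
#'
#' * `heterogeneous` — mixed-sign edge correlations scattered around a
#'   moderate mean (young-adult-like diversity); params `target` (mean,
#'   default 0.35) and `spread` (sd of the scatter, default 0.25).
#' * `homogeneous_high` — a single high positive correlation on every edge
#'   (amyloid-negative old-age-like metabolic homogeneity); param `target`
#'   (default 0.75).
#' * `intermediate` — homogeneous but dampened (dual-risk-factor-like);
#'   params `target` (default 0.55) and `jitter` (sd, default 0.05).
#' * `long_range_decayed` — correlation decays with inter-ROI distance so
#'   short-range edges stay strong while long-range ones collapse
#'   (disease-like); params `base` (short-range level, default 0.7),
#'   `decay` (exponential rate per distance unit, default 0.06), and
#'   optionally `distances` (an ROI x ROI matrix, e.g. the `steps` field of
#'   a [pairwise_distance_matrix()] result, so the planted decay uses the
#'   same distances analyzed downstream; defaults to ROI index distance).
#'
#' All regime parameter defaults are illustrative: they are qualitative
#' stand-ins for covariance structure never quantified generatively in real
#' cohorts, not estimates of any population.
#'
#' @param group_name group label.
#' @param n_subjects number of subjects (>= 3).
#' @param n_rois number of ROIs.
#' @param mean_profile per-ROI expected SUVR (dimensionless, pons-normalized
#'   scale); default a fixed gradient over 0.8--1.6.
#' @param covariance_regime one of the four regimes above.
#' @param regime_params named list of regime parameters (see Details).
#' @param noise_sd per-ROI marginal SUVR standard deviation (default 0.1).
#' @param pib_mean,pib_sd,pib_range PIB-index distribution (DVR units);
#'   draws are truncated to `pib_range`.
#' @param apoe4_fraction proportion of ApoE e4 carriers in [0, 1].
#' @param age_mean,age_sd,edu_mean,edu_sd,female_fraction demographics.
#' @param seed integer seed; generation is a pure function of the spec.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(group_name, n_subjects, n_rois = 80,
                        mean_profile = NULL,
                        covariance_regime = c("heterogeneous", "homogeneous_high",
                                              "intermediate", "long_range_decayed"),
                        regime_params = list(),
                        noise_sd = 0.1,
                        pib_mean = 1.0, pib_sd = 0.05, pib_range = c(0.9, 1.1),
                        apoe4_fraction = 0.3,
                        age_mean = 75, age_sd = 4,
                        edu_mean = 16, edu_sd = 2,
                        female_fraction = 0.5,
                        seed = 1L) {
  covariance_regime <- match.arg(covariance_regime)
  if (n_subjects < 3L) stop("n_subjects must be >= 3 (correlations degenerate below)")
  if (n_rois < 2L) stop("n_rois must be >= 2")
  if (is.null(mean_profile)) mean_profile <- seq(0.8, 1.6, length.out = n_rois)
  if (length(mean_profile) != n_rois) stop("mean_profile length must equal n_rois")
  if (pib_range[1L] > pib_mean || pib_range[2L] < pib_mean) {
    stop("pib_range must contain pib_mean")
  }
  if (apoe4_fraction < 0 || apoe4_fraction > 1) stop("apoe4_fraction must be in [0, 1]")
  tgt <- c(regime_params$target, regime_params$base)
  if (length(tgt) && any(abs(tgt) >= 1)) stop("target correlations must lie in (-1, 1)")
  structure(list(group_name = group_name, n_subjects = as.integer(n_subjects),
                 n_rois = as.integer(n_rois), mean_profile = mean_profile,
                 covariance_regime = covariance_regime,
                 regime_params = regime_params, noise_sd = noise_sd,
                 pib_mean = pib_mean, pib_sd = pib_sd, pib_range = pib_range,
                 apoe4_fraction = apoe4_fraction,
                 age_mean = age_mean, age_sd = age_sd,
                 edu_mean = edu_mean, edu_sd = edu_sd,
                 female_fraction = female_fraction,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# nearest-PSD repair: clip eigenvalues at a small floor, recompose,
# renormalize to unit diagonal. Deterministic.
nearest_psd_corr <- function(C, floor = 1e-8, regime = "target") {
  C <- (C + t(C)) / 2
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) < floor) {
    C <- e$vectors %*% (pmax(e$values, floor) * t(e$vectors))
    d <- diag(C)
    if (any(d <= 0) || any(!is.finite(C))) {
      stop("covariance regime '", regime, "' produced an irreparable target matrix")
    }
    C <- stats::cov2cor(C)
  }
  C
}

# planted correlation target for a regime; may consume RNG (call under the
# spec's seed)
regime_target_corr <- function(spec) {
  R <- spec$n_rois
  p <- spec$regime_params
  C <- switch(spec$covariance_regime,
    homogeneous_high = {
      target <- if (is.null(p$target)) 0.75 else p$target
      m <- matrix(target, R, R)
      diag(m) <- 1
      m
    },
    intermediate = {
      target <- if (is.null(p$target)) 0.55 else p$target
      jitter <- if (is.null(p$jitter)) 0.05 else p$jitter
      v <- stats::rnorm(R * (R - 1L) / 2L, target, jitter)
      m <- matrix(0, R, R)
      m[upper.tri(m)] <- pmin(pmax(v, -0.95), 0.95)
      m <- m + t(m)
      diag(m) <- 1
      m
    },
    heterogeneous = {
      # one-factor Gram construction: loadings scattered around
      # sqrt(target) give mean edge correlation ~ target with mixed-sign
      # tails, and lambda lambda' + diag(1 - lambda^2) is PSD by
      # construction (no repair distortion of the planted mean)
      target <- if (is.null(p$target)) 0.35 else p$target
      spread <- if (is.null(p$spread)) 0.35 else p$spread
      lam <- stats::rnorm(R, sqrt(max(target, 0)), spread)
      lam <- pmin(pmax(lam, -0.99), 0.99)
      m <- tcrossprod(lam)
      diag(m) <- 1
      m
    },
    long_range_decayed = {
      base <- if (is.null(p$base)) 0.7 else p$base
      decay <- if (is.null(p$decay)) 0.06 else p$decay
      d <- p$distances
      if (is.null(d)) d <- abs(outer(seq_len(R), seq_len(R), "-"))
      if (!all(dim(d) == c(R, R))) stop("regime 'distances' must be n_rois x n_rois")
      m <- base * exp(-decay * d)
      diag(m) <- 1
      m
    })
  nearest_psd_corr(C, regime = spec$covariance_regime)
}

# truncated-normal draws by rejection; deterministic under the active seed
rtruncnorm_rej <- function(n, mean, sd, lower, upper, max_iter = 10000L) {
  out <- numeric(0)
  it <- 0L
  while (length(out) < n && it < max_iter) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
    it <- it + 1L
  }
  if (length(out) < n) stop("truncated-normal rejection failed; widen pib_range")
  out[seq_len(n)]
}

#' Generate a synthetic cohort with planted covariance structure
#'
#' Draws a subjects x ROIs SUVR table from a multivariate normal with the
#' spec's mean profile and planted correlation regime (repaired to the
#' nearest positive semi-definite correlation matrix when needed), together
#' with per-subject metadata: demographics, ApoE e4 status, the four
#' regional amyloid (DVR) composites and the PIB index they average to.
#' Generation is a pure function of the spec, so identical specs yield
#' bit-identical output.
#'
#' @param spec a [cohort_spec()].
#' @return a list with elements `table` (a [suvr_table()]), `subjects`
#'   (a data frame of subject records), and `target_corr` (the planted,
#'   PSD-repaired correlation matrix).
#' @examples
#' cohort <- generate_cohort(cohort_spec("demo", 16, 20,
#'   covariance_regime = "homogeneous_high", seed = 7))
#' dim(cohort$table)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  C <- regime_target_corr(spec)
  sds <- rep_len(spec$noise_sd, spec$n_rois)
  Sigma <- C * tcrossprod(sds)
  X <- MASS::mvrnorm(spec$n_subjects, mu = spec$mean_profile, Sigma = Sigma)
  dimnames(X) <- list(sprintf("%s_%03d", spec$group_name, seq_len(spec$n_subjects)),
                      sprintf("ROI%03d", seq_len(spec$n_rois)))
  tab <- suvr_table(X, group = spec$group_name)

  n <- spec$n_subjects
  pib <- rtruncnorm_rej(n, spec$pib_mean, spec$pib_sd,
                        spec$pib_range[1L], spec$pib_range[2L])
  # four regional DVR composites whose mean is exactly the PIB index
  jit <- matrix(stats::rnorm(4L * n, 0, 0.03), n, 4L)
  jit <- jit - rowMeans(jit)
  dvr <- pmax(pib + jit, 0.05)
  # renormalize in the rare event the positivity floor shifted the mean
  dvr <- dvr + (pib - rowMeans(dvr))
  colnames(dvr) <- c("dvr_prefrontal", "dvr_lattemp", "dvr_parietal", "dvr_cingulate")
  subjects <- data.frame(
    subject_id = rownames(X),
    group = spec$group_name,
    age = round(stats::rnorm(n, spec$age_mean, spec$age_sd), 1),
    sex = ifelse(stats::runif(n) < spec$female_fraction, "F", "M"),
    education = pmax(round(stats::rnorm(n, spec$edu_mean, spec$edu_sd)), 8),
    apoe4 = stats::runif(n) < spec$apoe4_fraction,
    dvr, stringsAsFactors = FALSE)
  subjects$pib_index <- rowMeans(dvr)
  list(table = tab, subjects = subjects, target_corr = C)
}

#' Cohort specs emulating the motivating six-group study design
#'
#' Returns specs for a young group (n = 17, heterogeneous mixed-sign
#' covariance), an Alzheimer's-disease group (n = 22, long-range-decayed),
#' and four old subgroups of 16 crossing amyloid (PIB) status with ApoE e4
#' carriage: the amyloid-negative subgroups get the homogeneous-high regime,
#' PIB+/e4- homogeneous-high, and the dual-risk PIB+/e4+ subgroup the
#' intermediate (dampened) regime. PIB-index distributions follow the
#' published group summaries (means, SDs and ranges); regime correlation
#' levels are illustrative.
#'
#' @param seed master seed; per-group seeds are derived deterministically.
#' @param n_rois number of ROIs (default 80).
#' @return named list of [cohort_spec()] objects.
#' @export
study_cohort_specs <- function(seed = 1L, n_rois = 80) {
  s <- derive_seeds(seed, 6L)
  list(
    young = cohort_spec("young", 17, n_rois,
      covariance_regime = "heterogeneous",
      pib_mean = 0.98, pib_sd = 0.04, pib_range = c(0.92, 1.05),
      apoe4_fraction = 6 / 17, age_mean = 23.59, age_sd = 2.79,
      edu_mean = 15.59, edu_sd = 1.68, female_fraction = 10 / 17, seed = s[1L]),
    ad = cohort_spec("ad", 22, n_rois,
      covariance_regime = "long_range_decayed",
      pib_mean = 1.62, pib_sd = 0.25, pib_range = c(1.11, 2.09),
      apoe4_fraction = 14 / 21, age_mean = 74.82, age_sd = 4.98,
      edu_mean = 16.27, edu_sd = 2.72, female_fraction = 12 / 22, seed = s[2L]),
    old_pibneg_e4neg = cohort_spec("old_pibneg_e4neg", 16, n_rois,
      covariance_regime = "homogeneous_high",
      pib_mean = 1.01, pib_sd = 0.03, pib_range = c(0.96, 1.06),
      apoe4_fraction = 0, age_mean = 75.19, age_sd = 3.68,
      edu_mean = 16.88, edu_sd = 2.23, female_fraction = 7 / 16, seed = s[3L]),
    old_pibneg_e4pos = cohort_spec("old_pibneg_e4pos", 16, n_rois,
      covariance_regime = "homogeneous_high",
      pib_mean = 1.00, pib_sd = 0.08, pib_range = c(0.72, 1.07),
      apoe4_fraction = 1, age_mean = 74.81, age_sd = 3.76,
      edu_mean = 16.88, edu_sd = 2.42, female_fraction = 7 / 16, seed = s[4L]),
    old_pibpos_e4neg = cohort_spec("old_pibpos_e4neg", 16, n_rois,
      covariance_regime = "homogeneous_high",
      pib_mean = 1.26, pib_sd = 0.14, pib_range = c(1.09, 1.54),
      apoe4_fraction = 0, age_mean = 76.31, age_sd = 3.23,
      edu_mean = 16.63, edu_sd = 1.36, female_fraction = 9 / 16, seed = s[5L]),
    old_pibpos_e4pos = cohort_spec("old_pibpos_e4pos", 16, n_rois,
      covariance_regime = "intermediate",
      pib_mean = 1.37, pib_sd = 0.24, pib_range = c(1.08, 1.76),
      apoe4_fraction = 1, age_mean = 75.23, age_sd = 4.57,
      edu_mean = 16.75, edu_sd = 2.22, female_fraction = 11 / 16, seed = s[6L]))
}

#' Generate a toy labeled voxel volume and grey-matter mask
#'
#' Builds small 3-D fixtures for the distance module: an integer label
#' volume (0 = background, 1..k = ROIs) plus a logical grey-matter mask.
#' Layouts:
#'
#' * `corridor` — a straight single-voxel corridor along x with one-voxel
#'   ROIs at both ends; the endpoint geodesic is analytically
#'   `length - 1` steps.
#' * `blocks_with_wall` — two cubic ROI blocks separated by a full-height
#'   wall with a single gap, forcing a detour whose Chebyshev step count is
#'   recorded analytically from the gap geometry.
#' * `random_blobs` — `n_rois` disjoint Chebyshev balls seeded at random
#'   positions in an open mask.
#'
#' @param grid_shape integer vector of 3 dimensions, each >= 3.
#' @param roi_layout one of `"corridor"`, `"blocks_with_wall"`,
#'   `"random_blobs"`.
#' @param seed integer seed (used by `random_blobs`).
#' @param n_rois number of blobs for `random_blobs`.
#' @return list with `labels` (integer array), `mask` (logical array), and
#'   `known_steps` (named list of analytically known geodesic step counts,
#'   where the layout admits them).
#' @export
generate_label_volume <- function(grid_shape, roi_layout = c("corridor",
                                  "blocks_with_wall", "random_blobs"),
                                  seed = 1L, n_rois = 4L) {
  roi_layout <- match.arg(roi_layout)
  if (length(grid_shape) != 3L || any(grid_shape < 3L)) {
    stop("grid_shape must be 3 dimensions, each >= 3")
  }
  d <- as.integer(grid_shape)
  labels <- array(0L, d)
  mask <- array(FALSE, d)
  known <- list()
  if (roi_layout == "corridor") {
    L <- d[1L]
    mask[, 2L, 2L] <- TRUE
    labels[1L, 2L, 2L] <- 1L
    labels[L, 2L, 2L] <- 2L
    known$endpoint_steps <- L - 1L
  } else if (roi_layout == "blocks_with_wall") {
    # the y extent must exceed the x extent so that reaching the gap costs
    # more Chebyshev steps than the direct crossing it replaces
    if (any(d < c(7L, 5L, 3L)) || d[2L] < d[1L]) {
      stop("blocks_with_wall needs a grid of at least 7 x 5 x 3 with y >= x extent")
    }
    mask[] <- TRUE
    wx <- (d[1L] + 1L) %/% 2L        # wall plane
    mask[wx, , ] <- FALSE
    gap <- c(wx, d[2L], d[3L])       # single gap at a far corner
    mask[gap[1L], gap[2L], gap[3L]] <- TRUE
    a <- c(2L, 2L, 2L)
    b <- c(d[1L] - 1L, 2L, 2L)
    labels[a[1L], a[2L], a[3L]] <- 1L
    labels[b[1L], b[2L], b[3L]] <- 2L
    cheb <- function(p, q) max(abs(p - q))
    known$detour_steps <- cheb(a, gap) + cheb(gap, b)
    known$direct_steps <- cheb(a, b)
  } else {
    set.seed(seed)
    mask[] <- TRUE
    radius <- 1L
    centers <- matrix(0L, 0L, 3L)
    tries <- 0L
    while (nrow(centers) < n_rois && tries < 1000L) {
      c0 <- vapply(d, function(k) sample(seq(1L + radius, k - radius), 1L), integer(1))
      ok <- nrow(centers) == 0L ||
        all(apply(abs(sweep(centers, 2L, c0)), 1L, max) > 2L * radius)
      if (ok) centers <- rbind(centers, c0)
      tries <- tries + 1L
    }
    if (nrow(centers) < n_rois) stop("could not place ", n_rois, " disjoint blobs; enlarge grid")
    for (i in seq_len(n_rois)) {
      rng <- lapply(1:3, function(ax) (centers[i, ax] - radius):(centers[i, ax] + radius))
      labels[rng[[1L]], rng[[2L]], rng[[3L]]] <- i
    }
  }
  for (l in seq_len(max(labels))) {
    if (!any(labels == l)) stop("layout produced ROI with zero voxels: label ", l)
  }
  list(labels = labels, mask = mask, known_steps = known)
}

#' Write / read label volumes as plain-text voxel lists
#'
#' One row per in-mask voxel with 0-based integer coordinates and its ROI
#' label (0 for unlabeled grey matter). The grid dimensions are carried in
#' a header comment line.
#'
#' @param labels integer array; @param mask logical array; @param path file.
#' @return `read_voxel_list()` returns `list(labels, mask)`.
#' @export
write_voxel_list <- function(labels, mask, path) {
  idx <- which(mask | labels > 0L, arr.ind = TRUE)
  df <- data.frame(x = idx[, 1L] - 1L, y = idx[, 2L] - 1L, z = idx[, 3L] - 1L,
                   label = labels[idx])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dims %d %d %d", dim(labels)[1L], dim(labels)[2L],
                     dim(labels)[3L]), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_voxel_list
#' @export
read_voxel_list <- function(path) {
  hdr <- readLines(path, n = 1L)
  d <- as.integer(strsplit(sub("^# dims ", "", hdr), " ")[[1L]])
  df <- utils::read.csv(path, comment.char = "#")
  labels <- array(0L, d)
  mask <- array(FALSE, d)
  lin <- cbind(df$x + 1L, df$y + 1L, df$z + 1L)
  mask[lin] <- TRUE
  labels[lin] <- as.integer(df$label)
  list(labels = labels, mask = mask)
}
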