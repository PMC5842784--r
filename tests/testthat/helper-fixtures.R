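# shared fixtures and independent oracles, all built in code

# small SUVR table with hand-enterable values
toy_table <- function() {
  suvr_table(matrix(c(1, 2, 3, 4,    # ROI A
                      2, 4, 6, 8,    # ROI B = 2A, r(A,B) = 1
                      4, 3, 2, 1),   # ROI C = 5 - A, r(A,C) = -1
                    nrow = 4, dimnames = list(paste0("s", 1:4), c("A", "B", "C"))),
             group = "toy")
}

# random metabolic network via a random cohort draw
random_network <- function(seed, n_rois = 12, n_subjects = 30,
                           regime = "heterogeneous") {
  co <- generate_cohort(cohort_spec("rand", n_subjects, n_rois,
                                    covariance_regime = regime, seed = seed))
  build_network(co$table)
}

# independent shortest-path oracle: voxel graph + igraph distances
# (26-neighborhood, unit edge cost)
oracle_vox_distance <- function(mask, a, b) {
  lin <- which(mask)
  d <- dim(mask)
  id <- array(NA_integer_, d)
  id[lin] <- seq_along(lin)
  co <- arrayInd(lin, d)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0L, , drop = FALSE]
  edges <- matrix(integer(0), 0, 2)
  for (k in seq_len(nrow(off))) {
    nb <- sweep(co, 2L, off[k, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    tgt <- rep(NA_integer_, nrow(co))
    tgt[ok] <- id[nb[ok, , drop = FALSE]]
    keep <- !is.na(tgt)
    edges <- rbind(edges, cbind(seq_along(lin)[keep], tgt[keep]))
  }
  g <- igraph::make_empty_graph(n = length(lin), directed = FALSE)
  g <- igraph::add_edges(g, t(edges))
  ia <- id[a[1], a[2], a[3]]
  ib <- id[b[1], b[2], b[3]]
  igraph::distances(g, v = ia, to = ib)[1, 1]
}

# the matching cost exactly as documented, for the exhaustive subset oracle
oracle_match_cost <- function(reference, pool) {
  feats <- c("age", "education")
  all_vals <- rbind(reference[feats], pool[feats])
  mu <- colMeans(all_vals)
  sdv <- apply(all_vals, 2, sd)
  sdv[sdv == 0] <- 1
  zref <- colMeans(scale(reference[feats], mu, sdv))
  zpool <- scale(pool[feats], mu, sdv)
  rowMeans(abs(sweep(zpool, 2, zref))) +
    abs(as.numeric(pool$sex == "F") - mean(reference$sex == "F"))
}

fake_subjects <- function(n, group = "old", seed = 1, age_mean = 75,
                          edu_mean = 16, female_frac = 0.5) {
  set.seed(seed)
  data.frame(subject_id = sprintf("%s_%02d", group, seq_len(n)), group = group,
             age = rnorm(n, age_mean, 4), sex = ifelse(runif(n) < female_frac, "F", "M"),
             education = round(rnorm(n, edu_mean, 2)),
             apoe4 = runif(n) < 0.5, stringsAsFactors = FALSE)
}
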