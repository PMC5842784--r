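test_that("geodesic basics: identity, diagonal step, open-mask Chebyshev", {
  mask <- array(TRUE, c(5, 5, 5))
  expect_identical(grey_matter_geodesic(mask, c(2, 2, 2), c(2, 2, 2)), 0L)
  expect_identical(grey_matter_geodesic(mask, c(2, 2, 2), c(3, 3, 3)), 1L)
  # Chebyshev property on a fully open mask
  set.seed(8)
  for (i in 1:10) {
    a <- sample(5, 3, replace = TRUE)
    b <- sample(5, 3, replace = TRUE)
    expect_identical(grey_matter_geodesic(mask, a, b), as.integer(max(abs(a - b))))
  }
})

test_that("a wall forces a detour matching the brute-force oracle", {
  v <- generate_label_volume(c(9, 9, 3), "blocks_with_wall")
  a <- which(v$labels == 1L, arr.ind = TRUE)[1, ]
  b <- which(v$labels == 2L, arr.ind = TRUE)[1, ]
  got <- grey_matter_geodesic(v$mask, a, b)
  expect_identical(got, as.integer(oracle_vox_distance(v$mask, a, b)))
  expect_identical(got, v$known_steps$detour_steps)
  expect_gt(got, v$known_steps$direct_steps)
})

test_that("disconnected components raise a descriptive error", {
  mask <- array(FALSE, c(5, 3, 3))
  mask[1, 1, 1] <- TRUE
  mask[5, 3, 3] <- TRUE
  expect_error(grey_matter_geodesic(mask, c(1, 1, 1), c(5, 3, 3)), "disconnected")
  expect_error(grey_matter_geodesic(mask, c(2, 2, 2), c(1, 1, 1)), "inside")
})

test_that("geodesic equals the independent oracle on random masks", {
  set.seed(14)
  for (i in 1:15) {
    d <- sample(4:9, 3, replace = TRUE)
    mask <- array(runif(prod(d)) < 0.7, d)
    vox <- which(mask, arr.ind = TRUE)
    if (nrow(vox) < 2) next
    pick <- sample(nrow(vox), 2)
    a <- vox[pick[1], ]
    b <- vox[pick[2], ]
    oracle <- oracle_vox_distance(mask, a, b)
    if (is.infinite(oracle)) {
      expect_error(grey_matter_geodesic(mask, a, b), "disconnected")
    } else {
      expect_identical(grey_matter_geodesic(mask, a, b), as.integer(oracle))
    }
  }
})

test_that("center of mass minimizes summed geodesics, ties lexicographic", {
  mask <- array(TRUE, c(5, 5, 3))
  # symmetric 3x3x1 block: the central voxel wins
  block <- as.matrix(expand.grid(2:4, 2:4, 2))
  expect_identical(roi_center_of_mass(mask, block), c(3L, 3L, 2L))
  # single voxel ROI is its own center
  expect_identical(roi_center_of_mass(mask, matrix(c(4L, 4L, 2L), 1)),
                   c(4L, 4L, 2L))
  # L-shaped ROI: exhaustive oracle over candidate voxels
  L <- rbind(c(1, 1, 1), c(2, 1, 1), c(3, 1, 1), c(3, 2, 1), c(3, 3, 1))
  costs <- apply(L, 1, function(v) {
    sum(apply(L, 1, function(w) oracle_vox_distance(mask, v, w)))
  })
  best <- L[order(costs, L[, 1], L[, 2], L[, 3])[1], ]
  expect_identical(roi_center_of_mass(mask, L), as.integer(best))
})

test_that("pairwise distances: corridor spacing, median split, triangle inequality", {
  # straight corridor with single-voxel ROIs 6 apart
  mask <- array(FALSE, c(9, 3, 3))
  mask[, 2, 2] <- TRUE
  labels <- array(0L, c(9, 3, 3))
  labels[2, 2, 2] <- 1L
  labels[8, 2, 2] <- 2L
  dm <- pairwise_distance_matrix(mask, labels)
  expect_identical(dm$steps[1, 2], 6L)
  expect_identical(unname(dm$centers[1, ]), c(2L, 2L, 2L))

  # 4 ROIs on a line at x = 1, 2, 4, 8: pairwise steps {1,3,7,2,6,4}
  mask2 <- array(FALSE, c(9, 3, 3))
  mask2[, 2, 2] <- TRUE
  lab2 <- array(0L, c(9, 3, 3))
  lab2[cbind(c(1, 2, 4, 8), 2, 2)] <- 1:4
  dm2 <- pairwise_distance_matrix(mask2, lab2)
  expect_equal(sort(dm2$steps[upper.tri(dm2$steps)]), c(1, 2, 3, 4, 6, 7))
  expect_equal(dm2$median_steps, 3.5)  # mean of middle order statistics
  # strictly-above-median rule
  long <- dm2$steps[upper.tri(dm2$steps)] > 3.5
  expect_identical(unname(dm2$long_edge_mask[upper.tri(dm2$long_edge_mask)]), long)
  expect_identical(sum(long), 3L)
  # inclusive rule can only add edges
  dm2i <- pairwise_distance_matrix(mask2, lab2, long_rule = "inclusive")
  expect_gte(sum(dm2i$long_edge_mask), sum(dm2$long_edge_mask))

  # triangle inequality and symmetry on a random blob volume
  v <- generate_label_volume(c(8, 8, 8), "random_blobs", seed = 6, n_rois = 4)
  dmr <- pairwise_distance_matrix(v$mask, v$labels)
  s <- dmr$steps
  expect_identical(s, t(s))
  for (i in 1:4) for (j in 1:4) for (k in 1:4) {
    expect_lte(s[i, j], s[i, k] + s[k, j])
  }
  # all distances equal => no long edges under the strict rule
  same <- matrix(5L, 2, 2)
  diag(same) <- 0L
  expect_true(all(same[upper.tri(same)] <= median(same[upper.tri(same)])))
})

test_that("long-distance restriction behaves and decayed networks weaken with distance", {
  net <- random_network(77, n_rois = 6)
  dm <- list(roi_labels = net$roi_labels,
             steps = matrix(3L, 6, 6) - diag(3L, 6),
             median_steps = 2,
             long_edge_mask = matrix(TRUE, 6, 6) & !diag(TRUE, 6),
             long_rule = "strict")
  class(dm) <- "gm_distance"
  # all edges long: restricted strength equals global strength
  expect_equal(long_distance_strength(net, dm), mean_strength(net))
  dm$long_edge_mask[] <- FALSE
  expect_error(long_distance_strength(net, dm), "no long-distance")

  # planted distance decay: long-distance strength < all-edge strength,
  # and edge Z correlates negatively with distance
  steps <- abs(outer(1:20, 1:20, "-"))
  co <- generate_cohort(cohort_spec("adlike", 40, 20,
    covariance_regime = "long_range_decayed",
    regime_params = list(base = 0.7, decay = 0.15, distances = steps),
    seed = 12))
  netd <- build_network(co$table)
  med <- median(steps[upper.tri(steps)])
  dmd <- structure(list(roi_labels = netd$roi_labels, steps = steps,
                        median_steps = med, long_edge_mask = steps > med,
                        long_rule = "strict"), class = "gm_distance")
  expect_lt(long_distance_strength(netd, dmd), mean_strength(netd))
  dc <- distance_correlation(netd, dmd)
  expect_lt(dc$r, -0.5)
  expect_lt(dc$p, 1e-6)
  expect_identical(dc$n_edges, 190L)
})

test_that("distance correlation closed forms: affine decay and printed toy", {
  # edge Z exactly affine-decreasing in steps -> r = -1
  z <- matrix(NA_real_, 4, 4)
  steps <- matrix(0L, 4, 4)
  pairs <- which(upper.tri(z), arr.ind = TRUE)
  svals <- c(1, 2, 3, 4, 5, 6)
  for (k in seq_len(nrow(pairs))) {
    steps[pairs[k, 1], pairs[k, 2]] <- steps[pairs[k, 2], pairs[k, 1]] <- svals[k]
    zv <- 1 - 0.1 * svals[k]
    z[pairs[k, 1], pairs[k, 2]] <- z[pairs[k, 2], pairs[k, 1]] <- zv
  }
  net <- structure(list(roi_labels = paste0("R", 1:4), corr = tanh(z), z = z,
                        n_subjects = 10, group = "toy"),
                   class = "metabolic_network")
  dm <- structure(list(roi_labels = paste0("R", 1:4), steps = steps,
                       median_steps = median(svals),
                       long_edge_mask = steps > median(svals),
                       long_rule = "strict"), class = "gm_distance")
  expect_equal(distance_correlation(net, dm)$r, -1)

  # 5-edge toy with hand-computed Pearson r
  s5 <- c(1, 2, 3, 4, 5)
  z5 <- c(0.9, 0.7, 0.8, 0.3, 0.2)
  r_hand <- sum((s5 - mean(s5)) * (z5 - mean(z5))) /
    sqrt(sum((s5 - mean(s5))^2) * sum((z5 - mean(z5))^2))
  expect_equal(cor(z5, s5), r_hand)
})
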