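test_that("edge ANOVA degrees of freedom follow k and E analytically", {
  # property over several (k, R) shapes: df_error = kE - k, df_between = k - 1
  for (shape in list(c(2, 10), c(3, 15), c(5, 8))) {
    k <- as.integer(shape[1])
    R <- shape[2]
    nets <- lapply(seq_len(k), function(i) random_network(100 + i, n_rois = R))
    names(nets) <- paste0("g", seq_len(k))
    a <- edge_anova(nets)
    E <- R * (R - 1) / 2
    expect_identical(a$n_edges, as.integer(E))
    expect_identical(a$df_between, k - 1L)
    expect_identical(a$df_error, as.integer(k * E - k))
  }
})

test_that("identical group networks give F = 0 and no Tukey hits", {
  net <- random_network(7, n_rois = 10)
  a <- edge_anova(list(g1 = net, g2 = net))
  expect_equal(a$F, 0)
  tk <- tukey_hsd_edges(list(g1 = edge_z_values(net), g2 = edge_z_values(net)))
  expect_false(any(tk$contrasts$significant))
  n2 <- random_network(8, n_rois = 11)
  expect_error(edge_anova(list(a = net, b = n2)), "mismatched")
})

test_that("a strongly shifted group is the only Tukey-significant contrast", {
  # planted edge-Z means 0.2 / 0.2 / 0.8 at E = 3160: power ~ 1 at this
  # separation, and the equal pair should rarely separate
  set.seed(31)
  hits <- replicate(20, {
    E <- 3160
    zs <- list(g1 = rnorm(E, 0.2, 0.3), g2 = rnorm(E, 0.2, 0.3),
               g3 = rnorm(E, 0.8, 0.3))
    tk <- tukey_hsd_edges(zs)$contrasts
    third <- grepl("g3", tk$pair)
    c(all(tk$significant[third]), tk$significant[!third])
  })
  expect_gte(mean(hits[1, ]), 0.99)   # contrasts involving g3 always found
  expect_lte(mean(hits[2, ]), 0.2)    # null pair rarely flagged
})

test_that("Tukey simultaneous intervals cover a true zero difference", {
  set.seed(77)
  covered <- replicate(200, {
    zs <- list(a = rnorm(100, 0.3, 0.25), b = rnorm(100, 0.3, 0.25),
               c = rnorm(100, 0.3, 0.25))
    tk <- tukey_hsd_edges(zs)$contrasts
    all(tk$lwr <= 0 & tk$upr >= 0)
  })
  expect_equal(mean(covered), 0.95, tolerance = 0.05)
})

test_that("pooling concatenates subjects and rejects duplicates", {
  specs <- study_cohort_specs(seed = 9, n_rois = 12)
  tabs <- lapply(specs[c("old_pibneg_e4neg", "old_pibneg_e4pos",
                         "old_pibpos_e4neg")],
                 function(s) generate_cohort(s)$table)
  pooled <- pool_groups(tabs, group = "other_old")
  expect_identical(nrow(pooled), 48L)
  expect_identical(colnames(pooled), colnames(tabs[[1]]))
  expect_identical(pool_groups(tabs[1]), tabs[[1]])
  expect_error(pool_groups(list(tabs[[1]], tabs[[1]])), "duplicate subject_id")
})

test_that("identical tables yield zero observed differences and no hits", {
  co <- generate_cohort(cohort_spec("g", 10, 8, seed = 15))
  pr <- permutation_regional_diff(co$table, co$table, n_perm = 200, seed = 1)
  expect_equal(unname(pr$observed_diff), rep(0, 8))
  expect_false(any(pr$significant))
  expect_true(all(pr$p_uncorrected > 0 & pr$p_uncorrected <= 1))
})

test_that("sampled permutation null matches exhaustive enumeration on 3+3", {
  co <- generate_cohort(cohort_spec("a", 6, 5, seed = 23))
  xa <- unclass(co$table)[1:3, , drop = FALSE]
  xb <- unclass(co$table)[4:6, , drop = FALSE]
  ta <- suvr_table(xa, group = "a")
  tb <- suvr_table(xb, group = "b")
  ex <- permutation_regional_diff(ta, tb, exhaustive = TRUE)
  expect_identical(ex$n_perm, 20L)  # all C(6,3) assignments

  # independent oracle: enumerate assignments with plain cor/atanh arithmetic
  pooled <- rbind(xa, xb)
  regz <- function(x) {
    z <- atanh(pmin(pmax(cor(x), -1 + 1e-12), 1 - 1e-12))
    diag(z) <- NA
    rowMeans(z, na.rm = TRUE)
  }
  oracle <- t(apply(combn(6, 3), 2, function(idx) {
    tanh(regz(pooled[idx, , drop = FALSE]) - regz(pooled[-idx, , drop = FALSE]))
  }))
  for (j in 1:5) {
    expect_equal(sort(ex$null[, j]), sort(oracle[, j]), tolerance = 1e-12)
  }

  # interval decisions of a sampled null agree with full enumeration
  sa <- permutation_regional_diff(ta, tb, n_perm = 4000, seed = 99)
  expect_identical(sa$significant, ex$significant)
})

test_that("permutation results are bit-reproducible given the seed", {
  co <- generate_cohort(cohort_spec("a", 8, 6, seed = 40))
  cb <- generate_cohort(cohort_spec("b", 7, 6, seed = 41))
  p1 <- permutation_regional_diff(co$table, cb$table, n_perm = 300, seed = 5)
  p2 <- permutation_regional_diff(co$table, cb$table, n_perm = 300, seed = 5)
  expect_identical(p1$null, p2$null)
  expect_identical(p1$p_uncorrected, p2$p_uncorrected)
  p3 <- permutation_regional_diff(co$table, cb$table, n_perm = 300, seed = 6)
  expect_false(identical(p1$null, p3$null))
})

test_that("significance is exactly interval exclusion and p is super-uniform", {
  co <- generate_cohort(cohort_spec("a", 12, 10, seed = 50))
  cb <- generate_cohort(cohort_spec("b", 12, 10, seed = 51))
  pr <- permutation_regional_diff(co$table, cb$table, n_perm = 500, seed = 2)
  expect_identical(unname(pr$significant),
                   unname(pr$observed_diff < pr$null_lower |
                          pr$observed_diff > pr$null_upper))
  expect_true(all(pr$null_lower <= pr$null_upper))
  # exchangeable null: pooled p-values should not pile up below uniform
  set.seed(60)
  ps <- unlist(lapply(1:10, function(i) {
    a <- generate_cohort(cohort_spec("a", 10, 6,
      regime_params = list(target = 0, spread = 0), seed = 600 + i))$table
    b <- generate_cohort(cohort_spec("b", 10, 6,
      regime_params = list(target = 0, spread = 0), seed = 700 + i))$table
    permutation_regional_diff(a, b, n_perm = 400, seed = i)$p_uncorrected
  }))
  expect_lte(mean(ps <= 0.05), 0.05 + 2.576 * sqrt(0.05 * 0.95 / length(ps)))
})
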