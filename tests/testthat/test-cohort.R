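test_that("PIB index is the mean of the four regional composites", {
  expect_equal(pib_index(c(1.0, 1.0, 1.0, 1.0)), 1.00)
  expect_equal(pib_index(c(1.2, 1.3, 1.25, 1.45)), 1.30)
  expect_equal(pib_index(c(0.92, 0.96, 1.00, 1.04)), 0.98)
  expect_error(pib_index(c(1.2, 1.3, 1.25)), "4 regional")
  expect_error(pib_index(c(1.2, 1.3, NA, 1.45)), "missing")
  expect_true(is.na(pib_index(c(1.2, 1.3, NA, 1.45), allow_missing = TRUE)))
  expect_error(pib_index(c(-1, 1, 1, 1)), "positive")
})

test_that("amyloid classification is threshold-inclusive and monotone", {
  expect_identical(classify_amyloid(1.08), "PIB+")   # boundary is positive
  expect_identical(classify_amyloid(1.0799), "PIB-")
  expect_identical(classify_amyloid(1.62), "PIB+")
  idx <- seq(0.9, 1.8, by = 0.01)
  cls <- classify_amyloid(idx)
  expect_true(all(diff(cls == "PIB+") >= 0))  # monotone in the index
  expect_identical(classify_amyloid(1.3, threshold = 1.4), "PIB-")
  expect_error(classify_amyloid(NA_real_), "missing")
})

test_that("stratification partitions old subjects into the four risk cells", {
  subj <- fake_subjects(64, "old", seed = 2)
  subj$pib_index <- rep(c(1.2, 1.2, 1.0, 1.0), each = 16)
  subj$apoe4 <- rep(c(TRUE, FALSE, TRUE, FALSE), each = 16)
  st <- stratify(subj)
  expect_named(st, c("PIB-/e4-", "PIB-/e4+", "PIB+/e4-", "PIB+/e4+"))
  expect_true(all(vapply(st, nrow, integer(1)) == 16L))
  # exhaustive and disjoint
  ids <- unlist(lapply(st, `[[`, "subject_id"))
  expect_setequal(ids, subj$subject_id)
  expect_identical(anyDuplicated(ids), 0L)
  # degenerate: all in one cell
  subj$pib_index <- 1.0
  subj$apoe4 <- FALSE
  st2 <- stratify(subj)
  expect_identical(nrow(st2$`PIB-/e4-`), 64L)
  expect_identical(sum(vapply(st2[c("PIB-/e4+", "PIB+/e4-", "PIB+/e4+")],
                              nrow, integer(1))), 0L)
  # classification of an already-stratified cohort is idempotent
  st3 <- stratify(do.call(rbind, st2))
  expect_identical(vapply(st3, nrow, integer(1)), vapply(st2, nrow, integer(1)))
  subj$apoe4[3] <- NA
  expect_error(stratify(subj), subj$subject_id[3])
})

test_that("young and AD groups pass through stratification unchanged", {
  subj <- rbind(fake_subjects(5, "young"), fake_subjects(4, "ad"))
  subj$pib_index <- 1.0
  st <- stratify(subj)
  expect_identical(nrow(st$young), 5L)
  expect_identical(nrow(st$ad), 4L)
})

test_that("matching selects exact demographic copies at cost zero", {
  ref <- fake_subjects(6, "ref", seed = 3)
  copies <- ref
  copies$subject_id <- paste0("copy_", seq_len(6))
  # distractors far from the reference demographics
  far <- fake_subjects(6, "far", seed = 4, age_mean = 40, edu_mean = 8)
  # a perfect pool member has the reference MEAN demographics
  ideal <- ref[1, ]
  ideal$subject_id <- "ideal"
  ideal$age <- mean(ref$age)
  ideal$education <- mean(ref$education)
  pool <- rbind(ideal, far)
  got <- match_subgroups(ref, pool, 1)
  expect_identical(got$subject_id, "ideal")
  # matching a group against itself with k = n returns itself
  self <- match_subgroups(ref, ref, nrow(ref))
  expect_setequal(self$subject_id, ref$subject_id)
  expect_error(match_subgroups(ref, far, 10), "pool smaller")
})

test_that("greedy matching agrees with the exhaustive subset oracle", {
  ref <- fake_subjects(5, "ref", seed = 11)
  pool <- fake_subjects(7, "pool", seed = 12)
  k <- 3
  got <- match_subgroups(ref, pool, k)
  cost <- oracle_match_cost(ref, pool)
  subsets <- combn(nrow(pool), k)
  best <- subsets[, which.min(colSums(matrix(cost[subsets], nrow = k)))]
  expect_setequal(got$subject_id, pool$subject_id[best])
})

test_that("demographics tests match closed-form chi-squared arithmetic", {
  g1 <- fake_subjects(16, "a", seed = 5)
  g2 <- fake_subjects(16, "b", seed = 6)
  # planted 2x2 table (10,6; 4,12) on sex
  g1$sex <- rep(c("F", "M"), c(10, 6))
  g2$sex <- rep(c("F", "M"), c(4, 12))
  res <- demographics_tests(list(a = g1, b = g2))
  O <- rbind(c(10, 6), c(4, 12))
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  expect_equal(res$dichotomous$sex$pairwise$statistic[1], sum((O - E)^2 / E))
  expect_equal(res$dichotomous$sex$omnibus$statistic, sum((O - E)^2 / E))
  # identical sex ratios give statistic 0
  g2$sex <- g1$sex
  res0 <- demographics_tests(list(a = g1, b = g2))
  expect_equal(res0$dichotomous$sex$omnibus$statistic, 0)
  expect_error(demographics_tests(list(a = g1, b = g2[1, ])), "size < 2")
})

test_that("Bonferroni adjustment multiplies by the test count and caps at 1", {
  expect_equal(p.adjust(0.01, "bonferroni", n = 6), 0.06)
  g <- lapply(1:4, function(i) fake_subjects(10, paste0("g", i), seed = i))
  names(g) <- paste0("g", 1:4)
  res <- demographics_tests(g)
  pw <- res$dichotomous$sex$pairwise
  expect_equal(pw$p_bonferroni, pmin(pw$p_raw * nrow(pw), 1))
})

test_that("matched groups are rarely flagged (calibration)", {
  flags <- vapply(1:40, function(i) {
    g1 <- fake_subjects(30, "a", seed = 100 + i)
    g2 <- fake_subjects(30, "b", seed = 200 + i)
    length(demographics_tests(list(a = g1, b = g2))$significant)
  }, integer(1))
  # 4 features, each protected at FWE 0.05: flag-free runs should dominate
  expect_gte(mean(flags == 0), 0.7)
})
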