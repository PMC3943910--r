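test_that("c_statistic equals brute-force Mann-Whitney pair counting", {
  expect_identical(c_statistic(c(2, 4), c(1, 3)), 0.75)
  expect_identical(c_statistic(c(10, 11), c(1, 2)), 1)
  expect_identical(c_statistic(c(1, 2, 3), c(1, 2, 3)), 0.5)
  expect_identical(c_statistic(c(5, 5), c(5, 5, 5)), 0.5)  # pure ties
  expect_error(c_statistic(numeric(0), 1), "non-empty")
  expect_error(c_statistic(c(1, NA), 1), "finite")

  set.seed(101)
  for (i in 1:300) {
    nd <- sample(1:8, 1); nc <- sample(1:8, 1)
    d <- sample(0:6, nd, replace = TRUE) / 2  # plenty of ties
    c <- sample(0:6, nc, replace = TRUE) / 2
    expect_identical(c_statistic(d, c), cstat_brute(d, c))
    # antisymmetry under group exchange (exact up to one ulp of 1 - x)
    expect_equal(c_statistic(d, c), 1 - c_statistic(c, d), tolerance = 1e-12)
    # folding is invariant under relabelling of the groups
    expect_equal(max(c_statistic(d, c), 1 - c_statistic(d, c)),
                 max(c_statistic(c, d), 1 - c_statistic(c, d)),
                 tolerance = 1e-12)
  }
})

test_that("score_segments matches the per-column C-statistic oracle", {
  X <- cbind(c(1, 2, 10, 11), c(3, 1, 2, 4))  # col 1 separates perfectly
  gm <- make_gm(X, c("control", "control", "disease", "disease"))
  sc <- score_segments(gm)
  expect_equal(sc$segment, 1:2)
  for (k in 1:2)
    expect_identical(sc$auc[k], c_statistic(X[3:4, k], X[1:2, k]))
  expect_identical(sc$folded_auc[1], 1)
  expect_equal(sc$rank, c(1L, 2L))
  expect_equal(sc$direction[1], "disease_higher")

  const <- make_gm(matrix(7, 4, 3), c("disease", "disease", "control", "control"))
  sc0 <- score_segments(const)
  expect_true(all(sc0$folded_auc == 0.5))
  expect_true(all(sc0$direction == "disease_higher"))  # tie convention
  expect_equal(sc0$rank, 1:3)  # folded ties break by segment index

  expect_error(score_segments(make_gm(X, rep("disease", 4))), "per class")
})

test_that("permutation_null is seed-reproducible and matches exact enumeration", {
  set.seed(5)
  X <- matrix(rnorm(8 * 4), 8, 4)
  gm <- make_gm(X, rep(c("disease", "control"), each = 4))
  n1 <- permutation_null(gm, n_reps = 10, seed = 3)
  n2 <- permutation_null(gm, n_reps = 10, seed = 3)
  expect_identical(n1, n2)
  expect_equal(dim(n1$folded), c(10L, 4L))
  expect_equal(nrow(permutation_null(gm, n_reps = 1, seed = 1)$folded), 1L)
  expect_error(permutation_null(gm, n_reps = 0, seed = 1), "n_reps")

  # 3+3 subjects: the sampled null must match the exhaustive 20-arrangement
  # distribution of the folded AUC (independent enumeration oracle)
  v <- c(0.3, 1.2, -0.5, 2.2, 0.9, -1.4)
  gm6 <- make_gm(matrix(v, 6, 1), rep(c("disease", "control"), each = 3))
  exact <- exact_folded_null(v, 3)
  emp <- permutation_null(gm6, n_reps = 4000, seed = 8)$folded[, 1]
  expect_true(all(emp %in% unique(exact)))
  expect_equal(mean(emp), mean(exact), tolerance = 0.02)

  # mean folded AUC under the null approximates E[max(U, 1-U)] by enumeration
  expect_equal(mean(permutation_null(gm, n_reps = 500, seed = 2)$folded),
               mean(exact_folded_null(rnorm(8), 4)), tolerance = 0.03)
})

test_that("rank-abundance curves count candidates above each accuracy level", {
  scores <- data.frame(segment = 1:3, auc = c(1, 0.25, 0.5),
                       folded_auc = c(1, 0.75, 0.5),
                       direction = c("disease_higher", "disease_lower",
                                     "disease_higher"),
                       rank = c(1L, 2L, 3L))
  null <- structure(list(folded = rbind(c(0.5, 0.5, 0.75), c(0.5, 0.6, 0.5)),
                         n_reps = 2L, seed = 1L),
                    class = "permutation_null")
  ra <- rank_abundance(scores, null, grid_step = 0.25)
  expect_equal(ra$curves$accuracy, c(0.5, 0.75, 1))
  expect_equal(ra$curves$correct_count, c(3, 2, 1))   # hand tally
  expect_equal(ra$curves$random_count, c(3, 0.5, 0))  # mean of the two reps
  # boundary: both curves equal n_segments at accuracy 0.5
  expect_equal(ra$curves$correct_count[1], 3)
  expect_equal(ra$curves$random_count[1], 3)
  # both curves non-increasing
  expect_true(all(diff(ra$curves$correct_count) <= 0))
  expect_true(all(diff(ra$curves$random_count) <= 0))

  expect_error(rank_abundance(scores[1:2, ], null), "different segment sets")
})

test_that("the below-one rule selects where the random curve declines under 1", {
  scores <- data.frame(segment = 1:3, auc = c(1, 0.25, 0.5),
                       folded_auc = c(1, 0.75, 0.5),
                       direction = c("disease_higher", "disease_lower",
                                     "disease_higher"),
                       rank = c(1L, 2L, 3L))
  null <- structure(list(folded = rbind(c(0.5, 0.5, 0.75), c(0.5, 0.6, 0.5)),
                         n_reps = 2L, seed = 1L),
                    class = "permutation_null")
  ra <- rank_abundance(scores, null, grid_step = 0.25)
  sel <- select_biomarkers(ra, scores)
  expect_equal(sel$threshold, 0.75)  # first grid point with random < 1
  expect_equal(sel$selected$segment, c(1, 2))
  expect_equal(sel$excess_count, 2 - 0.5)

  # random curve never below 1 -> empty selection with a warning, not error
  flat_null <- structure(list(folded = matrix(1, 2, 3), n_reps = 2L, seed = 1L),
                         class = "permutation_null")
  ra2 <- rank_abundance(scores, flat_null, grid_step = 0.25)
  expect_warning(sel2 <- select_biomarkers(ra2, scores), "never declines")
  expect_equal(nrow(sel2$selected), 0L)
  expect_true(is.na(sel2$threshold))
})

test_that("adjacent selected segments merge into single biomarker peaks", {
  sel <- data.frame(segment = c(10L, 11L, 12L, 40L),
                    auc = c(0.9, 0.95, 0.85, 0.8),
                    folded_auc = c(0.9, 0.95, 0.85, 0.8),
                    direction = "disease_higher", rank = 1:4)
  m <- merge_adjacent(sel, max_gap = 1)
  expect_equal(nrow(m), 2L)
  expect_equal(m$start_segment, c(10L, 40L))
  expect_equal(m$end_segment, c(12L, 40L))
  expect_equal(m$representative, c(11L, 40L))  # highest folded AUC in run

  # representative tie -> earliest segment
  tie <- data.frame(segment = 5:6, auc = c(0.9, 0.9), folded_auc = c(0.9, 0.9),
                    direction = "disease_higher", rank = 1:2)
  expect_equal(merge_adjacent(tie)$representative, 5L)
  # max rule from the module contract: folded {0.8, 0.9} -> representative 6
  tie$folded_auc <- c(0.8, 0.9)
  expect_equal(merge_adjacent(tie)$representative, 6L)

  # a gap of exactly max_gap merges; one more splits
  g <- data.frame(segment = c(1L, 3L), auc = c(0.9, 0.8),
                  folded_auc = c(0.9, 0.8), direction = "disease_higher",
                  rank = 1:2)
  expect_equal(nrow(merge_adjacent(g, max_gap = 1)), 1L)
  expect_equal(nrow(merge_adjacent(g, max_gap = 0)), 2L)

  expect_equal(nrow(merge_adjacent(NULL)), 0L)
  expect_equal(nrow(merge_adjacent(sel[0, ])), 0L)
})

test_that("discovery recovers a planted separator and stays quiet on nulls", {
  set.seed(17)
  n <- 20
  X <- matrix(rnorm(n * 25), n, 25)
  lab <- rep(c("disease", "control"), each = n / 2)
  X[lab == "disease", 7] <- X[lab == "disease", 7] + 4  # near-perfect marker
  gm <- make_gm(X, lab)
  disc <- discover_biomarkers(gm, seed = 2)
  expect_gte(nrow(disc$merged), 1L)
  expect_true(7 %in% disc$selected$segment)
  expect_true(any(disc$merged$start_segment <= 7 & disc$merged$end_segment >= 7))
  expect_true(all(disc$selected$folded_auc >= disc$threshold - 1e-9))
})
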