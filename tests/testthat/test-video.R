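test_that("subset curve at k = V reproduces the full-sample rho exactly", {
  pl <- planted_cells(P = 30, V = 6, seed = 21)
  curve <- subset_effect_curve(pl$cells, pl$questionnaires,
                               k_min = 2, iters = 50, seed = 22)
  full <- curve$mean_rho[curve$k == 6]
  expect_identical(full, attr(curve, "full_rho"))
  expect_equal(curve$iterations[curve$k == 6], 1L)
  # and the full rho is just the pooled-accuracy Spearman
  Z <- tidyr::pivot_wider(pl$cells[, c("participant_id", "video_id", "r")],
                          names_from = "video_id", values_from = "r")
  pooled <- tanh(rowMeans(atanh(pmin(pmax(as.matrix(Z[, -1]), -1 + 1e-7), 1 - 1e-7))))
  expect_equal(full, unname(cor(pooled, pl$questionnaires$aq, method = "spearman")),
               tolerance = 1e-12)
})

test_that("sampled subset means agree with exhaustive enumeration at toy scale", {
  pl <- planted_cells(P = 25, V = 6, seed = 23)
  cm_subsets <- utils::combn(6, 2, simplify = FALSE)
  # exhaustive oracle, coded independently: mean over all C(6,2) subsets
  Z <- tidyr::pivot_wider(pl$cells[, c("participant_id", "video_id", "r")],
                          names_from = "video_id", values_from = "r")
  Z <- as.matrix(Z[, -1])[, order(colnames(Z)[-1])]
  zf <- atanh(pmin(pmax(Z, -1 + 1e-7), 1 - 1e-7))
  rho_of <- function(sel) {
    pooled <- tanh(rowMeans(zf[, sel, drop = FALSE]))
    cor(rank(pooled), rank(pl$questionnaires$aq))
  }
  exhaustive <- tanh(mean(atanh(vapply(cm_subsets, rho_of, numeric(1)))))
  curve <- subset_effect_curve(pl$cells, pl$questionnaires,
                               k_min = 2, k_max = 2, iters = 4000, seed = 24)
  expect_lt(abs(curve$mean_rho[1] - exhaustive), 0.02)
})

test_that("curve magnitude is non-decreasing in k up to Monte-Carlo noise", {
  pl <- planted_cells(P = 60, V = 8, signal = sprintf("V%02d", 1:8), seed = 25)
  curve <- subset_effect_curve(pl$cells, pl$questionnaires,
                               k_min = 2, iters = 500, seed = 26)
  expect_true(all(diff(abs(curve$mean_rho)) > -0.02))
})

test_that("threshold arithmetic and sentinel behave per contract", {
  curve <- tibble::tibble(k = 5:8, mean_rho = c(0.20, 0.25, 0.28, 0.30))
  res <- min_videos_for_threshold(curve, full_rho = 0.37, fraction = 0.75)
  expect_equal(res$threshold, 0.2775)
  expect_equal(res$k_star, 7L)
  expect_true(res$reached)

  res2 <- min_videos_for_threshold(
    tibble::tibble(k = 5:8, mean_rho = rep(0.1, 4)), full_rho = 0.37)
  expect_false(res2$reached)
  expect_true(is.na(res2$k_star))

  expect_error(min_videos_for_threshold(
    tibble::tibble(k = c(5, 7), mean_rho = c(0.1, 0.2)), full_rho = 0.37),
    class = "iettrack_invalid_argument")
})

test_that("best_videos recovers a planted signal subset and breaks ties by id", {
  sig <- c("V02", "V05", "V07", "V09")
  pl <- planted_cells(P = 200, V = 10, signal = sig, slope = -0.025,
                      noise = 0.05, seed = 27)
  sel <- best_videos(pl$cells, pl$questionnaires, n_best = 4)
  expect_setequal(sel$selected, sig)
  expect_equal(nrow(sel$table), 10L)

  # stable under row-order permutation of the input cells
  shuf <- pl$cells[withr::with_seed(28, sample.int(nrow(pl$cells))), ]
  sel2 <- best_videos(shuf, pl$questionnaires, n_best = 4)
  expect_identical(sel$selected, sel2$selected)
  expect_equal(sel$table, sel2$table)

  # n_best = V returns everything, ordered by rho then id
  all_v <- best_videos(pl$cells, pl$questionnaires, n_best = 10)
  expect_equal(sort(all_v$selected), sort(unique(pl$cells$video_id)))
  expect_error(best_videos(pl$cells, pl$questionnaires, n_best = 11),
               class = "iettrack_invalid_argument")
})

test_that("cross-validated correlation: chunk sizes, extremes, determinism", {
  withr::with_seed(29, {
    x <- rnorm(102)
  })
  res <- crossval_correlation(x, x + 1, folds = 5, iters = 200, seed = 30)
  expect_gt(res$mean_rho, 0.99)
  expect_gt(res$ci_low, 0.9)
  expect_equal(res$n, 102L)

  # partition arithmetic: 102 into 5 chunks of {21, 21, 20, 20, 20}
  sizes <- rep(102 %/% 5, 5); sizes[1:2] <- sizes[1:2] + 1L
  expect_equal(sort(sizes, decreasing = TRUE), c(21, 21, 20, 20, 20))

  res2 <- crossval_correlation(x, x + 1, folds = 5, iters = 200, seed = 30)
  expect_identical(res, res2)
})

test_that("median split halves the cohort with rank-allocated ties", {
  withr::with_seed(31, {
    score <- pmin(pmax(rnorm(102, 0.6, 0.15), -0.99), 0.99)
    aq <- sample(9:33, 102, replace = TRUE)
  })
  gs <- group_split_comparison(score, aq, mode = "median", seed = 32, B = 1000)
  expect_equal(gs$groups$n, c(51L, 51L))
  expect_setequal(gs$groups$group, c("low", "high"))
  expect_lte(max(gs$groups$trait_min[gs$groups$group == "high"]),
             min(gs$groups$trait_max[gs$groups$group == "high"]))
  # groups partition the cohort
  expect_equal(nrow(gs$membership), 102L)
  expect_equal(anyDuplicated(gs$membership$participant_id), 0L)
})

test_that("quartile split sizes are 25/25/25/27 at n = 102", {
  withr::with_seed(33, {
    score <- pmin(pmax(rnorm(102, 0.6, 0.15), -0.99), 0.99)
    aq <- sample(9:33, 102, replace = TRUE)
  })
  gs <- group_split_comparison(score, aq, mode = "quartile", seed = 34, B = 1000)
  expect_equal(gs$groups$n, c(25L, 25L, 25L, 27L))
  expect_lte(diff(range(gs$groups$n)), 2L)
  expect_equal(nrow(gs$pairwise), 6L)
})

test_that("identical groups give a null-consistent bootstrap p", {
  score <- rep(c(0.4, 0.5, 0.6, 0.7), 6)
  aq <- rep(c(10, 30), each = 12)   # split is deterministic on AQ
  gs <- group_split_comparison(score, aq, mode = "median", seed = 35, B = 1000)
  expect_gt(min(gs$pairwise$p), 0.5)
})

test_that("a real trait effect separates the split groups", {
  withr::with_seed(36, {
    aq <- sample(9:33, 102, replace = TRUE)
    score <- pmin(pmax(0.9 - 0.012 * aq + rnorm(102, sd = 0.05), -0.99), 0.99)
  })
  gs <- group_split_comparison(score, aq, mode = "median", seed = 37, B = 1000)
  low <- gs$groups$pooled_accuracy[gs$groups$group == "low"]
  high <- gs$groups$pooled_accuracy[gs$groups$group == "high"]
  expect_gt(low, high)
  expect_lt(gs$pairwise$p[1], 0.01)
})
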