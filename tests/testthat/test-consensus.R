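# Independent oracle for the consensus: explicit eigendecomposition of the
# covariance of the standardised columns, deliberately separate from the
# prcomp-based implementation path.
eigen_consensus_oracle <- function(m) {
  z <- scale(m)
  ee <- eigen(stats::cov(z), symmetric = TRUE)
  v <- ee$vectors[, 1]
  if (mean(v) < 0 || (mean(v) == 0 && v[1] < 0)) v <- -v
  list(scores = as.vector(z %*% v), loadings = v,
       evf = ee$values[1] / sum(ee$values))
}

ratings_from_matrix <- function(m, video_id = "V01", hz = 10) {
  n <- nrow(m)
  tibble::tibble(
    participant_id = rep(colnames(m), each = n),
    video_id = video_id,
    t_s = rep((seq_len(n) - 1) / hz, ncol(m)),
    valence = as.vector(m),
    arousal = as.vector(m)
  )
}

test_that("rating matrix assembly is shaped and ordered deterministically", {
  m0 <- matrix(rnorm(1200 * 5), 1200, 5,
               dimnames = list(NULL, sprintf("P%03d", 5:1)))
  ratings <- ratings_from_matrix(tanh(m0))
  m <- build_rating_matrix(ratings, "V01", "valence")
  expect_equal(dim(m), c(1200L, 5L))
  expect_identical(colnames(m), sort(colnames(m0)))
  # shuffling row order changes nothing
  shuf <- ratings[sample.int(nrow(ratings)), ]
  expect_identical(build_rating_matrix(shuf, "V01", "valence"), m)
})

test_that("matrix assembly enforces >= 3 raters and complete series", {
  m0 <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  ratings <- ratings_from_matrix(tanh(m0))
  expect_error(
    build_rating_matrix(ratings[ratings$participant_id != "c", ], "V01"),
    class = "iettrack_structural_error"
  )
  truncated <- ratings[-nrow(ratings), ]   # drop c's final sample
  expect_error(build_rating_matrix(truncated, "V01"), regexp = "c",
               class = "iettrack_structural_error")
})

test_that("identical raters give a rank-1 consensus equal to their series", {
  u <- sin(seq(0, 6 * pi, length.out = 200))
  m <- matrix(u, 200, 4, dimnames = list(NULL, paste0("P", 1:4)))
  cons <- compute_consensus(m)
  expect_equal(cons$explained_variance_fraction, 1)
  expect_equal(unname(cons$loadings), rep(cons$loadings[[1]], 4))
  # scores proportional to the standardised series, positive scale
  expect_equal(cor(cons$scores, u), 1, tolerance = 1e-12)
})

test_that("sign convention: mean loading >= 0, ties broken by first id", {
  u <- as.vector(scale(rnorm(300)))
  m <- cbind(a = u, b = u, c = -u, d = -u)
  cons <- compute_consensus(m)
  expect_gte(mean(cons$loadings), -1e-12)   # numerically zero mean allowed
  expect_gte(cons$loadings[["a"]], 0)
})

test_that("consensus matches the eigendecomposition oracle on random matrices", {
  withr::with_seed(42, {
    for (i in 1:5) {
      m <- matrix(rnorm(200 * 6), 200, 6, dimnames = list(NULL, paste0("P", 1:6)))
      cons <- compute_consensus(m)
      oracle <- eigen_consensus_oracle(m)
      expect_lt(max(abs(cons$scores - oracle$scores)), 1e-8)
      expect_lt(abs(cons$explained_variance_fraction - oracle$evf), 1e-10)
    }
  })
})

test_that("degenerate and zero-variance columns are handled per contract", {
  m <- cbind(a = rep(0.2, 50), b = rep(-0.1, 50), c = rep(0, 50))
  expect_error(suppressWarnings(compute_consensus(m)),
               class = "iettrack_degenerate_input")
  m2 <- cbind(a = rnorm(50), b = rnorm(50), c = rep(0.5, 50))
  expect_warning(cons <- compute_consensus(m2), regexp = "c")
  expect_identical(cons$dropped, "c")
  expect_equal(length(cons$loadings), 2L)
})

test_that("scoring is the Pearson correlation with missing for flat raters", {
  s <- rnorm(100)
  expect_equal(score_participant(s, s), 1)
  expect_equal(score_participant(-s, s), -1)
  expect_true(is.na(score_participant(rep(0.3, 100), s)))
  expect_error(score_participant(s[1:50], s), class = "iettrack_invalid_argument")
})

test_that("noise attenuates accuracy as (1 + sigma^2)^(-1/2)", {
  withr::with_seed(7, {
    s <- rnorm(50000)
    r <- score_participant(s + rnorm(50000, sd = 1), s)
    expect_lt(abs(r - 1 / sqrt(2)), 0.02)
  })
})

test_that("Fisher-Z pooling matches hand-computed values and clips infinities", {
  expect_equal(pool_fisher_z(c(0.5, 0.5)), 0.5, tolerance = 1e-12)
  expect_equal(pool_fisher_z(c(0, 0.8)), 0.5, tolerance = 1e-6)
  p1 <- pool_fisher_z(1)
  expect_true(is.finite(p1) && p1 < 1 && p1 > 1 - 1e-6)
  expect_error(pool_fisher_z(numeric(0)), class = "iettrack_invalid_argument")
  expect_error(pool_fisher_z(1.5), class = "iettrack_invalid_argument")
  # identical values pool to themselves
  expect_equal(pool_fisher_z(rep(0.3, 7)), 0.3, tolerance = 1e-12)
})

test_that("a noise-free cohort scores accuracy 1 everywhere", {
  coh <- generate_cohort(noise_free_config())
  acc <- score_study(coh$ratings)
  expect_true(all(abs(acc$cells$r - 1) < 1e-9))
})

test_that("a flat trajectory becomes a missing cell, not a zero", {
  coh <- generate_cohort(noise_free_config(n = 5, V = 3))
  flat <- coh$ratings$participant_id == "P001" & coh$ratings$video_id == "V01"
  coh$ratings$valence[flat] <- 0.4
  acc <- score_study(coh$ratings)
  expect_equal(nrow(acc$missing_cells), 1L)
  expect_equal(acc$missing_cells$participant_id, "P001")
  pp <- acc$participant_pooled
  expect_equal(pp$n_videos[pp$participant_id == "P001" & pp$dimension == "valence"], 2L)
})

test_that("pooled accuracy recovers the competency ordering", {
  coh <- generate_cohort(synthetic_config(
    n_participants = 50, n_videos = 4, duration_range = c(40, 50),
    noise_sd = 0.05, video_noise_range = c(1, 1), trait_loading = 0, seed = 31
  ))
  acc <- score_study(coh$ratings, dimensions = "valence")
  pp <- acc$participant_pooled
  comp <- coh$ground_truth$profiles$competency[
    match(pp$participant_id, coh$ground_truth$profiles$participant_id)]
  expect_gt(cor(pp$pooled_accuracy, comp, method = "spearman"), 0.9)
})

test_that("accuracies are invariant to positive-gain affine maps of raters", {
  coh <- generate_cohort(small_config(seed = 55L))
  acc1 <- score_study(coh$ratings, dimensions = "valence")
  mapped <- coh$ratings |>
    dplyr::group_by(participant_id) |>
    dplyr::mutate(valence = 0.5 * valence + 0.1) |>
    dplyr::ungroup()
  acc2 <- score_study(mapped, dimensions = "valence")
  expect_equal(acc1$cells$r, acc2$cells$r, tolerance = 1e-10)
})

test_that("a phantom consensus rater barely perturbs other accuracies", {
  coh <- generate_cohort(synthetic_config(
    n_participants = 50, n_videos = 2, duration_range = c(40, 40),
    video_noise_range = c(1, 1), seed = 61
  ))
  acc1 <- score_study(coh$ratings, dimensions = "valence")
  phantom <- acc1$consensus[acc1$consensus$dimension == "valence", ] |>
    dplyr::transmute(participant_id = "Pzzz_phantom", video_id, t_s,
                     valence = pmin(pmax(score / 10, -1), 1), arousal = 0)
  aug <- dplyr::bind_rows(coh$ratings, phantom)
  acc2 <- score_study(aug, dimensions = "valence")
  both <- dplyr::inner_join(acc1$cells, acc2$cells,
                            by = c("participant_id", "video_id", "dimension"))
  expect_false(any(sign(both$r.x) != sign(both$r.y)))
  expect_lt(max(both$r.y - both$r.x), 0.01)
})

test_that("leave-in and leave-out consensus scores differ negligibly at n = 50", {
  coh <- generate_cohort(synthetic_config(
    n_participants = 50, n_videos = 2, duration_range = c(60, 60), seed = 71
  ))
  acc_in <- score_study(coh$ratings, dimensions = "valence")
  acc_out <- score_study(coh$ratings, loo_consensus = TRUE, dimensions = "valence")
  both <- dplyr::inner_join(acc_in$cells, acc_out$cells,
                            by = c("participant_id", "video_id", "dimension"))
  expect_lt(max(abs(both$r.x - both$r.y)), 0.05)
})

test_that("tidy and glance expose cells and per-dimension summaries", {
  coh <- generate_cohort(noise_free_config(n = 4, V = 2))
  acc <- score_study(coh$ratings)
  expect_identical(tidy(acc), acc$cells)
  g <- glance(acc)
  expect_setequal(g$dimension, c("valence", "arousal"))
  expect_true(all(g$mean_accuracy > 0.99))
})
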