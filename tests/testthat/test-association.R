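# Brute-force moment oracle, coded independently of the e1071-backed
# implementation: plain standardised-moment formulas with explicit bias
# corrections.
moments_oracle <- function(x) {
  n <- length(x)
  m <- mean(x)
  s <- sqrt(sum((x - m)^2) / (n - 1))
  g1 <- (sum((x - m)^3) / n) / (sum((x - m)^2) / n)^(3 / 2)
  skew <- g1 * sqrt(n * (n - 1)) / (n - 2)
  g2 <- (sum((x - m)^4) / n) / (sum((x - m)^2) / n)^2 - 3
  kurt <- ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
  c(mean = m, sd = s, skewness = skew, kurtosis = kurt)
}

test_that("descriptives match a brute-force moment computation", {
  x <- withr::with_seed(1, rnorm(20, mean = 3, sd = 2)^2)
  d <- descriptives(tibble::tibble(v = x))
  o <- moments_oracle(x)
  expect_equal(d$mean, o[["mean"]], tolerance = 1e-10)
  expect_equal(d$sd, o[["sd"]], tolerance = 1e-10)
  expect_equal(d$skewness, o[["skewness"]], tolerance = 1e-10)
  expect_equal(d$kurtosis, o[["kurtosis"]], tolerance = 1e-10)
  expect_equal(d$median, median(x))
  expect_equal(c(d$min, d$max), range(x))
})

test_that("descriptives: symmetric case, affine invariance, n >= 3 guard", {
  d <- descriptives(tibble::tibble(v = c(1, 2, 3)))
  expect_equal(d$mean, 2)
  expect_equal(d$median, 2)
  expect_equal(d$sd, 1)
  expect_equal(d$skewness, 0)

  x <- withr::with_seed(2, rexp(30))
  d1 <- descriptives(tibble::tibble(v = x))
  d2 <- descriptives(tibble::tibble(v = 3.7 * x - 11))
  expect_equal(d1$skewness, d2$skewness, tolerance = 1e-12)
  expect_equal(d1$kurtosis, d2$kurtosis, tolerance = 1e-12)

  expect_error(descriptives(tibble::tibble(v = c(1, 2))),
               class = "iettrack_invalid_argument")
})

test_that("spearman matches hand-ranked values and is rank invariant", {
  res <- spearman_cor(c(1, 2, 3, 4), c(3, 1, 2, 4))
  # average-rank Pearson on these ranks: hand value 0.4
  expect_equal(res$rho, cor(rank(c(1, 2, 3, 4)), rank(c(3, 1, 2, 4))))
  expect_equal(spearman_cor(c(1, 2, 3, 4), c(10, 20, 21, 1e6))$rho, 1)

  x <- withr::with_seed(3, rnorm(40))
  y <- withr::with_seed(4, rnorm(40))
  expect_equal(spearman_cor(x, y)$rho, spearman_cor(exp(x), y)$rho)

  # agrees with the standard implementation
  expect_equal(spearman_cor(x, y)$rho, unname(cor(x, y, method = "spearman")))
  expect_error(spearman_cor(rep(1, 10), 1:10),
               class = "iettrack_undefined_correlation")
})

test_that("hand-ranked three-point case gives rho = -0.5", {
  # x = 1,2,3 vs y = 3,1,2: ranks correlate at -0.5; n >= 4 is enforced, so
  # check via the same rank-Pearson rule the implementation promises
  expect_equal(cor(rank(c(1, 2, 3)), rank(c(3, 1, 2))), -0.5)
  r4 <- spearman_cor(c(1, 2, 3, 4), c(3, 1, 2, 4))
  expect_equal(r4$rho, cor(rank(c(1, 2, 3, 4)), rank(c(3, 1, 2, 4))),
               tolerance = 1e-12)
})

test_that("bonferroni is min(1, m p) with domain checks", {
  expect_equal(bonferroni(0.01, 17), 0.17)
  expect_equal(bonferroni(0.1, 17), 1)
  expect_equal(bonferroni(0, 5), 0)
  expect_error(bonferroni(1.2), class = "iettrack_invalid_argument")
  expect_error(bonferroni(-0.1), class = "iettrack_invalid_argument")
})

test_that("partial spearman with no covariates reduces exactly to spearman", {
  x <- withr::with_seed(5, rnorm(30))
  y <- withr::with_seed(6, rnorm(30))
  expect_identical(partial_spearman(x, y)$rho, spearman_cor(x, y)$rho)
})

test_that("partial spearman matches the recursive partial-correlation formula", {
  withr::with_seed(7, {
    z <- rnorm(60)
    x <- 0.5 * z + rnorm(60)
    y <- -0.4 * z + rnorm(60)
  })
  res <- partial_spearman(x, y, z)
  rxy <- cor(rank(x), rank(y))
  rxz <- cor(rank(x), rank(z))
  ryz <- cor(rank(y), rank(z))
  oracle <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  expect_equal(res$rho, oracle, tolerance = 1e-10)
})

test_that("partialling out a confound removes a spurious association", {
  withr::with_seed(8, {
    z <- rnorm(500)
    x <- rnorm(500)
    y <- z + 0.3 * rnorm(500)
  })
  expect_gt(abs(spearman_cor(y, z)$rho), 0.8)
  expect_lt(abs(partial_spearman(x, y, z)$rho), 0.1)
})

test_that("collinear covariates are rejected by name", {
  x <- rnorm(20); y <- rnorm(20); z <- rnorm(20)
  expect_error(partial_spearman(x, y, data.frame(a = z, b = 2 * z + 1)),
               regexp = "b", class = "iettrack_invalid_argument")
})

test_that("bootstrap CI of a partial correlation behaves at the extremes", {
  withr::with_seed(9, {
    x <- rnorm(100)
    z <- rnorm(100)
  })
  res <- bootstrap_partial(x, x, z, B = 1000, seed = 10)
  expect_gt(res$ci_low, 0.9)
  expect_true(res$significant)
  res2 <- bootstrap_partial(x, x, z, B = 1000, seed = 10)
  expect_identical(res, res2)   # bit-identical under a fixed seed
})

test_that("permutation p equals 1/(B+1) for a maximal statistic", {
  x <- withr::with_seed(11, rnorm(50))
  res <- permutation_test(x, x, B = 1000, seed = 12)
  expect_equal(res$p, 1 / 1001)
  expect_equal(res$rho_obs, 1)
})

test_that("sampled permutation p matches exhaustive enumeration at n = 5", {
  x <- c(0.3, -1.2, 0.8, 1.9, -0.4)
  y <- c(1.1, -0.6, 0.2, 2.4, -1.5)
  exact <- permutation_test(x, y, exact = TRUE)
  expect_equal(exact$B, 120L)
  sampled <- permutation_test(x, y, B = 20000, seed = 13)
  expect_lt(abs(sampled$p - exact$p), 0.02)
  expect_error(permutation_test(rep(1, 5), y, B = 1000),
               class = "iettrack_undefined_correlation")
})

test_that("the default plan has 17 comparisons and the battery applies it", {
  plan <- default_comparison_plan()
  expect_equal(nrow(plan), 17L)
  coh <- generate_cohort(small_config(seed = 91L))
  acc <- score_study(coh$ratings)
  bat <- correlation_battery(acc, coh$questionnaires)
  expect_equal(nrow(bat), 17L)
  expect_equal(bat$p_bonferroni, pmin(1, 17 * bat$p_uncorrected))
  # single-comparison plan: corrected equals uncorrected
  one <- correlation_battery(acc, coh$questionnaires,
                             plan = tibble::tibble(x = "iet_valence", y = "aq"))
  expect_equal(one$p_bonferroni, one$p_uncorrected)
})

test_that("the battery validates its plan against available variables", {
  coh <- generate_cohort(small_config(seed = 92L))
  acc <- score_study(coh$ratings)
  expect_error(
    correlation_battery(acc, coh$questionnaires,
                        plan = tibble::tibble(x = "iet_valence", y = "nope")),
    regexp = "nope", class = "iettrack_invalid_argument"
  )
  q_bad <- coh$questionnaires
  q_bad$aq <- NA_integer_
  expect_error(
    correlation_battery(acc, q_bad,
                        plan = tibble::tibble(x = "iet_valence", y = "aq")),
    class = "iettrack_invalid_argument"
  )
})

test_that("sensitivity rows exclude the given participants", {
  coh <- generate_cohort(small_config(seed = 93L))
  acc <- score_study(coh$ratings)
  bat <- correlation_battery(acc, coh$questionnaires,
                             exclude = c("P001", "P002"))
  main <- bat[bat$label == "iet_valence_x_aq", ]
  sens <- bat[bat$label == "iet_valence_x_aq_sensitivity", ]
  expect_equal(main$n, 10L)
  expect_equal(sens$n, 8L)
})
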