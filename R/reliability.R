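# Reliability diagnostics: bootstrap confidence intervals, circular-shift
# permutation nulls for accuracy, the video difficulty function, and
# leave-one-out difficulty correlations used to flag random responders.

#' Percentile bootstrap confidence interval
#'
#' @param values Nonempty numeric vector.
#' @param B Number of bootstrap resamples (>= 1000).
#' @param seed Integer seed; the interval is deterministic given `(B, seed)`.
#' @param statistic Function of a numeric vector; default [mean()].
#' @param conf Coverage level; default 0.95.
#' @return Named numeric `c(low, high)`: the (1-conf)/2 and 1-(1-conf)/2
#'   percentiles of the resampled statistic.
#' @export
bootstrap_ci <- function(values, B = 5000, seed = 1L, statistic = mean,
                         conf = 0.95) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) {
    abort("`values` must be nonempty.", class = "iettrack_invalid_argument")
  }
  assert_count(B, "B", min = 1000L)
  stats_b <- withr::with_seed(seed, {
    n <- length(values)
    vapply(seq_len(B),
           function(b) statistic(values[sample.int(n, n, replace = TRUE)]),
           numeric(1))
  })
  alpha <- (1 - conf) / 2
  ci <- unname(quantile(stats_b, c(alpha, 1 - alpha), names = FALSE))
  c(low = ci[1], high = ci[2])
}

#' Rank videos by pooled accuracy (the difficulty function)
#'
#' @param accuracy An `iet_accuracy` object from [score_study()].
#' @param dimension Affect dimension to rank on.
#' @return A tibble (`video_id`, `pooled_accuracy`, `rank`) sorted ascending
#'   by accuracy: hardest video first.
#' @export
difficulty_function <- function(accuracy, dimension = c("valence", "arousal")) {
  dimension <- match.arg(dimension)
  vp <- accuracy$video_pooled[accuracy$video_pooled$dimension == dimension, ]
  vp <- vp[order(vp$pooled_accuracy, vp$video_id), ]
  tibble::tibble(
    video_id = vp$video_id,
    pooled_accuracy = vp$pooled_accuracy,
    rank = seq_len(nrow(vp))
  )
}

#' Circular-shift permutation null for IET accuracy
#'
#' Builds a null distribution of pooled accuracies by re-scoring every
#' participant against the (unpermuted) consensus after a uniformly random
#' circular time-shift of that participant's trajectory within each video.
#' Circular shifting preserves each series' autocorrelation and marginal
#' distribution while destroying its temporal alignment with the consensus;
#' shifts are kept at least `min_shift_s` seconds away from zero (in both
#' directions) so no permutation is a near-identity.
#'
#' @param ratings Long-format ratings tibble.
#' @param B Number of permutations (>= 1000).
#' @param seed Integer seed.
#' @param dimension Affect dimension.
#' @param min_shift_s Minimum shift from zero, seconds (default 10).
#' @return An `iet_null` list: `statistic`, `samples` (per-permutation,
#'   per-participant pooled null accuracies), `ci95`, `mean`.
#' @export
permuted_accuracy_null <- function(ratings, B = 5000, seed = 1L,
                                   dimension = c("valence", "arousal"),
                                   min_shift_s = 10) {
  dimension <- match.arg(dimension)
  assert_count(B, "B", min = 1000L)
  vids <- sort(unique(ratings$video_id))

  prepared <- purrr::map(vids, function(v) {
    m <- build_rating_matrix(ratings, v, dimension)
    cons <- withCallingHandlers(compute_consensus(m),
                                warning = function(w) invokeRestart("muffleWarning"))
    t_v <- sort(unique(ratings$t_s[ratings$video_id == v]))
    dt <- if (length(t_v) > 1L) t_v[2] - t_v[1] else 1
    n_t <- nrow(m)
    min_shift <- ceiling(min_shift_s / dt)
    if (n_t <= 2L * min_shift) {
      abort(sprintf(
        "Video '%s' is too short (%d samples) for a %g s minimum circular shift.",
        v, n_t, min_shift_s), class = "iettrack_invalid_argument")
    }
    xc <- sweep(m, 2, colMeans(m))
    sx <- apply(m, 2, sd)
    sc <- (cons$scores - mean(cons$scores)) / sd(cons$scores)
    list(xc = xc, sx = sx, sc = sc, n_t = n_t, min_shift = min_shift,
         pids = colnames(m))
  })
  pids <- sort(unique(unlist(purrr::map(prepared, "pids"))))

  samples <- withr::with_seed(seed, {
    out <- matrix(NA_real_, B, length(pids), dimnames = list(NULL, pids))
    for (b in seq_len(B)) {
      z_acc <- matrix(NA_real_, length(pids), length(prepared),
                      dimnames = list(pids, NULL))
      for (k in seq_along(prepared)) {
        pv <- prepared[[k]]
        shifts <- sample(seq.int(pv$min_shift, pv$n_t - pv$min_shift),
                         length(pv$pids), replace = TRUE)
        idx0 <- seq_len(pv$n_t) - 1L
        for (j in seq_along(pv$pids)) {
          if (pv$sx[j] == 0) next
          xs <- pv$xc[((idx0 + shifts[j]) %% pv$n_t) + 1L, j]
          r <- sum(xs * pv$sc) / ((pv$n_t - 1) * pv$sx[j])
          z_acc[pv$pids[j], k] <- atanh(clip_r(r))
        }
      }
      out[b, ] <- tanh(rowMeans(z_acc, na.rm = TRUE))
    }
    out
  })
  all_samples <- as.vector(samples)
  structure(
    list(
      statistic = sprintf("pooled %s accuracy under circular-shift null", dimension),
      samples = all_samples,
      per_permutation = samples,
      ci95 = unname(quantile(all_samples, c(0.025, 0.975), na.rm = TRUE)),
      mean = mean(all_samples, na.rm = TRUE),
      B = B
    ),
    class = "iet_null"
  )
}

#' Leave-one-out difficulty-function correlations
#'
#' For each participant, correlates their own per-video accuracy vector with
#' the group's per-video pooled accuracy computed *excluding* them (over the
#' same videos), and builds a per-participant permutation null by shuffling
#' the video labels of the participant's own vector. A participant whose
#' correlation falls inside the null 95% CI is indistinguishable from a
#' random responder on the difficulty gradient.
#'
#' @param accuracy An `iet_accuracy` object.
#' @param dimension Affect dimension (default valence).
#' @param B Permutations per participant (default 5000).
#' @param seed Integer seed.
#' @return An `iet_loo` tibble: `participant_id`, `r`, `null_low`,
#'   `null_high`, `n_videos`, `flagged` (TRUE when `r` lies inside the null
#'   CI or fewer than 3 non-missing videos are available).
#' @export
loo_difficulty_correlations <- function(accuracy,
                                        dimension = c("valence", "arousal"),
                                        B = 5000, seed = 1L) {
  dimension <- match.arg(dimension)
  assert_count(B, "B", min = 1000L)
  cells <- accuracy$cells[accuracy$cells$dimension == dimension, ]
  wide <- tidyr::pivot_wider(cells[, c("participant_id", "video_id", "r")],
                             names_from = "video_id", values_from = "r")
  pids <- wide$participant_id
  R <- as.matrix(wide[, -1, drop = FALSE])
  if (length(pids) < 3L || ncol(R) < 3L) {
    abort("Need >= 3 participants and >= 3 videos.",
          class = "iettrack_invalid_argument")
  }
  Z <- atanh(clip_r(R))
  col_sum <- colSums(Z, na.rm = TRUE)
  col_n <- colSums(!is.na(Z))

  seeds <- derive_seeds(seed, length(pids))
  rows <- purrr::map(seq_along(pids), function(i) {
    own <- R[i, ]
    ok <- !is.na(own) & (col_n - !is.na(Z[i, ])) >= 1
    if (sum(ok) < 3L) {
      return(tibble::tibble(participant_id = pids[i], r = NA_real_,
                            null_low = NA_real_, null_high = NA_real_,
                            n_videos = sum(ok), flagged = TRUE))
    }
    loo_pool <- tanh((col_sum[ok] - ifelse(is.na(Z[i, ok]), 0, Z[i, ok])) /
                       (col_n[ok] - !is.na(Z[i, ok])))
    o <- own[ok]
    r_i <- cor(o, loo_pool)
    null <- withr::with_seed(seeds[i], {
      V <- length(o)
      perm <- replicate(B, o[sample.int(V)])
      gs <- (loo_pool - mean(loo_pool)) / sd(loo_pool)
      ps <- sweep(perm, 2, colMeans(perm))
      psd <- apply(perm, 2, sd)
      as.vector(crossprod(ps, gs)) / ((V - 1) * psd)
    })
    ci <- unname(quantile(null, c(0.025, 0.975)))
    tibble::tibble(participant_id = pids[i], r = r_i,
                   null_low = ci[1], null_high = ci[2],
                   n_videos = sum(ok),
                   flagged = r_i >= ci[1] & r_i <= ci[2])
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("iet_loo", class(out))
  attr(out, "dimension") <- dimension
  attr(out, "B") <- B
  out
}

#' Flag participants indistinguishable from random responders
#'
#' @param loo_result Output of [loo_difficulty_correlations()].
#' @return Character vector of flagged participant ids (possibly empty).
#' @export
flag_inconsistent_participants <- function(loo_result) {
  if (!inherits(loo_result, "iet_loo")) {
    abort("`loo_result` must come from loo_difficulty_correlations().",
          class = "iettrack_invalid_argument")
  }
  loo_result$participant_id[loo_result$flagged]
}
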