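# Monte-Carlo item analysis over the video set: subset effect curves, the
# minimum number of videos needed to recover a fraction of the full effect,
# best-video selection, chunked cross-validated correlations, and
# median/quartile AQ group splits.

# Per-participant x per-video accuracy cells for one dimension, as a matrix
# of Fisher-Z transformed accuracies, aligned with a trait vector.
cells_matrix <- function(scores, questionnaires,
                         dimension = "valence", trait = "aq") {
  cells <- if (inherits(scores, "iet_accuracy")) scores$cells else scores
  cells <- cells[cells$dimension == dimension, c("participant_id", "video_id", "r")]
  wide <- tidyr::pivot_wider(cells, names_from = "video_id", values_from = "r")
  wide <- wide[order(wide$participant_id), ]
  q <- questionnaires[match(wide$participant_id, questionnaires$participant_id), ]
  keep <- !is.na(q[[trait]])
  Z <- atanh(clip_r(as.matrix(wide[keep, -1, drop = FALSE])))
  Z <- Z[, order(colnames(Z)), drop = FALSE]
  list(
    Z = Z,
    trait = q[[trait]][keep],
    participant_id = wide$participant_id[keep],
    video_id = colnames(Z)
  )
}

#' Monte-Carlo video-subset effect curve
#'
#' For each subset size `k` between `k_min` and `k_max`, repeatedly samples
#' `k` videos without replacement, pools every participant's accuracy over
#' the sampled videos (Fisher-Z), computes the Spearman correlation of the
#' pooled accuracy with the trait (AQ by default), and Fisher-Z averages the
#' correlation across iterations. At `k = k_max = V` all iterations coincide,
#' so the curve value equals the full-sample rho exactly.
#'
#' @param scores An `iet_accuracy` object (or its `cells` tibble).
#' @param questionnaires Questionnaire tibble keyed by `participant_id`.
#' @param k_min,k_max Inclusive subset-size range; `k_max` defaults to the
#'   number of videos.
#' @param iters Monte-Carlo iterations per subset size (default 5000).
#' @param seed Integer seed.
#' @param dimension Affect dimension scored (default valence).
#' @param trait Questionnaire column to correlate with (default `"aq"`).
#' @return An `iet_subset_curve` tibble: `k`, `mean_rho`, `iterations`, with
#'   the full-sample rho in `attr(, "full_rho")`.
#' @export
subset_effect_curve <- function(scores, questionnaires, k_min = 5, k_max = NULL,
                                iters = 5000, seed = 1L,
                                dimension = c("valence", "arousal"),
                                trait = "aq") {
  dimension <- match.arg(dimension)
  cm <- cells_matrix(scores, questionnaires, dimension, trait)
  V <- ncol(cm$Z)
  k_max <- k_max %||% V
  k_min <- assert_count(k_min, "k_min", min = 1L)
  k_max <- assert_count(k_max, "k_max", min = k_min)
  if (k_max > V) {
    abort(sprintf("k_max = %d exceeds the number of videos (%d).", k_max, V),
          class = "iettrack_invalid_argument")
  }
  assert_count(iters, "iters", min = 1L)
  trait_rank <- rank(cm$trait)
  rho_for <- function(sel) {
    pooled <- tanh(rowMeans(cm$Z[, sel, drop = FALSE], na.rm = TRUE))
    cor(rank(pooled), trait_rank)
  }
  full_rho <- rho_for(seq_len(V))
  seeds <- derive_seeds(seed, k_max - k_min + 1L)
  rows <- purrr::map(seq.int(k_min, k_max), function(k) {
    if (k == V) {
      return(tibble::tibble(k = k, mean_rho = full_rho, iterations = 1L))
    }
    rhos <- withr::with_seed(seeds[k - k_min + 1L], vapply(
      seq_len(iters), function(i) rho_for(sample.int(V, k)), numeric(1)))
    tibble::tibble(k = k, mean_rho = pool_fisher_z(rhos), iterations = iters)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("iet_subset_curve", class(out))
  attr(out, "full_rho") <- full_rho
  attr(out, "dimension") <- dimension
  attr(out, "trait") <- trait
  out
}

#' Minimum videos needed to reach a fraction of the full effect
#'
#' The threshold is `fraction * |full_rho|`; the answer is the smallest `k`
#' on the curve whose mean correlation magnitude meets it. Magnitudes are
#' compared because the hypothesised effect is signed (negative) while the
#' threshold is conventionally reported as a positive rho.
#'
#' @param curve An [subset_effect_curve()] result (or a tibble with `k` and
#'   `mean_rho`).
#' @param full_rho Full-sample correlation; defaults to the curve's own
#'   recorded value.
#' @param fraction Fraction of the full effect to reach (default 0.75).
#' @return A one-row tibble: `k_star` (NA when never reached), `threshold`,
#'   `reached`, `fraction`, `full_rho`.
#' @export
min_videos_for_threshold <- function(curve, full_rho = NULL, fraction = 0.75) {
  full_rho <- full_rho %||% attr(curve, "full_rho")
  if (is.null(full_rho)) {
    abort("Supply `full_rho` (the curve carries none).",
          class = "iettrack_invalid_argument")
  }
  assert_probability(fraction, "fraction")
  ks <- curve$k
  if (any(diff(sort(ks)) != 1L)) {
    abort("Curve must cover a contiguous k range.",
          class = "iettrack_invalid_argument")
  }
  threshold <- fraction * abs(full_rho)
  ok <- abs(curve$mean_rho) >= threshold
  k_star <- if (any(ok)) min(ks[ok]) else NA_integer_
  tibble::tibble(k_star = k_star, threshold = threshold, reached = any(ok),
                 fraction = fraction, full_rho = full_rho)
}

#' Select the videos most predictive of the trait
#'
#' Computes the per-video Spearman correlation between participants'
#' single-video accuracy and the trait, ranks videos by most-negative rho
#' (the hypothesised direction: higher AQ, lower accuracy) and returns the
#' top `n_best`. Ties at the selection boundary are broken by sorted
#' `video_id`; the full per-video rho table is returned alongside.
#'
#' @inheritParams subset_effect_curve
#' @param n_best Number of videos to select (default 7).
#' @return A list: `selected` (character vector of `n_best` video ids) and
#'   `table` (tibble `video_id`, `rho`, `n`, `rank`).
#' @export
best_videos <- function(scores, questionnaires, n_best = 7,
                        dimension = c("valence", "arousal"), trait = "aq") {
  dimension <- match.arg(dimension)
  cm <- cells_matrix(scores, questionnaires, dimension, trait)
  V <- ncol(cm$Z)
  n_best <- assert_count(n_best, "n_best", min = 1L)
  if (n_best > V) {
    abort(sprintf("n_best = %d exceeds the number of videos (%d).", n_best, V),
          class = "iettrack_invalid_argument")
  }
  vids <- colnames(cm$Z)
  tab <- purrr::map(vids, function(v) {
    r_v <- tanh(cm$Z[, v])
    keep <- !is.na(r_v)
    if (sum(keep) < 4L) {
      return(tibble::tibble(video_id = v, rho = NA_real_, n = sum(keep)))
    }
    tibble::tibble(video_id = v,
                   rho = cor(rank(r_v[keep]), rank(cm$trait[keep])),
                   n = sum(keep))
  }) |> dplyr::bind_rows()
  tab <- tab[order(tab$rho, tab$video_id), ]
  tab$rank <- seq_len(nrow(tab))
  list(selected = utils::head(tab$video_id[!is.na(tab$rho)], n_best),
       table = tibble::as_tibble(tab))
}

#' Chunked cross-validated trait correlation
#'
#' Per iteration, partitions participants at random into `folds` near-equal
#' chunks, computes the Spearman correlation of score with trait inside each
#' chunk, and Fisher-Z averages across chunks; reports the Fisher-Z mean and
#' the percentile 95% CI over iterations. Chunks in which the trait is
#' constant are skipped (logged); an iteration needs at least 3 valid chunks.
#'
#' @param scores Named numeric vector / tibble column of per-participant
#'   scores, or a tibble with `participant_id` and a score column `score`.
#' @param trait Numeric trait vector aligned with `scores` (or a
#'   questionnaire column name when `scores` is a tibble).
#' @param folds Number of chunks (default 5).
#' @param iters Iterations (default 5000).
#' @param seed Integer seed.
#' @return A one-row tibble: `mean_rho`, `ci_low`, `ci_high`, `iterations`,
#'   `skipped_chunks`, `folds`, `n`.
#' @export
crossval_correlation <- function(scores, trait, folds = 5, iters = 5000,
                                 seed = 1L) {
  x <- as.numeric(scores)
  y <- as.numeric(trait)
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  folds <- assert_count(folds, "folds", min = 2L)
  assert_count(iters, "iters", min = 1L)
  if (n < folds * 4L) {
    abort(sprintf("Need at least %d participants for %d chunks.", folds * 4L, folds),
          class = "iettrack_invalid_argument")
  }
  sizes <- rep(n %/% folds, folds)
  extra <- n %% folds
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  grp_template <- rep(seq_len(folds), times = sizes)
  skipped <- 0L
  means <- withr::with_seed(seed, vapply(seq_len(iters), function(i) {
    grp <- grp_template[sample.int(n)]
    rhos <- vapply(seq_len(folds), function(g) {
      xi <- x[grp == g]; yi <- y[grp == g]
      if (sd(yi) == 0 || sd(xi) == 0) return(NA_real_)
      cor(rank(xi), rank(yi))
    }, numeric(1))
    bad <- sum(is.na(rhos))
    if (bad > 0) skipped <<- skipped + bad
    if (sum(!is.na(rhos)) < 3L) return(NA_real_)
    pool_fisher_z(rhos)
  }, numeric(1)))
  means <- means[!is.na(means)]
  if (length(means) == 0L) {
    abort("No iteration produced 3 valid chunks.",
          class = "iettrack_degenerate_input")
  }
  ci <- unname(quantile(means, c(0.025, 0.975)))
  tibble::tibble(mean_rho = pool_fisher_z(means), ci_low = ci[1], ci_high = ci[2],
                 iterations = length(means), skipped_chunks = skipped,
                 folds = folds, n = n)
}

#' Median / quartile trait split with bootstrap group comparisons
#'
#' Splits the cohort on the trait (AQ by default). `"median"` mode orders by
#' trait then participant id and halves the cohort, so ties at the median are
#' allocated by rank and group sizes differ by at most 1. `"quartile"` mode
#' cuts at rank quartiles with group sizes differing by at most 2 (for
#' n = 102 the sizes are 25/25/25/27, the top quartile absorbing the
#' remainder). Each group's accuracy is summarised by its Fisher-Z mean, and
#' every group pair is compared by a two-sided bootstrap sign test on the
#' resampled difference: `p = 2 * min(P(diff* <= 0), P(diff* >= 0))`, capped
#' at 1.
#'
#' @param scores Per-participant accuracy vector (aligned with `trait`), or a
#'   tibble with `participant_id` and `score`.
#' @param trait Numeric trait vector (AQ scores).
#' @param mode `"median"` or `"quartile"`.
#' @param seed Integer seed for the bootstrap.
#' @param B Bootstrap resamples per pairwise test (default 5000).
#' @param ids Optional participant ids used for deterministic tie-breaking
#'   and group membership listings.
#' @return An `iet_group_split` list: `groups` (tibble `group`, `n`,
#'   `trait_min`, `trait_max`, `pooled_accuracy`), `membership`, `pairwise`
#'   (tibble `group_1`, `group_2`, `difference`, `p`), `mode`.
#' @export
group_split_comparison <- function(scores, trait, mode = c("median", "quartile"),
                                   seed = 1L, B = 5000, ids = NULL) {
  mode <- match.arg(mode)
  assert_count(B, "B", min = 1000L)
  x <- as.numeric(scores)
  y <- as.numeric(trait)
  ids <- ids %||% sprintf("P%03d", seq_along(x))
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]; ids <- ids[keep]
  n <- length(x)
  if (n < 8L) abort("Need at least 8 participants.", class = "iettrack_invalid_argument")

  ord <- order(y, ids)
  n_groups <- if (mode == "median") 2L else 4L
  if (mode == "median") {
    sizes <- c(floor(n / 2), n - floor(n / 2))
    labels <- c("low", "high")
  } else {
    base <- n %/% 4L
    rem <- n %% 4L
    sizes <- rep(base, 4L)
    if (rem == 1L) sizes[4] <- sizes[4] + 1L
    if (rem == 2L) sizes[4] <- sizes[4] + 2L
    if (rem == 3L) { sizes[3] <- sizes[3] + 1L; sizes[4] <- sizes[4] + 2L }
    labels <- c("q1", "q2", "q3", "q4")
  }
  if (any(sizes < 4L)) {
    abort("A split group would have fewer than 4 participants.",
          class = "iettrack_invalid_argument")
  }
  grp <- rep(labels, times = sizes)[order(ord)]

  groups <- tibble::tibble(id = ids, score = x, trait = y, group = grp) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      trait_min = min(.data$trait), trait_max = max(.data$trait),
      pooled_accuracy = pool_fisher_z(.data$score),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$group, labels))

  pairs <- utils::combn(labels, 2, simplify = FALSE)
  seeds <- derive_seeds(seed, length(pairs))
  pairwise <- purrr::map2(pairs, seeds, function(pr, s) {
    a <- x[grp == pr[1]]; b <- x[grp == pr[2]]
    diff_obs <- pool_fisher_z(a) - pool_fisher_z(b)
    diffs <- withr::with_seed(s, vapply(seq_len(B), function(i) {
      pool_fisher_z(sample(a, length(a), replace = TRUE)) -
        pool_fisher_z(sample(b, length(b), replace = TRUE))
    }, numeric(1)))
    p <- min(1, 2 * min(mean(diffs <= 0), mean(diffs >= 0)))
    tibble::tibble(group_1 = pr[1], group_2 = pr[2],
                   difference = diff_obs, p = p)
  }) |> dplyr::bind_rows()

  structure(
    list(groups = groups,
         membership = tibble::tibble(participant_id = ids, group = grp),
         pairwise = pairwise, mode = mode, B = B),
    class = "iet_group_split"
  )
}

#' @export
print.iet_group_split <- function(x, ...) {
  cat(sprintf("<iet_group_split> %s split, %d groups\n", x$mode, nrow(x$groups)))
  print(x$groups)
  invisible(x)
}

#' @rdname group_split_comparison
#' @param x An `iet_group_split` object.
#' @param ... Unused.
#' @method tidy iet_group_split
#' @export
tidy.iet_group_split <- function(x, ...) x$pairwise

#' @rdname group_split_comparison
#' @method glance iet_group_split
#' @export
glance.iet_group_split <- function(x, ...) {
  tibble::tibble(mode = x$mode, n_groups = nrow(x$groups),
                 n = sum(x$groups$n), B = x$B,
                 n_significant_pairs = sum(x$pairwise$p < 0.05))
}
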