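# Informal Cultural Consensus Model scoring: per-video consensus trajectories
# as first principal-component factor scores of all raters' series, Pearson
# accuracies against the consensus, and Fisher-Z pooling.

#' Assemble the time x participant rating matrix for one video and dimension
#'
#' @param ratings Long-format ratings tibble (`participant_id`, `video_id`,
#'   `t_s`, `valence`, `arousal`).
#' @param video_id Video to extract.
#' @param dimension `"valence"` or `"arousal"`.
#' @return A numeric matrix, rows = time samples, columns = participants in
#'   sorted `participant_id` order (column names are the ids).
#' @details At least 3 complete trajectories are required: the consensus is
#'   undefined below 3 raters. A participant whose series length differs from
#'   the video's common time base raises a structural error naming them.
#' @export
build_rating_matrix <- function(ratings, video_id, dimension = c("valence", "arousal")) {
  dimension <- match.arg(dimension)
  sub <- ratings[ratings$video_id == video_id, , drop = FALSE]
  if (nrow(sub) == 0L) {
    abort(sprintf("No ratings for video '%s'.", video_id),
          class = "iettrack_structural_error")
  }
  sub <- sub[order(sub$participant_id, sub$t_s), , drop = FALSE]
  lens <- table(sub$participant_id)
  n_t <- as.integer(max(lens))
  bad <- names(lens)[lens != n_t]
  if (length(bad) > 0L) {
    abort(sprintf(
      "Video '%s': participant(s) %s have truncated or oversampled series (expected %d samples).",
      video_id, paste(bad, collapse = ", "), n_t),
      class = "iettrack_structural_error")
  }
  pids <- sort(names(lens))
  if (length(pids) < 3L) {
    abort(sprintf("Video '%s': consensus undefined below 3 raters (got %d).",
                  video_id, length(pids)),
          class = "iettrack_structural_error")
  }
  m <- matrix(sub[[dimension]], nrow = n_t, ncol = length(pids),
              dimnames = list(NULL, pids))
  # column order from arrange by participant_id matches sort(pids) because the
  # long table was sorted above; verify time base alignment across columns
  t_ref <- sub$t_s[seq_len(n_t)]
  if (any(abs(matrix(sub$t_s, nrow = n_t) - t_ref) > 1e-9)) {
    abort(sprintf("Video '%s': participants are not on a common time base.", video_id),
          class = "iettrack_structural_error")
  }
  m
}

#' Compute a per-video consensus trajectory (first PC factor scores)
#'
#' Standardises every rater's column (zero mean, unit variance; zero-variance
#' columns are dropped with a warning), extracts the first principal component
#' of the standardised matrix, and returns its factor scores over time as the
#' consensus series. Because all downstream accuracies are correlations, the
#' overall scale of the scores is irrelevant; their sign is fixed by the
#' convention that the mean participant loading is non-negative (an exact-zero
#' mean is broken toward a non-negative loading for the first sorted
#' participant id).
#'
#' @param m Time x participant matrix from [build_rating_matrix()].
#' @return An `iet_consensus` list: `scores` (factor-score series),
#'   `loadings` (named per-participant weights), `explained_variance_fraction`
#'   (leading eigenvalue over trace), `dropped` (ids of zero-variance columns).
#' @export
compute_consensus <- function(m) {
  if (!is.matrix(m) || ncol(m) < 1L || nrow(m) < 3L) {
    abort("Consensus needs a time x participant matrix with >= 3 time samples.",
          class = "iettrack_invalid_argument")
  }
  sds <- apply(m, 2, sd)
  dropped <- colnames(m)[sds == 0 | is.na(sds)]
  if (length(dropped) > 0L) {
    warn(sprintf("Dropping zero-variance rater column(s): %s.",
                 paste(dropped, collapse = ", ")))
    m <- m[, !(colnames(m) %in% dropped), drop = FALSE]
  }
  if (ncol(m) == 0L) {
    abort("All rater columns are constant; consensus is degenerate.",
          class = "iettrack_degenerate_input")
  }
  z <- scale(m)
  pc <- prcomp(z, center = FALSE, scale. = FALSE)
  loadings <- pc$rotation[, 1]
  scores <- pc$x[, 1]
  ml <- mean(loadings)
  # an exactly balanced +/- loading pattern leaves the mean at numerical zero;
  # break the tie by the first column's sign
  flip <- if (abs(ml) < 1e-12) loadings[1] < 0 else ml < 0
  if (flip) {
    loadings <- -loadings
    scores <- -scores
  }
  ev <- pc$sdev^2
  structure(
    list(
      scores = unname(scores),
      loadings = loadings,
      explained_variance_fraction = ev[1] / sum(ev),
      dropped = dropped
    ),
    class = "iet_consensus"
  )
}

#' Score one rater against a consensus trajectory
#'
#' Cultural-consensus accuracy: the Pearson correlation between the rater's
#' series and the consensus factor scores. A rater who never moved the cursor
#' (zero-variance trajectory) has no defined correlation; the cell is returned
#' as `NA` and recorded as missing by the pipeline, never as 0.
#'
#' @param trajectory Numeric rating series.
#' @param consensus Consensus factor-score series (or an `iet_consensus`).
#' @return Pearson r in `[-1, 1]`, or `NA` for a zero-variance trajectory.
#' @export
score_participant <- function(trajectory, consensus) {
  if (inherits(consensus, "iet_consensus")) consensus <- consensus$scores
  if (length(trajectory) != length(consensus) || length(trajectory) < 3L) {
    abort("Trajectory and consensus must have equal length >= 3.",
          class = "iettrack_invalid_argument")
  }
  if (sd(trajectory) == 0 || sd(consensus) == 0) return(NA_real_)
  cor(trajectory, consensus)
}

#' Score a whole study: accuracies, pooled scores, consensus trajectories
#'
#' Runs the Informal Cultural Consensus Model over every video and dimension:
#' builds the rating matrix, computes the consensus, correlates every
#' participant with it, and Fisher-Z pools per participant (over videos) and
#' per video (over participants). Structural failures on one video are
#' collected and reported without aborting the remaining videos.
#'
#' @param ratings Long-format ratings tibble.
#' @param loo_consensus If `TRUE`, each participant is scored against a
#'   consensus recomputed without their own column (leave-one-out). The
#'   default leaves the scored rater in, matching consensus computed from all
#'   ratings of a video.
#' @param dimensions Which affect dimensions to score.
#' @return An `iet_accuracy` object: list with `cells` (tibble
#'   `participant_id`, `video_id`, `dimension`, `r`), `participant_pooled`,
#'   `video_pooled`, `consensus` (tibble `video_id`, `dimension`, `t_s`,
#'   `score`, `explained_variance_fraction`), `missing_cells`, `failures`.
#' @export
score_study <- function(ratings, loo_consensus = FALSE,
                        dimensions = c("valence", "arousal")) {
  dimensions <- match.arg(dimensions, several.ok = TRUE)
  vids <- sort(unique(ratings$video_id))
  failures <- list()
  cells <- list()
  cons_rows <- list()

  for (v in vids) {
    for (dm in dimensions) {
      m <- tryCatch(build_rating_matrix(ratings, v, dm), error = function(e) e)
      if (inherits(m, "error")) {
        failures[[length(failures) + 1L]] <-
          tibble::tibble(video_id = v, dimension = dm,
                         message = conditionMessage(m))
        next
      }
      cons <- withCallingHandlers(
        compute_consensus(m),
        warning = function(w) invokeRestart("muffleWarning")
      )
      pids <- colnames(m)
      if (loo_consensus) {
        r <- vapply(pids, function(p) {
          rest <- m[, setdiff(colnames(m), p), drop = FALSE]
          if (ncol(rest) < 2L) return(NA_real_)
          loo_cons <- withCallingHandlers(
            tryCatch(compute_consensus(rest), error = function(e) NULL),
            warning = function(w) invokeRestart("muffleWarning")
          )
          if (is.null(loo_cons)) return(NA_real_)
          score_participant(m[, p], loo_cons)
        }, numeric(1))
      } else {
        r <- vapply(pids, function(p) score_participant(m[, p], cons), numeric(1))
      }
      cells[[length(cells) + 1L]] <- tibble::tibble(
        participant_id = pids, video_id = v, dimension = dm, r = unname(r)
      )
      cons_rows[[length(cons_rows) + 1L]] <- tibble::tibble(
        video_id = v, dimension = dm,
        t_s = sort(unique(ratings$t_s[ratings$video_id == v])),
        score = cons$scores,
        explained_variance_fraction = cons$explained_variance_fraction
      )
    }
  }
  if (length(cells) == 0L) {
    abort("No video could be scored.", class = "iettrack_degenerate_input")
  }
  cells <- dplyr::bind_rows(cells)
  missing_cells <- cells[is.na(cells$r), c("participant_id", "video_id", "dimension")]

  participant_pooled <- cells |>
    dplyr::filter(!is.na(.data$r)) |>
    dplyr::group_by(.data$participant_id, .data$dimension) |>
    dplyr::summarise(pooled_accuracy = pool_fisher_z(.data$r),
                     n_videos = dplyr::n(), .groups = "drop")
  video_pooled <- cells |>
    dplyr::filter(!is.na(.data$r)) |>
    dplyr::group_by(.data$video_id, .data$dimension) |>
    dplyr::summarise(pooled_accuracy = pool_fisher_z(.data$r),
                     n_participants = dplyr::n(), .groups = "drop")

  structure(
    list(
      cells = cells,
      participant_pooled = participant_pooled,
      video_pooled = video_pooled,
      consensus = dplyr::bind_rows(cons_rows),
      missing_cells = missing_cells,
      failures = if (length(failures)) dplyr::bind_rows(failures) else
        tibble::tibble(video_id = character(), dimension = character(),
                       message = character()),
      loo_consensus = loo_consensus
    ),
    class = "iet_accuracy"
  )
}

#' @export
print.iet_accuracy <- function(x, ...) {
  cat(sprintf(
    "<iet_accuracy> %d cells (%d missing), %d participants, %d videos%s\n",
    nrow(x$cells), nrow(x$missing_cells),
    dplyr::n_distinct(x$cells$participant_id),
    dplyr::n_distinct(x$cells$video_id),
    if (x$loo_consensus) " [leave-one-out consensus]" else ""
  ))
  invisible(x)
}

#' @rdname score_study
#' @param x An `iet_accuracy` object.
#' @param ... Unused.
#' @method tidy iet_accuracy
#' @export
tidy.iet_accuracy <- function(x, ...) x$cells

#' @rdname score_study
#' @method glance iet_accuracy
#' @export
glance.iet_accuracy <- function(x, ...) {
  x$participant_pooled |>
    dplyr::group_by(.data$dimension) |>
    dplyr::summarise(
      mean_accuracy = mean(.data$pooled_accuracy),
      sd_accuracy = sd(.data$pooled_accuracy),
      n_participants = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(n_missing_cells = nrow(x$missing_cells),
                  n_failed_videos = nrow(x$failures))
}
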