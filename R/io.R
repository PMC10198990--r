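# File I/O contracts, configuration, and end-to-end orchestration.

required_rating_cols <- c("participant_id", "video_id", "t_s", "valence", "arousal")

#' Read and validate a long-format ratings CSV
#'
#' Expected header: `participant_id, video_id, t_s, valence, arousal`, one
#' row per time sample, UTF-8, '.' decimal separator. Validation enforces the
#' structural contract the scorer relies on: affect values in `[-1, 1]`
#' (violations are reported with their row numbers), no duplicated
#' `(participant, video, t)` samples, and a strictly increasing, uniformly
#' spaced time base shared by every participant within a video.
#'
#' @param path Path to the CSV file.
#' @return A validated ratings tibble.
#' @export
read_ratings <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: '%s'.", path), class = "iettrack_io_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(required_rating_cols, names(df))
  if (length(missing) > 0L) {
    abort(sprintf("Missing required column(s): %s.", paste(missing, collapse = ", ")),
          class = "iettrack_validation_error")
  }
  validate_ratings(df)
}

validate_ratings <- function(df) {
  bad <- which(abs(df$valence) > 1 | abs(df$arousal) > 1 |
                 is.na(df$valence) | is.na(df$arousal))
  if (length(bad) > 0L) {
    abort(sprintf(
      "Affect values outside [-1, 1] (or missing) at data row(s): %s.",
      paste(utils::head(bad, 10), collapse = ", ")),
      class = "iettrack_validation_error")
  }
  key <- paste(df$participant_id, df$video_id, df$t_s, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0L) {
    abort(sprintf("Duplicated (participant, video, t) row(s): %s.",
                  paste(utils::head(dup, 10), collapse = ", ")),
          class = "iettrack_validation_error")
  }
  check <- df |>
    dplyr::group_by(.data$video_id, .data$participant_id) |>
    dplyr::summarise(
      monotone = all(diff(sort(.data$t_s)) > 0) && !is.unsorted(.data$t_s),
      uniform = dplyr::n() < 3L ||
        diff(range(diff(sort(.data$t_s)))) < 1e-6,
      .groups = "drop"
    )
  if (any(!check$monotone)) {
    bad <- check[!check$monotone, ]
    abort(sprintf("Non-monotone time base for participant '%s' on video '%s'.",
                  bad$participant_id[1], bad$video_id[1]),
          class = "iettrack_validation_error")
  }
  if (any(!check$uniform)) {
    bad <- check[!check$uniform, ]
    abort(sprintf("Non-uniform sample spacing for participant '%s' on video '%s'.",
                  bad$participant_id[1], bad$video_id[1]),
          class = "iettrack_validation_error")
  }
  tibble::as_tibble(df)
}

#' Read a questionnaire CSV (one row per participant)
#'
#' @param path Path to the CSV file.
#' @return A tibble with `participant_id` and questionnaire total columns.
#' @export
read_questionnaires <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: '%s'.", path), class = "iettrack_io_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"participant_id" %in% names(df)) {
    abort("Questionnaire file must contain `participant_id`.",
          class = "iettrack_validation_error")
  }
  if (any(duplicated(df$participant_id))) {
    abort("Duplicated participant_id in questionnaire file.",
          class = "iettrack_validation_error")
  }
  tibble::as_tibble(df)
}

#' Read a flat key-value configuration file (YAML or JSON)
#'
#' @param path Path to a YAML (or JSON; YAML is a superset) file whose keys
#'   mirror [pipeline_config()] / [synthetic_config()] arguments.
#' @return A named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: '%s'.", path), class = "iettrack_io_error")
  }
  yaml::read_yaml(path)
}

#' Assemble a pipeline configuration
#'
#' Every stage has its own explicit seed and resample count so that the full
#' run is a pure function of `(inputs, config)`; no global RNG state is used.
#'
#' @param plan Comparison plan for the correlation battery.
#' @param loo_consensus Score each rater against a leave-one-out consensus.
#' @param drop_flagged Re-run the battery without flagged participants and
#'   attach the sensitivity block to the report (the sensitivity *row* of the
#'   default plan is always computed).
#' @param b_loo,b_bootstrap,b_split Resample counts for the leave-one-out
#'   null, the headline bootstrap CI and the group-split tests.
#' @param iters_subset,iters_crossval Monte-Carlo iterations for the subset
#'   curve and the chunked cross-validation.
#' @param folds_crossval Number of chunks for the cross-validated correlation.
#' @param n_best Videos to select in the item analysis.
#' @param fraction Fraction of the full effect for the minimum-video search.
#' @param seed_loo,seed_bootstrap,seed_subset,seed_crossval,seed_split
#'   Per-stage integer seeds.
#' @return An `iet_pipeline_config` list.
#' @export
pipeline_config <- function(plan = default_comparison_plan(),
                            loo_consensus = FALSE,
                            drop_flagged = TRUE,
                            b_loo = 5000, b_bootstrap = 5000, b_split = 5000,
                            iters_subset = 5000, iters_crossval = 5000,
                            folds_crossval = 5,
                            n_best = 7, fraction = 0.75,
                            seed_loo = 101L, seed_bootstrap = 102L,
                            seed_subset = 103L, seed_crossval = 104L,
                            seed_split = 105L) {
  structure(
    list(plan = plan, loo_consensus = loo_consensus,
         drop_flagged = drop_flagged,
         b_loo = b_loo, b_bootstrap = b_bootstrap, b_split = b_split,
         iters_subset = iters_subset, iters_crossval = iters_crossval,
         folds_crossval = folds_crossval,
         n_best = n_best, fraction = fraction,
         seed_loo = seed_loo, seed_bootstrap = seed_bootstrap,
         seed_subset = seed_subset, seed_crossval = seed_crossval,
         seed_split = seed_split),
    class = "iet_pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' Orchestrates the analysis end to end in study order: consensus scoring,
#' leave-one-out difficulty diagnostics with responder flagging, the planned
#' correlation battery (with a bootstrap CI on the headline IET-valence x AQ
#' correlation), and the video item analysis (subset curve, minimum-video
#' threshold, best videos, chunked cross-validation, median split). When
#' `drop_flagged` is on, the battery is additionally re-run without flagged
#' participants and attached as the sensitivity block.
#'
#' @param ratings Long-format ratings tibble (or a path to a ratings CSV).
#' @param questionnaires Questionnaire tibble (or a path to a CSV).
#' @param config An [pipeline_config()] object.
#' @param out_dir Optional directory; when given, stage outputs (accuracy
#'   cells, pooled scores, consensus trajectories, difficulty function,
#'   subset curve, per-video correlations) are written as CSV and the report
#'   as JSON.
#' @return An `iet_report` list; see Details.
#' @details The report contains `config` (echo), `version`, `accuracy`
#'   (glance), `flagged`, `battery`, `headline` (rho, p, bootstrap CI),
#'   `video_analysis` (`curve`, `min_videos`, `best_videos`, `crossval`,
#'   `median_split`), and `sensitivity` (battery without flagged
#'   participants, when enabled). Identical inputs and config reproduce the
#'   report bit-identically.
#' @export
run_pipeline <- function(ratings, questionnaires, config = pipeline_config(),
                         out_dir = NULL) {
  if (is.character(ratings)) ratings <- read_ratings(ratings)
  if (is.character(questionnaires)) questionnaires <- read_questionnaires(questionnaires)
  if (!inherits(config, "iet_pipeline_config")) {
    abort("`config` must come from pipeline_config().",
          class = "iettrack_invalid_argument")
  }

  accuracy <- score_study(ratings, loo_consensus = config$loo_consensus)
  loo <- loo_difficulty_correlations(accuracy, "valence",
                                     B = config$b_loo, seed = config$seed_loo)
  flagged <- flag_inconsistent_participants(loo)

  battery <- correlation_battery(accuracy, questionnaires,
                                 plan = config$plan, exclude = flagged)

  joined <- join_scores(accuracy, questionnaires)
  headline_boot <- bootstrap_partial(joined$iet_valence, joined$aq,
                                     B = config$b_bootstrap,
                                     seed = config$seed_bootstrap)
  headline_row <- battery[battery$x == "iet_valence" & battery$y == "aq" &
                            !grepl("_sensitivity$", battery$label), ][1, ]
  headline <- tibble::tibble(
    rho = headline_row$rho,
    p_uncorrected = headline_row$p_uncorrected,
    p_bonferroni = headline_row$p_bonferroni,
    ci_low = headline_boot$ci_low, ci_high = headline_boot$ci_high,
    B = headline_boot$B, n = headline_row$n
  )

  curve <- subset_effect_curve(accuracy, questionnaires,
                               k_min = min(5L, dplyr::n_distinct(ratings$video_id)),
                               iters = config$iters_subset,
                               seed = config$seed_subset)
  min_v <- min_videos_for_threshold(curve, fraction = config$fraction)
  best <- best_videos(accuracy, questionnaires, n_best = config$n_best)

  best_cells <- accuracy$cells[accuracy$cells$video_id %in% best$selected &
                                 accuracy$cells$dimension == "valence", ]
  best_scores <- best_cells |>
    dplyr::filter(!is.na(.data$r)) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(score = pool_fisher_z(.data$r), .groups = "drop") |>
    dplyr::inner_join(questionnaires, by = "participant_id")
  crossval <- crossval_correlation(best_scores$score, best_scores$aq,
                                   folds = config$folds_crossval,
                                   iters = config$iters_crossval,
                                   seed = config$seed_crossval)
  median_split <- group_split_comparison(best_scores$score, best_scores$aq,
                                         mode = "median", seed = config$seed_split,
                                         B = config$b_split,
                                         ids = best_scores$participant_id)

  sensitivity <- NULL
  if (config$drop_flagged && length(flagged) > 0L) {
    q_sub <- questionnaires[!(questionnaires$participant_id %in% flagged), ]
    sensitivity <- correlation_battery(accuracy, q_sub, plan = config$plan)
  }

  report <- structure(
    list(
      config = config,
      version = as.character(utils::packageVersion("iettrack")),
      accuracy = accuracy,
      accuracy_summary = glance(accuracy),
      loo = loo,
      flagged = flagged,
      battery = battery,
      headline = headline,
      video_analysis = list(curve = curve, min_videos = min_v,
                            best_videos = best, crossval = crossval,
                            median_split = median_split),
      sensitivity = sensitivity
    ),
    class = "iet_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

write_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  acc <- report$accuracy
  readr::write_csv(acc$cells, file.path(out_dir, "accuracy_cells.csv"))
  readr::write_csv(acc$participant_pooled, file.path(out_dir, "participant_pooled.csv"))
  readr::write_csv(acc$video_pooled, file.path(out_dir, "video_pooled.csv"))
  readr::write_csv(acc$consensus, file.path(out_dir, "consensus_trajectories.csv"))
  readr::write_csv(difficulty_function(acc), file.path(out_dir, "difficulty_function.csv"))
  readr::write_csv(tibble::as_tibble(report$video_analysis$curve),
                   file.path(out_dir, "subset_curve.csv"))
  readr::write_csv(report$video_analysis$best_videos$table,
                   file.path(out_dir, "per_video_rho.csv"))
  readr::write_csv(report$battery, file.path(out_dir, "battery.csv"))
  jsonlite::write_json(
    list(
      version = report$version,
      flagged = report$flagged,
      missing_cells = report$accuracy$missing_cells,
      failures = report$accuracy$failures,
      headline = report$headline,
      min_videos = report$video_analysis$min_videos,
      best_videos = report$video_analysis$best_videos$selected,
      crossval = report$video_analysis$crossval,
      median_split_pairwise = report$video_analysis$median_split$pairwise,
      sensitivity = report$sensitivity
    ),
    file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(out_dir)
}

#' @export
print.iet_report <- function(x, ...) {
  cat("<iet_report>\n")
  cat(sprintf("  participants flagged as inconsistent: %d\n", length(x$flagged)))
  cat(sprintf("  headline IET-valence x AQ: rho = %.3f, p(Bonferroni) = %.4g, 95%% CI [%.3f, %.3f]\n",
              x$headline$rho, x$headline$p_bonferroni,
              x$headline$ci_low, x$headline$ci_high))
  mv <- x$video_analysis$min_videos
  cat(sprintf("  minimum videos for %.0f%% of full effect: %s (threshold %.3f)\n",
              100 * mv$fraction,
              ifelse(mv$reached, as.character(mv$k_star), "not reached"),
              mv$threshold))
  invisible(x)
}
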