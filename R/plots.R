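# ggplot2 layers over the tabular stage outputs. Plot styling is deliberately
# thin: every figure is a direct view of a CSV-serialisable table.

#' Plot ranked participant (or video) accuracies
#'
#' @param object An `iet_accuracy` object.
#' @param dimension Affect dimension to plot.
#' @param by Rank participants or videos.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot iet_accuracy
#' @export
autoplot.iet_accuracy <- function(object, dimension = c("valence", "arousal"),
                                  by = c("participant", "video"), ...) {
  dimension <- match.arg(dimension)
  by <- match.arg(by)
  df <- if (by == "participant") {
    object$participant_pooled |>
      dplyr::filter(.data$dimension == !!dimension) |>
      dplyr::rename(unit = "participant_id")
  } else {
    object$video_pooled |>
      dplyr::filter(.data$dimension == !!dimension) |>
      dplyr::rename(unit = "video_id")
  }
  df <- df |> dplyr::arrange(.data$pooled_accuracy) |>
    dplyr::mutate(rank = dplyr::row_number())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$pooled_accuracy)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = sprintf("%s (ranked)", by),
                  y = sprintf("pooled %s accuracy (r)", dimension))
}

#' Plot the video difficulty function
#'
#' @param accuracy An `iet_accuracy` object.
#' @param dimension Affect dimension.
#' @return A ggplot object: videos ranked by pooled accuracy.
#' @export
plot_difficulty <- function(accuracy, dimension = c("valence", "arousal")) {
  dimension <- match.arg(dimension)
  df <- difficulty_function(accuracy, dimension)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$pooled_accuracy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "video (ranked by accuracy)",
                  y = sprintf("pooled %s accuracy (r)", dimension),
                  title = "Difficulty function")
}

#' Plot a Monte-Carlo subset effect curve
#'
#' @param object An `iet_subset_curve` from [subset_effect_curve()].
#' @param fraction Reference fraction of the full effect to draw (default 0.75).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot iet_subset_curve
#' @export
autoplot.iet_subset_curve <- function(object, fraction = 0.75, ...) {
  full_rho <- attr(object, "full_rho")
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$k, y = abs(.data$mean_rho))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = fraction * abs(full_rho),
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "number of videos",
                  y = "|Fisher-Z mean Spearman rho|",
                  title = "Videos needed to recover the trait effect")
}

#' Plot group-split accuracies
#'
#' @param object An `iet_group_split` from [group_split_comparison()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot iet_group_split
#' @export
autoplot.iet_group_split <- function(object, ...) {
  ggplot2::ggplot(object$groups,
                  ggplot2::aes(x = .data$group, y = .data$pooled_accuracy)) +
    ggplot2::geom_col(width = 0.6, fill = "grey35") +
    ggplot2::labs(x = sprintf("%s-split group", object$mode),
                  y = "Fisher-Z mean accuracy (r)")
}
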