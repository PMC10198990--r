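# Correlation battery: descriptive statistics, Spearman correlations with
# Bonferroni correction over a declared comparison plan, rank-based partial
# correlations with bootstrap CIs, and permutation tests.

#' Descriptive statistics in the standard summary-table layout
#'
#' One row per variable: mean, median, sample SD (n-1 denominator), min, max,
#' adjusted Fisher-Pearson skewness and bias-corrected excess kurtosis (the
#' conventions most statistics software prints by default).
#'
#' @param data A data frame.
#' @param ... <tidy-select> columns to summarise; defaults to every numeric
#'   column.
#' @return A tibble with columns `variable`, `n`, `mean`, `median`, `sd`,
#'   `min`, `max`, `skewness`, `kurtosis`.
#' @export
descriptives <- function(data, ...) {
  sel <- rlang::enquos(...)
  if (length(sel) == 0L) {
    vars <- names(data)[vapply(data, is.numeric, logical(1))]
  } else {
    vars <- names(dplyr::select(data, !!!sel))
  }
  lapply(vars, function(v) {
    x <- data[[v]]
    x <- x[!is.na(x)]
    if (length(x) < 3L) {
      abort(sprintf("Variable '%s' has fewer than 3 observations; higher moments undefined.", v),
            class = "iettrack_invalid_argument")
    }
    tibble::tibble(
      variable = v, n = length(x),
      mean = mean(x), median = median(x), sd = sd(x),
      min = min(x), max = max(x),
      skewness = e1071::skewness(x, type = 2),
      kurtosis = if (length(x) >= 4) e1071::kurtosis(x, type = 2) else NA_real_
    )
  }) |> dplyr::bind_rows()
}

#' Spearman rank correlation with a large-sample p-value
#'
#' rho is the Pearson correlation of average ranks (ties allowed); the
#' p-value uses the standard t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#' Pairs with a missing value in either variable are dropped listwise.
#'
#' @param x,y Paired numeric vectors (n >= 4 complete pairs).
#' @return A one-row tibble: `rho`, `p_uncorrected`, `n`, `method`.
#' @export
spearman_cor <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4L) {
    abort("Need at least 4 complete pairs.", class = "iettrack_invalid_argument")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Correlation undefined: a variable is constant.",
          class = "iettrack_undefined_correlation")
  }
  rho <- cor(rank(x), rank(y))
  p <- spearman_p(rho, n)
  tibble::tibble(rho = rho, p_uncorrected = p, n = n, method = "spearman")
}

spearman_p <- function(rho, n, df_used = n - 2) {
  if (abs(rho) >= 1) return(0)
  tstat <- rho * sqrt(df_used / (1 - rho^2))
  2 * pt(-abs(tstat), df_used)
}

#' Bonferroni correction
#'
#' @param p P-value(s) in `[0, 1]`.
#' @param m Number of planned comparisons (default 17, the size of the
#'   default comparison plan).
#' @return `min(1, m * p)`, elementwise.
#' @export
bonferroni <- function(p, m = 17) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    abort("`p` must lie in [0, 1].", class = "iettrack_invalid_argument")
  }
  assert_count(m, "m", min = 1L)
  pmin(1, m * p)
}

rank_df <- function(covariates, n) {
  if (is.null(covariates) || (is.data.frame(covariates) && ncol(covariates) == 0L)) {
    return(NULL)
  }
  if (is.numeric(covariates) && is.null(dim(covariates))) {
    covariates <- data.frame(z = covariates)
  }
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != n) {
    abort("Covariates must have one row per observation.",
          class = "iettrack_invalid_argument")
  }
  covariates
}

#' Partial Spearman correlation by rank residualisation
#'
#' Every variable (x, y and each covariate) is transformed to average ranks;
#' x-ranks and y-ranks are then residualised on the covariate ranks plus an
#' intercept by least squares, and the partial rho is the Pearson correlation
#' of the residuals. With an empty covariate set this reduces *exactly* to
#' [spearman_cor()].
#'
#' @param x,y Paired numeric vectors.
#' @param covariates Optional data frame / matrix / numeric vector of
#'   covariates (listwise-complete with x and y).
#' @return A one-row tibble: `rho`, `p_uncorrected`, `n`, `n_covariates`,
#'   `method`.
#' @export
partial_spearman <- function(x, y, covariates = NULL) {
  covariates <- rank_df(covariates, length(x))
  if (is.null(covariates)) {
    out <- spearman_cor(x, y)
    out$n_covariates <- 0L
    out$method <- "spearman"
    return(out[, c("rho", "p_uncorrected", "n", "n_covariates", "method")])
  }
  keep <- stats::complete.cases(x, y, covariates)
  x <- x[keep]; y <- y[keep]
  covariates <- covariates[keep, , drop = FALSE]
  n <- length(x)
  k <- ncol(covariates)
  if (k > n - 3L) {
    abort("Too many covariates for the sample size.",
          class = "iettrack_invalid_argument")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Correlation undefined: a variable is constant.",
          class = "iettrack_undefined_correlation")
  }
  Z <- cbind("(intercept)" = 1, apply(as.matrix(covariates), 2, rank))
  qrz <- qr(Z)
  if (qrz$rank < ncol(Z)) {
    dep <- colnames(Z)[qrz$pivot[(qrz$rank + 1L):ncol(Z)]]
    abort(sprintf("Collinear covariates: %s.", paste(dep, collapse = ", ")),
          class = "iettrack_invalid_argument")
  }
  rx <- qr.resid(qrz, rank(x))
  ry <- qr.resid(qrz, rank(y))
  if (sd(rx) == 0 || sd(ry) == 0) {
    abort("Correlation undefined after residualisation.",
          class = "iettrack_undefined_correlation")
  }
  rho <- cor(rx, ry)
  tibble::tibble(rho = rho, p_uncorrected = spearman_p(rho, n, n - 2 - k),
                 n = n, n_covariates = k, method = "partial_spearman")
}

#' Bootstrap mean and CI for a (partial) Spearman correlation
#'
#' Case-resamples participants with replacement, recomputes the partial
#' Spearman per resample, Fisher-Z averages the resampled coefficients and
#' reports the percentile 95% CI. Significance is read from whether the CI
#' excludes zero. Resamples in which a variable collapses to a constant are
#' redrawn (bounded retries).
#'
#' @inheritParams partial_spearman
#' @param B Resamples (>= 1000; default 5000).
#' @param seed Integer seed; the CI is bit-identical across runs at a fixed
#'   seed.
#' @param conf Coverage level (default 0.95).
#' @return A one-row tibble: `mean_rho`, `ci_low`, `ci_high`, `significant`,
#'   `B`, `n`.
#' @export
bootstrap_partial <- function(x, y, covariates = NULL, B = 5000, seed = 1L,
                              conf = 0.95) {
  assert_count(B, "B", min = 1000L)
  covariates <- rank_df(covariates, length(x))
  keep <- if (is.null(covariates)) stats::complete.cases(x, y) else
    stats::complete.cases(x, y, covariates)
  x <- x[keep]; y <- y[keep]
  if (!is.null(covariates)) covariates <- covariates[keep, , drop = FALSE]
  n <- length(x)
  rhos <- withr::with_seed(seed, {
    vapply(seq_len(B), function(b) {
      for (try in 1:25) {
        idx <- sample.int(n, n, replace = TRUE)
        res <- tryCatch(
          partial_spearman(x[idx], y[idx],
                           if (is.null(covariates)) NULL else
                             covariates[idx, , drop = FALSE])$rho,
          error = function(e) NA_real_)
        if (!is.na(res)) return(res)
      }
      abort("Bootstrap resampling kept producing constant variables.",
            class = "iettrack_degenerate_input")
    }, numeric(1))
  })
  alpha <- (1 - conf) / 2
  ci <- unname(quantile(rhos, c(alpha, 1 - alpha)))
  tibble::tibble(
    mean_rho = pool_fisher_z(rhos),
    ci_low = ci[1], ci_high = ci[2],
    significant = ci[1] > 0 | ci[2] < 0,
    B = B, n = n
  )
}

# All permutations of 1..n (n <= 8), used for exact permutation p-values.
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  smaller <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[smaller], nrow(smaller)))
  }))
}

#' Permutation test for a correlation
#'
#' Permutes `y` uniformly at random and recomputes the correlation; the
#' two-sided p-value is `(1 + #{|rho_perm| >= |rho_obs|}) / (B + 1)`. With
#' `exact = TRUE` (n <= 8) all `n!` permutations are enumerated instead and
#' the p-value is the exact tail proportion.
#'
#' @param x,y Paired numeric vectors.
#' @param B Random permutations (>= 1000); ignored when `exact = TRUE`.
#' @param seed Integer seed.
#' @param method Correlation flavour: `"spearman"` (default) or `"pearson"`.
#' @param exact Enumerate all permutations (small n only).
#' @return An `iet_permutation` list: `p`, `rho_obs`, `null` (the permuted
#'   statistics), `B`, `exact`.
#' @export
permutation_test <- function(x, y, B = 5000, seed = 1L,
                             method = c("spearman", "pearson"),
                             exact = FALSE) {
  method <- match.arg(method)
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Correlation undefined: a variable is constant.",
          class = "iettrack_undefined_correlation")
  }
  if (method == "spearman") { x <- rank(x); y <- rank(y) }
  rho_obs <- cor(x, y)
  if (exact) {
    if (n > 8L) abort("Exact enumeration supported only for n <= 8.",
                      class = "iettrack_invalid_argument")
    P <- all_perms(n)
    null <- apply(P, 1, function(ix) cor(x, y[ix]))
    p <- mean(abs(null) >= abs(rho_obs) - 1e-12)
    B_used <- nrow(P)
  } else {
    assert_count(B, "B", min = 1000L)
    null <- withr::with_seed(seed, vapply(
      seq_len(B), function(b) cor(x, y[sample.int(n)]), numeric(1)))
    p <- (1 + sum(abs(null) >= abs(rho_obs) - 1e-12)) / (B + 1)
    B_used <- B
  }
  structure(list(p = p, rho_obs = rho_obs, null = null, B = B_used,
                 exact = exact, method = method),
            class = "iet_permutation")
}

#' The default 17-comparison plan
#'
#' The main-results plan: the four task scores (IET valence accuracy, IET
#' arousal accuracy, Eyes Test, Films task) crossed with the four trait
#' measures (AQ, EQ, fluid intelligence / matrices, crystallised
#' intelligence / vocabulary), 16 pairs, plus the IET-valence x AQ
#' sensitivity re-run without flagged participants (17th). The plan is
#' explicit and user-editable; pass your own tibble to
#' [correlation_battery()] to change it.
#'
#' @return A tibble with columns `x`, `y`, `label`.
#' @export
default_comparison_plan <- function() {
  tasks <- c("iet_valence", "iet_arousal", "eyes_test", "films_task")
  traits <- c("aq", "eq", "matrices", "vocabulary")
  base <- tidyr::expand_grid(x = tasks, y = traits)
  base$label <- paste(base$x, base$y, sep = "_x_")
  dplyr::bind_rows(
    base,
    tibble::tibble(x = "iet_valence", y = "aq",
                   label = "iet_valence_x_aq_sensitivity")
  )
}

#' Run the planned Spearman correlation battery
#'
#' Joins task scores to questionnaire totals on `participant_id`, runs
#' [spearman_cor()] for every planned pair and applies [bonferroni()] with
#' `m` equal to the plan size. Plan rows whose label ends in `_sensitivity`
#' are computed after dropping `exclude` participants (the flagged-responder
#' sensitivity re-run); when `exclude` is empty they equal the main row.
#'
#' @param scores Either an `iet_accuracy` object or a wide tibble with
#'   `participant_id` plus task-score columns (e.g. `iet_valence`).
#' @param questionnaires Questionnaire tibble keyed by `participant_id`.
#' @param plan Comparison plan tibble (`x`, `y`, optional `label`); default
#'   [default_comparison_plan()].
#' @param exclude Participant ids to drop from `_sensitivity` rows.
#' @return An `iet_battery` tibble: `label`, `x`, `y`, `rho`,
#'   `p_uncorrected`, `p_bonferroni`, `n`, `m`.
#' @export
correlation_battery <- function(scores, questionnaires,
                                plan = default_comparison_plan(),
                                exclude = character()) {
  joined <- join_scores(scores, questionnaires)
  if (!all(c("x", "y") %in% names(plan))) {
    abort("`plan` needs columns `x` and `y`.", class = "iettrack_invalid_argument")
  }
  if (!"label" %in% names(plan)) plan$label <- paste(plan$x, plan$y, sep = "_x_")
  unknown <- setdiff(unique(c(plan$x, plan$y)), names(joined))
  if (length(unknown) > 0L) {
    abort(sprintf("Plan references unknown variable(s): %s.",
                  paste(unknown, collapse = ", ")),
          class = "iettrack_invalid_argument")
  }
  m <- nrow(plan)
  rows <- lapply(seq_len(m), function(i) {
    x <- plan$x[i]; y <- plan$y[i]; label <- plan$label[i]
    dat <- joined
    if (grepl("_sensitivity$", label) && length(exclude) > 0L) {
      dat <- dat[!(dat$participant_id %in% exclude), ]
    }
    if (all(is.na(dat[[x]])) || all(is.na(dat[[y]]))) {
      abort(sprintf("Variable all-missing in comparison '%s'.", label),
            class = "iettrack_invalid_argument")
    }
    res <- spearman_cor(dat[[x]], dat[[y]])
    tibble::tibble(label = label, x = x, y = y, rho = res$rho,
                   p_uncorrected = res$p_uncorrected,
                   p_bonferroni = bonferroni(res$p_uncorrected, m),
                   n = res$n, m = m)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("iet_battery", class(out))
  attr(out, "plan") <- plan
  attr(out, "excluded") <- exclude
  out
}

# Accepts either an iet_accuracy (pooled per-participant accuracies are
# spread to iet_valence / iet_arousal columns) or an already-wide tibble.
join_scores <- function(scores, questionnaires) {
  if (inherits(scores, "iet_accuracy")) {
    scores <- scores$participant_pooled |>
      dplyr::mutate(dimension = paste0("iet_", .data$dimension)) |>
      tidyr::pivot_wider(id_cols = "participant_id",
                         names_from = "dimension",
                         values_from = "pooled_accuracy")
  }
  if (!"participant_id" %in% names(scores)) {
    abort("`scores` must contain `participant_id`.",
          class = "iettrack_invalid_argument")
  }
  dplyr::inner_join(scores, questionnaires, by = "participant_id")
}

#' @export
print.iet_battery <- function(x, ...) {
  cat(sprintf("<iet_battery> %d planned comparisons (Bonferroni m = %d)\n",
              nrow(x), x$m[1]))
  NextMethod()
}

#' @rdname correlation_battery
#' @param x An `iet_battery` object.
#' @param ... Unused.
#' @method glance iet_battery
#' @export
glance.iet_battery <- function(x, ...) {
  tibble::tibble(
    m = x$m[1],
    n_significant_bonferroni = sum(x$p_bonferroni < 0.05),
    n_significant_uncorrected = sum(x$p_uncorrected < 0.05),
    min_p_bonferroni = min(x$p_bonferroni)
  )
}
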