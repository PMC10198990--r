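# Synthetic cohort generator: latent affect trajectories, rater model, and
# questionnaire totals with a configurable competency-AQ coupling. The
# generator is first-class, tested code: every downstream stage is verified
# against cohorts whose ground truth (per-video latent trajectories and
# per-participant competencies) is known.

# Table-1-style questionnaire catalogue: observed means/SDs and admissible
# spans, instrument maxima, plus latent loadings. `load_aq` couples a total to
# the autism-trait factor, `load_comp` to latent tracking competency (fluid
# and crystallised intelligence correlate with tracking accuracy).
questionnaire_catalogue <- function() {
  tibble::tribble(
    ~variable,         ~mean,  ~sd,   ~min, ~max, ~instrument_max, ~load_aq, ~load_comp,
    "eyes_test",       25.17,  5.37,  5,    33,   36,              -0.15,    0.30,
    "films_task",      27.53,  3.45,  10,   32,   32,              -0.20,    0.25,
    "matrices",        28.61,  4.39,  12,   35,   35,               0.00,    0.35,
    "vocabulary",      13.17,  3.60,  1,    20,   20,               0.00,    0.30,
    "swls",            23.23,  6.62,  5,    35,   35,              -0.30,    0.00,
    "eq",              43.69, 12.45,  15,   68,   80,              -0.45,    0.15,
    "stai_state",      42.54, 12.08,  20,   70,   80,               0.30,    0.00,
    "stai_trait",      45.86, 10.46,  20,   74,   80,               0.40,    0.00,
    "bdi",              9.64,  7.89,  0,    37,   63,               0.35,    0.00,
    "cape_psychosis",  72.33, 15.39,  46,  126,  168,               0.30,    0.00,
    "cape_depressive", 16.96,  5.36,  7,    33,   32,               0.30,    0.00,
    "cape_negative",   28.02,  7.68,  16,   61,   64,               0.30,    0.00,
    "cape_positive",   27.35,  5.81,  16,   44,   80,               0.25,    0.00
  )
}

#' Configuration for a synthetic Inferential Emotion Tracking cohort
#'
#' Bundles and validates every knob of the cohort generator. Defaults emulate
#' the study conditions the package targets: 102 participants rating 35 video
#' clips of 1-3 minutes each on a 2D valence-arousal grid, with latent rater
#' competency negatively coupled to the Autism-Spectrum Quotient.
#'
#' @param n_participants Number of raters (>= 3).
#' @param n_videos Number of video clips (>= 2).
#' @param duration_range Two-element range (seconds) from which each clip's
#'   duration is drawn uniformly; default 60-180 s (1-3 minute clips).
#' @param sample_hz Rating samples per second; default 10.
#' @param trajectory_smoothness Correlation length (seconds) of the latent
#'   affect process; larger values give slower-moving trajectories. The
#'   default (3 s) keeps the correlation length well below the 10 s minimum
#'   circular shift used by the permutation null, so shifted trajectories are
#'   genuinely decorrelated from the consensus.
#' @param competency_range Interval within `[0, 1]` from which each rater's
#'   latent tracking competency is drawn uniformly (via a Gaussian copula so
#'   competency can correlate with AQ).
#' @param noise_sd Baseline standard deviation of additive per-sample rating
#'   noise, in grid units.
#' @param video_noise_range Range of the per-video multiplier applied to
#'   `noise_sd` (uniform draw per video). The default (0.1-4) gives the
#'   cohort a pronounced common video difficulty gradient: every rater finds
#'   the same clips harder, which is what the leave-one-out difficulty
#'   diagnostics detect.
#' @param lapse_prob Per-sample probability that a rater freezes and holds the
#'   previous cursor position.
#' @param trait_loading Target (signed) correlation between latent competency
#'   and AQ, in `[-1, 1]`. Negative values emulate the hypothesis that high
#'   autism-trait scorers track context-based emotion less accurately.
#' @param bias_sd Standard deviation of each rater's constant 2D grid offset.
#' @param gain_sd Log-scale standard deviation of each rater's positive gain.
#' @param aq_range Integer span to which generated AQ totals are clipped;
#'   defaults to the observed span `[9, 33]` (the instrument range is 0-50)
#'   so that median-split and quartile analyses behave like typical
#'   non-clinical cohorts.
#' @param seed Integer RNG seed; fixing it fixes the whole cohort.
#' @return An object of class `iet_config` (a named list).
#' @export
synthetic_config <- function(n_participants = 102,
                             n_videos = 35,
                             duration_range = c(60, 180),
                             sample_hz = 10,
                             trajectory_smoothness = 3,
                             competency_range = c(0.3, 0.95),
                             noise_sd = 0.25,
                             video_noise_range = c(0.1, 4),
                             lapse_prob = 0.01,
                             trait_loading = -0.4,
                             bias_sd = 0.05,
                             gain_sd = 0.1,
                             aq_range = c(9L, 33L),
                             seed = 1L) {
  assert_count(n_participants, "n_participants", min = 3L)
  assert_count(n_videos, "n_videos", min = 2L)
  assert_scalar_number(sample_hz, "sample_hz", positive = TRUE)
  assert_scalar_number(trajectory_smoothness, "trajectory_smoothness")
  if (trajectory_smoothness <= 0) {
    abort("`trajectory_smoothness` must be > 0.", class = "iettrack_invalid_argument")
  }
  if (length(duration_range) != 2L || any(!is.finite(duration_range)) ||
      duration_range[1] <= 0 || diff(duration_range) < 0) {
    abort("`duration_range` must be a non-decreasing positive pair of seconds.",
          class = "iettrack_invalid_argument")
  }
  if (length(competency_range) != 2L || any(competency_range < 0) ||
      any(competency_range > 1) || diff(competency_range) < 0) {
    abort("`competency_range` must be a non-decreasing pair inside [0, 1].",
          class = "iettrack_invalid_argument")
  }
  assert_scalar_number(noise_sd, "noise_sd")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.", class = "iettrack_invalid_argument")
  if (length(video_noise_range) != 2L || any(video_noise_range < 0) ||
      diff(video_noise_range) < 0) {
    abort("`video_noise_range` must be a non-decreasing non-negative pair.",
          class = "iettrack_invalid_argument")
  }
  assert_probability(lapse_prob, "lapse_prob")
  assert_scalar_number(trait_loading, "trait_loading")
  if (abs(trait_loading) > 1) {
    abort("`trait_loading` must lie in [-1, 1].", class = "iettrack_invalid_argument")
  }
  assert_scalar_number(bias_sd, "bias_sd")
  assert_scalar_number(gain_sd, "gain_sd")
  if (bias_sd < 0 || gain_sd < 0) {
    abort("`bias_sd` and `gain_sd` must be >= 0.", class = "iettrack_invalid_argument")
  }
  if (length(aq_range) != 2L || diff(aq_range) <= 0 || aq_range[1] < 0 || aq_range[2] > 50) {
    abort("`aq_range` must be an increasing pair within the 0-50 instrument range.",
          class = "iettrack_invalid_argument")
  }
  seed <- assert_count(seed, "seed", min = 0L)
  structure(
    list(
      n_participants = as.integer(n_participants),
      n_videos = as.integer(n_videos),
      duration_range = as.numeric(duration_range),
      sample_hz = sample_hz,
      trajectory_smoothness = trajectory_smoothness,
      competency_range = as.numeric(competency_range),
      noise_sd = noise_sd,
      video_noise_range = as.numeric(video_noise_range),
      lapse_prob = lapse_prob,
      trait_loading = trait_loading,
      bias_sd = bias_sd,
      gain_sd = gain_sd,
      aq_range = as.integer(aq_range),
      seed = seed
    ),
    class = "iet_config"
  )
}

# Stationary AR(1) path of length n with lag-1 autocorrelation phi and unit
# stationary variance. phi may be 1 (infinite correlation length): the path is
# then constant at its stationary draw.
ar1_path <- function(n, phi) {
  z <- rnorm(n)
  x <- numeric(n)
  x[1] <- z[1]
  if (phi >= 1) return(rep(x[1], n))
  s <- sqrt(1 - phi^2)
  for (i in seq_len(n)[-1]) x[i] <- phi * x[i - 1] + s * z[i]
  x
}

#' Generate one latent affect trajectory
#'
#' Draws a smooth, bounded two-dimensional affect course: each dimension is a
#' stationary Ornstein-Uhlenbeck-style AR(1) process with unit stationary
#' variance and correlation length `smoothness`, squashed into the rating grid
#' by `tanh`. This is the documented default latent process for synthetic
#' clips; any smooth bounded process would serve, but one smoothness knob
#' keeps the generator auditable.
#'
#' @param duration_s Clip duration in seconds (> 0).
#' @param sample_hz Samples per second (> 0).
#' @param smoothness Correlation length in seconds (> 0; `Inf` gives a
#'   constant trajectory).
#' @param seed Integer seed; the same seed reproduces the trajectory exactly.
#' @return A tibble with columns `t_s`, `valence`, `arousal`; all affect
#'   values lie in `(-1, 1)`.
#' @export
generate_latent_trajectory <- function(duration_s, sample_hz, smoothness, seed = NULL) {
  assert_scalar_number(duration_s, "duration_s", positive = TRUE)
  assert_scalar_number(sample_hz, "sample_hz", positive = TRUE)
  if (!is.numeric(smoothness) || length(smoothness) != 1L || is.na(smoothness) ||
      smoothness <= 0) {
    abort("`smoothness` must be > 0 (Inf allowed).", class = "iettrack_invalid_argument")
  }
  draw <- function() {
    n <- round(duration_s * sample_hz)
    if (n < 1L) {
      abort("duration_s * sample_hz must give at least one sample.",
            class = "iettrack_invalid_argument")
    }
    phi <- if (is.infinite(smoothness)) 1 else exp(-1 / (sample_hz * smoothness))
    tibble::tibble(
      t_s = (seq_len(n) - 1L) / sample_hz,
      valence = tanh(ar1_path(n, phi)),
      arousal = tanh(ar1_path(n, phi))
    )
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# One rater's observed trajectory for one video: a competency-weighted mix of
# the true latent course and an independent distractor course (so
# low-competency raters are internally consistent but wrong), passed through
# the rater's gain/bias, plus white noise and lapse-and-hold events, clipped
# to the grid.
observe_trajectory <- function(latent, distractor, competency, gain, bias,
                               noise_sd, lapse_prob) {
  n <- length(latent)
  y <- gain * (competency * latent + (1 - competency) * distractor) + bias
  if (noise_sd > 0) y <- y + rnorm(n, sd = noise_sd)
  if (lapse_prob > 0) {
    hold <- runif(n) < lapse_prob
    hold[1] <- FALSE
    for (i in which(hold)) y[i] <- y[i - 1]
  }
  pmin(pmax(y, -1), 1)
}

#' Generate a full synthetic cohort
#'
#' Builds everything a scoring run needs: long-format ratings for every
#' participant x video x time sample, a questionnaire table whose AQ total is
#' coupled to latent competency through a Gaussian copula at the configured
#' `trait_loading`, and the ground truth (latent trajectories and participant
#' profiles) for parameter-recovery tests.
#'
#' The observation model for each sample is
#' `gain * (competency * latent + (1 - competency) * distractor) + bias +
#' noise`, clipped to the grid, with lapse-and-hold events; the distractor is
#' an independent draw of the same latent process per participant-video.
#'
#' @param config An [synthetic_config()] object.
#' @return An object of class `iet_cohort`: a list with `ratings` (tibble:
#'   `participant_id`, `video_id`, `t_s`, `valence`, `arousal`),
#'   `questionnaires` (one row per participant), and `ground_truth` (list with
#'   `latent` trajectories and participant `profiles`).
#' @export
generate_cohort <- function(config = synthetic_config()) {
  if (!inherits(config, "iet_config")) {
    abort("`config` must come from synthetic_config().",
          class = "iettrack_invalid_argument")
  }
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  P <- cfg$n_participants
  V <- cfg$n_videos
  pid <- sprintf("P%03d", seq_len(P))
  vid <- sprintf("V%02d", seq_len(V))

  durations <- runif(V, cfg$duration_range[1], cfg$duration_range[2])
  video_noise <- cfg$noise_sd *
    runif(V, cfg$video_noise_range[1], cfg$video_noise_range[2])
  phi <- if (is.infinite(cfg$trajectory_smoothness)) 1 else
    exp(-1 / (cfg$sample_hz * cfg$trajectory_smoothness))
  n_samp <- pmax(1L, round(durations * cfg$sample_hz))

  latent <- purrr::map2(vid, n_samp, function(v, n) {
    tibble::tibble(
      video_id = v,
      t_s = (seq_len(n) - 1L) / cfg$sample_hz,
      valence = tanh(ar1_path(n, phi)),
      arousal = tanh(ar1_path(n, phi))
    )
  })
  names(latent) <- vid

  # Gaussian copula: z_comp drives competency, z_aq = loading * z_comp + rest
  # drives AQ, so corr(competency, AQ) tracks trait_loading up to the mild
  # attenuation of the uniform/discretised margins.
  tl <- cfg$trait_loading
  z_comp <- rnorm(P)
  z_aq <- tl * z_comp + sqrt(1 - tl^2) * rnorm(P)
  competency <- cfg$competency_range[1] +
    diff(cfg$competency_range) * pnorm(z_comp)
  profiles <- tibble::tibble(
    participant_id = pid,
    competency = competency,
    bias_valence = rnorm(P, sd = cfg$bias_sd),
    bias_arousal = rnorm(P, sd = cfg$bias_sd),
    gain = exp(rnorm(P, sd = cfg$gain_sd))
  )

  questionnaires <- build_questionnaires(pid, z_comp, z_aq, cfg)

  ratings <- purrr::map(vid, function(v) {
    lat <- latent[[v]]
    n <- nrow(lat)
    vals <- matrix(NA_real_, n, P)
    ars <- matrix(NA_real_, n, P)
    for (j in seq_len(P)) {
      dis_v <- tanh(ar1_path(n, phi))
      dis_a <- tanh(ar1_path(n, phi))
      nv <- video_noise[match(v, vid)]
      vals[, j] <- observe_trajectory(lat$valence, dis_v, competency[j],
                                      profiles$gain[j], profiles$bias_valence[j],
                                      nv, cfg$lapse_prob)
      ars[, j] <- observe_trajectory(lat$arousal, dis_a, competency[j],
                                     profiles$gain[j], profiles$bias_arousal[j],
                                     nv, cfg$lapse_prob)
    }
    tibble::tibble(
      participant_id = rep(pid, each = n),
      video_id = v,
      t_s = rep(lat$t_s, P),
      valence = as.vector(vals),
      arousal = as.vector(ars)
    )
  })
  ratings <- dplyr::bind_rows(ratings) |>
    dplyr::arrange(.data$participant_id, .data$video_id, .data$t_s)

  structure(
    list(
      ratings = ratings,
      questionnaires = questionnaires,
      ground_truth = list(
        latent = dplyr::bind_rows(latent),
        profiles = dplyr::left_join(
          profiles,
          dplyr::select(questionnaires, "participant_id", "aq"),
          by = "participant_id"
        )
      ),
      config = cfg
    ),
    class = "iet_cohort"
  )
}

build_questionnaires <- function(pid, z_comp, z_aq, cfg) {
  P <- length(pid)
  aq <- as.integer(pmin(pmax(round(18.95 + 5.13 * z_aq),
                             cfg$aq_range[1]), cfg$aq_range[2]))
  cat_ <- questionnaire_catalogue()
  totals <- purrr::pmap(cat_, function(variable, mean, sd, min, max,
                                       instrument_max, load_aq, load_comp) {
    resid_sd <- sqrt(pmax(0, 1 - load_aq^2 - load_comp^2))
    z <- load_aq * z_aq + load_comp * z_comp + resid_sd * rnorm(P)
    as.integer(pmin(pmax(round(mean + sd * z), min), pmin(max, instrument_max)))
  })
  names(totals) <- cat_$variable
  tibble::tibble(
    participant_id = pid,
    aq = aq,
    eq = totals$eq,
    eyes_test = totals$eyes_test,
    films_task = totals$films_task,
    matrices = totals$matrices,
    vocabulary = totals$vocabulary,
    swls = totals$swls,
    stai_state = totals$stai_state,
    stai_trait = totals$stai_trait,
    bdi = totals$bdi,
    cape_psychosis = totals$cape_psychosis,
    cape_depressive = totals$cape_depressive,
    cape_negative = totals$cape_negative,
    cape_positive = totals$cape_positive,
    age = as.integer(pmin(18L + round(stats::rexp(P, rate = 1 / 2.2)), 42L)),
    gender = sample(c("woman", "man"), P, replace = TRUE, prob = c(63, 39) / 102)
  )
}

#' Write a cohort to long-format CSV files
#'
#' Emits `ratings.csv` (long format: `participant_id`, `video_id`, `t_s`,
#' `valence`, `arousal`; one row per time sample) and `questionnaires.csv`
#' (one row per participant) into `out_dir`. A read-back with
#' [read_ratings()] / [read_questionnaires()] reproduces all values to full
#' stored precision.
#'
#' @param ratings Long-format ratings tibble (or an `iet_cohort`, whose two
#'   tables are then both written).
#' @param questionnaires Questionnaire tibble; ignored when `ratings` is an
#'   `iet_cohort`.
#' @param out_dir Writable output directory (created if absent).
#' @return Named character vector of the files written, invisibly.
#' @export
write_cohort <- function(ratings, questionnaires = NULL, out_dir) {
  if (inherits(ratings, "iet_cohort")) {
    questionnaires <- ratings$questionnaires
    ratings <- ratings$ratings
  }
  if (!is.data.frame(ratings) || nrow(ratings) == 0L ||
      !is.data.frame(questionnaires) || nrow(questionnaires) == 0L) {
    abort("Refusing to write an empty cohort.", class = "iettrack_invalid_argument")
  }
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("Cannot create directory '%s'.", out_dir),
                   class = "iettrack_io_error")
  }
  paths <- c(
    ratings = file.path(out_dir, "ratings.csv"),
    questionnaires = file.path(out_dir, "questionnaires.csv")
  )
  readr::write_csv(ratings, paths[["ratings"]])
  readr::write_csv(questionnaires, paths[["questionnaires"]])
  invisible(paths)
}

#' @export
print.iet_cohort <- function(x, ...) {
  cat(sprintf(
    "<iet_cohort> %d participants x %d videos (%d rating rows)\n",
    dplyr::n_distinct(x$ratings$participant_id),
    dplyr::n_distinct(x$ratings$video_id),
    nrow(x$ratings)
  ))
  invisible(x)
}
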