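# Shared cohort builders for the test suite. All cohorts are generated in
# code under fixed seeds; nothing is read from disk.

small_config <- function(..., seed = 2024L) {
  synthetic_config(
    n_participants = 10, n_videos = 4,
    duration_range = c(30, 40), sample_hz = 10,
    seed = seed, ...
  )
}

# Perfect raters: competency 1, no noise, no lapses, unit gain, zero bias.
noise_free_config <- function(n = 6, V = 3, seed = 77L) {
  synthetic_config(
    n_participants = n, n_videos = V,
    duration_range = c(30, 30), sample_hz = 10,
    competency_range = c(1, 1), noise_sd = 0,
    video_noise_range = c(1, 1), lapse_prob = 0,
    bias_sd = 0, gain_sd = 0, seed = seed
  )
}

# Replace the given participants' ratings with independent smooth
# trajectories: internally plausible series carrying no information about any
# video (planted random responders).
plant_random_responders <- function(cohort, pids, seed = 999L) {
  ratings <- cohort$ratings
  hz <- cohort$config$sample_hz
  smooth <- cohort$config$trajectory_smoothness
  seeds <- withr::with_seed(seed, sample.int(1e6, length(pids) * 100))
  k <- 0L
  for (p in pids) {
    for (v in unique(ratings$video_id)) {
      k <- k + 1L
      sel <- ratings$participant_id == p & ratings$video_id == v
      n <- sum(sel)
      tr <- generate_latent_trajectory(n / hz, hz, smooth, seed = seeds[k])
      ratings$valence[sel] <- tr$valence
      ratings$arousal[sel] <- tr$arousal
    }
  }
  cohort$ratings <- ratings
  cohort
}

# Pooled valence accuracy aligned with the questionnaire table.
valence_scores <- function(accuracy, questionnaires) {
  pp <- accuracy$participant_pooled
  pp <- pp[pp$dimension == "valence", ]
  q <- questionnaires[match(pp$participant_id, questionnaires$participant_id), ]
  list(score = pp$pooled_accuracy, aq = q$aq, id = pp$participant_id)
}

# Accuracy cells with a planted structure: `signal` videos carry a linear
# trait effect, the rest are pure noise. Built directly at the cell level so
# the selection machinery is tested against exactly known ground truth.
planted_cells <- function(P = 60, V = 10, signal = sprintf("V%02d", 1:4),
                          slope = -0.02, noise = 0.08, seed = 1L) {
  withr::with_seed(seed, {
    aq <- sample(9:33, P, replace = TRUE)
    pid <- sprintf("P%03d", seq_len(P))
    vids <- sprintf("V%02d", seq_len(V))
    cells <- tidyr::expand_grid(participant_id = pid, video_id = vids)
    cells$dimension <- "valence"
    base <- 0.5 + slope * (aq - 21)[match(cells$participant_id, pid)]
    is_sig <- cells$video_id %in% signal
    cells$r <- ifelse(is_sig, base, 0.4) + rnorm(nrow(cells), sd = noise)
    cells$r <- pmin(pmax(cells$r, -0.99), 0.99)
    list(cells = cells,
         questionnaires = tibble::tibble(participant_id = pid, aq = aq))
  })
}
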