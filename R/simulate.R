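#' Default per-species simulation parameters
#'
#' Study conditions for the synthetic generator: per-species courtship and
#' copulation duration distributions (mean, sd and observed range, in
#' minutes, used as truncation bounds) with the per-species sample sizes
#' of the copulation-duration analysis, and the per-species true mean
#' top-view mating angle (degrees; positive = male on the female's right).
#' Only *D. pachea* and *D. nannoptera* mate right-sidedly (true means
#' +21.4 and +32.5 degrees); the remaining species are genuinely
#' symmetric (true mean 0). The between-experiment angle sd defaults to 12
#' degrees. *D. acanthoptera* courtship was not measured, so its courtship
#' parameters are missing and simulated trials of that species carry no
#' courtship start.
#'
#' @return Tibble with one row per species.
#' @export
species_sim_specs <- function() {
  tibble::tribble(
    ~species_code, ~courtship_mean_min, ~courtship_sd_min,
    ~courtship_min_min, ~courtship_max_min,
    ~copulation_mean_min, ~copulation_sd_min,
    ~copulation_min_min, ~copulation_max_min, ~n_experiments,
    ~angle_mean_deg,
    "aca", NA,    NA,   NA,   NA,    88.49, 35.18, 38.85, 144.3, 12L, 0,
    "pac", 4.67,  3.91, 0.17, 12.37, 29.58, 7.86,  7.33,  42.63, 21L, 21.4011,
    "nan", 1.89,  3.25, 0.05, 12.67, 11.9,  4.2,   4.03,  20.1,  21L, 32.5346,
    "mac", 1.97,  3.44, 0.08, 11.85, 2.28,  0.53,  1.07,  3.55,  18L, 0,
    "bro", 2.07,  2.4,  0.23, 8.37,  0.92,  0.28,  0.65,  1.73,  12L, 0,
    "moj", 1.56,  2.71, 0.13, 5.63,  2.3,   0.35,  1.83,  2.57,  4L,  0,
    "buz", 2.87,  5.26, 0.08, 18.87, 1.79,  0.65,  1.13,  3.42,  17L, 0,
    "tri", 5.17,  5.98, 0.68, 13.82, 33.34, 9.54,  20.47, 42.15, 4L,  0,
    "wil", 5.72,  5.39, 0.53, 14.65, 16.88, 2.58,  13.9,  21.55, 6L,  0,
    "mel", 13.48, 8.9,  2.55, 40.23, 13.83, 4.33,  7.57,  24.55, 31L, 0
  ) |>
    mutate(angle_sd_deg = 12, landmark_noise_px = 2)
}

#' True frontal-tilt trajectory for *D. nannoptera*
#'
#' Per-minute true mean and sd (degrees) of the frontal tilt angle after
#' copulation start: an initial moderate right tilt that rises over the
#' first minutes and plateaus around 25-30 degrees.
#'
#' @return Tibble with `interval_min`, `mean_deg`, `sd_deg`.
#' @export
nannoptera_frontal_trajectory <- function() {
  tibble(
    interval_min = 0:11,
    mean_deg = c(10.36, 15.46, 23.44, 27.16, 29.1, 28.97,
                 32.48, 26.44, 23.21, 24.7, 18.65, 8.07),
    sd_deg = c(6.88, 8.82, 12.15, 10.81, 11.62, 11.92,
               8.29, 10.2, 11.8, 13.66, 14.03, 10)
  )
}

# one truncated-normal draw per (mean, sd) row, by rejection
rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  lo <- ifelse(is.na(lo), -Inf, lo)
  hi <- ifelse(is.na(hi), Inf, hi)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- rnorm(1, mean, sd)
      if (x >= lo && x <= hi) break
    }
    out[i] <- x
  }
  out
}

# random camera pose: rotation U[0, 2pi), uniform scale U[0.5, 2],
# translation inside an 800 x 600 frame; returns a function mapping an
# n x 2 coordinate matrix
random_pose <- function() {
  phi <- runif(1, 0, 2 * pi)
  s <- runif(1, 0.5, 2)
  tx <- runif(1, 200, 600)
  ty <- runif(1, 150, 450)
  function(xy) {
    z <- s * exp(1i * phi) * complex(real = xy[, 1], imaginary = xy[, 2])
    cbind(Re(z) + tx, Im(z) + ty)
  }
}

# ideal top-view landmark triplet realising a given signed angle (deg):
# P1 = (0,0), P2 = (0,100), P3 = P2 + 80 (sin a, cos a) in y-down pixels
ideal_top_landmarks <- function(angle_deg) {
  a <- angle_deg * pi / 180
  rbind(c(0, 0), c(0, 100), c(80 * sin(a), 100 + 80 * cos(a)))
}

# ideal frontal triplet: P4 = (0,-100), P5 = (0,0),
# P6 = -80 (sin a, cos a); positive angle tilts toward -x (female's right)
ideal_frontal_landmarks <- function(angle_deg) {
  a <- angle_deg * pi / 180
  rbind(c(0, -100), c(0, 0), c(-80 * sin(a), -80 * cos(a)))
}

#' Simulate a multi-species mating-posture study
#'
#' Generates the full synthetic analogue of the video study: per-species
#' event tables (courtship start, copulation start, settling, copulation
#' end), a posture-measurement schedule per trial, and for every scheduled
#' frame two replicate top-view landmark acquisitions (P1, P2, P3) of an
#' ideal couple under an arbitrary random camera pose (rotation, uniform
#' scaling, translation in an 800 x 600 pixel frame) with per-replicate
#' Gaussian landmark noise. Durations are truncated-normal draws within
#' each species' observed range (never below the 15-second copulation
#' rule); the settling time point falls uniformly in the first 20% of
#' copulation. True angles combine the species mean, an experiment-level
#' random intercept (trials keep their individual posture over time) and
#' frame-level noise so that the between-experiment sd at a fixed time
#' point matches `angle_sd_deg`.
#'
#' Optionally, extra discarded trials with sampled exclusion reasons are
#' appended so that filter accounting can be exercised.
#'
#' @param specs Tibble of per-species parameters, see
#'   [species_sim_specs()].
#' @param seed Integer seed; identical seeds give identical output.
#' @param exp_intercept_sd Sd (degrees) of the experiment-level random
#'   intercept, a component of `angle_sd_deg`.
#' @param n_discarded Number of additional discarded trials to append.
#' @param exclusion_probs Named probability vector over
#'   [exclusion_reasons()] used to sample reasons for discarded trials.
#' @return List of class `sim_study`: `experiments` (with usability
#'   flags), `landmarks` (long format, 2 replicates per frame), `truth`
#'   (true angle per frame and true species means), `specs`, `seed`.
#' @export
simulate_study <- function(specs = species_sim_specs(), seed,
                           exp_intercept_sd = 5,
                           n_discarded = 0L,
                           exclusion_probs = NULL) {
  stopifnot(is.data.frame(specs), !missing(seed))
  if (any(specs$copulation_sd_min < 0, na.rm = TRUE) ||
      any(specs$angle_sd_deg < 0) || any(specs$landmark_noise_px < 0)) {
    abort("sds and noise levels must be non-negative")
  }
  if (any(specs$angle_sd_deg < exp_intercept_sd)) {
    abort("exp_intercept_sd cannot exceed angle_sd_deg")
  }
  withr::with_seed(seed, {
    experiments <- purrr::pmap(specs, function(species_code, n_experiments,
                                               courtship_mean_min,
                                               courtship_sd_min,
                                               courtship_min_min,
                                               courtship_max_min,
                                               copulation_mean_min,
                                               copulation_sd_min,
                                               copulation_min_min,
                                               copulation_max_min, ...) {
      n <- n_experiments
      cop_min <- rtruncnorm1(n, copulation_mean_min, copulation_sd_min,
                             max(copulation_min_min, 0.25, na.rm = TRUE),
                             copulation_max_min)
      if (is.na(courtship_mean_min)) {
        court_min <- rep(NA_real_, n)
        court_start <- rep(NA_real_, n)
        cop_start <- runif(n, 60, 300)
      } else {
        court_min <- rtruncnorm1(n, courtship_mean_min, courtship_sd_min,
                                 max(courtship_min_min, 0, na.rm = TRUE),
                                 courtship_max_min)
        court_start <- runif(n, 0, 60)
        cop_start <- court_start + court_min * 60
      }
      tibble(
        experiment_id = sprintf("%s_%02d", species_code, seq_len(n)),
        species_code = species_code,
        courtship_start_s = court_start, copulation_start_s = cop_start,
        settling_s = cop_start + runif(n, 0, 0.2) * cop_min * 60,
        copulation_end_s = cop_start + cop_min * 60,
        exclusion_reasons = ""
      )
    }) |> bind_rows()

    params <- left_join(
      experiments,
      select(specs, "species_code", "copulation_mean_min", "angle_mean_deg",
             "angle_sd_deg", "landmark_noise_px"),
      by = "species_code"
    )
    params$b_i <- rnorm(nrow(params), 0, exp_intercept_sd)

    frames <- purrr::pmap(
      params[c("experiment_id", "settling_s", "copulation_end_s",
               "copulation_mean_min")],
      function(experiment_id, settling_s, copulation_end_s,
               copulation_mean_min) {
        sched <- sampling_schedule(settling_s, copulation_end_s,
                                   copulation_mean_min)
        sched$experiment_id <- experiment_id
        sched
      }) |> bind_rows()
    frames <- left_join(frames,
                        params[c("experiment_id", "species_code",
                                 "angle_mean_deg", "angle_sd_deg",
                                 "landmark_noise_px", "b_i")],
                        by = "experiment_id")
    nf <- nrow(frames)
    within_sd <- sqrt(frames$angle_sd_deg^2 - exp_intercept_sd^2)
    frames$true_angle_deg <- frames$angle_mean_deg + frames$b_i +
      rnorm(nf, 0, within_sd)
    truth <- tibble(
      experiment_id = frames$experiment_id,
      species_code = frames$species_code,
      timepoint_label = frames$label, time_s = frames$time_s,
      true_angle_deg = frames$true_angle_deg,
      true_species_mean_deg = frames$angle_mean_deg
    )

    # one random camera pose per frame, applied to the ideal triplet
    a <- frames$true_angle_deg * pi / 180
    ideal <- rbind(
      complex(real = 0, imaginary = 0),
      complex(real = 0, imaginary = 100),
      complex(real = 80 * sin(a), imaginary = 100 + 80 * cos(a))
    )  # 3 x nf (row recycling for P1, P2)
    pose_rot <- runif(nf, 0, 2 * pi)
    pose_scale <- runif(nf, 0.5, 2)
    pose_t <- complex(real = runif(nf, 200, 600),
                      imaginary = runif(nf, 150, 450))
    posed <- sweep(ideal, 2, pose_scale * exp(1i * pose_rot), `*`)
    posed <- sweep(posed, 2, pose_t, `+`)
    # long layout: frames x replicates x 3 landmarks
    idx <- rep(seq_len(nf), each = 6)
    lmk <- rep(rep(c("P1", "P2", "P3"), 2), times = nf)
    rep_id <- rep(rep(1:2, each = 3), times = nf)
    z <- as.vector(posed[rep(1:3, 2), , drop = FALSE])
    noise_sd <- frames$landmark_noise_px[idx]
    landmarks <- tibble(
      experiment_id = frames$experiment_id[idx], view = "top",
      timepoint_label = frames$label[idx], time_s = frames$time_s[idx],
      replicate_id = rep_id, landmark = lmk,
      x = Re(z) + rnorm(6 * nf, 0, noise_sd),
      y = Im(z) + rnorm(6 * nf, 0, noise_sd)
    )
    if (n_discarded > 0L) {
      experiments <- bind_rows(
        experiments,
        simulate_discarded(n_discarded, exclusion_probs)
      )
    }
    structure(list(experiments = derive_usability(experiments),
                   landmarks = bind_rows(landmarks),
                   truth = bind_rows(truth),
                   specs = specs, seed = seed),
              class = "sim_study")
  })
}

simulate_discarded <- function(n, exclusion_probs = NULL) {
  if (is.null(exclusion_probs)) {
    # relative frequencies of the discard categories in the video study
    exclusion_probs <- c(no_copulation_45min = 129,
                         incomplete_courtship_recording = 43,
                         leg_or_wing_damaged = 27,
                         incomplete_copulation_recording = 7,
                         camera_or_file_damaged = 4)
    exclusion_probs <- exclusion_probs / sum(exclusion_probs)
  }
  stopifnot(all(names(exclusion_probs) %in% exclusion_reasons()),
            sum(exclusion_probs) <= 1 + 1e-9)
  sp <- sample(species_codes()$species_code, n, replace = TRUE)
  tibble(
    experiment_id = sprintf("%s_x%03d", sp, seq_len(n)),
    species_code = sp,
    courtship_start_s = NA_real_, copulation_start_s = NA_real_,
    settling_s = NA_real_, copulation_end_s = NA_real_,
    exclusion_reasons = sample(names(exclusion_probs), n, replace = TRUE,
                               prob = exclusion_probs)
  )
}

#' Simulate frontal-view tilt recordings of *D. nannoptera*
#'
#' Generates frontal-perspective trials whose true tilt angle follows a
#' per-minute trajectory (default: [nannoptera_frontal_trajectory()]).
#' Each trial draws a copulation duration from the *D. nannoptera*
#' distribution and is measured at the midpoint of every elapsed minute
#' until copulation end; frames are emitted as frontal landmarks P4, P5,
#' P6 under random camera pose and landmark noise.
#'
#' @param trajectory Tibble `interval_min`, `mean_deg`, `sd_deg`.
#' @param n_experiments Number of trials.
#' @param seed Integer seed.
#' @param exp_intercept_sd Sd of the experiment-level random intercept
#'   (degrees), bounded above by each bin's sd.
#' @param landmark_noise_px Per-replicate landmark noise (pixels).
#' @return List of class `sim_frontal`: `experiments`, `landmarks`,
#'   `truth`, `seed`.
#' @export
simulate_frontal <- function(trajectory = nannoptera_frontal_trajectory(),
                             n_experiments = 29L, seed,
                             exp_intercept_sd = 5,
                             landmark_noise_px = 2) {
  stopifnot(!missing(seed), all(diff(trajectory$interval_min) > 0),
            all(trajectory$sd_deg >= 0))
  withr::with_seed(seed, {
    experiments <- list(); landmarks <- list(); truth <- list()
    for (i in seq_len(n_experiments)) {
      id <- sprintf("nanf_%02d", i)
      cop_min <- rtruncnorm1(1, 11.9, 4.2, 4.03, 20.1)
      cop_start <- runif(1, 60, 300)
      cop_end <- cop_start + cop_min * 60
      experiments[[id]] <- tibble(
        experiment_id = id, species_code = "nan",
        courtship_start_s = NA_real_, copulation_start_s = cop_start,
        settling_s = NA_real_, copulation_end_s = cop_end,
        exclusion_reasons = ""
      )
      b_i <- rnorm(1, 0, exp_intercept_sd)
      mins <- seq(0.5, cop_min, by = 1)
      for (t_min in mins) {
        bin <- trajectory[trajectory$interval_min == floor(t_min), ]
        if (!nrow(bin)) next
        within_sd <- sqrt(max(bin$sd_deg^2 - exp_intercept_sd^2, 1))
        true_angle <- bin$mean_deg + b_i + rnorm(1, 0, within_sd)
        t_s <- cop_start + t_min * 60
        pose <- random_pose()
        ideal <- pose(ideal_frontal_landmarks(true_angle))
        key <- paste(id, round(t_min, 2), sep = ".")
        truth[[key]] <- tibble(
          experiment_id = id, time_s = t_s,
          interval_min = floor(t_min),
          true_angle_deg = true_angle,
          true_bin_mean_deg = bin$mean_deg
        )
        noisy <- ideal + matrix(rnorm(6, 0, landmark_noise_px), ncol = 2)
        landmarks[[key]] <- tibble(
          experiment_id = id, view = "frontal",
          timepoint_label = paste0("clock", round(t_min, 2)),
          time_s = t_s, replicate_id = 1L,
          landmark = c("P4", "P5", "P6"),
          x = noisy[, 1], y = noisy[, 2]
        )
      }
    }
    structure(list(experiments = bind_rows(experiments),
                   landmarks = bind_rows(landmarks),
                   truth = bind_rows(truth), seed = seed),
              class = "sim_frontal")
  })
}

#' Default bilateral-structure simulation parameters
#'
#' Study conditions for the paired left/right length generator: the
#' *D. acanthoptera* ventral spur pair with a consistently longer right
#' spur (true normalized index -0.2, i.e. right about 20% longer than
#' left, n = 10) and symmetric structures with zero true index for
#' *D. nannoptera* apical elongations (n = 15), *D. machalilla* lateral
#' hooks (n = 10) and *D. bromeliae* lateral ridges (n = 10).
#'
#' @return Tibble with one row per species/structure.
#' @export
bilateral_sim_specs <- function() {
  tibble::tribble(
    ~species_code, ~structure, ~true_index, ~index_sd, ~n, ~base_um,
    "aca", "ventral_tip_spur",      -0.2, 0.05, 10L, 100,
    "nan", "apical_elongation",      0,   0.05, 15L, 80,
    "mac", "lateral_hook",           0,   0.05, 10L, 60,
    "bro", "lateral_ridge",          0,   0.05, 10L, 60
  )
}

#' Simulate paired left/right structure lengths
#'
#' Draws a per-specimen normalized asymmetry `d ~ Normal(true_index,
#' index_sd)` and a baseline size, and emits lengths
#' `L = base (1 + d/2)`, `R = base (1 - d/2)` so that the realized
#' normalized index `2 (L - R) / (L + R)` equals `d` exactly.
#'
#' @param specs Tibble as [bilateral_sim_specs()] (columns `species_code`,
#'   `structure`, `true_index`, `index_sd`, `n`, `base_um`).
#' @param seed Integer seed.
#' @param base_cv Coefficient of variation of the per-specimen baseline
#'   size.
#' @return List of class `sim_bilateral`: `records` (bilateral table) and
#'   `truth` (the specs).
#' @export
simulate_bilateral <- function(specs = bilateral_sim_specs(), seed,
                               base_cv = 0.05) {
  stopifnot(!missing(seed), all(specs$n >= 1))
  if (any(specs$index_sd < 0)) abort("index_sd must be non-negative")
  withr::with_seed(seed, {
    records <- purrr::pmap(specs, function(species_code, structure,
                                           true_index, index_sd, n,
                                           base_um, ...) {
      d <- rnorm(n, true_index, index_sd)
      base <- base_um * exp(rnorm(n, 0, base_cv))
      tibble(
        specimen_id = sprintf("%s_%s_%02d", species_code, structure,
                              seq_len(n)),
        species_code = species_code, structure = structure,
        left_um = base * (1 + d / 2), right_um = base * (1 - d / 2)
      )
    }) |> bind_rows()
    structure(list(records = records, truth = specs, seed = seed),
              class = "sim_bilateral")
  })
}
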