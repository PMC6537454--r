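#' Minimum mount duration that counts as a copulation
#'
#' A mounting event is scored as a copulation start only when the male
#' remains mounted for at least 15 seconds; shorter mounts are courtship
#' attempts, not copulations.
#'
#' @param mount_duration_s Non-negative mount duration(s) in seconds.
#' @return Logical vector, `TRUE` when the mount qualifies as copulation.
#' @export
#' @examples
#' is_valid_copulation(c(14.9, 15, 120))
is_valid_copulation <- function(mount_duration_s) {
  if (any(mount_duration_s < 0, na.rm = TRUE)) {
    abort("mount duration must be non-negative")
  }
  mount_duration_s >= 15
}

#' Courtship and copulation durations in minutes
#'
#' Courtship runs from courtship start to copulation start; copulation
#' from copulation start to the male's complete descent from the female
#' abdomen. Durations with a missing endpoint are reported missing, never
#' zero. Works row-wise on an experiment table.
#'
#' @param experiments Data frame with event columns `courtship_start_s`,
#'   `copulation_start_s`, `copulation_end_s` (seconds).
#' @return The input tibble with `courtship_min`, `copulation_min` and a
#'   logical `valid_copulation` column (15-second rule; `NA` when the
#'   duration is missing).
#' @export
durations <- function(experiments) {
  ex <- as_tibble(experiments)
  for (col in c("courtship_start_s", "copulation_start_s", "copulation_end_s")) {
    if (!col %in% names(ex)) ex[[col]] <- NA_real_
  }
  ex <- mutate(
    ex,
    courtship_min = (.data$copulation_start_s - .data$courtship_start_s) / 60,
    copulation_min = (.data$copulation_end_s - .data$copulation_start_s) / 60,
    valid_copulation = ifelse(is.na(.data$copulation_min), NA,
                              .data$copulation_min * 60 >= 15)
  )
  ex
}

#' Posture-measurement sampling schedule for one copulation
#'
#' Mating angles are measured at two cross-species comparable time points:
#' the settling time point (when the mounted male first adopts an
#' invariant position) and the 10% stable copulation time point (at 10% of
#' the elapsed time between settling and copulation end). For species
#' whose mean copulation exceeds 2.5, 15 or 60 minutes, an additional
#' periodic grid at 2.5, 5 or 10-minute steps (strict thresholds) is
#' anchored at the settling time point, running to copulation end; a grid
#' point within 1 s of the 10% point is dropped as a duplicate.
#'
#' @param settling_s,copulation_end_s Settling and copulation-end times in
#'   seconds; settling must precede copulation end.
#' @param species_mean_copulation_min Species mean copulation duration in
#'   minutes (computed over the trials retained for copulation duration).
#' @return Tibble with columns `label` (`settling`, `pct10`, `grid1`,
#'   `grid2`, ...) and `time_s`, strictly increasing.
#' @export
#' @examples
#' sampling_schedule(120, 720, species_mean_copulation_min = 11.9)
sampling_schedule <- function(settling_s, copulation_end_s,
                              species_mean_copulation_min) {
  stopifnot(length(settling_s) == 1L, length(copulation_end_s) == 1L)
  if (is.na(settling_s) || is.na(copulation_end_s)) {
    abort("settling and copulation end must both be present")
  }
  if (settling_s >= copulation_end_s) {
    abort("settling time must precede copulation end")
  }
  pct10 <- settling_s + 0.10 * (copulation_end_s - settling_s)
  step_min <- grid_step_min(species_mean_copulation_min)
  pts <- tibble(label = c("settling", "pct10"),
                time_s = c(settling_s, pct10))
  if (!is.na(step_min)) {
    step_s <- step_min * 60
    grid <- if (settling_s + step_s > copulation_end_s) numeric(0) else {
      seq(settling_s + step_s, copulation_end_s, by = step_s)
    }
    grid <- grid[abs(grid - pct10) > 1]
    if (length(grid)) {
      pts <- bind_rows(pts, tibble(label = paste0("grid", seq_along(grid)),
                                   time_s = grid))
    }
  }
  pts <- arrange(pts, .data$time_s)
  stopifnot(all(diff(pts$time_s) > 0),
            all(pts$time_s >= settling_s),
            all(pts$time_s <= copulation_end_s))
  pts
}

# periodic-grid step (minutes) by species mean copulation duration;
# NA means settling + 10% points only
grid_step_min <- function(species_mean_copulation_min) {
  m <- species_mean_copulation_min
  if (is.na(m)) return(NA_real_)
  if (m > 60) 10 else if (m > 15) 5 else if (m > 2.5) 2.5 else NA_real_
}

#' Snap schedule times to available frame times
#'
#' Maps each scheduled measurement time to the nearest available frame
#' time; ties break toward the earlier frame.
#'
#' @param schedule Tibble from [sampling_schedule()].
#' @param frame_times_s Sorted numeric vector of available frame times.
#' @return `schedule` with an extra `frame_time_s` column.
#' @export
snap_to_frames <- function(schedule, frame_times_s) {
  if (!length(frame_times_s)) abort("no frame times supplied")
  ft <- sort(frame_times_s)
  schedule$frame_time_s <- vapply(schedule$time_s, function(t) {
    d <- abs(ft - t)
    ft[which.min(d)]  # which.min takes the first (earlier) tie
  }, numeric(1))
  schedule
}
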