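#' Run the full posture/asymmetry analysis and write a report bundle
#'
#' Orchestrates the analysis stages on an experiment table, a landmark
#' table, a bilateral-length table and a character-on-cladogram input, and
#' writes the standard report files to `out_dir`:
#' `accounting.txt` (retained/discarded per reason for each endpoint),
#' `table1.csv` (per-species courtship/copulation duration summaries),
#' `anova.txt` (duration ANOVA), `tests.csv` (per-species directional
#' angle tests at each labelled time point), `table3.csv` (interval
#' summary of frontal angles, when frontal data are present),
#' `asymmetry_report.csv`, and `parsimony.txt`. Every file carries a
#' header comment stamped with the seed and package version. No statistic
#' is computed in this layer; each number comes from exactly one exported
#' stage function.
#'
#' @param experiments Experiment tibble (see [read_experiments()]).
#' @param landmarks Long-format landmark tibble, or `NULL` to skip angle
#'   stages.
#' @param bilateral Bilateral-length tibble, or `NULL` to skip.
#' @param tree An [ape::phylo] cladogram, or `NULL` to skip.
#' @param characters Leaf-state tibble (`leaf`, `character`, `state`), or
#'   `NULL` to skip.
#' @param out_dir Output directory (created if needed).
#' @param seed Seed stamp recorded in the outputs (the analysis itself is
#'   deterministic).
#' @param alpha Significance level for the asymmetry classifier.
#' @param bonferroni_m Family size for the angle tests.
#' @return Invisibly, a named list with every computed table.
#' @export
run_pipeline <- function(experiments, landmarks = NULL, bilateral = NULL,
                         tree = NULL, characters = NULL,
                         out_dir, seed = NA_integer_, alpha = 0.05,
                         bonferroni_m = 10L) {
  stopifnot(alpha > 0, alpha < 1)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- paste0("# seed: ", seed, "; matingasym ",
                  as.character(utils::packageVersion("matingasym")))
  results <- list()

  ex <- derive_usability(experiments)
  acc <- purrr::map(c(courtship = "courtship", copulation = "copulation",
                      posture = "posture"),
                    ~ accounting(ex, .x))
  results$accounting <- acc
  acc_lines <- purrr::imap(acc, function(tab, ep) {
    c(paste0("[", ep, "]"),
      sprintf("  %-35s %d", tab$category, tab$n))
  })
  writeLines(c(stamp, unlist(acc_lines)), file.path(out_dir, "accounting.txt"))

  dur <- durations(ex)
  results$table1 <- full_join(
    species_summary(filter(dur, .data$usable_courtship), "courtship_min") |>
      rename_with(~ paste0("courtship_", .x), -"species_code"),
    species_summary(filter(dur, .data$usable_copulation), "copulation_min") |>
      rename_with(~ paste0("copulation_", .x), -"species_code"),
    by = "species_code"
  )
  write_stamped_csv(results$table1, file.path(out_dir, "table1.csv"), stamp)

  dur_ok <- filter(dur, .data$usable_copulation, !is.na(.data$copulation_min))
  if (dplyr::n_distinct(dur_ok$species_code) >= 2L) {
    results$duration_anova <- one_way_anova(dur_ok, "copulation_min",
                                            "species_code")
    writeLines(c(stamp, utils::capture.output(print(
      as.data.frame(results$duration_anova)))),
      file.path(out_dir, "anova.txt"))
  }

  if (!is.null(landmarks)) {
    top <- filter(landmarks, .data$view == "top",
                  .data$experiment_id %in%
                    ex$experiment_id[ex$usable_posture])
    if (nrow(top)) {
      angles <- measure_angles(top)
      results$angles <- angles
      per_frame <- angles |>
        group_by(across(any_of(c("experiment_id", "species_code",
                                 "timepoint_label", "time_s")))) |>
        summarise(angle_deg = mean(.data$angle_deg), .groups = "drop")
      if (!"species_code" %in% names(per_frame)) {
        per_frame <- left_join(per_frame,
                               select(ex, "experiment_id", "species_code"),
                               by = "experiment_id")
      }
      results$tests <- per_frame |>
        filter(.data$timepoint_label %in% c("settling", "pct10")) |>
        group_by(.data$timepoint_label) |>
        group_modify(~ species_angle_test(.x, m = bonferroni_m,
                                          timepoint_label = .y$timepoint_label) |>
                       select(-"timepoint_label")) |>
        ungroup()
      write_stamped_csv(results$tests, file.path(out_dir, "tests.csv"), stamp)
    }
    frontal <- filter(landmarks, .data$view == "frontal")
    if (nrow(frontal)) {
      fa <- measure_angles(frontal) |>
        left_join(select(ex, "experiment_id", "copulation_start_s"),
                  by = "experiment_id")
      results$table3 <- interval_summary(fa)
      write_stamped_csv(results$table3, file.path(out_dir, "table3.csv"),
                        stamp)
    }
  }

  if (!is.null(bilateral)) {
    results$asymmetry <- asymmetry_report(bilateral, alpha = alpha)
    write_stamped_csv(results$asymmetry,
                      file.path(out_dir, "asymmetry_report.csv"), stamp)
  }

  if (!is.null(tree) && !is.null(characters)) {
    fits <- characters |>
      group_by(.data$character) |>
      group_map(~ fitch_min_changes(tree, .x, character_name = .y$character))
    results$parsimony <- fits
    writeLines(c(stamp, unlist(purrr::map(fits, ~ utils::capture.output(print(.x))))),
               file.path(out_dir, "parsimony.txt"))
  }

  invisible(results)
}

write_stamped_csv <- function(x, path, stamp) {
  writeLines(stamp, path)
  suppressWarnings(readr::write_csv(x, path, append = TRUE,
                                    col_names = TRUE, na = "NA"))
  invisible(path)
}
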