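#' Read a mating-experiment event table
#'
#' Reads a CSV of mating trials, one row per recorded couple. Required
#' columns: `experiment_id`, `species_code`. Optional columns:
#' `temperature_C`, the event times in seconds from recording start
#' (`courtship_start_s`, `copulation_start_s`, `settling_s`,
#' `copulation_end_s`; empty or `NA` cells stay missing, never zero) and
#' `exclusion_reasons` (`;`-separated labels from [exclusion_reasons()]).
#' Usability flags are derived on read.
#'
#' Species codes outside the closed ten-species set and event times that
#' violate the ordering courtship start <= copulation start <= settling <=
#' copulation end are rejected with the offending row numbers.
#'
#' @param path Path to a CSV file with a header row, `.` decimal separator
#'   and `NA` for missing values.
#' @return A tibble of experiments with usability flags.
#' @export
read_experiments <- function(path) {
  ex <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_guess()))
  required <- c("experiment_id", "species_code")
  missing_cols <- setdiff(required, names(ex))
  if (length(missing_cols)) {
    abort(paste0("missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  for (col in event_cols()) if (!col %in% names(ex)) ex[[col]] <- NA_real_
  ex <- mutate(ex, across(all_of(event_cols()), as.numeric))
  validate_experiments(ex)
  derive_usability(ex)
}

event_cols <- function() {
  c("courtship_start_s", "copulation_start_s", "settling_s",
    "copulation_end_s")
}

validate_experiments <- function(ex) {
  bad_sp <- which(!ex$species_code %in% species_codes()$species_code)
  if (length(bad_sp)) {
    abort(paste0("unknown species code(s) '",
                 paste(unique(ex$species_code[bad_sp]), collapse = "', '"),
                 "' in row(s): ", paste(bad_sp, collapse = ", ")))
  }
  if (anyDuplicated(ex$experiment_id)) {
    abort("duplicate experiment_id values")
  }
  ev <- event_cols()
  neg <- which(apply(ex[ev] < 0, 1, any, na.rm = TRUE))
  if (length(neg)) {
    abort(paste0("negative event time(s) in row(s): ",
                 paste(neg, collapse = ", ")))
  }
  for (i in seq_len(length(ev) - 1L)) {
    for (j in seq(i + 1L, length(ev))) {
      bad <- which(ex[[ev[i]]] > ex[[ev[j]]])
      if (length(bad)) {
        abort(paste0("event ordering violated (", ev[i], " > ", ev[j],
                     ") in row(s): ", paste(bad, collapse = ", ")))
      }
    }
  }
  invisible(ex)
}

#' Write a mating-experiment event table
#'
#' Inverse of [read_experiments()]: writes the parsed columns so that a
#' read/write round trip reproduces every field.
#'
#' @param experiments Experiment tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_experiments <- function(experiments, path) {
  keep <- intersect(c("experiment_id", "species_code", "temperature_C",
                      event_cols(), "exclusion_reasons"),
                    names(experiments))
  readr::write_csv(experiments[keep], path, na = "NA")
  invisible(path)
}

#' Read a landmark-coordinate table
#'
#' Reads a CSV of manually placed landmarks, one row per landmark per
#' extracted video frame. Columns: `experiment_id`, `view` (`top` or
#' `frontal`), `timepoint_label`, `time_s`, `replicate_id`, `landmark`
#' (`P1`..`P3` for the top view, `P4`..`P6` for the frontal view), `x`,
#' `y`. Coordinates are in pixels with the y axis pointing down (image
#' convention).
#'
#' @param path Path to a CSV file.
#' @return A tibble in long format, one row per landmark.
#' @export
read_landmarks <- function(path) {
  lm <- readr::read_csv(path, show_col_types = FALSE)
  needed <- c("experiment_id", "view", "replicate_id", "landmark", "x", "y")
  missing_cols <- setdiff(needed, names(lm))
  if (length(missing_cols)) {
    abort(paste0("missing landmark column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad_view <- which(!lm$view %in% c("top", "frontal"))
  if (length(bad_view)) {
    abort(paste0("view must be 'top' or 'frontal'; bad row(s): ",
                 paste(head(bad_view, 10), collapse = ", ")))
  }
  ok <- (lm$view == "top" & lm$landmark %in% c("P1", "P2", "P3")) |
    (lm$view == "frontal" & lm$landmark %in% c("P4", "P5", "P6"))
  if (any(!ok)) {
    abort(paste0("landmark labels must be P1-P3 (top) or P4-P6 (frontal); ",
                 "bad row(s): ", paste(head(which(!ok), 10), collapse = ", ")))
  }
  as_tibble(lm)
}

#' Read paired left/right structure lengths
#'
#' Reads a CSV of bilateral measurements, one row per specimen and
#' structure, with columns `specimen_id`, `species_code`, `structure`,
#' `left_um`, `right_um` (lengths in micrometers, strictly positive).
#'
#' @param path Path to a CSV file.
#' @return A tibble of bilateral records.
#' @export
read_bilateral <- function(path) {
  bl <- readr::read_csv(path, show_col_types = FALSE)
  needed <- c("specimen_id", "species_code", "structure", "left_um", "right_um")
  missing_cols <- setdiff(needed, names(bl))
  if (length(missing_cols)) {
    abort(paste0("missing bilateral column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad <- which(!(bl$left_um > 0 & bl$right_um > 0))
  if (length(bad)) {
    abort(paste0("non-positive length(s) in row(s): ",
                 paste(bad, collapse = ", ")))
  }
  as_tibble(bl)
}

#' Read a rooted cladogram from newick text
#'
#' Thin wrapper over [ape::read.tree()] that enforces the invariants the
#' parsimony machinery needs: a single rooted tree (polytomies allowed)
#' with unique leaf labels.
#'
#' @param source A newick string or the path to a newick file.
#' @return An [ape::phylo] object.
#' @export
read_cladogram <- function(source) {
  is_path <- length(source) == 1L && !grepl("\\(", source) && file.exists(source)
  tr <- if (is_path) ape::read.tree(source) else ape::read.tree(text = source)
  if (is.null(tr)) abort("could not parse newick input")
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1L) abort("expected exactly one tree")
    tr <- tr[[1]]
  }
  if (anyDuplicated(tr$tip.label)) abort("duplicate leaf labels in tree")
  tr
}

#' Read a leaf-character-state table
#'
#' Reads a CSV with columns `leaf`, `character`, `state`; the state `nd`
#' (not determined) marks missing data and imposes no constraint in
#' parsimony reconstruction.
#'
#' @param path Path to a CSV file.
#' @return A tibble with one row per leaf and character.
#' @export
read_characters <- function(path) {
  ch <- readr::read_csv(path, show_col_types = FALSE)
  missing_cols <- setdiff(c("leaf", "character", "state"), names(ch))
  if (length(missing_cols)) {
    abort(paste0("missing character column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  dup <- duplicated(ch[c("leaf", "character")])
  if (any(dup)) abort("duplicate (leaf, character) rows")
  as_tibble(ch)
}

#' Blind movie names with seven-digit codes
#'
#' Replaces each (distinct) movie name by a random seven-digit code so
#' that posture quantification can be performed blind to species identity.
#' Codes are drawn without replacement from 1000000..9999999, so they are
#' collision-free and always seven digits; the map is reproducible from
#' the seed.
#'
#' @param names Character vector of distinct original names.
#' @param seed Integer seed.
#' @return A tibble with columns `original` and `code` (character).
#' @export
#' @examples
#' blind_names(c("pac01_01", "nan02_07"), seed = 42)
blind_names <- function(names, seed) {
  if (anyDuplicated(names)) abort("input names must be distinct")
  n <- length(names)
  if (n == 0L) {
    return(tibble(original = character(0), code = character(0)))
  }
  if (n > 9e6) abort("more names than available seven-digit codes")
  codes <- withr::with_seed(seed, sample.int(9e6, n) + 999999L)
  tibble(original = as.character(names), code = sprintf("%07d", codes))
}
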