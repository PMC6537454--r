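#' Per-specimen bilateral asymmetry scores
#'
#' For each paired left/right length the signed difference
#' `diff_um = left - right` (micrometers) and the dimensionless normalized
#' asymmetry index `2 (L - R) / (L + R)` (range (-2, 2); positive when the
#' left side is longer). Swapping the left and right labels negates both
#' scores.
#'
#' @param records Data frame of bilateral records with columns `left_um`
#'   and `right_um` (strictly positive).
#' @return The input tibble with `diff_um` and `asym_index` columns added.
#' @export
#' @examples
#' asymmetry_scores(tibble::tibble(left_um = 110, right_um = 100))
asymmetry_scores <- function(records) {
  stopifnot(all(c("left_um", "right_um") %in% names(records)))
  bad <- which(!(records$left_um > 0 & records$right_um > 0))
  if (length(bad)) {
    abort(paste0("non-positive length(s) in row(s): ",
                 paste(bad, collapse = ", ")))
  }
  mutate(as_tibble(records),
         diff_um = .data$left_um - .data$right_um,
         asym_index = 2 * (.data$left_um - .data$right_um) /
           (.data$left_um + .data$right_um))
}

#' Directional versus fluctuating asymmetry test
#'
#' Classifies the left/right variation of one structure in one species as
#' directional asymmetry (a consistent side bias, e.g. "right spur
#' consistently longer") or fluctuating asymmetry (random, zero-mean
#' deviations). Two tests are combined conservatively: an exact two-sided
#' binomial sign test on the non-tied signs of `left - right` and a
#' two-sided one-sample t test of the signed differences against zero. A
#' directional verdict requires both tests below `alpha` and the majority
#' of non-tied signs to agree with the sign of the mean difference;
#' direction follows the longer side (`directional_left` when the left
#' side is longer on average). Fewer than five specimens is reported as
#' `insufficient` (the sign test cannot reach p < 0.05 below n = 6).
#'
#' Differences smaller than `tie_um` in magnitude (measurement resolution)
#' are treated as ties and excluded from the sign test.
#'
#' @param scores Data frame from [asymmetry_scores()] for a single
#'   species/structure: columns `diff_um` and `asym_index`.
#' @param alpha Significance level for the directional verdict.
#' @param tie_um Tie threshold in micrometers.
#' @return One-row tibble: `n`, `mean_diff_um`, `asym_index_mean`,
#'   `n_left_longer`, `n_right_longer`, `n_ties`, `p_sign`, `p_t`,
#'   `verdict`.
#' @export
directional_asymmetry_test <- function(scores, alpha = 0.05, tie_um = 0.5) {
  stopifnot(all(c("diff_um", "asym_index") %in% names(scores)),
            alpha > 0, alpha < 1)
  d <- scores$diff_um[!is.na(scores$diff_um)]
  n <- length(d)
  if (n < 1L) abort("need at least one specimen")
  nontied <- d[abs(d) >= tie_um]
  n_l <- sum(nontied > 0)
  n_r <- sum(nontied < 0)
  p_sign <- if (n_l + n_r > 0) {
    binom.test(n_l, n_l + n_r, p = 0.5)$p.value
  } else {
    NA_real_
  }
  p_t <- if (n >= 2L && sd(d) > 0) {
    t.test(d, mu = 0)$p.value
  } else if (n >= 2L && mean(d) != 0) {
    0  # constant nonzero differences: perfectly directional
  } else {
    NA_real_
  }
  mean_diff <- mean(d)
  majority_agrees <- (mean_diff > 0 && n_l > n_r) ||
    (mean_diff < 0 && n_r > n_l)
  directional <- isTRUE(p_sign < alpha) &&
    (isTRUE(p_t < alpha) || is.na(p_t)) && majority_agrees
  verdict <- if (n < 5L) {
    "insufficient"
  } else if (directional) {
    if (mean_diff > 0) "directional_left" else "directional_right"
  } else {
    "fluctuating_only"
  }
  tibble(n = n,
         mean_diff_um = mean_diff,
         asym_index_mean = mean(scores$asym_index, na.rm = TRUE),
         n_left_longer = n_l, n_right_longer = n_r,
         n_ties = n - n_l - n_r,
         p_sign = p_sign, p_t = p_t,
         verdict = verdict)
}

#' Asymmetry report across species and structures
#'
#' Runs [directional_asymmetry_test()] within every species-by-structure
#' group of a bilateral-length table.
#'
#' @param records Data frame of bilateral records (see [read_bilateral()]).
#' @inheritParams directional_asymmetry_test
#' @return Tibble with one row per species and structure.
#' @export
asymmetry_report <- function(records, alpha = 0.05, tie_um = 0.5) {
  scored <- asymmetry_scores(records)
  grp <- intersect(c("species_code", "structure"), names(scored))
  scored |>
    group_by(across(all_of(grp))) |>
    group_modify(~ directional_asymmetry_test(.x, alpha = alpha,
                                              tie_um = tie_um)) |>
    ungroup()
}
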