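#' Per-species directional test of the mean mating angle
#'
#' Fits a one-way gaussian linear model without intercept
#' (`angle ~ species - 1`) to signed angles pooled across species and
#' tests, for each species, the null hypothesis that its mean angle is
#' zero (a symmetric mating position). Each species estimate is its sample
#' mean; its standard error uses the pooled residual standard deviation;
#' the Wald statistic `z = estimate / se` is referred to the standard
#' normal, matching the usual GLM contrast machinery. Raw p-values are
#' Bonferroni-corrected for the family of `m` species tested.
#'
#' @param angles Data frame with columns `species_code` and `angle_deg`
#'   (one row per experiment at a fixed time point).
#' @param m Bonferroni family size (number of simultaneous species tests);
#'   must be given explicitly.
#' @param timepoint_label Optional label stored with the results.
#' @return A tibble of class `angle_test` with one row per species:
#'   `species_code`, `timepoint_label`, `n`, `estimate_deg`, `se`, `z`,
#'   `p_raw`, `p_bonf`. Attributes `sigma` (pooled residual sd),
#'   `df_residual` and `m`.
#' @export
species_angle_test <- function(angles, m, timepoint_label = NA_character_) {
  stopifnot(is.data.frame(angles),
            all(c("species_code", "angle_deg") %in% names(angles)))
  if (missing(m)) abort("Bonferroni family size m must be given explicitly")
  ang <- filter(as_tibble(angles), !is.na(.data$angle_deg))
  empty <- setdiff(unique(angles$species_code), unique(ang$species_code))
  if (length(empty)) {
    warn(paste0("species with no angle measurements omitted: ",
                paste(empty, collapse = ", ")))
  }
  k <- dplyr::n_distinct(ang$species_code)
  if (k < 2L) abort("need at least two species to pool residual variance")
  by_sp <- summarise(group_by(ang, .data$species_code),
                     n = dplyr::n(),
                     estimate_deg = mean(.data$angle_deg),
                     sse = sum((.data$angle_deg - mean(.data$angle_deg))^2),
                     .groups = "drop")
  df_res <- sum(by_sp$n) - k
  if (df_res < 1L) abort("no residual degrees of freedom")
  sigma <- sqrt(sum(by_sp$sse) / df_res)
  if (sigma == 0) abort("zero residual variance; test undefined")
  out <- mutate(by_sp,
                timepoint_label = timepoint_label,
                se = sigma / sqrt(.data$n),
                z = .data$estimate_deg / .data$se,
                p_raw = 2 * pnorm(-abs(.data$z)),
                p_bonf = bonferroni(.data$p_raw, m))
  out <- select(out, "species_code", "timepoint_label", "n",
                "estimate_deg", "se", "z", "p_raw", "p_bonf")
  structure(out, sigma = sigma, df_residual = df_res, m = m,
            class = c("angle_test", class(out)))
}

#' Bonferroni correction
#'
#' Multiplies a raw p-value by the family size and caps at 1.
#'
#' @param p_raw Raw p-value(s) in `[0, 1]`.
#' @param m Positive integer family size.
#' @return Corrected p-value(s) in `(0, 1]`.
#' @export
bonferroni <- function(p_raw, m) {
  stopifnot(length(m) == 1L, m >= 1)
  if (any(p_raw < 0 | p_raw > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]")
  }
  pmin(1, m * p_raw)
}

#' One-way ANOVA of a response across groups
#'
#' Standard fixed-effects one-way analysis of variance (via [stats::lm()]
#' and [stats::anova()]), e.g. of copulation durations across species.
#'
#' @param data Data frame.
#' @param value,group Column names (strings) of the response and the
#'   grouping factor.
#' @return A tibble of class `anova_tbl` with columns `term`, `df`,
#'   `sumsq`, `meansq`, `statistic`, `p.value` (residual row last). When
#'   the within-group variance is zero the F statistic is `Inf` (or `NaN`
#'   when all values are identical) and attribute `degenerate` is `TRUE`.
#' @export
one_way_anova <- function(data, value, group) {
  stopifnot(is.data.frame(data), value %in% names(data),
            group %in% names(data))
  d <- tibble(y = as.numeric(data[[value]]),
              g = factor(data[[group]]))
  d <- filter(d, !is.na(.data$y))
  k <- nlevels(droplevels(d$g))
  if (k < 2L) abort("need at least two groups")
  if (nrow(d) <= k) abort("need more observations than groups")
  fit <- lm(y ~ g, data = d)
  # degenerate (perfect) fits are detected and flagged below
  tab <- anova_to_tibble(suppressWarnings(anova(fit)), terms = group)
  # relative zero guards against floating-point residual sums of squares
  total_ss <- sum(tab$sumsq)
  degenerate <- tab$sumsq[nrow(tab)] <= 1e-12 * max(total_ss, .Machine$double.xmin)
  if (degenerate) {
    ss_b <- tab$sumsq[1]
    tab$statistic[1] <- if (ss_b > 0) Inf else NaN
    tab$p.value[1] <- if (ss_b > 0) 0 else NaN
    warn("zero within-group variance; F flagged degenerate")
  }
  structure(tab, degenerate = degenerate,
            class = c("anova_tbl", class(tab)))
}

#' Repeatability ANOVA of duplicate landmark measurements
#'
#' Assesses repeatability of landmark placement from two (or more)
#' independent acquisition rounds of the same images with the additive
#' two-factor fixed-effects model `angle ~ image + replicate`, testing
#' each factor against the residual. Landmark placement is repeatable
#' when variation is attributable to images, not to acquisition rounds;
#' the verdict is "replicate effect negligible" when the replicate factor
#' has p > 0.05. The layout must be complete: every image measured under
#' every replicate exactly once.
#'
#' @param angles Data frame with columns `image_id`, `replicate_id`,
#'   `angle_deg`.
#' @return A tibble of class `anova_tbl` (terms `image`, `replicate`,
#'   `Residuals`) with attribute `verdict`.
#' @export
repeatability_anova <- function(angles) {
  stopifnot(all(c("image_id", "replicate_id", "angle_deg") %in% names(angles)))
  d <- tibble(y = as.numeric(angles$angle_deg),
              image = factor(angles$image_id),
              replicate = factor(angles$replicate_id))
  counts <- count(d, .data$image, .data$replicate)
  if (any(counts$n != 1L) ||
      nrow(counts) != nlevels(d$image) * nlevels(d$replicate)) {
    full <- tidyr::expand_grid(image = levels(d$image),
                               replicate = levels(d$replicate))
    miss <- anti_join(full,
                      mutate(counts, image = as.character(.data$image),
                             replicate = as.character(.data$replicate)),
                      by = c("image", "replicate"))
    bad <- unique(c(miss$image, counts$image[counts$n > 1L]))
    abort(paste0("incomplete or duplicated two-way layout; image id(s): ",
                 paste(head(as.character(bad), 10), collapse = ", ")))
  }
  fit <- lm(y ~ image + replicate, data = d)
  tab <- anova_to_tibble(suppressWarnings(anova(fit)),
                         terms = c("image", "replicate"))
  # a factor explaining (relatively) zero variation gets F = 0 exactly,
  # even when the residual sum of squares is itself numerically zero
  null_term <- tab$sumsq <= 1e-12 * max(sum(tab$sumsq), .Machine$double.xmin)
  null_term[tab$term == "Residuals"] <- FALSE
  tab$statistic[null_term] <- 0
  tab$p.value[null_term] <- 1
  verdict <- if (tab$p.value[tab$term == "replicate"] > 0.05) {
    "replicate effect negligible"
  } else {
    "replicate effect detected"
  }
  structure(tab, verdict = verdict, class = c("anova_tbl", class(tab)))
}

anova_to_tibble <- function(a, terms) {
  tab <- as_tibble(as.data.frame(a), rownames = "term")
  names(tab) <- c("term", "df", "sumsq", "meansq", "statistic", "p.value")
  tab$term <- c(terms, "Residuals")
  tab
}

#' Interval summary of frontal tilt angles over copulation
#'
#' Bins frontal-view angle measurements into one-minute intervals after
#' copulation start. Within each experiment, multiple measurements falling
#' in the same bin are first averaged; the reported mean and sd for a bin
#' are then taken across experiments, with `n` the number of experiments
#' contributing. The sd is reported missing when a single experiment
#' contributes.
#'
#' @param angles Data frame with columns `experiment_id`, `time_s`,
#'   `copulation_start_s` and `angle_deg`.
#' @return Tibble with `interval_min` (bin start, minutes after copulation
#'   start), `interval` (label like `"0-1"`), `mean_deg`, `sd_deg`, `n`.
#' @export
interval_summary <- function(angles) {
  needed <- c("experiment_id", "time_s", "copulation_start_s", "angle_deg")
  stopifnot(all(needed %in% names(angles)))
  d <- as_tibble(angles)
  rel <- (d$time_s - d$copulation_start_s) / 60
  if (any(rel < 0, na.rm = TRUE)) {
    abort(paste0("measurement(s) before copulation start in row(s): ",
                 paste(head(which(rel < 0), 10), collapse = ", ")))
  }
  d$interval_min <- floor(rel)
  per_exp <- summarise(group_by(d, .data$experiment_id, .data$interval_min),
                       angle_deg = mean(.data$angle_deg), .groups = "drop")
  out <- summarise(group_by(per_exp, .data$interval_min),
                   mean_deg = mean(.data$angle_deg),
                   sd_deg = if (dplyr::n() > 1L) sd(.data$angle_deg)
                            else NA_real_,
                   n = dplyr::n(),
                   .groups = "drop")
  out <- arrange(out, .data$interval_min)
  mutate(out,
         interval = paste0(.data$interval_min, "-", .data$interval_min + 1),
         .after = "interval_min")
}

#' Per-species duration summary
#'
#' Sample mean, sample standard deviation (n - 1 denominator), range and
#' count of a duration (or any value) per species — the building block of
#' courtship/copulation summary tables.
#'
#' @param data Data frame with a `species_code` column.
#' @param value Column name (string) of the value to summarise.
#' @return Tibble with `species_code`, `mean`, `sd`, `min`, `max`, `n`.
#' @export
species_summary <- function(data, value) {
  stopifnot("species_code" %in% names(data), value %in% names(data))
  d <- tibble(species_code = data$species_code,
              y = as.numeric(data[[value]]))
  d <- filter(d, !is.na(.data$y))
  if (nrow(d) == 0L) {
    return(tibble(species_code = character(0), mean = numeric(0),
                  sd = numeric(0), min = numeric(0), max = numeric(0),
                  n = integer(0)))
  }
  summarise(group_by(d, .data$species_code),
            mean = mean(.data$y),
            sd = if (dplyr::n() > 1L) sd(.data$y) else NA_real_,
            min = min(.data$y),
            max = max(.data$y),
            n = dplyr::n(),
            .groups = "drop")
}
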