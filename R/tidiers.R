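#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a per-species angle test
#'
#' @param x An `angle_test` object from [species_angle_test()].
#' @param ... Unused.
#' @return A plain tibble of the per-species rows.
#' @export
tidy.angle_test <- function(x, ...) {
  as_tibble(unclass(x)[names(x)])
}

#' One-row summary of a per-species angle test
#'
#' @param x An `angle_test` object.
#' @param ... Unused.
#' @return Tibble with `sigma` (pooled residual sd, degrees),
#'   `df.residual`, `n.species`, `n.obs`, `m` (Bonferroni family size).
#' @export
glance.angle_test <- function(x, ...) {
  tibble(sigma = attr(x, "sigma"),
         df.residual = attr(x, "df_residual"),
         n.species = nrow(x),
         n.obs = sum(x$n),
         m = attr(x, "m"))
}

#' Tidy an ANOVA table
#'
#' @param x An `anova_tbl` object from [one_way_anova()] or
#'   [repeatability_anova()].
#' @param ... Unused.
#' @return A plain tibble of terms.
#' @export
tidy.anova_tbl <- function(x, ...) {
  as_tibble(unclass(x)[names(x)])
}

#' One-row summary of an ANOVA table
#'
#' @param x An `anova_tbl` object.
#' @param ... Unused.
#' @return Tibble with the leading term's `statistic`, `df1`, `df2` and
#'   `p.value`, plus `verdict` where one was attached.
#' @export
glance.anova_tbl <- function(x, ...) {
  res <- x$df[x$term == "Residuals"]
  tibble(statistic = x$statistic[1],
         df1 = x$df[1],
         df2 = res,
         p.value = x$p.value[1],
         verdict = attr(x, "verdict") %||% NA_character_)
}

#' Tidy a parsimony reconstruction
#'
#' @param x A `parsimony_fit` from [fitch_min_changes()].
#' @param ... Unused.
#' @return The node-by-node labeling tibble.
#' @export
tidy.parsimony_fit <- function(x, ...) {
  x$labeling
}

#' One-row summary of a parsimony reconstruction
#'
#' @param x A `parsimony_fit`.
#' @param ... Unused.
#' @return Tibble with `character_name`, `min_changes`, `n_leaves`,
#'   `n_root_states`.
#' @export
glance.parsimony_fit <- function(x, ...) {
  tibble(character_name = x$character_name,
         min_changes = x$min_changes,
         n_leaves = length(x$tree$tip.label),
         n_root_states = length(x$root_states))
}
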