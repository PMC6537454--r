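test_that("species angle test equals the GLM contrast machinery", {
  skip_if_not_installed("multcomp")
  set.seed(3)
  ang <- tibble::tibble(
    species_code = rep(c("nan", "pac", "mel", "bro"), times = c(8, 6, 10, 5)),
    angle_deg = rnorm(29, rep(c(30, 20, 0, -2), times = c(8, 6, 10, 5)), 10)
  )
  res <- species_angle_test(ang, m = 4)

  fit <- stats::glm(angle_deg ~ species_code - 1, family = gaussian(),
                    data = ang)
  gl <- summary(multcomp::glht(fit, linfct = diag(4)),
                test = multcomp::adjusted("none"))
  ord <- order(sub("species_code", "", names(coef(fit))))
  expect_equal(res$estimate_deg, unname(coef(fit))[ord], tolerance = 1e-10)
  expect_equal(res$z, unname(gl$test$tstat)[ord], tolerance = 1e-8)
  expect_equal(res$p_raw, unname(gl$test$pvalues)[ord], tolerance = 1e-8)
  expect_equal(res$p_bonf, pmin(1, 4 * res$p_raw))
})

test_that("species angle test estimates, symmetry and edge cases", {
  set.seed(4)
  ang <- tibble::tibble(
    species_code = rep(c("a", "b"), each = 6),
    angle_deg = c(rep(12.5, 6), rnorm(6, 0, 5))
  )
  res <- species_angle_test(ang, m = 2)
  # constant species: estimate equals that constant
  expect_equal(res$estimate_deg[res$species_code == "a"], 12.5)

  # negating every angle negates estimates, keeps |z| and p
  res_neg <- species_angle_test(dplyr::mutate(ang, angle_deg = -angle_deg),
                                m = 2)
  expect_equal(res_neg$estimate_deg, -res$estimate_deg)
  expect_equal(abs(res_neg$z), abs(res$z))
  expect_equal(res_neg$p_raw, res$p_raw)

  expect_error(species_angle_test(ang[1:6, ], m = 2), "two species")
  expect_error(
    species_angle_test(tibble::tibble(species_code = c("a", "a", "b", "b"),
                                      angle_deg = c(1, 1, 2, 2)), m = 2),
    "zero residual variance")
  expect_warning(
    species_angle_test(tibble::tibble(
      species_code = c("a", "a", "b", "b", "c"),
      angle_deg = c(1, 2, 3, 5, NA)), m = 3),
    "omitted")

  g <- glance(res)
  expect_equal(g$df.residual, 10)
  expect_equal(g$m, 2)
})

test_that("bonferroni caps at one and preserves order", {
  expect_equal(bonferroni(0.2, 10), 1)
  expect_equal(bonferroni(0.004, 10), 0.04)
  p <- sort(runif(20))
  expect_true(all(diff(bonferroni(p, 7)) >= 0))   # monotone
  expect_true(all(bonferroni(p, 7) >= p))         # never decreases
  expect_error(bonferroni(1.2, 3), "\\[0, 1\\]")
})

test_that("one-way ANOVA matches a permutation oracle and decomposes SS", {
  set.seed(5)
  d <- tibble::tibble(g = rep(letters[1:3], each = 6),
                      y = rnorm(18, rep(c(0, 1, 0.5), each = 6)))
  tab <- one_way_anova(d, "y", "g")
  expect_equal(tab$df, c(2, 15))
  # SS decomposition against the total
  expect_equal(sum(tab$sumsq), sum((d$y - mean(d$y))^2), tolerance = 1e-8)
  # F invariant under adding a constant
  tab2 <- one_way_anova(dplyr::mutate(d, y = y + 100), "y", "g")
  expect_equal(tab2$statistic[1], tab$statistic[1], tolerance = 1e-8)

  # permutation oracle for the p-value
  f_obs <- tab$statistic[1]
  perm <- replicate(4000, {
    one_way_anova(dplyr::mutate(d, y = sample(y)), "y", "g")$statistic[1]
  })
  p_perm <- mean(perm >= f_obs)
  expect_lt(abs(p_perm - tab$p.value[1]),
            3 * sqrt(p_perm * (1 - p_perm) / 4000) + 0.01)

  # degenerate: zero within-group variance
  expect_warning(
    tab3 <- one_way_anova(tibble::tibble(g = c("a", "a", "b", "b"),
                                         y = c(0, 0, 1, 1)), "y", "g"),
    "degenerate")
  expect_equal(tab3$statistic[1], Inf)
  expect_true(attr(tab3, "degenerate"))
})

test_that("repeatability ANOVA partitions image and replicate effects", {
  set.seed(6)
  n_img <- 40
  img_effect <- rnorm(n_img, 0, 10)
  d <- tidyr::expand_grid(image_id = sprintf("i%02d", 1:n_img),
                          replicate_id = 1:2)
  d$angle_deg <- img_effect[as.integer(factor(d$image_id))] + rnorm(nrow(d), 0, 1)
  tab <- repeatability_anova(d)
  expect_equal(tab$df, c(n_img - 1, 1, n_img - 1))
  expect_gt(tab$statistic[tab$term == "image"],
            tab$statistic[tab$term == "replicate"])
  expect_equal(attr(tab, "verdict"), "replicate effect negligible")

  # replicate 2 identical to replicate 1: replicate SS and F exactly 0
  d2 <- d
  d2$angle_deg[d2$replicate_id == 2] <- d2$angle_deg[d2$replicate_id == 1]
  tab2 <- repeatability_anova(d2)
  expect_equal(tab2$sumsq[tab2$term == "replicate"], 0, tolerance = 1e-20)
  expect_equal(tab2$statistic[tab2$term == "replicate"], 0, tolerance = 1e-10)

  # incomplete layout rejected with the offending image id
  expect_error(repeatability_anova(d[-1, ]), "incomplete.*i01")

  # image variance dominates replicate shifts across simulated layouts
  wins <- 0
  for (s in 1:100) {
    set.seed(s)
    eff <- rnorm(30, 0, 10)
    dd <- tidyr::expand_grid(image_id = sprintf("i%02d", 1:30),
                             replicate_id = 1:2)
    dd$angle_deg <- eff[as.integer(factor(dd$image_id))] +
      rnorm(nrow(dd), 0, 1)
    tt <- repeatability_anova(dd)
    wins <- wins + (tt$statistic[1] > tt$statistic[2])
  }
  expect_gte(wins, 99)
})

test_that("interval summary averages within experiments first", {
  ang <- tibble::tibble(
    experiment_id = c("e1", "e1", "e2"),
    time_s = c(110, 140, 130),
    copulation_start_s = 100,
    angle_deg = c(10, 14, 12)
  )
  out <- interval_summary(ang)
  expect_equal(out$mean_deg, 12)    # (mean(10,14), 12) -> 12
  expect_equal(out$n, 2)
  expect_equal(out$interval, "0-1")

  # single contributing experiment: sd reported missing
  one <- interval_summary(tibble::tibble(
    experiment_id = "e1", time_s = 160, copulation_start_s = 100,
    angle_deg = 8.07))
  expect_true(is.na(one$sd_deg))
  expect_equal(one$n, 1)

  expect_error(interval_summary(tibble::tibble(
    experiment_id = "e1", time_s = 90, copulation_start_s = 100,
    angle_deg = 5)), "before copulation start")
})

test_that("species summaries use the n-1 sd and true ranges", {
  d <- tibble::tibble(species_code = "nan", v = c(1, 2, 3))
  s <- species_summary(d, "v")
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)
  expect_equal(c(s$min, s$max), c(1, 3))
  expect_equal(s$n, 3)
})
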