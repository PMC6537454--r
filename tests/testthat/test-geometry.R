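test_that("signed angles match closed-form arctangent values", {
  # collinear: male directly behind the female
  expect_equal(signed_angle_top(c(0, 0), c(0, 1), c(0, 2)), 0)
  # male displaced to the female's right by atan(0.1/1)
  expect_equal(signed_angle_top(c(0, 0), c(0, 1), c(0.1, 2)),
               atan(0.1 / 1) * 180 / pi, tolerance = 1e-9)
  expect_equal(signed_angle_top(c(0, 0), c(0, 1), c(0.1, 2)), 5.7106,
               tolerance = 1e-4)

  # frontal: male on the female dorso-ventral axis
  expect_equal(signed_angle_frontal(c(0, -1), c(0, 0), c(0, -2)), 0)
  # tilt toward the female's right (viewer's left) by atan(0.1/2)
  expect_equal(signed_angle_frontal(c(0, -1), c(0, 0), c(-0.1, -2)),
               atan(0.1 / 2) * 180 / pi, tolerance = 1e-9)
  expect_equal(signed_angle_frontal(c(0, -1), c(0, 0), c(-0.1, -2)),
               2.8624, tolerance = 1e-4)

  expect_error(signed_angle_top(c(0, 0), c(0, 0), c(1, 1)), "coincident")
  expect_error(signed_angle_frontal(c(0, 1), c(0, 0), c(0, 0)), "coincident")
})

test_that("angles are similarity-invariant and mirror-antisymmetric", {
  set.seed(42)
  for (i in 1:300) {
    p1 <- runif(2, -10, 10); p2 <- runif(2, -10, 10); p3 <- runif(2, -10, 10)
    if (sum((p2 - p1)^2) < 1e-6 || sum((p3 - p2)^2) < 1e-6 ||
        sum((p3 - p1)^2) < 1e-6) next
    a_top <- signed_angle_top(p1, p2, p3)
    a_fro <- signed_angle_frontal(p1, p2, p3)
    expect_true(a_top > -180 && a_top <= 180)

    tf <- random_similarity()
    expect_equal(signed_angle_top(tf(p1), tf(p2), tf(p3)), a_top,
                 tolerance = 1e-9)
    expect_equal(signed_angle_frontal(tf(p1), tf(p2), tf(p3)), a_fro,
                 tolerance = 1e-9)

    # reflection across the y axis flips the sign, keeps the magnitude
    rx <- function(p) c(-p[1], p[2])
    expect_equal(signed_angle_top(rx(p1), rx(p2), rx(p3)), -a_top,
                 tolerance = 1e-9)
    expect_equal(signed_angle_frontal(rx(p1), rx(p2), rx(p3)), -a_fro,
                 tolerance = 1e-9)
  }
})

test_that("two-point registration fixes the baseline and keeps angles", {
  lm1 <- tibble::tibble(experiment_id = "a", replicate_id = 1L,
                        landmark = c("P1", "P2", "P3"),
                        x = c(3, 3, 3.2), y = c(4, 6, 8))
  reg <- bookstein_register(lm1)
  expect_equal(reg$x, c(0, 0, 0.1), tolerance = 1e-12)
  expect_equal(reg$y, c(0, 1, 2), tolerance = 1e-12)
  # idempotence on already-registered input
  expect_equal(bookstein_register(reg)[c("x", "y")], reg[c("x", "y")],
               tolerance = 1e-12)

  # 124 random-pose frames: all baselines land on (0,0)-(0,1) exactly
  set.seed(9)
  frames <- purrr::map(1:124, function(i) {
    ang <- runif(1, -60, 60)
    tf <- random_similarity()
    ideal <- 100 * rbind(c(0, 0), c(0, 1), c(sin(ang * pi / 180),
                                             1 + cos(ang * pi / 180)))
    posed <- t(apply(ideal, 1, tf))
    tibble::tibble(experiment_id = sprintf("e%03d", i), replicate_id = 1L,
                   landmark = c("P1", "P2", "P3"),
                   x = posed[, 1], y = posed[, 2], true_angle = ang)
  }) |> dplyr::bind_rows()
  reg2 <- bookstein_register(frames)
  p1 <- dplyr::filter(reg2, landmark == "P1")
  p2 <- dplyr::filter(reg2, landmark == "P2")
  expect_true(all(abs(c(p1$x, p1$y)) < 1e-9))
  expect_true(all(abs(p2$x) < 1e-9) && all(abs(p2$y - 1) < 1e-9))

  # angle measured before and after registration is identical
  a_before <- measure_angles(dplyr::mutate(frames, view = "top"))
  a_after <- measure_angles(dplyr::mutate(reg2, view = "top"))
  expect_equal(a_after$angle_deg, a_before$angle_deg, tolerance = 1e-9)
  expect_equal(a_before$angle_deg, a_before$true_angle, tolerance = 1e-9)

  expect_error(
    bookstein_register(tibble::tibble(
      experiment_id = "bad", replicate_id = 1L,
      landmark = c("P1", "P2", "P3"),
      x = c(0, 0.5, 3), y = c(0, 0, 4))),
    "degenerate.*bad")
})
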