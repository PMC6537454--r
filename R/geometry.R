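#' Signed top-view mating angle from landmarks P1, P2, P3
#'
#' Computes the signed deviation of the male from the female midline in a
#' dorsal (top) view, from three landmarks: the anterior tip of the female
#' head along its midline (P1), the distal tip of the female scutellum
#' (P2) and the most posterior medial point of the male head (P3). With
#' `u = P2 - P1` (female head to scutellum) and `v = P3 - P2`, the angle
#' is the deviation of `v` from the posterior extension of the female
#' midline, so a male sitting directly behind the female scores 0. Under
#' the y-down pixel convention the sign is chosen so that positive means
#' the male head lies on the female's right and negative on her left.
#'
#' Coordinates may be given as length-2 vectors (one triplet) or as
#' two-column matrices (vectorised over rows).
#'
#' @param p1,p2,p3 Landmark coordinates in pixels, y axis pointing down.
#' @return Signed angle(s) in degrees, in (-180, 180].
#' @export
#' @examples
#' signed_angle_top(c(0, 0), c(0, 1), c(0.1, 2))  # male slightly right
signed_angle_top <- function(p1, p2, p3) {
  signed_deviation_deg(as_xy(p1), as_xy(p2), as_xy(p3), origin = "mid")
}

#' Signed frontal tilt angle from landmarks P4, P5, P6
#'
#' Computes the inclination of the male body relative to the female
#' dorso-ventral axis in a frontal view, from three landmarks: the medial
#' most dorsal edge of the female head (P4), the most ventral medial
#' position of the female head, i.e. the proboscis (P5), and the medial
#' most dorsal edge of the male head (P6). With `u = P4 - P5` (female
#' ventral-to-dorsal axis) and `v = P6 - P5`, the angle is the signed
#' deviation of `v` from `u`. Because the female faces the camera, her
#' right is the viewer's left; the sign is chosen so that positive still
#' means a tilt toward the female's right.
#'
#' @param p4,p5,p6 Landmark coordinates in pixels, y axis pointing down.
#' @return Signed angle(s) in degrees, in (-180, 180].
#' @export
#' @examples
#' signed_angle_frontal(c(0, -1), c(0, 0), c(-0.1, -2))  # tilt to her right
signed_angle_frontal <- function(p4, p5, p6) {
  signed_deviation_deg(as_xy(p5), as_xy(p4), as_xy(p6), origin = "first")
}

as_xy <- function(p) {
  if (is.null(dim(p))) {
    stopifnot(length(p) == 2L)
    matrix(as.numeric(p), ncol = 2L)
  } else {
    stopifnot(ncol(p) == 2L)
    matrix(as.numeric(as.matrix(p)), ncol = 2L)
  }
}

# signed angle (deg) of v relative to the reference direction u in y-down
# pixel coordinates; see callers for the anatomical reading of the sign.
# origin = "mid": u = b - a, v = c - b (top view, P1 P2 P3)
# origin = "first": u = b - a, v = c - a (frontal view, a = P5)
signed_deviation_deg <- function(a, b, c, origin = c("mid", "first")) {
  origin <- match.arg(origin)
  u <- b - a
  v <- if (origin == "mid") c - b else c - a
  if (any(rowSums(u^2) == 0) || any(rowSums(v^2) == 0)) {
    abort("coincident landmarks: baseline or target vector has zero length")
  }
  cross <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  dot <- u[, 1] * v[, 1] + u[, 2] * v[, 2]
  ang <- -atan2(cross, dot) * 180 / pi
  # atan2 negation can land exactly on -180; fold into (-180, 180]
  ang[ang <= -180] <- ang[ang <= -180] + 360
  ang
}

#' Two-point (Bookstein) registration of top-view landmark frames
#'
#' Maps every frame's landmarks by the unique orientation-preserving
#' similarity transform (translation, rotation, uniform positive scaling;
#' never a reflection) that sends P1 to (0, 0) and P2 to (0, 1). After
#' registration the male-head landmarks P3 of all frames can be overlaid
#' in a common female-centred coordinate system. Signed angles are
#' invariant under this transform.
#'
#' @param landmarks Long-format landmark tibble (see [read_landmarks()])
#'   restricted to the top view: columns `experiment_id`, `replicate_id`,
#'   `landmark` (`P1`, `P2`, `P3`), `x`, `y`, plus any frame identifiers
#'   (e.g. `timepoint_label`, `time_s`).
#' @param min_baseline_px Frames whose P1-P2 baseline is shorter than this
#'   (pixels) are rejected as degenerate rather than registered.
#' @return A tibble of the same shape with `x`, `y` replaced by registered
#'   coordinates.
#' @export
bookstein_register <- function(landmarks, min_baseline_px = 1) {
  lm <- as_tibble(landmarks)
  needed <- c("experiment_id", "replicate_id", "landmark", "x", "y")
  stopifnot(all(needed %in% names(lm)))
  if (!all(lm$landmark %in% c("P1", "P2", "P3"))) {
    abort("bookstein_register expects top-view landmarks P1, P2, P3")
  }
  keys <- setdiff(names(lm), c("landmark", "x", "y"))
  wide <- tidyr::pivot_wider(lm, names_from = "landmark",
                             values_from = c("x", "y"))
  if (anyNA(wide[c("x_P1", "y_P1", "x_P2", "y_P2")])) {
    abort("every frame needs both P1 and P2")
  }
  z  <- function(x, y) complex(real = x, imaginary = y)
  p1 <- z(wide$x_P1, wide$y_P1)
  p2 <- z(wide$x_P2, wide$y_P2)
  base <- p2 - p1
  short <- Mod(base) < min_baseline_px
  if (any(short)) {
    ids <- do.call(paste, c(wide[short, intersect(keys, names(wide))],
                            sep = "/"))
    abort(paste0("degenerate P1-P2 baseline (< ", min_baseline_px,
                 " px) in frame(s): ", paste(head(ids, 10), collapse = ", ")))
  }
  # z -> i (z - p1) / (p2 - p1): orientation-preserving similarity with
  # P1 -> 0, P2 -> i, i.e. (0, 1) in (x, y)
  reg <- function(p) 1i * (z(wide[[paste0("x_", p)]],
                             wide[[paste0("y_", p)]]) - p1) / base
  for (p in c("P1", "P2", "P3")) {
    w <- reg(p)
    wide[[paste0("x_", p)]] <- Re(w)
    wide[[paste0("y_", p)]] <- Im(w)
  }
  out <- tidyr::pivot_longer(wide, cols = tidyr::matches("^[xy]_P[123]$"),
                             names_to = c(".value", "landmark"),
                             names_sep = "_")
  out[!is.na(out$x) & !is.na(out$y), c(keys, "landmark", "x", "y")]
}

#' Measure signed mating angles from a landmark table
#'
#' Computes one signed angle per frame and replicate from a long-format
#' landmark table: the top-view angle from P1, P2, P3 and/or the frontal
#' tilt angle from P4, P5, P6 (see [signed_angle_top()],
#' [signed_angle_frontal()]).
#'
#' @param landmarks Long-format landmark tibble (see [read_landmarks()]).
#' @return Tibble with one row per frame and replicate: the frame key
#'   columns, `view` and `angle_deg`.
#' @export
measure_angles <- function(landmarks) {
  lm <- as_tibble(landmarks)
  stopifnot(all(c("view", "landmark", "x", "y") %in% names(lm)))
  keys <- setdiff(names(lm), c("landmark", "x", "y"))
  wide <- tidyr::pivot_wider(lm, names_from = "landmark",
                             values_from = c("x", "y"))
  pt <- function(p) {
    cbind(wide[[paste0("x_", p)]], wide[[paste0("y_", p)]])
  }
  ang <- rep(NA_real_, nrow(wide))
  top <- wide$view == "top"
  if (any(top)) {
    ang[top] <- signed_angle_top(pt("P1")[top, , drop = FALSE],
                                 pt("P2")[top, , drop = FALSE],
                                 pt("P3")[top, , drop = FALSE])
  }
  if (any(!top)) {
    ang[!top] <- signed_angle_frontal(pt("P4")[!top, , drop = FALSE],
                                      pt("P5")[!top, , drop = FALSE],
                                      pt("P6")[!top, , drop = FALSE])
  }
  out <- wide[keys]
  out$angle_deg <- ang
  out
}
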