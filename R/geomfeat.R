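# Mouth characteristic-triangle geometry: corner angles, deviation angles,
# and the neutral-vs-smile-apex difference features used to quantify
# hypomimia. All angles are degrees; signed angles follow the image y-down
# convention (a positive overall deviation means the image-right corner sits
# lower than the image-left corner).
#
# The characteristic triangle uses outer-lip landmarks only: the two mouth
# corners p48 (image left) and p54 (image right) as corner vertices, with
# the upper-lip center p51 and lower-lip center p57 forming the opposing
# edge. As a smile widens the mouth, the angle at each corner shrinks, so
# the neutral-minus-apex change measures smile amplitude.

#' Inter-ocular distance of a landmark set
#'
#' Euclidean distance between the right- and left-eye centers.
#'
#' @param landmarks a 68 x 2 landmark matrix.
#' @return Distance in pixels.
#' @export
interocular_distance <- function(landmarks) {
  ec <- eye_centers(landmarks)
  sqrt(sum((ec$left - ec$right)^2))
}

#' Mouth width relative to inter-ocular distance
#'
#' `||p54 - p48|| / inter-ocular distance`; a dimensionless, similarity-
#' invariant openness measure used to select neutral and smile-apex frames.
#'
#' @param landmarks a 68 x 2 landmark matrix.
#' @return A scalar ratio.
#' @export
mouth_width_ratio <- function(landmarks) {
  landmarks <- as_landmarks(landmarks)
  iod <- interocular_distance(landmarks)
  if (iod < 1e-9) {
    fs_error("fs_degenerate_geometry", "zero inter-ocular distance")
  }
  sqrt(sum((lm_pt(landmarks, 54) - lm_pt(landmarks, 48))^2)) / iod
}

# Unsigned angle in degrees at vertex v between rays v->p and v->q.
angle_at <- function(v, p, q) {
  u1 <- p - v
  u2 <- q - v
  n1 <- sqrt(sum(u1^2))
  n2 <- sqrt(sum(u2^2))
  if (n1 < 1e-12 || n2 < 1e-12) {
    fs_error("fs_degenerate_geometry", "coincident points give a zero-length ray")
  }
  rad2deg(acos(clamp(sum(u1 * u2) / (n1 * n2), -1, 1)))
}

#' Mouth corner angles of the characteristic triangle
#'
#' The angle at each mouth corner between the rays to the upper-lip center
#' p51 and the lower-lip center p57: `theta_left` at p48, `theta_right` at
#' p54.
#'
#' @param landmarks a 68 x 2 landmark matrix (canonical frame).
#' @return Named numeric `c(theta_left, theta_right)` in degrees.
#' @export
corner_angles <- function(landmarks) {
  landmarks <- as_landmarks(landmarks)
  p48 <- lm_pt(landmarks, 48)
  p51 <- lm_pt(landmarks, 51)
  p54 <- lm_pt(landmarks, 54)
  p57 <- lm_pt(landmarks, 57)
  c(
    theta_left = angle_at(p48, p51, p57),
    theta_right = angle_at(p54, p51, p57)
  )
}

#' Overall deviation angle of the mouth
#'
#' Signed angle between the mouth axis p48 -> p54 and the horizontal,
#' `atan2(y54 - y48, x54 - x48)` in degrees. Positive means the image-right
#' corner is lower than the image-left corner (y grows downward).
#'
#' @param landmarks a 68 x 2 landmark matrix (canonical frame).
#' @return Signed angle in degrees.
#' @export
overall_deviation <- function(landmarks) {
  landmarks <- as_landmarks(landmarks)
  d <- lm_pt(landmarks, 54) - lm_pt(landmarks, 48)
  if (sqrt(sum(d^2)) < 1e-12) {
    fs_error("fs_degenerate_geometry", "mouth corners coincide")
  }
  rad2deg(atan2(d[2], d[1]))
}

#' Per-side mouth deviation angles
#'
#' With the mouth center C = midpoint(p51, p57), the elevation angle of each
#' corner above C: `dev_left = atan2(-(y48 - yC), xC - x48)` and
#' `dev_right = atan2(-(y54 - yC), x54 - xC)`. Positive means the corner is
#' elevated above the mouth center.
#'
#' @param landmarks a 68 x 2 landmark matrix (canonical frame).
#' @return Named numeric `c(dev_left, dev_right)` in degrees.
#' @export
side_deviations <- function(landmarks) {
  landmarks <- as_landmarks(landmarks)
  ctr <- (lm_pt(landmarks, 51) + lm_pt(landmarks, 57)) / 2
  p48 <- lm_pt(landmarks, 48)
  p54 <- lm_pt(landmarks, 54)
  if (sqrt(sum((p48 - ctr)^2)) < 1e-12 || sqrt(sum((p54 - ctr)^2)) < 1e-12) {
    fs_error("fs_degenerate_geometry", "mouth corner coincides with mouth center")
  }
  c(
    dev_left = rad2deg(atan2(-(p48[2] - ctr[2]), ctr[1] - p48[1])),
    dev_right = rad2deg(atan2(-(p54[2] - ctr[2]), p54[1] - ctr[1]))
  )
}

#' All mouth angles of one frame
#'
#' @param landmarks a 68 x 2 landmark matrix (canonical frame).
#' @return A list with `theta_left`, `theta_right`, `delta_overall`,
#'   `dev_left`, `dev_right`, all degrees.
#' @export
mouth_angles <- function(landmarks) {
  ca <- corner_angles(landmarks)
  sd_ <- side_deviations(landmarks)
  list(
    theta_left = unname(ca["theta_left"]),
    theta_right = unname(ca["theta_right"]),
    delta_overall = overall_deviation(landmarks),
    dev_left = unname(sd_["dev_left"]),
    dev_right = unname(sd_["dev_right"])
  )
}

#' Select neutral and smile-apex key frames
#'
#' The neutral frame is the minimizer of [mouth_width_ratio()] restricted to
#' the first 40% of the sequence (the instruction order puts the poker face
#' first); the apex frame is the global maximizer. Ties break toward the
#' earlier frame. Frame indices are 1-based.
#'
#' @param landmark_sequence a list of 68 x 2 landmark matrices, one per
#'   frame, in a common (normalized) frame.
#' @return A list of class `key_frame_pair`: `neutral_index`, `apex_index`,
#'   `neutral_landmarks`, `apex_landmarks`, and logical `constant` flagging
#'   a degenerate all-constant sequence (in which case the pair is
#'   (first, last) and a warning is raised).
#' @export
select_key_frames <- function(landmark_sequence) {
  n <- length(landmark_sequence)
  if (n < 2L) {
    fs_error("fs_config_error", "need at least 2 frames to select key frames")
  }
  ratios <- vapply(landmark_sequence, mouth_width_ratio, numeric(1))
  constant <- (max(ratios) - min(ratios)) < 1e-12
  if (constant) {
    fs_warning("fs_constant_sequence",
               "mouth width ratio constant across frames; using (first, last)")
    neutral <- 1L
    apex <- n
  } else {
    window <- seq_len(max(1L, floor(0.4 * n)))
    neutral <- window[which.min(ratios[window])]
    apex <- which.max(ratios)
  }
  structure(
    list(
      neutral_index = neutral,
      apex_index = apex,
      neutral_landmarks = landmark_sequence[[neutral]],
      apex_landmarks = landmark_sequence[[apex]],
      constant = constant
    ),
    class = "key_frame_pair"
  )
}

#' Geometric feature vector of a neutral/apex frame pair
#'
#' The main features are the corner-angle changes `d_theta_left` and
#' `d_theta_right` (apex minus neutral; negative for a normal smile since
#' the corner angle shrinks as the mouth widens). Auxiliary features are the
#' apex-frame overall deviation, the per-side deviations, and the absolute
#' left/right deviation asymmetry `asym_apex`.
#'
#' @param pair a `key_frame_pair` from [select_key_frames()], or any list
#'   with `neutral_landmarks` and `apex_landmarks`.
#' @return Named numeric vector with elements `d_theta_left`,
#'   `d_theta_right`, `delta_overall_apex`, `dev_left_apex`,
#'   `dev_right_apex`, `asym_apex` (degrees).
#' @export
geometric_feature_vector <- function(pair) {
  neutral <- corner_angles(pair$neutral_landmarks)
  apex <- corner_angles(pair$apex_landmarks)
  dev <- side_deviations(pair$apex_landmarks)
  c(
    d_theta_left = unname(apex["theta_left"] - neutral["theta_left"]),
    d_theta_right = unname(apex["theta_right"] - neutral["theta_right"]),
    delta_overall_apex = overall_deviation(pair$apex_landmarks),
    dev_left_apex = unname(dev["dev_left"]),
    dev_right_apex = unname(dev["dev_right"]),
    asym_apex = unname(abs(dev["dev_left"] - dev["dev_right"]))
  )
}
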