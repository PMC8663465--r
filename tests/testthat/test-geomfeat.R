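mk_lm <- function(p48, p51, p54, p57, base = NULL) {
  lm <- base %||% random_landmarks(99)
  lm[49, ] <- p48
  lm[52, ] <- p51
  lm[55, ] <- p54
  lm[58, ] <- p57
  lm
}

test_that("corner angles match the worked characteristic-triangle example", {
  lm <- mk_lm(c(0, 0), c(2, -1), c(4, 0), c(2, 1))
  ca <- corner_angles(lm)
  expect_equal(unname(ca["theta_left"]), acos(3 / 5) * 180 / pi,
               tolerance = 1e-12)
  expect_equal(unname(ca["theta_right"]), acos(3 / 5) * 180 / pi,
               tolerance = 1e-12)
})

test_that("corner angles agree with a law-of-cosines oracle on random mouths", {
  set.seed(42)
  for (i in 1:250) {
    lm <- random_landmarks(i)
    ca <- corner_angles(lm)
    o_left <- oracle_angle_loc(lm[49, ], lm[52, ], lm[58, ])
    o_right <- oracle_angle_loc(lm[55, ], lm[52, ], lm[58, ])
    expect_lt(abs(ca["theta_left"] - o_left), 1e-9)
    expect_lt(abs(ca["theta_right"] - o_right), 1e-9)
  }
})

test_that("collinear and degenerate mouths are handled per contract", {
  lm <- mk_lm(c(0, 0), c(2, 0), c(4, 0), c(3, 0))
  ca <- corner_angles(lm)
  expect_equal(unname(ca["theta_left"]), 0, tolerance = 1e-9)
  lm_deg <- mk_lm(c(2, -1), c(2, -1), c(4, 0), c(2, 1))
  expect_error(corner_angles(lm_deg), class = "fs_degenerate_geometry")
})

test_that("overall deviation follows the signed atan2 convention", {
  base <- random_landmarks(7)
  expect_equal(overall_deviation(mk_lm(c(0, 0), c(2, -1), c(4, 0), c(2, 1), base)), 0)
  expect_equal(overall_deviation(mk_lm(c(0, 0), c(2, -3), c(4, -4), c(2, 1), base)),
               -45)
  # reflecting about the vertical midline flips the sign
  lm <- mk_lm(c(0, 0), c(2, -1), c(4, -2), c(2, 1), base)
  refl <- lm
  refl[, 1] <- 256 - lm[, 1]
  swap <- function(m, i, j) {
    tmp <- m[i, ]
    m[i, ] <- m[j, ]
    m[j, ] <- tmp
    m
  }
  refl <- swap(refl, 49, 55) # p48 <-> p54 after reflection
  expect_equal(overall_deviation(refl), -overall_deviation(lm), tolerance = 1e-9)
})

test_that("side deviations measure elevation above the mouth center", {
  base <- random_landmarks(8)
  lm <- mk_lm(c(0, 0), c(2, -1), c(5, 1), c(2, 1), base)
  # C = (2, 0); left corner level with C
  expect_equal(unname(side_deviations(lm)["dev_left"]), 0, tolerance = 1e-9)
  lm2 <- mk_lm(c(0, -2), c(2, -1), c(5, 1), c(2, 1), base)
  expect_equal(unname(side_deviations(lm2)["dev_left"]), 45, tolerance = 1e-9)
  # symmetric smile: equal elevations
  lm3 <- mk_lm(c(0, -1), c(2, -1), c(4, -1), c(2, 1), base)
  dv <- side_deviations(lm3)
  expect_equal(unname(dv["dev_left"]), unname(dv["dev_right"]), tolerance = 1e-9)
  # deviations match a direct atan2 oracle on random mouths
  for (i in 1:100) {
    lm <- random_landmarks(i + 500)
    ctr <- (lm[52, ] + lm[58, ]) / 2
    dv <- side_deviations(lm)
    expect_lt(abs(dv["dev_left"] -
                    atan2(ctr[2] - lm[49, 2], ctr[1] - lm[49, 1]) * 180 / pi), 1e-9)
    expect_lt(abs(dv["dev_right"] -
                    atan2(ctr[2] - lm[55, 2], lm[55, 1] - ctr[1]) * 180 / pi), 1e-9)
  }
})

test_that("mouth width ratio is a similarity-invariant length ratio", {
  lm <- random_landmarks(9)
  r <- mouth_width_ratio(lm)
  expect_gt(r, 0)
  for (seed in 1:5) {
    expect_equal(mouth_width_ratio(random_rigid(lm, seed)), r,
                 tolerance = 1e-9)
  }
  wide <- lm
  wide[c(49, 55), 1] <- wide[c(49, 55), 1] + c(-5, 5)
  expect_gt(mouth_width_ratio(wide), r)
})

test_that("key-frame selection finds the half-sine apex and obeys tie-breaks", {
  params <- sample_subject_params(cohort_config(rng_seed = 5), "control", 8)
  phases <- phase_profile(11)
  seq_lm <- lapply(phases, function(p) landmarks_from_params(params, p))
  kf <- select_key_frames(seq_lm)
  expect_identical(kf$neutral_index, 1L)
  expect_identical(kf$apex_index, 6L) # analytic phase maximum of 11 frames
  expect_false(kf$constant)
  # monotone openness: neutral first, apex last
  mono <- lapply(seq(0, 1, length.out = 6), function(p) {
    landmarks_from_params(params, p)
  })
  kf2 <- select_key_frames(mono)
  expect_identical(kf2$neutral_index, 1L)
  expect_identical(kf2$apex_index, 6L)
  # two equal maxima: the earlier frame wins
  two_max <- lapply(c(0, 0.4, 1, 1, 0.2), function(p) {
    landmarks_from_params(params, p)
  })
  expect_identical(select_key_frames(two_max)$apex_index, 3L)
  # constant sequence falls back to (first, last) with a warning
  const <- lapply(rep(0.5, 5), function(p) landmarks_from_params(params, p))
  expect_warning(kf3 <- select_key_frames(const), class = "fs_constant_sequence")
  expect_identical(c(kf3$neutral_index, kf3$apex_index), c(1L, 5L))
})

test_that("feature vector is zero for identical frames and recovers the gain", {
  params <- sample_subject_params(cohort_config(rng_seed = 6), "control", 9)
  lm <- landmarks_from_params(params, 0)
  same <- list(neutral_landmarks = lm, apex_landmarks = lm)
  g0 <- geometric_feature_vector(same)
  expect_equal(unname(g0["d_theta_left"]), 0)
  expect_equal(unname(g0["d_theta_right"]), 0)
  # a subject with known gain and no asymmetry
  params$smile_angle_gain <- 10
  params$asymmetry <- 0
  pair <- list(neutral_landmarks = landmarks_from_params(params, 0),
               apex_landmarks = landmarks_from_params(params, 1))
  g <- geometric_feature_vector(pair)
  expect_lt(abs(-g["d_theta_left"] - 10), 0.5)
  expect_lt(abs(-g["d_theta_right"] - 10), 0.5)
  expect_lt(unname(g["asym_apex"]), 0.5)
  # asymmetry of 4 degrees appears in the apex side deviations
  params$asymmetry <- 4
  apex <- landmarks_from_params(params, 1)
  dv <- side_deviations(apex)
  expect_lt(abs((dv["dev_left"] - dv["dev_right"]) - 4), 0.5)
})

test_that("geometric features are similarity-invariant through normalization", {
  params <- sample_subject_params(cohort_config(rng_seed = 7), "patient", 10)
  seq_lm <- lapply(phase_profile(7), function(p) landmarks_from_params(params, p))
  feat_of <- function(lms) {
    norm <- lapply(lms, function(l) normalize_face(l)$landmarks)
    geometric_feature_vector(select_key_frames(norm))
  }
  ref <- feat_of(seq_lm)
  for (seed in 1:8) {
    moved <- lapply(seq_lm, random_rigid, seed = seed)
    expect_lt(max(abs(feat_of(moved) - ref)), 0.1)
  }
})

test_that("mirror reflection swaps left/right angles and negates the overall deviation", {
  for (seed in 1:20) {
    lm <- random_landmarks(seed + 2000)
    refl <- lm
    refl[, 1] <- 256 - lm[, 1]
    # re-index to keep iBUG semantics after reflection
    swap_rows <- function(m, pairs) {
      for (pr in pairs) {
        tmp <- m[pr[1], ]
        m[pr[1], ] <- m[pr[2], ]
        m[pr[2], ] <- tmp
      }
      m
    }
    mouth_pairs <- list(c(49, 55), c(50, 54), c(51, 53), c(60, 56), c(59, 57),
                        c(61, 65), c(62, 64), c(66, 68))
    eye_pairs <- list(c(37, 46), c(38, 45), c(39, 44), c(40, 43), c(41, 48),
                      c(42, 47))
    refl <- swap_rows(refl, c(mouth_pairs, eye_pairs))
    ca <- corner_angles(lm)
    ca_r <- corner_angles(refl)
    expect_equal(unname(ca_r["theta_left"]), unname(ca["theta_right"]),
                 tolerance = 1e-9)
    expect_equal(unname(ca_r["theta_right"]), unname(ca["theta_left"]),
                 tolerance = 1e-9)
    dv <- side_deviations(lm)
    dv_r <- side_deviations(refl)
    expect_equal(unname(dv_r["dev_left"]), unname(dv["dev_right"]),
                 tolerance = 1e-9)
    expect_equal(overall_deviation(refl), -overall_deviation(lm),
                 tolerance = 1e-9)
  }
})
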