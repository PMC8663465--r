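test_that("config validation enforces counts and effect ranges", {
  expect_error(cohort_config(n_patient = 0), class = "fs_config_error")
  expect_error(cohort_config(effect_texture = 1.5), class = "fs_config_error")
  expect_error(cohort_config(n_frames = 1), class = "fs_config_error")
  expect_s3_class(cohort_config(), "cohort_config")
})

test_that("subject parameter draws are deterministic and respect the group effect", {
  cfg <- cohort_config(effect_angle = 1.5, rng_seed = 3)
  a <- sample_subject_params(cfg, "patient", 77)
  b <- sample_subject_params(cfg, "patient", 77)
  expect_identical(a, b)
  expect_error(sample_subject_params(cfg, "case", 1), class = "fs_config_error")

  # with zero effects the two groups follow the identical distribution:
  # the same per-subject seed yields bit-identical draws up to the label
  cfg0 <- cohort_config(rng_seed = 4)
  p <- sample_subject_params(cfg0, "patient", 123)
  q <- sample_subject_params(cfg0, "control", 123)
  p$group <- q$group
  expect_identical(p, q)

  # Monte-Carlo: group means of the gain differ by ~1.5 SD under the effect
  gains <- function(grp) {
    base <- if (grp == "patient") 10000L else 20000L
    vapply(1:200, function(i) {
      sample_subject_params(cfg, grp, base + i)$smile_angle_gain
    }, numeric(1))
  }
  d <- (mean(gains("control")) - mean(gains("patient"))) / cfg$sd_gain
  expect_lt(abs(d - 1.5), 0.25)
})

test_that("ground-truth landmarks are analytically consistent with the traits", {
  cfg <- cohort_config(rng_seed = 8)
  for (i in 1:10) {
    params <- sample_subject_params(cfg, sample(c("patient", "control"), 1), i)
    lm0 <- landmarks_from_params(params, 0)
    lm1 <- landmarks_from_params(params, 1)
    # neutral mouth width matches the trait
    expect_lt(abs(sqrt(sum((lm0[55, ] - lm0[49, ])^2)) - params$mouth_width), 0.5)
    # corner-angle change from neutral to apex equals the smile gain
    d_left <- corner_angles(lm0)["theta_left"] - corner_angles(lm1)["theta_left"]
    d_right <- corner_angles(lm0)["theta_right"] - corner_angles(lm1)["theta_right"]
    expect_lt(abs(d_left - params$smile_angle_gain), 0.5)
    expect_lt(abs(d_right - params$smile_angle_gain), 0.5)
    # apex side deviations differ by the asymmetry trait
    dv <- side_deviations(lm1)
    expect_lt(abs((dv["dev_left"] - dv["dev_right"]) - params$asymmetry), 0.5)
    # interocular distance matches
    expect_lt(abs(interocular_distance(lm0) - params$interocular), 0.5)
  }
  expect_error(landmarks_from_params(sample_subject_params(cfg, "control", 1), 1.2),
               class = "fs_config_error")
})

test_that("neutral faces with zero asymmetry are mirror-symmetric", {
  cfg <- cohort_config(rng_seed = 9)
  params <- sample_subject_params(cfg, "control", 2)
  params$asymmetry <- 0
  lm <- landmarks_from_params(params, 0)
  refl_x <- 256 - lm[, 1]
  mirror_map <- integer(68)
  mirror_map[1:17] <- 17:1
  mirror_map[18:27] <- 27:18
  mirror_map[28:31] <- 28:31
  mirror_map[32:36] <- 36:32
  mirror_map[37:48] <- c(46, 45, 44, 43, 48, 47, 40, 39, 38, 37, 42, 41)
  mirror_map[49:60] <- c(55, 54, 53, 52, 51, 50, 49, 60, 59, 58, 57, 56)
  mirror_map[61:68] <- c(65, 64, 63, 62, 61, 68, 67, 66)
  err <- max(abs(cbind(refl_x[mirror_map], lm[mirror_map, 2]) - lm))
  expect_lt(err, 0.5)
})

test_that("mouth width and corner elevation interpolate monotonically in phase", {
  params <- sample_subject_params(cohort_config(rng_seed = 10), "control", 3)
  params$asymmetry <- 1
  phases <- seq(0, 1, by = 0.1)
  widths <- numeric(length(phases))
  elev <- numeric(length(phases))
  for (i in seq_along(phases)) {
    lm <- landmarks_from_params(params, phases[i])
    widths[i] <- sqrt(sum((lm[55, ] - lm[49, ])^2))
    ctr <- (lm[52, ] + lm[58, ]) / 2
    elev[i] <- ctr[2] - lm[49, 2]
  }
  expect_true(all(diff(widths) > 0))
  expect_true(all(diff(elev) >= 0))
})

test_that("rendering is deterministic, texture-sensitive, and bounded", {
  cfg <- cohort_config(rng_seed = 11)
  params <- sample_subject_params(cfg, "control", 4)
  lm <- landmarks_from_params(params, 1)
  img1 <- render_face(lm, params, seed = 21)
  img2 <- render_face(lm, params, seed = 21)
  expect_identical(img1, img2)
  expect_true(all(img1 >= 0 & img1 <= 255))

  flat <- params
  flat$texture_contrast <- 0
  full <- params
  full$texture_contrast <- 1
  roi_var <- function(img) {
    ec <- eye_centers(attr(img, "landmarks"))
    r <- round(ec$right)
    var(as.numeric(img[(r[2] - 12):(r[2] + 12) + 1, (r[1] - 20):(r[1] + 5) + 1]))
  }
  expect_lt(roi_var(render_face(lm, flat, seed = 5)),
            roi_var(render_face(lm, full, seed = 5)))

  # mouth corner darker than a cheek probe
  p48 <- round(lm[49, ])
  cheek <- p48 + c(-18, -22)
  expect_lt(img1[p48[2] + 1, p48[1] + 1], img1[cheek[2] + 1, cheek[1] + 1])

  # landmarks outside the canvas are rejected
  bad <- lm
  bad[1, 1] <- -5
  expect_error(render_face(bad, params, seed = 1), class = "fs_schema_error")
})

test_that("cohort generation conserves counts and is fully reproducible", {
  cfg <- tiny_config(seed = 12)
  coh1 <- generate_cohort(cfg, render = "none")
  coh2 <- generate_cohort(cfg, render = "none")
  expect_length(coh1$subjects, 8)
  expect_identical(sum(coh1$manifest$group == "patient"), 4L)
  expect_identical(coh1$manifest, coh2$manifest)
  expect_identical(coh1$subjects[[3]]$landmark_sequence,
                   coh2$subjects[[3]]$landmark_sequence)
  # one landmark set per frame, phases follow the half-sine
  expect_length(coh1$subjects[[1]]$landmark_sequence, cfg$n_frames)
  expect_equal(coh1$subjects[[1]]$phases, phase_profile(cfg$n_frames))
})

test_that("cohort written to disk round-trips through the readers", {
  dir <- withr::local_tempdir()
  cfg <- cohort_config(n_patient = 2, n_control = 2, n_frames = 5,
                       image_size = 128, interocular = 50, rng_seed = 13)
  coh <- generate_cohort(cfg, render = "key", out_dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- read_cohort(dir)
  expect_length(back$subjects, 4)
  expect_equal(back$subjects[[1]]$landmark_sequence,
               coh$subjects[[1]]$landmark_sequence, tolerance = 1e-12)
  img <- back$subjects[[1]]$frames[[1]]
  expect_false(is.null(img))
  # PNG quantizes to 8 bits: intensities agree within half a level
  expect_lt(max(abs(img - coh$subjects[[1]]$frames[[1]])), 0.51)
})

test_that("covariates stay independent of facial traits unless linked", {
  cfg <- cohort_config(n_patient = 40, n_control = 10, rng_seed = 14,
                       covariate_link = TRUE, effect_angle = 1)
  coh <- generate_cohort(cfg, render = "none")
  pat <- which(coh$manifest$group == "patient")
  gains <- vapply(coh$subjects[pat], function(s) s$params$smile_angle_gain,
                  numeric(1))
  r <- cor(gains, coh$manifest$updrs_total[pat])
  expect_lt(r, -0.25) # linked draw targets r = -0.6
})
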