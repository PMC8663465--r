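# Synthetic two-group face-cohort generator.
#
# Emulates a screening study in which each participant is filmed while
# producing a poker face followed by a smile: per subject we draw latent
# expression traits (smile amplitude, mouth asymmetry, texture contrast),
# build an analytic 68-point landmark sequence whose expression phase rises
# 0 -> 1 -> 0 as a half-sine, render parametric line-art frames with
# band-noise facial texture, and sample clinical covariates that are by
# default statistically independent of the facial traits. Ground-truth
# landmarks make every downstream stage testable without patient data.

#' Cohort generation configuration
#'
#' @param n_patient,n_control subjects per group.
#' @param effect_angle standardized group shift (SD units) by which the
#'   patient smile corner-angle change is reduced (hypomimia effect).
#' @param effect_asym standardized group increase in mouth-asymmetry
#'   dispersion for patients.
#' @param effect_texture multiplicative reduction of rendered texture
#'   contrast for patients, in \[0, 1\] (0 = none, 1 = flat).
#' @param n_frames frames per subject sequence.
#' @param image_size square canvas size in pixels.
#' @param rng_seed integer root seed; all cohort randomness derives from it.
#' @param covariate_link if `TRUE`, UPDRS total is linked to smile-amplitude
#'   deficit (correlation -0.6 with `smile_angle_gain`); default `FALSE`,
#'   i.e. covariates independent of facial traits.
#' @param mu_gain,sd_gain mean and SD (degrees) of the control-group smile
#'   corner-angle change.
#' @param sd_asym SD (degrees) of mouth asymmetry in controls.
#' @param interocular inter-ocular distance in pixels.
#' @param neutral_angle_mean,neutral_angle_sd mean/SD (degrees) of the
#'   neutral mouth corner angle.
#' @param width_gain fractional mouth-width increase at smile apex.
#' @param base_elevation corner elevation angle (degrees) at smile apex.
#' @param noise_sd SD of additive Gaussian pixel noise in rendered frames.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_patient = 70, n_control = 70,
                          effect_angle = 0, effect_asym = 0,
                          effect_texture = 0,
                          n_frames = 11, image_size = 256,
                          rng_seed = 1, covariate_link = FALSE,
                          mu_gain = 12, sd_gain = 3, sd_asym = 1.5,
                          interocular = 100,
                          neutral_angle_mean = 55, neutral_angle_sd = 3,
                          width_gain = 0.3, base_elevation = 6,
                          noise_sd = 2) {
  if (!is_count(n_patient) || !is_count(n_control)) {
    fs_error("fs_config_error", "group sizes must be counts >= 1")
  }
  if (!is_count(n_frames) || n_frames < 2) {
    fs_error("fs_config_error", "n_frames must be a count >= 2")
  }
  if (!is_scalar(effect_texture) || effect_texture < 0 || effect_texture > 1) {
    fs_error("fs_config_error", "effect_texture must lie in [0, 1]")
  }
  if (!is_count(image_size) || image_size < 64) {
    fs_error("fs_config_error", "image_size must be a count >= 64")
  }
  structure(
    list(
      n_patient = as.integer(n_patient), n_control = as.integer(n_control),
      effect_angle = effect_angle, effect_asym = effect_asym,
      effect_texture = effect_texture,
      n_frames = as.integer(n_frames), image_size = as.integer(image_size),
      rng_seed = as.integer(rng_seed), covariate_link = isTRUE(covariate_link),
      mu_gain = mu_gain, sd_gain = sd_gain, sd_asym = sd_asym,
      interocular = interocular,
      neutral_angle_mean = neutral_angle_mean,
      neutral_angle_sd = neutral_angle_sd,
      width_gain = width_gain, base_elevation = base_elevation,
      noise_sd = noise_sd
    ),
    class = "cohort_config"
  )
}

#' Sample the latent expression traits of one subject
#'
#' Patients receive a smile-amplitude reduction of
#' `effect_angle * sd_gain` degrees (truncated at 0), an asymmetry SD
#' inflated by `1 + effect_asym`, and a texture contrast multiplied by
#' `1 - effect_texture`. With all effects 0 the two groups are drawn from
#' identical distributions.
#'
#' @param config a [cohort_config()].
#' @param group `"patient"` or `"control"`.
#' @param seed integer seed for this subject's draw.
#' @return A list of class `subject_params`.
#' @export
sample_subject_params <- function(config, group, seed) {
  if (!group %in% c("patient", "control")) {
    fs_error("fs_config_error", sprintf("invalid group label '%s'", group))
  }
  pat <- group == "patient"
  with_seed(seed, {
    gain_mu <- config$mu_gain - if (pat) config$effect_angle * config$sd_gain else 0
    gain <- max(0, stats::rnorm(1, gain_mu, config$sd_gain))
    asym <- stats::rnorm(1, 0, config$sd_asym * (1 + if (pat) config$effect_asym else 0))
    contrast <- stats::runif(1, 0.8, 1) * (1 - if (pat) config$effect_texture else 0)
    structure(
      list(
        group = group,
        neutral_corner_angle = stats::rnorm(1, config$neutral_angle_mean,
                                            config$neutral_angle_sd),
        smile_angle_gain = gain,
        asymmetry = asym,
        mouth_width = max(20, stats::rnorm(1, 0.58 * config$interocular, 2)),
        interocular = config$interocular,
        texture_contrast = contrast
      ),
      class = "subject_params"
    )
  })
}

# Clinical covariates sampled from plausible scale ranges. Independent of
# the facial traits unless `link` is TRUE, in which case UPDRS total is
# constructed with correlation -0.6 to the subject's smile_angle_gain.
sample_covariates <- function(config, group, params, seed) {
  pat <- group == "patient"
  with_seed(seed, {
    rnc <- function(mu, sd, lo, hi) clamp(stats::rnorm(1, mu, sd), lo, hi)
    age <- rnc(if (pat) 66 else 65, 8, 40, 85)
    duration <- if (pat) clamp(stats::rgamma(1, shape = 2, scale = 3), 0.5, 25) else 0
    updrs <- if (pat) {
      if (config$covariate_link) {
        z_face <- (params$smile_angle_gain -
                     (config$mu_gain - config$effect_angle * config$sd_gain)) /
          config$sd_gain
        r <- 0.6
        clamp(45 + 14 * (-r * z_face + sqrt(1 - r^2) * stats::rnorm(1)), 10, 80)
      } else {
        rnc(45, 14, 10, 80)
      }
    } else {
      rnc(3, 2, 0, 10)
    }
    list(
      age = age,
      age_onset = if (pat) age - duration else NA_real_,
      duration = duration,
      ledd = if (pat) rnc(600, 250, 0, 2500) else 0,
      updrs_total = updrs,
      hy_stage = if (pat) sample(1:5, 1, prob = c(0.15, 0.3, 0.3, 0.15, 0.1)) else 0,
      mmse = round(rnc(if (pat) 27 else 28, 2, 10, 30)),
      nmss = rnc(if (pat) 45 else 10, if (pat) 25 else 8, 0, 200),
      pdq39 = rnc(if (pat) 30 else 5, if (pat) 15 else 4, 0, 100),
      ham_a = rnc(if (pat) 12 else 5, if (pat) 6 else 4, 0, 56),
      rbd = rnc(if (pat) 20 else 8, if (pat) 12 else 6, 0, 100),
      quip = rnc(if (pat) 6 else 1, if (pat) 4 else 1.5, 0, 28),
      fog = rnc(if (pat) 8 else 1, if (pat) 5 else 1.5, 0, 24)
    )
  })
}

#' Expression phase profile of a frame sequence
#'
#' Half-sine over the sequence: `sin(pi * (j - 1) / (n - 1))` for frame j of
#' n, so the sequence starts neutral, peaks at the middle frame, and relaxes
#' back (poker face, smile, relax).
#'
#' @param n_frames number of frames (>= 2).
#' @return Numeric vector of phases in \[0, 1\].
#' @export
phase_profile <- function(n_frames) {
  if (!is_count(n_frames) || n_frames < 2) {
    fs_error("fs_config_error", "n_frames must be a count >= 2")
  }
  sin(pi * (seq_len(n_frames) - 1) / (n_frames - 1))
}

# Mean mouth-corner angle (radians) of the parametric mouth for lip
# half-height lh, half-width wh and corner elevations eL, eR.
mean_corner_angle <- function(lh, wh, eL, eR) {
  aL <- atan((lh - eL) / wh) + atan((lh + eL) / wh)
  aR <- atan((lh - eR) / wh) + atan((lh + eR) / wh)
  (aL + aR) / 2
}

#' Ground-truth landmark set of a subject at an expression phase
#'
#' Builds the full 68-point set analytically: eyes, brows, nose and jaw are
#' expression-invariant and mirror-symmetric; the mouth widens by
#' `width_gain * phase`, its corner angle shrinks linearly from the neutral
#' angle by `smile_angle_gain * phase` (lip height solved so that the mean
#' corner angle hits the target exactly), and corner elevations at apex
#' differ by `asymmetry` degrees of per-side deviation.
#'
#' @param params a `subject_params` list.
#' @param phase scalar in \[0, 1\]: 0 = neutral, 1 = smile apex.
#' @param image_size canvas size in pixels.
#' @param width_gain fractional width increase at apex.
#' @param base_elevation symmetric corner elevation (degrees) at apex.
#' @return A 68 x 2 landmark matrix (0-based pixel coordinates, y down).
#' @export
landmarks_from_params <- function(params, phase, image_size = 256,
                                  width_gain = 0.3, base_elevation = 6) {
  if (!is_scalar(phase) || phase < 0 || phase > 1) {
    fs_error("fs_config_error", "phase must lie in [0, 1]")
  }
  s <- image_size
  io <- params$interocular
  cx <- s / 2
  ey <- 0.4 * s
  my <- ey + 0.74 * io

  lm <- matrix(NA_real_, 68, 2)
  set_pt <- function(i, p) lm[i + 1L, ] <<- p # 0-based index
  mirror <- function(p) c(2 * cx - p[1], p[2])

  # jaw 0-16: half-ellipse from image-left temple through chin
  a_j <- 0.85 * io
  b_j <- (my - ey) + 0.50 * io
  for (i in 0:16) {
    ang <- pi * i / 16
    set_pt(i, c(cx - a_j * cos(ang), ey + b_j * sin(ang)))
  }

  # brows 17-26 (right brow explicit, left mirrored; 17+k <-> 26-k)
  ox <- c(-0.30, -0.15, 0, 0.15, 0.30) * io
  oy <- c(-0.20, -0.24, -0.26, -0.24, -0.21) * io
  for (k in 0:4) {
    p <- c(cx - io / 2 + ox[k + 1], ey + oy[k + 1])
    set_pt(17 + k, p)
    set_pt(26 - k, mirror(p))
  }

  # nose 27-35 (self-symmetric)
  for (k in 0:3) set_pt(27 + k, c(cx, ey + c(0.05, 0.18, 0.31, 0.44)[k + 1] * io))
  nx <- c(-0.16, -0.08, 0, 0.08, 0.16) * io
  ny <- c(0.50, 0.52, 0.53, 0.52, 0.50) * io
  for (k in 0:4) set_pt(31 + k, c(cx + nx[k + 1], ey + ny[k + 1]))

  # eyes 36-47: right eye explicit, left eye mirrored
  w_e <- 0.15 * io
  h_e <- 0.06 * io
  re <- c(cx - io / 2, ey)
  eye_off <- rbind(
    c(-w_e, 0), c(-w_e / 3, -h_e), c(w_e / 3, -h_e),
    c(w_e, 0), c(w_e / 3, h_e), c(-w_e / 3, h_e)
  )
  eye_mirror_map <- c(45L, 44L, 43L, 42L, 47L, 46L) # of 36..41
  for (k in 0:5) {
    p <- re + eye_off[k + 1, ]
    set_pt(36 + k, p)
    set_pt(eye_mirror_map[k + 1], mirror(p))
  }

  # mouth: width, target corner angle and corner elevations at this phase
  w <- params$mouth_width * (1 + width_gain * phase)
  wh <- w / 2
  theta <- max(5, params$neutral_corner_angle - params$smile_angle_gain * phase)
  dev_l <- (base_elevation + params$asymmetry / 2) * phase
  dev_r <- (base_elevation - params$asymmetry / 2) * phase
  eL <- tan(deg2rad(dev_l)) * wh
  eR <- tan(deg2rad(dev_r)) * wh
  lh <- stats::uniroot(
    function(l) mean_corner_angle(l, wh, eL, eR) - deg2rad(theta),
    lower = 1e-9, upper = 10 * wh, tol = 1e-12
  )$root

  ctr <- c(cx, my)
  r48 <- c(-wh, -eL)
  r54 <- c(wh, -eR)
  r51 <- c(0, -lh)
  r57 <- c(0, lh)
  bez <- function(p0, pc, p1, t) {
    (1 - t)^2 * p0 + 2 * t * (1 - t) * pc + t^2 * p1
  }
  cU_L <- c(-wh * 0.5, -lh * 1.1 - eL * 0.5)
  cU_R <- c(wh * 0.5, -lh * 1.1 - eR * 0.5)
  cD_L <- c(-wh * 0.5, lh * 1.15 - eL * 0.5)
  cD_R <- c(wh * 0.5, lh * 1.15 - eR * 0.5)
  set_pt(48, ctr + r48)
  set_pt(49, ctr + bez(r48, cU_L, r51, 1 / 3))
  set_pt(50, ctr + bez(r48, cU_L, r51, 2 / 3))
  set_pt(51, ctr + r51)
  set_pt(52, ctr + bez(r54, cU_R, r51, 2 / 3))
  set_pt(53, ctr + bez(r54, cU_R, r51, 1 / 3))
  set_pt(54, ctr + r54)
  set_pt(55, ctr + bez(r54, cD_R, r57, 1 / 3))
  set_pt(56, ctr + bez(r54, cD_R, r57, 2 / 3))
  set_pt(57, ctr + r57)
  set_pt(58, ctr + bez(r48, cD_L, r57, 2 / 3))
  set_pt(59, ctr + bez(r48, cD_L, r57, 1 / 3))
  # inner lip: outer lip scaled toward the mouth center
  inner_src <- c(48L, 50L, 51L, 52L, 54L, 56L, 57L, 58L)
  for (k in 0:7) {
    src <- lm[inner_src[k + 1] + 1L, ]
    set_pt(60 + k, ctr + 0.62 * (src - ctr))
  }
  as_landmarks(lm)
}

# Rasterize a polyline onto a canvas matrix (value painted at rounded pixel
# positions; thick = 2 also paints 4-neighbours).
draw_polyline <- function(canvas, pts, value, thick = 1, closed = FALSE) {
  if (closed) pts <- rbind(pts, pts[1, , drop = FALSE])
  h <- nrow(canvas)
  w <- ncol(canvas)
  for (i in seq_len(nrow(pts) - 1)) {
    p0 <- pts[i, ]
    p1 <- pts[i + 1, ]
    len <- sqrt(sum((p1 - p0)^2))
    nsteps <- max(2L, ceiling(2 * len))
    t <- seq(0, 1, length.out = nsteps)
    xs <- round(p0[1] + t * (p1[1] - p0[1]))
    ys <- round(p0[2] + t * (p1[2] - p0[2]))
    if (thick >= 2) {
      xs <- c(xs, xs + 1, xs - 1, xs, xs)
      ys <- c(ys, ys, ys, ys + 1, ys - 1)
    }
    ok <- xs >= 0 & xs <= w - 1 & ys >= 0 & ys <= h - 1
    canvas[cbind(ys[ok] + 1, xs[ok] + 1)] <- value
  }
  canvas
}

#' Render a synthetic grayscale face frame
#'
#' Draws a head ellipse filled with a skin tone on a dark background, line
#' art through the landmark contours (jaw, brows, eyes, nose, lips), fine
#' sinusoidal wrinkle bands near the eye corners and around the mouth with
#' amplitude proportional to `texture_contrast`, and additive Gaussian pixel
#' noise (`noise_sd`, default 2 intensity levels). The returned matrix
#' carries the ground-truth landmarks and head box as attributes
#' `"landmarks"` and `"face_box"` for the synthetic detector backend.
#'
#' @param landmarks 68 x 2 landmark matrix from [landmarks_from_params()].
#' @param params the subject's `subject_params`.
#' @param seed integer seed for the pixel noise.
#' @param image_size canvas size in pixels.
#' @param noise_sd SD of the additive Gaussian noise.
#' @return An `image_size` x `image_size` intensity matrix in \[0, 255\].
#' @export
render_face <- function(landmarks, params, seed, image_size = 256,
                        noise_sd = 2) {
  landmarks <- as_landmarks(landmarks)
  s <- image_size
  if (any(landmarks < 0) || any(landmarks > s - 1)) {
    fs_error("fs_schema_error", "landmarks outside the canvas")
  }
  bg <- 60
  skin <- 170
  ink <- 40
  xs <- matrix(rep(0:(s - 1), each = s), s, s)    # xs[r, c] = c - 1
  ys <- matrix(rep(0:(s - 1), times = s), s, s)   # ys[r, c] = r - 1

  iod <- interocular_distance(landmarks)
  ec <- eye_centers(landmarks)
  jaw <- landmarks[1:17, ]
  cx <- mean(range(jaw[, 1]))
  a <- diff(range(jaw[, 1])) / 2 * 1.02 + 3
  bottom <- max(jaw[, 2]) + 2
  top <- max(0, (ec$right[2] + ec$left[2]) / 2 - 0.58 * iod)
  yc <- (top + bottom) / 2
  b <- (bottom - top) / 2
  inface <- ((xs - cx) / a)^2 + ((ys - yc) / b)^2 <= 1
  img <- matrix(bg, s, s)
  img[inface] <- skin

  # wrinkle bands: crow's feet at each outer eye corner, perioral rings
  amp <- 20 * params$texture_contrast
  if (amp > 0) {
    add_band <- function(img, center, rx, ry, pattern) {
      m <- ((xs - center[1]) / rx)^2 + ((ys - center[2]) / ry)^2 <= 1
      m <- m & inface
      img[m] <- img[m] + pattern[m]
      img
    }
    stripes_v <- amp * sin(2 * pi * xs / 4)
    stripes_d <- amp * sin(2 * pi * (xs + ys) / 5)
    p36 <- lm_pt(landmarks, 36)
    p45 <- lm_pt(landmarks, 45)
    img <- add_band(img, p36 + c(-0.12 * iod, 0), 0.22 * iod, 0.15 * iod, stripes_v)
    img <- add_band(img, p45 + c(0.12 * iod, 0), 0.22 * iod, 0.15 * iod, stripes_v)
    mouth_ctr <- (lm_pt(landmarks, 51) + lm_pt(landmarks, 57)) / 2
    img <- add_band(img, mouth_ctr, 0.45 * iod, 0.30 * iod, stripes_d)
  }

  # line art through the landmark contours
  pts <- function(idx) landmarks[idx + 1L, , drop = FALSE] # 0-based
  img <- draw_polyline(img, pts(0:16), ink)
  img <- draw_polyline(img, pts(17:21), ink)
  img <- draw_polyline(img, pts(22:26), ink)
  img <- draw_polyline(img, pts(27:30), ink)
  img <- draw_polyline(img, pts(31:35), ink)
  img <- draw_polyline(img, pts(36:41), ink, closed = TRUE)
  img <- draw_polyline(img, pts(42:47), ink, closed = TRUE)
  img <- draw_polyline(img, pts(48:59), ink, thick = 2, closed = TRUE)
  img <- draw_polyline(img, pts(60:67), ink, closed = TRUE)

  img <- img + with_seed(seed, matrix(stats::rnorm(s * s, 0, noise_sd), s, s))
  img <- clamp(img, 0, 255)

  x0 <- max(0, floor(cx - a))
  y0 <- max(0, floor(top))
  attr(img, "landmarks") <- landmarks
  attr(img, "face_box") <- list(
    x = x0, y = y0,
    w = min(s - x0, ceiling(2 * a) + 1),
    h = min(s - y0, ceiling(bottom - top) + 1)
  )
  img
}

#' Generate a synthetic two-group cohort
#'
#' Draws `n_patient + n_control` subjects; each has latent expression
#' parameters, a full ground-truth landmark sequence over the half-sine
#' expression profile, clinical covariates, and (optionally) rendered
#' frames. Rendering is the only expensive step, so by default only the key
#' frames (first = neutral, middle = apex) are rendered; geometric features
#' need only the landmark sequence.
#'
#' @param config a [cohort_config()].
#' @param render `"key"` (default: neutral and apex frames), `"all"`, or
#'   `"none"`.
#' @param out_dir optional directory: writes per-subject PNG frames
#'   (`<id>/frame_%04d.png`), per-subject landmark JSON (ibug68-v1 schema),
#'   and `manifest.csv`.
#' @return A list of class `face_cohort` with `subjects` (list), `manifest`
#'   (data.frame of subject_id, group and covariates) and `config`.
#' @export
generate_cohort <- function(config, render = c("key", "all", "none"),
                            out_dir = NULL) {
  render <- match.arg(render)
  stopifnot(inherits(config, "cohort_config"))
  groups <- c(rep("patient", config$n_patient), rep("control", config$n_control))
  phases <- phase_profile(config$n_frames)
  apex_j <- which.max(phases)
  render_js <- switch(render,
    key = unique(c(1L, apex_j)),
    all = seq_along(phases),
    none = integer(0)
  )
  subjects <- vector("list", length(groups))
  cov_rows <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    grp <- groups[i]
    params <- sample_subject_params(config, grp, derive_seed(config$rng_seed, i, 1))
    covs <- sample_covariates(config, grp, params, derive_seed(config$rng_seed, i, 2))
    lms <- lapply(phases, function(p) {
      landmarks_from_params(params, p, config$image_size,
                            width_gain = config$width_gain,
                            base_elevation = config$base_elevation)
    })
    frames <- vector("list", length(phases))
    for (j in render_js) {
      frames[[j]] <- render_face(lms[[j]], params,
                                 seed = derive_seed(config$rng_seed, i, 100 + j),
                                 image_size = config$image_size,
                                 noise_sd = config$noise_sd)
    }
    id <- sprintf("%s%03d", if (grp == "patient") "P" else "C",
                  if (grp == "patient") i else i - config$n_patient)
    subjects[[i]] <- list(
      subject_id = id, group = grp, params = params, phases = phases,
      landmark_sequence = lms, frames = frames, covariates = covs
    )
    cov_rows[[i]] <- data.frame(subject_id = id, group = grp,
                                as.data.frame(covs), stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, cov_rows)
  rownames(manifest) <- NULL
  cohort <- structure(
    list(subjects = subjects, manifest = manifest, config = config),
    class = "face_cohort"
  )
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

#' @export
print.face_cohort <- function(x, ...) {
  cat(sprintf(
    "<face cohort> %d subjects (%d patient / %d control), %d frames each\n",
    length(x$subjects), x$config$n_patient, x$config$n_control,
    x$config$n_frames
  ))
  invisible(x)
}

#' Write a cohort to disk
#'
#' Writes `manifest.csv`, one landmark JSON per subject
#' (`<id>_landmarks.json`, ibug68-v1 schema), and any rendered frames as
#' PNGs under `<id>/frame_%04d.png`.
#'
#' @param cohort a `face_cohort`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  for (subj in cohort$subjects) {
    write_landmark_file(subj$landmark_sequence,
                        file.path(out_dir, paste0(subj$subject_id, "_landmarks.json")))
    rendered <- which(!vapply(subj$frames, is.null, logical(1)))
    if (length(rendered)) {
      sd <- file.path(out_dir, subj$subject_id)
      dir.create(sd, showWarnings = FALSE)
      for (j in rendered) {
        png::writePNG(subj$frames[[j]] / 255,
                      file.path(sd, sprintf("frame_%04d.png", j)))
      }
    }
  }
  invisible(out_dir)
}
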