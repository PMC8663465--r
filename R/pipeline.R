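# File formats and the one-shot pipeline runner: normalize -> key-frame
# selection -> geometric + texture features -> stratified split -> train
# (3 algorithms x 3 feature sets) -> ROC/Youden evaluation -> covariate
# correlation. All randomness derives from the cohort root seed.

#' Read a landmark sequence file (ibug68-v1 schema)
#'
#' Schema: `{"schema":"ibug68-v1","frames":[{"index":0,"points":[[x,y],...68]}]}`
#' with 0-based frame indices and 0-based pixel coordinates. Violations are
#' rejected with messages naming the offending frame.
#'
#' @param path path to a JSON file.
#' @return A list of 68 x 2 landmark matrices in frame-index order.
#' @export
read_landmark_file <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) {
                    fs_error("fs_schema_error", sprintf(
                      "cannot parse '%s' as JSON: %s", path, conditionMessage(e)
                    ))
                  })
  if (!identical(doc$schema, "ibug68-v1")) {
    fs_error("fs_schema_error", sprintf(
      "unknown landmark schema tag '%s' (expected 'ibug68-v1')",
      doc$schema %||% "<missing>"
    ))
  }
  if (is.null(doc$frames) || length(doc$frames) == 0L) {
    fs_error("fs_schema_error", "landmark file contains no frames")
  }
  idx <- vapply(doc$frames, function(f) as.integer(f$index %||% NA_integer_),
                integer(1))
  frames <- lapply(seq_along(doc$frames), function(i) {
    f <- doc$frames[[i]]
    pts <- f$points
    if (length(pts) != 68L) {
      fs_error("fs_schema_error", sprintf(
        "frame index %s has %d points (expected 68)",
        (f$index %||% (i - 1)), length(pts)
      ))
    }
    m <- do.call(rbind, lapply(pts, function(p) as.numeric(unlist(p))))
    if (ncol(m) != 2L || !all(is.finite(m))) {
      fs_error("fs_schema_error", sprintf(
        "frame index %s has malformed or non-finite coordinates", (f$index %||% (i - 1))
      ))
    }
    as_landmarks(m)
  })
  frames[order(idx)]
}

#' Write a landmark sequence file (ibug68-v1 schema)
#'
#' @param frames a list of 68 x 2 landmark matrices.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_landmark_file <- function(frames, path) {
  doc <- list(
    schema = "ibug68-v1",
    frames = lapply(seq_along(frames), function(i) {
      m <- as_landmarks(frames[[i]])
      list(index = i - 1L,
           points = lapply(seq_len(68), function(j) as.numeric(m[j, ])))
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' Expects `manifest.csv`, per-subject `<id>_landmarks.json`, and optional
#' `<id>/frame_%04d.png` frame directories. Ground-truth landmarks are
#' attached to loaded frames so the synthetic detector backend works.
#'
#' @param dir cohort directory.
#' @return A `face_cohort`-shaped list (without generator parameters).
#' @export
read_cohort <- function(dir) {
  mpath <- file.path(dir, "manifest.csv")
  if (!file.exists(mpath)) {
    fs_error("fs_schema_error", sprintf("no manifest.csv under '%s'", dir))
  }
  manifest <- utils::read.csv(mpath, stringsAsFactors = FALSE)
  subjects <- lapply(seq_len(nrow(manifest)), function(i) {
    id <- manifest$subject_id[i]
    lms <- read_landmark_file(file.path(dir, paste0(id, "_landmarks.json")))
    fdir <- file.path(dir, id)
    frames <- vector("list", length(lms))
    if (dir.exists(fdir)) {
      for (f in list.files(fdir, pattern = "^frame_\\d+\\.png$")) {
        j <- as.integer(sub("frame_(\\d+)\\.png", "\\1", f))
        img <- png::readPNG(file.path(fdir, f))
        if (length(dim(img)) == 3L) img <- img[, , 1]
        img <- img * 255
        attr(img, "landmarks") <- lms[[j]]
        frames[[j]] <- img
      }
    }
    cov <- as.list(manifest[i, setdiff(names(manifest), c("subject_id", "group"))])
    list(subject_id = id, group = manifest$group[i], params = NULL,
         landmark_sequence = lms, frames = frames, covariates = cov)
  })
  structure(list(subjects = subjects, manifest = manifest, config = NULL),
            class = "face_cohort")
}

# Render a missing frame of a generated subject on demand, reproducing the
# exact seed stream used by generate_cohort.
subject_frame <- function(cohort, i, j) {
  subj <- cohort$subjects[[i]]
  if (!is.null(subj$frames[[j]])) return(subj$frames[[j]])
  cfg <- cohort$config
  if (is.null(cfg)) {
    fs_error("fs_config_error", sprintf(
      "frame %d of subject %s is not available on disk", j, subj$subject_id
    ))
  }
  render_face(subj$landmark_sequence[[j]], subj$params,
              seed = derive_seed(cfg$rng_seed, i, 100 + j),
              image_size = cfg$image_size, noise_sd = cfg$noise_sd)
}

#' Extract geometric and texture features for every cohort subject
#'
#' Per subject: every frame's landmarks are normalized to the canonical
#' frame, neutral/apex key frames are selected on the normalized sequence,
#' the geometric feature vector is computed from the pair, and the texture
#' feature vector is computed on the normalized apex frame image.
#'
#' @param cohort a `face_cohort`.
#' @param texture compute texture features (needs frame images)?
#' @param hog,lbp_mouth,lbp_eyes descriptor parameters, see
#'   [texture_feature_vector()].
#' @return A list with `geom` (n x 6 matrix), `tex` (n x p matrix or NULL),
#'   `labels` (1 = patient), `subject_ids`, `key_frames` (data.frame),
#'   `tex_layout`.
#' @export
cohort_features <- function(cohort, texture = TRUE,
                            hog = hog_params(),
                            lbp_mouth = lbp_params(cell_grid = c(4, 8)),
                            lbp_eyes = lbp_params(cell_grid = c(4, 16))) {
  n <- length(cohort$subjects)
  geom <- matrix(NA_real_, n, 6)
  tex <- NULL
  tex_layout <- NULL
  kf <- data.frame(subject_id = character(n), neutral_index = integer(n),
                   apex_index = integer(n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    subj <- cohort$subjects[[i]]
    norm_lms <- lapply(subj$landmark_sequence,
                       function(lm) normalize_face(lm)$landmarks)
    pair <- select_key_frames(norm_lms)
    g <- geometric_feature_vector(pair)
    geom[i, ] <- g
    if (i == 1L) colnames(geom) <- names(g)
    kf[i, ] <- list(subj$subject_id, pair$neutral_index, pair$apex_index)
    if (texture) {
      img <- subject_frame(cohort, i, pair$apex_index)
      face <- normalize_face(subj$landmark_sequence[[pair$apex_index]], img)
      tf <- texture_feature_vector(face, hog = hog, lbp_mouth = lbp_mouth,
                                   lbp_eyes = lbp_eyes)
      if (is.null(tex)) {
        tex <- matrix(NA_real_, n, length(tf$vector))
        colnames(tex) <- names(tf$vector)
        tex_layout <- tf$layout
      }
      tex[i, ] <- tf$vector
    }
  }
  ids <- vapply(cohort$subjects, `[[`, character(1), "subject_id")
  rownames(geom) <- ids
  if (!is.null(tex)) rownames(tex) <- ids
  list(
    geom = geom, tex = tex,
    labels = as.integer(vapply(cohort$subjects, `[[`, character(1), "group") == "patient"),
    subject_ids = ids, key_frames = kf, tex_layout = tex_layout
  )
}

#' Run the full screening pipeline on a cohort
#'
#' Executes feature extraction, a stratified train/test split, training of
#' every requested algorithm on every requested feature set, ROC/Youden
#' evaluation on the test set, and patient-group correlation of each
#' model's scores with the clinical covariates.
#'
#' @param config a [cohort_config()] (used to generate a cohort), or pass
#'   `cohort` directly.
#' @param cohort optional pre-built `face_cohort`.
#' @param n_train training-set size (default 80, with the remainder the
#'   test set).
#' @param algos classifier algorithms to run.
#' @param feature_sets any of `"geometric"`, `"texture"`, `"combined"`.
#' @param out_dir optional directory for the report bundle
#'   (`report.json`, `roc_points.csv`, `correlations.csv`).
#' @return A list of class `report_bundle`: `metrics` (data.frame),
#'   `roc_points`, `correlations`, `scores`, `split`, `provenance`.
#' @export
run_pipeline <- function(config = cohort_config(), cohort = NULL,
                         n_train = 80,
                         algos = c("svm", "knn", "rf"),
                         feature_sets = c("geometric", "texture", "combined"),
                         out_dir = NULL) {
  if (is.null(cohort)) cohort <- generate_cohort(config, render = "key")
  root_seed <- if (!is.null(cohort$config)) cohort$config$rng_seed else 1L
  feats <- cohort_features(cohort, texture = any(feature_sets != "geometric"))
  n <- length(feats$labels)
  split <- split_dataset(feats$labels, n_train, n - n_train,
                         seed = derive_seed(root_seed, 9001))

  fset_matrix <- function(fs) {
    switch(fs,
      geometric = feats$geom,
      texture = feats$tex,
      combined = cbind(feats$geom, feats$tex)
    )
  }

  metrics <- list()
  rocs <- list()
  cors <- list()
  scores <- list()
  pat_rows <- which(feats$labels == 1L)
  covs <- cohort$manifest[pat_rows,
                          setdiff(names(cohort$manifest), c("subject_id", "group")),
                          drop = FALSE]
  k <- 1L
  for (fs in feature_sets) {
    raw <- fset_matrix(fs)
    stats_fit <- fit_standardization(raw[split$train_idx, , drop = FALSE])
    x <- apply_standardization(raw, stats_fit)
    for (algo in algos) {
      model <- train_classifier(x[split$train_idx, , drop = FALSE],
                                feats$labels[split$train_idx], algo = algo,
                                seed = derive_seed(root_seed, 9100, k))
      ev <- evaluate_model(model, x[split$test_idx, , drop = FALSE],
                           feats$labels[split$test_idx])
      m <- ev$metrics
      metrics[[k]] <- data.frame(
        algorithm = algo, feature_set = fs,
        auc = ev$roc$auc, youden_j = ev$roc$youden_j,
        threshold = ev$roc$youden_threshold,
        accuracy = m$accuracy, precision = m$precision,
        recall = m$recall, f_measure = m$f_measure
      )
      rocs[[k]] <- data.frame(algorithm = algo, feature_set = fs,
                              ev$roc$points)
      all_scores <- score_classifier(model, x)
      scores[[k]] <- data.frame(
        subject_id = feats$subject_ids, algorithm = algo, feature_set = fs,
        score = all_scores,
        in_test = seq_len(n) %in% split$test_idx
      )
      ct <- correlate_with_covariates(all_scores[pat_rows], covs)
      cors[[k]] <- data.frame(algorithm = algo, feature_set = fs, ct)
      k <- k + 1L
    }
  }
  metrics <- do.call(rbind, metrics)
  rownames(metrics) <- NULL
  cfg_json <- if (!is.null(cohort$config)) {
    as.character(jsonlite::toJSON(unclass(cohort$config), auto_unbox = TRUE,
                                  digits = I(17)))
  } else {
    "external-cohort"
  }
  tf <- tempfile()
  writeLines(cfg_json, tf)
  bundle <- structure(
    list(
      metrics = metrics,
      roc_points = do.call(rbind, rocs),
      correlations = do.call(rbind, cors),
      scores = do.call(rbind, scores),
      split = split,
      provenance = list(
        package = "facescreen",
        version = as.character(utils::packageVersion("facescreen")),
        seed = root_seed,
        config = cfg_json,
        config_hash = unname(tools::md5sum(tf))
      )
    ),
    class = "report_bundle"
  )
  unlink(tf)
  if (!is.null(out_dir)) write_report(bundle, out_dir)
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report bundle>\n")
  print(x$metrics, digits = 4)
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Writes `report.json` (metrics + provenance), `roc_points.csv` and
#' `correlations.csv`. Output is deterministic: two runs with the same
#' configuration and seed produce byte-identical files.
#'
#' @param bundle a `report_bundle`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(metrics = bundle$metrics, provenance = bundle$provenance),
    file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = I(17), na = "null"
  )
  utils::write.csv(bundle$roc_points, file.path(out_dir, "roc_points.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$correlations, file.path(out_dir, "correlations.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}
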