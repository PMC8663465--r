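# Landmark schema, face/landmark detection interface, and similarity-based
# normalization of faces into a canonical 256x256 frame.
#
# Conventions used throughout the package:
#   * Images are numeric matrices, nrow = height, ncol = width, grayscale
#     intensities in [0, 255]; origin top-left, x rightward, y downward.
#     Pixel (x, y) in 0-based coordinates lives at img[y + 1, x + 1].
#   * Landmark sets are 68 x 2 matrices (columns "x", "y") in continuous
#     pixel units with the same 0-based, y-down convention, indexed by the
#     iBUG-68 scheme: jaw 0-16, brows 17-26, nose 27-35, right eye 36-41,
#     left eye 42-47, outer lip 48-59, inner lip 60-67. "Right eye" is the
#     subject's right, which appears on the image left (smaller x); lip
#     corner p48 is the image-left corner, p54 the image-right corner.
#     R row i holds 0-based landmark i - 1.

# Canonical frame constants. Not tunable per run: eye anchors at 35%/65% of
# the frame width and 40% of its height give an inter-ocular distance of
# 76.8 px on a 256 px canvas.
CANONICAL_SIZE <- 256
CANONICAL_RIGHT_EYE <- c(x = 89.6, y = 102.4)
CANONICAL_LEFT_EYE <- c(x = 166.4, y = 102.4)

#' Validate and coerce a 68-point landmark set
#'
#' @param x a 68 x 2 numeric matrix (or coercible object) of landmark
#'   coordinates, columns x then y, iBUG-68 row order (0-based index i in
#'   row i + 1).
#' @return A validated 68 x 2 matrix with columns named `x`, `y`.
#' @export
as_landmarks <- function(x) {
  m <- as.matrix(x)
  if (nrow(m) != 68L || ncol(m) != 2L) {
    fs_error("fs_schema_error", sprintf(
      "landmark set must be 68 x 2, got %d x %d", nrow(m), ncol(m)
    ))
  }
  if (!all(is.finite(m))) {
    fs_error("fs_schema_error", "landmark coordinates must be finite")
  }
  storage.mode(m) <- "double"
  colnames(m) <- c("x", "y")
  rownames(m) <- NULL
  m
}

# Extract landmark i (0-based iBUG index) as a length-2 (x, y) vector.
lm_pt <- function(landmarks, i) as.numeric(landmarks[i + 1L, ])

#' Eye centers of a landmark set
#'
#' Right-eye center is the mean of points 36-41, left-eye center the mean of
#' points 42-47 (0-based iBUG indices).
#'
#' @param landmarks a 68 x 2 landmark matrix.
#' @return A list with numeric `right` and `left` (x, y) centers.
#' @export
eye_centers <- function(landmarks) {
  landmarks <- as_landmarks(landmarks)
  list(
    right = colMeans(landmarks[37:42, , drop = FALSE]),
    left = colMeans(landmarks[43:48, , drop = FALSE])
  )
}

#' Similarity transforms
#'
#' A 4-degree-of-freedom similarity transform (uniform scale, rotation,
#' translation) represented internally as the complex map z -> a z + b on
#' x + iy. Angles are degrees, y-down image convention (a positive rotation
#' turns x toward y, i.e. clockwise on screen).
#'
#' @param scale positive scale factor.
#' @param rotation rotation in degrees.
#' @param translation numeric (tx, ty) in pixels.
#' @return An object of class `similarity_transform` with fields `scale`,
#'   `rotation`, `translation`.
#' @export
similarity_transform <- function(scale = 1, rotation = 0, translation = c(0, 0)) {
  if (!is_scalar(scale) || scale <= 0) {
    fs_error("fs_degenerate_geometry", "scale must be a positive scalar")
  }
  a <- scale * exp(1i * deg2rad(rotation))
  b <- complex(real = translation[1], imaginary = translation[2])
  new_similarity(a, b)
}

new_similarity <- function(a, b) {
  structure(
    list(
      a = a, b = b,
      scale = Mod(a),
      rotation = rad2deg(Arg(a)),
      translation = c(Re(b), Im(b))
    ),
    class = "similarity_transform"
  )
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf(
    "<similarity transform> scale %.6g, rotation %.6g deg, translation (%.6g, %.6g)\n",
    x$scale, x$rotation, x$translation[1], x$translation[2]
  ))
  invisible(x)
}

#' Apply a similarity transform to points
#'
#' @param transform a `similarity_transform`.
#' @param points an n x 2 matrix of (x, y) points.
#' @return The transformed n x 2 matrix.
#' @export
transform_points <- function(transform, points) {
  pts <- as.matrix(points)
  z <- complex(real = pts[, 1], imaginary = pts[, 2]) * transform$a + transform$b
  out <- cbind(x = Re(z), y = Im(z))
  out
}

#' Invert a similarity transform
#'
#' @param transform a `similarity_transform`.
#' @return The inverse `similarity_transform`.
#' @export
invert_transform <- function(transform) {
  new_similarity(1 / transform$a, -transform$b / transform$a)
}

#' Compose two similarity transforms
#'
#' Returns the transform equivalent to applying `first`, then `second`.
#'
#' @param second,first `similarity_transform` objects.
#' @return A `similarity_transform`.
#' @export
compose_transforms <- function(second, first) {
  new_similarity(second$a * first$a, second$a * first$b + second$b)
}

#' Estimate the normalization transform for a landmark set
#'
#' Computes the similarity transform that maps the face into the canonical
#' 256 x 256 frame. The default two-point method maps the right-eye center
#' exactly to (89.6, 102.4) and the left-eye center exactly to
#' (166.4, 102.4); the closed form is exact, so the residual at the anchors
#' is at machine precision. The least-squares method aligns all 68 points to
#' a supplied canonical template in the least-squares sense (orthogonal
#' Procrustes restricted to similarity).
#'
#' @param landmarks a 68 x 2 landmark matrix in raw image coordinates.
#' @param method `"eyes"` (default, exact two-point alignment) or
#'   `"procrustes"` (least squares over all 68 points).
#' @param template canonical 68 x 2 target layout, required for
#'   `method = "procrustes"`.
#' @return A `similarity_transform`.
#' @export
estimate_normalization_transform <- function(landmarks,
                                             method = c("eyes", "procrustes"),
                                             template = NULL) {
  landmarks <- as_landmarks(landmarks)
  method <- match.arg(method)
  if (method == "eyes") {
    ec <- eye_centers(landmarks)
    e1 <- complex(real = ec$right[1], imaginary = ec$right[2])
    e2 <- complex(real = ec$left[1], imaginary = ec$left[2])
    if (Mod(e2 - e1) < 1e-9) {
      fs_error("fs_degenerate_geometry", "eye centers coincide; cannot align")
    }
    t1 <- complex(real = CANONICAL_RIGHT_EYE[1], imaginary = CANONICAL_RIGHT_EYE[2])
    t2 <- complex(real = CANONICAL_LEFT_EYE[1], imaginary = CANONICAL_LEFT_EYE[2])
    a <- (t2 - t1) / (e2 - e1)
    b <- t1 - a * e1
    new_similarity(a, b)
  } else {
    if (is.null(template)) {
      fs_error("fs_config_error", "procrustes method requires a canonical template")
    }
    template <- as_landmarks(template)
    zs <- complex(real = landmarks[, 1], imaginary = landmarks[, 2])
    zt <- complex(real = template[, 1], imaginary = template[, 2])
    ms <- mean(zs)
    mt <- mean(zt)
    zs_c <- zs - ms
    denom <- sum(Mod(zs_c)^2)
    if (denom < 1e-12) {
      fs_error("fs_degenerate_geometry", "all landmarks coincide; cannot align")
    }
    a <- sum(Conj(zs_c) * (zt - mt)) / denom
    b <- mt - a * ms
    new_similarity(a, b)
  }
}

#' Detect the face bounding box in an image
#'
#' Pluggable contract: synthetic frames produced by [render_face()] carry
#' their ground-truth head box, which is returned exactly. For plain images
#' a simple intensity-based fallback locates pixels that deviate from the
#' border background; an external pretrained detector can be wrapped by
#' passing a function `backend(image)` returning a box.
#'
#' @param image a grayscale image matrix.
#' @param backend `"auto"` (ground truth when present, else intensity
#'   fallback) or a function taking the image and returning a box.
#' @return A list `(x, y, w, h)` in 0-based pixel coordinates, fully inside
#'   the image.
#' @export
detect_face_box <- function(image, backend = "auto") {
  if (is.function(backend)) {
    return(validate_box(backend(image), image))
  }
  if (!is.matrix(image) || length(image) == 0L) {
    fs_error("fs_config_error", "image must be a nonempty matrix")
  }
  gt <- attr(image, "face_box")
  if (!is.null(gt)) {
    return(validate_box(gt, image))
  }
  border <- c(image[1, ], image[nrow(image), ], image[, 1], image[, ncol(image)])
  bg <- stats::median(border)
  mask <- abs(image - bg) > 10
  if (!any(mask)) {
    fs_error("fs_no_face", "no face found in image")
  }
  rows <- which(rowSums(mask) > 0)
  cols <- which(colSums(mask) > 0)
  validate_box(list(
    x = min(cols) - 1L, y = min(rows) - 1L,
    w = max(cols) - min(cols) + 1L, h = max(rows) - min(rows) + 1L
  ), image)
}

validate_box <- function(box, image) {
  box <- box[c("x", "y", "w", "h")]
  if (any(vapply(box, function(v) !is_scalar(v), logical(1)))) {
    fs_error("fs_schema_error", "bounding box must have scalar x, y, w, h")
  }
  if (box$w <= 0 || box$h <= 0 ||
      box$x < 0 || box$y < 0 ||
      box$x + box$w > ncol(image) || box$y + box$h > nrow(image)) {
    fs_error("fs_schema_error", "bounding box outside image bounds")
  }
  box
}

#' Locate the 68 facial landmarks within a face box
#'
#' The synthetic backend returns the ground-truth landmark set embedded in
#' frames from [render_face()]; an external pretrained landmark model can be
#' wrapped by passing a function `backend(image, box)` returning a 68 x 2
#' matrix. Points are checked to lie inside the box expanded by a 10%
#' margin.
#'
#' @param image a grayscale image matrix.
#' @param box bounding box from [detect_face_box()].
#' @param backend `"synthetic"` or a function `(image, box) -> landmarks`.
#' @return A 68 x 2 landmark matrix.
#' @export
locate_landmarks <- function(image, box, backend = "synthetic") {
  box <- validate_box(box, image)
  lm <- if (is.function(backend)) {
    backend(image, box)
  } else if (identical(backend, "synthetic")) {
    gt <- attr(image, "landmarks")
    if (is.null(gt)) {
      fs_error("fs_config_error",
               "synthetic landmark backend requires a frame with embedded ground truth")
    }
    gt
  } else {
    fs_error("fs_config_error", sprintf("unknown landmark backend '%s'", backend))
  }
  lm <- as_landmarks(lm)
  mx <- 0.1 * box$w
  my <- 0.1 * box$h
  inside <- lm[, 1] >= box$x - mx & lm[, 1] <= box$x + box$w + mx &
    lm[, 2] >= box$y - my & lm[, 2] <= box$y + box$h + my
  if (!all(inside)) {
    fs_error("fs_schema_error", sprintf(
      "%d landmark(s) fall outside the expanded face box", sum(!inside)
    ))
  }
  lm
}

# Inverse-mapping bilinear warp of `image` under `transform` into a square
# canonical canvas. Out-of-frame samples are 0. Coordinates are 0-based
# pixel centers on both sides.
warp_image <- function(image, transform, out_size = CANONICAL_SIZE) {
  inv <- invert_transform(transform)
  xs <- rep(seq_len(out_size) - 1, each = out_size)
  ys <- rep(seq_len(out_size) - 1, times = out_size)
  src <- transform_points(inv, cbind(xs, ys))
  v <- bilinear_sample(image, src[, 1], src[, 2])
  matrix(v, nrow = out_size, ncol = out_size)
}

#' Normalize a face into the canonical frame
#'
#' Estimates the similarity transform from the landmarks (see
#' [estimate_normalization_transform()]), maps the landmarks by it, and, if
#' an image is supplied, resamples the image into the canonical 256 x 256
#' frame with bilinear interpolation (out-of-frame pixels set to 0).
#'
#' @param landmarks a 68 x 2 landmark matrix in raw coordinates.
#' @param image optional grayscale image matrix in the same raw frame.
#' @param method transform estimation method, see
#'   [estimate_normalization_transform()].
#' @param template optional template for the procrustes method.
#' @return An object of class `normalized_face`: a list with `image`
#'   (canonical matrix or `NULL`), `landmarks` (canonical coordinates) and
#'   `transform`.
#' @export
normalize_face <- function(landmarks, image = NULL, method = "eyes",
                           template = NULL) {
  landmarks <- as_landmarks(landmarks)
  tf <- estimate_normalization_transform(landmarks, method = method,
                                         template = template)
  out_img <- if (!is.null(image)) warp_image(image, tf) else NULL
  structure(
    list(
      image = out_img,
      landmarks = as_landmarks(transform_points(tf, landmarks)),
      transform = tf
    ),
    class = "normalized_face"
  )
}

#' @export
print.normalized_face <- function(x, ...) {
  cat(sprintf(
    "<normalized face> %s image, eyes at (%.1f, %.1f)/(%.1f, %.1f)\n",
    if (is.null(x$image)) "no" else paste(dim(x$image), collapse = "x"),
    eye_centers(x$landmarks)$right[1], eye_centers(x$landmarks)$right[2],
    eye_centers(x$landmarks)$left[1], eye_centers(x$landmarks)$left[2]
  ))
  invisible(x)
}
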